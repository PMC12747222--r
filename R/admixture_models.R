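#' Matrix of f4 statistics with jackknife covariance
#'
#' Builds the qpWave/qpAdm substrate: the (nL-1) x (nR-1) matrix
#' `X[i-1, j-1] = f4(L1, Li; R1, Rj)` together with delete-one-block
#' replicates and the weighted-jackknife covariance of `vec(X)`.
#'
#' @param counts A [count_table()].
#' @param L Left (source-side) population labels, `nL >= 2`; `L[1]` is the
#'   base.
#' @param R Right (reference-side) population labels, `nR >= 2`; `R[1]` is
#'   the base.
#' @param allsnps Per-statistic maximal SNP sets (default, mirroring sparse
#'   capture practice); otherwise every statistic is restricted to SNPs at
#'   which all populations of `L` and `R` are observed.
#' @return Object of class `f4_matrix`: `X`, `est` (vec, column-major),
#'   `loo` (blocks x entries delete-one estimates), `Q` (covariance of
#'   `vec(X)`), `weights` (blocks x entries SNP counts), `L`, `R`, `n_snps`.
#' @export
f4_matrix <- function(counts, L, R, allsnps = TRUE) {
  stop_if_not(length(L) >= 2 && length(R) >= 2, "need nL >= 2 and nR >= 2")
  stop_if_not(!anyDuplicated(c(L, R)), "L and R labels must be distinct")
  a <- length(L) - 1L; b <- length(R) - 1L
  pl <- lapply(c(L, R), function(g) freq_of(counts, g))
  names(pl) <- c(L, R)
  inter <- if (!allsnps) Reduce("&", lapply(pl, function(f) f$n > 0)) else NULL
  K <- a * b
  n_snp <- nrow(counts$x)
  num <- matrix(0, n_snp, K)
  use <- matrix(FALSE, n_snp, K)
  k <- 0L
  for (j in seq_len(b)) for (i in seq_len(a)) {
    k <- k + 1L
    A <- pl[[L[1]]]; Bp <- pl[[L[i + 1]]]; C <- pl[[R[1]]]; D <- pl[[R[j + 1]]]
    u <- A$n > 0 & Bp$n > 0 & C$n > 0 & D$n > 0
    if (!is.null(inter)) u <- u & inter
    if (!any(u)) {
      stop(sprintf("no usable SNPs for f4(%s,%s;%s,%s)",
                   L[1], L[i + 1], R[1], R[j + 1]), call. = FALSE)
    }
    v <- (A$p - Bp$p) * (C$p - D$p)
    v[!u | !is.finite(v)] <- 0
    num[, k] <- v
    use[, k] <- u & is.finite((A$p - Bp$p) * (C$p - D$p))
  }
  bl <- counts$block
  sums <- rowsum(num * use, bl)
  w <- rowsum(use + 0, bl)
  g <- nrow(sums)
  stop_if_not(g >= 2, "need at least 2 blocks")
  tot <- colSums(sums); W <- colSums(w)
  est <- tot / W
  loo <- sweep(-sums, 2, tot, "+") / sweep(-w, 2, W, "+")
  h <- sweep(1 / w, 2, W, "*")                    # blocks x entries
  tau <- h * matrix(est, g, K, byrow = TRUE) - (h - 1) * loo
  jk <- colSums((1 - sweep(w, 2, W, "/")) * loo)
  jk_est <- g * est - jk
  dev <- (tau - matrix(jk_est, g, K, byrow = TRUE)) / sqrt(pmax(h - 1, 1e-12))
  dev[!is.finite(dev)] <- 0
  Q <- crossprod(dev) / g
  structure(list(X = matrix(est, a, b), est = est, loo = loo, Q = Q,
                 weights = w, L = L, R = R, n_snps = W, n_blocks = g),
            class = "f4_matrix")
}

# Covariance-safe inverse with logged ridge regularization.
safe_inverse <- function(Q) {
  K <- nrow(Q)
  kappa_ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  if (min(kappa_ev) <= 0 || max(kappa_ev) / max(min(kappa_ev), 1e-300) > 1e12) {
    ridge <- 1e-6 * sum(diag(Q)) / K
    message(sprintf("covariance ill-conditioned; adding ridge %.3g", ridge))
    Q <- Q + diag(ridge, K)
  }
  solve(Q)
}

#' qpWave rank test
#'
#' Tests whether the f4 matrix `X` is consistent with rank `r`, i.e. with
#' `r + 1` independent streams of ancestry relating the left and right sets.
#' The best rank-r approximation `X ~ A B'` is fitted by alternating
#' generalized least squares under the jackknife covariance; the minimized
#' quadratic form is referred to a chi-square with
#' `(nL - 1 - r)(nR - 1 - r)` degrees of freedom.
#'
#' @param fm An [f4_matrix()].
#' @param r Tested rank, `0 <= r < min(nL-1, nR-1)`.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum alternating iterations.
#' @return List with `r`, `statistic`, `dof`, `p`, and the fitted `E`.
#' @export
qpwave_rank_test <- function(fm, r, tol = 1e-9, max_iter = 500) {
  stopifnot(inherits(fm, "f4_matrix"))
  a <- nrow(fm$X); b <- ncol(fm$X)
  stop_if_not(r >= 0 && r < min(a, b), "need 0 <= r < min(nL-1, nR-1)")
  dof <- (a - r) * (b - r)
  x <- fm$est
  Qi <- safe_inverse(fm$Q)
  if (r == 0) {
    stat <- drop(t(x) %*% Qi %*% x)
    return(list(r = 0L, statistic = stat, dof = dof,
                p = pchisq(stat, dof, lower.tail = FALSE),
                E = matrix(0, a, b)))
  }
  sv <- svd(fm$X)
  A <- sv$u[, seq_len(r), drop = FALSE] %*% diag(sqrt(sv$d[seq_len(r)]), r)
  B <- sv$v[, seq_len(r), drop = FALSE] %*% diag(sqrt(sv$d[seq_len(r)]), r)
  obj <- function(E) { d <- x - as.vector(E); drop(t(d) %*% Qi %*% d) }
  gls <- function(M) {
    # minimize (x - M t)' Qi (x - M t) over t
    MtQ <- crossprod(M, Qi)
    solve(MtQ %*% M, MtQ %*% x)
  }
  last <- obj(A %*% t(B))
  for (it in seq_len(max_iter)) {
    MA <- B %x% diag(1, a)                 # vec(A B') = (B (x) I) vec(A)
    A <- matrix(gls(MA), a, r)
    MB <- diag(1, b) %x% A                 # vec(A B') = (I (x) A) vec(B')
    B <- t(matrix(gls(MB), r, b))
    cur <- obj(A %*% t(B))
    if (abs(last - cur) <= tol * max(1e-30, abs(last))) { last <- cur; break }
    last <- cur
  }
  stat <- max(last, 0)
  list(r = as.integer(r), statistic = stat, dof = dof,
       p = pchisq(stat, dof, lower.tail = FALSE), E = A %*% t(B))
}

# GLS objective for admixture weights w (sum 1): residual r_j = sum_i w_i X_ij,
# covariance C(w) = (I (x) w)' Q (I (x) w).
qpadm_objective <- function(w, Xl, Q) {
  b <- ncol(Xl)
  r <- drop(crossprod(Xl, w))
  Wm <- diag(1, b) %x% matrix(w, ncol = 1)
  C <- crossprod(Wm, Q %*% Wm)
  Ci <- tryCatch(safe_inverse(C), error = function(e) NULL)
  if (is.null(Ci)) return(1e12)
  drop(t(r) %*% Ci %*% r)
}

solve_weights <- function(Xl, Q, init = NULL) {
  k <- nrow(Xl)
  if (k == 1) return(1)
  if (k == 2) {
    op <- optimize(function(w1) qpadm_objective(c(w1, 1 - w1), Xl, Q),
                   c(-2, 3), tol = 1e-10)
    return(c(op$minimum, 1 - op$minimum))
  }
  par0 <- init %||% rep(1 / k, k - 1)
  fn <- function(par) {
    w <- c(par, 1 - sum(par))
    qpadm_objective(w, Xl, Q)
  }
  opt <- suppressMessages(optim(par0, fn, method = "BFGS",
                                control = list(maxit = 500, reltol = 1e-12)))
  c(opt$par, 1 - sum(opt$par))
}

#' qpAdm admixture-weight estimation
#'
#' Models a target population T as a mixture of `sources` with respect to a
#' set of distal `refs`. Weights (constrained to sum to 1, possibly negative)
#' minimize the covariance-weighted norm of
#' \eqn{\sum_i w_i f_4(T, L_i; R_1, R_j)}; standard errors come from
#' re-solving the weights on each delete-one-block replicate; the model
#' p-value is the [qpwave_rank_test()] at rank `|L| - 1` on the f4 matrix of
#' `(T, L; R)`, so a small p means T cannot be written as a mixture of the
#' sources relative to these references.
#'
#' @param counts A [count_table()].
#' @param target Target population label.
#' @param sources Character vector of source labels (>= 1).
#' @param refs Character vector of reference labels (>= length(sources) + 1).
#' @param allsnps Per-statistic maximal SNP sets (default TRUE).
#' @return Object of class `qpadm_fit`: `weights`, `se`, `p`, `feasible`
#'   (all weights in `[0, 1]`), `rank_test`, `n_snps`.
#' @export
qpadm_fit <- function(counts, target, sources, refs, allsnps = TRUE) {
  k <- length(sources)
  stop_if_not(k >= 1, "need at least one source")
  stop_if_not(length(refs) >= k + 1, "need |refs| >= |sources| + 1")
  fm <- f4_matrix(counts, L = c(target, sources), R = refs, allsnps = allsnps)
  a <- k; b <- length(refs) - 1L
  Xl <- matrix(fm$est, a, b)
  if (k > 1) {
    cc <- tryCatch(qr(Xl)$rank, error = function(e) k)
    if (cc < min(k, b)) stop("collinear sources: f4 system is rank-deficient", call. = FALSE)
  }
  w_hat <- solve_weights(Xl, fm$Q)
  rt <- qpwave_rank_test(fm, r = k - 1)
  # delete-one-block replicate weights
  g <- fm$n_blocks
  reps <- matrix(NA_real_, g, k)
  for (j in seq_len(g)) {
    Xj <- matrix(fm$loo[j, ], a, b)
    reps[j, ] <- solve_weights(Xj, fm$Q, init = w_hat[-k])
  }
  bw <- rowSums(fm$weights)
  W <- sum(bw); h <- W / bw
  se <- sqrt(vapply(seq_len(k), function(i) {
    loo <- reps[, i]
    tau <- h * w_hat[i] - (h - 1) * loo
    jk <- g * w_hat[i] - sum((1 - bw / W) * loo)
    sum((tau - jk)^2 / (h - 1)) / g
  }, numeric(1)))
  structure(list(target = target, sources = sources, refs = refs,
                 weights = setNames(w_hat, sources), se = setNames(se, sources),
                 p = rt$p, rank_test = rt,
                 feasible = all(w_hat >= 0 & w_hat <= 1),
                 n_snps = round(mean(fm$n_snps)), n_blocks = g),
            class = "qpadm_fit")
}

#' @export
print.qpadm_fit <- function(x, ...) {
  cat(sprintf("qpAdm: %s ~ %s (p = %.3g, %s)\n", x$target,
              paste(x$sources, collapse = " + "), x$p,
              if (x$feasible) "feasible" else "INFEASIBLE"))
  for (i in seq_along(x$weights)) {
    cat(sprintf("  %-20s %6.3f +/- %.3f\n", x$sources[i], x$weights[i], x$se[i]))
  }
  invisible(x)
}

#' Rotating qpAdm model assessment
#'
#' Cyclically assesses admixture models for a target: every subset of the
#' candidate `pool` of size up to `max_sources` is tried as the source set,
#' with the remaining candidates moved to the reference side alongside the
#' fixed distal references. A model passes if its rank-test p-value is at
#' least `p_floor` and its weights are feasible. Single-source models are
#' tried first; complexity is added only when every simpler model fails.
#'
#' @param counts A [count_table()].
#' @param target Target label.
#' @param pool Candidate source labels (rotated between L and R).
#' @param fixed_refs Distal references always kept on the right side.
#' @param max_sources Largest source-set size to consider.
#' @param p_floor Passing threshold on the rank-test p-value (default 0.05).
#' @param allsnps Per-statistic maximal SNP sets.
#' @return Data frame of evaluated models ranked by p-value, with columns
#'   `sources`, `p`, `feasible`, `pass`, `weights` (list column), `se`
#'   (list column), `n_sources`.
#' @export
rotate_models <- function(counts, target, pool, fixed_refs, max_sources = 2,
                          p_floor = 0.05, allsnps = TRUE) {
  stop_if_not(length(pool) >= 1, "pool must be non-empty")
  rows <- list()
  for (size in seq_len(min(max_sources, length(pool)))) {
    subsets <- combn(pool, size, simplify = FALSE)
    for (L in subsets) {
      R <- c(fixed_refs, setdiff(pool, L))
      if (length(R) < size + 1) next
      fit <- tryCatch(qpadm_fit(counts, target, L, R, allsnps = allsnps),
                      error = function(e) NULL)
      if (is.null(fit)) next
      rows[[length(rows) + 1]] <-
        data.frame(sources = paste(L, collapse = "+"), n_sources = size,
                   p = fit$p, feasible = fit$feasible,
                   pass = fit$p >= p_floor && fit$feasible,
                   stringsAsFactors = FALSE)
      rows[[length(rows)]]$weights <- list(fit$weights)
      rows[[length(rows)]]$se <- list(fit$se)
    }
    done <- do.call(rbind, rows)
    if (any(done$pass[done$n_sources == size])) break
  }
  out <- do.call(rbind, rows)
  out[order(-out$pass, -out$p), , drop = FALSE]
}

#' Inverse-variance meta-analysis of admixture proportions
#'
#' Pools the weight of a shared source of interest across passing qpAdm
#' models: pooled = sum(w/se^2) / sum(1/se^2), pooled SE = sqrt(1/sum(1/se^2)).
#'
#' @param fits List of `qpadm_fit` objects (or a data frame from
#'   [rotate_models()]).
#' @param source Label of the source of interest present in every fit.
#' @param require_pass Only use feasible fits (and `pass == TRUE` rows when a
#'   data frame is given).
#' @param p_floor Passing threshold when filtering `qpadm_fit` lists.
#' @return List with `estimate`, `se`, `n_models`.
#' @export
meta_weights <- function(fits, source, require_pass = TRUE, p_floor = 0.05) {
  if (is.data.frame(fits)) {
    keep <- if (require_pass) fits$pass else rep(TRUE, nrow(fits))
    w <- vapply(fits$weights[keep], function(x) unname(x[source]), numeric(1))
    s <- vapply(fits$se[keep], function(x) unname(x[source]), numeric(1))
  } else {
    keep <- vapply(fits, function(f) (!require_pass || (f$feasible && f$p >= p_floor)) &&
                     source %in% f$sources, logical(1))
    w <- vapply(fits[keep], function(f) unname(f$weights[source]), numeric(1))
    s <- vapply(fits[keep], function(f) unname(f$se[source]), numeric(1))
  }
  ok <- is.finite(w) & is.finite(s) & s > 0
  stop_if_not(any(ok), "no usable fits: all infeasible, failing, or zero-variance")
  w <- w[ok]; s <- s[ok]
  prec <- 1 / s^2
  list(estimate = sum(w * prec) / sum(prec), se = sqrt(1 / sum(prec)),
       n_models = length(w))
}
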