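---
title: "Models and methods behind driftkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind driftkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

driftkit implements the allele-frequency inference stack used for
SNP-capture ancient DNA. This vignette records the models, the estimator
conventions, the tunable parameters with their defaults, what the
synthetic-data generators do and do not emulate, and the numerical choices
made where the design was genuinely open. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## Genotype substrate and the block jackknife

All f-statistics run on per-(group, SNP) derived-allele counts $(x, n)$,
with frequency $\hat p = x/n$ and no shrinkage. Pseudo-haploid individuals
contribute one chromosome per covered site ($n$ counts observed
chromosomes, so a group genotyped pseudo-haploid at depth-1 sites behaves
as a set of haploid lineages); $n = 0$ encodes a group-missing site.
EIGENSTRAT input/output follows the text dialect: the `.geno` code is the
count of the `.snp` file's first allele, pseudo-haploid samples are written
as diploid homozygotes (0/2/9), and columns observed only as 0/2/9 are
auto-flagged pseudo-haploid on read. Physical positions are 1-based and no
strand flipping is ever performed; capture data are assumed
pre-harmonized.

Uncertainty comes from a weighted delete-one block jackknife over
contiguous blocks. Blocks default to 0.05 Morgan when genetic positions are
available and 5 Mb otherwise (the ADMIXTOOLS convention; the block length
is a free parameter of `assign_blocks()`), and chromosome boundaries always
break blocks. With per-block weights $m_j$ (used-SNP counts),
$h_j = W/m_j$, full-data estimate $\hat\theta$ and leave-one-out estimates
$\hat\theta_{-j}$, the variance uses the unequal-block pseudovalue form
$\tau_j = h_j\hat\theta - (h_j-1)\hat\theta_{-j}$,
$\mathrm{Var} = g^{-1}\sum_j (\tau_j - \theta_J)^2/(h_j-1)$; with equal
weights this is exactly the classic delete-one jackknife. Reported
estimates are the full-data statistics; the bias-corrected jackknife mean
is also returned. With 50 blocks the Z-score is effectively a $t_{49}$
variable, so the nominal $|Z|>1.96$ exceedance under a true null is 5.6%,
not 5.0% — the calibration experiments account for this.

## f-statistics

Per SNP, using only SNPs where the populations involved are observed:

- $f_2$: $(\hat p_A-\hat p_B)^2 - h_A/n_A - h_B/n_B$ with
  $h/n = \hat p(1-\hat p)/(n-1)$. The correction requires $n \ge 2$; groups
  observed as a single chromosome are left uncorrected with a warning
  (outgroup-mode practice). On exact frequencies pass
  `correction = FALSE`.
- $f_3(A;B,C)$: $(\hat p_A-\hat p_B)(\hat p_A-\hat p_C) - h_A/n_A$; in
  outgroup mode the correction is omitted, since only relative magnitudes
  across pairs matter there. Which correction the original outgroup-mode
  runs used is not fully documented upstream, so both behaviors are
  exposed.
- $f_4$: $(\hat p_A-\hat p_B)(\hat p_C-\hat p_D)$, no correction needed.
  `allsnps = TRUE` (default) gives each statistic its own maximal SNP set;
  `FALSE` restricts to the intersection over a population set. Site
  missingness for `filter_sites()` is measured at the group level
  (fraction of groups with $n=0$), matching the extract-style bookkeeping;
  individual-level filtering can be had by pre-subsetting.
- Hudson Fst: ratio of averages, numerator as $f_2$'s corrected form,
  denominator $\hat p_1(1-\hat p_2)+\hat p_2(1-\hat p_1)$, jackknifed as a
  ratio. The `inbreed` mode treats samples as haploid lineages (the
  pseudo-haploid-safe convention) and requires $n \ge 2$ chromosomes per
  group per SNP. A floor of 5000 usable SNPs per pair is enforced by
  default. Note that literally identical count tables give
  $-1/(n-1)$, not 0: the correct null ("no differentiation") is two
  independent samples of one population.
- Benjamini–Yekutieli: two-sided $p = 2(1-\Phi(|Z|))$, step-up with
  $c(m)=\sum_k 1/k$, significance at FDR < 0.05, and the signed adjusted
  score $Z_{BY}=\mathrm{sign}(Z)\Phi^{-1}(1-p_{adj}/2)$. The implementation
  is cross-checked against `p.adjust(..., "BY")` in the tests.

## qpWave and qpAdm

For left set $L$ and right set $R$, `f4_matrix()` builds
$X_{ij}=f_4(L_1,L_i;R_1,R_j)$ with delete-one-block replicates and the
jackknife covariance of $\mathrm{vec}(X)$ (pseudovalue cross-products; a
ridge of $10^{-6}\,\mathrm{tr}/K$ is added, with a message, when the
condition number exceeds $10^{12}$). The rank-$r$ test fits $X\approx AB'$
by alternating generalized least squares (SVD initialization, relative
objective tolerance $10^{-9}$, 500 iterations) and refers the minimized
quadratic form to $\chi^2$ with $(n_L-1-r)(n_R-1-r)$ dof.

qpAdm models target $T$ from sources $L$ against references $R$: with
$\sum_i w_i = 1$, the residual $r_j(w)=\sum_i w_i f_4(T,L_i;R_1,R_j)$ has
covariance $(I\otimes w)'Q(I\otimes w)$, and weights minimize the
GLS quadratic form (1-D `optimize` for two sources, BFGS above that).
Standard errors re-solve the weights on each delete-one-block replicate;
the model p-value is the rank-$(|L|-1)$ test on the $(T\cup L, R)$ matrix,
with $(1)\times(n_R-1-(|L|-1)) = n_R-|L|$ degrees of freedom. Weights may leave $[0,1]$; such fits are returned with
`feasible = FALSE`. Model rotation tries all source subsets of increasing
size, moving unused pool members to the right side, and escalates
complexity only when every simpler model fails; the passing threshold
defaults to `p_floor = 0.05` and is a flag. Inverse-variance meta-analysis
pools a shared source's weight across passing models.

## Admixture graphs

Expected $f_2$ between leaves uses path-overlap algebra: each admixture
node routes a root-to-leaf path through one of its two parents with
probability $\gamma$/$1-\gamma$, and a pair of paths contributes the summed
drift on the symmetric difference of their edge sets. For fixed $\gamma$
the expectation is linear in edge lengths, so `fit_graph()` profiles
lengths by weighted (diagonal $1/\mathrm{se}^2$) non-negative least squares
— a tiny ridge ($10^{-6}$ of the design scale) resolves jointly
identifiable splits such as the two root edges — and optimizes each
$\gamma$ by a 13-point grid plus 1-D refinement, two coordinate passes. The
score is the weighted squared deviation over all leaf pairs; the worst
residual is the largest jackknife $|Z|$ over all implied f4 statistics
(f4 is reconstructed exactly from the f2 basis, the corrections cancel).

Important identifiability facts the tests respect: root placement is
invisible to f2, so all rootings of one unrooted topology tie (three
populations are therefore a single equivalence class); and fitted drift on
weakly constrained branches may legitimately be zero. `find_graphs()`
restarts hill climbs from random trees with the requested number of
admixture events, proposing leaf swaps, subtree regrafts and admixture
relocations (probabilities 0.3/0.5/0.2; the original tool's exact move set
is undocumented, so this module defines its own and validates by recovery),
accepting strict improvements, stopping after 25 consecutive failures or
200 proposals. Final topologies are deduplicated by a canonical hash:
iterative label refinement from leaf names after suppressing pass-through
nodes, so isomorphic graphs hash equally. `compare_fits()` fits both graphs
on the odd blocks and bootstrap-resamples the per-block out-of-sample score
difference on the even blocks (two-sided p, floor $1/n_{boot}$).

## The adaptive pseudo-haploid caller

Directed error rates $E(a\to b)$ are estimated from reads at sites assumed
monomorphic, stratified by library type, ordered base pair, read-position
class (central iff both read-end distances exceed 10 bp; ties go to the 5'
class), strand, MQ bin and BQ bin. Bin boundaries are a design choice the
upstream description leaves open: 2 MQ bins (<30, ≥30) and 3 BQ bins
(<20, 20–29, ≥30). Zero-observation strata are undefined and conservatively
fail the threshold; no pooling or smoothing across strata is performed. At
a biallelic site the symmetric rate $S=\max\{E(a,b),E(b,a)\}$ avoids the
bias of thresholding a direction-specific estimate; reads pass with
$S < 0.02$ (the default threshold) and a base equal to ref or alt
(tri-allelic reads never qualify). One reliable base is selected uniformly
— reads are treated as exchangeable, so the draw is over the sorted base
multiset — using an RNG keyed by `(seed, chrom, pos)`, which makes calls
deterministic and independent of read order and processing partition.
The threshold bounds the achieved per-call error from above; the
acceptance experiment measures the achieved error at truth-homozygous
sites. Damage QC flags libraries whose terminal C→T rate falls below 3%
(UDG-treated) or 10% (non-UDG).

## Kinship from pairwise mismatch rates

For two pseudo-haploid genomes the PMR over jointly covered (ideally
non-CpG autosomal) sites has expectation $b=\mathrm{E}[2p(1-p)]$ for
unrelated individuals, $0.75b$ for 1st degree, $0.875b$ for 2nd, and
$0.5b$ for identical genomes (the within-individual rate between two call
replicates of one sample anchors $b/2$ directly). Classification uses
midpoint boundaries $(0.625, 0.8125, 0.90625)\,b$ and asserts a related
class only when the rate sits at least two jackknife SEs below the
unrelated boundary. The baseline is the median pair rate of the screened
set (robust to a few relatives; whether the original analyses normalized
per group or globally is not stated, so the baseline construction is a
documented choice), and the within-individual anchor is preferred when
replicates exist. Pairs below 5000 overlapping sites are uninformative and
never classified. Pairs at 2nd degree or closer are recommended for
exclusion, keeping the higher-coverage member.

## ROH and effective population size

The generator tiles each chromosome with homozygosity-by-descent segments:
per segment a coalescence time $g\sim\Gamma(2, \beta)$ with
$\beta=1/(2N_e)$ — the length-biased form of the stationary exponential
law, so the time at a random genomic point is $\mathrm{Exp}(\beta)$ with
mean $2N_e$ generations — and a length $\ell\sim\mathrm{Exp}(2g)$ per
Morgan. Only segments of at least 4 cM (the hapROH calling floor) are
retained; when retained segments are rare (large $N_e$) the equivalent
marked-Poisson limit is simulated directly. This renewal law yields a
closed-form segment intensity $8\beta/(2\ell+\beta)^3$ per Morgan, and the
estimator uses exactly that law: Poisson counts over 8 log-spaced bins on
4–20 cM (the background-relatedness window), expected counts per
chromosome $(L_c-\bar\ell_{bin})\int_{bin} 8\beta/(2\ell+\beta)^3 d\ell$,
fractional individual weights multiplying log-likelihood contributions,
MLE by 1-D bounded search on $\log N_e$, and a likelihood-ratio 95% CI
(drop of 1.92; zero in-range segments flag the upper bound as infinite).
The upstream MLE's internals are not published, so this likelihood is the
package's own documented constant-$N_e$ approximation, validated by
parameter recovery against the shared generative law — agreement with any
particular published table is a stretch goal, not a contract. Eligibility
rules: at least 400,000 covered SNPs; for $N_e$ additionally a mean date of
at most 3000 BP and cumulative ROH > 20 cM strictly below 50 cM (guarding
against recent inbreeding). Group contrasts use tie-corrected
Kruskal–Wallis on per-individual $\sum$ROH > 20 cM plus Conover–Iman
pairwise rank tests (pooled tie-corrected variance, $N-k$ dof) with BH
correction at FDR < 0.05 — deliberately BH, not the BY procedure used for
f4 scores. The temporal regression is OLS of the 4–12 cM sum on mean date
for individuals younger than 2500 BP, with a degenerate-response flag.

## Synthetic data: what it does and does not emulate

Balding–Nichols drift was chosen over explicit Wright–Fisher generations
for its closed-form parameterization: child frequency
$\sim\mathrm{Beta}(p(1-F)/F,\,(1-p)(1-F)/F)$ with mean $p$, variance
$Fp(1-p)$, and exact moment bookkeeping
($\mathrm{E}[p(1-p)]$ shrinks by $1-F$ per edge), which the test oracles
exploit. Ancestral frequencies default to Uniform(0.05, 0.95) to avoid
monomorphic sites; admixture edges mix frequencies linearly
($\alpha p_a + (1-\alpha)p_b$) with optional residual drift. Pseudo-haploid
genotypes are Bernoulli draws with independent missingness; jackknife
blocks are equal-SNP contiguous runs; one global RNG stream per run with a
mandatory seed, and helpers restore the caller's RNG state.

The generators deliberately omit: linkage between SNPs (blocks are labels,
not LD), sequence-level artifacts beyond the stratified base-error model
(no indels, no reference bias, no FASTQ), ascertainment of the capture
panel, time-stratified sampling within a population, and non-constant
$N_e$. Passing tests therefore demonstrate estimator correctness under the
stated models — unbiasedness, calibration, recovery — not robustness to
real-data pathologies such as LD-induced jackknife underdispersion, batch
effects, or reference bias.

Desk-scale problem sizes used by the validation experiments (all chosen
once as realistic for capture-style data): clade-null calibration uses 40
independent 8-population star clades of $10^5$ SNPs and 50 blocks with 25
mutually uncorrelated f4 statistics each (statistics sharing a same-side
pair are correlated, and magnitudes on one dataset are dependent, so the
selection keeps the exceedance count near-binomial); qpAdm recovery plants
$\alpha = 0.3$ in an interleaved 6-branch backbone at $2\times10^5$ SNPs,
20 chromosomes per group, 200 replicates; graph recovery draws one of the
15 labeled 4-leaf rooted topologies with per-edge drift Uniform(0.01, 0.06)
at $5\times10^4$ SNPs; the caller experiment plants 30% terminal C→T
damage over $10^5$ C/T sites at mean depth 3; ROH recovery uses
$N_e = 500$, 40 individuals, a 22-chromosome human-like 35.5 Morgan map,
100 replicates; kinship uses $5\times10^4$ overlapping sites and 30 pairs
per degree.

## Known limitations

- The jackknife assumes block exchangeability; simulated SNPs are
  independent, so real-LD underdispersion is untested by construction.
- qpAdm's rank-test p-value and the weight GLS share one covariance
  estimated from 50 blocks; with many more f4 entries than blocks the
  covariance would need shrinkage beyond the ridge guard.
- Admixture-graph search is validated to 4–5 leaves and one admixture
  event; the move set is not guaranteed irreducible for large graphs, which
  is why independent restarts are the default protocol (100 iterations per
  admixture count).
- The ROH likelihood is composite (bins treated independently); its CI
  coverage is verified empirically at the study conditions rather than
  guaranteed analytically.
- Real-data benchmarks against restricted-access ancient genomes are out of
  desk scope; the package validates against its own generative models.
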