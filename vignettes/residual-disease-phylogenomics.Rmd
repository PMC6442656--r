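---
title: "Testing true absence of truncal mutations in residual glioblastoma disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing true absence of truncal mutations in residual glioblastoma disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Glioblastoma recurs from residual disease: scattered cancer cells in the
infiltrative margin beyond the resection border and in the sub-ventricular
zone (SVZ). Margin samples are histologically near-normal brain containing
only 5–10% tumour cells, so a mutation present in every cancer cell can
still yield zero variant reads at exome depth — a false negative, not
evidence of absence. Yet whether the margin *lacks* mutations that are
clonal in the tumour mass is exactly what distinguishes an early-diverging
ancestral clone (left behind before the tumour mass acquired its later
truncal-looking mutations) from ordinary infiltration out of the mass.
`resiphy` implements that distinction as a statistical test and propagates
it into sample-level phylogenies.

The pipeline per patient:

1. **Putative truncal selection.** From joint multi-sample SNV calls,
   compute cancer cell fractions (CCF) in every tumour-mass (`T`) sample
   and keep SNVs with CCF ≥ 0.8 in *all* of them and an identical
   copy-number state across them.
2. **Truncal VAF model.** Fit a beta-binomial to the variant read counts
   of those SNVs in a high-purity `T` sample, one fit per copy-number
   state.
3. **Absence test.** For truncal SNVs undetected in a margin/SVZ sample by
   any assay, rescale the model to a deliberately pessimistic worst-case
   purity (1% tumour, 99% normal) and compute the one-sided probability of
   seeing so few variant reads if the mutation were present. Bonferroni
   correction across the testable candidates of the sample; rejections are
   called ABSENT.
4. **Phylogeny.** Build an exact maximum-parsimony tree over samples from
   presence/absence, rooted on the blood (germline) sample, treating
   mutations whose margin status the test could not resolve as missing
   data there rather than discarding them globally, with bootstrap support.

## Cancer cell fractions

For an SNV with variant allele fraction $v = x/n$ in a sample of purity
$\pi$, tumour total copy number $C_t$, normal copy number $C_n$ and
mutation multiplicity $m$ (mutated copies per tumour cell),

$$\mathrm{CCF} \;=\; \frac{v\,\big(\pi C_t + (1-\pi) C_n\big)}{\pi\, m},
\qquad
\hat m \;=\; \mathrm{clamp}\!\left(\mathrm{round}\!\left(
  \frac{v\,(\pi C_t + (1-\pi) C_n)}{\pi}\right),\, 1,\, C_{maj}\right).$$

This is the standard purity/ploidy correction; the multiplicity estimator
is the same expression without the division by $m$, rounded and clamped to
the major allele count. CCFs are capped at 1 and flagged when the raw
value is supraclonal (noise or a wrong multiplicity). We cap rather than
exclude: at WES depth the sampling noise of a truly clonal SNV regularly
crosses 1, and exclusion would bias the truncal set towards under-covered
loci. CCFs are computed from WES counts because truncal selection precedes
the targeted panels. Positions outside every copy-number segment fall back
to diploid heterozygous (2/1) and are flagged; flagged SNVs may be tested
but are excluded from model training, which keeps the training set
conservative.

## The beta-binomial model and purity rescaling

Counts are modelled as $X \sim \mathrm{BetaBin}(n, \mu, \rho)$ with mean
$\mu$ and overdispersion $\rho \in [0,1)$; shape parameters are
$\alpha = \mu(1-\rho)/\rho$, $\beta = (1-\mu)(1-\rho)/\rho$, and $\rho = 0$
is the binomial. The fit is maximum likelihood with method-of-moments
initialisation and Nelder–Mead on the logit scale of both parameters,
which is robust when the optimum sits at the $\rho \to 0$ boundary.
Copy-number states with fewer than `min_training` (default 10) SNVs are
pooled into the nearest state by total, then major, copy number and
flagged. One model is fitted per `T` sample; the highest-purity sample's
model is used for testing, as it gives the tightest truncal VAF estimate.

The expected VAF of a clonal mutation at purity $\pi$ is

$$f(\pi) = \frac{\pi m}{\pi C_t + (1-\pi) C_n},$$

so a model trained at purity $\pi_0$ is rescaled to the worst-case purity
$\pi^\*$ by **multiplicative thinning**: $\mu' = \mu \, f(\pi^\*)/f(\pi_0)$
with the shape parameter $\alpha$ preserved and $\beta$ recomputed, i.e.
the *relative* dispersion of the VAF survives dilution and $\rho$ shrinks
roughly in proportion to the mean. This is the model of physically mixing
tumour DNA into normal DNA: each locus's latent VAF is scaled by a common
factor, so its coefficient of variation is unchanged. The tempting
alternative — keeping the concentration $\alpha + \beta$ fixed and only
moving the mean — drives $\alpha$ towards $\mu'(1-\rho)/\rho \approx 1$ at
$\pi^\* = 0.01$ for any realistic trained $\rho$, which piles prior mass
on zero variant reads and makes $P(X{=}0)$ on the order of 0.05–0.15 even
at depth 4000: the test would be powerless exactly where it is needed.
Thinning preserves the power that deep targeted coverage buys, and makes
rescaling to the training purity an exact identity.

## The absence test

A truncal SNV is **undetected** in one assay when
`alt_count < max(min_alt, depth * min_frac)` (defaults: 2 reads, 0.05% of
depth) — a reproducible stand-in for the upstream caller's detection
floor. A truncal SNV undetected by *every* covering assay is a candidate;
the deepest assay at the locus is used for the test. The p-value is the
lower tail $P(X \le x)$ under the rescaled model; for the usual $x = 0$
case the closed form

$$P(X = 0) = \frac{B(\alpha,\, \beta + n)}{B(\alpha,\, \beta)}$$

is evaluated in log space, and the generalisation to $P(X \le x)$ handles
near-zero observations (1 stray read at depth 4000) uniformly instead of
special-casing exact zeros.

**Testability.** A candidate whose depth could never produce a significant
result should not dilute the Bonferroni correction, so a candidate is
*testable* only if the largest p-value attainable while still undetected,
$P(X \le \text{detection bound} \mid n)$, falls below
$\alpha / n_{\text{tests}}$. Because $n_{\text{tests}}$ is itself the
number of testable candidates, the pair is resolved by fixed-point
iteration starting from all candidates; in the (rare) event of a 2-cycle
the larger, more conservative family size is kept. Decisions are ABSENT
(testable, adjusted p < α), DETECTED, or UNDETERMINED (untestable, or
testable but not significant, or uncovered). The Bonferroni family is the
testable candidates within one target sample of one patient; patients are
analysed independently throughout.

## Parsimony phylogenies

The presence matrix has samples in rows and SNVs in columns: `T` samples
are called by the detection rule on WES counts, blood is germline and
all-ABSENT, and margin/SVZ cells are PRESENT when detected by any assay,
ABSENT when the test rejected, and UNKNOWN (missing data) when it could
not decide — so an undetermined mutation is excluded from the parsimony
cost at that leaf only, not dropped from the analysis.

Search is an exact branch-and-bound over rooted topologies with the blood
leaf as outgroup: taxa are inserted sequentially on every edge, and a
partial tree's Fitch score (a lower bound for every completion) prunes the
enumeration against the incumbent. *All* maximum-parsimony trees are
collected; the reported tree is the lexicographic minimum of a canonical
children-sorted Newick form, a deterministic tie-break. The search refuses
more than 12 non-blood samples; the cohorts this design targets have at
most nine.

Mutation assignment is minimum-change Sankoff backtracking, vectorised
over characters. Root ties resolve to the ancestral (absent) state; other
ties keep the parent's state, which places ambiguous changes tipward. We
prefer this to the accelerated (rootward) convention because with
missing-data leaves the rootward choice can manufacture state changes that
the parsimony score never counted; the tipward rule reproduces exactly
`score` changes and leaves UNKNOWN leaves imputed from their
neighbourhood. Branch lengths are the assigned mutation counts; internal
edges carrying zero mutations are collapsed, so indistinguishable samples
form multifurcations (identical samples give a star).

**Bootstrap.** Characters are resampled with replacement; each replicate
is re-solved exactly, and a clade of the full-data tree is credited with
the *fraction* of the replicate's equally parsimonious trees containing
it. Averaging over the MP set rather than picking one tree keeps supports
deterministic and symmetric: with two characters supporting two
incompatible splits, each split earns support near 50 instead of 25/75
depending on an arbitrary tie-break.

## The simulator

`simulate_patient()` draws a clone tree (germline root, trunk clone,
sequential attachment), Poisson mutation counts per edge, Dirichlet
clone mixtures per sample concentrated on a dominant clone, and read
counts with negative-binomial depths and beta-binomial noise around the
true VAF. Defaults encode the sampling design the package targets: 4
tumour-mass samples at purity 0.45–0.75 (median near 0.59), one SVZ
sample at 0.15–0.30, one margin sample at 0.05–0.10, blood at 0; WES
depth ×157 and targeted depths ×4050 (TES1) and ×1128 (TES2);
overdispersion 0.005. Copy number is clonal: most mutations are diploid,
a minority sit in a shared 3/2 gain or 1/1 loss (multiplicity follows the
major allele in the gain, as for mutations preceding a clonal gain), and
a small fraction lies outside every segment to exercise the default-state
fallback. In the `ancestral_margin` scenario the margin contains *only*
the trunk clone while every tumour-mass dominant clone descends from a
later shared ancestor — so the mutations of that later edge look truncal
from the tumour mass but are truly absent in the margin, which is the
configuration the test exists to detect.

What the simulator does **not** model, and what passing checks therefore
do not show about real data: sequencing-error reads at truly absent loci
(a truly absent SNV draws exactly zero variant reads; in real data the
error rate is folded into ρ and into the ≥2-read detection floor),
subclonal copy number, mutation multiplicity heterogeneity within a
copy-number state, spatial structure beyond the clone mixtures, and
germline contamination of the blood sample.

## Numerical and scale choices

All randomness flows from explicit seeds; identical configurations
produce byte-identical outputs. The operating-characteristic checks in
the test suite and acceptance script use: an 80-point $(\alpha, \beta,
n)$ grid against numerical integration for the closed form; 500 training
SNVs at depth 157 for parameter recovery; 1000 truly-present candidates
at 5% purity and depth 500 for the type-I rate; 50 truly-absent SNVs at
depth 4000 for power; twelve random 6-taxon, 20-character matrices
against exhaustive enumeration (105 topologies) for the search; one
noiseless 6-clone patient with 1000 bootstrap replicates for tree
recovery; and 100 seeded ancestral-margin patients for the end-to-end
rootward-margin property. These sizes make the whole suite run in well
under a minute while leaving the Monte-Carlo margins comfortable.

## Limitations

The test is one-directional: it can demonstrate absence, never presence —
UNDETERMINED is an honest third state, and shallow or low-multiplicity
loci stay in it. Truncal selection at WES depth is noisy near the CCF
threshold, so the truncal set (and hence the candidate list) varies with
coverage. The detection floor is a proxy for the upstream caller;
pipelines whose callers behave very differently near 2 supporting reads
should adjust `min_alt`/`min_frac`. Finally, parsimony over bulk samples
reconstructs sample genealogies, not clone trees: a sample dominated by a
mixture of distant clones can attach between its components' true
positions.
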