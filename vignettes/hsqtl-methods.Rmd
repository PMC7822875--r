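---
title: "Methods: QTL mapping in heterogeneous stock populations with hsqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTL mapping in heterogeneous stock populations with hsqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsqtl)
```

# The problem

Heterogeneous stock (HS) populations descend from eight inbred founder
strains, outbred for on the order of 70 generations. Each animal's genome
is a fine-grained mosaic of founder haplotypes, which makes HS ideal for
mapping quantitative trait loci (QTL) at sub-megabase resolution — but it
also means the genotype data (a ~10K SNP array) only indirectly reveal the
quantity the genetic models care about: which founder haplotype an animal
carries at each locus. `hsqtl` implements the complete analysis chain:

1. haplotype reconstruction (HMM) and dosage imputation,
2. Bayesian narrow-sense heritability,
3. LMM association scans with parametric-bootstrap genome-wide thresholds
   and r²-defined LD support intervals,
4. founder haplotype-effect estimation at detected peaks under diplotype
   uncertainty (additive + heterozygous dominance deviations),
5. a four-criterion expression mediation analysis,

plus a synthetic HS generator with known truth, so every stage is
verifiable by parameter recovery without access to any animal data.

# Haplotype model

## State space and transitions

At each marker the latent state is the *diplotype*: the unordered pair of
founder haplotypes, `F(F+1)/2 = 36` states for `F = 8` founders (8
homozygous, 28 heterozygous). States are ordered lexicographically in
`(f1, f2)` with `f1 <= f2`; this ordering is frozen and relied upon
throughout.

Ancestry along a chromosome follows a Markov jump process with rate `G`
per Morgan (`G` = generations of outbreeding, default 70) and uniform jump
target over founders, including the current one. Over a map distance `d`
Morgans the per-haplotype kernel is

```
P(same founder)  = e^(-G d) + (1 - e^(-G d)) / F
P(specific other)=            (1 - e^(-G d)) / F
```

(Haldane map, no interference). The diplotype kernel is the product of two
independent haplotype kernels mapped to unordered pairs. This exchangeable
jump-process family was chosen over a pedigree-derived parameterisation
because it is the exchangeable-founder limit, matches the synthetic
generator by construction, and leaves `G` as a single interpretable
parameter.

The initial distribution is uniform *per haplotype*, i.e. Hardy–Weinberg
over diplotypes (`1/F²` homozygous, `2/F²` heterozygous). This is the
stationary law of the kernel, so a chromosome with no genotype information
returns exactly this law at every marker. (A uniform law over the 36
unordered states is *not* stationary and would make uninformative
posteriors drift.)

## Emissions and inference

Founders are inbred, so each founder contributes one known allele per
marker. Each of the two transmitted alleles is observed flipped
independently with probability `eps` (default 0.01, CLI-exposed); the
observed genotype is their sum; missing genotypes contribute likelihood 1.
Forward–backward with per-marker scaling gives exact marginal posteriors
and the data log-likelihood; the implementation advances the whole cohort
through each marker with one matrix product, so a 245-animal, 8,000-marker
dataset takes seconds. Founder dosages (expected copies of each founder,
summing to 2) and SNP allele dosages follow by linear collapse of the
posterior.

**What a green test establishes.** Forward–backward is checked against
brute-force path enumeration (all `S^M` paths) on small instances to
1e-10, so the *algorithm* is exact. Whether the *posterior is
concentrated* depends on the data: at HS-array density (~5 markers/cM,
`G = 70`, segments ~1.4 cM) the per-marker diplotype is intrinsically
uncertain (mean maximum posterior ≈ 0.68 in simulation). That is a fact
about the design, not a defect: downstream stages consume dosages and
full posteriors, never hard assignments. The mosaic-recovery property
(≥95% posterior-mode accuracy) is therefore tested in an identifiable
regime — 40 markers/cM, ≈20 markers per ancestry segment — where
near-certain reconstruction is actually attainable.

Markers used for inference are "informative": polymorphic across founders
and (when genotypes are supplied) call rate ≥ 0.9 — a documented stand-in
for the array-specific filter that reduced the original 10,846-SNP array
to 8,218 usable markers.

# Linear mixed model core

All association and mediation tests use the model
`y = X b + u + e`, `u ~ N(0, tau2 K)`, `e ~ N(0, sigma2 I)`.

**Kinship.** `K` is the founder-dosage cross-product over markers, with
each marker's dose columns *centred* before the product, rescaled to mean
diagonal 1. Centring matters: under exchangeable founders every animal
carries ~`2/F` doses of every founder, and the uncentred cross-product
contains that shared baseline as a dominant eigen-direction, which
distorts the variance-ratio scale (in simulation it biased h² modes from
0.45 up to ~0.65). What remains after centring is relatedness *variation*,
the quantity the polygenic model actually uses. The formula is a
documented design choice and swappable.

**Fitting.** A single eigendecomposition of `K` turns every likelihood
evaluation into O(n) diagonal algebra. The variance ratio
`h2 = tau2/(tau2 + sigma2)` is profiled and maximised by coarse grid plus
Brent refinement on the closed domain [0, 0.995] (ratio ≤ 199; the cap
avoids numerically divergent boundary fits). ML is the default so
likelihood-ratio tests of fixed effects are valid; REML is available for
variance reporting. Rank-deficient covariates are rejected, never dropped.

**Scan.** Each marker's dose enters as one fixed effect;
`logP = -log10 p` from the 1-df LRT. The per-marker alternative-model
ratio is re-maximised over a dense grid (200 points plus the exact null
ratio) *shared* between null and alternative, so the LRT is non-negative
by construction and the grid resolution contributes < ~0.01 logP. The
shared-grid formulation makes the scan a batched matrix computation
across markers *and* phenotypes, which is what keeps 200-fold bootstrap
rescans in the seconds range. Monomorphic dose columns get logP 0 with a
warning.

**Thresholds.** Genome-wide significance uses the parametric bootstrap:
`B` (default 1000) phenotype vectors simulated from the fitted null
(`N(X b, tau2 K + sigma2 I)`, drawn directly in the eigenbasis), each
rescanned, and the empirical `1 - alpha` quantile (type 7) of the maxima
taken. `B < 50` is rejected as unstable. Thresholds are per trait; no
cross-trait multiplicity correction is applied.

**LD intervals.** From the peak, expand over *consecutive* markers of the
same chromosome while dosage r² with the peak stays ≥ 0.5 (shipped
default), stopping at the first failure per side; the interval is the bp
span of retained markers, closed on both ends. Dosage r² (not genotype
r²) is used because dosage is what the scan tests. The contiguous-run
rule (rather than any-marker-above-r²) reflects the window-of-neighbours
reading of LD support.

# Phenotype preparation

Traits are rank-based inverse-normal transformed: Blom plotting positions
`(rank - 3/8)/(n + 1/4)` (offset configurable), average ranks for ties,
then centred/scaled to mean 0, SD 1; missing values pass through. INT is
invariant to monotone pre-transforms, so whether a raw trait was
log-transformed first is immaterial. Expression counts are
counts-per-million normalised (each sample scaled to 10⁶) before the same
INT treatment — expression enters every test exactly as traits do.

# Bayesian heritability

Model: `y = mu + u + e` with Gamma(1,1) priors on the precisions
`tau^-2` and `sigma^-2`. This prior pair makes the induced prior on
`h2 = tau2/(tau2 + sigma2)` exactly Uniform(0,1) (the ratio of reciprocal
i.i.d. Gamma(1,1) variables is Beta(1,1)); the package verifies this by a
prior-only sampling mode and a KS test. Inference is Gibbs sampling in
the eigenbasis of `K`, where the polygenic effect decomposes into
independent scalars and every update is O(n); zero eigenvalues are
handled by restriction to the range of `K`. Defaults: 10,000 iterations,
1,000 burn-in.

Summaries follow the posterior-mode + 95% HPD convention: the mode comes
from a Gaussian KDE on the *logit* scale (Silverman bandwidth),
back-transformed with the Jacobian — a direct KDE on (0,1) is
boundary-biased; the HPD is the shortest interval over sorted draws.
Effective sample size uses the AR-spectral estimator. The Gibbs sampler
was validated against an independent 2-D grid-integration oracle of the
exact posterior.

**Identifiability and the sibship layer.** Heritability is only
identifiable when relatedness *varies* across pairs. A population of
independently simulated mosaics is nearly exchangeable — everyone is
equally related — and the h² posterior then stays diffuse regardless of
sampler quality (we verified this against the grid oracle). Real HS
colonies are bred in families. The generator therefore groups animals
into sibships (`family_size`, default 5): parental haplotypes follow the
ancestry jump process, and sibs are meiotic recombinants (crossover rate
1/Morgan) of the same two parents. Within-animal haplotype independence
is preserved. With this design, 20-replicate recovery at true h² = 0.45,
n = 250 gives mean posterior mode ≈ 0.44 with nominal HPD coverage.

# Founder haplotype effects at a QTL

At a detected peak the model is

```
y = mu + sum_f dose_f * beta_f + gamma_state(het) + u + e
beta_f ~ N(0, tau2_add)          f = 1..8
gamma_s ~ N(0, tau2_dom)         s over the 28 heterozygous states
u ~ N(0, tau2_poly K)
```

with Gamma(1,1) priors on all precisions. Dominance deviations are
indexed by heterozygous states only (homozygous contrasts are carried by
the additive doses); their inclusion stabilises the additive estimates.
Because the diplotype at the peak is uncertain, `M` (default 200)
configurations are sampled from the per-animal posteriors; each is fitted
by Gibbs (the heterozygous-state indicator columns are mutually
exclusive, so their updates are scalar; everything runs in the
eigenbasis), and configurations are weighted by a plug-in marginal
likelihood of the phenotype evaluated at the posterior means of the
variance components — the dominant term of a Laplace approximation, whose
curvature factor varies little between configurations. Duplicate sampled
configurations are fitted once and weighted by multiplicity, so fully
certain diplotypes reduce exactly to the single-configuration fit with
uniform weights. Weight entropy and importance effective sample size are
reported, and degenerate weight sets trigger a warning — with diffuse
diplotype posteriors and n in the hundreds, weight degeneracy is intrinsic
to this importance scheme and should be inspected, not ignored.

**Effect size.** The QTL effect size is the intraclass correlation
`h2_QTL = var_QTL / (var_QTL + var_poly + sigma2)`, computed per draw from
the *realised* variance components: the sample variance of the QTL linear
predictor and of the polygenic effect. The hyperparameters
`tau2_add + tau2_dom` are *not* used as the numerator because with
Gamma(1,1) priors they are informed by only 8 + 28 shrunken effects and
are prior-dominated: a truly null QTL still yields
`tau2_add ~ InvGamma(5, ~1)` concentrated near 0.25, i.e. a nonsense
"25% effect size". Even on the realised scale there is a floor: the prior
puts essentially no mass on `tau2_dom` below ~1/15, so the 28 dominance
deviations never contract entirely and their posterior sampling noise
contributes ≈0.05–0.10 of apparent QTL variance at n = 500. A null QTL
thus reports an effect-size mode around 0.07–0.11, not < 0.05; this is a
property of the stated prior, documented rather than patched.

# Mediation analysis

Given a detected QTL (criterion 1), each annotated gene is processed
sequentially with short-circuiting, retaining every computed value:

2. *cis-eQTL*: the gene must be local (any overlap with the LD interval,
   boundary-straddling genes included), pass the strict >25% non-zero
   expression filter (exactly 25% fails), and show an LMM LRT association
   between its INT-CPM expression and the peak dose, Benjamini–Hochberg
   FDR ≤ 0.1 *within the local gene set* (testing is constrained to the
   locus, so genome-wide correction is unnecessary).
3. *Full mediation*: the peak-marker LRT is re-run with the mediator as a
   fixed covariate in **both** null and alternative models; a conditioned
   p > 0.05 makes full mediation plausible (the both-models conditioning
   is the statistically coherent reading and is noted as an
   interpretation).
4. *Partial mediation*: 1-df LRT for the mediator given the marker, BH
   q ≤ 0.1 within the evaluated genes.

Verdict: `candidate_mediator` iff criterion 2 holds and (3 or 4) holds;
otherwise the most specific failure label (`not_local`, `filtered`,
`no_cis_eqtl`, `not_mediator`). A gene with a cis-eQTL but no causal path
to the trait — the pattern seen at a single-gene locus whose candidate is
expressed in the wrong tissue — lands in `not_mediator` via a small
conditioned p (the QTL survives conditioning) and a null partial test.

# Synthetic data: the stated world

The generator's defaults are the design under study: 8 founders, G = 70,
20 autosomes × 100 cM × 400 markers (≈8,000 informative SNPs; 1 cM is laid
out as 2 Mb), n = 245 animals in sibships of 5, genotyping error 0.01,
missingness 0.01, founder allele patterns drawn with the allele-1 count
uniform on {1,…,7} so no marker is monomorphic in founders. Traits are
built as QTL + polygenic + noise with each component rescaled to its
exact target sample-variance fraction (targets: h² in 0.3–0.85, QTL
fraction ~0.2). A pipeline QTL may specify `effects: "snp"`, meaning the
causal contrast *is* the marker's founder allele pattern — the regime in
which a SNP-dosage scan has the power the mapped loci showed; an
arbitrary founder-effect pattern tagged by a single biallelic SNP can
carry much less scannable variance.

Expression scenarios wire explicit causal graphs (x = standardised peak
dose, z = gene liability): `full_mediation` (x → z → y),
`colocal_no_mediation` (x → z and x → y, no z → y), `partial_mediation`
(both paths), `none`; plus local and off-chromosome decoy genes and one
zero-inflated gene (80% zeros) that must fail the expression filter.
Counts are Poisson with a log link on the liability, so CPM + INT
recovers an approximately linear readout.

**What the generator does not emulate:** linkage disequilibrium between
founder allele patterns at nearby markers beyond what the shared mosaic
induces, selection and drift, sex chromosomes, genotyping batch effects,
and count overdispersion beyond Poisson. Green recovery tests therefore
establish correctness of the inference under the model's own assumptions,
not robustness to real-data artefacts.

# Numerical choices

- Variance-ratio domain closed at 0.995; scan grid of 200 points shared
  between null and alternative (LRT ≥ 0 by construction).
- Likelihood scaling per marker in the HMM; no log-space arithmetic
  needed up to 10⁴ markers.
- RSS floored at 1e-290 so collinear covariates (e.g. a mediator
  identical to the response) yield p → 0 with a "degenerate" warning
  instead of an error.
- HPD = shortest window over sorted draws; modes via logit-scale KDE;
  ties in the rank transform get average ranks.
- All randomness flows from one master seed through tagged integer
  sub-streams (`derive_seed`), all below 2³¹; reruns are byte-identical.

# Known limitations

- The HMM assumes exchangeable founders; a founder-biased breeding
  history would need the full pedigree-derived kernel.
- Importance-sampling ESS at a weakly-identified peak can approach 1;
  results then effectively condition on the best-supported configuration.
- The mediation tests are conditional-independence tests in a linear
  model; they cannot distinguish mediation from reverse causation or a
  shared upstream driver, and inherit the usual FDR caveats at a handful
  of local genes.
- Leave-one-chromosome-out kinship is available
  (`kinship_from_dosages(exclude_chrom = )`) but off by default, matching
  the analysed design.
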