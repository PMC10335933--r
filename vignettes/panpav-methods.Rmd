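---
title: "Methods: pan-genome PAV analysis, selection scans and genomic prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome PAV analysis, selection scans and genomic prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panpav)
library(dplyr)
```

panpav implements the analytical layer of a crop pan-genome study built on
two marker classes: gene-family presence/absence across assembled accessions,
and structural-variant derived presence/absence variants (PAVs, insertions
and deletions of at least 50 bp carried as binary genotypes). The package
covers pan-genome composition and growth, frequency-based selection scans
across a wild / landrace / cultivar panel, transposon-derived PAV calling,
windowed diversity scans, mixed-model association with locus clustering, and
genomic selection with breeding-potential enumeration. A synthetic population
generator with complete ground truth exercises every stage, so the package is
testable end-to-end without external data.

## The synthetic population generator

`simulate_population()` emulates a three-group diversity panel. Its defaults
are the package's reference study conditions and were fixed once, on the
following grounds:

* **Panel sizes 35/40/35** (wild/landrace/cultivar): mirrors a realistic
  assembly panel of about 110 accessions; a larger panel can be configured
  for association and prediction experiments.
* **Balding–Nichols drift, `F_drift = 0.05`.** Each marker's ancestral
  frequency $p_0 \sim U(0.05, 0.95)$; group frequencies are drawn from
  $\mathrm{Beta}\!\left(p_0\frac{1-F}{F},\,(1-p_0)\frac{1-F}{F}\right)$,
  the minimal model producing realistic $F_{ST}$-like differentiation
  ($E[F_{ST}] \approx F$). 0.05 is a modest neutral background: in a
  domestication panel the selected loci, not the genome-wide background,
  should carry the strong frequency signal. The lower bound 0.05 on $p_0$
  keeps most markers above the MAF 0.05 filter used downstream.
* **Planted selected PAVs.** `n_selected_pav` PAVs receive monotone
  wild $\to$ landrace $\to$ cultivar carrier frequencies with a shift of
  `delta_f` (default 0.5) in the labeled contrast (domestication: wild vs
  landrace; improvement: landrace vs cultivar) and a 0.15–0.30 buffer in the
  other step. The buffer exists because genotypes are sampled binomially:
  with ~35–40 accessions per group the realized frequencies fluctuate by
  $\approx 0.08$, and a smaller planted gap would frequently break the
  monotone ordering that defines a favorable PAV, making "recovery of the
  planted truth" ill-posed.
* **TE fraction 0.6** of the genome, matching the TE share typical of these
  genomes; TE and gap lengths are log-normal/exponential with matched means
  so realized coverage concentrates tightly around the target.
* **Planted TSDs, lengths 4–10 bp.** Target-site duplications are exact
  duplicated k-mers ending at the left breakpoint and beginning at the right
  breakpoint. Single-base-run TSDs are resampled and the bases immediately
  outside the duplication are forced to differ from its termini — otherwise a
  planted duplication could extend by chance and exact-length recovery would
  be impossible by construction.
* **Phenotypes**: `n_causal` markers (SNPs and PAVs) with N(0,1) additive
  effects; noise scaled so the genic variance fraction equals `h2`
  (default 0.5); per-environment main effects with one record per accession
  and environment.
* **One master seed, per-component sub-streams**, so enlarging one component
  (say, adding markers) does not perturb another (say, phenotypes), and
  identical configurations are byte-identical after serialization.

What the generator does **not** emulate: linkage disequilibrium (loci are
independent; LD-dependent analyses construct LD explicitly by duplicating
and perturbing genotype columns), recombination maps, coalescent genealogy,
genotyping error beyond uniform missingness, and G×E interaction. Passing
tests therefore demonstrate the correctness and operating characteristics of
the procedures under drift-plus-selection allele-frequency structure, not
their behavior under realistic haplotype structure.

## Pan-genome composition and growth

`classify_families()` assigns each gene family a category from its occupancy
count $c$ over $N$ accessions: core ($c = N$), soft-core
($\lceil 0.9N\rceil \le c \le N-1$), dispensable ($2 \le c <
\lceil 0.9N\rceil$), private ($c = 1$). The soft-core boundary is written as
$\lceil 0.9N \rceil$ so that the conventional "present in more than 90% but
not all" range reproduces the familiar 100–110 band at $N = 111$ while
generalizing to any panel size.

`growth_curves()` adds accessions in `R` random orders and tracks the
cumulative union (pan) and intersection (core) family counts; within every
single ordering pan is non-decreasing and core non-increasing by
construction. For $N \le 8$ an exhaustive all-orderings mode provides exact
means. The *detrended* curve is taken to be the increment series
$\Delta\mathrm{pan}(n)$; since the term has no standard definition, this
choice is a documented convention. `fit_closure()` fits
$\mathrm{pan}(n) = K n^\gamma + C$ by nonlinear least squares
(Levenberg–Marquardt, log–log starting values) and calls the pan-genome
closed when $\gamma < 1 - \mathrm{tol}$ (default tol 0.05, a Heaps-law style
criterion) **and** the final increment is below $\varepsilon \cdot
\mathrm{pan}(N)$ (default $\varepsilon = 10^{-3}$); the plateau size is the
first $n$ whose increment falls below that threshold. Degenerate constant
curves short-circuit to $\gamma = 0$, closed.

## PAV selection scans

Carrier frequencies are computed per group as carriers over non-missing
calls; translocations are excluded from frequency work because their carrier
semantics are ambiguous. Each PAV is tested between the two groups of a
contrast with a two-sided Fisher exact test (vectorized hypergeometric
enumeration with de-duplication of identical tables, matching
`stats::fisher.test` to numerical precision), followed by Benjamini–Hochberg
adjustment. A PAV is *selected* when $q \le q_{max}$ **and**
$|\Delta f| \ge \delta_{min}$; the defaults $q_{max} = 0.01$,
$\delta_{min} = 0.25$ operationalize "substantially different frequencies" —
a p-value alone conflates sample size with effect size, hence the joint
rule. A selected PAV is *favorable* (favPAV) when its frequencies are weakly
monotone across wild $\to$ landrace $\to$ cultivar with strict inequality in
the flagged contrast; ties in the other step are tolerated because sampled
frequencies tie easily at these group sizes.

Two operating-characteristic experiments back the scan:

* **Error control** is evaluated on an exchangeable null (`F_drift = 0`, no
  planted shifts). Under a drifted background the groups' frequencies
  genuinely differ at every PAV, so a "false positive rate" against planted
  truth would be ill-defined.
* **Recovery** plants monotone shifts of 0.5 on the same exchangeable
  background and measures sensitivity and precision of favPAV calls at the
  nominal $q = 0.05$ of the error-control experiment. At the stricter
  default $q = 0.01$ the scan loses marginal improvement-contrast PAVs
  (sensitivity drops to roughly 0.77 at these group sizes) — the
  documented power cost of the conservative default.

`map_pavs_to_genes()` associates PAVs with gene bodies or strand-aware
promoter windows (default 2,000 bp upstream of the transcription start — the
usual convention where "promoter region" is otherwise unspecified; unknown
strands take both sides and are flagged). `te_overlap_enrichment()` compares
the observed TE-overlap fraction against uniform random placement per
chromosome with the add-one permutation p-value
$(1 + \#\{null \ge obs\})/(1 + n_{perm})$.

## TE-derived PAV calling

`detect_tsd()` reports the longest exact duplicated k-mer (k in 4–10 by
default) anchored at the two breakpoints; at a given length the anchored
candidate is unique, so the only tie-break needed is longest-first. On
i.i.d. uniform flanks the false-positive rate is $4^{-k_{min}}$ ($\approx$
1/256 at the default), which the tests verify by simulation.
`classify_te_derived()` requires intersection with exactly one intact TE,
reciprocal overlap $\ge 0.8$ (a configurable strictness choice for
"colocated"), and a detected TSD; breakpoint-to-junction distances are
emitted. The rule operates on reference-spanning records (deletions,
inversions); insertion PAVs are zero-length reference intervals whose TE
evidence is the TSD itself.

## Windowed diversity and selection signatures

Windows default to 20 kb sliding with a 2-kb step. Per window,
$\pi = \sum_{sites} 2\hat p\hat q\,\tfrac{n}{n-1} / L$ — the unbiased
per-site heterozygosity from non-missing allele counts summed over variant
sites and divided by the full window span, so monomorphic and unobserved
sites count as zero difference (the standard windowed-$\pi$ convention).
$F_{ST}$ is the Weir & Cockerham (1984) estimator, windowed as a ratio of
sums of the per-site variance components $a/(a+b+c)$; monomorphic or
under-genotyped sites are excluded and empty windows masked. The $\pi$ ratio
is taken per window ($\pi_{wild}/\pi_{landrace}$; a high ratio marks
diversity loss in the derived group). `scan_candidates()` flags the upper
empirical tail (default 1% per statistic) and the joint intersection —
cutoffs are data quantiles, not fixed constants, because published cutoff
values are properties of their own data sets.

## Mixed-model association and loci

`lmm_assoc()` follows the EMMAX scheme: variance components of
$y = Xb + u + e$, $u \sim N(0, \sigma_g^2 K)$ are estimated once on the null
model by REML via the eigendecomposition of the VanRaden kinship $K$; each
marker is then tested by generalized least squares in the whitened space,
with the residual scale re-estimated per marker so the test is an exact OLS
t-test after whitening (with $K = I$ and no covariates it reproduces
`lm()` p-values to numerical precision). Principal components (default 10)
enter as fixed covariates; kinship is the random effect. This is the
conventional EMMAX decomposition — treating PCs as "a random effect matrix"
has no standard meaning, so the fixed-covariate reading is used and
recorded as a deviation.

The effective marker number uses a blockwise Li–Ji-style eigenvalue
estimator on LD correlation matrices (default block 1,000 markers):
$M_{eff} = \sum_\lambda [I(\lambda \ge 1) + (\lambda - \lfloor\lambda\rfloor)]$.
Duplicated markers halve the count; orthogonal markers keep it. When a block
holds more markers than accessions the correlation matrix is rank-limited
and the estimate is bounded by the sample size — an inherent property of
eigenvalue estimators worth remembering at desk scale. Bonferroni thresholds
$\alpha/M_{eff}$ are reported at both $\alpha = 0.05$ and $0.01$ because the
conventional genome-wide cutoff $7.81\times10^{-8}$ corresponds to
$0.05/640{,}288$ while the accompanying text cites $\alpha = 0.01$; both are
surfaced rather than silently choosing one.

`cluster_loci()` clusters significant markers greedily: the smallest-p
unassigned marker leads a locus and absorbs unassigned significant markers
within 50 kb and with dosage $R^2 \ge 0.3$ against the lead
(pairwise-complete correlation); p ties break by chromosome order then
position, making the partition deterministic. Candidate genes are those
intersecting $\pm 50$ kb of the lead. `sv_snp_ld_complement()` reports each
SV's maximum $R^2$ against flanking SNPs ($\pm 50$ kb) and the untagged
fraction below $R^2 = 0.5$ — the share of SV association signal invisible
to SNP-only scans.

## Genomic selection and breeding potential

`feature_gain()` fits gradient-boosted regression trees (xgboost; depth 4,
learning rate 0.1, 150 rounds by default) and attributes to each marker its
total split gain (FG). The selection statistic is
$\mathrm{ROF}_i = 1 - \mathrm{FG}_i/\mathrm{FG}_{max}$ with threshold 0.99,
i.e. markers with at least 1% of the maximum gain are kept. Note the
orientation: written the other way around ($1 - \mathrm{FG}_{max} /
\mathrm{FG}_i$) the statistic is non-positive for every marker and the 0.99
cutoff would select everything; the form used here is the one that makes
the threshold meaningful, and the selection is invariant to rescaling FG.

Six panels combine highly effective ("cg") markers with GWAS-significant
markers by set union: `SNP_cg`, `SNP_cg_gwas`, `SV_cg`, `SV_cg_gwas`,
`SNPSV_cg`, `SNPSV_cg_gwas`. The combined `SNPSV_cg_gwas` panel unions both
the GWAS SNP and GWAS SV sets — the symmetric reading of panel definitions
whose printed form mentions only the SV side.

`cross_validate()` reports the Pearson correlation between observed
phenotypes and predicted GEBVs over repeated train/held-out splits (default
100 replicates at 85%/15%; a panel of exactly 680 accessions uses the
conventional 580/100 split). Two predictors sit behind one contract:
gradient-boosted trees (primary, same family as the feature-gain model) and
a closed-form ridge regression (GBLUP-style linear cross-check; with a
near-zero penalty it recovers noiseless additive phenotypes essentially
exactly). Null calibration of the precision estimate deserves care: on a
single dataset the replicate precisions share a dataset-level spurious-fit
component (of order $\sqrt{p/n}$), so the null experiment pools independent
null datasets in a $p \ll n$ regime, where the pooled mean precision is
within Monte-Carlo error of zero.

`enumerate_breeding()` takes the highest-GEBV (cultivated) accession as
background and enumerates all $2^k$ assignments of the $k$ highest-FG
markers to reference (0) or maximum observed alternate dosage, reporting the
best simulated haplotype GEBV and the improvement percentage
$(\mathrm{GEBV}_{max.haplotype} - \mathrm{GEBV}_{max.cultivated}) /
\mathrm{GEBV}_{max.cultivated} \times 100$. The default cap of $2^{20}$
(1,048,576 combinations) is enforced with an explicit refusal above it;
under the linear model the enumeration provably attains the closed-form
optimum (alternate allele wherever the effect is positive), which the tests
assert exactly. The improvement percentage is undefined when the cultivated
maximum is zero and is reported as such; its sign convention assumes a
positive denominator, as in the source formulation.

## Numerical conventions and degenerate inputs

* Coordinates are 0-based half-open internally; VCF (1-based), BED (0-based
  half-open) and GFF3 (1-based inclusive) conversions happen only at format
  boundaries and round-trip losslessly.
* Fisher p-values use the conventional $1 + 10^{-7}$ relative tolerance when
  summing point probabilities "at most as likely as observed"; empty margins
  return p = 1.
* Missing dosages are mean-imputed for kinship, PCA, association and
  prediction; frequency and diversity statistics instead exclude missing
  calls exactly.
* Zero-variance markers are dropped from kinship, $M_{eff}$, and LD; a
  genotype matrix with no polymorphic marker yields a zero kinship with a
  warning.
* Eigenvalues are snapped to integers within $10^{-9}$ in the $M_{eff}$
  estimator so exact duplicates do not fall on the wrong side of the floor
  discontinuity.
* Monomorphic SVs are excluded (and counted) from LD complementarity;
  held-out splits with constant phenotypes are recorded as undefined
  replicates and excluded from means with a count.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
sim <- simulate_population(cfg)

# pan-genome composition and closure
comp <- classify_families(sim$presence)
glance(comp)
fit_closure(growth_curves(sim$presence, R = 50, seed = 1))

# selection scan
freqs <- pav_frequencies(sim$pav, sim$groups)
calls <- dplyr::bind_rows(scan_selected(freqs, "domestication"),
                          scan_selected(freqs, "improvement"))
fav <- classify_favpav(calls, freqs)
sum(fav$favpav)

# full pipeline with provenance manifest
res <- run_pipeline(pipeline_config(sim = cfg), "out")
```

The problem sizes used by the test suite and the acceptance script (for
example 10,000 families at $N = 111$ for classification, 200 replicate null
scans of 2,000 PAVs, 50-seed recovery and power experiments, 25-replicate
cross-validation, and the full $2^{20}$ haplotype enumeration under the
linear model) are the package's reference experiment sizes; they keep every
experiment's Monte-Carlo error well inside the margins being asserted.

## Known limitations

* No LD realism in the generator: tagging, clustering and complementarity
  behavior under realistic haplotype structure is exercised only through
  explicitly constructed LD (duplicated/perturbed columns).
* The association module analyzes one phenotype dataset at a time; no
  multi-trait or G×E joint models.
* XPCLR-style composite-likelihood sweep statistics are out of scope; the
  diversity scan covers the $\pi$-ratio and $F_{ST}$ components.
* The growth-curve closure verdict depends on the documented conventions for
  detrending and plateau; alternative definitions would shift the plateau
  estimate but not the closed/open call on clearly saturating or linear
  curves.
* $M_{eff}$ is sample-rank limited when blocks exceed the accession count.
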