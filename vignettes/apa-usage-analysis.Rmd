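---
title: "Methods: differential 3'UTR usage, correlation and survival analysis of APA indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential 3'UTR usage, correlation and survival analysis of APA indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apakit)
```

# The data model

Alternative polyadenylation (APA) in the 3'UTR moves the mRNA cleavage
site between a *proximal* position (near the stop codon) and one or more
positions farther along the transcript, the farthest being the *distal*
site. `apakit` stores one row per cleavage site with a 1-based genomic
coordinate — the convention in which site coordinates are printed and
typed by users — while every interval (3'UTR regions, BED export, track
overlap) is 0-based half-open internally. The conversion happens only at
the I/O boundary, so BED files need no off-by-one adjustment and printed
coordinates match user expectations.

Usage indices are kept as they come from the quantifiers, in $[0,1]$:

* **PAU** (QAPA): the share of a gene's transcript expression on one
  isoform, $\mathrm{PAU}_i = \mathrm{TPM}_i / \sum_j \mathrm{TPM}_j$.
  Per gene and sample, non-missing PAUs sum to 1. A gene with zero total
  TPM yields *missing* PAU for all isoforms: absence of usage evidence
  is not zero usage, and imputing 0 or a uniform split would manufacture
  signal in downstream rank tests.
* **PDUI** (DaPars): the fraction of transcripts using the distal site;
  1 means all-long 3'UTR. DaPars emits `NA` for low-coverage samples;
  these are stored as missing and dropped pairwise by every statistic,
  never imputed.

Site ranks are assigned from coordinates alone (`order_sites()`): on the
plus strand ranks increase with the genomic coordinate, on the minus
strand they decrease, so the proximal site is always nearest the stop
codon in the transcript's sense direction. The assignment is invariant
under input permutation, and flipping the strand swaps the proximal and
distal labels — both properties are tested.

## Gene-level usage for multi-isoform PAU data

PDUI is naturally "higher = longer 3'UTR". PAU is per isoform, so a gene
with several isoforms needs a summary before it can be compared to PDUI
results. `gene_usage()` uses the PAU of the *distal-ranked* isoform as
the gene's index. This makes ΔPAU sign-compatible with ΔPDUI (a negative
difference always means 3'UTR shortening in group 1) at the cost of
ignoring internal sites; for genes with more than two sites the distal
isoform's share remains a monotone proxy for "long-3'UTR preference".
This was a genuinely open design point — averaging UTR lengths weighted
by PAU would be an alternative — but the distal-share convention keeps
the index in $[0,1]$ and directly comparable between the two quantifier
dialects.

# Differential usage

For two groups the effect size is the difference of group means,
$\Delta = \bar{u}_{g_1} - \bar{u}_{g_2}$, computed over non-missing
values; the caller's declared group order fixes the sign and is recorded
in the result. Significance uses the two-sided Mann–Whitney rank-sum
test: exact enumeration whenever both groups have at most 8 usable
values and no ties (where the exact distribution equals the full
permutation distribution — verified in the test suite against an
independent enumeration of all $\binom{n_1+n_2}{n_1}$ assignments), and
the normal approximation with tie correction otherwise. More than two
groups use the Kruskal–Wallis omnibus test; no post-hoc pairing is
performed. Fully tied input carries no rank information and returns the
degenerate statistic with $p = 1$ rather than `NaN`.

Raw p-values are always reported. Because a screen across thousands of
features needs error control, Benjamini–Hochberg q-values are computed
across all features of a run, and the trend call uses them:

* *lengthened*: $\Delta \ge \delta_{\min}$ and $q < \alpha$;
* *shortened*: $\Delta \le -\delta_{\min}$ and $q < \alpha$;
* *unchanged* otherwise.

Defaults are $\delta_{\min} = 0.1$ (usage units; a 10-point shift in
usage is the smallest effect we consider biologically meaningful — no
published cutoff exists, so the gate is exposed as a parameter) and
$\alpha = 0.05$. Features where any group has fewer than two usable
values are skipped and listed in the result's `skipped` attribute.

`top_bottom_split()` implements high-vs-low comparisons (e.g. top 30 /
bottom 30 samples by PDUI). Boundary ties are broken by lexicographic
sample-id order, making the split reproducible across runs regardless of
input order.

# Correlation

The relationship studied between an APA index and expression is linear,
so Pearson correlation is the default (Spearman is available for
robustness). The p-value is the two-sided t-test on
$t = r\sqrt{n-2}/\sqrt{1-r^2}$ with $n-2$ degrees of freedom; at least 3
complete pairs are required and constant input is a defined error rather
than `NaN` propagation. The regression line comes from OLS and the 95%
band is the *mean-response* confidence interval from the t distribution,
evaluated at the observed x values; it widens with distance from
$\bar{x}$ and its empirical coverage is checked in the tests
(95% ± 2% over 1,000 bivariate-normal replicates at $n = 30$).
Expression enters on the TPM scale un-logged by default, matching how
usage–expression dot plots are conventionally drawn; a `log2_y` flag
applies $\log_2(\mathrm{TPM}+1)$.

The screen (`screen_correlated()`) keeps features with $|r| > 0.3$ and
$p < 0.05$ — the customary gates for this analysis — sorted by $|r|$;
both gates are parameters.

# Survival

For a chosen feature, samples are split at the *median* of its usage
index: values at or below the median go to `low`, values above to
`high`. Ties at the median go low — an arbitrary but deterministic and
documented convention. If the median coincides with the maximum (heavy
upper ties) the strict rule would empty the high group, so max-valued
samples are then assigned high to keep both groups non-empty. A constant
usage row has no defined split and errors.

The two groups are compared with the standard two-group log-rank test
(1 df; $p$ from the upper $\chi^2$ tail). The Kaplan–Meier product-limit
estimator provides the curves; the median survival time is the earliest
event time at which $S(t) \le 0.5$, undefined when never reached. With
no censoring the estimator equals the empirical survival function
exactly (tested). The hazard ratio shown with the curves is the
observed/expected (Pike) estimate
$\mathrm{HR} = (O_{high}/E_{high})/(O_{low}/E_{low})$ — no Cox model is
fitted because no covariates enter the analysis; the estimate is flagged
unstable when a group has zero events. Parameter recovery is verified by
simulation (true HR 2, $n = 200$/group, ~20% censoring: estimate within
[1.6, 2.5] in ≥ 90% of seeds). Time units are whatever the clinical
table declares (days, months); no conversion is attempted.

# Motif scanning and annotation

Polyadenylation signals are scanned on the *sense strand* in a window
upstream of the cleavage site: the default motif set is AATAAA (the
canonical PAS, typically 10–40 nt upstream), ATTAAA (its most common
variant) and TGTA (the DNA-strand form of the UGUA element bound by
cleavage factor I / NUDT21). The default window is 100 nt — wide enough
to cover both the canonical PAS placement and upstream UGUA elements —
and both window and motif set are caller-overridable. All occurrences
are reported, including overlapping ones; offsets count from the motif's
first base to the cleavage base. Equivalence with an exhaustive
all-substring scan is tested on 1,000 random 200-mers. Minus-strand
windows are extracted from the genomic FASTA and reverse-complemented
before scanning, keeping genome handling at the I/O edge.

Track overlap uses 0-based half-open semantics on both sides (an
interval ending at 200 does not touch one starting at 200) and requires
at least 1 nt of intersection; a stranded mode additionally requires
strand agreement, with `*` matching either. Results are verified against
an $O(n \cdot m)$ brute-force scan on 1,000 × 1,000 random intervals.

User-facing range queries are typed as `chrom:start-end` with 1-based
inclusive coordinates (how coordinates are printed), converted
internally; a site matches when its cleavage position lies inside.
Unknown query keys are returned in an `unmatched` report, never silently
dropped.

# The synthetic-data generator

`gen_usage()` emulates a quantified usage matrix with known truth:
per-feature baselines uniform on $[0.2, 0.8]$ (keeping room for shifts
without immediate boundary clipping), i.i.d. gaussian noise per sample
(default sd 0.1, a typical between-sample spread for usage indices),
and an injected mean difference `delta` (group 1 minus group 2) for a
fraction of features. Values are clipped to $[0,1]$ after noising;
clipping slightly compresses extreme means, which is acceptable because
the recovery checks use tolerant bands. Defaults — 500 features, 30
samples per group, 20% affected, `delta = -0.3` — represent a
moderately powered two-cohort comparison. Generation is fully seeded
and byte-deterministic; values are rounded to 6 decimals so fixture
files round-trip losslessly.

`gen_coupled_expression()` makes expression linear in usage on a
TPM-like scale (intercept 50, slope 100), with the noise variance solved
from the target correlation
($\sigma_\varepsilon = |a|\,\sigma_u\sqrt{1/r^2 - 1}$); clipping at 0 is
rare on this scale. `gen_coupled_survival()` draws exponential times
with log-hazard proportional to standardized usage (per-SD hazard ratio
`hr`) and independent exponential censoring at rate
$\lambda_0\,c/(1-c)$, which censors roughly the fraction $c$ under the
null.

What the generator does *not* emulate: compositional coupling between
isoforms beyond the two-isoform complement, coverage-dependent
missingness (missing cells are uniform), overdispersed or multimodal
usage, batch effects, and correlated features. Passing the recovery
tests therefore demonstrates the statistical machinery is correct under
clean conditions, not that real QAPA/DaPars output will be as well
behaved.

# Numerical and interface choices

* Suffix-based sample-column detection (`…_TPM`/`…_PAU`/`…PDUI`,
  case-sensitive terminal token) follows how the quantifiers label their
  outputs; mandatory columns are matched against documented synonyms
  because header spellings vary between versions.
* Decimal parsing is strict (`.` only, UTF-8/ASCII) for determinism.
* The DaPars distal site is placed at the 3'UTR locus end on `+` and the
  locus start on `-`; the predicted proximal coordinate is taken as-is.
* The project bundle written by `apa_ingest()` is a plain directory of
  TSVs plus a JSON manifest (counts, checksums) — transparent,
  diff-able, and trivially versionable; no binary container. Identical
  invocations produce byte-identical outputs, which the tests assert.
* CLI exit codes: 0 success, 1 user error (arguments, missing paths),
  2 data error (parse or analysis failures).

Problem sizes in the test suite were chosen to make each check sharp but
quick: exhaustive Mann–Whitney enumeration up to 8 + 8, 1,000-instance
brute-force equivalence for motifs and overlaps, 500-feature /
30-per-group recovery for the differential module, 1,000 null
replicates at 50 per group for the log-rank type-I rate, and 1,000
replicates for band coverage. The whole suite runs in about a minute.

# Known limitations

* Internal (intronic) APA is out of scope: only 3'UTR sites are
  modelled.
* No covariate adjustment in differential usage or survival; no paired
  designs; no post-hoc tests after Kruskal–Wallis.
* The distal-share convention for multi-isoform genes discards internal
  site structure.
* The O/E hazard-ratio estimate is biased toward 1 in small samples
  relative to a Cox fit; it is reported as a descriptive companion to
  the log-rank p-value, not as a modelled effect.
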