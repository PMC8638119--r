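---
title: "Methods: stratified alternative-splicing analysis with spliceStrata"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified alternative-splicing analysis with spliceStrata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Splicing factors are frequently dysregulated in tumors, and a natural
question for a bulk RNA-seq cohort is whether the expression level of one
driver factor (for example SF3B1 in pancreatic ductal adenocarcinoma)
reorganizes the downstream alternative-splicing landscape. spliceStrata
implements that analysis as a reusable, fully testable pipeline:

1. derive a catalog of **local alternative-splicing events** from a
   transcript annotation, classified into the seven canonical types —
   skipped exon (SE), mutually exclusive exons (MX), alternative 5'/3'
   splice site (A5/A3), retained intron (RI), alternative first/last exon
   (AF/AL);
2. quantify each event's **percent spliced in** (PSI, $\Psi$) per sample
   from transcript-level TPM abundances;
3. **stratify samples** into low / intermediate / high driver expression
   with a univariate equal-variance Gaussian mixture on TMM-normalized
   expression;
4. call **differential splicing** ($\Delta\Psi$ with rank-sum tests and
   Benjamini–Hochberg control) between the high and low strata;
5. compare the per-sample **splicing-event composition** between strata
   using a relative-frequency statistic;
6. optional **associations**: gene–gene rank correlations, hypergeometric
   gene-set over-representation with a gene-ratio summary, and an
   immunohistochemistry combined score.

Because cohort-scale patient data cannot ship with a package, a
synthetic-cohort generator with planted ground truth stands in for the
data at every stage, and the test suite scores the pipeline against that
truth.

# Event detection

Events are detected per gene by pairwise isoform comparison in
*transcription-order space*: minus-strand exons are mapped through
$x \mapsto -x$, so 5'→3' always runs left to right and one set of rules
covers both strands. A junction is a (donor end, acceptor start) pair.

* **SE** — a junction chain $(d_1,a_1),(d_2,a_2)$ in one form versus the
  skip junction $(d_1,a_2)$ in the other; inclusion = the exon-containing
  form.
* **MX** — two chains sharing outer endpoints with disjoint middle exons,
  each exclusive to one form; inclusion = the form whose middle exon is
  5'-most.
* **A5 / A3** — two donors sharing an acceptor (or two acceptors sharing
  a donor) where the variable-side exons overlap; inclusion = the
  longer-exon (proximal-intron) form.
* **RI** — one exon spanning exactly an exon–intron–exon triple of the
  other form; inclusion = the intron-retaining form.
* **AF / AL** — non-overlapping first (last) exons joined to a common
  acceptor (donor); inclusion = the form whose variable exon is 5'-most.

Inclusion-form conventions are fixed per type because PSI needs a
deterministic orientation; the choices above follow the de-facto
conventions of ioe-style event catalogs. Events are deduplicated by
coordinate signature, all compatible transcripts are pooled into each
form's set, and the output ordering (gene, type, coordinates) makes runs
byte-identical.

A note on symmetry: flipping only the *strand label* of an annotation
swaps A5↔A3 and AF↔AL (the same splice sites read in the opposite
transcription order), and the test suite asserts exactly that. Mirroring
coordinates *and* flipping strand is the reverse-complement view and
preserves every label — the two operations are easily conflated, so the
oracle used in the tests is the strand-label flip.

# PSI quantification

$$\Psi_{e,s} = \frac{\sum_{t \in \mathrm{inclusion}(e)} \mathrm{TPM}_{t,s}}
                    {\sum_{t \in \mathrm{total}(e)} \mathrm{TPM}_{t,s}}$$

Events with total-form TPM below `min_total_tpm` (default **1 TPM**) in a
sample are *missing*, not zero: PSI ratios are unstable at low
expression, and a 1-TPM floor is the conventional default for an
expression filter that upstream PSI tools leave unstated. Missing values
propagate; they are never imputed, because imputation would fabricate
signal in the composition statistic. `filter_psi()` drops events missing
in more than `max_missing_frac` (default **0.2**) of samples.

# TMM normalization and mixture stratification

Gene-level expression is normalized by the trimmed mean of M-values:
per-sample factors are weighted means of gene-wise log2 ratios against a
reference sample (upper-quartile closest to the mean upper-quartile),
after removing genes zero in either sample and double-trimming by M
(default 30% per tail) and by average log-abundance A (default 5% per
tail), with inverse asymptotic-variance weights; factors are rescaled to
geometric mean one. The implementation is validated against
edgeR's `calcNormFactors(method = "TMM")` to 1e-8 in the test suite.

The driver gene's normalized per-million expression is transformed to
`log2(x + 1)` — mixtures of Gaussians are a reasonable description on
that roughly symmetric scale — and fitted with a univariate
**equal-variance** Gaussian mixture for $G = 1..5$ components. Each $G$
gets eight deterministic EM starts (quantile-spread means plus seeded
perturbations); each start runs a capped 75-iteration EM and the best
start is polished to convergence (relative log-likelihood change
$< 10^{-8}$, at most 500 iterations). The reported fit minimizes
$\mathrm{BIC} = -2\,\ell + 2G\log n$ ($G$ means, $G-1$ weights, one
shared variance). $G$ is *selected*, not fixed: on well-separated
three-group data the selection is 3 in ≈99% of seeds, which is what the
acceptance suite asserts.

Samples map to components by maximum posterior (ties toward the
lower-mean component); the lowest-mean component is "low", the
highest-mean "high", the rest "intermediate". Downstream tests use only
the low and high strata; intermediate samples are carried but excluded.

A calibration note: at $n = 94$ with component sd 0.5 and weights
(0.3, 0.4, 0.3), the sampling error of a component mean is
$\approx 0.5/\sqrt{28} \approx 0.095$, so demanding all three fitted
means within ±0.15 of the *generating* truth jointly succeeds only
$\approx 0.886^3 \approx 0.69$ of the time — even for an oracle given
the true labels. The parameter-recovery test therefore compares the EM
estimates to those oracle (true-label) sample means, which is the part
an estimator can control; agreement there exceeds 95%.

# Differential splicing

Per event, $\Delta\Psi$ = mean $\Psi$(high) − mean $\Psi$(low) over
non-missing samples. Significance uses a two-sided Mann–Whitney rank-sum
test (normal approximation with tie and continuity correction) —
distribution-free and standard for bounded quantities like $\Psi$ — with
Benjamini–Hochberg adjustment across tested events. Events with fewer
than `min_per_group` (default **5**) non-missing values in either
stratum are excluded from testing and reported with missing p-values. An
event is *significant* when adjusted p < `alpha` (default **0.05**,
applied to the adjusted value; the raw p is also reported) and
$|\Delta\Psi| \ge$ `min_dpsi` (default **0.1**, a conventional
effect-size floor). The rank-sum approximation is validated against
exact permutation p-values (all label assignments at $n \le 8$ per
group, agreement within ±0.02), and BH against the step-up formula
directly.

# Composition profiles

Per sample, the relative frequency of event $i$ is
$\mathrm{rf}(i) = \Psi_i / \sum_j \Psi_j$ over the sample's non-missing
events; summing rf over the events of each type gives the sample's
7-type composition profile (an exact partition, summing to one).
Profiles are compared between strata per type with a two-sided rank-sum
test and a two-sample Kolmogorov–Smirnov test at p < 0.05. The default
significance rule is rank-sum p < alpha with the KS p reported alongside
(rank-sum is the location test; KS adds shape sensitivity); a
`require_both` switch demands both. No multiplicity adjustment is
applied across the seven types by default, matching a raw-cutoff
convention; `bh_across_types` switches it on. `event_type_spectrum()`
summarizes counts/percentages per type for "all detected" versus
"significant" event sets.

# Associations

* `correlate_genes()` — Spearman rank correlation (exact p for
  $n \le 9$ without ties, t-approximation otherwise), chosen over
  Pearson for robustness to heavy-tailed expression scales; the method is
  recorded in the output metadata.
* `hypergeometric_ora()` — upper-tail hypergeometric p for query hits in
  each user-supplied gene set (GMT), BH across sets, and the gene ratio
  hits / (in-universe set size). No pathway database content is bundled
  (version drift and licensing); sets are user inputs.
* `ihc_combined_score()` — percentage-positive bin (0; (0,25]; (25,50];
  (50,75]; (75,100] mapping to 0–4) × intensity (0–3), range 0–12.
  Non-integer percentages fall in half-open bins; the printed bin labels
  are integers, so the boundary convention is this package's choice.

# The synthetic cohort: what it emulates, and what it does not

`generate_annotation()` plants one two-isoform gene per requested event
(default 10 per type) on non-overlapping windows, half on each strand;
the truth catalog is built from the templates, so
`detect_events()` must reproduce it *exactly* — the generator is the
detection oracle. `generate_cohort()` then simulates, per seed:

* driver expression from the 3-component equal-variance mixture —
  defaults **means (2, 5, 8)** log2 per-million units, **sd 0.5**,
  **weights (0.3, 0.4, 0.3)** at **n = 94** samples: a separation at
  which BIC cleanly recovers three groups, emulating a ~94-sample tumor
  cohort with a trimodal driver;
* per-event baseline $\Psi \sim U(0.2, 0.8)$; a fraction
  (`shifted_fraction`, default **0.5**) of each type's events get a
  high-stratum target of baseline ± **0.3** (`delta_psi_effect`, kept
  inside [0.05, 0.95]); the shift *direction* per type follows the sign
  of `composition_bias` — defaults +SE, +A5, +A3 / −MX, −AF, −AL, RI
  neutral, the qualitative pattern reported for high- versus low-driver
  tumors;
* realized $\Psi$ = logit-normal noise (sd **0.05** on the logit scale,
  the noise level at which the documented power simulations are stated)
  around the stratum target; logit-normal keeps $\Psi$ in (0,1);
* transcript TPMs split each gene's abundance (log-normal across genes,
  20% per-sample jitter) between the inclusion and exclusion isoforms by
  realized $\Psi$; gene-level counts are Poisson draws at library sizes
  uniform in **2–5 million**, with filler genes padding the matrix to
  `n_genes` (default 300) so TMM has a stable background.

What a green test establishes: the pipeline recovers planted catalogs
exactly, strata with ≥90% agreement, ≥90% of 0.3-shifted events at
adjusted p < 0.05 with ~5% raw type-I error on nulls, and every planted
composition direction. What it does not establish: robustness to
empirical features the generator lacks — overdispersed counts, correlated
events within genes, isoforms shared across events, partial annotations,
batch effects, or realistic genome coordinates. Those require real
cohorts.

# Numerical and design choices

* Coordinates are 1-based inclusive (GTF dialect) throughout; junctions
  are (donor end, acceptor start) pairs.
* EM asserts log-likelihood monotonicity at every iteration and fails
  loudly rather than returning a silently degraded fit; all-equal input
  is a degenerate-variance error.
* Posterior ties in stratum assignment break toward the lower-mean
  component; BH output is capped at 1 and monotone-enforced.
* All tables are TSV with `NA` for missing values and `#` comment
  headers; writes are atomic (temp file + rename); every stage logs
  package version, config hash, seed and input checksums, and derives
  its own seed from the master seed and stage name so stages can be
  rerun independently.
* Known limitations: event detection targets binary local events (a
  three-way alternative donor yields pairwise events, which is the
  ioe-style convention); PSI from transcript abundances inherits any
  quantification bias of the upstream TPM estimates; the composition
  statistic is compositional, so a strong shift in one type necessarily
  moves the others — directions, not magnitudes, are the tested claim;
  at default settings a neutral type (RI) can still reach nominal
  significance through that renormalization, which is a property of the
  statistic, not a bug.
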