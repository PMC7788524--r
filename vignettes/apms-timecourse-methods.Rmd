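---
title: "Methods: discovering bait interactors from AP-MS time courses"
author: "apmsTimeCourse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering bait interactors from AP-MS time courses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apmsTimeCourse)
```

# The problem

Affinity-purification mass spectrometry (AP-MS) isolates a bait protein —
here modelled on the insulin receptor (INSR), a receptor tyrosine kinase —
together with whatever is bound to it, and identifies the co-purified
proteins by mass spectrometry. Two difficulties dominate the analysis.
First, immunoprecipitation co-isolates abundant sticky proteins, so a large
fraction of identifications are background rather than genuine partners.
Second, signalling interactions are dynamic: a partner may be recruited
within minutes of ligand stimulation and released again, so a single
snapshot misses it. This package implements a complete desk-side workflow
for such experiments: a literature interactome with an evidence-based
confidence score, label-free time-course quantification filters,
contaminant-frequency categorisation, anchored temporal clustering,
fold-change/significance shortlisting, and one-hop network expansion — all
exercisable end to end on a synthetic data generator with known ground
truth.

# The literature interactome and its confidence score

Two database exports are merged by **union**: a BioGRID-style evidence table
(one row per experimental observation) and a STRING-style links table.
Union, never intersection, so an interaction reported in only one source is
retained. Partners appearing only in the links table carry no experimental
evidence rows; they receive a single synthetic evidence record of type
`other` with string-style provenance, and the links-table combined score is
kept as provenance only — it does not enter the confidence score.

The confidence score is banded by the amount of evidence:

| band   | evidence records | score range |
|--------|------------------|-------------|
| low    | 1                | 0.1–0.3     |
| medium | 2–3              | 0.4–0.6     |
| high   | >3               | 0.7–0.9     |

The banding follows the categories of admissible experiment types
(affinity-capture MS and yeast two-hybrid at one record; plus
affinity-capture immunoblot, resonance-energy transfer, and
kinase/phosphatase activity at two to three; plus crystal-structure
reconstituted complexes above three). Within each band the published scheme
leaves the exact value open, so the package fixes a deterministic, monotone
map: one record scores 0.2 (0.1 when it is only links-table provenance —
absent experimental evidence is minimal confidence); two records score 0.4
and three 0.5, with +0.1 (capped at 0.6) when enzymatic evidence is present;
four to five records score 0.7, six to nine 0.8, and ten or more — or any
crystal structure — 0.9. Monotonicity (more evidence never lowers the
score) and band consistency are asserted property-style in the tests.

The spoke network places one node per partner, every edge incident to the
bait, rings 1/2/3 assigned to high/medium/low confidence, node size equal to
the evidence count, and a throughput flag for the node border. Whether
"amount of evidence" should count publications or experiment rows is not
decidable from the published description; the package counts distinct
evidence records.

# Quantification tables and acceptance filters

The canonical dialect mirrors a Progenesis-style protein-measurement export:
protein rows with peptide counts (and, when a Scaffold-style search
validated them, peptide/protein probabilities), and one MS1 abundance column
per run named `t<minutes>_rep<k>`. Missing abundances are `NA`, never
silent zeros.

Two acceptance filters are applied exactly at their boundaries, both
inclusive:

* **identification**: at least 2 unique validated peptides, each with
  probability ≥ 0.90, and protein-level probability ≥ 0.99. Tables without
  probability columns (the Progenesis-style case) enforce only the
  peptide-count rule, with a logged warning; a strict mode raises the
  peptide minimum to 3.
* **quantification**: at least 3 quantified peptides per protein.

Normalisation is median-of-ratios on the log2 scale: the pseudo-reference is
the per-protein geometric mean across runs (over anchor proteins with
complete data), each run's factor is its median log-ratio to that reference,
and factors are re-anchored so the first run's factor is zero. The
re-anchoring makes the transform exactly idempotent and exactly invariant to
multiplying any run by a positive constant, and the per-run median
log-ratio to the stored reference is zero by construction. Downstream
statistics operate on log2 normalised abundances. A protein–time-point cell
enters statistics only when at least two replicates are present; there is no
imputation by default.

# Temporal clustering anchored on known binders

Profiles are built per protein as the per-time-point replicate means of the
z-scored log2 normalised abundances (four ordered values for 0/2/7/15 min).
Constant (zero-variance) profiles cannot be standardised; they are excluded
and listed separately.

The dissimilarity is $d = 1 - r$ with $r$ the **uncentred Pearson
correlation** — the cosine $\sum x_i y_i / (\|x\|\,\|y\|)$, i.e. correlation
without mean subtraction, sensitive to shared direction from the origin.
Agglomeration uses **complete linkage** (inter-cluster distance is the
maximum pairwise member distance), which guarantees monotone merge heights.
The agglomerative routine is authored in the package because determinism
matters here: clusters are identified by their lexicographically smallest
member label and, among candidate merges at the minimal distance, the pair
whose sorted label pair is smallest merges first, so the tree is invariant
to input row order. `stats::hclust` on the same dissimilarity serves as an
independent oracle in the tests (equal merge heights and partitions on
fixtures up to 12 profiles), never as the implementation.

Cluster extraction is anchored: for each known bait binder present in the
data the tree is cut at height $1 - r_{\min}$ (default $r_{\min} = 0.7$) and
the binder's cluster reported. The published procedure is ambiguous on
whether 0.7 bounds the anchor–member correlation or all pairwise
correlations; the package cuts the tree and then post-filters members on
anchor correlation, so the stated guarantee — every reported member has
$r \ge 0.7$ with its anchor — holds under either reading. Clusters from
distinct anchors may overlap and are reported separately.

# Differential recruitment and the candidate filters

Fold changes are computed per protein and stimulated time point as the
difference of mean log2 abundances against the unstimulated baseline
(time 0). Significance is assessed two ways and both are reported: a
classical one-way ANOVA (equal-variance F test) across the four time-point
groups — one p per protein, the time-course test named in the study design
and the statistic the mirrored quantification software exports — and a
per-time-point Welch two-sample t-test against baseline. Welch is used
because replicate variances are not assumed equal. Degenerate cells
(zero variance everywhere, or fewer than two replicates) report a
not-evaluable `NA`, never 0. Raw p-values are the default, matching common
reporting practice for this workflow; Benjamini–Hochberg adjustment is
available as an option.

The filter cascade shortlists a protein when it has enough unique peptides
(2, or 3 in strict mode), is no worse than the allowed contaminant category
(default `<=10%`), and at one or more stimulated time points is evaluable
with $|\log_2 FC| \ge 1$ and $p \le 0.05$. The published criteria name the
filters but not the fold-change or p thresholds; the defaults here are
conventional proteomics choices, all exposed in the configuration. The
significance criterion defaults to the per-protein ANOVA p (`pSource =
"anova"`); the per-time-point t-test is selectable. The ANOVA default
follows the study's own framing — comparing means of more than two samples
is an ANOVA question, the t-test being reserved for two-sample comparisons —
and, at three replicates, retains usable power; the t-test alternative is
materially more conservative at this design size.

Temporal classes label the passing pattern: `early`, `intermediate` and
`late` for single passing points at 2, 7 and 15 min; `dissociating` when
every passing point has negative fold change; for multiple positive passing
points the class is the latest passing point when the fold changes are
monotone non-decreasing, otherwise `mixed`. The monotone tie rule matches
the natural narrative assignment of progressively recruited partners to the
latest time point.

# Contaminant-frequency categories

The contaminant repository records, for each protein, in how many
negative-control AP-MS experiments it was detected, out of a total of 411
in the reference snapshot. Detection frequency is expressed as a percentage
and bucketed into three tiers: counts 0–4 (`<=1%`), 5–41 (`<=10%`) and
42–411 (`<=100%`). For repositories of other sizes the boundaries re-derive
from the same percentage rule (the largest counts not exceeding 1% and 10%),
which leaves the reference values unchanged at a total of 411. Proteins
absent from the repository count as never observed but carry an `absent`
flag, since absence of evidence is weaker than evidence of absence; the
category is an optional filter criterion rather than a hard rule, matching
its published role of guiding rather than deciding the shortlist.

# One-hop expansion

Known interactors detected in the dataset seed a one-hop expansion against a
local interaction edge table: every non-seed dataset protein adjacent to at
least one seed joins the network, capped at 500 nodes in total. The
published analysis used a live database search with a 500-protein limit per
search; this package requires a local edge-table snapshot instead, because
live queries are version-unstable and untestable, and reads the limit as an
output cap with documented truncation: expansion nodes are dropped in
ascending order of (seed-neighbour count, then summed edge weight to seeds),
lexicographically larger identifiers first, so the best-connected nodes
survive and the result is deterministic. Contaminant categories are then
overlaid on every node to separate likely background from candidate novel
partners.

# The synthetic data generator

The generator emulates the study conditions: a bait pulled down over an
insulin-stimulation time course of 0/2/7/15 minutes, three replicates per
time point, label-free MS1 quantification. It does **not** simulate raw
spectra, peptide sequences, chromatographic alignment or search-engine
scoring — its output enters the pipeline where a Progenesis/Scaffold-style
export would.

Per-protein baseline log2 abundance is Normal(20, 2) — a typical MS1
intensity scale spanning roughly three orders of magnitude. Five classes
with proportions 0.10 / 0.05 / 0.05 / 0.40 / 0.40 follow the qualitative
recruitment patterns of bait time-course AP-MS, with mean shifts in
multiples of the effect size $e$ (default $e = 2$, i.e. four-fold):

* `progressive_association`: $(0, e/3, 2e/3, e)$ — rising to full effect;
* `early_transient`: $(0, e, e/3, 0)$ — peak at 2 min, gone by 15;
* `dissociating`: $(0, -e, -e, -e)$ — released upon stimulation;
* `flat_specific` and `contaminant`: $(0, 0, 0, 0)$.

Replicate noise is i.i.d. Normal(0, 0.5) on the log2 scale (multiplicative
on the raw scale). Class proportions convert to integer counts by
largest-remainder rounding, so stated proportions are met exactly.
Contaminant-class proteins receive repository counts uniform in [42, 411]
(the highest category); all others in [0, 4]. Unique peptide counts are
3 + Poisson(3), quantified counts add Poisson(2); a planted 10% of the
flat-specific and contaminant classes is forced below the 2-/3-peptide
thresholds so the acceptance filters are exercised. The low-peptide planting
deliberately avoids the temporal-signal classes: those model genuine,
well-sampled interactors, so the generator's recovery properties measure the
statistical filters rather than identification dropout. An optional per-cell
dropout probability (default 0) exercises the not-evaluable paths. The same
seed yields byte-identical output.

What passing tests on this generator do and do not show: they verify the
pipeline's decision rules, determinism and statistical calibration under a
clean multiplicative-noise model. Real AP-MS data additionally exhibit
intensity-dependent variance, correlated missingness, shared peptides,
ratio compression and batch structure, none of which the generator
emulates; conclusions about real-data sensitivity should not be read off
the recovery rates.

# Numerical choices and problem sizes

* Scores, percentages and correlations are plain doubles; cosine
  similarities are clamped to $[-1, 1]$ and distances below $10^{-12}$
  snapped to zero so exact duplicates merge at height exactly 0.
* Linkage ties break lexicographically (see above); candidate tables sort
  by best p, then descending |log2 FC|, then identifier.
* The ANOVA null-calibration check uses 2000 simulated null proteins —
  large enough that the binomial 99% band around a 5% type-I rate is about
  ±1.3 points; the recovery check uses the default 200-protein dataset; the
  clustering oracle runs on fixtures of up to 12 profiles, where exhaustive
  comparison is exact. These sizes keep the whole suite in well under a
  minute of compute while leaving the checks statistically meaningful.
* The permutation cross-check of the ANOVA p uses $10^5$ draws; at that
  depth Monte-Carlo error is ~0.004 on the probability scale, and the
  residual gap between the permutation null and the F distribution at
  $n = 12$ motivates the 0.02 comparison tolerance.

# Known limitations

* Identifier harmonisation is by upper-cased gene symbol with numeric taxon
  prefixes stripped; paralogue ambiguity and true cross-species orthologue
  mapping are out of scope.
* The evidence-confidence scheme is rule-based; it does not re-weigh
  publication quality or experiment redundancy within a category.
* Gene-ontology and pathway enrichment of networks and shortlists are
  deliberately delegated to external tools.
* The spectral-count table is carried as supporting metadata only; all
  statistics run on MS1 intensities.
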