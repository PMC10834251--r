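---
title: "Splicing dysregulation as a cross-dataset biomarker: models and methods"
author: "spliceshift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Splicing dysregulation as a cross-dataset biomarker}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceshift)
library(SummarizedExperiment)
```

# The problem

CAG-repeat-expansion spinocerebellar ataxias (SCA1, 2, 3, 7, 17) are
dominantly inherited neurodegenerative diseases. Across mouse models of
these diseases, bulk RNA-seq of cerebellum, brainstem and other brain
regions shows a recurrent signature: cassette (skipped) exons whose
inclusion level shifts between disease and wild-type animals.
`spliceshift` implements the quantitative machinery needed to treat
that signature as a biomarker: PSI estimation from junction counts,
differential-splicing calls under dual significance thresholds,
cross-dataset harmonization of events, a four-way classification of
therapeutic rescue, and allele-specific expression for knock-in models
carrying one expanded and one wild-type allele. A seeded simulator
generates multi-dataset junction-count studies with ground truth so the
whole pipeline is testable without any sequencing download.

# PSI and the differential test

For one event in one replicate, with inclusion-junction reads $I$,
skipping-junction reads $S$ and effective form lengths $l_I, l_S$:

$$\psi = 100\cdot\frac{I/l_I}{I/l_I + S/l_S}.$$

In junction-count mode a cassette exon offers two inclusion junctions
and one skipping junction, hence the defaults $l_I = 2$, $l_S = 1$;
ingested tables carry their own per-event lengths, which are used
verbatim. A replicate's PSI is reported only when its coverage
$I+S$ reaches the floor (`min_coverage`, default 10 reads); an event
needs at least two covered replicates per group to be tested, and
untested events are excluded from the multiple-testing denominator.
Group PSI is the unweighted mean of per-replicate PSI (matching how
ingested tables average their inclusion levels), and
$\Delta\mathrm{PSI}$ is case minus control, in percentage points.

The test statistic is $|\bar\psi_2 - \bar\psi_1|$. When the number of
group-label assignments $\binom{n_1+n_2}{n_1}$ is at most 20,000 the
permutation null is enumerated exactly and the p-value is the exact
proportion of assignments reaching the observed statistic; otherwise
`n_perm` Monte-Carlo shuffles are drawn with the supplied seed and the
add-one correction $(k+1)/(n_\mathrm{perm}+1)$ keeps $p > 0$.
Statistics that are mathematically tied (an assignment and its
complement always are) are compared with a $10^{-9}$ tolerance so
floating-point summation order cannot break exact ties. False-discovery
rates are Benjamini–Hochberg, computed across the tested events of one
event type within one comparison.

Two significance rules are applied, all inequalities strict:

* **primary**: FDR $< 0.1$ and $|\Delta\mathrm{PSI}| > 10$ percentage
  points;
* **secondary**: $p < 0.05$ and the same $\Delta$PSI threshold.

A consequence of the exact permutation null worth knowing: with 4
replicates per group there are only 70 assignments, the statistic is
complement-paired, and the smallest attainable p-value is $2/70
\approx 0.029$. The test is therefore *conservative* at
$\alpha = 0.05$ (its null rejection rate is $1/35$, not $0.05$), and
FDR-level detections require a sufficient mass of true signals so that
the BH threshold clears the p-value floor. Real studies, with hundreds
of truly dysregulated exons among the tested events and a likelihood
test with a continuous null, do not face this granularity; the
simulator's power analyses do, and the package's calibration tests
assert the discrete null rate exactly rather than pretending the test
is uniform.

# Study gate and cross-dataset analysis

Detecting splicing events requires reads that span exon–exon junctions,
so sensitivity depends directly on depth. Studies enter the
meta-analysis only when a comparison's average read depth strictly
exceeds 35 million reads (`readDepthFilter`; ties fail). The bundled
survey table reproduces the published inventory of SCA mouse RNA-seq
studies:

```{r gate}
gate <- readDepthFilter(scaDatasetTable(), 35e6)
length(gate$passing_studies)
gate$n_comparisons
```

Events are matched across datasets by a canonical key built from event
type, chromosome, strand and the complete coordinate tuple — never by
gene symbol, so the same cassette exon in two different flanking-exon
contexts stays two events. `sharedEventCounts` produces the
upset-style membership matrix and the sharing-degree histogram;
`selectShared` extracts events dysregulated in $\ge d$ datasets.

`psiPca` runs PCA on a shared-event PSI matrix with samples as
observations. Design choices, made where the upstream analysis left
them open: missing cells are imputed with the event's mean over
observed samples (preserves between-sample contrasts on the observed
cells), events are centered but *not* variance-scaled (PSI already
shares the 0–100 scale), and each component's sign is fixed by forcing
its largest-magnitude loading positive so results are reproducible
across BLAS implementations.

# Rescue classification

For an event significantly dysregulated between control and disease,
with a treated condition available, percent rescue is gap-normalized:

$$\mathrm{rescue} = 100\cdot
  \frac{\psi_\mathrm{treated}-\psi_\mathrm{disease}}
       {\psi_\mathrm{control}-\psi_\mathrm{disease}}.$$

This is the only reading consistent with rescue magnitudes like 78%
reported alongside raw PSI shifts far smaller than 78 points: +100
means full restoration of the control PSI, 0 no change, negative a
shift away from control. The four-way classification applies, in
order: no treated value → `no_information`; treated-vs-disease shift
of at most 5 PSI percentage points → `non_rescue` (the minimum-shift
gate precedes direction); percent rescue > 10 → `rescued`; percent
rescue < −10 → `opposite_effect`; otherwise `non_rescue`. The "5%" in
the shift gate is PSI percentage points; the "10%" thresholds are in
percent-rescue units. A control-equals-disease gap is an error by
construction, because classification is only applied to events already
significant in the control-vs-disease comparison.

```{r rescue}
classifyRescue(30, 60, 36.6)
```

# Allele-specific expression

Knock-in models carry one wild-type (e.g. 2Q) and one expanded
(e.g. 154Q) allele whose transcripts differ by the repeat length plus a
handful of substitutions. `buildAlleleReference` records the
discriminating sites from a pairwise alignment: one site per
substitution column, and one site per maximal gap run anchored at its
first column — so a long repeat indel counts once, not once per base.
`validateReference` enforces the window rule: every read-length window
fully inside the discriminating span must cover at least `min_sites`
sites (default 3). When the span is shorter than the read there is no
such window and the reference is trivially valid; reads elsewhere are
protected by the assignment rule itself, which refuses to assign any
read covering fewer than `min_sites` informative sites. Assignment
demands consistency at *every* covered site; a read matching neither
allele at all covered sites is `unassigned`.

Indel sites store the anchor base of each allele; when those anchor
bases coincide the site still counts as a sequence difference for the
window rule but is uninformative for point comparison. The read
simulator therefore requires substitution-only (colinear) references,
where offsets are shared between the two framings — the configuration
the tests and acceptance checks use.

Abundances use standard TPM
($\mathrm{TPM}_i = 10^6 (c_i/\ell_i)/\sum_j c_j/\ell_j$), summarized
per condition as mean ± standard error; `relativeReduction` and
`log2FoldChange` express allele contrasts, and `deltaDeltaCt`
implements the RT-qPCR $2^{-\Delta\Delta C_t}$ utility.

# Gene-set over-representation

The functional stage is a self-contained hypergeometric
over-representation test over user-supplied GMT sets: population =
background, successes = set ∩ background, draws = query, p =
$P[X \ge k]$, BH across sets. The background should be the genes
carrying at least one testable event in the comparison, not the whole
genome. Symbols are matched upper-cased. This replaces web-service
enrichment with something reproducible offline; real GO collections
can be supplied as GMT files.

# The simulator

`simulateStudy` emulates the statistical structure the analysis
assumes, with all randomness flowing from one seed through per-dataset
streams (each dataset is reproducible in isolation):

* **events**: five types with SE predominance (default fractions
  0.6/0.1/0.1/0.1/0.1), random coordinates satisfying the cassette
  layout;
* **baseline PSI**: per-region Beta distributions, so
  region-specific inclusion profiles (such as an exon mostly included
  in one brain region and nearly constitutive in another) can be
  configured;
* **effects**: a configurable fraction of events is affected with
  $|\Delta\mathrm{PSI}|$ = `effect_size` (default 20 pp), direction
  random, scaled per dataset by repeat-length and age multipliers
  (short-repeat controls get multiplier 0); affected events are
  either shared across all datasets or specific to one;
* **replicate scatter**: $\psi_\mathrm{rep}\sim
  \mathrm{Beta}(\mu\kappa,(1-\mu)\kappa)$ with $\kappa = 100$,
  about ±4 pp at $\psi = 0.5$ — a qualitative calibration to typical
  violin spreads, a tunable rather than a claim;
* **counts**: totals $n \sim \mathrm{Poisson}(\mathrm{coverage})$,
  inclusion reads $I \sim \mathrm{Binomial}(n, q)$ with
  $q = \psi l_I/(\psi l_I + (1-\psi)l_S)$, which inverts the PSI
  estimator exactly so the estimator is unbiased by construction;
* **treatment arm**: true treated PSI is
  $\psi_\mathrm{disease} + r(\psi_\mathrm{control} -
  \psi_\mathrm{disease})$ for rescue fraction $r$ (default 0.8).

Defaults mirror the surveyed studies where they state a value
(3–4 replicates per group; junction coverage in the tens to hundreds
of reads, default 200) and field-typical values elsewhere.

What the simulator does *not* model: read-level sequencing (no FASTQ),
GC/length biases, batch effects between datasets, correlated events
within genes, or differential gene expression. Passing tests on
simulated data therefore demonstrate the correctness and calibration
of the estimators and decision rules under the stated generative
model, not robustness to every artefact of real libraries.

## Problem sizes used in validation

The package's validation experiments use: 2,000 events (4 vs 4
replicates, coverage 200) for null calibration; 1,000 events with
half affected at $|\Delta\mathrm{PSI}| = 30$ pp for detection power —
a balanced power-evaluation design that estimates the detection and
false-positive rates from a single run and supplies enough true
signals for the BH threshold to clear the exhaustive-permutation
p-value floor discussed above; 500 events at coverage 5,000 for
estimator accuracy, where estimated PSI is compared with the
*realized* replicate-level $\psi$ that generated the counts (the
quantity the estimator actually estimates; comparing with the
condition mean would measure the configured replicate dispersion, not
accuracy). Accuracy there is ~99% of cells within 2 pp. The rescue
truth-table check enumerates the full 0.5-pp grid over
$[0,100]^3$ with gap $\ge 10$ (about 6.6 million triples).

# Worked example

```{r example}
cfg <- simConfig(n_events = 300, n_datasets = 2, n_replicates = 4,
                 coverage = 200, affected_fraction = 0.3,
                 effect_size = 25, treatment = TRUE, seed = 7)
sim <- simulateStudy(cfg)
res <- lapply(sim$datasets, diffSplicing, seed = 1)
sig <- lapply(res, function(r)
  r$event_key[r$sig_secondary & r$event_type == "SE"])
sc <- sharedEventCounts(sig)
sc$histogram
head(selectShared(sc, 2))
```

# Known limitations

* The permutation test's discreteness at small replicate numbers
  caps attainable significance (see above); with $n \le 4$ per group
  the primary FDR rule behaves as a cohort-level rule, not a
  per-event one.
* PCA imputation by event means shrinks missing samples toward the
  center; with heavy missingness PC structure can be attenuated.
* Allele read assignment is site-anchored, not a full aligner; it
  presumes reads are placed at their true offsets and, for
  simulation, substitution-only references.
* The enrichment stage tests user-supplied sets only; no ontology
  topology is used.
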