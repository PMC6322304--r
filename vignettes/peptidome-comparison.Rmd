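---
title: "Comparing endogenous peptidomes: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing endogenous peptidomes: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepdegradome)
```

## The problem

Endogenous peptidomics asks what the pool of non-digested peptides in a
sample looks like: which precursor proteins are being proteolysed, where on
the protein the cuts fall, how the pool differs between compartments (here
an intracellular peptidome versus a secretome) and how it responds to a
treatment (here a stress-hormone stimulus applied to a control culture).
Because these peptides arise from degradation rather than targeted
processing, the analysis is statistical throughout: set algebra over
replicated identifications, positional histograms along precursors,
composition and physicochemical screens, and enrichment tests.

This package implements that comparison pipeline end to end, together with
an in-silico proteolysis simulator, so that every stage can be validated
closed-loop against known ground truth without access to any particular
mass-spectrometry dataset.

## The analysis model, stage by stage

**Replicate filtering.** Endogenous pools are heterogeneous between
biological repeats, so a peptide only counts as identified in a
(compartment, condition) group when it is seen in at least `min_repeats`
(default 2) of the biological repeats. "Identified in a condition" always
means "passes this filter there"; the shared set of two conditions is the
intersection of the two filtered sets. The retained set can only shrink as
`min_repeats` grows, which the tests assert as a property.

**Set algebra and treatment response.** Venn partitions of the filtered
sequence sets quantify the treatment-unique pool; among treatment-unique
peptides, those whose precursors contribute no peptide at all to the
control set are counted as coming from *new precursors* — proteolysis of
proteins newly targeted under treatment. The dispersion of the shared
percentage is estimated by recomputing it one biological repeat at a time.
Peptides matching several precursors contribute to every matched
precursor's positional analyses but are counted once in sequence-level set
algebra; counting them per match would inflate the Venn counts.

**Quantification.** Per-peptide intensities are averaged over the observed
repeats (missing values stay missing; they are never zero-filled or
imputed) and fold change is `log2(mean treated / mean control)`, defined
only when both sides have at least `min_repeats` observations. Peptides
seen in only one condition are flagged present-only rather than forced to
an infinite fold change. Cross-condition agreement is summarized by the
Pearson correlation of log10 mean intensities; log-scale correlation is the
default because XIC intensities are lognormal-like over orders of
magnitude (a raw-scale option exists).

**Degradation patterns (PDP).** Each precursor is split into
`n_pdp_windows` (default 10, i.e. 10%-of-length) windows; window *i* covers
residues `floor((i-1)L/n)+1 .. floor(iL/n)`, so windows tile the protein
exactly and differ by at most one residue in width. Counting peptide
*start* positions per window gives the PDP row; the 10% window width is
itself the device that absorbs peptide ladders (families of near-identical
peptides trimmed by a few residues), so no additional ladder collapsing is
applied. Patterns are compared by cosine similarity of unit-sum-normalized
rows; the source analyses report pattern similarity only qualitatively, so
the cosine statistic is this package's own, explicitly labelled choice.

**Composition.** Amino-acid frequencies are pooled over residues
(non-standard residues excluded from numerator and denominator), and
compared per residue with a 2x2 Fisher exact test (residue vs rest),
BH-corrected across the 20 residues — the comparison test is again this
package's choice, since a conclusion without a named test is not
reproducible otherwise. The background set is sampled from protein regions
*not* covered by any observed peptide: observed spans are masked, lengths
are resampled from the observed length distribution and placements are
uniform over the unmasked runs, so a background peptide never intersects an
observed residue. Terminal profiles take the first/last `terminal_k`
(default 5) residues, position 1 being the terminus; per-position
information content is `log2(20) - H` bits.

**Physicochemical screen.** Every peptide is scored on every complete
AAindex1 entry as the mean per-residue value (a homopolymer scores exactly
its residue's value; the statistic is linear under length-weighted
concatenation). The 544-entry AAindex1 release ships with seqinr and is
loaded from there; 13 entries with missing residue values are excluded,
and the usable-index count is reported rather than hard-coded. Each index
is tested between compartments with a two-sided Mann-Whitney U test:
exhaustive enumeration (exact under ties) when both groups are small,
otherwise the tie-corrected normal approximation — with thousands of
peptides per compartment the approximation is the operative path, and the
tests verify both paths against enumeration and `wilcox.test`
respectively. Raw p-values are binned into nested tiers (`sig` p<1e-5,
`sigAA` p<1e-15, `top` p<1e-25); BH q-values are reported alongside
everywhere, but the tiers are deliberately raw-p because that is how such
screens are conventionally summarized.

Indexes are then clustered: profiles across the pooled peptides are
z-scored, distances are Euclidean, linkage is Ward (`ward.D2`), and the
tree is cut into `n_clusters` (default 6) groups. Columns are processed in
lexical accession order so the result does not depend on input order. The
cluster containing the plurality of four canonical hydrophobicity scales
(Kyte-Doolittle KYTJ820101, Eisenberg EISD840101, Fauchere-Pliska
FAUJ830101, Nozaki-Tanford NOZY710101) is labelled the hydrophobicity
cluster, and per-cluster enrichment in the significant-index set is tested
by Fisher's exact test with BH correction across clusters.

**Topology localization.** Peptides are located relative to
TMHMM-style membrane topology segments by majority residue overlap, with an
explicit `mixed` class for exact ties (the assignment rule for straddling
peptides had to be fixed somewhere; majority-overlap with a visible tie
class is the least surprising option) and `unannotated` for precursors
without topology. Compartment-by-location over-representation uses 2x2
Fisher tests per label, with mixed/unannotated peptides excluded from the
margins but reported.

**Antimicrobial triage.** External predictor scores (CAMP, iAMPpred, ADAM)
are consumed from files; the predictors themselves are out of scope. Calls
use `>= 0.5` for the two probabilities and strictly `> 0` for ADAM, and the
consensus is their conjunction; peptides missing any score are
undetermined, reported separately, and excluded from the rate denominator.
Candidates are ranked by consensus first, then the product of the two
predictor probabilities, then log2 fold change, with an up-regulated flag
at log2FC > 1. A published "probability of misclassification < 5%" filter
has no reproducible definition per predictor, so it is deliberately not
implemented; an optional user-supplied exclusion list stands in for it.

## What the simulator emulates

`sim_config()` defines a synthetic study with the same structure the
analyses assume, and its defaults are the study conditions: 3 biological
repeats, peptide lengths centred on 15 aa, 1,000 proteins with lognormal
lengths (median ~300 aa, minimum 60), 2,000 primary peptide draws per
compartment, a treated-unique fraction of 5.5% of which 27% come from
held-out new precursors, and per-compartment biases — a C-terminal start
bias in the cell compartment (weight 5; because a peptide must still fit
before the protein end this lands roughly a third of cell peptides within
50 aa of the C-terminus, versus ~11% in the unbiased secretome), a
hydrophobicity sampling tilt
delta = 0.5 in the secretome (exponential tilting of window-level
hydropathy z-scores under the same Kyte-Doolittle scale the analyzer
reads, so simulator and analyzer share one definition), topology biases
beta = 3 toward inside windows (cell) and outside windows (secretome), and
mildly different N-terminal residue preferences (cell A/S, secretome G/T)
standing in for compartment-specific protease specificities. Ladder
children are spawned from 30% of peptides by trimming 1-3 terminal
residues, inheriting the parent intensity scaled by 0.5 per trimmed
residue. Detection is Bernoulli per repeat (p = 0.9) and intensities are
lognormal (base sdlog 1 across peptides, repeat noise sdlog 0.4) — values
chosen once as representative of label-free XIC data. Predictor scores are
drawn so that the consensus call equals the planted truth flag, with true
antimicrobial fractions of 4% (cell) and 3.5% (secretome).

What it does **not** emulate: identification error (no false-positive
sequences), shared peptides between compartments beyond chance, protein
inference ambiguity from homologous precursors, retention-time or spectral
properties, and intensity-dependent detection. Passing closed-loop tests
therefore demonstrates that the statistics recover what was injected under
the model's assumptions — not that any particular biological dataset
satisfies those assumptions.

## Numerical choices and degenerate inputs

- Coordinates are 1-based inclusive everywhere; the one conversion helper
  to half-open form is tested as an identity round trip.
- Proteins shorter than the number of PDP windows simply produce empty
  windows; the tiling property holds for every length.
- Zero-variance indexes cannot be z-scored and are excluded from
  clustering with a warning; incomplete indexes are excluded from all
  property computations.
- Background sampling redraws an infeasible length up to 50 times before
  erroring; a fully covered proteome errors immediately.
- Fisher tests with a zero margin report p = 1 with a warning instead of
  failing the run.
- Mann-Whitney exactness threshold is 8 per group; above it the
  tie-corrected normal approximation without continuity correction is
  used (matching `wilcox.test(exact = FALSE, correct = FALSE)`).
- All randomness flows from explicit seeds (`rng_seed` in the configs, a
  `seed` argument in `background_peptides()`); identical seed and
  configuration reproduce byte-identical simulator files and report
  bundles.

## Problem sizes used in validation

The closed-loop recovery checks run the default synthetic scale (1,000
proteins, 2,000 peptides per compartment, 3 repeats) over 20 seeds per
scenario; elementary statistics are validated against exhaustive
enumeration oracles (all Mann-Whitney group sizes up to 6, Fisher tables
with margins up to 20, every PDP length up to 200 residues); conservation
and normalization invariants run on 100 randomized fixtures. These sizes
were chosen so the full suite exercises every code path at the default
study scale while remaining comfortable to run on a laptop.

## A worked example

```{r example, eval = FALSE}
library(pepdegradome)

cfg <- sim_config(rng_seed = 1)
sim <- simulate_peptidome(cfg)
run <- run_pipeline(sim$table, sim$proteome, sim$topology, sim$amp_scores,
                    config = run_config(rng_seed = 1))
summary(run)
truth_recovery_report(run, sim)
```

## Known limitations

The pipeline treats peptide sequences as the unit of identity (no
modification states), assumes exact substring mapping to precursors, and
consumes topology and antimicrobial predictions as given input rather than
recomputing them. The PDP similarity statistic and the per-residue Fisher
composition test are this package's own choices where the field reports
such comparisons informally; both are labelled as such in the outputs so
downstream users can substitute their own.
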