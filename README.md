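# pepdegradome

Comparative analysis of endogenous peptidomes — the pools of non-digested
peptides released by proteolysis of functional proteins ("degradome" or
cryptic peptides) — between cellular and secreted compartments and between
control and stress-hormone-treated conditions.

## Who it is for and what it does

Peptidomics labs working from search-engine peptide tables (MaxQuant
`peptides.txt`-style TSV) who want a reproducible, tested version of the
standard comparison workflow:

- **Mapping and filtering** — exact-substring peptide-to-precursor mapping
  with full ambiguity tracking, and a replicate filter keeping peptides
  identified in ≥ 2 biological repeats of their group.
- **Set algebra and quantification** — Venn partitions of condition sets,
  the fraction of treatment-unique peptides arising from *new* precursors,
  log2 fold changes `log2(x̄_treated / x̄_control)` over observed XIC
  intensities, Pearson correlation of log10 intensities, C-terminal
  classification (start within 50 aa of the precursor C-terminus) and
  small-protein (< 200 aa) flags.
- **Protein degradation patterns (PDP)** — per-precursor counts of peptide
  start positions over 10 relative-length windows (window *i* covers
  residues `⌊(i−1)L/n⌋+1 … ⌊iL/n⌋`), compared by cosine similarity of
  normalized rows.
- **Composition and physicochemistry** — amino-acid frequency profiles
  with a masked-region background peptide generator, 5-residue terminal
  position-frequency matrices with information content, per-peptide mean
  AAindex descriptors over the full 544-entry AAindex1 release,
  Mann–Whitney screening into nested tiers (p < 1e-5 / 1e-15 / 1e-25),
  Ward clustering of indexes and Fisher cluster enrichment with an
  explicitly labelled hydrophobicity cluster.
- **Topology localization** — majority-overlap classification of peptides
  against TMHMM-style inside/outside/TMhelix segments and compartment ×
  location Fisher enrichment.
- **Antimicrobial triage** — consensus calls over CAMP/iAMPpred/ADAM score
  tables (≥ 0.5, ≥ 0.5, > 0), consensus rates and candidate ranking with
  an up-regulated (log2FC > 1) flag.
- **A seeded proteolysis simulator** — synthetic proteomes, topologies,
  peptide ladders, compartment biases (C-terminal start bias,
  hydrophobicity sampling tilt, topology bias), treatment effects with
  known log2FC and new precursors, Bernoulli detection and lognormal
  intensities, all with ground-truth labels for closed-loop validation.

## Worked example

```r
library(pepdegradome)

cfg <- sim_config(rng_seed = 1)            # default synthetic study
sim <- simulate_peptidome(cfg)
run <- run_pipeline(sim$table, sim$proteome, sim$topology, sim$amp_scores,
                    config = run_config(rng_seed = 1))
summary(run)
```

prints (abridged):

```
peptidome_run (11387 rows in, 11083 after the >=2-repeat filter)
  cell: 2970 peptides; treated-unique 179; shared 91.4%; new-precursor 43 (24%)
  secretome: 2828 peptides; treated-unique 184; shared 90.9%; new-precursor 44 (24%)
  property screen: ns=171, sig=122, sigAA=73, top=165
  cell condition correlation: r=0.926 (n=2714)
  cell PDP similarity (median cosine): 1.000
  cell C-terminal fraction: 34.3%
  ...
  cell consensus AMP rate: 3.80%
  secretome consensus AMP rate: 3.75%
```

Reading: after the replicate filter the cell compartment holds 2,970
distinct peptides, of which 179 appear only under treatment and 43 of
those come from precursors with no control peptide at all; 360 of the 531
complete AAindex scales separate the compartments at p < 1e-5, dominated
by the hydrophobicity family (the secretome is sampled with a
hydrophobicity tilt); the degradation patterns of shared precursors are
essentially unchanged by treatment (median cosine 1.0); and the consensus
antimicrobial rate is close to the simulated 4% / 3.5% truth.
`truth_recovery_report(run, sim)` compares every recovered quantity with
the generator's ground truth.

For real data, replace the simulated inputs with
`read_peptide_table()`, `read_proteome_fasta()`, `read_topology()` and
`read_amp_scores()` (an `inst/exec/pepdegradome` Rscript wraps the same
calls for shell use), and `write_run_bundle()` writes all stage outputs as
TSV plus a JSON manifest with checksums.

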