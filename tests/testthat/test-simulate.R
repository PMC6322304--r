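small_cfg <- function(seed = 1, ...) {
  sim_config(n_proteins = 80, n_peptides = c(cell = 150, secretome = 150),
             rng_seed = seed, ...)
}

test_that("the simulator is fully deterministic given seed and config", {
  s1 <- simulate_peptidome(small_cfg(3))
  s2 <- simulate_peptidome(small_cfg(3))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in c("proteome.fasta", "topology.tsv", "peptides.tsv", "truth.tsv",
              "amp_scores.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  # a different seed changes the output
  s3 <- simulate_peptidome(small_cfg(4))
  expect_false(identical(s1$table$sequence, s3$table$sequence))
})

test_that("generated proteomes respect the length floor and record topology truth", {
  cfg <- small_cfg(5, len_min = 50L)
  prot <- generate_proteome(cfg)
  expect_true(all(prot$proteome$lengths >= 50L))
  expect_equal(length(prot$topology), 80L)
  expect_equal(sum(prot$protein_truth$held_out), 8L)
  tm <- prot$protein_truth$protein[prot$protein_truth$is_tm]
  for (p in tm) {
    expect_true("TMhelix" %in% prot$topology[[p]]$label)
  }
  expect_error(generate_proteome(sim_config(n_proteins = 0, rng_seed = 1)),
               "n_proteins")
  # byte-identical FASTA under the same seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_proteome_fasta(generate_proteome(cfg)$proteome, f1)
  write_proteome_fasta(generate_proteome(cfg)$proteome, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every emitted peptide is an exact substring at its stated coordinates", {
  sim <- simulate_peptidome(small_cfg(7))
  tab <- sim$table
  for (i in seq_len(nrow(tab))) {
    expect_identical(substr(sim$proteome$seq[[tab$proteins[i]]],
                            tab$start[i], tab$end[i]),
                     tab$sequence[i])
  }
  # truth rows match one-to-one per (compartment, peptide)
  key_tab <- unique(paste(tab$compartment, tab$sequence))
  key_tr <- paste(sim$truth$compartment, sim$truth$sequence)
  expect_true(all(key_tab %in% key_tr))
  expect_false(anyDuplicated(key_tr) > 0)
})

test_that("perfect detection makes every peptide pass the replicate filter", {
  cfg <- small_cfg(9, detection_p = 1)
  sim <- simulate_digestion(generate_proteome(cfg), cfg, aaindex_db())
  reps <- lengths(strsplit(sim$table$repeats, ";"))
  expect_true(all(reps == cfg$n_repeats))
  filtered <- replicate_filter(sim$table, 2)
  expect_equal(nrow(filtered), nrow(sim$table))
})

test_that("ladder children are terminal trims of their parent", {
  cfg <- small_cfg(11, ladder_prob = 1, ladder_max_children = 1L,
                   ladder_trim_max = 1L)
  sim <- simulate_digestion(generate_proteome(cfg), cfg, aaindex_db())
  tr <- sim$truth
  kids <- tr[tr$is_ladder_child, ]
  expect_gt(nrow(kids), 50)
  parents <- tr[!tr$is_ladder_child & !is.na(tr$ladder_group), ]
  for (i in seq_len(nrow(kids))) {
    par <- parents[parents$ladder_group == kids$ladder_group[i] &
                   parents$compartment == kids$compartment[i], ]
    if (nrow(par) == 0) next   # parent sequence deduplicated away
    # one-residue trim from either terminus
    expect_equal(nchar(par$sequence) - nchar(kids$sequence[i]), 1L)
    expect_true(startsWith(par$sequence, kids$sequence[i]) ||
                endsWith(par$sequence, kids$sequence[i]))
  }
})

test_that("the new-precursor fraction of treated-unique peptides matches the binomial design", {
  cfg <- sim_config(n_proteins = 300,
                    n_peptides = c(cell = 2000, secretome = 200),
                    treated_extra_frac = 0.05, new_precursor_frac = 0.3,
                    detection_p = 1, ladder_prob = 0, rng_seed = 13)
  sim <- simulate_digestion(generate_proteome(cfg), cfg, aaindex_db())
  tr <- sim$truth[sim$truth$compartment == "cell", ]
  uniq <- tr[!tr$in_control, ]
  expect_equal(nrow(uniq), 100L)
  n_new <- sum(uniq$is_new_precursor)
  # 30 expected; binomial sampling slack only (dedup collisions are rare)
  expect_true(abs(n_new - 30) <= 15)
  # new-precursor peptides come from proteins with zero control weight
  held <- sim$protein_truth$protein[sim$protein_truth$held_out]
  expect_true(all(uniq$protein[uniq$is_new_precursor] %in% held))
  ctrl_prots <- unique(tr$protein[tr$in_control])
  expect_length(intersect(ctrl_prots, held), 0L)
})

test_that("compartment biases shape the sampled peptides as configured", {
  cfg <- sim_config(n_proteins = 300,
                    n_peptides = c(cell = 800, secretome = 800), rng_seed = 19)
  sim <- simulate_digestion(generate_proteome(cfg), cfg, aaindex_db())
  tr <- sim$truth
  # C-terminal bias: cell >> secretome
  L <- sim$proteome$lengths[tr$protein]
  ct <- is_cterminal(tr$start, L, 50)
  frac_cell <- mean(ct[tr$compartment == "cell"])
  frac_sec <- mean(ct[tr$compartment == "secretome"])
  expect_gt(frac_cell, frac_sec + 0.1)
  # hydrophobicity tilt: secretome peptides score higher on Kyte-Doolittle
  db <- aaindex_db()
  kd_cell <- property_matrix(tr$sequence[tr$compartment == "cell"], db,
                             ids = "KYTJ820101")
  kd_sec <- property_matrix(tr$sequence[tr$compartment == "secretome"], db,
                            ids = "KYTJ820101")
  expect_gt(mean(kd_sec), mean(kd_cell) + 0.1)
})
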