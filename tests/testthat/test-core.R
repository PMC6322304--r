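test_that("locate_peptides finds all sites and flags ambiguity", {
  prot <- proteome_map(c(P1 = "MKKAAPLQG", P2 = "MKMK"))
  tab <- peptide_table(data.frame(
    sequence = c("AAPLQ", "MK", "WWW"),
    condition = "control", compartment = "cell", repeats = "1;2",
    stringsAsFactors = FALSE))
  out <- locate_peptides(tab, prot)
  # single exact hit with manual coordinates
  expect_equal(out$proteins[1], "P1")
  expect_equal(c(out$start[1], out$end[1]), c(4L, 8L))
  expect_false(out$ambiguous[1])
  # "MK" hits P1 once and P2 twice: three sites, ambiguous
  expect_equal(out$proteins[2], "P1;P2;P2")
  expect_equal(out$starts[2], "1;1;3")
  expect_true(out$ambiguous[2])
  # no tryptophan anywhere: unmapped but kept
  expect_true(out$unmapped[3])
  expect_equal(nrow(out), 3L)
})

test_that("replicate filter keeps >=k-repeat peptides and is monotone", {
  tab <- tiny_table()
  f2 <- replicate_filter(tab, 2)
  expect_setequal(f2$sequence, c("AAPLQ", "ACDEF", "WSTNN"))
  # presence {1} dropped at min 2
  expect_false("GGGG" %in% f2$sequence)
  expect_error(replicate_filter(tab, 5), "exceeds")

  # monotone non-increasing in min_repeats, on random tables
  prot <- random_proteome(10, seed = 1)
  for (seed in 1:5) {
    rt <- random_table(60, prot, seed)
    sizes <- vapply(1:3, function(k) nrow(replicate_filter(rt, k)), integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("venn partition is additive and handles identity", {
  v <- venn_counts(c("x", "y"), c("y", "z"))
  expect_equal(c(v$unique_a, v$shared, v$unique_b), c(1L, 1L, 1L))
  v <- venn_counts(c("a", "b"), c("a", "b"))
  expect_equal(c(v$unique_a, v$shared, v$unique_b), c(0L, 2L, 0L))
  expect_equal(v$percent_shared, 100)

  # additivity property on random sets
  set.seed(42)
  for (i in 1:20) {
    a <- sample(letters, sample(0:20, 1))
    b <- sample(letters, sample(0:20, 1))
    v <- venn_counts(a, b)
    expect_equal(v$unique_a + v$shared + v$unique_b, length(union(a, b)))
  }
})

test_that("new-precursor fraction counts treated-unique peptides from novel proteins", {
  prot <- proteome_map(c(P1 = "AAAACCCC", P2 = "GGGGTTTT"))
  tab <- peptide_table(data.frame(
    sequence = c("AAAA", "CCCC", "GGGG"),
    proteins = c("P1", "P1", "P2"),
    starts = c("1", "5", "1"), ends = c("4", "8", "4"),
    condition = c("control", "treated", "treated"),
    compartment = "cell", repeats = "1;2", stringsAsFactors = FALSE))
  v <- venn_counts("AAAA", c("CCCC", "GGGG"))
  np <- new_precursor_fraction(v, tab)
  # CCCC is from P1 (already a control precursor), GGGG from new P2
  expect_equal(np$count, 1L)
  expect_equal(np$fraction, 0.5)
  expect_equal(np$sequences, "GGGG")

  # all unique peptides from control precursors -> zero
  v0 <- venn_counts(c("AAAA", "GGGG"), c("AAAA", "GGGG", "CCCC"))
  expect_equal(new_precursor_fraction(v0, tab)$count, 0L)
  # empty unique set -> fraction undefined
  vI <- venn_counts("AAAA", "AAAA")
  expect_true(is.na(new_precursor_fraction(vI, tab)$fraction))
})

test_that("C-terminal rule matches the window arithmetic and a brute-force oracle", {
  expect_true(is_cterminal(60, 100, 50))    # 60 >= 100 - 50 + 1
  expect_false(is_cterminal(1, 100, 50))
  expect_true(is_cterminal(1, 40, 50))      # whole protein inside the window

  # brute-force oracle over all start positions, lengths and windows
  for (L in c(1:15, 49:52, 99:101, 120)) {
    for (w in c(0, 1, 25, 50, 60)) {
      starts <- seq_len(L)
      oracle <- vapply(starts, function(s) {
        # distance from start to the C-terminus is L - s; "within w residues"
        (L - s) <= (w - 1)
      }, logical(1))
      expect_identical(is_cterminal(starts, L, w), oracle,
                       info = sprintf("L=%d w=%d", L, w))
    }
  }
})

test_that("classify_cterminal uses any qualifying site and rejects unmapped rows", {
  prot <- proteome_map(c(P1 = paste(rep("A", 100), collapse = ""),
                         P2 = "AAAA"))
  tab <- peptide_table(data.frame(
    sequence = c("AAAA", "AAAA"),
    proteins = c("P1", "P1;P2"),
    starts = c("1", "1;1"), ends = c("4", "4;4"),
    condition = "control", compartment = "cell", repeats = "1;2",
    stringsAsFactors = FALSE))
  ct <- classify_cterminal(tab, prot, 50)
  expect_false(ct[1])          # start 1 on a 100-aa protein
  expect_true(ct[2])           # the P2 site (whole protein in window) qualifies

  tab$unmapped[1] <- TRUE
  expect_error(classify_cterminal(tab, prot), "unmapped")
})

test_that("log2 fold change handles statuses and is antisymmetric", {
  expect_equal(log2_fold_change(c(100, 100), c(200, 200))$log2fc, 1)
  expect_equal(log2_fold_change(c(5, 5, 5), c(5, 5))$log2fc, 0)
  expect_equal(log2_fold_change(c(NA, NA), c(1, 2))$status, "present_only_to")
  expect_equal(log2_fold_change(c(1, 2), c(NA, NA))$status, "present_only_from")
  expect_equal(log2_fold_change(c(NA, NA), c(NA, NA))$status, "not_quantified")
  expect_equal(log2_fold_change(c(1, NA), c(1, 2))$status, "low_evidence")

  set.seed(7)
  for (i in 1:10) {
    a <- runif(3, 10, 100)
    b <- runif(3, 10, 100)
    expect_equal(log2_fold_change(a, b)$log2fc, -log2_fold_change(b, a)$log2fc)
  }
})

test_that("noise-free simulated treatment effect is recovered exactly", {
  cfg <- sim_config(n_proteins = 60, n_peptides = c(cell = 80, secretome = 80),
                    log2fc_mean = log2(2.5), log2fc_sd = 0,
                    noise_sdlog = 0, detection_p = 1, ladder_prob = 0,
                    treated_extra_frac = 0, rng_seed = 5)
  sim <- simulate_digestion(generate_proteome(cfg), cfg, aaindex_db())
  fc <- fold_change_table(replicate_filter(sim$table), "cell")
  q <- fc[fc$status == "quantified", ]
  expect_gt(nrow(q), 50)
  expect_equal(q$log2fc, rep(log2(2.5), nrow(q)), tolerance = 1e-10)
})

test_that("intensity correlation matches known cases and a Monte-Carlo target", {
  expect_equal(intensity_correlation(1:3, 1:3, use_log10 = FALSE)$r, 1)
  expect_equal(intensity_correlation(1:3, 3:1, use_log10 = FALSE)$r, -1)
  expect_error(intensity_correlation(1:2, 1:2), "at least 3")

  # shared lognormal signal plus noise sized for population r = 0.7
  set.seed(123)
  rs <- replicate(40, {
    s <- rnorm(100)
    sd_noise <- sqrt(1 / 0.7 - 1)
    x <- 10^(5 + s + rnorm(100, 0, sd_noise))
    y <- 10^(5 + s + rnorm(100, 0, sd_noise))
    intensity_correlation(x, y)$r
  })
  expect_true(mean(abs(rs - 0.7) <= 0.15) >= 0.95)
})

test_that("small-protein flags use a strict inequality", {
  prot <- proteome_map(c(P1 = paste(rep("A", 199), collapse = ""),
                         P2 = paste(rep("A", 200), collapse = "")))
  expect_equal(small_protein_flags(prot, 200), "P1")
  expect_length(small_protein_flags(prot, 0), 0L)
})
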