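test_that("amino-acid frequencies pool residues and skip non-standard ones", {
  p <- aa_frequencies(c("AA", "GG"))
  expect_equal(unname(p$freq[c("A", "G")]), c(0.5, 0.5))
  p <- aa_frequencies("AXAG")
  expect_equal(unname(p$freq["A"]), 2 / 3)
  expect_equal(unname(p$freq["G"]), 1 / 3)
  expect_equal(p$total, 3L)
  expect_error(aa_frequencies(character(0)), "empty")

  set.seed(1)
  for (i in 1:10) {
    peps <- replicate(20, paste(sample(pepdegradome:::AA_STANDARD,
                                       sample(5:20, 1), replace = TRUE),
                                collapse = ""))
    expect_equal(sum(aa_frequencies(peps)$freq), 1, tolerance = 1e-9)
  }
})

test_that("AAF comparison finds no differences between identical sets and detects enrichment", {
  set.seed(2)
  peps <- replicate(200, paste(sample(pepdegradome:::AA_STANDARD, 15,
                                      replace = TRUE), collapse = ""))
  p <- aa_frequencies(peps)
  cmp <- compare_aaf(p, p)
  expect_true(all(cmp$q_value == 1))
  expect_equal(sum(cmp$significant), 0L)

  # alanine-doubled set vs background, ~10,000 residues: A must light up
  freq_bg <- rep(1 / 20, 20)
  freq_en <- freq_bg
  freq_en[1] <- 2 * freq_bg[1]
  freq_en <- freq_en / sum(freq_en)
  mk <- function(fr) replicate(700, paste(
    sample(pepdegradome:::AA_STANDARD, 15, replace = TRUE, prob = fr),
    collapse = ""))
  cmp <- compare_aaf(aa_frequencies(mk(freq_en)), aa_frequencies(mk(freq_bg)))
  expect_true(cmp$significant[cmp$residue == "A"])
  expect_gt(cmp$odds_ratio[cmp$residue == "A"], 1)
})

test_that("Fisher two-sided p matches hypergeometric enumeration", {
  # frozen diagonal case: only the two perfect tables are as extreme
  ft <- stats::fisher.test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(ft$p.value, 2 / 184756, tolerance = 1e-12)

  # random tables with margins <= 20 against the enumeration oracle
  set.seed(11)
  for (i in 1:40) {
    a <- sample(0:8, 1); b <- sample(0:8, 1)
    c <- sample(0:8, 1); d <- sample(0:8, 1)
    if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
    p_pkg <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))$p.value
    p_orc <- hypergeom_fisher_p(a, b, c, d)
    expect_equal(p_pkg, p_orc, tolerance = 1e-9,
                 info = sprintf("table %d %d / %d %d", a, b, c, d))
  }
})

test_that("background peptides avoid observed spans and are reproducible", {
  prot <- proteome_map(c(P1 = "AAAAACCCCC", P2 = "GGGGGGGGGG"))
  tab <- peptide_table(data.frame(
    sequence = c("AAAAA", "GGGG"), proteins = c("P1", "P2"),
    starts = c("1", "4"), ends = c("5", "7"),
    condition = "control", compartment = "cell", repeats = "1;2",
    stringsAsFactors = FALSE))
  bg <- background_peptides(prot, tab, 40, seed = 3)
  sp <- attr(bg, "spans")
  # P1 draws must lie inside 6..10 (the only unmasked run)
  p1 <- sp[sp$protein == "P1", ]
  expect_true(all(p1$start >= 6 & p1$end <= 10))
  # no draw intersects any masked residue on P2 (mask 4..7)
  p2 <- sp[sp$protein == "P2", ]
  expect_true(all(p2$end < 4 | p2$start > 7))
  # sampled sequences really are the stated substrings
  expect_equal(bg, unname(substring(prot$seq[sp$protein], sp$start, sp$end)),
               ignore_attr = TRUE)
  # determinism under a fixed seed
  expect_identical(bg, background_peptides(prot, tab, 40, seed = 3))

  # a fully covered proteome cannot be sampled
  full <- peptide_table(data.frame(
    sequence = c("AAAAACCCCC", "GGGGGGGGGG"), proteins = c("P1", "P2"),
    starts = "1", ends = "10", condition = "control",
    compartment = "cell", repeats = "1", stringsAsFactors = FALSE))
  expect_error(background_peptides(prot, full, 5, seed = 1), "no unmasked")
})

test_that("background non-overlap holds across randomized fixtures", {
  for (seed in 1:10) {
    prot <- random_proteome(6, seed = seed, lmin = 50, lmax = 100)
    tab <- locate_peptides(random_table(25, prot, seed + 100), prot)
    bg <- background_peptides(prot, tab, 30, seed = seed)
    sp <- attr(bg, "spans")
    sites <- pepdegradome:::mapping_sites(tab)
    for (j in seq_len(nrow(sp))) {
      obs <- sites[sites$protein == sp$protein[j], ]
      overlap <- obs$start <= sp$end[j] & obs$end >= sp$start[j]
      expect_false(any(overlap))
    }
  }
})

test_that("terminal profiles read inward from each terminus and normalize", {
  tp <- terminal_profile("ACDEFGHIKL", "N", 5)
  hit <- apply(tp$pfm, 2, function(col) rownames(tp$pfm)[col == 1])
  expect_equal(unname(hit), c("A", "C", "D", "E", "F"))
  tp <- terminal_profile("ACDEFGHIKL", "C", 5)
  hit <- apply(tp$pfm, 2, function(col) rownames(tp$pfm)[col == 1])
  expect_equal(unname(hit), c("L", "K", "I", "H", "G"))

  # per-position normalization on random sets
  set.seed(5)
  peps <- replicate(300, paste(sample(pepdegradome:::AA_STANDARD,
                                      sample(5:20, 1), replace = TRUE),
                               collapse = ""))
  for (term in c("N", "C")) {
    tp <- terminal_profile(peps, term, 5)
    expect_equal(unname(colSums(tp$pfm)), rep(1, 5), tolerance = 1e-9)
  }

  # uniform residue usage carries no information
  big <- replicate(5000, paste(sample(pepdegradome:::AA_STANDARD, 8,
                                      replace = TRUE), collapse = ""))
  tp <- terminal_profile(big, "N", 5)
  expect_true(all(abs(tp$information) <= 0.05))

  # short peptides are excluded, all-short errors
  tp <- terminal_profile(c("ACDEFGH", "AC"), "N", 5)
  expect_equal(tp$n_used, 1L)
  expect_equal(tp$n_excluded, 1L)
  expect_error(terminal_profile(c("AC", "DE"), "N", 5), "length >= 5")
})

test_that("peptide property is the residue mean and is concatenation-linear", {
  db <- aaindex_db()
  g <- db[["KYTJ820101"]]$values[["G"]]
  expect_equal(peptide_property("GGG", db[["KYTJ820101"]]), g)
  vals <- setNames(rep(0, 20), pepdegradome:::AA_STANDARD)
  vals["A"] <- 1
  expect_equal(peptide_property("AG", vals), 0.5)

  # net charge of KKDD under the net-charge scale, straight from the table
  klep <- db[["KLEP840101"]]$values
  expect_equal(peptide_property("KKDD", db[["KLEP840101"]]),
               mean(klep[c("K", "K", "D", "D")]))

  # linearity: property(xy) weighted by lengths
  set.seed(6)
  for (i in 1:10) {
    x <- paste(sample(pepdegradome:::AA_STANDARD, sample(3:10, 1), TRUE),
               collapse = "")
    y <- paste(sample(pepdegradome:::AA_STANDARD, sample(3:10, 1), TRUE),
               collapse = "")
    idx <- db[["EISD840101"]]
    expect_equal(peptide_property(paste0(x, y), idx),
                 (nchar(x) * peptide_property(x, idx) +
                  nchar(y) * peptide_property(y, idx)) / (nchar(x) + nchar(y)),
                 tolerance = 1e-12)
  }

  expect_error(peptide_property("AXA", db[["KYTJ820101"]]), "non-standard")
  incomplete <- list(values = c(setNames(rep(NA_real_, 20),
                                         pepdegradome:::AA_STANDARD)))
  expect_error(peptide_property("AAA", incomplete), "incomplete")
})

test_that("Mann-Whitney exact p matches brute-force enumeration (sizes <= 6, with ties)", {
  expect_equal(mw_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)

  set.seed(13)
  for (i in 1:25) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    # draw from a small integer range to force ties often
    x <- sample(1:5, n1, replace = TRUE)
    y <- sample(1:5, n2, replace = TRUE)
    expect_equal(mw_test(x, y)$p_value, bruteforce_mw_p(x, y),
                 tolerance = 1e-12,
                 info = paste(paste(x, collapse = ","), "vs",
                              paste(y, collapse = ",")))
  }
})

test_that("Mann-Whitney large-sample path agrees with wilcox.test", {
  set.seed(14)
  for (i in 1:10) {
    x <- round(rnorm(30, 0, 2), 1)
    y <- round(rnorm(25, 0.5, 2), 1)
    ours <- mw_test(x, y)
    ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                               correct = FALSE))
    expect_equal(ours$u, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("property screen: identical sets are ns, shifted sets are flagged with direction", {
  db <- aaindex_db()
  set.seed(15)
  peps <- replicate(60, paste(sample(pepdegradome:::AA_STANDARD, 12, TRUE),
                              collapse = ""))
  sc <- property_screen(peps, peps, db)
  expect_true(all(sc$tier == "ns"))
  expect_true(all(sc$p_value > 0.99))

  # hydrophobic-residue-enriched set vs uniform: Kyte-Doolittle must flag
  hydro <- c("I", "V", "L", "F", "C", "M", "A")
  pa <- replicate(300, paste(sample(pepdegradome:::AA_STANDARD, 12, TRUE),
                             collapse = ""))
  pb <- replicate(300, paste(sample(c(pepdegradome:::AA_STANDARD, hydro), 12,
                                    TRUE), collapse = ""))
  sc <- property_screen(pa, pb, db, labels = c("plain", "greasy"))
  kd <- sc[sc$index == "KYTJ820101", ]
  expect_true(kd$p_value < 1e-5)
  expect_equal(kd$direction, "greasy")
  # tiers are nested by construction of the thresholds
  expect_true(all(sc$p_value[sc$tier == "top"] < 1e-25))
  expect_true(all(sc$p_value[sc$tier == "sigAA"] < 1e-15))
  expect_true(all(sc$p_value[sc$tier == "sig"] < 1e-5))
  expect_equal(attr(sc, "n_indexes"), 531L)
})

test_that("null screens over identically drawn arms rarely reach p < 1e-5", {
  db <- aaindex_db()
  hits <- vapply(1:20, function(seed) {
    set.seed(seed)
    pa <- replicate(500, paste(sample(pepdegradome:::AA_STANDARD, 15, TRUE),
                               collapse = ""))
    pb <- replicate(500, paste(sample(pepdegradome:::AA_STANDARD, 15, TRUE),
                               collapse = ""))
    sc <- property_screen(pa, pb, db)
    sum(sc$tier != "ns")
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("index clustering groups identical profiles and recovers planted families", {
  db <- aaindex_db()
  set.seed(16)
  peps <- replicate(80, paste(sample(pepdegradome:::AA_STANDARD, 12, TRUE),
                              collapse = ""))
  # three planted families of residue scales around distinct latent vectors
  mk_family <- function(base, k, tag) {
    out <- list()
    for (j in seq_len(k)) {
      vals <- setNames(base + rnorm(20, 0, 0.02), pepdegradome:::AA_STANDARD)
      out[[paste0(tag, j)]] <- list(id = paste0(tag, j), description = tag,
                                    values = vals, complete = TRUE)
    }
    out
  }
  fam <- c(mk_family(rnorm(20), 4, "FAMA"),
           mk_family(rnorm(20), 4, "FAMB"),
           mk_family(rnorm(20), 4, "FAMC"))
  synth <- structure(fam, class = "aaindex_table")
  pm <- property_matrix(peps, synth)
  cl <- cluster_indexes(pm, 3)
  truth <- substr(names(cl$cluster), 1, 4)
  # Adjusted Rand Index against the planted labels
  ari <- function(a, b) {
    tab <- table(a, b)
    sij <- sum(choose(tab, 2))
    ai <- sum(choose(rowSums(tab), 2)); bj <- sum(choose(colSums(tab), 2))
    n2 <- choose(sum(tab), 2)
    (sij - ai * bj / n2) / ((ai + bj) / 2 - ai * bj / n2)
  }
  expect_equal(ari(cl$cluster, truth), 1)

  # identical profiles always co-cluster; result is input-order independent
  pm2 <- property_matrix(peps, db, ids = c("KYTJ820101", "KLEP840101",
                                           "ZIMJ680104", "EISD840101",
                                           "FAUJ880111", "ARGP820101"))
  pm2 <- cbind(pm2, DUPKD0101 = pm2[, "KYTJ820101"])
  cl2 <- cluster_indexes(pm2, 3)
  expect_equal(cl2$cluster[["DUPKD0101"]], cl2$cluster[["KYTJ820101"]])
  cl3 <- cluster_indexes(pm2[, rev(colnames(pm2))], 3)
  expect_equal(cl3$cluster[names(cl2$cluster)], cl2$cluster)

  # constant indexes are excluded with a warning
  pm3 <- cbind(pm2, CONST0101 = 1)
  expect_warning(cl4 <- cluster_indexes(pm3, 3), "constant")
  expect_false("CONST0101" %in% names(cl4$cluster))
})

test_that("cluster enrichment matches the hypergeometric oracle", {
  clustering <- list(cluster = setNames(rep(1:3, each = 10),
                                        sprintf("IDX%02d", 1:30)))
  # significant set = exactly cluster 1
  enr <- cluster_enrichment(clustering, sprintf("IDX%02d", 1:10))
  expect_equal(which.min(enr$p_value), 1L)
  expect_equal(enr$p_value[1], hypergeom_fisher_p(10, 0, 0, 20),
               tolerance = 1e-9)
  # empty significant set: all p = 1
  enr0 <- cluster_enrichment(clustering, character(0))
  expect_true(all(enr0$p_value == 1))
})
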