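# Shared fixture builders: everything is generated in code at test time.

# A tiny deterministic proteome.
tiny_proteome <- function() {
  proteome_map(c(P1 = "MKKAAPLQGWSTNNNAAPL",
                 P2 = "ACDEFGHIKLMNPQRSTVWY",
                 P3 = "MKMKMKGGGG"))
}

# A small peptide table over tiny_proteome(), already mapped.
tiny_table <- function() {
  peptide_table(data.frame(
    sequence = c("AAPLQ", "ACDEF", "AAPLQ", "GGGG", "WSTNN"),
    proteins = c("P1", "P2", "P1", "P3", "P1"),
    starts = c("4", "1", "4", "7", "10"),
    ends = c("8", "5", "8", "10", "14"),
    condition = c("control", "control", "treated", "treated", "control"),
    compartment = c("cell", "cell", "cell", "cell", "secretome"),
    repeats = c("1;2", "1;2;3", "2;3", "1", "1;3"),
    intensity_r1 = c(100, 200, NA, 50, 10),
    intensity_r2 = c(110, 210, 420, NA, NA),
    intensity_r3 = c(NA, 190, 400, NA, 12),
    stringsAsFactors = FALSE))
}

# Random peptide table rows for property-style tests.
random_table <- function(n, proteome, seed) {
  set.seed(seed)
  ids <- names(proteome$seq)
  pick <- sample(ids, n, replace = TRUE)
  L <- proteome$lengths[pick]
  len <- pmin(pmax(3L, as.integer(round(rnorm(n, 8, 3)))), L)
  start <- vapply(seq_len(n), function(i) sample.int(L[i] - len[i] + 1L, 1L),
                  integer(1))
  peptide_table(data.frame(
    sequence = substring(proteome$seq[pick], start, start + len - 1L),
    proteins = pick,
    starts = as.character(start),
    ends = as.character(start + len - 1L),
    condition = sample(c("control", "treated"), n, replace = TRUE),
    compartment = sample(c("cell", "secretome"), n, replace = TRUE),
    repeats = vapply(seq_len(n), function(i) {
      paste(sort(sample(1:3, sample(1:3, 1))), collapse = ";")
    }, character(1)),
    intensity_r1 = runif(n, 1e4, 1e6),
    intensity_r2 = runif(n, 1e4, 1e6),
    intensity_r3 = runif(n, 1e4, 1e6),
    stringsAsFactors = FALSE))
}

# Random proteome of n proteins with lengths in [lmin, lmax].
random_proteome <- function(n, seed, lmin = 30L, lmax = 120L) {
  set.seed(seed)
  lens <- sample(lmin:lmax, n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(pepdegradome:::AA_STANDARD, L, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("R%03d", seq_len(n))
  proteome_map(seqs)
}

# Independent brute-force Mann-Whitney two-sided p: enumerate every
# assignment of group labels, computing U from pairwise comparisons.
bruteforce_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  N <- length(pooled)
  u_of <- function(idx) {
    a <- pooled[idx]
    b <- pooled[-idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  mu <- n1 * (N - n1) / 2
  combs <- utils::combn(N, n1)
  u_all <- apply(combs, 2, u_of)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Independent two-sided Fisher p from hypergeometric enumeration:
# sum of P(table) over all tables with the observed margins whose
# probability does not exceed the observed table's.
hypergeom_fisher_p <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Default AAindex database, loaded once per test session.
aaindex_db <- local({
  db <- NULL
  function() {
    if (is.null(db)) db <<- load_aaindex()
    db
  }
})
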