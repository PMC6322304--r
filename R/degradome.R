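#' One protein degradation pattern (PDP) row
#'
#' Splits a precursor of length `L` into `n_windows` near-equal windows —
#' window `i` covers residues `floor((i-1)*L/n)+1 .. floor(i*L/n)` — and
#' counts peptide start positions per window. The windows tile `1..L`
#' exactly (no gaps, no overlaps) and differ in width by at most one
#' residue, so the 10-window default is the "10% of precursor length"
#' binning that absorbs peptide ladders. Each start falls in exactly one
#' window; the result does not depend on the order of the starts.
#'
#' @param protein_length Precursor length (>= 1).
#' @param start_positions Integer vector of 1-based peptide start positions.
#' @param n_windows Number of windows (default 10).
#' @return Integer count vector of length `n_windows`; its sum equals the
#'   number of starts.
#' @examples
#' pdp_row(100, c(5, 15, 95))
#' @export
pdp_row <- function(protein_length, start_positions, n_windows = 10L) {
  L <- as.integer(protein_length)
  n <- as.integer(n_windows)
  if (is.na(L) || L < 1L) stop2("protein_length must be >= 1")
  if (n < 1L) stop2("n_windows must be >= 1")
  starts <- as.integer(start_positions)
  if (length(starts) && (any(starts < 1L) || any(starts > L))) {
    stop2("start position(s) outside 1..", L)
  }
  bounds <- floor(seq_len(n) * L / n)   # upper bound of each window
  win <- findInterval(starts - 1L, bounds) + 1L
  tabulate(win, nbins = n)
}

# Window spans as a data.frame (used by tests and reports).
pdp_windows <- function(protein_length, n_windows = 10L) {
  L <- as.integer(protein_length)
  n <- as.integer(n_windows)
  upper <- floor(seq_len(n) * L / n)
  lower <- c(1L, head(upper, -1L) + 1L)
  data.frame(window = seq_len(n), start = lower, end = upper)
}

#' Protein degradation pattern matrix
#'
#' One PDP row per precursor with at least one mapped peptide start in the
#' table. Ambiguous peptides contribute one count per matched site, so row
#' sums equal per-precursor mapped-start events and the grand total equals
#' the total number of mapped sites.
#'
#' @param table A mapped `peptide_table` (typically one compartment and
#'   condition, already replicate-filtered).
#' @param proteome A `proteome_map`.
#' @param n_windows Number of windows (default 10).
#' @return Integer matrix of class `pdp_matrix` (rows = precursor ids,
#'   columns = `win1..winN`).
#' @export
pdp_matrix <- function(table, proteome, n_windows = 10L) {
  sites <- mapping_sites(table)
  sites <- sites[sites$protein %in% names(proteome$seq), , drop = FALSE]
  by_prot <- split(sites$start, sites$protein)
  prots <- sort(names(by_prot))
  mat <- t(vapply(prots, function(p) {
    pdp_row(proteome$lengths[[p]], by_prot[[p]], n_windows)
  }, integer(n_windows)))
  if (!length(prots)) {
    mat <- matrix(integer(0), nrow = 0, ncol = n_windows)
  }
  colnames(mat) <- paste0("win", seq_len(n_windows))
  rownames(mat) <- prots
  structure(mat, class = c("pdp_matrix", class(mat)))
}

#' Compare degradation patterns between two PDP matrices
#'
#' For each shared precursor, rows are normalized to unit sum and compared
#' by cosine similarity (1 = identical pattern, 0 = starts in disjoint
#' windows). All-zero rows are skipped. The median across shared precursors
#' summarizes global PDP agreement; the metric itself is this package's
#' choice of statistic for "how similar are the patterns".
#'
#' @param matrix_a,matrix_b `pdp_matrix` objects with the same number of
#'   windows.
#' @param shared_ids Precursor ids to compare; defaults to the row
#'   intersection.
#' @return List with `per_protein` (named cosine similarities) and
#'   `median`.
#' @export
pdp_similarity <- function(matrix_a, matrix_b, shared_ids = NULL) {
  if (is.null(shared_ids)) {
    shared_ids <- intersect(rownames(matrix_a), rownames(matrix_b))
  }
  if (!length(shared_ids)) stop2("no shared precursors between the PDP matrices")
  sims <- vapply(shared_ids, function(id) {
    a <- matrix_a[id, ]; b <- matrix_b[id, ]
    if (sum(a) == 0 || sum(b) == 0) return(NA_real_)
    a <- a / sum(a); b <- b / sum(b)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  sims <- sims[!is.na(sims)]
  if (!length(sims)) stop2("no comparable (non-empty) shared rows")
  list(per_protein = sims, median = stats::median(sims))
}
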