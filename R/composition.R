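#' Pooled amino-acid frequency profile of a peptide set
#'
#' Frequencies over all residues of all peptides pooled together.
#' Non-standard residues (X, U, ...) are excluded from both numerator and
#' denominator, so the 20 frequencies always sum to 1.
#'
#' @param peptides Character vector of peptide sequences (non-empty).
#' @return List of class `aaf_profile` with `freq` (named over the 20
#'   standard residues), `counts` and `total`.
#' @export
aa_frequencies <- function(peptides) {
  if (!length(peptides)) stop2("empty peptide set")
  chars <- unlist(strsplit(toupper(peptides), ""), use.names = FALSE)
  chars <- chars[chars %in% AA_STANDARD]
  if (!length(chars)) stop2("no standard residues in peptide set")
  counts <- table(factor(chars, levels = AA_STANDARD))
  counts <- setNames(as.integer(counts), AA_STANDARD)
  structure(list(freq = counts / sum(counts), counts = counts,
                 total = sum(counts)),
            class = "aaf_profile")
}

#' Compare two amino-acid frequency profiles
#'
#' Per residue, a 2x2 two-sided Fisher exact test of residue-vs-rest counts
#' between the two sets, BH-corrected across the 20 residues. "No
#' significant compositional difference" corresponds to zero residues with
#' q < 0.05.
#'
#' @param profile_a,profile_b `aaf_profile` objects.
#' @return data.frame with per-residue counts, frequencies, odds ratio,
#'   `p_value`, `q_value` and `significant` (q < 0.05).
#' @export
compare_aaf <- function(profile_a, profile_b) {
  res <- lapply(AA_STANDARD, function(aa) {
    tab <- matrix(c(profile_a$counts[[aa]], profile_a$total - profile_a$counts[[aa]],
                    profile_b$counts[[aa]], profile_b$total - profile_b$counts[[aa]]),
                  nrow = 2, byrow = TRUE)
    ft <- stats::fisher.test(tab)
    data.frame(residue = aa,
               count_a = tab[1, 1], count_b = tab[2, 1],
               freq_a = unname(profile_a$freq[aa]),
               freq_b = unname(profile_b$freq[aa]),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value < 0.05
  out
}

#' Sample background peptides from unobserved protein regions
#'
#' Builds the artificial comparison set: all observed peptide spans are
#' masked on their precursors, then `n` peptides are drawn with lengths
#' resampled (with replacement) from the observed length distribution and
#' start positions uniform over all placements that fit entirely inside a
#' contiguous unmasked run. A sampled peptide therefore never intersects
#' any observed residue. If a drawn length fits nowhere it is redrawn up to
#' `max_redraw` times before erroring.
#'
#' @param proteome A `proteome_map`.
#' @param table A mapped `peptide_table` providing the observed spans and
#'   the length distribution.
#' @param n Number of background peptides to draw.
#' @param seed RNG seed (sampling is fully reproducible given the seed).
#' @param max_redraw Redraw cap per peptide (default 50).
#' @return Character vector of `n` background peptide sequences; attribute
#'   `spans` records (protein, start, end) of every draw.
#' @export
background_peptides <- function(proteome, table, n, seed, max_redraw = 50L) {
  set.seed(seed)
  sites <- mapping_sites(table)
  runs <- unmasked_runs(proteome, sites)
  if (!nrow(runs)) stop2("no unmasked region available for background sampling")
  lens <- nchar(unique(table$sequence))
  out <- character(n)
  prot <- character(n); st <- integer(n)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_redraw)) {
      len <- lens[sample.int(length(lens), 1L)]
      ok <- which(runs$len >= len)
      if (!length(ok)) next
      w <- runs$len[ok] - len + 1L
      pick <- ok[sample.int(length(ok), 1L, prob = w)]
      offset <- sample.int(runs$len[pick] - len + 1L, 1L) - 1L
      prot[i] <- runs$protein[pick]
      st[i] <- runs$start[pick] + offset
      out[i] <- substr(proteome$seq[[prot[i]]], st[i], st[i] + len - 1L)
      placed <- TRUE
      break
    }
    if (!placed) stop2("could not place a background peptide after ", max_redraw, " redraws")
  }
  attr(out, "spans") <- data.frame(protein = prot, start = st,
                                   end = st + nchar(out) - 1L,
                                   stringsAsFactors = FALSE)
  out
}

# Contiguous unmasked runs per protein after masking observed spans.
unmasked_runs <- function(proteome, sites) {
  res <- lapply(names(proteome$seq), function(p) {
    L <- proteome$lengths[[p]]
    mask <- rep(FALSE, L)
    sp <- sites[sites$protein == p, , drop = FALSE]
    for (j in seq_len(nrow(sp))) {
      mask[sp$start[j]:min(sp$end[j], L)] <- TRUE
    }
    r <- rle(!mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    if (!any(keep)) return(NULL)
    data.frame(protein = p, start = starts[keep], len = r$lengths[keep],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(protein = character(0), start = integer(0), len = integer(0))
  }
  out
}

#' Terminal-residue position-frequency profile
#'
#' Position-frequency matrix of the first (N) or last (C) `k` residues of a
#' peptide set, position 1 being the terminal residue itself and positions
#' counted inward. Peptides shorter than `k` or containing non-standard
#' residues are excluded (their number is reported). Per-position
#' information content is `log2(20) - H` with `H` the Shannon entropy in
#' bits, so a uniform position scores 0 and an invariant one log2(20).
#'
#' @param peptides Character vector of peptides.
#' @param terminus `"N"` or `"C"`.
#' @param k Number of terminal positions (default 5).
#' @return List of class `terminal_profile` with `pfm` (20 residues x k
#'   positions, each column summing to 1), `information` (bits per
#'   position), `n_used` and `n_excluded`.
#' @export
terminal_profile <- function(peptides, terminus = c("N", "C"), k = 5L) {
  terminus <- match.arg(terminus)
  if (k < 1L) stop2("k must be >= 1")
  peptides <- toupper(peptides)
  use <- nchar(peptides) >= k & is_standard_seq(peptides)
  n_excluded <- sum(!use)
  peps <- peptides[use]
  if (!length(peps)) stop2("no peptide of length >= ", k, " to profile")
  pfm <- vapply(seq_len(k), function(pos) {
    res <- if (terminus == "N") substr(peps, pos, pos)
           else substr(peps, nchar(peps) - pos + 1L, nchar(peps) - pos + 1L)
    tab <- table(factor(res, levels = AA_STANDARD))
    as.numeric(tab) / length(res)
  }, numeric(20))
  rownames(pfm) <- AA_STANDARD
  colnames(pfm) <- paste0("pos", seq_len(k))
  info <- apply(pfm, 2, function(p) {
    p <- p[p > 0]
    log2(20) + sum(p * log2(p))
  })
  structure(list(terminus = terminus, pfm = pfm, information = info,
                 n_used = length(peps), n_excluded = n_excluded),
            class = "terminal_profile")
}

#' @export
print.terminal_profile <- function(x, ...) {
  cat(sprintf("terminal_profile (%s-terminus, %d positions, %d peptides)\n",
              x$terminus, ncol(x$pfm), x$n_used))
  cat("information (bits):", paste(sprintf("%.2f", x$information), collapse = " "), "\n")
  invisible(x)
}
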