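#' Filter peptides by biological-repeat support
#'
#' Endogenous peptide pools are heterogeneous, so only peptides identified
#' in at least `min_repeats` biological repeats of their
#' (compartment, condition) group are retained for analysis.
#'
#' @param table A `peptide_table`.
#' @param min_repeats Minimum repeats (default 2).
#' @param n_repeats Number of repeats in the design; inferred from the
#'   intensity columns or the largest repeat index when NULL.
#' @return The retained rows (a `peptide_table`); attribute `filter_counts`
#'   tabulates rows before/after per group. Retained sets shrink (never
#'   grow) as `min_repeats` increases.
#' @export
replicate_filter <- function(table, min_repeats = 2L, n_repeats = NULL) {
  reps <- repeat_sets(table)
  if (is.null(n_repeats)) {
    n_int <- length(intensity_cols(table))
    n_repeats <- max(n_int, if (length(reps)) max(unlist(reps)) else 0L)
  }
  if (min_repeats > n_repeats) {
    stop2("min_repeats (", min_repeats, ") exceeds the number of repeats in the design (",
          n_repeats, ")")
  }
  keep <- lengths(reps) >= min_repeats
  grp <- interaction(table$compartment, table$condition, drop = FALSE)
  counts <- data.frame(group = levels(grp),
                       before = as.integer(table(grp)),
                       after = as.integer(table(grp[keep])))
  out <- table[keep, , drop = FALSE]
  attr(out, "filter_counts") <- counts
  out
}

# Distinct peptide sequences of one (compartment, condition) group.
peptide_set <- function(table, compartment, condition) {
  unique(table$sequence[table$compartment == compartment &
                        table$condition == condition])
}

#' Two-set Venn partition of peptide sequences
#'
#' @param set_a,set_b Character vectors of peptide sequences.
#' @param labels Length-2 labels for reporting.
#' @return A `venn_summary`: counts and sequence lists of the three
#'   partitions plus `percent_shared` (shared / union, percent). The counts
#'   always satisfy unique_a + shared + unique_b = |union|.
#' @export
venn_counts <- function(set_a, set_b, labels = c("A", "B")) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  shared <- intersect(set_a, set_b)
  ua <- setdiff(set_a, set_b)
  ub <- setdiff(set_b, set_a)
  n_union <- length(shared) + length(ua) + length(ub)
  structure(list(labels = labels,
                 unique_a = length(ua), shared = length(shared),
                 unique_b = length(ub),
                 unique_a_seqs = ua, shared_seqs = shared, unique_b_seqs = ub,
                 percent_shared = if (n_union) 100 * length(shared) / n_union else NA_real_),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("venn: %s-unique %d | shared %d (%.1f%% of union) | %s-unique %d\n",
              x$labels[1], x$unique_a, x$shared,
              x$percent_shared, x$labels[2], x$unique_b))
  invisible(x)
}

#' Per-repeat dispersion of the shared fraction
#'
#' Recomputes the shared percentage of two peptide groups restricting both
#' to one biological repeat at a time, giving a mean and standard deviation
#' across repeat pairings (the dispersion shown alongside Venn counts).
#'
#' @param table A filtered `peptide_table`.
#' @param compartment Compartment to compare within.
#' @param conditions Length-2 condition labels.
#' @return List with `per_repeat` (percent shared per repeat index),
#'   `mean` and `sd`.
#' @export
percent_shared_by_repeat <- function(table, compartment = "cell",
                                     conditions = c("control", "treated")) {
  sub <- table[table$compartment == compartment, , drop = FALSE]
  reps <- repeat_sets(sub)
  all_reps <- sort(unique(unlist(reps)))
  per <- vapply(all_reps, function(r) {
    in_r <- vapply(reps, function(v) r %in% v, logical(1))
    a <- unique(sub$sequence[in_r & sub$condition == conditions[1]])
    b <- unique(sub$sequence[in_r & sub$condition == conditions[2]])
    venn_counts(a, b)$percent_shared
  }, numeric(1))
  list(per_repeat = setNames(per, all_reps),
       mean = mean(per, na.rm = TRUE), sd = stats::sd(per))
}

#' Treatment-unique peptides arising from new precursors
#'
#' Among the peptides unique to the treated condition, counts those whose
#' precursor proteins contribute no peptide at all to the control set —
#' i.e. proteolysis of proteins newly targeted under treatment rather than
#' intensified degradation of already-processed precursors.
#'
#' @param venn A `venn_summary` of control (A) vs treated (B) peptide sets.
#' @param table The `peptide_table` the sets came from (used for the
#'   peptide-to-precursor map).
#' @return List with `count`, `fraction` (NA when there are no
#'   treatment-unique peptides) and the new-precursor peptide sequences.
#' @export
new_precursor_fraction <- function(venn, table) {
  seq_prot <- mapping_sites(table)
  prot_of <- split(seq_prot$protein, seq_prot$sequence)
  control_seqs <- c(venn$unique_a_seqs, venn$shared_seqs)
  control_prots <- unique(unlist(prot_of[intersect(control_seqs, names(prot_of))],
                                 use.names = FALSE))
  uniq <- venn$unique_b_seqs
  if (!length(uniq)) {
    return(list(count = 0L, fraction = NA_real_, sequences = character(0)))
  }
  is_new <- vapply(uniq, function(s) {
    prots <- prot_of[[s]]
    length(prots) > 0L && !any(prots %in% control_prots)
  }, logical(1))
  list(count = sum(is_new), fraction = sum(is_new) / length(uniq),
       sequences = uniq[is_new])
}

#' Is a peptide C-terminal?
#'
#' A peptide is C-terminal when it starts within `window_aa` residues of
#' its precursor's C-terminus, i.e. `start >= L - window_aa + 1` for a
#' precursor of length `L`. The rule uses the start position only; a
#' precursor shorter than the window makes every peptide C-terminal.
#'
#' @param start Peptide start position(s), 1-based.
#' @param protein_length Precursor length(s).
#' @param window_aa Window size (default 50).
#' @return Logical vector.
#' @export
is_cterminal <- function(start, protein_length, window_aa = 50L) {
  start >= protein_length - window_aa + 1L
}

#' Classify every mapped peptide row as C-terminal or not
#'
#' Ambiguous multi-site peptides are C-terminal if any matched site
#' qualifies (such rows keep their `ambiguous` flag). Unmapped rows are an
#' error: the rule needs coordinates.
#'
#' @param table A mapped `peptide_table`.
#' @param proteome A `proteome_map`.
#' @param window_aa Window size (default 50).
#' @return Logical vector along the rows of `table`.
#' @export
classify_cterminal <- function(table, proteome, window_aa = 50L) {
  if (any(table$unmapped)) {
    stop2(sum(table$unmapped), " unmapped row(s): C-terminal classification needs coordinates")
  }
  sites <- mapping_sites(table)
  L <- proteome$lengths[sites$protein]
  if (anyNA(L)) stop2("mapped protein(s) absent from proteome")
  site_ct <- is_cterminal(sites$start, L, window_aa)
  out <- rep(FALSE, nrow(table))
  hit <- tapply(site_ct, sites$row, any)
  out[as.integer(names(hit))] <- as.logical(hit)
  out
}

#' Log2 fold change between two intensity vectors
#'
#' Mean-of-observed intensities in each condition, then
#' `log2(mean_to / mean_from)`. Rows quantified in fewer than `min_obs`
#' repeats of either condition are flagged rather than forced to a number:
#' `present_only_from` / `present_only_to` when one side has no signal at
#' all, `not_quantified` when neither does, `low_evidence` otherwise.
#'
#' @param from,to Numeric vectors of per-repeat intensities (NA = missing).
#' @param min_obs Minimum observed repeats per side for a quantified call.
#' @return List with `log2fc` (NA unless status is `quantified`) and
#'   `status`.
#' @export
log2_fold_change <- function(from, to, min_obs = 2L) {
  n_from <- sum(!is.na(from))
  n_to <- sum(!is.na(to))
  if (n_from == 0L && n_to == 0L) {
    return(list(log2fc = NA_real_, status = "not_quantified"))
  }
  if (n_from == 0L) return(list(log2fc = NA_real_, status = "present_only_to"))
  if (n_to == 0L) return(list(log2fc = NA_real_, status = "present_only_from"))
  if (n_from < min_obs || n_to < min_obs) {
    return(list(log2fc = NA_real_, status = "low_evidence"))
  }
  list(log2fc = log2(mean(to, na.rm = TRUE) / mean(from, na.rm = TRUE)),
       status = "quantified")
}

#' Per-peptide fold-change table between conditions
#'
#' Joins the control and treated rows of each peptide within a compartment
#' and applies [log2_fold_change()].
#'
#' @param table A filtered `peptide_table`.
#' @param compartment Compartment to work within.
#' @param min_obs Minimum observed repeats per condition (default 2).
#' @param upregulated_log2fc Cutoff for the `upregulated` flag (default 1).
#' @return data.frame with per-peptide condition means, `log2fc`, `status`
#'   and `upregulated`.
#' @export
fold_change_table <- function(table, compartment = "cell", min_obs = 2L,
                              upregulated_log2fc = 1) {
  sub <- table[table$compartment == compartment, , drop = FALSE]
  icols <- intensity_cols(sub)
  seqs <- unique(sub$sequence)
  side <- function(cond) {
    rows <- sub$condition == cond
    I <- as.matrix(as.data.frame(sub)[rows, icols, drop = FALSE])
    storage.mode(I) <- "double"
    grp <- match(sub$sequence[rows], seqs)
    sums <- rowsum(ifelse(is.na(I), 0, I), grp)
    ns <- rowsum((!is.na(I)) * 1L, grp)
    n <- setNames(integer(length(seqs)), seqs)
    s <- setNames(numeric(length(seqs)), seqs)
    idx <- as.integer(rownames(sums))
    n[idx] <- rowSums(ns)
    s[idx] <- rowSums(sums)
    list(n = n, mean = ifelse(n > 0, s / pmax(n, 1L), NA_real_))
  }
  ctl <- side("control")
  trt <- side("treated")
  status <- rep("quantified", length(seqs))
  status[ctl$n < min_obs | trt$n < min_obs] <- "low_evidence"
  status[ctl$n == 0L] <- "present_only_to"
  status[trt$n == 0L] <- "present_only_from"
  status[ctl$n == 0L & trt$n == 0L] <- "not_quantified"
  out <- data.frame(sequence = seqs,
                    mean_control = unname(ctl$mean),
                    mean_treated = unname(trt$mean),
                    n_control = unname(ctl$n), n_treated = unname(trt$n),
                    log2fc = ifelse(status == "quantified",
                                    log2(trt$mean / ctl$mean), NA_real_),
                    status = status, stringsAsFactors = FALSE)
  out$upregulated <- !is.na(out$log2fc) & out$log2fc > upregulated_log2fc
  out
}

#' Pearson correlation of peptide intensities between two groups
#'
#' Correlates (by default log10-transformed) mean intensities of the
#' peptides quantified in both groups. One-condition-only peptides carry no
#' pair and are excluded upstream.
#'
#' @param x,y Numeric vectors of paired mean intensities.
#' @param use_log10 Correlate log10 intensities (default TRUE).
#' @return List with `r`, `p_value` and `n`.
#' @export
intensity_correlation <- function(x, y, use_log10 = TRUE) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop2("need at least 3 paired intensities, have ", length(x))
  if (use_log10) {
    x <- log10(x); y <- log10(y)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Cross-condition intensity correlation within a compartment
#'
#' @param table A filtered `peptide_table`.
#' @param compartment Compartment to work within.
#' @param min_obs Minimum observed repeats per condition.
#' @param use_log10 Correlate log10 mean intensities (default TRUE).
#' @return List with `r`, `p_value` and `n`.
#' @export
condition_correlation <- function(table, compartment = "cell", min_obs = 2L,
                                  use_log10 = TRUE) {
  fc <- fold_change_table(table, compartment, min_obs)
  q <- fc[fc$status == "quantified", , drop = FALSE]
  intensity_correlation(q$mean_control, q$mean_treated, use_log10 = use_log10)
}

#' Small-precursor flags
#'
#' @param proteome A `proteome_map`.
#' @param threshold_aa Strict upper bound (default 200): proteins with
#'   length < threshold are flagged.
#' @return Character vector of small-protein ids.
#' @export
small_protein_flags <- function(proteome, threshold_aa = 200L) {
  names(proteome$lengths)[proteome$lengths < threshold_aa]
}
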