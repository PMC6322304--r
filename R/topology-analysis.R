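#' Locate a peptide relative to membrane topology
#'
#' Assigns each mapped peptide the topology label (`inside`, `outside`,
#' `TMhelix`) covering the strict majority of its residues on its precursor;
#' an exact tie gives `mixed`, and peptides whose precursor has no topology
#' record (or whose span lies outside every annotated segment) are
#' `unannotated`. Ambiguous multi-site peptides are classified at their
#' first site. Splitting a segment into adjacent same-label pieces does not
#' change the call.
#'
#' @param table A mapped `peptide_table`.
#' @param topology A `topology_map`.
#' @return data.frame with one row per table row: `sequence`, `protein`,
#'   `location` and per-label overlap residue counts.
#' @export
classify_location <- function(table, topology) {
  labs <- c("inside", "outside", "TMhelix")
  n <- nrow(table)
  loc <- rep("unannotated", n)
  ov <- matrix(0L, nrow = n, ncol = 3, dimnames = list(NULL, labs))
  prot1 <- vapply(split_field(table$proteins),
                  function(v) if (length(v)) v[1] else NA_character_, character(1))
  for (i in seq_len(n)) {
    p <- prot1[i]
    if (is.na(p) || is.null(topology[[p]]) || is.na(table$start[i])) next
    seg <- topology[[p]]
    for (j in seq_len(nrow(seg))) {
      o <- min(table$end[i], seg$end[j]) - max(table$start[i], seg$start[j]) + 1L
      if (o > 0L) ov[i, seg$label[j]] <- ov[i, seg$label[j]] + o
    }
    if (sum(ov[i, ]) == 0L) next
    top <- max(ov[i, ])
    winners <- labs[ov[i, ] == top]
    loc[i] <- if (length(winners) == 1L) winners else "mixed"
  }
  data.frame(sequence = table$sequence, protein = prot1, location = loc,
             inside = ov[, "inside"], outside = ov[, "outside"],
             TMhelix = ov[, "TMhelix"], stringsAsFactors = FALSE)
}

#' Compartment x location over-representation tests
#'
#' For each location label of interest (by default `inside` and `outside`),
#' a two-sided Fisher exact test of the 2x2 table compartment x is-label
#' over the classified peptides of the two compartments. `mixed` and
#' `unannotated` peptides are excluded from the margins (their counts are
#' reported). A zero margin yields p = 1 with a warning. Swapping the
#' compartments inverts each odds ratio.
#'
#' @param locations_a,locations_b Outputs of [classify_location()] for the
#'   two compartments (e.g. cell and secretome).
#' @param labels Compartment labels for reporting.
#' @param which_labels Location labels to test.
#' @return data.frame with per-label counts, `odds_ratio` (label odds in
#'   compartment A over B), `p_value`; attribute `excluded` counts
#'   mixed/unannotated peptides per compartment.
#' @export
location_enrichment <- function(locations_a, locations_b,
                                labels = c("cell", "secretome"),
                                which_labels = c("inside", "outside")) {
  core <- c("inside", "outside", "TMhelix")
  a <- locations_a$location[locations_a$location %in% core]
  b <- locations_b$location[locations_b$location %in% core]
  res <- lapply(which_labels, function(lab) {
    tab <- matrix(c(sum(a == lab), sum(a != lab),
                    sum(b == lab), sum(b != lab)), nrow = 2, byrow = TRUE)
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      warning("zero margin for label '", lab, "'; p reported as 1", call. = FALSE)
      return(data.frame(location = lab,
                        count_a = tab[1, 1], total_a = sum(tab[1, ]),
                        count_b = tab[2, 1], total_b = sum(tab[2, ]),
                        odds_ratio = NA_real_, p_value = 1,
                        stringsAsFactors = FALSE))
    }
    ft <- stats::fisher.test(tab)
    data.frame(location = lab,
               count_a = tab[1, 1], total_a = sum(tab[1, ]),
               count_b = tab[2, 1], total_b = sum(tab[2, ]),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[names(out) == "count_a"] <- paste0("count_", labels[1])
  names(out)[names(out) == "total_a"] <- paste0("total_", labels[1])
  names(out)[names(out) == "count_b"] <- paste0("count_", labels[2])
  names(out)[names(out) == "total_b"] <- paste0("total_", labels[2])
  attr(out, "excluded") <-
    c(setNames(sum(!locations_a$location %in% core), labels[1]),
      setNames(sum(!locations_b$location %in% core), labels[2]))
  out
}
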