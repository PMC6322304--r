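# AAindex accessions of well-known hydrophobicity scales (Kyte-Doolittle
# hydropathy, Eisenberg consensus, Fauchere-Pliska partition coefficient pi,
# Nozaki-Tanford transfer energy). The index cluster containing these is
# labelled the hydrophobicity cluster in reports.
HYDROPHOBICITY_REFERENCE_IDS <- c("KYTJ820101", "EISD840101",
                                  "FAUJ830101", "NOZY710101")

#' Two-sided Mann-Whitney U test
#'
#' The two-group test used throughout the property screen. For small
#' samples (both groups <= `exact_max`) the p-value is computed by
#' exhaustive enumeration of all group labelings of the pooled values
#' (exact even under ties, two-sided by symmetric distance of U from its
#' null mean). Larger samples use the tie-corrected normal approximation
#' without continuity correction.
#'
#' @param x,y Numeric vectors (each of length >= 1).
#' @param exact_max Largest per-group size for the exact path (default 8).
#' @return List with `u` (U statistic of `x`), `p_value`, `method`.
#' @export
mw_test <- function(x, y, exact_max = 8L) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop2("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (max(n1, n2) <= exact_max) {
    p <- mw_exact_p(r, n1, u)
    method <- "exact enumeration"
  } else {
    p <- mw_normal_p(r, n1, n2, u)
    method <- "normal approximation (tie-corrected)"
  }
  list(u = u, p_value = p, method = method)
}

# Exact two-sided p by enumerating all choose(N, n1) labelings of the
# pooled ranks; extremeness measured as |U - n1*n2/2|.
mw_exact_p <- function(ranks, n1, u_obs) {
  N <- length(ranks)
  n2 <- N - n1
  mu <- n1 * n2 / 2
  combs <- utils::combn(N, n1)
  u_all <- colSums(matrix(ranks[combs], nrow = n1)) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Tie-corrected normal approximation (no continuity correction).
mw_normal_p <- function(ranks, n1, n2, u) {
  N <- n1 + n2
  ties <- table(ranks)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  z <- (u - n1 * n2 / 2) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}

#' AAindex property screen between two peptide sets
#'
#' Scores both sets on every complete AAindex entry (mean per-residue value
#' per peptide) and tests each index with a two-sided Mann-Whitney U test.
#' Raw p-values are binned into nested significance tiers (by default
#' `sig` p < 1e-5, `sigAA` p < 1e-15, `top` p < 1e-25; each tier is a
#' subset of the previous one) and BH-adjusted q-values are reported as
#' well. Direction is the group with the larger median descriptor.
#'
#' @param peptides_a,peptides_b Character vectors of peptides (at least 2
#'   usable standard-alphabet peptides each).
#' @param aaindex An `aaindex_table`.
#' @param p_tiers Named, strictly decreasing significance thresholds.
#' @param labels Group labels used for the direction column.
#' @return data.frame of class `property_screen` with one row per complete
#'   index: `index`, `description`, `u`, `p_value`, `q_value`, `direction`,
#'   `tier`; attribute `n_indexes` records the usable-index count.
#' @export
property_screen <- function(peptides_a, peptides_b, aaindex,
                            p_tiers = c(sig = 1e-5, sigAA = 1e-15, top = 1e-25),
                            labels = c("A", "B")) {
  pa <- property_matrix(peptides_a, aaindex)
  pb <- property_matrix(peptides_b, aaindex)
  if (nrow(pa) < 2L || nrow(pb) < 2L) {
    stop2("need at least 2 usable peptides per group")
  }
  ids <- intersect(colnames(pa), colnames(pb))
  n1 <- nrow(pa); n2 <- nrow(pb)
  small <- max(n1, n2) <= 8L
  stats_list <- lapply(ids, function(id) {
    if (small) {
      mw <- mw_test(pa[, id], pb[, id])
      c(u = mw$u, p = mw$p_value)
    } else {
      pooled <- c(pa[, id], pb[, id])
      r <- rank(pooled)
      u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
      c(u = u, p = mw_normal_p(r, n1, n2, u))
    }
  })
  u <- vapply(stats_list, `[[`, numeric(1), "u")
  p <- vapply(stats_list, `[[`, numeric(1), "p")
  med_a <- apply(pa[, ids, drop = FALSE], 2, stats::median)
  med_b <- apply(pb[, ids, drop = FALSE], 2, stats::median)
  direction <- ifelse(med_a > med_b, labels[1],
                      ifelse(med_b > med_a, labels[2], "tie"))
  out <- data.frame(index = ids,
                    description = vapply(aaindex[ids], `[[`, character(1), "description"),
                    u = u, p_value = p,
                    q_value = stats::p.adjust(p, method = "BH"),
                    direction = direction,
                    tier = assign_tier(p, p_tiers),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_indexes") <- length(ids)
  attr(out, "labels") <- labels
  class(out) <- c("property_screen", "data.frame")
  out
}

# Deepest tier whose threshold the p-value beats; "ns" otherwise.
assign_tier <- function(p, p_tiers) {
  tier <- rep("ns", length(p))
  for (i in seq_along(p_tiers)) {
    tier[p < p_tiers[i]] <- names(p_tiers)[i]
  }
  tier
}

#' @export
print.property_screen <- function(x, ...) {
  tiers <- table(x$tier)
  cat("property_screen:", nrow(x), "indexes;",
      paste(names(tiers), tiers, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Ward clustering of AAindex entries
#'
#' Each index's profile across the pooled peptides is z-scored and indexes
#' are clustered by Ward linkage (ward.D2) on Euclidean distance, cutting
#' the tree into `n_clusters` groups. Zero-variance indexes cannot be
#' z-scored and are excluded with a warning. Columns are processed in
#' lexical index-id order, making the result independent of input order.
#'
#' @param property_mat Peptide x index matrix from [property_matrix()]
#'   (typically over both peptide sets pooled).
#' @param n_clusters Number of clusters (default 6).
#' @return List of class `index_clustering` with `cluster` (named integer),
#'   `members` (per-cluster id lists), `hclust` and `excluded`.
#' @export
cluster_indexes <- function(property_mat, n_clusters = 6L) {
  property_mat <- property_mat[, order(colnames(property_mat)), drop = FALSE]
  sds <- apply(property_mat, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant index(es) excluded from clustering",
            call. = FALSE)
  }
  keep <- sds > 0
  if (sum(keep) < n_clusters) {
    stop2("fewer variable indexes (", sum(keep), ") than clusters (", n_clusters, ")")
  }
  z <- scale(property_mat[, keep, drop = FALSE])
  hc <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  cl <- stats::cutree(hc, k = n_clusters)
  structure(list(cluster = cl,
                 members = split(names(cl), cl),
                 hclust = hc,
                 excluded = colnames(property_mat)[!keep]),
            class = "index_clustering")
}

#' @export
print.index_clustering <- function(x, ...) {
  cat("index_clustering:", length(x$cluster), "indexes in",
      length(x$members), "clusters (sizes",
      paste(lengths(x$members), collapse = ", "), ")\n")
  invisible(x)
}

#' Which cluster is the hydrophobicity cluster?
#'
#' The cluster holding the plurality of the reference hydrophobicity scales
#' (Kyte-Doolittle, Eisenberg, Fauchere-Pliska partition coefficient,
#' Nozaki-Tanford transfer energy) present in the clustering.
#'
#' @param clustering An `index_clustering`.
#' @param reference_ids Reference accession ids.
#' @return The cluster label (integer), or NA if no reference id was
#'   clustered.
#' @export
hydrophobicity_cluster <- function(clustering,
                                   reference_ids = HYDROPHOBICITY_REFERENCE_IDS) {
  hit <- clustering$cluster[intersect(reference_ids, names(clustering$cluster))]
  if (!length(hit)) return(NA_integer_)
  as.integer(names(sort(table(hit), decreasing = TRUE))[1])
}

#' Cluster enrichment in a significant index set
#'
#' For every cluster, a two-sided Fisher exact test of the 2x2 table
#' (in cluster x significant), BH-corrected across clusters. Used to ask
#' which property family (e.g. the hydrophobicity cluster) carries the
#' between-compartment differences.
#'
#' @param clustering An `index_clustering`.
#' @param significant_ids Character vector of significant index ids (a
#'   subset of the clustered universe; ids outside it are ignored).
#' @return data.frame with per-cluster counts, `odds_ratio`, `p_value`,
#'   `q_value`.
#' @export
cluster_enrichment <- function(clustering, significant_ids) {
  universe <- names(clustering$cluster)
  sig <- universe %in% significant_ids
  res <- lapply(sort(unique(clustering$cluster)), function(k) {
    in_k <- clustering$cluster == k
    tab <- matrix(c(sum(in_k & sig), sum(in_k & !sig),
                    sum(!in_k & sig), sum(!in_k & !sig)), nrow = 2, byrow = TRUE)
    ft <- stats::fisher.test(tab)
    data.frame(cluster = k, size = sum(in_k), n_significant = sum(in_k & sig),
               odds_ratio = unname(ft$estimate), p_value = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}
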