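#' Analysis run configuration
#'
#' Collects the fixed analysis constants in one validated object: the
#' replicate filter, the C-terminal window, the number of PDP windows, the
#' terminal-profile width, the significance tiers of the property screen,
#' the number of index clusters, the small-protein cutoff, the consensus
#' thresholds of the antimicrobial predictors, and the up-regulation
#' fold-change cutoff.
#'
#' @param min_repeats Minimum biological repeats a peptide must be
#'   identified in to be retained (default 2).
#' @param cterm_window_aa C-terminal window: a peptide is C-terminal when it
#'   starts within this many residues of the precursor C-terminus
#'   (default 50).
#' @param n_pdp_windows Number of relative-position windows in the PDP
#'   matrix (default 10, i.e. 10% of precursor length each).
#' @param terminal_k Number of terminal residues profiled at each end
#'   (default 5).
#' @param p_tiers Strictly decreasing significance tiers of the property
#'   screen (defaults 1e-5, 1e-15, 1e-25: tiers `sig`, `sigAA`, `top`).
#' @param n_clusters Number of Ward clusters cut from the index tree
#'   (default 6).
#' @param small_protein_aa Strict upper bound defining a small precursor
#'   (default 200 aa).
#' @param amp_thresholds Named list of predictor call thresholds: `camp`
#'   and `iamppred` probabilities called at >= threshold (default 0.5),
#'   `adam` score called at > threshold (default 0).
#' @param upregulated_log2fc Log2 fold change above which a peptide is
#'   flagged up-regulated (default 1).
#' @param rng_seed Seed for the stochastic steps (background sampling).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(min_repeats = 2L,
                       cterm_window_aa = 50L,
                       n_pdp_windows = 10L,
                       terminal_k = 5L,
                       p_tiers = c(sig = 1e-5, sigAA = 1e-15, top = 1e-25),
                       n_clusters = 6L,
                       small_protein_aa = 200L,
                       amp_thresholds = list(camp = 0.5, iamppred = 0.5, adam = 0),
                       upregulated_log2fc = 1,
                       rng_seed = 1L) {
  cfg <- list(min_repeats = as.integer(min_repeats),
              cterm_window_aa = as.integer(cterm_window_aa),
              n_pdp_windows = as.integer(n_pdp_windows),
              terminal_k = as.integer(terminal_k),
              p_tiers = p_tiers,
              n_clusters = as.integer(n_clusters),
              small_protein_aa = as.integer(small_protein_aa),
              amp_thresholds = amp_thresholds,
              upregulated_log2fc = upregulated_log2fc,
              rng_seed = as.integer(rng_seed))
  stopifnot(cfg$min_repeats >= 1L, cfg$cterm_window_aa >= 0L,
            cfg$n_pdp_windows >= 1L, cfg$terminal_k >= 1L,
            cfg$n_clusters >= 1L, cfg$small_protein_aa >= 0L)
  if (is.null(names(cfg$p_tiers)) || length(cfg$p_tiers) < 1L) {
    stop2("p_tiers must be a named vector of significance thresholds")
  }
  if (any(diff(cfg$p_tiers) >= 0)) stop2("p_tiers must be strictly decreasing")
  for (k in c("camp", "iamppred", "adam")) {
    if (is.null(cfg$amp_thresholds[[k]])) stop2("amp_thresholds must name ", k)
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Keys absent from the file keep the [run_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$p_tiers)) raw$p_tiers <- unlist(raw$p_tiers)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) stop2("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config: min_repeats=", x$min_repeats,
      ", cterm_window=", x$cterm_window_aa,
      ", pdp_windows=", x$n_pdp_windows,
      ", terminal_k=", x$terminal_k,
      ", clusters=", x$n_clusters,
      ", tiers=", paste(format(x$p_tiers, digits = 3), collapse = "/"),
      "\n", sep = "")
  invisible(x)
}
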