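#' Run the full peptidome comparison pipeline
#'
#' Orchestrates every stage on one peptide table: replicate filtering,
#' condition set algebra (Venn, new-precursor fraction, shared-percent
#' dispersion), C-terminal and small-protein classification, fold changes
#' and cross-condition intensity correlation, PDP matrices and similarity,
#' amino-acid and terminal composition with a background peptide set,
#' AAindex property screening with optional Ward clustering and cluster
#' enrichment, topology localization enrichment, and consensus
#' antimicrobial triage when predictor scores are supplied.
#'
#' @param table A `peptide_table` (mapped; will be validated against the
#'   proteome).
#' @param proteome A `proteome_map`.
#' @param topology Optional `topology_map`; when NULL or empty the
#'   localization stage is skipped with a warning.
#' @param amp_scores Optional `amp_scores` table; when NULL the triage
#'   stage is skipped.
#' @param config A `run_config`.
#' @param aaindex An `aaindex_table` (default [load_aaindex()]).
#' @param background_n Background peptides to sample (default 1000).
#' @param do_clustering Run index clustering + cluster enrichment
#'   (default TRUE; the screen itself always runs).
#' @return An object of class `peptidome_run` collecting every stage's
#'   output plus row-count logging per stage.
#' @export
run_pipeline <- function(table, proteome, topology = NULL, amp_scores = NULL,
                         config = run_config(), aaindex = load_aaindex(),
                         background_n = 1000L, do_clustering = TRUE) {
  log <- list(rows_in = nrow(table))
  filtered <- replicate_filter(table, config$min_repeats)
  log$rows_filtered <- nrow(filtered)
  log$filter_counts <- attr(filtered, "filter_counts")

  compartments <- intersect(c("cell", "secretome"), unique(filtered$compartment))
  core <- list()
  for (comp in compartments) {
    ctl <- peptide_set(filtered, comp, "control")
    trt <- peptide_set(filtered, comp, "treated")
    venn <- venn_counts(ctl, trt, labels = c("control", "treated"))
    sub <- filtered[filtered$compartment == comp, , drop = FALSE]
    fc <- fold_change_table(filtered, comp, config$min_repeats,
                            config$upregulated_log2fc)
    corr <- tryCatch(condition_correlation(filtered, comp, config$min_repeats),
                     error = function(e) NULL)
    ct <- classify_cterminal(sub[!sub$unmapped, , drop = FALSE], proteome,
                             config$cterm_window_aa)
    core[[comp]] <- list(
      venn = venn,
      shared_dispersion = percent_shared_by_repeat(filtered, comp),
      new_precursor = new_precursor_fraction(venn, sub),
      fold_change = fc,
      correlation = corr,
      cterm_fraction = mean(ct[!duplicated(sub$sequence[!sub$unmapped])]),
      n_peptides = length(union(ctl, trt)))
  }
  small <- small_protein_flags(proteome, config$small_protein_aa)

  pdp <- list()
  for (comp in compartments) {
    mats <- lapply(c("control", "treated"), function(cond) {
      pdp_matrix(filtered[filtered$compartment == comp &
                          filtered$condition == cond, , drop = FALSE],
                 proteome, config$n_pdp_windows)
    })
    names(mats) <- c("control", "treated")
    sim <- tryCatch(pdp_similarity(mats$control, mats$treated),
                    error = function(e) NULL)
    pdp[[comp]] <- list(matrices = mats, similarity = sim)
  }

  physchem <- list()
  comp_seqs <- lapply(compartments, function(comp) {
    unique(filtered$sequence[filtered$compartment == comp])
  })
  names(comp_seqs) <- compartments
  bg <- tryCatch(
    background_peptides(proteome, filtered, background_n, config$rng_seed),
    error = function(e) {
      warning("background sampling failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
  physchem$background <- bg
  physchem$aaf <- lapply(comp_seqs, aa_frequencies)
  if (!is.null(bg)) physchem$aaf$background <- aa_frequencies(bg)
  if (length(compartments) == 2L) {
    physchem$aaf_compare <- compare_aaf(physchem$aaf[[1]], physchem$aaf[[2]])
  }
  physchem$terminal <- lapply(comp_seqs, function(s) {
    list(N = terminal_profile(s, "N", config$terminal_k),
         C = terminal_profile(s, "C", config$terminal_k))
  })
  if (length(compartments) == 2L) {
    screen <- property_screen(comp_seqs[[1]], comp_seqs[[2]], aaindex,
                              config$p_tiers, labels = compartments)
    physchem$screen <- screen
    if (do_clustering) {
      pooled <- unique(unlist(comp_seqs))
      pm <- property_matrix(pooled, aaindex)
      clustering <- cluster_indexes(pm, config$n_clusters)
      sig_ids <- screen$index[screen$tier != "ns"]
      physchem$clustering <- clustering
      physchem$cluster_enrichment <- cluster_enrichment(clustering, sig_ids)
      physchem$hydrophobicity_cluster <- hydrophobicity_cluster(clustering)
    }
  }

  topo_res <- NULL
  if (is.null(topology) || length(topology) == 0L) {
    warning("no topology annotations: localization stage skipped", call. = FALSE)
  } else if (length(compartments) == 2L) {
    locs <- lapply(compartments, function(comp) {
      sub <- filtered[filtered$compartment == comp, , drop = FALSE]
      sub <- sub[!duplicated(sub$sequence) & !sub$unmapped, , drop = FALSE]
      classify_location(sub, topology)
    })
    names(locs) <- compartments
    topo_res <- list(locations = locs,
                     enrichment = location_enrichment(locs[[1]], locs[[2]],
                                                      labels = compartments))
  }

  amp <- NULL
  if (!is.null(amp_scores)) {
    calls <- consensus_amp(amp_scores, config$amp_thresholds)
    amp <- list(calls = calls)
    for (comp in compartments) {
      universe <- comp_seqs[[comp]]
      amp[[comp]] <- list(
        rate = tryCatch(amp_rate(calls, universe), error = function(e) NA_real_),
        candidates = prioritize_candidates(
          calls[calls$peptide %in% universe, , drop = FALSE], amp_scores,
          core[[comp]]$fold_change, compartment = comp,
          upregulated_log2fc = config$upregulated_log2fc))
    }
  }

  structure(list(config = config, filtered = filtered, core = core,
                 small_proteins = small, pdp = pdp, physchem = physchem,
                 topology = topo_res, amp = amp, log = log,
                 compartments = compartments),
            class = "peptidome_run")
}

#' @export
print.peptidome_run <- function(x, ...) {
  cat("peptidome_run (", x$log$rows_in, " rows in, ", x$log$rows_filtered,
      " after the >=", x$config$min_repeats, "-repeat filter)\n", sep = "")
  for (comp in x$compartments) {
    v <- x$core[[comp]]$venn
    cat(sprintf("  %s: %d peptides; treated-unique %d; shared %.1f%%",
                comp, x$core[[comp]]$n_peptides, v$unique_b, v$percent_shared))
    np <- x$core[[comp]]$new_precursor
    if (!is.na(np$fraction)) {
      cat(sprintf("; new-precursor %d (%.0f%%)", np$count, 100 * np$fraction))
    }
    cat("\n")
  }
  if (!is.null(x$physchem$screen)) {
    tiers <- table(x$physchem$screen$tier)
    cat("  property screen:", paste(names(tiers), tiers, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.peptidome_run <- function(object, ...) {
  x <- object
  print(x)
  for (comp in x$compartments) {
    cc <- x$core[[comp]]$correlation
    if (!is.null(cc)) {
      cat(sprintf("  %s condition correlation: r=%.3f (n=%d)\n", comp, cc$r, cc$n))
    }
    ps <- x$pdp[[comp]]$similarity
    if (!is.null(ps)) {
      cat(sprintf("  %s PDP similarity (median cosine): %.3f\n", comp, ps$median))
    }
    cat(sprintf("  %s C-terminal fraction: %.1f%%\n", comp,
                100 * x$core[[comp]]$cterm_fraction))
  }
  if (!is.null(x$topology)) {
    print(x$topology$enrichment)
  }
  if (!is.null(x$amp)) {
    for (comp in x$compartments) {
      cat(sprintf("  %s consensus AMP rate: %.2f%%\n", comp,
                  100 * x$amp[[comp]]$rate))
    }
  }
  invisible(x)
}

#' Write a pipeline run as a TSV bundle with a manifest
#'
#' Emits the filtered table, per-compartment Venn/fold-change summaries,
#' PDP matrices and similarities, screen results, clusters, terminal
#' profiles, location enrichment and AMP candidate rankings, plus a JSON
#' manifest with the configuration, seed and per-file md5 checksums.
#'
#' @param run A `peptidome_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_run_bundle <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  write_peptide_table(run$filtered, file.path(dir, "filtered_peptides.tsv"))
  venn <- do.call(rbind, lapply(run$compartments, function(comp) {
    v <- run$core[[comp]]$venn
    np <- run$core[[comp]]$new_precursor
    data.frame(compartment = comp, unique_control = v$unique_a,
               shared = v$shared, unique_treated = v$unique_b,
               percent_shared = v$percent_shared,
               new_precursor_count = np$count,
               new_precursor_fraction = np$fraction)
  }))
  wt(venn, "venn_summary.tsv")
  for (comp in run$compartments) {
    wt(run$core[[comp]]$fold_change, paste0("fold_change_", comp, ".tsv"))
    for (cond in names(run$pdp[[comp]]$matrices)) {
      m <- run$pdp[[comp]]$matrices[[cond]]
      wt(data.frame(protein = rownames(m), as.data.frame(unclass(m))),
         paste0("pdp_", comp, "_", cond, ".tsv"))
    }
  }
  if (!is.null(run$physchem$screen)) wt(run$physchem$screen, "screen_results.tsv")
  if (!is.null(run$physchem$clustering)) {
    cl <- run$physchem$clustering$cluster
    wt(data.frame(index = names(cl), cluster = unname(cl)), "clusters.tsv")
    wt(run$physchem$cluster_enrichment, "cluster_enrichment.tsv")
  }
  for (comp in run$compartments) {
    for (term in c("N", "C")) {
      tp <- run$physchem$terminal[[comp]][[term]]
      wt(data.frame(residue = rownames(tp$pfm), as.data.frame(tp$pfm)),
         paste0("terminal_profile_", comp, "_", term, ".tsv"))
    }
  }
  if (!is.null(run$topology)) wt(run$topology$enrichment, "location_enrichment.tsv")
  if (!is.null(run$amp)) {
    for (comp in run$compartments) {
      wt(run$amp[[comp]]$candidates, paste0("candidates_ranked_", comp, ".tsv"))
    }
  }
  files <- setdiff(list.files(dir, full.names = TRUE),
                   file.path(dir, "manifest.json"))
  manifest <- list(config = unclass(run$config),
                   seed = run$config$rng_seed,
                   package_version = as.character(utils::packageVersion("pepdegradome")),
                   rows = run$log[c("rows_in", "rows_filtered")],
                   files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Compare pipeline output against simulator ground truth
#'
#' Closed-loop validation metrics: bias and RMSE of recovered vs injected
#' log2 fold changes, recovered vs true treated-unique and new-precursor
#' counts, whether the designated hydrophobicity indexes were flagged with
#' the correct direction, the inside/outside localization enrichment
#' direction, and the consensus AMP rate vs the configured fraction.
#'
#' @param run A `peptidome_run` produced from the simulated table.
#' @param sim The `synthetic_peptidome` it came from.
#' @return List of class `truth_recovery` of per-aspect metrics.
#' @export
truth_recovery_report <- function(run, sim) {
  out <- list()
  for (comp in run$compartments) {
    fc <- run$core[[comp]]$fold_change
    tr <- sim$truth[sim$truth$compartment == comp, , drop = FALSE]
    m <- merge(fc[fc$status == "quantified", c("sequence", "log2fc")],
               tr[, c("sequence", "true_log2fc")], by = "sequence")
    m <- m[!is.na(m$true_log2fc), , drop = FALSE]
    err <- m$log2fc - m$true_log2fc
    true_unique <- tr$sequence[!tr$in_control]
    out[[comp]] <- list(
      fc_bias = mean(err), fc_rmse = sqrt(mean(err^2)), fc_n = nrow(m),
      treated_unique_recovered = run$core[[comp]]$venn$unique_b,
      treated_unique_true = length(true_unique),
      new_precursor_recovered = run$core[[comp]]$new_precursor$count,
      new_precursor_true = sum(tr$is_new_precursor))
  }
  if (!is.null(run$physchem$screen)) {
    sc <- run$physchem$screen
    ref <- sc[sc$index %in% HYDROPHOBICITY_REFERENCE_IDS, , drop = FALSE]
    out$hydrophobicity <- list(
      reference = ref[, c("index", "p_value", "direction", "tier")],
      n_sigAA = sum(sc$tier %in% c("sigAA", "top")),
      n_sig = sum(sc$tier != "ns"))
  }
  if (!is.null(run$topology)) {
    enr <- run$topology$enrichment
    ins <- enr[enr$location == "inside", , drop = FALSE]
    outl <- enr[enr$location == "outside", , drop = FALSE]
    out$location <- list(
      inside_or = ins$odds_ratio[1], inside_p = ins$p_value[1],
      outside_or = outl$odds_ratio[1], outside_p = outl$p_value[1])
  }
  if (!is.null(run$amp) && !is.null(sim$amp_truth)) {
    out$amp <- lapply(setNames(run$compartments, run$compartments), function(comp) {
      tt <- sim$amp_truth[sim$amp_truth$compartment == comp, , drop = FALSE]
      list(rate_recovered = run$amp[[comp]]$rate,
           rate_true = mean(tt$is_amp))
    })
  }
  structure(out, class = "truth_recovery")
}
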