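#' Configuration of the in-silico proteolysis simulator
#'
#' Parameters of the synthetic study: a random proteome with membrane
#' topology, two compartments (cell, secretome) sampled with compartment-
#' specific biases, two conditions (control, treated) where treatment adds
#' extra unique peptides partly from held-out new precursors, peptide
#' ladders, per-repeat Bernoulli detection and lognormal intensities.
#' Defaults emulate the study design the analyses assume: 3 biological
#' repeats, ~15-aa peptides, a treated-unique fraction of about 5.5% with
#' about 27% of it from new precursors, a C-terminal start bias in the cell
#' compartment, a hydrophobicity sampling shift in the secretome, and
#' inside/outside topology biases for cell/secretome respectively.
#'
#' @param n_proteins Number of proteins (default 1000).
#' @param len_meanlog,len_sdlog,len_min Lognormal protein length
#'   distribution (median ~300 aa) and minimum length.
#' @param tm_fraction Fraction of proteins given a multi-segment
#'   transmembrane architecture (default 0.3); the rest get one full-length
#'   inside or outside segment.
#' @param n_peptides Named vector: primary peptide draws per compartment
#'   (default 2000 each; ladder children add a few percent on top).
#' @param pep_len_mean,pep_len_sd,pep_len_min,pep_len_max Discretized
#'   normal peptide length distribution (default mean 15).
#' @param cterm_bias Named start-weight multiplier for starts within 50 aa
#'   of the C-terminus, per compartment (default cell 3, secretome 1).
#' @param nterm_pref Per-compartment named residue multipliers applied to
#'   the start residue (defaults: cell favours A/S, secretome G/T).
#' @param hydrophobicity_delta Named exponential-tilt coefficient on the
#'   window-level hydropathy z-score (default cell 0, secretome 0.5).
#' @param topology_beta Named weight multiplier for windows whose midpoint
#'   lies in the favoured topology class (inside for cell, outside for
#'   secretome; default 3 each).
#' @param hydropathy_index AAindex accession of the hydropathy scale the
#'   tilt uses (default Kyte-Doolittle, read from the same AAindex table
#'   the analyses use).
#' @param new_precursor_pool_frac Fraction of proteins held out of control
#'   sampling so that "new precursor" is unambiguous (default 0.1).
#' @param treated_extra_frac Treated-unique peptides as a fraction of the
#'   primary draws (default 0.055).
#' @param new_precursor_frac Fraction of treated-unique peptides drawn from
#'   the held-out precursors (default 0.27).
#' @param log2fc_mean,log2fc_sd Injected log2 fold-change distribution for
#'   peptides present in both conditions (default N(0, 0.5)).
#' @param ladder_prob,ladder_max_children,ladder_trim_max Peptide-ladder
#'   model: probability a sampled peptide spawns children, how many at
#'   most, and the maximum terminal trim (1..3 residues).
#' @param ladder_intensity_penalty Per-trimmed-residue intensity scaling of
#'   ladder children (default 0.5).
#' @param n_repeats Biological repeats per condition (default 3).
#' @param detection_p Per-repeat detection probability (default 0.9).
#' @param intensity_meanlog,intensity_sdlog Lognormal base abundance across
#'   peptides.
#' @param noise_sdlog Per-repeat lognormal intensity noise (default 0.4).
#' @param amp_frac Named true antimicrobial fraction per compartment
#'   (default cell 0.04, secretome 0.035).
#' @param rng_seed Mandatory RNG seed; identical seed and config give
#'   byte-identical output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 1000L,
                       len_meanlog = log(300), len_sdlog = 0.45, len_min = 60L,
                       tm_fraction = 0.3,
                       n_peptides = c(cell = 2000L, secretome = 2000L),
                       pep_len_mean = 15, pep_len_sd = 4,
                       pep_len_min = 7L, pep_len_max = 40L,
                       cterm_bias = c(cell = 5, secretome = 1),
                       nterm_pref = list(cell = c(A = 3, S = 3),
                                         secretome = c(G = 3, T = 3)),
                       hydrophobicity_delta = c(cell = 0, secretome = 0.5),
                       topology_beta = c(cell = 3, secretome = 3),
                       hydropathy_index = "KYTJ820101",
                       new_precursor_pool_frac = 0.1,
                       treated_extra_frac = 0.055,
                       new_precursor_frac = 0.27,
                       log2fc_mean = 0, log2fc_sd = 0.5,
                       ladder_prob = 0.3, ladder_max_children = 2L,
                       ladder_trim_max = 3L,
                       ladder_intensity_penalty = 0.5,
                       n_repeats = 3L, detection_p = 0.9,
                       intensity_meanlog = log(1e6), intensity_sdlog = 1,
                       noise_sdlog = 0.4,
                       amp_frac = c(cell = 0.04, secretome = 0.035),
                       rng_seed) {
  if (missing(rng_seed) || is.null(rng_seed)) stop2("rng_seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(cfg$n_proteins >= 0L, cfg$tm_fraction >= 0, cfg$tm_fraction <= 1,
            cfg$detection_p >= 0, cfg$detection_p <= 1,
            cfg$treated_extra_frac >= 0, cfg$new_precursor_frac >= 0,
            cfg$new_precursor_frac <= 1, cfg$ladder_prob >= 0,
            cfg$ladder_prob <= 1, cfg$pep_len_min >= 1L,
            cfg$pep_len_max >= cfg$pep_len_min, cfg$n_repeats >= 1L,
            all(cfg$amp_frac >= 0), all(cfg$amp_frac <= 1))
  for (nm in c("n_peptides", "cterm_bias", "hydrophobicity_delta",
               "topology_beta", "amp_frac")) {
    if (!all(c("cell", "secretome") %in% names(cfg[[nm]]))) {
      stop2(nm, " must be named for both compartments")
    }
  }
  cfg$rng_seed <- as.integer(rng_seed)
  structure(cfg, class = "sim_config")
}

#' Generate a random proteome with topology and ground truth
#'
#' @param config A `sim_config`.
#' @return List with `proteome` (a `proteome_map`), `topology` (a
#'   `topology_map` covering every protein) and `protein_truth`
#'   (data.frame: protein, length, is_tm, held_out).
#' @export
generate_proteome <- function(config) {
  if (config$n_proteins < 1L) stop2("n_proteins must be >= 1")
  set.seed(config$rng_seed)
  n <- config$n_proteins
  lens <- pmax(config$len_min,
               as.integer(round(stats::rlnorm(n, config$len_meanlog, config$len_sdlog))))
  ids <- sprintf("SYN%04d", seq_len(n))
  seqs <- vapply(lens, function(L) {
    paste(sample(AA_STANDARD, L, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- ids
  is_tm <- stats::runif(n) < config$tm_fraction
  topo <- vector("list", n)
  names(topo) <- ids
  for (i in seq_len(n)) {
    L <- lens[i]
    if (!is_tm[i] || L < 80L) {
      is_tm[i] <- FALSE
      lab <- sample(c("inside", "outside"), 1)
      topo[[i]] <- data.frame(label = lab, start = 1L, end = L,
                              stringsAsFactors = FALSE)
    } else {
      segs <- list()
      pos <- 1L
      side <- sample(c("inside", "outside"), 1)
      while (pos <= L) {
        loop_len <- min(max(10L, as.integer(round(stats::rnorm(1, 40, 15)))), L - pos + 1L)
        segs[[length(segs) + 1L]] <- data.frame(label = side, start = pos,
                                                end = pos + loop_len - 1L,
                                                stringsAsFactors = FALSE)
        pos <- pos + loop_len
        if (pos > L) break
        tm_len <- min(21L, L - pos + 1L)
        segs[[length(segs) + 1L]] <- data.frame(label = "TMhelix", start = pos,
                                                end = pos + tm_len - 1L,
                                                stringsAsFactors = FALSE)
        pos <- pos + tm_len
        side <- if (side == "inside") "outside" else "inside"
      }
      topo[[i]] <- do.call(rbind, segs)
    }
  }
  held_out <- rep(FALSE, n)
  n_held <- round(config$new_precursor_pool_frac * n)
  if (n_held > 0L) held_out[sample.int(n, n_held)] <- TRUE
  list(proteome = proteome_map(seqs),
       topology = structure(topo, class = "topology_map"),
       protein_truth = data.frame(protein = ids, length = lens, is_tm = is_tm,
                                  held_out = held_out, stringsAsFactors = FALSE))
}

# Per-position topology label codes for one protein (1=inside, 2=outside,
# 3=TMhelix, 0=unannotated).
position_labels <- function(seg, L) {
  lab <- integer(L)
  code <- c(inside = 1L, outside = 2L, TMhelix = 3L)
  for (j in seq_len(nrow(seg))) {
    lab[seg$start[j]:min(seg$end[j], L)] <- code[[seg$label[j]]]
  }
  lab
}

# Draw n peptides from the allowed proteins with the compartment's biases.
# Returns data.frame(protein, start, end, sequence).
sample_peptide_set <- function(n, allowed, comp, proteome, pos_lab, hyd,
                               hyd_mu, hyd_sd, config) {
  if (!length(allowed)) stop2("no proteins available to sample from")
  lens_prot <- proteome$lengths[allowed]
  pick <- sample(allowed, n, replace = TRUE, prob = lens_prot)
  plen <- as.integer(pmin(pmax(round(stats::rnorm(n, config$pep_len_mean,
                                                  config$pep_len_sd)),
                               config$pep_len_min), config$pep_len_max))
  target_lab <- if (comp == "cell") 1L else 2L
  beta <- config$topology_beta[[comp]]
  delta <- config$hydrophobicity_delta[[comp]]
  cterm_w <- config$cterm_bias[[comp]]
  pref <- config$nterm_pref[[comp]]
  out_start <- integer(n)
  for (i in seq_len(n)) {
    p <- pick[i]
    L <- proteome$lengths[[p]]
    len <- min(plen[i], L)
    plen[i] <- len
    ns <- L - len + 1L
    w <- rep(1, ns)
    starts <- seq_len(ns)
    if (cterm_w != 1) {
      w[starts >= L - 50L + 1L] <- w[starts >= L - 50L + 1L] * cterm_w
    }
    if (length(pref)) {
      first_res <- substring(proteome$seq[[p]], starts, starts)
      mult <- pref[first_res]
      mult[is.na(mult)] <- 1
      w <- w * mult
    }
    if (delta != 0) {
      cs <- c(0, cumsum(hyd[[p]]))
      win_mean <- (cs[starts + len] - cs[starts]) / len
      z <- (win_mean - hyd_mu) / (hyd_sd / sqrt(len))
      w <- w * exp(pmin(delta * z, 30))
    }
    if (beta != 1) {
      mid <- starts + len %/% 2L
      w[pos_lab[[p]][mid] == target_lab] <- w[pos_lab[[p]][mid] == target_lab] * beta
    }
    out_start[i] <- sample.int(ns, 1L, prob = w)
  }
  data.frame(protein = pick, start = out_start, end = out_start + plen - 1L,
             sequence = substring(proteome$seq[pick], out_start,
                                  out_start + plen - 1L),
             stringsAsFactors = FALSE)
}

# Spawn ladder children (terminal trims of 1..trim_max residues). `pool`
# must carry columns `A` (parent intensity) and `ladder_group`.
spawn_ladders <- function(pool, config) {
  spawn <- which(stats::runif(nrow(pool)) < config$ladder_prob)
  empty <- data.frame(protein = character(0), start = integer(0),
                      end = integer(0), sequence = character(0),
                      ladder_group = character(0), trim = integer(0),
                      A = numeric(0))
  if (!length(spawn)) return(empty)
  k <- sample.int(config$ladder_max_children, length(spawn), replace = TRUE)
  par <- rep(spawn, k)
  n <- length(par)
  trim <- sample.int(config$ladder_trim_max, n, replace = TRUE)
  keep <- (pool$end[par] - pool$start[par] + 1L - trim) >= config$pep_len_min
  from_n <- sample(c(TRUE, FALSE), n, replace = TRUE)
  par <- par[keep]; trim <- trim[keep]; from_n <- from_n[keep]
  if (!length(par)) return(empty)
  st <- pool$start[par] + ifelse(from_n, trim, 0L)
  en <- pool$end[par] - ifelse(from_n, 0L, trim)
  data.frame(protein = pool$protein[par], start = st, end = en,
             sequence = substr(pool$sequence[par], st - pool$start[par] + 1L,
                               en - pool$start[par] + 1L),
             ladder_group = pool$ladder_group[par], trim = trim,
             A = pool$A[par] * config$ladder_intensity_penalty^trim,
             stringsAsFactors = FALSE)
}

#' Simulate endogenous peptide tables with ground truth
#'
#' Samples peptides per compartment with the configured biases, spawns
#' peptide ladders, assigns the treated condition its extra unique peptides
#' (partly from held-out new precursors), draws per-repeat detection and
#' lognormal intensities, and returns the peptide table together with one
#' truth row per emitted peptide. Every emitted peptide is an exact
#' substring of its stated precursor at its stated coordinates.
#'
#' @param prot Output of [generate_proteome()] (or a compatible list with
#'   `proteome`, `topology`, `protein_truth`).
#' @param config The `sim_config` used.
#' @param aaindex An `aaindex_table` providing the hydropathy scale
#'   (default [load_aaindex()]).
#' @return List of class `synthetic_peptidome`: `table` (a
#'   `peptide_table`), `truth` (one row per (compartment, peptide)),
#'   `config`, plus the inputs.
#' @export
simulate_digestion <- function(prot, config, aaindex = load_aaindex()) {
  set.seed(config$rng_seed + 1L)
  proteome <- prot$proteome
  topology <- prot$topology
  held_out <- prot$protein_truth$protein[prot$protein_truth$held_out]
  regular <- setdiff(names(proteome$seq), held_out)
  hyd_scale <- aaindex[[config$hydropathy_index]]
  if (is.null(hyd_scale) || !hyd_scale$complete) {
    stop2("hydropathy index ", config$hydropathy_index, " not available/complete")
  }
  hyd <- lapply(proteome$seq, function(s) {
    unname(hyd_scale$values[strsplit(s, "")[[1]]])
  })
  hyd_mu <- mean(hyd_scale$values)
  hyd_sd <- stats::sd(hyd_scale$values)
  pos_lab <- lapply(names(proteome$seq), function(p) {
    position_labels(topology[[p]], proteome$lengths[[p]])
  })
  names(pos_lab) <- names(proteome$seq)

  rows <- list()
  truth <- list()
  for (comp in c("cell", "secretome")) {
    n_base <- config$n_peptides[[comp]]
    base <- sample_peptide_set(n_base, regular, comp, proteome, pos_lab, hyd,
                               hyd_mu, hyd_sd, config)
    base$ladder_group <- paste0(comp, "_", seq_len(n_base))
    base$trim <- 0L
    base$A <- stats::rlnorm(n_base, config$intensity_meanlog,
                            config$intensity_sdlog)
    kids <- spawn_ladders(base, config)
    base <- rbind(base, kids)
    base$origin <- "base"
    n_extra <- round(config$treated_extra_frac * n_base)
    n_new <- round(config$new_precursor_frac * n_extra)
    extra_reg <- sample_peptide_set(n_extra - n_new, regular, comp, proteome,
                                    pos_lab, hyd, hyd_mu, hyd_sd, config)
    extra_new <- sample_peptide_set(n_new, held_out, comp, proteome, pos_lab,
                                    hyd, hyd_mu, hyd_sd, config)
    extra <- rbind(extra_reg, extra_new)
    extra$ladder_group <- rep(NA_character_, nrow(extra))
    extra$trim <- rep(0L, nrow(extra))
    extra$A <- stats::rlnorm(nrow(extra), config$intensity_meanlog,
                             config$intensity_sdlog)
    extra$origin <- rep(c("extra_regular", "extra_new"),
                        c(nrow(extra_reg), nrow(extra_new)))
    pool <- rbind(base, extra)
    # One peptide per distinct sequence within the compartment; the first
    # sampled site/origin wins (a treated-unique redraw of a base sequence
    # is the same peptide, hence not treated-unique).
    pool <- pool[!duplicated(pool$sequence), , drop = FALSE]
    npool <- nrow(pool)
    A <- pool$A
    is_kid <- pool$trim > 0L
    in_control <- pool$origin == "base"
    fc <- ifelse(in_control,
                 stats::rnorm(npool, config$log2fc_mean, config$log2fc_sd),
                 NA_real_)
    mean_control <- ifelse(in_control, A, NA_real_)
    mean_treated <- ifelse(in_control, A * 2^fc, A)
    loc_lab <- c("inside", "outside", "TMhelix")
    mid <- pool$start + (pool$end - pool$start) %/% 2L
    loc <- vapply(seq_len(npool), function(i) {
      code <- pos_lab[[pool$protein[i]]][mid[i]]
      if (code == 0L) "unannotated" else loc_lab[code]
    }, character(1))
    nr <- config$n_repeats
    for (cond in c("control", "treated")) {
      active <- if (cond == "control") which(in_control) else seq_len(npool)
      det <- matrix(stats::runif(length(active) * nr) < config$detection_p,
                    ncol = nr)
      mu <- if (cond == "control") mean_control[active] else mean_treated[active]
      ints <- matrix(NA_real_, nrow = length(active), ncol = nr)
      for (r in seq_len(nr)) {
        d <- det[, r]
        ints[d, r] <- mu[d] * stats::rlnorm(sum(d), 0, config$noise_sdlog)
      }
      seen <- rowSums(det) > 0L
      if (!any(seen)) next
      df <- data.frame(sequence = pool$sequence[active][seen],
                       proteins = pool$protein[active][seen],
                       starts = as.character(pool$start[active][seen]),
                       ends = as.character(pool$end[active][seen]),
                       condition = cond, compartment = comp,
                       repeats = apply(det[seen, , drop = FALSE], 1, function(v) {
                         paste(which(v), collapse = ";")
                       }),
                       stringsAsFactors = FALSE)
      for (r in seq_len(nr)) {
        df[[paste0("intensity_r", r)]] <- ints[seen, r]
      }
      rows[[length(rows) + 1L]] <- df
    }
    truth[[comp]] <- data.frame(
      compartment = comp, sequence = pool$sequence, protein = pool$protein,
      start = pool$start, end = pool$end,
      ladder_group = pool$ladder_group, is_ladder_child = is_kid,
      origin = pool$origin,
      is_new_precursor = pool$origin == "extra_new",
      in_control = in_control, in_treated = TRUE,
      true_log2fc = fc, base_intensity = A, location = loc,
      stringsAsFactors = FALSE)
  }
  table <- peptide_table(do.call(rbind, rows))
  structure(list(table = table, truth = do.call(rbind, truth),
                 proteome = proteome, topology = topology,
                 protein_truth = prot$protein_truth, config = config),
            class = "synthetic_peptidome")
}

#' @export
print.synthetic_peptidome <- function(x, ...) {
  cat("synthetic_peptidome:", nrow(x$truth), "peptides over",
      length(x$proteome$seq), "proteins; seed", x$config$rng_seed, "\n")
  invisible(x)
}

#' Simulate antimicrobial predictor score tables
#'
#' Draws CAMP/iAMPpred/ADAM-style scores for the simulated peptides: a
#' per-compartment fraction of peptides is truly antimicrobial and scores
#' above all three call thresholds; the rest fail at least one predictor
#' (one predictor chosen uniformly is forced below threshold, the others
#' are free), so the consensus call recovers the truth flag exactly and
#' the consensus rate matches the configured fraction up to sampling.
#'
#' @param sim A `synthetic_peptidome`.
#' @param thresholds Predictor thresholds (as in [consensus_amp()]).
#' @return List with `scores` (an `amp_scores` table for all peptides) and
#'   `truth` (data.frame: compartment, peptide, is_amp).
#' @export
simulate_amp_scores <- function(sim,
                                thresholds = list(camp = 0.5, iamppred = 0.5,
                                                  adam = 0)) {
  set.seed(sim$config$rng_seed + 2L)
  res <- lapply(c("cell", "secretome"), function(comp) {
    peps <- sim$truth$sequence[sim$truth$compartment == comp]
    n <- length(peps)
    is_amp <- stats::runif(n) < sim$config$amp_frac[[comp]]
    camp <- stats::runif(n, thresholds$camp, 1)
    iamp <- stats::runif(n, thresholds$iamppred, 1)
    adam <- stats::runif(n, thresholds$adam + 0.1, 3)
    fail <- sample.int(3L, n, replace = TRUE)
    idx <- which(!is_amp)
    camp[idx[fail[idx] == 1L]] <- stats::runif(sum(fail[idx] == 1L), 0, thresholds$camp - 1e-6)
    iamp[idx[fail[idx] == 2L]] <- stats::runif(sum(fail[idx] == 2L), 0, thresholds$iamppred - 1e-6)
    adam[idx[fail[idx] == 3L]] <- stats::runif(sum(fail[idx] == 3L), -3, thresholds$adam)
    list(scores = data.frame(peptide = peps, camp_prob = camp,
                             iamppred_prob = iamp, adam_score = adam,
                             stringsAsFactors = FALSE),
         truth = data.frame(compartment = comp, peptide = peps, is_amp = is_amp,
                            stringsAsFactors = FALSE))
  })
  scores <- do.call(rbind, lapply(res, `[[`, "scores"))
  scores <- scores[!duplicated(scores$peptide), , drop = FALSE]
  class(scores) <- c("amp_scores", "data.frame")
  list(scores = scores, truth = do.call(rbind, lapply(res, `[[`, "truth")))
}

#' Run the full simulator
#'
#' Convenience wrapper: [generate_proteome()], [simulate_digestion()] and
#' [simulate_amp_scores()] under one seed.
#'
#' @param config A `sim_config`.
#' @param aaindex An `aaindex_table` (default [load_aaindex()]).
#' @return A `synthetic_peptidome` with `amp_scores` and `amp_truth` added.
#' @export
simulate_peptidome <- function(config, aaindex = load_aaindex()) {
  prot <- generate_proteome(config)
  sim <- simulate_digestion(prot, config, aaindex)
  amp <- simulate_amp_scores(sim)
  sim$amp_scores <- amp$scores
  sim$amp_truth <- amp$truth
  sim
}

#' Write a simulated study to disk
#'
#' Emits `proteome.fasta`, `topology.tsv`, `peptides.tsv`, `truth.tsv`,
#' `amp_scores.tsv` and a JSON manifest (config, seed, file checksums).
#' Identical seed and config give byte-identical files.
#'
#' @param sim A `synthetic_peptidome`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_proteome_fasta(sim$proteome, file.path(dir, "proteome.fasta"))
  write_topology(sim$topology, file.path(dir, "topology.tsv"))
  write_peptide_table(sim$table, file.path(dir, "peptides.tsv"))
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  if (!is.null(sim$amp_scores)) {
    utils::write.table(sim$amp_scores, file.path(dir, "amp_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  }
  files <- list.files(dir, full.names = TRUE)
  manifest <- list(seed = sim$config$rng_seed,
                   config = unclass(sim$config),
                   files = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
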