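#' Read and merge antimicrobial predictor score tables
#'
#' Each predictor file is a TSV with columns `peptide` and `score`
#' (CAMP and iAMPpred probabilities in [0,1]; ADAM an unbounded score).
#' Peptides absent from a file have that score missing.
#'
#' @param camp,iamppred,adam Paths to the three score tables (any may be
#'   NULL) or data.frames with columns `peptide`, `score`.
#' @return data.frame of class `amp_scores` with columns `peptide`,
#'   `camp_prob`, `iamppred_prob`, `adam_score`.
#' @export
read_amp_scores <- function(camp = NULL, iamppred = NULL, adam = NULL) {
  read_one <- function(x) {
    if (is.null(x)) return(NULL)
    df <- if (is.data.frame(x)) x
          else utils::read.delim(x, sep = "\t", stringsAsFactors = FALSE)
    if (!all(c("peptide", "score") %in% names(df))) {
      stop2("score table needs columns 'peptide' and 'score'")
    }
    df$peptide <- toupper(df$peptide)
    df[c("peptide", "score")]
  }
  tabs <- list(camp_prob = read_one(camp), iamppred_prob = read_one(iamppred),
               adam_score = read_one(adam))
  peptides <- unique(unlist(lapply(tabs, function(t) t$peptide)))
  out <- data.frame(peptide = peptides, stringsAsFactors = FALSE)
  for (nm in names(tabs)) {
    t <- tabs[[nm]]
    out[[nm]] <- if (is.null(t)) NA_real_ else t$score[match(peptides, t$peptide)]
  }
  for (nm in c("camp_prob", "iamppred_prob")) {
    bad <- !is.na(out[[nm]]) & (out[[nm]] < 0 | out[[nm]] > 1)
    if (any(bad)) stop2(nm, " outside [0,1] for peptide(s): ",
                        paste(utils::head(out$peptide[bad], 3), collapse = ", "))
  }
  class(out) <- c("amp_scores", "data.frame")
  out
}

#' Consensus antimicrobial calls
#'
#' A peptide is called antimicrobial by CAMP or iAMPpred when its
#' probability is at or above the threshold (default 0.5) and by ADAM when
#' its score is strictly above the threshold (default 0). The consensus
#' call is the conjunction of all three; peptides missing any score are
#' `undetermined` (NA consensus) and reported separately. The consensus set
#' can only shrink as any threshold rises.
#'
#' @param scores An `amp_scores` table (or data.frame with the same
#'   columns).
#' @param thresholds Named list/vector with `camp`, `iamppred`, `adam`.
#' @return data.frame with per-predictor logical calls, `consensus`
#'   (NA = undetermined) and `complete` (all three scores present).
#' @export
consensus_amp <- function(scores,
                          thresholds = list(camp = 0.5, iamppred = 0.5, adam = 0)) {
  for (nm in c("camp_prob", "iamppred_prob")) {
    bad <- !is.na(scores[[nm]]) & (scores[[nm]] < 0 | scores[[nm]] > 1)
    if (any(bad)) stop2(nm, " outside [0,1]")
  }
  call_camp <- scores$camp_prob >= thresholds[["camp"]]
  call_iamp <- scores$iamppred_prob >= thresholds[["iamppred"]]
  call_adam <- scores$adam_score > thresholds[["adam"]]
  complete <- !is.na(scores$camp_prob) & !is.na(scores$iamppred_prob) &
    !is.na(scores$adam_score)
  consensus <- ifelse(complete, call_camp & call_iamp & call_adam, NA)
  data.frame(peptide = scores$peptide,
             camp_call = call_camp, iamppred_call = call_iamp,
             adam_call = call_adam, complete = complete,
             consensus = consensus, stringsAsFactors = FALSE)
}

#' Fraction of peptides called antimicrobial by consensus
#'
#' @param calls Output of [consensus_amp()].
#' @param universe Optional peptide universe to restrict to (defaults to
#'   all peptides in `calls`).
#' @return Fraction of consensus-positive peptides among the universe
#'   members with complete scores; always in [0,1] and independent of
#'   ordering.
#' @export
amp_rate <- function(calls, universe = NULL) {
  if (!is.null(universe)) {
    calls <- calls[calls$peptide %in% universe, , drop = FALSE]
  }
  denom <- sum(calls$complete)
  if (denom == 0L) stop2("no peptide with complete scores in the universe")
  sum(calls$consensus, na.rm = TRUE) / denom
}

#' Rank antimicrobial candidates
#'
#' Joins consensus calls with fold changes and ranks candidates: consensus
#' peptides first, then by the product of the two predictor probabilities,
#' then by log2 fold change. A non-consensus peptide never outranks a
#' consensus one.
#'
#' @param calls Output of [consensus_amp()].
#' @param scores The `amp_scores` table the calls came from.
#' @param fold_changes Optional [fold_change_table()] output joined by
#'   sequence.
#' @param compartment Compartment label carried into the output.
#' @param upregulated_log2fc Cutoff for the `upregulated` flag (default 1).
#' @param exclude Optional peptides to drop (e.g. a user-supplied
#'   unreliable-prediction list).
#' @return data.frame of ranked candidates with `rank`, calls, probability
#'   product, `log2fc` and `upregulated`.
#' @export
prioritize_candidates <- function(calls, scores, fold_changes = NULL,
                                  compartment = NA_character_,
                                  upregulated_log2fc = 1,
                                  exclude = NULL) {
  df <- merge(calls, as.data.frame(scores), by = "peptide")
  if (!is.null(exclude)) df <- df[!df$peptide %in% exclude, , drop = FALSE]
  df$prob_product <- df$camp_prob * df$iamppred_prob
  if (!is.null(fold_changes)) {
    df$log2fc <- fold_changes$log2fc[match(df$peptide, fold_changes$sequence)]
  } else {
    df$log2fc <- NA_real_
  }
  df$upregulated <- !is.na(df$log2fc) & df$log2fc > upregulated_log2fc
  df$compartment <- compartment
  cons <- ifelse(is.na(df$consensus), FALSE, df$consensus)
  ord <- order(-cons, -ifelse(is.na(df$prob_product), -Inf, df$prob_product),
               -ifelse(is.na(df$log2fc), -Inf, df$log2fc))
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  rownames(df) <- NULL
  df
}
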