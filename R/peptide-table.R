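#' Construct a peptide identification table
#'
#' The central tabular container: one row per peptide per
#' (compartment, condition) group, mirroring the layout of search-engine
#' peptide output (MaxQuant peptides.txt style). Mapping to precursors is
#' held in parallel semicolon-separated `proteins`/`starts`/`ends` fields so
#' a peptide matching several precursors (or several positions in one) keeps
#' every site; `start`/`end` expose the first site for convenience.
#'
#' @param df A data.frame with columns `sequence`, `condition`
#'   (`control`/`treated`), `compartment` (`cell`/`secretome`), `repeats`
#'   (semicolon-separated biological-repeat indices), optionally `proteins`,
#'   `starts`, `ends`, and any number of `intensity_r<k>` columns (NA = not
#'   observed; intensities are never zero-filled).
#' @return A data.frame of class `peptide_table` with logical flag columns
#'   `unmapped`, `ambiguous` and `nonstandard` added.
#' @export
peptide_table <- function(df) {
  required <- c("sequence", "condition", "compartment", "repeats")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop2("peptide table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$sequence <- toupper(as.character(df$sequence))
  if (any(!nzchar(df$sequence))) stop2("empty peptide sequence(s)")
  bad_cond <- setdiff(unique(df$condition), c("control", "treated"))
  if (length(bad_cond)) stop2("unknown condition label(s): ", paste(bad_cond, collapse = ", "))
  bad_comp <- setdiff(unique(df$compartment), c("cell", "secretome"))
  if (length(bad_comp)) stop2("unknown compartment label(s): ", paste(bad_comp, collapse = ", "))
  for (col in c("proteins", "starts", "ends")) {
    if (is.null(df[[col]])) df[[col]] <- NA_character_
    df[[col]] <- as.character(df[[col]])
  }
  reps <- split_field(df$repeats)
  if (any(lengths(reps) == 0L)) stop2("repeat_presence must be non-empty for every row")
  n_sites <- lengths(split_field(df$proteins))
  df$start <- vapply(split_field(df$starts),
                     function(v) if (length(v)) as.integer(v[1]) else NA_integer_, integer(1))
  df$end <- vapply(split_field(df$ends),
                   function(v) if (length(v)) as.integer(v[1]) else NA_integer_, integer(1))
  df$unmapped <- n_sites == 0L
  df$ambiguous <- n_sites > 1L
  df$nonstandard <- !is_standard_seq(df$sequence)
  class(df) <- c("peptide_table", "data.frame")
  df
}

#' @export
print.peptide_table <- function(x, ...) {
  cat("peptide_table:", nrow(x), "rows,",
      length(unique(x$sequence)), "distinct peptides;",
      sum(x$unmapped), "unmapped,", sum(x$ambiguous), "ambiguous\n")
  NextMethod()
}

# Names of the per-repeat intensity columns, in repeat order.
intensity_cols <- function(table) {
  cols <- grep("^intensity_r[0-9]+$", names(table), value = TRUE)
  cols[order(as.integer(sub("^intensity_r", "", cols)))]
}

# Repeat presence as a list of integer vectors.
repeat_sets <- function(table) {
  lapply(split_field(table$repeats), as.integer)
}

#' Read a peptide table from TSV
#'
#' Reads a tab-separated peptide table (columns as in [peptide_table()]) and,
#' when a proteome is supplied, validates the coordinates: rows whose span
#' does not match their precursor sequence are dropped (returned in the
#' `rejected` attribute with a reason), rows naming a protein absent from
#' the proteome are flagged `unmapped`, and rows lacking coordinates have
#' them back-filled by exact substring search via [locate_peptides()].
#'
#' @param path Path to a TSV file.
#' @param proteome Optional `proteome_map` used for validation and locating.
#' @return A `peptide_table`; attribute `rejected` holds dropped rows.
#' @export
read_peptide_table <- function(path, proteome = NULL) {
  if (!file.exists(path)) stop2("peptide table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, colClasses = "character")
  for (col in grep("^intensity_r[0-9]+$", names(df), value = TRUE)) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  tab <- peptide_table(df)
  if (!is.null(proteome)) tab <- validate_peptide_table(tab, proteome)
  tab
}

#' Write a peptide table to TSV
#'
#' Round-trips with [read_peptide_table()] (missing intensities written as
#' empty fields, read back as NA).
#'
#' @param table A `peptide_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(table, path) {
  drop <- c("start", "end", "unmapped", "ambiguous", "nonstandard")
  out <- as.data.frame(table)[, setdiff(names(table), drop), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Validate (and back-fill) peptide coordinates against a proteome
#'
#' @param table A `peptide_table`.
#' @param proteome A `proteome_map`.
#' @return The validated table; attribute `rejected` collects rows whose
#'   stated span is not an exact substring match.
#' @export
validate_peptide_table <- function(table, proteome) {
  needs_locate <- !nzchar(ifelse(is.na(table$proteins), "", table$proteins)) |
    !nzchar(ifelse(is.na(table$starts), "", table$starts))
  located <- locate_peptides(table[needs_locate, , drop = FALSE], proteome)
  keep <- rep(TRUE, nrow(table))
  reason <- rep(NA_character_, nrow(table))
  idx_check <- which(!needs_locate)
  for (i in idx_check) {
    prots <- split_field(table$proteins[i])[[1]]
    starts <- as.integer(split_field(table$starts[i])[[1]])
    ends <- as.integer(split_field(table$ends[i])[[1]])
    if (!(length(prots) == length(starts) && length(prots) == length(ends))) {
      keep[i] <- FALSE
      reason[i] <- "ragged proteins/starts/ends fields"
      next
    }
    unknown <- !(prots %in% names(proteome$seq))
    if (all(unknown)) {
      table$proteins[i] <- NA_character_
      table$starts[i] <- NA_character_
      table$ends[i] <- NA_character_
      table$unmapped[i] <- TRUE
      table$ambiguous[i] <- FALSE
      table$start[i] <- NA_integer_
      table$end[i] <- NA_integer_
      next
    }
    prots <- prots[!unknown]; starts <- starts[!unknown]; ends <- ends[!unknown]
    L <- proteome$lengths[prots]
    ok_span <- starts >= 1L & ends <= L & (ends - starts + 1L) == nchar(table$sequence[i])
    ok_seq <- ok_span & substr(proteome$seq[prots], starts, ends) == table$sequence[i]
    if (!any(ok_seq)) {
      keep[i] <- FALSE
      reason[i] <- if (any(!ok_span)) "coordinates outside precursor or wrong span length"
                   else "sequence mismatch at stated coordinates"
      next
    }
    prots <- prots[ok_seq]; starts <- starts[ok_seq]; ends <- ends[ok_seq]
    table$proteins[i] <- paste(prots, collapse = ";")
    table$starts[i] <- paste(starts, collapse = ";")
    table$ends[i] <- paste(ends, collapse = ";")
    table$start[i] <- starts[1]
    table$end[i] <- ends[1]
    table$unmapped[i] <- FALSE
    table$ambiguous[i] <- length(prots) > 1L
  }
  table[needs_locate, ] <- located
  rejected <- cbind(as.data.frame(table)[!keep, , drop = FALSE],
                    reason = reason[!keep])
  out <- table[keep, , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Map peptides to precursors by exact substring search
#'
#' Assigns each peptide every precursor containing it as an exact substring,
#' with all match coordinates (1-based inclusive). Peptides matching more
#' than one site are flagged `ambiguous`; peptides with no match are flagged
#' `unmapped` and kept (they still take part in sequence-level set algebra,
#' but are excluded from coordinate-based analyses).
#'
#' @param table A `peptide_table` (coordinates, if present, are recomputed).
#' @param proteome A `proteome_map`.
#' @return The table with `proteins`, `starts`, `ends` and flags filled in.
#' @export
locate_peptides <- function(table, proteome) {
  if (nrow(table) == 0L) return(table)
  seqs <- proteome$seq
  uniq <- unique(table$sequence)
  hits <- lapply(uniq, function(pep) {
    m <- gregexpr(pep, seqs, fixed = TRUE)
    prot <- character(0); st <- integer(0)
    for (j in seq_along(m)) {
      pos <- m[[j]]
      if (pos[1] != -1L) {
        prot <- c(prot, rep(names(seqs)[j], length(pos)))
        st <- c(st, as.integer(pos))
      }
    }
    list(proteins = prot, starts = st)
  })
  names(hits) <- uniq
  for (i in seq_len(nrow(table))) {
    h <- hits[[table$sequence[i]]]
    if (length(h$starts) == 0L) {
      table$proteins[i] <- NA_character_
      table$starts[i] <- NA_character_
      table$ends[i] <- NA_character_
      table$start[i] <- NA_integer_
      table$end[i] <- NA_integer_
      table$unmapped[i] <- TRUE
      table$ambiguous[i] <- FALSE
    } else {
      ends <- h$starts + nchar(table$sequence[i]) - 1L
      table$proteins[i] <- paste(h$proteins, collapse = ";")
      table$starts[i] <- paste(h$starts, collapse = ";")
      table$ends[i] <- paste(ends, collapse = ";")
      table$start[i] <- h$starts[1]
      table$end[i] <- ends[1]
      table$unmapped[i] <- FALSE
      table$ambiguous[i] <- length(h$starts) > 1L
    }
  }
  table
}

# All mapping sites of a table as a long data.frame
# (row, sequence, protein, start, end); unmapped rows contribute nothing.
mapping_sites <- function(table) {
  idx <- which(!table$unmapped & !is.na(table$proteins))
  if (!length(idx)) {
    return(data.frame(row = integer(0), sequence = character(0),
                      protein = character(0), start = integer(0),
                      end = integer(0)))
  }
  prots <- split_field(table$proteins[idx])
  starts <- lapply(split_field(table$starts[idx]), as.integer)
  ends <- lapply(split_field(table$ends[idx]), as.integer)
  n <- lengths(prots)
  data.frame(row = rep(idx, n),
             sequence = rep(table$sequence[idx], n),
             protein = unlist(prots, use.names = FALSE),
             start = unlist(starts, use.names = FALSE),
             end = unlist(ends, use.names = FALSE),
             stringsAsFactors = FALSE)
}
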