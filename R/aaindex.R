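#' Parse an AAindex1 flat file
#'
#' Reads the standard `aaindex1` flat-file dialect: records separated by
#' `//`, with `H` (accession), `D` (description) and `I` blocks, the `I`
#' block giving 20 values over two lines in the residue order
#' A R N D C Q E G H I / L K M F P S T W Y V. `NA` fields are recorded as
#' missing and mark the index incomplete.
#'
#' @param path Path to an aaindex1-format file.
#' @return An `aaindex_table`: named list of entries, each a list with
#'   `id`, `description`, `values` (named numeric over the 20 standard
#'   one-letter codes, NA allowed) and `complete` (TRUE iff no NA).
#' @export
read_aaindex1 <- function(path) {
  if (!file.exists(path)) stop2("aaindex file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(c(0, head(grepl("^//", lines), -1))))
  entries <- list()
  for (rec in recs) {
    rec <- rec[!grepl("^//", rec)]
    h <- grep("^H ", rec, value = TRUE)
    if (!length(h)) next
    id <- trimws(sub("^H ", "", h[1]))
    d_idx <- grep("^D ", rec)
    descr <- if (length(d_idx)) trimws(sub("^D ", "", rec[d_idx[1]])) else ""
    i_idx <- grep("^I ", rec)
    if (!length(i_idx)) stop2("entry ", id, ": no I-block")
    val_lines <- rec[(i_idx[1] + 1):min(i_idx[1] + 2, length(rec))]
    fields <- unlist(strsplit(trimws(val_lines), "[[:space:]]+"))
    fields <- fields[nzchar(fields)]
    if (length(fields) != 20L) {
      stop2("entry ", id, ": malformed I-block (", length(fields),
            " fields, expected 20)")
    }
    vals <- suppressWarnings(as.numeric(ifelse(fields == "NA", NA, fields)))
    if (any(is.na(vals) & fields != "NA")) {
      stop2("entry ", id, ": non-numeric I-block field")
    }
    # I-block order is columnar (A/L R/K ...): line 1 row = A R N D C Q E G H I,
    # line 2 row = L K M F P S T W Y V — together the canonical 20 order.
    names(vals) <- AA_STANDARD
    entries[[id]] <- list(id = id, description = descr, values = vals,
                          complete = !anyNA(vals))
  }
  structure(entries, class = "aaindex_table")
}

#' @export
print.aaindex_table <- function(x, ...) {
  cat("aaindex_table:", length(x), "indexes,",
      sum(vapply(x, `[[`, logical(1), "complete")), "complete\n")
  invisible(x)
}

#' Write an AAindex1 flat file
#'
#' Minimal writer (H/D/I records only) that round-trips through
#' [read_aaindex1()].
#'
#' @param aaindex An `aaindex_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aaindex1 <- function(aaindex, path) {
  fmt <- function(v) {
    ifelse(is.na(v), "    NA", formatC(v, width = 7, format = "g"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (e in aaindex) {
    writeLines(c(paste("H", e$id),
                 paste("D", e$description),
                 "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
                 paste(fmt(e$values[1:10]), collapse = ""),
                 paste(fmt(e$values[11:20]), collapse = ""),
                 "//"), con)
  }
  invisible(path)
}

#' Load the bundled AAindex1 release
#'
#' Returns the standard 544-entry AAindex1 database distributed with the
#' seqinr package as an `aaindex_table`, the same shape [read_aaindex1()]
#' produces from a flat file. Thirteen entries have missing residue values
#' and are marked incomplete; physicochemical screening uses complete
#' entries only.
#'
#' @return An `aaindex_table` with 544 entries.
#' @export
load_aaindex <- function() {
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  db <- env$aaindex
  entries <- lapply(db, function(e) {
    vals <- as.numeric(e$I[AA_THREE])
    names(vals) <- AA_STANDARD
    list(id = e$H, description = e$D, values = vals, complete = !anyNA(vals))
  })
  names(entries) <- vapply(entries, `[[`, character(1), "id")
  structure(entries, class = "aaindex_table")
}

#' Mean physicochemical descriptor of one peptide
#'
#' The per-peptide descriptor is the arithmetic mean of the per-residue
#' index values over the peptide sequence; a homopolymer therefore scores
#' exactly its residue's value.
#'
#' @param peptide A peptide sequence (standard 20-letter alphabet).
#' @param index One entry of an `aaindex_table`, or a named numeric vector
#'   of per-residue values.
#' @return The mean index value (numeric scalar).
#' @export
peptide_property <- function(peptide, index) {
  vals <- if (is.list(index)) index$values else index
  if (anyNA(vals)) stop2("index is incomplete (missing residue values)")
  if (!is_standard_seq(peptide)) {
    stop2("peptide contains non-standard residues: ", peptide)
  }
  mean(vals[strsplit(peptide, "")[[1]]])
}

#' Peptide-by-index property matrix
#'
#' Computes mean descriptor values for a set of peptides across the
#' complete entries of an AAindex table. Peptides containing non-standard
#' residues are excluded (their count is reported in the `n_excluded`
#' attribute), as are incomplete indexes.
#'
#' @param peptides Character vector of peptide sequences.
#' @param aaindex An `aaindex_table`.
#' @param ids Optional subset of index ids to compute.
#' @return Numeric matrix, rows = retained peptides (rownames = sequences),
#'   columns = index ids; attribute `n_excluded` counts dropped peptides.
#' @export
property_matrix <- function(peptides, aaindex, ids = NULL) {
  keep <- is_standard_seq(peptides)
  peps <- peptides[keep]
  if (!length(peps)) stop2("no standard-alphabet peptides to score")
  complete <- vapply(aaindex, `[[`, logical(1), "complete")
  use <- names(aaindex)[complete]
  if (!is.null(ids)) use <- intersect(ids, use)
  if (!length(use)) stop2("no complete indexes selected")
  V <- vapply(aaindex[use], function(e) e$values[AA_STANDARD],
              numeric(20))               # 20 x K
  counts <- residue_count_matrix(peps)   # n x 20
  pm <- (counts %*% V) / nchar(peps)
  rownames(pm) <- peps
  colnames(pm) <- use
  attr(pm, "n_excluded") <- sum(!keep)
  pm
}

# n x 20 matrix of residue counts per peptide (standard alphabet assumed).
residue_count_matrix <- function(peptides) {
  n <- length(peptides)
  chars <- strsplit(peptides, "")
  code <- match(unlist(chars, use.names = FALSE), AA_STANDARD)
  pep_i <- rep(seq_len(n), lengths(chars))
  counts <- matrix(tabulate((pep_i - 1L) * 20L + code, nbins = n * 20L),
                   nrow = n, ncol = 20L, byrow = TRUE)
  colnames(counts) <- AA_STANDARD
  counts
}
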