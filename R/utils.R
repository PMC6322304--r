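#' @keywords internal
#' @importFrom stats setNames
#' @importFrom utils head
"_PACKAGE"

# Canonical 20-letter amino-acid alphabet used throughout.
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Three-letter codes in the same order (used when importing AAindex entries).
AA_THREE <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
              "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
              "Tyr", "Val")

#' Convert 1-based inclusive coordinates to 0-based half-open and back
#'
#' All coordinates in this package (peptide spans, topology segments) are
#' 1-based inclusive, the convention proteomics tables print. These helpers
#' are the single place coordinate conversion happens; composing them is the
#' identity.
#'
#' @param start,end 1-based inclusive span.
#' @return For `to_half_open`, a list with 0-based `start` and exclusive
#'   `end`; for `from_half_open`, the 1-based inclusive span back.
#' @examples
#' from_half_open(to_half_open(3, 7)$start, to_half_open(3, 7)$end)
#' @export
to_half_open <- function(start, end) {
  list(start = start - 1L, end = end)
}

#' @rdname to_half_open
#' @export
from_half_open <- function(start, end) {
  list(start = start + 1L, end = end)
}

#' Span length under the 1-based inclusive convention
#' @param start,end 1-based inclusive span.
#' @return Integer length `end - start + 1`.
#' @export
span_length <- function(start, end) {
  end - start + 1L
}

# TRUE for sequences made only of the 20 standard residues.
is_standard_seq <- function(x) {
  !grepl(paste0("[^", paste(AA_STANDARD, collapse = ""), "]"), x)
}

# Split a semicolon-separated field into a character vector (no empties).
split_field <- function(x) {
  out <- strsplit(as.character(x), ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

# Collapse a vector into a semicolon-separated field.
join_field <- function(x) {
  vapply(x, function(v) paste(v, collapse = ";"), character(1))
}

stop2 <- function(...) stop(..., call. = FALSE)
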