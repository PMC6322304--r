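#' Read a precursor proteome from FASTA
#'
#' Loads the protein sequences the peptides are mapped against. The protein
#' id is the header token before the first whitespace, taken verbatim.
#' Sequences are uppercased on read; the 20 standard residues plus X and U
#' are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A `proteome_map`: list with `seq` (named uppercase character
#'   vector) and `lengths` (named integer vector).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 demo", "MKKA"), fa)
#' read_proteome_fasta(fa)$lengths
#' @export
read_proteome_fasta <- function(path) {
  if (!file.exists(path)) stop2("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  if (anyDuplicated(ids)) {
    stop2("duplicate protein id(s) in FASTA: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(as.character(aa))
  if (any(!nzchar(seqs))) {
    stop2("empty sequence(s) in FASTA: ",
          paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  names(seqs) <- ids
  proteome_map(seqs)
}

#' Construct a proteome map from named sequences
#'
#' @param seqs Named character vector of amino-acid sequences.
#' @return A `proteome_map` object.
#' @export
proteome_map <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop2("sequences must be named by protein id")
  }
  if (anyDuplicated(names(seqs))) stop2("protein ids must be unique")
  if (any(!nzchar(seqs))) stop2("sequences must be non-empty")
  seqs <- toupper(seqs)
  structure(list(seq = seqs, lengths = setNames(nchar(seqs), names(seqs))),
            class = "proteome_map")
}

#' @export
print.proteome_map <- function(x, ...) {
  cat("proteome_map:", length(x$seq), "proteins, median length",
      stats::median(x$lengths), "aa\n")
  invisible(x)
}

#' Write a proteome map to FASTA
#'
#' Round-trips with [read_proteome_fasta()]: reading the written file
#' reproduces the same ids and (uppercase) sequences.
#'
#' @param proteome A `proteome_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path) {
  aa <- Biostrings::AAStringSet(proteome$seq)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}
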