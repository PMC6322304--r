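#' Read membrane topology segments (TMHMM long format)
#'
#' Parses TMHMM-2.0-style long output lines
#' `<protein> TMHMM2.0 <label> <start> <end>` with labels `inside`,
#' `outside` or `TMhelix` and 1-based inclusive coordinates. Comment lines
#' (`#`) and blank lines are skipped. Segments per protein are sorted by
#' start; overlapping segments or unknown labels are errors. An empty file
#' yields an empty map (downstream localization then reports everything
#' unannotated).
#'
#' @param path Path to a topology file.
#' @return A `topology_map`: named list of data.frames with columns
#'   `label`, `start`, `end`.
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop2("topology file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) {
    return(structure(list(), class = "topology_map"))
  }
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- lengths(parts) < 5L
  if (any(bad)) stop2("malformed topology line(s): ", lines[which(bad)[1]])
  df <- data.frame(protein = vapply(parts, `[[`, character(1), 1),
                   label = vapply(parts, `[[`, character(1), 3),
                   start = as.integer(vapply(parts, `[[`, character(1), 4)),
                   end = as.integer(vapply(parts, `[[`, character(1), 5)),
                   stringsAsFactors = FALSE)
  bad_lab <- setdiff(unique(df$label), c("inside", "outside", "TMhelix"))
  if (length(bad_lab)) stop2("unknown topology label(s): ", paste(bad_lab, collapse = ", "))
  if (any(is.na(df$start)) || any(is.na(df$end)) || any(df$start > df$end)) {
    stop2("invalid segment coordinates in topology file")
  }
  topo <- lapply(split(df[c("label", "start", "end")], df$protein), function(seg) {
    seg <- seg[order(seg$start), , drop = FALSE]
    rownames(seg) <- NULL
    if (nrow(seg) > 1L && any(seg$start[-1] <= seg$end[-nrow(seg)])) {
      stop2("overlapping topology segments for protein ",
            df$protein[match(seg$start[1], df$start)])
    }
    seg
  })
  structure(topo, class = "topology_map")
}

#' @export
print.topology_map <- function(x, ...) {
  cat("topology_map:", length(x), "proteins,",
      sum(vapply(x, function(s) sum(s$label == "TMhelix"), numeric(1))),
      "TM helices\n")
  invisible(x)
}

#' Write a topology map in TMHMM long format
#'
#' Round-trips with [read_topology()].
#'
#' @param topology A `topology_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  lines <- character(0)
  for (id in names(topology)) {
    seg <- topology[[id]]
    lines <- c(lines, sprintf("%s\tTMHMM2.0\t%s\t%d\t%d",
                              id, seg$label, seg$start, seg$end))
  }
  writeLines(lines, path)
  invisible(path)
}
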