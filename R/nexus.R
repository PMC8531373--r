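#' Write a split system as a SplitsTree-compatible NEXUS file
#'
#' Emits a TAXA block and a SPLITS block in the SplitsTree 4 dialect: the
#' dimensions, a FORMAT line, the CYCLE line (1-based taxon indices of the
#' circular ordering) and a MATRIX with one line per split carrying its
#' weight and the 1-based indices of one side. Splits are written by weight
#' descending, ties by the lexicographic order of their member list, so the
#' output is deterministic.
#'
#' @param css A [CircularSplitSystem-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeNexusSplits <- function(css, path) {
  n <- length(css@taxa)
  keymat <- vapply(css@splits, function(s)
    paste(formatC(s, width = 4, flag = "0"), collapse = " "), character(1))
  ord <- order(-css@weights, keymat)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("#nexus")
  w("")
  w("BEGIN Taxa;")
  w("DIMENSIONS ntax=%d;", n)
  w("TAXLABELS")
  for (i in seq_len(n)) w("[%d] '%s'", i, css@taxa[i])
  w(";")
  w("END; [Taxa]")
  w("")
  w("BEGIN Splits;")
  w("DIMENSIONS ntax=%d nsplits=%d;", n, length(css@splits))
  w("FORMAT labels=no weights=yes confidences=no intervals=no;")
  w("PROPERTIES fit=-1.0 cyclic;")
  w("CYCLE %s;", paste(css@cycle, collapse = " "))
  w("MATRIX")
  for (k in seq_along(ord)) {
    s <- css@splits[[ord[k]]]
    w("[%d, size=%d]\t%.10g\t%s,", k, length(s), css@weights[ord[k]],
      paste(s, collapse = " "))
  }
  w(";")
  w("END; [Splits]")
  invisible(path)
}

#' Read a NEXUS splits file written by [writeNexusSplits()]
#'
#' @param path NEXUS file path.
#' @return A [CircularSplitSystem-class] (RSS is not stored in the file and
#'   comes back as `NA`).
#' @export
readNexusSplits <- function(path) {
  lines <- readLines(path)
  lab_idx <- grep("^\\[\\d+\\] '", lines)
  taxa <- sub("^\\[\\d+\\] '(.*)'$", "\\1", lines[lab_idx])
  cyc_line <- grep("^CYCLE ", lines, value = TRUE)
  cycle <- as.integer(strsplit(sub("^CYCLE (.*);$", "\\1", cyc_line),
                               " ")[[1]])
  mstart <- grep("^MATRIX$", lines)
  mend <- which(lines == ";" & seq_along(lines) > mstart)[1]
  body <- lines[seq(mstart + 1L, mend - 1L)]
  splits <- list(); weights <- numeric(0)
  for (line in body) {
    line <- sub("^\\[[^]]*\\]", "", line)
    line <- sub(",\\s*$", "", trimws(line))
    parts <- strsplit(line, "[[:space:]]+")[[1]]
    weights <- c(weights, as.numeric(parts[1]))
    splits <- c(splits, list(sort.int(as.integer(parts[-1]))))
  }
  new("CircularSplitSystem", taxa = taxa, cycle = cycle, splits = splits,
      weights = weights, rss = NA_real_)
}
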