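# Internucleotide readers: RING/PAIR correlation tables (whitespace
# separated, one header line, columns i and j then named statistics;
# unknown statistic columns are kept by name) and pairing-probability
# dotplot text (rows of i, j, -log10 p).

#' Read an internucleotide interaction table
#'
#' @param path Input file.
#' @param tag One of `ring`, `pair`, `pairprob-dp`.
#' @param sequence Optional [sequence_record()]; inferred as an N-run up to
#'   the largest endpoint when absent.
#' @return An [interaction_set()]. For `pair`, the dialect's class column
#'   becomes `class_label` (`"primary"`/`"secondary"`); for `pairprob-dp`
#'   the third column x becomes statistic `"probability"` = 10^(-x).
#' @export
read_interactions <- function(path, tag = c("ring", "pair", "pairprob-dp"),
                              sequence = NULL) {
  tag <- match.arg(tag)
  out <- switch(tag,
                ring = read_ring_pair_table(path, classed = FALSE),
                pair = read_ring_pair_table(path, classed = TRUE),
                "pairprob-dp" = read_pairprob_dp(path))
  if (is.null(sequence)) {
    n <- max(c(out$j, 1L), na.rm = TRUE)
    sequence <- sequence_record(basename(path),
                                paste(rep("N", n), collapse = ""))
  }
  interaction_set(sequence, out)
}

read_ring_pair_table <- function(path, classed = FALSE) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("i", "j")
  ii <- pmin(df$i, df$j)
  jj <- pmax(df$i, df$j)
  bad <- ii == jj
  if (any(bad)) {
    warning(sum(bad), " record(s) with j <= i rejected in '", path, "'")
    df <- df[!bad, , drop = FALSE]
    ii <- ii[!bad]; jj <- jj[!bad]
  }
  df$i <- ii
  df$j <- jj
  if (classed) {
    cls <- grep("^class$", names(df), ignore.case = TRUE, value = TRUE)
    if (length(cls)) {
      v <- df[[cls[1]]]
      df$class_label <- ifelse(v %in% c(1, "1", "primary"),
                               "primary", "secondary")
      df[[cls[1]]] <- NULL
    }
  }
  df
}

read_pairprob_dp <- function(path) {
  lines <- trimws(read_text_lines(path))
  lines <- lines[nzchar(lines)]
  # skip the leading length line and the column-header line if present
  is_row <- grepl("^[0-9]+\\s+[0-9]+\\s+[-0-9.eE+]+$", lines)
  rows <- lines[is_row]
  if (!length(rows)) {
    stop("dotplot file '", path, "' has no 'i j -log10(p)' rows")
  }
  m <- do.call(rbind, strsplit(rows, "\\s+"))
  i <- as.integer(m[, 1])
  j <- as.integer(m[, 2])
  nlp <- as.numeric(m[, 3])
  p <- 10^(-nlp)
  if (any(p <= 0 | p > 1)) {
    stop("dotplot file '", path, "' yields probabilities outside (0, 1]")
  }
  ii <- pmin(i, j); jj <- pmax(i, j)
  bad <- ii == jj
  if (any(bad)) {
    warning(sum(bad), " record(s) with j <= i rejected in '", path, "'")
  }
  data.frame(i = ii, j = jj, probability = p)[!bad, , drop = FALSE]
}

write_pairprob_dp <- function(iset, path) {
  stopifnot("probability" %in% names(iset$records))
  writeLines(c(
    as.character(iset$sequence$length),
    "i\tj\t-log10(Probability)",
    sprintf("%d %d %.6f", iset$records$i, iset$records$j,
            -log10(iset$records$probability))
  ), path)
  invisible(path)
}
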