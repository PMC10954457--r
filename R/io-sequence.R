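#' Read a FASTA sequence
#'
#' Returns the first record unless `id` is given. Sequence lines are
#' stripped of whitespace, digits and any other non-letter decoration, so
#' wrapped and numbered FASTA dialects parse to the bare residue string.
#'
#' @param path FASTA file (plain text or gzip).
#' @param id Optional record id to select; an error if absent or duplicated.
#' @return A [sequence_record()].
#' @export
read_sequence <- function(path, id = NULL) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("FASTA file '", path, "' is empty")
  hdr <- grep("^>", lines)
  if (!length(hdr) || hdr[1] != 1L) {
    stop("FASTA parse error in '", path, "' line 1: expected '>' header")
  }
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  ends <- c(hdr[-1] - 1L, length(lines))
  pick <- 1L
  if (!is.null(id)) {
    pick <- which(ids == id)
    if (!length(pick)) stop("id '", id, "' not found in '", path, "'")
    if (length(pick) > 1L) stop("id '", id, "' is duplicated in '", path, "'")
  }
  body <- lines[seq(hdr[pick] + 1L, ends[pick])]
  residues <- gsub("[^A-Za-z]", "", paste(body, collapse = ""))
  if (!nchar(residues)) {
    stop("FASTA record '", ids[pick], "' in '", path, "' has no residues")
  }
  sequence_record(ids[pick], residues)
}

write_fasta <- function(seq, path, width = 70L) {
  chars <- seq_chars(seq)
  body <- vapply(split(chars, (seq_along(chars) - 1L) %/% width),
                 paste, "", collapse = "")
  writeLines(c(paste0(">", seq$id), body), path)
  invisible(path)
}
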