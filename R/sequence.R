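#' Transcript sequence record
#'
#' The primary sequence anchoring every other data object. Residues are kept
#' as supplied (DNA or RNA alphabet, either case); all identity comparisons
#' treat T and U as equal and are case-insensitive.
#'
#' @param id Short text label for the transcript.
#' @param residues Single string of residues over `{A,C,G,U,T,N}` (either
#'   case). Whitespace is stripped; any other character is an error.
#' @return An object of class `SequenceRecord` with fields `id`, `residues`
#'   and `length`.
#' @examples
#' sequence_record("toy", "GGGGAAAACCCC")
#' @export
sequence_record <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L)
  residues <- gsub("[[:space:]]", "", paste(residues, collapse = ""))
  if (nchar(residues) < 1L) {
    stop("sequence '", id, "' is empty; length must be >= 1")
  }
  if (grepl("[^ACGUTNacgutn]", residues)) {
    bad <- regmatches(residues, regexpr("[^ACGUTNacgutn]", residues))
    stop("sequence '", id, "' contains invalid residue '", bad, "'")
  }
  structure(
    list(id = id, residues = residues, length = nchar(residues)),
    class = "SequenceRecord"
  )
}

#' @export
print.SequenceRecord <- function(x, ...) {
  cat("<SequenceRecord>", x$id, "-", x$length, "nt\n")
  invisible(x)
}

#' @export
length.SequenceRecord <- function(x) x$length

# canonical comparison form: uppercase, T -> U
seq_identity_form <- function(x) {
  if (inherits(x, "SequenceRecord")) x <- x$residues
  chartr("T", "U", toupper(x))
}

#' Compare two sequences for identity (T equivalent to U, case-insensitive)
#'
#' @param a,b `SequenceRecord` objects or residue strings.
#' @return `TRUE` if the residue strings are identical under the T/U and
#'   case equivalences.
#' @export
same_sequence <- function(a, b) {
  identical(seq_identity_form(a), seq_identity_form(b))
}

seq_chars <- function(x) strsplit(x$residues, "", fixed = TRUE)[[1]]

# ensure `data` (any of the five classes, or a SequenceRecord) is defined on
# the same sequence as `sequence`; used as a precondition in analyses.
# An all-N record is a placeholder from a sequence-less file format and
# matches any sequence of the same length.
check_same_sequence <- function(a, b, what = "data") {
  placeholder <- grepl("^[Nn]+$", a$residues) || grepl("^[Nn]+$", b$residues)
  if (placeholder && a$length == b$length) return(invisible(TRUE))
  if (!same_sequence(a, b)) {
    stop(what, " is defined on sequence '", a$id, "' (", a$length,
         " nt) but expected sequence '", b$id, "' (", b$length, " nt)")
  }
  invisible(TRUE)
}

rna_complement <- function(x) chartr("ACGUTacgut", "UGCAAugcaa", x)
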