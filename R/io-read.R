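#' Read any supported format into its data class
#'
#' Central dispatch used by [create_sample()] and the CLI: looks up `tag`
#' in the format registry and calls the matching reader.
#'
#' @param path Input file.
#' @param tag Format tag (see [list_input_formats()]).
#' @param ... Passed to the reader (`sequence=`, `chain=`, `component=`,
#'   `id=`, ...).
#' @return A `SequenceRecord`, `SecondaryStructure`, `TertiaryStructure`,
#'   `Profile`, `InteractionSet`, or list of `Annotation`s, per the
#'   registry.
#' @export
read_data <- function(path, tag, ...) {
  reg <- format_registry()
  if (!tag %in% reg$tag) {
    stop("unknown format tag '", tag, "'; valid tags: ",
         paste(reg$tag, collapse = ", "))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(tag,
    "fasta" = read_sequence(path, ...),
    "ct" = ,
    "dotbracket" = ,
    "varna" = ,
    "xrna" = ,
    "forna" = ,
    "r2dt" = ,
    "nsd" = read_secondary_structure(path, tag = tag, ...),
    "pdb" = ,
    "cif" = read_tertiary(path, tag = tag, ...),
    "shapemapper-profile" = ,
    "map" = ,
    "shape" = ,
    "rnaframework-xml" = ,
    "dance-reactivities" = ,
    "wig" = read_profile(path, tag = tag, ...),
    "ring" = ,
    "pair" = ,
    "pairprob-dp" = read_interactions(path, tag = tag, ...),
    "bed-narrowpeak" = ,
    "gff-gtf" = read_annotations(path, tag = tag, ...)
  )
}

read_text_lines <- function(path) {
  raw <- readBin(path, "raw", n = min(file.size(path), 4096))
  if (any(raw == as.raw(0))) {
    stop("file '", path, "' is not plain text (NUL byte found)")
  }
  readLines(path, warn = FALSE)
}
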