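# Position mapping between sequences. Probing comparisons typically involve
# near-identical sequences with terminal truncations (primer trimming), so
# the default is an end-gap-free global alignment: match +1, mismatch -1,
# gap open -5, gap extend -1, end gaps free. T and U compare equal.

#' Align two sequences and build a position mapping
#'
#' Identical sequences (under the T/U and case equivalences) short-circuit
#' to the identity map; otherwise an end-gap-free global pairwise alignment
#' (Biostrings) produces a strictly monotone partial map from positions of
#' `seq_a` to positions of `seq_b`.
#'
#' @param seq_a,seq_b [sequence_record()] objects.
#' @param match,mismatch,gap_open,gap_extend Alignment scores (defaults
#'   +1/-1/-5/-1; end gaps are always free).
#' @return An object of class `PositionMapping` with fields `seq_a`,
#'   `seq_b`, `a_to_b` (integer vector, `NA` where unmapped) and `score`.
#' @export
align_positions <- function(seq_a, seq_b, match = 1, mismatch = -1,
                            gap_open = -5, gap_extend = -1) {
  if (seq_a$length < 1L || seq_b$length < 1L) stop("empty sequence")
  if (same_sequence(seq_a, seq_b)) {
    return(new_position_mapping(seq_a, seq_b, seq_len(seq_a$length),
                                score = match * seq_a$length))
  }
  a <- Biostrings::RNAString(seq_identity_form(seq_a))
  b <- Biostrings::RNAString(seq_identity_form(seq_b))
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE,
                                                  type = "RNA")
  # With end gaps free in BOTH sequences, the optimal alignment is exactly
  # the best single affine-gap segment (terminal gaps cost nothing, so the
  # optimum never extends into negative-scoring ends); Smith-Waterman
  # therefore computes the end-gap-free global optimum here.
  pa <- Biostrings::pairwiseAlignment(
    a, b, type = "local", substitutionMatrix = sub,
    gapOpening = -gap_open, gapExtension = -gap_extend
  )
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ai <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  bi <- Biostrings::start(Biostrings::subject(pa)) - 1L
  a_to_b <- rep(NA_integer_, seq_a$length)
  for (k in seq_along(ap)) {
    if (ap[k] != "-") ai <- ai + 1L
    if (as_[k] != "-") bi <- bi + 1L
    if (ap[k] != "-" && as_[k] != "-") a_to_b[ai] <- bi
  }
  new_position_mapping(seq_a, seq_b, a_to_b, score = pa@score)
}

new_position_mapping <- function(seq_a, seq_b, a_to_b, score = NA_real_) {
  mapped <- a_to_b[!is.na(a_to_b)]
  if (length(mapped) > 1L && any(diff(mapped) <= 0)) {
    stop("position map is not strictly monotone")
  }
  structure(list(seq_a = seq_a, seq_b = seq_b,
                 a_to_b = as.integer(a_to_b), score = score),
            class = "PositionMapping")
}

#' @export
print.PositionMapping <- function(x, ...) {
  cat("<PositionMapping>", x$seq_a$id, "->", x$seq_b$id, "-",
      sum(!is.na(x$a_to_b)), "of", x$seq_a$length, "positions mapped\n")
  invisible(x)
}

#' Invert a position mapping
#'
#' @param mapping A `PositionMapping`.
#' @return The mapping from `seq_b` to `seq_a` (defined on the image).
#' @export
invert_mapping <- function(mapping) {
  b_to_a <- rep(NA_integer_, mapping$seq_b$length)
  idx <- which(!is.na(mapping$a_to_b))
  b_to_a[mapping$a_to_b[idx]] <- idx
  new_position_mapping(mapping$seq_b, mapping$seq_a, b_to_a, mapping$score)
}

#' Compose two position mappings (a->b then b->c)
#'
#' @param m_ab,m_bc `PositionMapping` objects with a shared middle sequence.
#' @return The composed a->c `PositionMapping`.
#' @export
compose_mappings <- function(m_ab, m_bc) {
  check_same_sequence(m_ab$seq_b, m_bc$seq_a, "mapping middle sequence")
  a_to_c <- rep(NA_integer_, m_ab$seq_a$length)
  ok <- !is.na(m_ab$a_to_b)
  a_to_c[ok] <- m_bc$a_to_b[m_ab$a_to_b[ok]]
  new_position_mapping(m_ab$seq_a, m_bc$seq_b, a_to_c)
}

#' Carry a data object across a position mapping
#'
#' Transfers any of the five data classes from `mapping$seq_a` onto
#' `mapping$seq_b`. Profile values are carried to mapped positions
#' (unmapped targets become no-data); annotation spans are clipped to
#' their mapped extent; base pairs and interactions survive only if both
#' endpoints map (interactions with a lost endpoint stay in the record
#' list but are masked out); drawing coordinates travel with their
#' nucleotides.
#'
#' @param mapping A [align_positions()] result.
#' @param data A `Profile`, `Annotation`, `SecondaryStructure`,
#'   `InteractionSet`, `TertiaryStructure` or `SequenceRecord` on
#'   `mapping$seq_a`.
#' @return The same class of object on `mapping$seq_b`.
#' @export
map_data <- function(mapping, data) {
  stopifnot(inherits(mapping, "PositionMapping"))
  check_same_sequence(data$sequence %||% data, mapping$seq_a, "data")
  UseMethod("map_data", data)
}

#' @export
map_data.SequenceRecord <- function(mapping, data) mapping$seq_b

#' @export
map_data.Profile <- function(mapping, data) {
  nb <- mapping$seq_b$length
  values <- rep(NA_real_, nb)
  raw <- if (!is.null(data$raw)) rep(NA_real_, nb)
  stderr <- if (!is.null(data$stderr)) rep(NA_real_, nb)
  src <- which(!is.na(mapping$a_to_b))
  dst <- mapping$a_to_b[src]
  values[dst] <- data$values[src]
  if (!is.null(raw)) raw[dst] <- data$raw[src]
  if (!is.null(stderr)) stderr[dst] <- data$stderr[src]
  nodata <- rep(TRUE, nb)
  nodata[dst] <- data$nodata[src]
  nt_profile(mapping$seq_b, values, raw = raw, stderr = stderr,
             nodata = nodata, metric = data$metric)
}

#' @export
map_data.Annotation <- function(mapping, data) {
  spans <- lapply(seq_len(nrow(data$entries)), function(k) {
    lo <- min(data$entries$start[k], data$entries$end[k])
    hi <- max(data$entries$start[k], data$entries$end[k])
    tgt <- mapping$a_to_b[lo:hi]
    tgt <- tgt[!is.na(tgt)]
    if (!length(tgt)) return(NULL)
    if (data$entries$start[k] > data$entries$end[k]) {
      data.frame(start = max(tgt), end = min(tgt))   # reverse primer
    } else {
      data.frame(start = min(tgt), end = max(tgt))
    }
  })
  spans <- do.call(rbind, spans)
  if (is.null(spans)) spans <- data.frame(start = integer(0), end = integer(0))
  annotation(data$name, data$category, spans, mapping$seq_b, data$color)
}

#' @export
map_data.SecondaryStructure <- function(mapping, data) {
  pairs <- data$pairs
  if (nrow(pairs)) {
    mi <- mapping$a_to_b[pairs[, 1]]
    mj <- mapping$a_to_b[pairs[, 2]]
    keep <- !is.na(mi) & !is.na(mj)
    pairs <- cbind(mi[keep], mj[keep])
  }
  drawing <- NULL
  if (!is.null(data$drawing)) {
    drawing <- data.frame(x = rep(NA_real_, mapping$seq_b$length),
                          y = rep(NA_real_, mapping$seq_b$length))
    src <- which(!is.na(mapping$a_to_b))
    drawing[mapping$a_to_b[src], ] <- data$drawing[src, ]
  }
  secondary_structure(mapping$seq_b, pairs, drawing)
}

#' @export
map_data.InteractionSet <- function(mapping, data) {
  rec <- data$records
  mi <- mapping$a_to_b[rec$i]
  mj <- mapping$a_to_b[rec$j]
  lost <- is.na(mi) | is.na(mj)
  rec$i <- mi
  rec$j <- mj
  interaction_set(mapping$seq_b, rec, mask = data$mask & !lost)
}

#' @export
map_data.TertiaryStructure <- function(mapping, data) {
  sm <- data$seq_map
  sm$pos <- mapping$a_to_b[sm$pos]
  keep <- !is.na(sm$pos)
  atoms <- data$atoms
  atoms$pos <- NULL
  tertiary_structure(atoms, sm[keep, , drop = FALSE],
                     sequence = mapping$seq_b)
}
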