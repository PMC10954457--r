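#' Sequence annotation (regions, sites, groups, primers)
#'
#' Annotations mark regions of interest, single or grouped nucleotides, and
#' primer-binding sites on a transcript. All coordinates are 1-based
#' inclusive. For `category = "primers"` a span with `start > end` encodes a
#' reverse-strand primer; for every other category spans are normalized so
#' `start <= end`.
#'
#' @param name Text label.
#' @param category One of `"spans"`, `"sites"`, `"group"`, `"primers"`.
#' @param entries Data frame with integer columns `start` and `end`
#'   (`sites`/`group` entries have `start == end`).
#' @param sequence The [sequence_record()] the annotation indexes.
#' @param color Display color label.
#' @return An object of class `Annotation`.
#' @export
annotation <- function(name, category = c("spans", "sites", "group", "primers"),
                       entries, sequence, color = "blue") {
  category <- match.arg(category)
  entries <- as.data.frame(entries)
  stopifnot(all(c("start", "end") %in% names(entries)))
  entries$start <- as.integer(entries$start)
  entries$end <- as.integer(entries$end)
  if (category != "primers") {
    swap <- entries$start > entries$end
    tmp <- entries$start[swap]
    entries$start[swap] <- entries$end[swap]
    entries$end[swap] <- tmp
  }
  if (category %in% c("sites", "group") && any(entries$start != entries$end)) {
    stop("'", category, "' annotation entries must have start == end")
  }
  pos <- c(entries$start, entries$end)
  if (length(pos) && (min(pos) < 1L || max(pos) > sequence$length)) {
    stop("annotation '", name, "' has positions outside [1, ",
         sequence$length, "]")
  }
  structure(
    list(name = name, category = category, entries = entries,
         color = color, sequence = sequence),
    class = "Annotation"
  )
}

#' @export
print.Annotation <- function(x, ...) {
  cat("<Annotation>", x$name, sprintf("[%s]", x$category),
      nrow(x$entries), "entries on", x$sequence$id, "\n")
  invisible(x)
}

#' Secondary structure model
#'
#' A base-pair list (1-based, unordered pairs stored as `i < j`) with an
#' optional per-nucleotide 2D drawing layout. Each position may occur in at
#' most one pair; pseudoknots are represented directly in the pair list and
#' only become bracket "layers" on dot-bracket output.
#'
#' @param sequence A [sequence_record()].
#' @param pairs Two-column integer matrix (or data frame) of paired
#'   positions; order within a row is irrelevant.
#' @param drawing Optional data frame with columns `x`, `y` and one row per
#'   nucleotide (arbitrary drawing units).
#' @return An object of class `SecondaryStructure`.
#' @export
secondary_structure <- function(sequence, pairs = NULL, drawing = NULL) {
  pairs <- normalize_pairs(pairs, sequence$length)
  if (!is.null(drawing)) {
    drawing <- as.data.frame(drawing)
    stopifnot(all(c("x", "y") %in% names(drawing)))
    if (nrow(drawing) != sequence$length) {
      stop("drawing has ", nrow(drawing), " coordinate rows for a ",
           sequence$length, " nt sequence")
    }
  }
  structure(
    list(sequence = sequence, pairs = pairs, drawing = drawing),
    class = "SecondaryStructure"
  )
}

# canonical pair matrix: integer, i < j, unique, sorted, validated
normalize_pairs <- function(pairs, n) {
  if (is.null(pairs) || NROW(pairs) == 0L) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  }
  pairs <- as.matrix(as.data.frame(pairs)[, 1:2])
  storage.mode(pairs) <- "integer"
  ij <- cbind(i = pmin(pairs[, 1], pairs[, 2]),
              j = pmax(pairs[, 1], pairs[, 2]))
  ij <- unique(ij)
  if (any(ij[, 1] < 1L) || any(ij[, 2] > n)) {
    stop("pair positions outside [1, ", n, "]")
  }
  if (any(ij[, 1] == ij[, 2])) stop("self-pair (i == j) is not allowed")
  pos <- c(ij[, 1], ij[, 2])
  if (anyDuplicated(pos)) {
    stop("position ", pos[duplicated(pos)][1],
         " occurs in more than one base pair")
  }
  ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
}

#' @export
print.SecondaryStructure <- function(x, ...) {
  cat("<SecondaryStructure>", x$sequence$id, "-", nrow(x$pairs), "pairs",
      if (!is.null(x$drawing)) "(with drawing coordinates)", "\n")
  invisible(x)
}

pair_keys <- function(pairs) {
  if (NROW(pairs) == 0L) return(character(0))
  paste(pairs[, 1], pairs[, 2], sep = ":")
}

# paired partner per position (0 = unpaired), as in a connectivity table
partner_vector <- function(ss) {
  partner <- integer(ss$sequence$length)
  if (nrow(ss$pairs)) {
    partner[ss$pairs[, 1]] <- ss$pairs[, 2]
    partner[ss$pairs[, 2]] <- ss$pairs[, 1]
  }
  partner
}

#' Tertiary structure model
#'
#' Atomic coordinates grouped by residue, plus a mapping from author residue
#' numbers to 1-based transcript positions.
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resname`, `atom`,
#'   `x`, `y`, `z` (coordinates in Angstroms).
#' @param seq_map Data frame with columns `chain`, `resno`, `pos` mapping
#'   residue numbers to transcript positions; must be injective in `pos`.
#' @param sequence Optional [sequence_record()]; reconstructed from residue
#'   names when omitted.
#' @return An object of class `TertiaryStructure`.
#' @export
tertiary_structure <- function(atoms, seq_map, sequence = NULL) {
  atoms <- as.data.frame(atoms)
  need <- c("chain", "resno", "resname", "atom", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  seq_map <- as.data.frame(seq_map)
  stopifnot(all(c("chain", "resno", "pos") %in% names(seq_map)))
  if (anyDuplicated(seq_map$pos)) {
    stop("seq_map is not injective: duplicated transcript positions")
  }
  key_atoms <- paste(atoms$chain, atoms$resno)
  key_map <- paste(seq_map$chain, seq_map$resno)
  if (!all(key_map %in% key_atoms)) {
    stop("seq_map refers to residues with no atoms")
  }
  atoms$pos <- seq_map$pos[match(key_atoms, key_map)]
  if (is.null(sequence)) {
    res1 <- one_letter_residue(seq_map$resname %||%
                                 atoms$resname[match(key_map, key_atoms)])
    ord <- order(seq_map$pos)
    n <- max(seq_map$pos)
    chars <- rep("N", n)
    chars[seq_map$pos[ord]] <- res1[ord]
    sequence <- sequence_record("tertiary", paste(chars, collapse = ""))
  }
  structure(
    list(sequence = sequence, atoms = atoms, seq_map = seq_map),
    class = "TertiaryStructure"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

NUCLEIC_RESNAMES <- c(A = "A", C = "C", G = "G", U = "U", T = "T",
                      RA = "A", RC = "C", RG = "G", RU = "U",
                      DA = "A", DC = "C", DG = "G", DT = "T", DU = "U")

one_letter_residue <- function(resname) {
  out <- NUCLEIC_RESNAMES[toupper(resname)]
  out[is.na(out)] <- "N"
  unname(out)
}

#' @export
print.TertiaryStructure <- function(x, ...) {
  cat("<TertiaryStructure>", nrow(x$seq_map), "mapped residues,",
      nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Per-nucleotide profile
#'
#' Holds one per-nucleotide metric (normalized reactivity, Shannon entropy,
#' conservation, ...) with optional raw values and standard errors, plus a
#' no-data mask. Positions flagged `nodata` are excluded from every
#' statistic. The default reactivity color scale breaks at 0.4 and 0.85
#' (low/mid/high).
#'
#' @param sequence A [sequence_record()].
#' @param values Numeric vector of length `sequence$length` (NA allowed).
#' @param raw,stderr Optional numeric vectors of the same length.
#' @param nodata Optional logical mask; defaults to `is.na(values)`.
#' @param metric Metric metadata: a list with `name` and numeric
#'   `breakpoints` (color-scale thresholds).
#' @return An object of class `Profile`.
#' @export
nt_profile <- function(sequence, values, raw = NULL, stderr = NULL,
                       nodata = NULL,
                       metric = list(name = "reactivity",
                                     breakpoints = c(0.4, 0.85))) {
  n <- sequence$length
  values <- as.numeric(values)
  if (length(values) != n) {
    stop("profile has ", length(values), " values for a ", n, " nt sequence")
  }
  if (is.null(nodata)) nodata <- is.na(values)
  nodata <- as.logical(nodata) | is.na(values)
  for (nm in c("raw", "stderr")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != n) {
      stop("'", nm, "' has ", length(v), " entries for a ", n, " nt sequence")
    }
  }
  structure(
    list(sequence = sequence, values = values, raw = raw, stderr = stderr,
         nodata = nodata, metric = metric),
    class = "Profile"
  )
}

#' @export
print.Profile <- function(x, ...) {
  cat("<Profile>", x$metric$name, "on", x$sequence$id, "-",
      sum(!x$nodata), "of", x$sequence$length, "positions measured\n")
  invisible(x)
}

valid_values <- function(profile) profile$values[!profile$nodata]

#' Internucleotide interaction set
#'
#' Records measurements made between two nucleotides: correlated-probing
#' RINGs and PAIRs, base-pairing probabilities (statistic `"probability"`),
#' cross-links. Filtering toggles a per-record logical mask; records are
#' never deleted.
#'
#' @param sequence A [sequence_record()].
#' @param records Data frame with integer columns `i`, `j` plus one column
#'   per named statistic; an optional `class_label` column carries PAIR
#'   classes (`"primary"`/`"secondary"`).
#' @param mask Optional logical vector (default: all `TRUE`).
#' @return An object of class `InteractionSet`.
#' @export
interaction_set <- function(sequence, records, mask = NULL) {
  records <- as.data.frame(records)
  stopifnot(all(c("i", "j") %in% names(records)))
  records$i <- as.integer(records$i)
  records$j <- as.integer(records$j)
  ii <- pmin(records$i, records$j)
  jj <- pmax(records$i, records$j)
  records$i <- ii
  records$j <- jj
  live <- !is.na(records$i) & !is.na(records$j)
  if (any(records$i[live] < 1L) || any(records$j[live] > sequence$length)) {
    stop("interaction endpoints outside [1, ", sequence$length, "]")
  }
  if (any(records$i[live] == records$j[live])) {
    stop("interaction with i == j is not allowed")
  }
  if (is.null(mask)) mask <- rep(TRUE, nrow(records))
  stopifnot(length(mask) == nrow(records))
  mask[!live] <- FALSE
  structure(
    list(sequence = sequence, records = records, mask = as.logical(mask)),
    class = "InteractionSet"
  )
}

#' @export
print.InteractionSet <- function(x, ...) {
  cat("<InteractionSet>", nrow(x$records), "records on", x$sequence$id,
      "-", sum(x$mask), "pass the current filter\n")
  invisible(x)
}

interaction_statistics <- function(iset) {
  setdiff(names(iset$records), c("i", "j", "class_label"))
}
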