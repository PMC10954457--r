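#' Create a sample: one experimental condition's data, keyed by keyword
#'
#' A sample groups parsed data objects for a single RNA under one
#' experimental condition. Each input is a `(path, format-tag)` pair;
#' parsing is delegated to the format registry's reader and the parsed
#' object is stored under its keyword. Stored objects keep their own
#' sequence records; [align_positions()]/[map_data()] reconcile sequences
#' when samples mix them.
#'
#' @param label Text label for the condition.
#' @param inputs Named list: `keyword = list(path=, format=, ...)` or
#'   `keyword = c(path, format)`. Extra list entries are passed to the
#'   reader (e.g. `sequence=` for sequence-less formats, `chain=` for
#'   tertiary structures).
#' @return An object of class `Sample` with fields `label` and `store`.
#' @examples
#' s <- create_sample("empty", list())
#' plot_options(s)
#' @export
create_sample <- function(label, inputs = list()) {
  stopifnot(is.list(inputs))
  if (length(inputs) && is.null(names(inputs))) {
    stop("inputs must be a named list (keyword -> path/format)")
  }
  if (anyDuplicated(names(inputs))) {
    stop("duplicate keyword in sample inputs: ",
         names(inputs)[duplicated(names(inputs))][1])
  }
  store <- lapply(names(inputs), function(kw) {
    inp <- inputs[[kw]]
    if (is.character(inp) && length(inp) == 2L && is.null(names(inp))) {
      inp <- list(path = inp[1], format = inp[2])
    }
    if (is.null(inp$path) || is.null(inp$format)) {
      stop("input '", kw, "' needs both a path and a format tag")
    }
    args <- inp[setdiff(names(inp), c("path", "format"))]
    do.call(read_data, c(list(path = inp$path, tag = inp$format), args))
  })
  names(store) <- names(inputs)
  store <- adopt_placeholder_sequences(store)
  structure(list(label = label, store = store), class = "Sample")
}

is_placeholder_seq <- function(seq) {
  !is.null(seq) && grepl("^[Nn]+$", seq$residues)
}

# readers for sequence-less dialects (dotplots, BED, shape, ...) synthesize
# an all-N placeholder; within a sample, adopt a real sequence of identical
# length from a sibling object so cross-object checks can succeed
adopt_placeholder_sequences <- function(store) {
  real <- list()
  for (obj in store) {
    s <- if (inherits(obj, "SequenceRecord")) obj else obj$sequence
    if (!is.null(s) && !is_placeholder_seq(s)) {
      real[[as.character(s$length)]] <- real[[as.character(s$length)]] %||% s
    }
  }
  for (kw in names(store)) {
    obj <- store[[kw]]
    s <- obj$sequence
    if (is_placeholder_seq(s) && !is.null(real[[as.character(s$length)]])) {
      obj$sequence <- real[[as.character(s$length)]]
      store[[kw]] <- obj
    }
  }
  store
}

#' @export
print.Sample <- function(x, ...) {
  cat("<Sample>", x$label, "-", length(x$store), "data objects\n")
  for (kw in names(x$store)) {
    cat("  $", kw, ": ", class(get_data(x, kw))[1], "\n", sep = "")
  }
  invisible(x)
}

#' Fetch a data object from a sample by keyword
#'
#' @param sample A `Sample`.
#' @param keyword Store keyword.
#' @return The stored data object (including its current filter mask).
#' @export
get_data <- function(sample, keyword) {
  if (!keyword %in% names(sample$store)) {
    stop("sample '", sample$label, "' has no data under keyword '", keyword,
         "'; available: ", paste(names(sample$store), collapse = ", "))
  }
  sample$store[[keyword]]
}

#' Store (or replace) a data object in a sample
#'
#' @param sample A `Sample`.
#' @param keyword Store keyword.
#' @param value One of the five data classes.
#' @return The updated `Sample`.
#' @export
set_data <- function(sample, keyword, value) {
  sample$store[[keyword]] <- value
  sample
}
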