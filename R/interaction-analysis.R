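# Internucleotide analytics: conjunctive filtering, pair-model comparison,
# multi-model consensus, 3D contact distances, histograms and density
# heatmaps.

#' Distance parameters for 3D contact measurements
#'
#' @param atom Atom used for internucleotide distances (default `"O2'"`,
#'   the ribose-centric convention for probing-adduct proximity).
#' @param fallback Atom used when `atom` is absent at a position
#'   (default `"C1'"`).
#' @return A `DistanceParams` list.
#' @export
distance_params <- function(atom = "O2'", fallback = "C1'") {
  list(atom = atom, fallback = fallback)
}

#' Filter an interaction set (mask update; records are never deleted)
#'
#' All supplied criteria compose conjunctively; the mask is recomputed from
#' scratch, so filtering is idempotent. `top_k` is applied last, among
#' records passing the other criteria.
#'
#' @param iset An [interaction_set()].
#' @param statistic Statistic name used by `min`/`max`/`sign`/`top_k`
#'   (default: the set's first statistic).
#' @param min,max Inclusive bounds on the statistic.
#' @param sign `"any"`, `"positive"` or `"negative"` (sign of the
#'   statistic; positive-correlation filtering).
#' @param class_label `"any"`, `"primary"` or `"secondary"`.
#' @param region Length-2 span; both endpoints must fall inside.
#' @param max_distance,min_distance 3D contact distance bounds in Angstroms
#'   (require `tertiary`).
#' @param top_k Keep only the k records with the largest statistic.
#' @param tertiary A [tertiary_structure()] for distance criteria.
#' @param dparams A [distance_params()].
#' @return The filtered `InteractionSet` with attribute `pass_count`.
#' @export
filter_interactions <- function(iset, statistic = NULL, min = NULL,
                                max = NULL, sign = c("any", "positive",
                                                     "negative"),
                                class_label = c("any", "primary",
                                                "secondary"),
                                region = NULL, max_distance = NULL,
                                min_distance = NULL, top_k = NULL,
                                tertiary = NULL,
                                dparams = distance_params()) {
  sign <- match.arg(sign)
  class_label <- match.arg(class_label)
  rec <- iset$records
  stats_avail <- interaction_statistics(iset)
  if (is.null(statistic)) statistic <- stats_avail[1]
  needs_stat <- !is.null(min) || !is.null(max) || sign != "any" ||
    !is.null(top_k)
  if (needs_stat) {
    if (is.na(statistic) || !statistic %in% stats_avail) {
      stop("unknown statistic '", statistic, "'; available: ",
           paste(stats_avail, collapse = ", "))
    }
  }
  live <- !is.na(rec$i) & !is.na(rec$j)
  mask <- live
  if (needs_stat) {
    v <- rec[[statistic]]
    if (!is.null(min)) mask <- mask & !is.na(v) & v >= min
    if (!is.null(max)) mask <- mask & !is.na(v) & v <= max
    if (sign == "positive") mask <- mask & !is.na(v) & v > 0
    if (sign == "negative") mask <- mask & !is.na(v) & v < 0
  }
  if (class_label != "any") {
    if (!"class_label" %in% names(rec)) {
      stop("interaction set has no class labels")
    }
    mask <- mask & !is.na(rec$class_label) & rec$class_label == class_label
  }
  if (!is.null(region)) {
    mask <- mask & rec$i >= region[1] & rec$j <= region[2]
  }
  if (!is.null(max_distance) || !is.null(min_distance)) {
    if (is.null(tertiary)) {
      stop("distance criteria require a tertiary structure")
    }
    d <- contact_distances(tertiary, rec$i, rec$j, dparams)
    if (!is.null(max_distance)) mask <- mask & !is.na(d) & d <= max_distance
    if (!is.null(min_distance)) mask <- mask & !is.na(d) & d >= min_distance
  }
  if (!is.null(top_k)) {
    v <- rec[[statistic]]
    v[!mask] <- NA
    keep <- order(v, decreasing = TRUE, na.last = TRUE)[seq_len(base::min(
      top_k, sum(mask)))]
    mask <- mask & seq_along(mask) %in% keep
  }
  iset$mask <- mask
  attr(iset, "pass_count") <- sum(mask)
  iset
}

#' Classify predicted base pairs against an accepted structure
#'
#' Pair-by-pair set algebra: `correct` = predicted and in the accepted
#' structure; `incorrect` = predicted and not accepted; `missing` =
#' accepted and not predicted. Sensitivity = correct/(correct+missing),
#' PPV = correct/(correct+incorrect) (NA when the denominator is zero).
#' Pair identity is exact (i, j) equality; `slip = TRUE` additionally
#' accepts a one-position slip in either endpoint when matching predicted
#' pairs (off by default; all reported numbers use exact identity).
#'
#' @param predicted,accepted [secondary_structure()]s on the same sequence.
#' @param slip Allow +/-1 slip when matching predicted pairs.
#' @return A `PairClassification` list: `labels` (data frame `i`, `j`,
#'   `label`), `correct`, `incorrect`, `missing`, `sensitivity`, `ppv`.
#' @export
classify_pairs <- function(predicted, accepted, slip = FALSE) {
  check_same_sequence(accepted$sequence, predicted$sequence, "accepted")
  pk <- pair_keys(predicted$pairs)
  ak <- pair_keys(accepted$pairs)
  match_acc <- if (slip) {
    vapply(seq_len(nrow(predicted$pairs)), function(k) {
      i <- predicted$pairs[k, 1]; j <- predicted$pairs[k, 2]
      any(abs(accepted$pairs[, 1] - i) <= 1L &
            abs(accepted$pairs[, 2] - j) <= 1L)
    }, TRUE)
  } else {
    pk %in% ak
  }
  correct <- sum(match_acc)
  incorrect <- length(pk) - correct
  missing_keys <- setdiff(ak, pk)
  labels <- rbind(
    if (length(pk)) data.frame(key = pk,
                               label = ifelse(match_acc, "correct",
                                              "incorrect")),
    if (length(missing_keys)) data.frame(key = missing_keys,
                                         label = "missing")
  )
  if (is.null(labels)) {
    labels <- data.frame(i = integer(0), j = integer(0),
                         label = character(0))
  } else {
    ij <- do.call(rbind, strsplit(labels$key, ":"))
    labels <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                         label = labels$label)
  }
  structure(list(
    labels = labels,
    correct = correct, incorrect = incorrect,
    missing = length(missing_keys),
    sensitivity = if (correct + length(missing_keys) > 0) {
      correct / (correct + length(missing_keys))
    } else NA_real_,
    ppv = if (length(pk) > 0) correct / length(pk) else NA_real_
  ), class = "PairClassification")
}

#' @export
print.PairClassification <- function(x, ...) {
  cat(sprintf(paste0("<PairClassification> correct %d, incorrect %d, ",
                     "missing %d (sens %.3f, ppv %.3f)\n"),
              x$correct, x$incorrect, x$missing, x$sensitivity, x$ppv))
  invisible(x)
}

#' Consensus base pairs across structure models
#'
#' Builds the union of pairs over k models, counts per-pair support, and
#' reports the consensus set (support >= `min_support`) and the fraction
#' of the union shared by all models (the denominator is the union of all
#' models' pairs, the only reading under which a single percentage is
#' well-defined).
#'
#' @param models List of >= 2 [secondary_structure()]s on a common
#'   coordinate system.
#' @param min_support Minimum number of supporting models (default 3).
#' @return A `ConsensusTable` list: `table` (data frame `i`, `j`,
#'   `support`), `k`, `consensus` (subset with support >= min_support),
#'   `fraction_shared_all`.
#' @export
consensus_pairs <- function(models, min_support = 3L) {
  if (length(models) < 2L) stop("consensus needs >= 2 models")
  keys <- lapply(models, function(m) pair_keys(m$pairs))
  support <- table(unlist(keys))
  ij <- do.call(rbind, strsplit(names(support), ":"))
  tab <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                    support = as.integer(support))
  tab <- tab[order(tab$i, tab$j), ]
  rownames(tab) <- NULL
  structure(list(
    table = tab,
    k = length(models),
    min_support = min_support,
    consensus = tab[tab$support >= min_support, , drop = FALSE],
    fraction_shared_all = if (nrow(tab)) {
      sum(tab$support == length(models)) / nrow(tab)
    } else NA_real_
  ), class = "ConsensusTable")
}

#' @export
print.ConsensusTable <- function(x, ...) {
  cat(sprintf(paste0("<Consensus> %d models, union %d pairs, %.1f%% shared ",
                     "by all, %d pairs with support >= %d\n"),
              x$k, nrow(x$table), 100 * x$fraction_shared_all,
              nrow(x$consensus), x$min_support))
  invisible(x)
}

atom_coords <- function(tertiary, positions, dparams = distance_params()) {
  at <- tertiary$atoms
  out <- matrix(NA_real_, nrow = length(positions), ncol = 3)
  fallback_used <- logical(length(positions))
  primary <- at[at$atom == dparams$atom, , drop = FALSE]
  second <- at[at$atom == dparams$fallback, , drop = FALSE]
  m1 <- match(positions, primary$pos)
  m2 <- match(positions, second$pos)
  use1 <- !is.na(m1)
  out[use1, ] <- as.matrix(primary[m1[use1], c("x", "y", "z")])
  use2 <- !use1 & !is.na(m2)
  out[use2, ] <- as.matrix(second[m2[use2], c("x", "y", "z")])
  fallback_used[use2] <- TRUE
  attr(out, "fallback") <- fallback_used
  out
}

#' 3D contact distance between two nucleotides
#'
#' Euclidean distance between the chosen atoms (default O2', falling back
#' to C1'); NA when neither atom is present at a position.
#'
#' @param tertiary A [tertiary_structure()].
#' @param i,j Transcript positions.
#' @param dparams A [distance_params()].
#' @return Distance in Angstroms (plain numeric).
#' @export
contact_distance <- function(tertiary, i, j, dparams = distance_params()) {
  as.numeric(contact_distances(tertiary, i, j, dparams))
}

#' Vectorized contact distances
#'
#' @inheritParams contact_distance
#' @return Numeric vector with attribute `fallback` flagging positions
#'   where the fallback atom was used.
#' @export
contact_distances <- function(tertiary, i, j, dparams = distance_params()) {
  a <- atom_coords(tertiary, i, dparams)
  b <- atom_coords(tertiary, j, dparams)
  d <- sqrt(rowSums((a - b)^2))
  d[!is.na(i) & !is.na(j) & i == j] <- 0
  attr(d, "fallback") <- attr(a, "fallback") | attr(b, "fallback")
  d
}

#' Histogram of interaction contact distances with an all-pairs background
#'
#' Masked-in records are binned by 3D contact distance; the background
#' histogram bins the distances of all position pairs (i, j) with
#' j > i + `gap`, for comparison.
#'
#' @param iset An [interaction_set()].
#' @param tertiary A [tertiary_structure()] covering the sequence.
#' @param breaks Histogram breakpoints in Angstroms (passed to `hist`).
#' @param gap Background excludes pairs closer than this in sequence
#'   (default 0: all j > i).
#' @param dparams A [distance_params()].
#' @return List with `counts`, `background`, `breaks`, `distances`.
#' @export
distance_histogram <- function(iset, tertiary, breaks = seq(0, 200, 10),
                               gap = 0L, dparams = distance_params()) {
  rec <- iset$records[iset$mask, , drop = FALSE]
  d <- if (nrow(rec)) {
    contact_distances(tertiary, rec$i, rec$j, dparams)
  } else numeric(0)
  d <- d[!is.na(d)]
  pos <- sort(unique(tertiary$seq_map$pos))
  bg_pairs <- expand.grid(i = pos, j = pos)
  bg_pairs <- bg_pairs[bg_pairs$j > bg_pairs$i + gap, , drop = FALSE]
  bg <- contact_distances(tertiary, bg_pairs$i, bg_pairs$j, dparams)
  bg <- bg[!is.na(bg)]
  top <- base::max(c(breaks, d, bg))
  breaks <- unique(c(breaks, top))
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  hb <- graphics::hist(bg, breaks = breaks, plot = FALSE)
  list(counts = h$counts, background = hb$counts, breaks = breaks,
       distances = d)
}

#' 2D density heatmap of interactions
#'
#' Masked-in records are accumulated into square sequence bins of width
#' `bin_size` by integer division of the endpoints (positions p with equal
#' `p %/% bin_size` share a bin); the matrix is upper-triangular
#' (bin_i <= bin_j) and its total mass equals the filter pass count.
#'
#' @param iset An [interaction_set()].
#' @param bin_size Bin width in nucleotides (>= 1).
#' @return List with `matrix` (n_bins x n_bins), `bin_size`, `n_bins`.
#' @export
density_heatmap <- function(iset, bin_size = 10L) {
  if (bin_size < 1L) stop("bin_size must be >= 1")
  n_bins <- iset$sequence$length %/% bin_size + 1L
  m <- matrix(0L, n_bins, n_bins)
  rec <- iset$records[iset$mask, , drop = FALSE]
  if (nrow(rec)) {
    bi <- rec$i %/% bin_size + 1L
    bj <- rec$j %/% bin_size + 1L
    for (k in seq_len(nrow(rec))) {
      m[bi[k], bj[k]] <- m[bi[k], bj[k]] + 1L
    }
  }
  list(matrix = m, bin_size = as.integer(bin_size), n_bins = n_bins)
}
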