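# Per-nucleotide analytics: normalization, windowed statistics, Shannon
# entropy from pairing probabilities, lowSS region calling, deltaSHAPE,
# windowed AUROC, and inter-profile regression.

#' Normalize raw reactivities
#'
#' Two community-standard schemes. `boxplot`: values above Q3 + 1.5*IQR are
#' outliers (at most 10% of the data may be removed); the normalization
#' factor is the mean of the top 10% of the remaining values. `percentile`:
#' the factor is the mean of values between the 90th and 99th percentiles.
#' Normalized values are unitless.
#'
#' @param values Numeric vector of raw reactivities (NA = no data).
#' @param method `"boxplot"` or `"percentile"`.
#' @return Normalized values (same length, NA preserved).
#' @export
normalize_profile <- function(values, method = c("boxplot", "percentile")) {
  method <- match.arg(method)
  v <- values[!is.na(values)]
  if (length(v) < 10L) {
    stop("normalization needs at least 10 valid values; got ", length(v))
  }
  factor <- if (method == "boxplot") {
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    cutoff <- q[2] + 1.5 * (q[2] - q[1])
    n_out <- min(sum(v > cutoff), floor(length(v) / 10))
    keep <- if (n_out > 0) sort(v)[seq_len(length(v) - n_out)] else sort(v)
    top <- keep[keep >= stats::quantile(keep, 0.9, names = FALSE)]
    mean(top)
  } else {
    q <- stats::quantile(v, c(0.90, 0.99), names = FALSE)
    sel <- v >= q[1] & v <= q[2]
    mean(v[sel])
  }
  if (!is.finite(factor) || factor == 0) {
    stop("normalization factor is degenerate (", factor, ")")
  }
  values / factor
}

#' Window parameters for centered per-nucleotide statistics
#'
#' @param w Odd window length in nucleotides (default 51).
#' @param edge `"truncate"` (shrink windows at the ends) or `"nodata"`
#'   (positions whose full window does not fit become no-data).
#' @return A `WindowParams` list.
#' @export
window_params <- function(w = 51L, edge = c("truncate", "nodata")) {
  w <- as.integer(w)
  if (w < 1L || w %% 2L == 0L) stop("window length must be odd and >= 1")
  list(w = w, edge = match.arg(edge))
}

#' Centered windowed median
#'
#' Median over a centered window of `w` positions; no-data values are
#' excluded from each window, and an all-no-data window yields NA.
#'
#' @param values Numeric vector (NA = no data).
#' @param params A [window_params()].
#' @return Numeric vector of per-position windowed medians.
#' @export
windowed_median <- function(values, params = window_params()) {
  n <- length(values)
  half <- (params$w - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    lo <- i - half
    hi <- i + half
    if (params$edge == "nodata" && (lo < 1L || hi > n)) next
    win <- values[max(1L, lo):min(n, hi)]
    win <- win[!is.na(win)]
    if (length(win)) out[i] <- stats::median(win)
  }
  out
}

#' Per-nucleotide Shannon entropy from pairing probabilities
#'
#' s_i = -sum_j p_ij log10(p_ij), summed over all recorded partners j of i
#' in either orientation; positions with no recorded partner get s_i = 0.
#' Base-10 logarithm, the convention under which the 0.15 lowSS threshold
#' is defined. The unpaired-probability term is excluded (the sum runs over
#' dotplot content only).
#'
#' @param pairprobs [interaction_set()] carrying statistic `"probability"`.
#' @return A [nt_profile()] of entropies (metric `"shannon_entropy"`).
#' @export
shannon_entropy <- function(pairprobs) {
  if (!"probability" %in% names(pairprobs$records)) {
    stop("interaction set has no 'probability' statistic; available: ",
         paste(interaction_statistics(pairprobs), collapse = ", "))
  }
  n <- pairprobs$sequence$length
  s <- numeric(n)
  rec <- pairprobs$records
  term <- -rec$probability * log10(rec$probability)
  for (k in seq_len(nrow(rec))) {
    s[rec$i[k]] <- s[rec$i[k]] + term[k]
    s[rec$j[k]] <- s[rec$j[k]] + term[k]
  }
  nt_profile(pairprobs$sequence, s, nodata = rep(FALSE, n),
             metric = list(name = "shannon_entropy",
                           breakpoints = c(0.15, 0.5)))
}

#' lowSS parameters
#'
#' @param r_max Windowed-median reactivity threshold (default 0.4).
#' @param s_max Windowed-median Shannon entropy threshold (default 0.15).
#' @param window A [window_params()] (default 51-nt, truncated edges).
#' @param merge_gap Runs separated by fewer than this many nucleotides are
#'   merged (default 0: no merging).
#' @return A `LowSSParams` list.
#' @export
lowss_params <- function(r_max = 0.4, s_max = 0.15,
                         window = window_params(51L), merge_gap = 0L) {
  stopifnot(r_max > 0, s_max > 0, merge_gap >= 0)
  list(r_max = r_max, s_max = s_max, window = window,
       merge_gap = as.integer(merge_gap))
}

#' Find regions of low reactivity and low Shannon entropy (lowSS)
#'
#' Position i is "low" iff its windowed median reactivity is below `r_max`
#' and its windowed median entropy is below `s_max`; maximal runs of low
#' positions become regions, numbered 5' to 3'. Region boundaries are
#' reported at window centers.
#'
#' @param reactivity,entropy [nt_profile()]s on the same sequence.
#' @param params A [lowss_params()].
#' @return Data frame with columns `index`, `start`, `end` (1-based
#'   inclusive), plus the windowed median tracks as attributes
#'   `med_reactivity` and `med_entropy`.
#' @export
find_lowss <- function(reactivity, entropy, params = lowss_params()) {
  check_same_sequence(entropy$sequence, reactivity$sequence, "entropy profile")
  vr <- reactivity$values
  vr[reactivity$nodata] <- NA
  ve <- entropy$values
  ve[entropy$nodata] <- NA
  med_r <- windowed_median(vr, params$window)
  med_e <- windowed_median(ve, params$window)
  low <- !is.na(med_r) & !is.na(med_e) &
    med_r < params$r_max & med_e < params$s_max
  regions <- runs_to_regions(low, params$merge_gap)
  attr(regions, "med_reactivity") <- med_r
  attr(regions, "med_entropy") <- med_e
  regions
}

runs_to_regions <- function(low, merge_gap = 0L) {
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg <- data.frame(start = starts[r$values], end = ends[r$values])
  if (merge_gap > 0L && nrow(reg) > 1L) {
    merged <- reg[1, , drop = FALSE]
    for (k in 2:nrow(reg)) {
      if (reg$start[k] - merged$end[nrow(merged)] - 1L < merge_gap) {
        merged$end[nrow(merged)] <- reg$end[k]
      } else {
        merged <- rbind(merged, reg[k, ])
      }
    }
    reg <- merged
  }
  if (nrow(reg)) reg <- cbind(index = seq_len(nrow(reg)), reg)
  else reg <- data.frame(index = integer(0), start = integer(0),
                         end = integer(0))
  rownames(reg) <- NULL
  reg
}

#' deltaSHAPE: error-aware detection of reactivity differences
#'
#' Values and standard errors of both profiles are smoothed over centered
#' windows (default 5 nt; errors combined as sqrt(sum err^2)/n). The
#' per-position difference d = smooth(a) - smooth(b) gets a Z-factor
#' 1 - z_mult*(sem_a + sem_b)/|d| and a standard score from the
#' distribution of d. A position is a site when Z-factor > 0 and
#' |standard score| >= `z_thresh` at >= `min_count` of the `site_window`
#' consecutive positions centered on it.
#'
#' @param profile_a,profile_b [nt_profile()]s on the same sequence, both
#'   with standard errors.
#' @param smooth_w Smoothing window (default 5 nt).
#' @param z_mult Error multiplier in the Z-factor (default 1.96).
#' @param z_thresh Standard-score magnitude threshold (default 1).
#' @param site_window,min_count Consecutiveness rule (default 3 of 5).
#' @return A `DeltaShapeResult` list: `diff`, `zfactor`, `std_score`,
#'   `site` (logical mask), `positions`.
#' @export
delta_shape <- function(profile_a, profile_b, smooth_w = 5L, z_mult = 1.96,
                        z_thresh = 1, site_window = 5L, min_count = 3L) {
  check_same_sequence(profile_b$sequence, profile_a$sequence, "profile_b")
  if (is.null(profile_a$stderr) || is.null(profile_b$stderr)) {
    stop("deltaSHAPE requires standard errors on both profiles")
  }
  va <- profile_a$values; va[profile_a$nodata] <- NA
  vb <- profile_b$values; vb[profile_b$nodata] <- NA
  sa <- smooth_mean(va, smooth_w)
  sb <- smooth_mean(vb, smooth_w)
  ea <- smooth_err(profile_a$stderr, va, smooth_w)
  eb <- smooth_err(profile_b$stderr, vb, smooth_w)
  d <- sa - sb
  zf <- 1 - z_mult * (ea + eb) / abs(d)
  zf[!is.finite(zf)] <- -Inf
  z <- (d - mean(d, na.rm = TRUE)) / stats::sd(d, na.rm = TRUE)
  pass <- !is.na(d) & zf > 0 & abs(z) >= z_thresh
  half <- (site_window - 1L) %/% 2L
  n <- length(d)
  site <- vapply(seq_len(n), function(i) {
    win <- pass[max(1L, i - half):min(n, i + half)]
    pass[i] && sum(win) >= min_count
  }, TRUE)
  structure(list(diff = d, zfactor = zf, std_score = z, site = site,
                 positions = seq_len(n), sequence = profile_a$sequence),
            class = "DeltaShapeResult")
}

smooth_mean <- function(v, w) {
  half <- (w - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    win <- v[max(1L, i - half):min(n, i + half)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, 0)
}

smooth_err <- function(err, v, w) {
  err[is.na(v)] <- NA
  half <- (w - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    win <- err[max(1L, i - half):min(n, i + half)]
    win <- win[!is.na(win)]
    if (!length(win)) NA_real_ else sqrt(sum(win^2)) / length(win)
  }, 0)
}

#' Windowed AUROC of reactivity as a paired/unpaired classifier
#'
#' For each centered window, the area under the ROC curve for values
#' classifying unpaired (positive class) versus paired (negative class)
#' nucleotides, with ties counted 1/2 (Mann-Whitney convention). Windows
#' lacking either class yield no-data.
#'
#' @param profile A [nt_profile()].
#' @param ss A [secondary_structure()] on the same sequence.
#' @param params A [window_params()].
#' @return A [nt_profile()] of AUROC values (metric `"auroc"`).
#' @export
windowed_auroc <- function(profile, ss, params = window_params()) {
  check_same_sequence(ss$sequence, profile$sequence, "structure")
  n <- profile$sequence$length
  paired <- partner_vector(ss) > 0L
  v <- profile$values
  v[profile$nodata] <- NA
  half <- (params$w - 1L) %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (params$edge == "nodata" && (i - half < 1L || i + half > n)) next
    idx <- max(1L, i - half):min(n, i + half)
    out[i] <- auroc(v[idx][!paired[idx]], v[idx][paired[idx]])
  }
  nt_profile(profile$sequence, out,
             metric = list(name = "auroc", breakpoints = c(0.5, 0.8)))
}

# rank-based AUROC: positives `pos` vs negatives `neg`, ties get 1/2 credit
auroc <- function(pos, neg) {
  pos <- pos[!is.na(pos)]
  neg <- neg[!is.na(neg)]
  if (!length(pos) || !length(neg)) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Regress one profile against another
#'
#' Least-squares slope/intercept and Pearson correlation over positions
#' valid in both profiles, plus the paired-value table (for kernel-density
#' rendering).
#'
#' @param profile_a,profile_b [nt_profile()]s on the same sequence.
#' @return A `RegressionResult` list: `slope`, `intercept`, `r`, `n`,
#'   `pairs` (data frame `position`, `a`, `b`).
#' @export
compare_profiles <- function(profile_a, profile_b) {
  check_same_sequence(profile_b$sequence, profile_a$sequence, "profile_b")
  ok <- !profile_a$nodata & !profile_b$nodata &
    !is.na(profile_a$values) & !is.na(profile_b$values)
  if (sum(ok) < 3L) {
    stop("profiles share only ", sum(ok), " valid positions; need >= 3")
  }
  a <- profile_a$values[ok]
  b <- profile_b$values[ok]
  fit <- stats::lm(b ~ a)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(a, b),
                 n = sum(ok),
                 pairs = data.frame(position = which(ok), a = a, b = b)),
            class = "RegressionResult")
}

#' @export
print.RegressionResult <- function(x, ...) {
  cat(sprintf("<Regression> n = %d, r = %.3f, slope = %.3f, intercept = %.3f\n",
              x$n, x$r, x$slope, x$intercept))
  invisible(x)
}
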