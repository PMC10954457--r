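test_that("percentile normalization divides by the 90-99th percentile mean", {
  v <- as.numeric(1:100)
  norm <- normalize_profile(v, "percentile")
  expect_equal(norm[95], 1.0)          # mean(91..99) = 95
  expect_equal(norm, v / 95)
  const <- rep(3.7, 20)
  expect_equal(normalize_profile(const, "percentile"), rep(1.0, 20))
  expect_error(normalize_profile(rep(NA_real_, 20)), "at least 10")
})

test_that("boxplot normalization removes outliers before scaling", {
  set.seed(3)
  v <- c(runif(95, 0, 2), rep(50, 5))   # 5% extreme outliers
  norm <- normalize_profile(v, "boxplot")
  # factor from the top 10% of the remaining (outlier-free) values
  q <- quantile(v, c(.25, .75), names = FALSE)
  keep <- sort(v)[1:(100 - min(sum(v > q[2] + 1.5 * diff(q)), 10))]
  top <- keep[keep >= quantile(keep, 0.9, names = FALSE)]
  expect_equal(norm, v / mean(top))
})

test_that("windowed medians match the sort-and-middle oracle", {
  expect_equal(windowed_median(c(1, 2, 3, 100, 5), window_params(3)),
               c(1.5, 2, 3, 5, 52.5))
  expect_equal(windowed_median(rep(7, 9), window_params(5)), rep(7, 9))
  expect_equal(windowed_median(c(3, 1, 4), window_params(1)), c(3, 1, 4))
  expect_error(window_params(4), "odd")
  set.seed(14)
  for (rep in 1:50) {
    v <- runif(sample(10:60, 1))
    v[sample(length(v), length(v) %/% 5)] <- NA
    w <- sample(c(1, 3, 5, 9, 51), 1)
    for (edge in c("truncate", "nodata")) {
      expect_equal(windowed_median(v, window_params(w, edge)),
                   oracle_window_median(v, w, edge),
                   label = paste("w", w, edge))
    }
  }
})

test_that("Shannon entropy equals direct summation", {
  seq <- sequence_record("t", strrep("A", 12))
  one <- interaction_set(seq, data.frame(i = 3, j = 9, probability = 1))
  expect_equal(shannon_entropy(one)$values, rep(0, 12))
  two <- interaction_set(seq, data.frame(i = c(3, 3), j = c(9, 10),
                                         probability = c(0.5, 0.5)))
  s <- shannon_entropy(two)$values
  expect_equal(s[3], -2 * 0.5 * log10(0.5))   # 0.30103
  expect_equal(s[9], -0.5 * log10(0.5))
  expect_equal(s[1], 0)                       # no partners
  set.seed(8)
  for (rep in 1:30) {
    n <- sample(10:30, 1)
    m <- sample(1:20, 1)
    rec <- data.frame(i = sample(n - 1, m, TRUE))
    rec$j <- rec$i + sample.int(3, m, TRUE)
    rec <- rec[rec$j <= n, , drop = FALSE]
    rec <- rec[!duplicated(rec), ]
    rec$probability <- runif(nrow(rec), 0.01, 1)
    iset <- interaction_set(sequence_record("r", strrep("A", n)), rec)
    expect_equal(shannon_entropy(iset)$values, oracle_entropy(rec, n))
  }
})

test_that("entropy is nonnegative and maximal for equiprobable partners", {
  seq <- sequence_record("t", strrep("A", 20))
  for (k in 2:5) {
    rec <- data.frame(i = 1, j = 1 + seq_len(k), probability = 1 / k)
    s <- shannon_entropy(interaction_set(seq, rec))$values
    expect_equal(s[1], log10(k))
    expect_true(all(s >= 0))
  }
})

test_that("lowSS calling matches brute-force window evaluation", {
  n <- 200
  react <- toy_profile(rep(0.1, n))
  ent <- toy_profile(rep(0.01, n))
  expect_equal(find_lowss(react, ent)[, c("start", "end")],
               data.frame(start = 1L, end = as.integer(n)))
  react_hi <- toy_profile(rep(0.9, n))
  expect_equal(nrow(find_lowss(react_hi, ent)), 0)
  # designed low block flanked by high signal
  v <- rep(1.2, n); v[50:120] <- 0.05
  e <- rep(0.5, n); e[50:120] <- 0.01
  got <- find_lowss(toy_profile(v), toy_profile(e),
                    lowss_params(window = window_params(51)))
  med_v <- oracle_window_median(v, 51)
  med_e <- oracle_window_median(e, 51)
  low <- med_v < 0.4 & med_e < 0.15
  expect_equal(got$start, which(low & !c(FALSE, low[-n])))
  expect_equal(got$end, which(low & !c(low[-1], FALSE)))
  expect_equal(got$index, seq_len(nrow(got)))
})

test_that("raising lowSS thresholds never shrinks the low region union", {
  set.seed(31)
  v <- runif(150, 0, 1.2)
  e <- runif(150, 0, 0.4)
  cover <- function(r_max, s_max) {
    reg <- find_lowss(toy_profile(v), toy_profile(e),
                      lowss_params(r_max, s_max, window_params(21)))
    unlist(mapply(seq, reg$start, reg$end, SIMPLIFY = FALSE))
  }
  base <- cover(0.4, 0.15)
  expect_true(all(base %in% cover(0.6, 0.15)))
  expect_true(all(base %in% cover(0.4, 0.3)))
})

test_that("merge_gap joins nearby lowSS runs", {
  v <- rep(0.05, 60)
  v[28:29] <- 2                     # 2-nt high gap
  got0 <- find_lowss(toy_profile(v), toy_profile(rep(0.01, 60)),
                     lowss_params(window = window_params(1)))
  expect_equal(nrow(got0), 2)       # default: no merging
  got1 <- find_lowss(toy_profile(v), toy_profile(rep(0.01, 60)),
                     lowss_params(window = window_params(1),
                                  merge_gap = 3))
  expect_equal(nrow(got1), 1)
  expect_equal(c(got1$start, got1$end), c(1L, 60L))
})

test_that("deltaSHAPE flags designed differences and nothing else", {
  n <- 60
  a <- toy_profile(rep(1, n), stderr = rep(0.01, n))
  b <- toy_profile(rep(1, n), stderr = rep(0.01, n))
  expect_equal(sum(delta_shape(a, b)$site), 0)           # identical
  vb <- rep(1, n); vb[25:34] <- 3
  b2 <- toy_profile(vb, stderr = rep(0.01, n))
  ds <- delta_shape(b2, a)
  expect_true(all(which(ds$site) %in% 22:37))            # near the block
  expect_true(all(27:32 %in% which(ds$site)))            # block interior
  huge <- toy_profile(vb, stderr = rep(100, n))
  expect_equal(sum(delta_shape(huge, a)$site), 0)        # Z-factor <= 0
  expect_error(delta_shape(toy_profile(rep(1, n)), a), "standard errors")
})

test_that("windowed AUROC equals exhaustive pair counting", {
  seq <- sequence_record("w", "GGAA")
  ss <- secondary_structure(seq, cbind(1, 2))   # 1,2 paired; 3,4 unpaired
  prof <- nt_profile(seq, c(0.1, 0.2, 0.15, 0.9))
  track <- windowed_auroc(prof, ss, window_params(7))
  expect_equal(track$values, rep(0.75, 4))      # (3 wins + 0 ties)/4
  sep <- nt_profile(seq, c(0.1, 0.2, 5, 9))
  expect_equal(windowed_auroc(sep, ss, window_params(7))$values, rep(1, 4))
  tie <- nt_profile(seq, rep(2, 4))
  expect_equal(windowed_auroc(tie, ss, window_params(7))$values,
               rep(0.5, 4))
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(8:30, 1)
    sq <- sequence_record("r", strrep("A", n))
    pr <- nt_profile(sq, round(runif(n), 1))    # rounding forces ties
    m <- sample(1:(n %/% 2 - 1), 1)
    ssr <- secondary_structure(sq, cbind(seq_len(m), n + 1 - seq_len(m)))
    w <- sample(c(3, 5, 11), 1)
    got <- windowed_auroc(pr, ssr, window_params(w))
    paired <- partner_vector(ssr) > 0
    half <- (w - 1) %/% 2
    want <- vapply(seq_len(n), function(i) {
      idx <- max(1, i - half):min(n, i + half)
      oracle_auroc(pr$values[idx][!paired[idx]], pr$values[idx][paired[idx]])
    }, 0)
    expect_equal(got$values, want)
  }
})

test_that("profile regression recovers affine relations and symmetry", {
  a <- toy_profile(c(0.1, 0.5, 0.9, 1.4, 0.3, 0.8))
  same <- compare_profiles(a, a)
  expect_equal(same$r, 1)
  expect_equal(same$slope, 1)
  expect_equal(same$intercept, 0)
  b <- toy_profile(2 * a$values + 1)
  aff <- compare_profiles(a, b)
  expect_equal(aff$r, 1)
  expect_equal(aff$slope, 2)
  expect_equal(aff$intercept, 1)
  # closed-form check on a fixed 10-point table
  x <- c(0.12, 0.40, 0.85, 1.30, 0.22, 0.65, 0.95, 0.33, 1.10, 0.51)
  y <- c(0.20, 0.35, 0.90, 1.10, 0.30, 0.60, 1.05, 0.25, 1.20, 0.45)
  fit <- compare_profiles(toy_profile(x), toy_profile(y))
  r_direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(fit$r, r_direct)
  expect_equal(fit$n, 10)
  rev <- compare_profiles(toy_profile(y), toy_profile(x))
  expect_equal(rev$r, fit$r)                       # symmetry of r
  expect_true(fit$slope * rev$slope <= 1 + 1e-12)  # = 1 iff r^2 = 1
  short <- toy_profile(c(1, 2, NA, NA, NA, NA))
  expect_error(compare_profiles(short, toy_profile(c(1, 2, 3, NA, NA, NA))),
               ">= 3")
})
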