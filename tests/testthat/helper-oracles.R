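# Independent oracles: deliberately naive re-implementations used to verify
# the package's vectorized/bookkeeping code paths.

# centered windowed median by explicit per-window sort-and-middle
oracle_window_median <- function(values, w, edge = "truncate") {
  n <- length(values)
  half <- (w - 1) %/% 2
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (edge == "nodata" && (i - half < 1 || i + half > n)) next
    win <- values[max(1, i - half):min(n, i + half)]
    win <- sort(win[!is.na(win)])    # sort() drops nothing else
    m <- length(win)
    if (m == 0) next
    out[i] <- if (m %% 2 == 1) win[(m + 1) / 2] else
      (win[m / 2] + win[m / 2 + 1]) / 2
  }
  out
}

# AUROC by exhaustive pair counting: wins + half-credit ties
oracle_auroc <- function(pos, neg) {
  pos <- pos[!is.na(pos)]
  neg <- neg[!is.na(neg)]
  if (!length(pos) || !length(neg)) return(NA_real_)
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Shannon entropy by direct per-position summation over records
oracle_entropy <- function(records, n) {
  s <- numeric(n)
  for (pos in seq_len(n)) {
    for (k in seq_len(nrow(records))) {
      if (records$i[k] == pos || records$j[k] == pos) {
        p <- records$probability[k]
        s[pos] <- s[pos] - p * log10(p)
      }
    }
  }
  s
}

# pair classification by explicit set enumeration
oracle_classify <- function(pred, acc) {
  pk <- apply(pred, 1, paste, collapse = ":")
  ak <- apply(acc, 1, paste, collapse = ":")
  correct <- 0; incorrect <- 0
  for (k in pk) {
    if (k %in% ak) correct <- correct + 1 else incorrect <- incorrect + 1
  }
  missing <- 0
  for (k in ak) if (!k %in% pk) missing <- missing + 1
  list(correct = correct, incorrect = incorrect, missing = missing)
}

# consensus support by counting each union pair in every model
oracle_consensus <- function(key_lists) {
  union_keys <- unique(unlist(key_lists))
  support <- integer(length(union_keys))
  for (u in seq_along(union_keys)) {
    for (kl in key_lists) {
      if (union_keys[u] %in% kl) support[u] <- support[u] + 1
    }
  }
  names(support) <- union_keys
  support
}

# exhaustive end-gap-free affine alignment over all monotone partial maps
# (anchors = aligned columns, matched or mismatched); feasible for <= 7 nt.
# Internal gap of length L costs open + L*ext (positive penalties);
# terminal gaps are free. Returns the best score and one best map.
oracle_align <- function(a, b, match = 1, mismatch = -1, open = 5, ext = 1) {
  a <- strsplit(chartr("Tt", "Uu", toupper(a)), "")[[1]]
  b <- strsplit(chartr("Tt", "Uu", toupper(b)), "")[[1]]
  na <- length(a); nb <- length(b)
  score_map <- function(map) {
    idx <- which(!is.na(map))
    s <- sum(ifelse(a[idx] == b[map[idx]], match, mismatch))
    if (length(idx) > 1) {
      for (k in 2:length(idx)) {
        ga <- idx[k] - idx[k - 1] - 1          # unmapped a between anchors
        gb <- map[idx[k]] - map[idx[k - 1]] - 1
        if (ga > 0) s <- s - (open + ga * ext)
        if (gb > 0) s <- s - (open + gb * ext)
      }
    }
    s
  }
  best <- list(score = 0, map = rep(NA_integer_, na))
  subsets <- function(v) {
    if (!length(v)) return(list(integer(0)))
    rest <- subsets(v[-1])
    c(rest, lapply(rest, function(s) c(v[1], s)))
  }
  for (asub in subsets(seq_len(na))) {
    if (!length(asub)) next
    k <- length(asub)
    for (bsub in subsets(seq_len(nb))) {
      if (length(bsub) != k) next
      map <- rep(NA_integer_, na)
      map[sort(asub)] <- sort(bsub)
      s <- score_map(map)
      if (s > best$score) best <- list(score = s, map = map)
    }
  }
  best
}

# score the package's map under the oracle's scoring model
oracle_score_of_map <- function(a, b, map, match = 1, mismatch = -1,
                                open = 5, ext = 1) {
  ac <- strsplit(chartr("Tt", "Uu", toupper(a)), "")[[1]]
  bc <- strsplit(chartr("Tt", "Uu", toupper(b)), "")[[1]]
  idx <- which(!is.na(map))
  if (!length(idx)) return(0)
  s <- sum(ifelse(ac[idx] == bc[map[idx]], match, mismatch))
  if (length(idx) > 1) {
    for (k in 2:length(idx)) {
      ga <- idx[k] - idx[k - 1] - 1
      gb <- map[idx[k]] - map[idx[k - 1]] - 1
      if (ga > 0) s <- s - (open + ga * ext)
      if (gb > 0) s <- s - (open + gb * ext)
    }
  }
  s
}

random_pairset <- function(n, m) {
  pos <- sample(n, min(2 * m, n - n %% 2))
  cbind(pos[seq_len(length(pos) / 2)],
        pos[seq(length(pos) / 2 + 1, length(pos))])
}
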