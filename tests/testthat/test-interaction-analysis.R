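seq30 <- sequence_record("t", strrep("A", 30))

test_that("filtering composes criteria conjunctively on the mask", {
  iset <- interaction_set(seq30, data.frame(i = c(2, 5, 8),
                                            j = c(12, 15, 18),
                                            statistic = c(3, -2, 1)))
  pos <- filter_interactions(iset, statistic = "statistic",
                             sign = "positive")
  expect_equal(pos$mask, c(TRUE, FALSE, TRUE))
  expect_equal(attr(pos, "pass_count"), 2)
  top <- filter_interactions(iset, statistic = "statistic", top_k = 1)
  expect_equal(top$mask, c(TRUE, FALSE, FALSE))
  both <- filter_interactions(iset, statistic = "statistic",
                              sign = "positive", min = 2)
  expect_equal(both$mask, c(TRUE, FALSE, FALSE))
  expect_equal(nrow(pos$records), 3)    # records never deleted
  expect_error(filter_interactions(iset, statistic = "nope", min = 1),
               "available")
})

test_that("filtering is idempotent", {
  iset <- interaction_set(seq30, data.frame(i = 1:10, j = 11:20,
                                            statistic = rnorm(10)))
  once <- filter_interactions(iset, statistic = "statistic", min = 0,
                              region = c(1, 18))
  twice <- filter_interactions(once, statistic = "statistic", min = 0,
                               region = c(1, 18))
  expect_identical(once$mask, twice$mask)
})

test_that("distance criteria keep near records (Euclidean oracle)", {
  atoms <- data.frame(chain = "A", resno = 1:3, resname = "A",
                      atom = "O2'",
                      x = c(0, 8, 35), y = 0, z = 0)
  seq_map <- data.frame(chain = "A", resno = 1:3, pos = 1:3)
  tert <- tertiary_structure(atoms, seq_map,
                             sequence = sequence_record("t", "AAA"))
  iset <- interaction_set(tert$sequence,
                          data.frame(i = c(1, 1), j = c(2, 3),
                                     statistic = c(1, 1)))
  f <- filter_interactions(iset, max_distance = 20, tertiary = tert)
  expect_equal(f$mask, c(TRUE, FALSE))   # 8 vs 35 Angstroms
  expect_error(filter_interactions(iset, max_distance = 20), "tertiary")
})

test_that("contact distances use O2' with C1' fallback", {
  atoms <- data.frame(chain = "A", resno = 1:2,
                      resname = "G",
                      atom = c("O2'", "C1'"),
                      x = c(0, 3), y = c(0, 4), z = 0)
  tert <- tertiary_structure(atoms,
                             data.frame(chain = "A", resno = 1:2, pos = 1:2),
                             sequence = sequence_record("t", "GG"))
  d <- contact_distances(tert, 1, 2)
  expect_equal(as.numeric(d), 5)
  expect_true(attr(d, "fallback"))       # residue 2 had no O2'
  expect_equal(as.numeric(contact_distances(tert, 2, 2)), 0)
  # a position with neither atom yields NA
  expect_true(is.na(contact_distances(tert, 1, 5)[1]))
})

test_that("pair classification follows the correct/incorrect/missing rule", {
  seq <- sequence_record("s", strrep("A", 12))
  pred <- secondary_structure(seq, rbind(c(1, 12), c(2, 11), c(5, 8)))
  acc <- secondary_structure(seq, rbind(c(1, 12), c(2, 11), c(3, 10)))
  cls <- classify_pairs(pred, acc)
  expect_equal(cls$correct, 2)
  expect_equal(cls$incorrect, 1)
  expect_equal(cls$missing, 1)
  expect_equal(cls$sensitivity, 2 / 3)
  expect_equal(cls$ppv, 2 / 3)
  all_good <- classify_pairs(pred, pred)
  expect_equal(all_good$sensitivity, 1)
  expect_equal(all_good$ppv, 1)
  none <- classify_pairs(secondary_structure(seq, NULL), acc)
  expect_equal(none$missing, 3)
  expect_true(is.na(none$ppv))
})

test_that("classification set identities hold on random pair sets", {
  set.seed(17)
  for (rep in 1:50) {
    n <- 40
    pred <- random_pairset(n, sample(3:8, 1))
    acc <- random_pairset(n, sample(3:8, 1))
    seq <- sequence_record("r", strrep("A", n))
    cls <- classify_pairs(secondary_structure(seq, pred),
                          secondary_structure(seq, acc))
    o <- oracle_classify(normalize_pairs(pred, n), normalize_pairs(acc, n))
    expect_equal(cls$correct, o$correct)
    expect_equal(cls$incorrect, o$incorrect)
    expect_equal(cls$missing, o$missing)
    expect_equal(cls$correct + cls$incorrect, nrow(pred))
    expect_equal(cls$correct + cls$missing, nrow(acc))
    expect_equal(nrow(cls$labels),
                 length(union(pair_keys(normalize_pairs(pred, n)),
                              pair_keys(normalize_pairs(acc, n)))))
  }
})

test_that("slip tolerance accepts one-off pairs only when enabled", {
  seq <- sequence_record("s", strrep("A", 12))
  pred <- secondary_structure(seq, rbind(c(2, 10)))
  acc <- secondary_structure(seq, rbind(c(3, 10)))
  expect_equal(classify_pairs(pred, acc)$correct, 0)
  expect_equal(classify_pairs(pred, acc, slip = TRUE)$correct, 1)
})

test_that("consensus counting matches set enumeration", {
  seq <- sequence_record("s", strrep("A", 20))
  mk <- function(...) secondary_structure(seq, rbind(...))
  A <- c(2, 18); B <- c(3, 17); C <- c(5, 15)
  models <- list(mk(A, B), mk(A), mk(A), mk(A, C))
  cons <- consensus_pairs(models, min_support = 3)
  expect_equal(nrow(cons$table), 3)
  expect_equal(sort(cons$table$support), c(1, 1, 4))
  expect_equal(cons$fraction_shared_all, 1 / 3)
  expect_equal(nrow(cons$consensus), 1)
  expect_equal(unlist(cons$consensus[1, c("i", "j")], use.names = FALSE),
               A)
  same4 <- consensus_pairs(list(mk(A, B), mk(A, B), mk(A, B), mk(A, B)))
  expect_equal(same4$fraction_shared_all, 1)
  expect_error(consensus_pairs(list(mk(A))), ">= 2")
  set.seed(23)
  for (rep in 1:30) {
    k <- sample(2:5, 1)
    ms <- lapply(seq_len(k), function(x) {
      secondary_structure(seq, random_pairset(20, sample(2:5, 1)))
    })
    cons <- consensus_pairs(ms)
    o <- oracle_consensus(lapply(ms, function(m) pair_keys(m$pairs)))
    got <- cons$table$support
    names(got) <- paste(cons$table$i, cons$table$j, sep = ":")
    expect_equal(got[names(o)], o)
    # supports sum to the multiset size of all models' pairs
    expect_equal(sum(cons$table$support),
                 sum(vapply(ms, function(m) nrow(m$pairs), 0L)))
  }
})

test_that("distance histograms bin records and enumerate the background", {
  atoms <- data.frame(chain = "A", resno = 1:4, resname = "A",
                      atom = "O2'", x = c(0, 5, 15, 40), y = 0, z = 0)
  tert <- tertiary_structure(atoms,
                             data.frame(chain = "A", resno = 1:4, pos = 1:4),
                             sequence = sequence_record("t", "AAAA"))
  iset <- interaction_set(tert$sequence,
                          data.frame(i = c(1, 1), j = c(2, 3),
                                     statistic = 1))
  dh <- distance_histogram(iset, tert, breaks = seq(0, 50, 10))
  expect_equal(dh$counts[1:2], c(1, 1))        # 5 and 15 Angstroms
  expect_equal(sum(dh$background), 6)          # all C(4,2) pairs
  # gap excludes sequence-adjacent pairs from the background
  dh2 <- distance_histogram(iset, tert, breaks = seq(0, 50, 10), gap = 1)
  expect_equal(sum(dh2$background), 3)
  empty <- filter_interactions(iset, statistic = "statistic", min = 99)
  dh3 <- distance_histogram(empty, tert, breaks = seq(0, 50, 10))
  expect_equal(sum(dh3$counts), 0)
})

test_that("density heatmaps conserve mass and bin by integer division", {
  iset <- interaction_set(sequence_record("t", strrep("A", 60)),
                          data.frame(i = c(10, 12), j = c(50, 52),
                                     statistic = 1))
  hm <- density_heatmap(iset, bin_size = 5)
  expect_equal(hm$matrix[3, 11], 2)            # both records in one cell
  expect_equal(sum(hm$matrix), 2)
  expect_error(density_heatmap(iset, 0), "bin_size")
  set.seed(41)
  for (rep in 1:20) {
    n <- 80
    m <- sample(5:30, 1)
    rec <- data.frame(i = sample(40, m, TRUE))
    rec$j <- rec$i + sample(5:30, m, TRUE)
    iset <- interaction_set(sequence_record("r", strrep("A", n)), rec)
    f <- filter_interactions(iset, region = c(1, sample(50:80, 1)))
    hm <- density_heatmap(f, sample(3:11, 1))
    expect_equal(sum(hm$matrix), attr(f, "pass_count"))
    expect_true(all(hm$matrix[lower.tri(hm$matrix)] == 0))
  }
})
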