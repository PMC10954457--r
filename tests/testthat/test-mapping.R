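test_that("identical sequences short-circuit to the identity map", {
  a <- sequence_record("a", "ACGUACGU")
  b <- sequence_record("b", "acgtACGT")   # T/U and case equivalent
  m <- align_positions(a, b)
  expect_equal(m$a_to_b, 1:8)
})

test_that("alignment scores match the exhaustive oracle on toy sequences", {
  # the frozen oracle answer for the classic one-insertion case: under
  # match +1 / mismatch -1 / gap open -5 with free end gaps, trimming the
  # trailing base (score 3) beats both the mismatch (2) and the gap (-2)
  o <- oracle_align("ACGU", "ACGGU")
  expect_equal(o$score, 3)
  expect_equal(o$map, c(1L, 2L, 3L, NA))
  m <- align_positions(sequence_record("a", "ACGU"),
                       sequence_record("b", "ACGGU"))
  expect_equal(m$a_to_b, o$map)
  # property: the package's map always achieves the oracle's best score
  set.seed(5)
  for (rep in 1:25) {
    sa <- paste(sample(c("A", "C", "G", "U"), sample(3:6, 1), TRUE),
                collapse = "")
    sb <- paste(sample(c("A", "C", "G", "U"), sample(3:6, 1), TRUE),
                collapse = "")
    m <- align_positions(sequence_record("a", sa), sequence_record("b", sb))
    expect_equal(oracle_score_of_map(sa, sb, m$a_to_b),
                 oracle_align(sa, sb)$score,
                 label = paste(sa, sb))
  }
})

test_that("position maps are strictly monotone partial maps", {
  set.seed(9)
  for (rep in 1:20) {
    sa <- paste(sample(c("A", "C", "G", "U"), 30, TRUE), collapse = "")
    sb <- paste(sample(c("A", "C", "G", "U"), 34, TRUE), collapse = "")
    m <- align_positions(sequence_record("a", sa), sequence_record("b", sb))
    mapped <- m$a_to_b[!is.na(m$a_to_b)]
    if (length(mapped) > 1) expect_true(all(diff(mapped) > 0))
  }
})

test_that("map_data over the identity mapping is the identity", {
  seq <- sequence_record("x", "GGGGAAAACCCC")
  m <- align_positions(seq, seq)
  prof <- nt_profile(seq, c(1:11, NA), stderr = rep(0.1, 12))
  expect_equal(map_data(m, prof)$values, prof$values)
  expect_equal(map_data(m, prof)$nodata, prof$nodata)
  ss <- secondary_structure(seq, cbind(1:4, 12:9),
                            drawing = data.frame(x = 1:12, y = 12:1))
  mss <- map_data(m, ss)
  expect_equal(mss$pairs, ss$pairs)
  expect_equal(mss$drawing$x, as.numeric(ss$drawing$x))
  iset <- interaction_set(seq, data.frame(i = c(2, 5), j = c(11, 8),
                                          statistic = c(1, -1)))
  expect_equal(map_data(m, iset)$records, iset$records)
  ann <- annotation("loop", "spans", data.frame(start = 5, end = 8), seq)
  expect_equal(map_data(m, ann)$entries, ann$entries)
})

test_that("data carried through a gapped map is renumbered per map", {
  # 3-nt insertion after position 8, with a long matching suffix so the
  # gap (cost 8) beats the mismatch route under the default scores
  a <- sequence_record("a", "GGGGAAAACCCCAAAAGGGG")
  b <- sequence_record("b", "GGGGAAAAUUUCCCCAAAAGGGG")
  m <- align_positions(a, b)
  expect_equal(m$a_to_b, c(1:8, 12:23))
  ss <- secondary_structure(a, cbind(1:4, 12:9))
  mss <- map_data(m, ss)
  expect_equal(unname(mss$pairs), cbind(1:4, 15:12)[order(1:4), ])
  prof <- nt_profile(a, 1:20)
  expect_equal(map_data(m, prof)$values,
               c(1:8, NA, NA, NA, 9:20))
})

test_that("interactions with unmapped endpoints are masked, not dropped", {
  a <- sequence_record("a", "GGGGAAAACCCC")
  b <- sequence_record("b", "GGGGAAAA")       # 3' truncation
  m <- align_positions(a, b)
  iset <- interaction_set(a, data.frame(i = c(2, 3), j = c(7, 11),
                                        statistic = c(1, 2)))
  mi <- map_data(m, iset)
  expect_equal(nrow(mi$records), 2)
  expect_equal(mi$mask, c(TRUE, FALSE))
})

test_that("mapping composition agrees with the direct map on toy triples", {
  a <- sequence_record("a", "GGGGAAAACCCC")
  b <- sequence_record("b", "GGGGAAAAUUUCCCC")
  c3 <- sequence_record("c", "GGGGAAAAUUUCCCCGG")
  m_ab <- align_positions(a, b)
  m_bc <- align_positions(b, c3)
  m_ac <- align_positions(a, c3)
  comp <- compose_mappings(m_ab, m_bc)
  both <- !is.na(comp$a_to_b) & !is.na(m_ac$a_to_b)
  expect_true(any(both))
  expect_equal(comp$a_to_b[both], m_ac$a_to_b[both])
  inv <- invert_mapping(m_ab)
  idx <- which(!is.na(m_ab$a_to_b))
  expect_equal(inv$a_to_b[m_ab$a_to_b[idx]], idx)
})

test_that("mapping never invents profile values", {
  set.seed(21)
  for (rep in 1:10) {
    a <- sequence_record("a", paste(sample(c("A", "C", "G", "U"), 40, TRUE),
                                    collapse = ""))
    b <- sequence_record("b", paste(sample(c("A", "C", "G", "U"), 45, TRUE),
                                    collapse = ""))
    prof <- nt_profile(a, runif(40))
    mapped <- map_data(align_positions(a, b), prof)
    carried <- mapped$values[!is.na(mapped$values)]
    expect_true(all(carried %in% prof$values))
  }
})

test_that("map_data refuses data on the wrong sequence", {
  a <- sequence_record("a", "ACGUACGU")
  b <- sequence_record("b", "ACGUACGG")
  m <- align_positions(a, b)
  prof <- nt_profile(b, 1:8)
  expect_error(map_data(m, prof), "expected sequence")
})
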