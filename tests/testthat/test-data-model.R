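test_that("sequence records validate and compare T/U case-insensitively", {
  s <- sequence_record("x", "ACGU")
  expect_equal(s$length, 4L)
  expect_true(same_sequence(s, sequence_record("y", "acgt")))
  expect_false(same_sequence(s, sequence_record("y", "ACGG")))
  expect_error(sequence_record("x", ""), "empty")
  expect_error(sequence_record("x", "ACXU"), "invalid residue")
})

test_that("secondary structure enforces pair invariants", {
  seq <- sequence_record("x", "GGGGAAAACCCC")
  ss <- secondary_structure(seq, rbind(c(12, 1), c(2, 11)))
  expect_equal(unname(ss$pairs), rbind(c(1L, 12L), c(2L, 11L)))
  expect_error(secondary_structure(seq, rbind(c(1, 12), c(1, 11))),
               "more than one")
  expect_error(secondary_structure(seq, cbind(1, 13)), "outside")
  expect_error(secondary_structure(seq, cbind(3, 3)), "self-pair")
  expect_error(secondary_structure(seq, cbind(1, 2),
                                   drawing = data.frame(x = 1, y = 1)),
               "coordinate rows")
})

test_that("profiles and interaction sets enforce length invariants", {
  seq <- sequence_record("x", "ACGUACGU")
  expect_error(nt_profile(seq, 1:3), "3 values")
  p <- nt_profile(seq, c(1, NA, 3, 4, 5, 6, 7, 8))
  expect_true(p$nodata[2])
  expect_equal(sum(!p$nodata), 7)
  expect_error(interaction_set(seq, data.frame(i = 1, j = 9)), "outside")
  expect_error(interaction_set(seq, data.frame(i = 3, j = 3)), "i == j")
  is1 <- interaction_set(seq, data.frame(i = 5, j = 2, statistic = 1))
  expect_equal(is1$records$i, 2L)   # endpoints normalized to i < j
})

test_that("annotations validate categories and positions", {
  seq <- sequence_record("x", "ACGUACGUAC")
  a <- annotation("utr", "spans", data.frame(start = 8, end = 3), seq)
  expect_equal(a$entries$start, 3L)  # normalized
  expect_error(annotation("s", "sites", data.frame(start = 2, end = 4), seq),
               "start == end")
  expect_error(annotation("s", "spans", data.frame(start = 0, end = 4), seq),
               "outside")
  p <- annotation("fwd", "primers", data.frame(start = 9, end = 5), seq)
  expect_equal(p$entries$start, 9L)  # reverse primer keeps orientation
})

test_that("create_sample parses keyword inputs and errors on bad tags", {
  s <- create_sample("toy", list(
    profile = list(path = fx("toy_profile.txt"),
                   format = "shapemapper-profile"),
    ss = list(path = fx("toy.ct"), format = "ct")
  ))
  expect_s3_class(get_data(s, "profile"), "Profile")
  expect_s3_class(get_data(s, "ss"), "SecondaryStructure")
  expect_length(s$store, 2)
  expect_length(create_sample("empty", list())$store, 0)
  expect_error(create_sample("x", list(a = list(path = fx("toy.ct"),
                                                format = "nonsense"))),
               "valid tags")
  expect_error(get_data(s, "nope"), "no data under keyword")
})

test_that("sample store is referentially stable across fetches", {
  s <- create_sample("toy", list(
    rings = list(path = fx("toy_rings.txt"), format = "ring")))
  r1 <- get_data(s, "rings")
  r1f <- filter_interactions(r1, statistic = "statistic", sign = "positive")
  s <- set_data(s, "rings", r1f)
  expect_identical(get_data(s, "rings")$mask, r1f$mask)
  expect_identical(get_data(s, "rings"), get_data(s, "rings"))
})

test_that("format and plot registries have the fixed rosters", {
  reg <- list_input_formats()
  expect_equal(nrow(reg), 21L)
  expect_true(all(c("ct", "pdb", "cif", "fasta", "pairprob-dp") %in% reg$tag))
  expect_false(anyDuplicated(reg$tag) > 0)
  kinds <- list_plot_kinds()
  expect_equal(nrow(kinds), 18L)
  expect_true(all(c("arcs", "circle", "skyline") %in% kinds$kind))
})

test_that("plot_options reflects the per-kind data requirements", {
  sp <- create_sample("p", list(profile = list(path = fx("toy.map"),
                                               format = "map")))
  opts <- plot_options(sp)
  expect_true(all(c("profile-bars", "skyline") %in% opts))
  expect_false("molecule" %in% opts)
  expect_false("arcs" %in% opts)
  expect_length(plot_options(create_sample("e", list())), 0)
  sfull <- create_sample("f", list(
    profile = list(path = fx("toy.map"), format = "map"),
    ss = list(path = fx("toy.ct"), format = "ct"),
    dp = list(path = fx("toy.dp"), format = "pairprob-dp")))
  expect_true("arcs" %in% plot_options(sfull))
  # plot_options is always a subset of the full roster
  expect_true(all(plot_options(sfull) %in% list_plot_kinds()$kind))
})
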