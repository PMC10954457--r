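test_that("every roster format gets a fixture file its reader parses", {
  m <- fixture_manifest()
  expect_setequal(m$tag, list_input_formats()$tag)
  for (k in seq_len(nrow(m))) {
    obj <- read_data(m$path[k], m$tag[k])
    expect_false(is.null(obj), label = m$tag[k])
  }
})

test_that("the same seed gives byte-identical fixture files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_fixture(fixture_spec(seed = 5, n = 80), d1)
  m2 <- generate_fixture(fixture_spec(seed = 5, n = 80), d2)
  expect_equal(m1$md5, m2$md5)
  m3 <- generate_fixture(fixture_spec(seed = 6, n = 80), d1)
  expect_false(all(m3$md5 == m1$md5))
})

test_that("reader-generator closure reconstructs the truth exactly", {
  m <- fixture_manifest()
  truth <- attr(m, "truth")
  ss <- read_data(fx("toy.ct"), "ct")
  expect_equal(unname(ss$pairs),
               unname(normalize_pairs(truth$design$pairs, truth$spec$n)))
  expect_true(same_sequence(ss$sequence, truth$sequence))
  prof <- read_data(fx("toy_profile.txt"), "shapemapper-profile")
  expect_equal(prof$values, round(truth$values, 4), tolerance = 1e-9)
  dp <- read_data(fx("toy.dp"), "pairprob-dp")
  expect_equal(nrow(dp$records), nrow(truth$dp))
  expect_equal(dp$records$probability, truth$dp$probability,
               tolerance = 1e-4)
})

test_that("the fixture pseudoknot needs two bracket layers", {
  db <- readLines(fx("toy.db"))[3]
  expect_true(grepl("\\[", db))
  ss <- read_data(fx("toy.db"), "dotbracket")
  ct <- read_data(fx("toy.ct"), "ct")
  expect_equal(ss$pairs, ct$pairs)
})

test_that("fixture reactivities separate pairing status across seeds", {
  for (seed in c(2, 9, 33)) {
    d <- withr::local_tempdir()
    m <- generate_fixture(fixture_spec(seed = seed, n = 120), d)
    truth <- attr(m, "truth")
    prof <- read_data(file.path(d, "toy_profile.txt"),
                      "shapemapper-profile")
    ss <- read_data(file.path(d, "toy.ct"), "ct")
    track <- windowed_auroc(prof, ss, window_params(51))
    expect_gt(mean(track$values, na.rm = TRUE), 0.5)
  }
})

test_that("fixture entropy is low inside helices, higher at helix ends", {
  m <- fixture_manifest()
  truth <- attr(m, "truth")
  dp <- read_data(fx("toy.dp"), "pairprob-dp")
  ent <- shannon_entropy(dp)$values
  h1 <- truth$design$helices[[1]]
  interior <- (h1$start + 2):(h1$start + h1$stem - 2)
  ends <- c(h1$start, h1$start + 2 * h1$stem + h1$loop - 1)
  expect_lt(mean(ent[interior]), mean(ent[ends]))
  expect_lt(mean(ent[interior]), 0.05)
})

test_that("fixture preconditions are enforced", {
  expect_error(fixture_spec(n = 10), ">= 20")
})
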