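# shared toy objects and one on-disk fixture set per test run

fixture_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "rnaprobr-fixtures")
      if (!file.exists(file.path(dir, "toy.fa"))) {
        generate_fixture(fixture_spec(seed = 1L, n = 120L), dir)
      }
    }
    dir
  }
})

fixture_manifest <- local({
  m <- NULL
  function() {
    if (is.null(m)) {
      m <<- generate_fixture(fixture_spec(seed = 1L, n = 120L),
                             fixture_dir())
    }
    m
  }
})

fx <- function(name) file.path(fixture_dir(), name)

hairpin_ss <- function() {
  secondary_structure(sequence_record("hairpin", "GGGGAAAACCCC"),
                      cbind(1:4, 12:9))
}

toy_profile <- function(values, id = "toy", stderr = NULL) {
  seq <- sequence_record(id, paste(rep("A", length(values)), collapse = ""))
  nt_profile(seq, values, stderr = stderr)
}
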