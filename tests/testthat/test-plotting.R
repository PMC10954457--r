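sample_full <- local({
  s <- NULL
  function() {
    if (is.null(s)) {
      s <<- create_sample("cond1", list(
        profile = list(path = fx("toy.map"), format = "map"),
        ss = list(path = fx("toy.varna"), format = "varna"),
        rings = list(path = fx("toy_rings.txt"), format = "ring"),
        dp = list(path = fx("toy.dp"), format = "pairprob-dp"),
        pdb = list(path = fx("toy.pdb"), format = "pdb"),
        sites = list(path = fx("toy.bed"), format = "bed-narrowpeak")))
    }
    s
  }
})

sample_second <- local({
  s <- NULL
  function() {
    if (is.null(s)) {
      s <<- create_sample("cond2", list(
        profile = list(path = fx("toy.map"), format = "map"),
        ss = list(path = fx("toy.ct"), format = "ct")))
    }
    s
  }
})

test_that("arc geometry follows the semicircle formula", {
  expect_equal(arc_geometry(1, 12), data.frame(center_x = 6.5,
                                               radius = 5.5))
  expect_equal(arc_geometry(5, 6)$radius, 0.5)
  expect_error(arc_geometry(3, 3), "i < j")
})

test_that("color assignment is a pure function of value and breakpoints", {
  v <- c(0.1, 0.4, 0.5, 0.85, 2, NA)
  expect_equal(color_class(v, c(0.4, 0.85)), c(1L, 2L, 2L, 3L, 3L, NA))
  expect_identical(color_class(v, c(0.4, 0.85)),
                   color_class(v, c(0.4, 0.85)))
})

test_that("every plot kind renders from fixtures with a layout report", {
  outdir <- withr::local_tempdir()
  for (kind in list_plot_kinds()$kind) {
    out <- render(plot_request(kind, list(sample_full(), sample_second())),
                  path = file.path(outdir, paste0(kind, ".pdf")))
    expect_true(file.exists(out$file), label = kind)
    expect_gt(file.size(out$file), 0, label = kind)
    expect_true(length(out$layout) >= 1, label = kind)
  }
})

test_that("arc plot layout matches the analytic geometry exactly", {
  out <- render(plot_request("arcs", sample_full()))
  arcs <- out$layout$arcs
  expect_true(nrow(arcs) > 0)
  expect_equal(arcs$center_x, (arcs$i + arcs$j) / 2)
  expect_equal(arcs$radius, (arcs$j - arcs$i) / 2)
  ss <- get_data(sample_full(), "ss")
  above <- arcs[arcs$track == "above", ]
  expect_equal(nrow(above), nrow(ss$pairs))
})

test_that("circle plot places nucleotide k at angle 2*pi*k/n", {
  out <- render(plot_request("circle", sample_full()))
  pts <- out$layout$points
  n <- nrow(pts)
  expect_equal(pts$angle, 2 * pi * seq_len(n) / n)
  expect_equal(pts$x, cos(pts$angle))
  expect_equal(pts$y, sin(pts$angle))
})

test_that("skyline reports one step series per sample on a shared axis", {
  out <- render(plot_request("skyline",
                             list(sample_full(), sample_second())))
  expect_length(out$layout$series, 2)
  expect_equal(out$layout$series[[1]]$pos, out$layout$series[[2]]$pos)
})

test_that("structure diagrams draw glyphs at the drawing coordinates", {
  out <- render(plot_request("ss-diagram", sample_full()))
  ss <- get_data(sample_full(), "ss")
  expect_equal(out$layout$glyphs$x, ss$drawing$x)
  expect_equal(out$layout$glyphs$y, ss$drawing$y)
  expect_equal(nrow(out$layout$lines), nrow(ss$pairs))
  # breakpoint color classes are attached per nucleotide
  prof <- get_data(sample_full(), "profile")
  expect_equal(out$layout$glyphs$class,
               color_class(prof$values, prof$metric$breakpoints))
  # structures without drawing coordinates are rejected with guidance
  s2 <- sample_second()
  expect_error(render(plot_request("ss-diagram", s2)), "drawing")
})

test_that("molecule export cylinders equal the contact-distance atoms", {
  s <- sample_full()
  rings <- filter_interactions(get_data(s, "rings"),
                               statistic = "statistic", sign = "positive",
                               top_k = 2)
  s <- set_data(s, "rings", rings)
  out <- render(plot_request("molecule", s))
  cyl <- out$export$cylinders
  expect_equal(nrow(cyl), 2)
  tert <- get_data(s, "pdb")
  d_cyl <- sqrt((cyl$x1 - cyl$x2)^2 + (cyl$y1 - cyl$y2)^2 +
                  (cyl$z1 - cyl$z2)^2)
  d_ref <- as.numeric(contact_distances(tert, cyl$i, cyl$j))
  expect_equal(d_cyl, d_ref)
  expect_true(all(c("atoms", "colors", "cylinders") %in%
                    names(out$export)))
})

test_that("render validates requirements naming the missing role", {
  s2 <- sample_second()   # no tertiary structure
  expect_error(render(plot_request("molecule", s2)), "tertiary")
  expect_error(plot_request("not-a-kind", s2), "unknown plot kind")
})

test_that("layout reports are deterministic for identical requests", {
  a <- render(plot_request("arcs", sample_full()))
  b <- render(plot_request("arcs", sample_full()))
  expect_identical(a$layout, b$layout)
})

test_that("consensus summary slices reflect pair support", {
  out <- render(plot_request("consensus-summary",
                             list(sample_full(), sample_second())))
  slices <- out$layout$slices
  expect_equal(sum(slices$count), nrow(out$consensus$table))
  expect_equal(sum(slices$fraction), 1)
})
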