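# Rendering. Every plot kind builds a ggplot plus a machine-readable
# layout report enumerating each drawn element with its data-space
# coordinates; tests and the run log consume the report, not pixels.

#' Build a plot request
#'
#' @param kind Plot-kind tag (see [list_plot_kinds()]).
#' @param samples A `Sample` or list of samples (ordered).
#' @param keywords Optional named list mapping roles (`profile`,
#'   `structure`, `interactions`, `annotations`, `tertiary`, plus
#'   kind-specific roles like `structure2`, `profile2`, `accepted`) to
#'   store keywords; roles are located by data class when omitted.
#' @param options Kind-specific options (colors, `region`, `window`,
#'   `bin_size`, output `path`, `format`, ...).
#' @return A `PlotRequest`.
#' @export
plot_request <- function(kind, samples, keywords = list(),
                         options = list()) {
  if (inherits(samples, "Sample")) samples <- list(samples)
  if (!kind %in% list_plot_kinds()$kind) {
    stop("unknown plot kind '", kind, "'; see list_plot_kinds()")
  }
  structure(list(kind = kind, samples = samples, keywords = keywords,
                 options = options),
            class = "PlotRequest")
}

# locate a sample's object for a role, honoring explicit keywords
role_data <- function(request, role, sample_index = 1L, required = TRUE,
                      base_role = role) {
  s <- request$samples[[sample_index]]
  kw <- request$keywords[[role]]
  if (!is.null(kw)) return(get_data(s, kw))
  hit <- Filter(function(obj) identical(data_role_ext(obj), base_role),
                s$store)
  if (length(hit)) return(hit[[1]])
  if (required) {
    stop("plot '", request$kind, "' requires data for role '", base_role,
         "' but sample '", s$label, "' has none")
  }
  NULL
}

data_role_ext <- function(obj) {
  if (is.list(obj) && !inherits(obj, c("Profile", "SecondaryStructure",
                                       "InteractionSet", "TertiaryStructure",
                                       "Annotation", "SequenceRecord")) &&
      length(obj) && all(vapply(obj, inherits, TRUE, "Annotation"))) {
    return("annotations")
  }
  data_role(obj)
}

#' Render a plot request to a figure file plus a layout report
#'
#' @param request A [plot_request()].
#' @param path Output file; defaults to `request$options$path` (no file is
#'   written when both are NULL).
#' @param format `"svg"`, `"png"` or `"pdf"`; defaults to
#'   `request$options$format`, else the path extension, else `"svg"`.
#' @param width,height Figure size in inches.
#' @return Invisibly, a list with `kind`, `file`, `layout` (named list of
#'   data frames of drawn elements in data coordinates), `plot` (the
#'   ggplot) and kind-specific extras (e.g. `export` for molecules).
#' @export
render <- function(request, path = NULL, format = NULL, width = 8,
                   height = 5) {
  stopifnot(inherits(request, "PlotRequest"))
  path <- path %||% request$options$path
  format <- format %||% request$options$format %||%
    (if (!is.null(path)) tolower(tools::file_ext(path)) else "svg")
  builder <- get(paste0("build_", gsub("-", "_", request$kind)),
                 mode = "function")
  out <- builder(request)
  out$kind <- request$kind
  if (!is.null(path)) {
    if (!format %in% c("svg", "png", "pdf")) {
      stop("unsupported figure format '", format, "'")
    }
    dev <- switch(format, svg = grDevices::svg, pdf = grDevices::pdf,
                  png = function(f, width, height) {
                    grDevices::png(f, width = width, height = height,
                                   units = "in", res = 150)
                  })
    dev(path, width = width, height = height)
    print(out$plot)
    grDevices::dev.off()
    out$file <- path
  }
  invisible(out)
}

# shared axis: map a profile onto the first sample's sequence if needed
harmonized_profile <- function(profile, ref_seq) {
  if (same_sequence(profile$sequence, ref_seq)) return(profile)
  map_data(align_positions(profile$sequence, ref_seq), profile)
}

profile_bar_layout <- function(profile) {
  data.frame(pos = seq_len(profile$sequence$length),
             value = profile$values,
             class = color_class(profile$values,
                                 profile$metric$breakpoints))
}

REACT_COLORS <- c("black", "orange", "red")

build_profile_bars <- function(request) {
  p <- role_data(request, "profile")
  bars <- profile_bar_layout(p)
  g <- ggplot2::ggplot(bars[!is.na(bars$value), ],
                       ggplot2::aes(x = pos, y = value,
                                    fill = factor(class))) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_fill_manual(values = REACT_COLORS, guide = "none") +
    ggplot2::labs(x = "nucleotide position", y = p$metric$name) +
    ggplot2::theme_classic()
  list(plot = g, layout = list(bars = bars))
}

build_skyline <- function(request) {
  ref <- role_data(request, "profile")$sequence
  series <- lapply(seq_along(request$samples), function(k) {
    pr <- harmonized_profile(role_data(request, "profile", k), ref)
    data.frame(sample = request$samples[[k]]$label,
               pos = seq_len(ref$length), value = pr$values)
  })
  df <- do.call(rbind, series)
  g <- ggplot2::ggplot(df[!is.na(df$value), ],
                       ggplot2::aes(pos, value, color = sample)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "nucleotide position", y = "value") +
    ggplot2::theme_classic()
  list(plot = g, layout = list(series = series))
}

arcs_from_pairs <- function(pairs, track, group, color_class = NA) {
  if (!NROW(pairs)) {
    return(data.frame(i = integer(0), j = integer(0), center_x = numeric(0),
                      radius = numeric(0), track = character(0),
                      group = character(0), class = numeric(0)))
  }
  geo <- arc_geometry(pairs[, 1], pairs[, 2])
  data.frame(i = pairs[, 1], j = pairs[, 2], center_x = geo$center_x,
             radius = geo$radius, track = track, group = group,
             class = color_class)
}

arc_panel <- function(arcs, n) {
  segs <- do.call(rbind, lapply(seq_len(nrow(arcs)), function(k) {
    pts <- arc_points(arcs$center_x[k], arcs$radius[k],
                      sign = if (arcs$track[k] == "above") 1 else -1)
    pts$id <- k
    pts$group <- arcs$group[k]
    pts
  }))
  g <- ggplot2::ggplot() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(x = "nucleotide position", y = NULL) +
    ggplot2::xlim(0, n + 1) +
    ggplot2::theme_classic() +
    ggplot2::theme(axis.line.y = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank(),
                   axis.ticks.y = ggplot2::element_blank())
  if (!is.null(segs)) {
    g <- g + ggplot2::geom_path(
      data = segs, ggplot2::aes(x, y, group = id, color = group),
      linewidth = 0.4)
  }
  g
}

build_arcs <- function(request) {
  ss <- role_data(request, "structure", required = FALSE)
  iset <- role_data(request, "interactions", required = FALSE)
  if (is.null(ss) && is.null(iset)) {
    stop("plot 'arcs' requires data for role 'structure' or 'interactions'")
  }
  n <- (ss %||% iset)$sequence$length
  arcs <- rbind(
    if (!is.null(ss)) arcs_from_pairs(ss$pairs, "above", "structure"),
    if (!is.null(iset)) {
      rec <- iset$records[iset$mask, , drop = FALSE]
      cls <- if ("probability" %in% names(rec)) {
        pairprob_class(rec$probability)
      } else NA
      arcs_from_pairs(cbind(rec$i, rec$j), "below", "interactions", cls)
    }
  )
  list(plot = arc_panel(arcs, n), layout = list(arcs = arcs))
}

build_arcs_compare <- function(request) {
  ss1 <- role_data(request, "structure")
  ss2 <- if (length(request$samples) > 1L) {
    role_data(request, "structure", 2L)
  } else {
    role_data(request, "structure2", base_role = "structure2")
  }
  cls <- classify_pairs(ss1, ss2)
  lab <- cls$labels
  arcs <- arcs_from_pairs(cbind(lab$i, lab$j),
                          ifelse(lab$label == "missing", "below", "above"),
                          lab$label)
  list(plot = arc_panel(arcs, ss1$sequence$length),
       layout = list(arcs = arcs), classification = cls)
}

build_circle <- function(request) {
  ss <- role_data(request, "structure", required = FALSE)
  iset <- role_data(request, "interactions", required = FALSE)
  if (is.null(ss) && is.null(iset)) {
    stop("plot 'circle' requires data for role 'structure' or 'interactions'")
  }
  n <- (ss %||% iset)$sequence$length
  pts <- circle_positions(n)
  chord_rows <- function(pairs, group) {
    if (!NROW(pairs)) return(NULL)
    data.frame(i = pairs[, 1], j = pairs[, 2],
               x1 = pts$x[pairs[, 1]], y1 = pts$y[pairs[, 1]],
               x2 = pts$x[pairs[, 2]], y2 = pts$y[pairs[, 2]],
               group = group)
  }
  chords <- rbind(
    if (!is.null(ss)) chord_rows(ss$pairs, "structure"),
    if (!is.null(iset)) {
      rec <- iset$records[iset$mask, , drop = FALSE]
      chord_rows(cbind(rec$i, rec$j), "interactions")
    }
  )
  g <- ggplot2::ggplot(pts, ggplot2::aes(x, y)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (!is.null(chords)) {
    g <- g + ggplot2::geom_segment(
      data = chords, ggplot2::aes(x = x1, y = y1, xend = x2, yend = y2,
                                  color = group), linewidth = 0.3)
  }
  list(plot = g, layout = list(points = pts,
                               chords = chords %||%
                                 data.frame(i = integer(0))))
}

build_ss_diagram <- function(request) {
  ss <- role_data(request, "structure")
  if (is.null(ss$drawing)) {
    stop("structure has no drawing coordinates; supply a drawing-file ",
         "input (varna/xrna/forna/r2dt/nsd)")
  }
  profile <- role_data(request, "profile", required = FALSE)
  iset <- role_data(request, "interactions", required = FALSE)
  glyphs <- data.frame(pos = seq_len(ss$sequence$length),
                       base = seq_chars(ss$sequence),
                       x = ss$drawing$x, y = ss$drawing$y,
                       class = if (!is.null(profile)) {
                         color_class(profile$values,
                                     profile$metric$breakpoints)
                       } else NA)
  lines <- if (nrow(ss$pairs)) {
    data.frame(i = ss$pairs[, 1], j = ss$pairs[, 2],
               x1 = glyphs$x[ss$pairs[, 1]], y1 = glyphs$y[ss$pairs[, 1]],
               x2 = glyphs$x[ss$pairs[, 2]], y2 = glyphs$y[ss$pairs[, 2]])
  } else data.frame()
  chords <- if (!is.null(iset)) {
    rec <- iset$records[iset$mask, , drop = FALSE]
    data.frame(i = rec$i, j = rec$j,
               x1 = glyphs$x[rec$i], y1 = glyphs$y[rec$i],
               x2 = glyphs$x[rec$j], y2 = glyphs$y[rec$j])
  } else data.frame()
  g <- ggplot2::ggplot(glyphs, ggplot2::aes(x, y)) +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (nrow(lines)) {
    g <- g + ggplot2::geom_segment(
      data = lines, ggplot2::aes(x = x1, y = y1, xend = x2, yend = y2),
      color = "grey60", linewidth = 0.3)
  }
  if (nrow(chords)) {
    g <- g + ggplot2::geom_segment(
      data = chords, ggplot2::aes(x = x1, y = y1, xend = x2, yend = y2),
      color = "red", linewidth = 0.4)
  }
  g <- g + ggplot2::geom_text(ggplot2::aes(label = base), size = 2)
  list(plot = g,
       layout = list(glyphs = glyphs, lines = lines, chords = chords))
}

build_molecule <- function(request) {
  tert <- role_data(request, "tertiary")
  iset <- role_data(request, "interactions", required = FALSE)
  profile <- role_data(request, "profile", required = FALSE)
  dparams <- request$options$dparams %||% distance_params()
  colors <- if (!is.null(profile)) {
    data.frame(pos = seq_len(profile$sequence$length),
               class = color_class(profile$values,
                                   profile$metric$breakpoints))
  } else {
    data.frame(pos = sort(unique(tert$seq_map$pos)), class = NA)
  }
  cylinders <- data.frame()
  skipped <- 0L
  if (!is.null(iset)) {
    rec <- iset$records[iset$mask, , drop = FALSE]
    if (nrow(rec)) {
      a <- atom_coords(tert, rec$i, dparams)
      b <- atom_coords(tert, rec$j, dparams)
      ok <- !is.na(a[, 1]) & !is.na(b[, 1])
      skipped <- sum(!ok)
      cylinders <- data.frame(i = rec$i[ok], j = rec$j[ok],
                              x1 = a[ok, 1], y1 = a[ok, 2], z1 = a[ok, 3],
                              x2 = b[ok, 1], y2 = b[ok, 2], z2 = b[ok, 3])
    }
  }
  atoms <- tert$atoms[!is.na(tert$atoms$pos), , drop = FALSE]
  # static projection: orthographic onto the x-y plane
  g <- ggplot2::ggplot(atoms, ggplot2::aes(x, y)) +
    ggplot2::geom_path(color = "grey70", linewidth = 0.3) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::coord_fixed() + ggplot2::theme_void()
  if (nrow(cylinders)) {
    g <- g + ggplot2::geom_segment(
      data = cylinders, ggplot2::aes(x = x1, y = y1, xend = x2, yend = y2),
      color = "red", linewidth = 0.6)
  }
  list(plot = g,
       layout = list(cylinders = cylinders, colors = colors),
       export = list(atoms = atoms, colors = colors,
                     cylinders = cylinders),
       report = list(skipped_cylinders = skipped))
}

build_heatmap_density <- function(request) {
  iset <- role_data(request, "interactions")
  hm <- density_heatmap(iset, request$options$bin_size %||% 10L)
  df <- expand.grid(bi = seq_len(hm$n_bins), bj = seq_len(hm$n_bins))
  df$count <- as.vector(hm$matrix)
  g <- ggplot2::ggplot(df[df$count > 0, ],
                       ggplot2::aes(bi, bj, fill = count)) +
    ggplot2::geom_tile() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "i bin", y = "j bin") +
    ggplot2::theme_classic()
  list(plot = g, layout = list(matrix = hm$matrix, bin_size = hm$bin_size))
}

build_contour <- function(request) {
  iset <- role_data(request, "interactions")
  rec <- iset$records[iset$mask, , drop = FALSE]
  if (nrow(rec) < 2L) stop("contour plot needs >= 2 masked-in interactions")
  n <- iset$sequence$length
  kde <- MASS::kde2d(rec$i, rec$j, n = 50, lims = c(1, n, 1, n))
  df <- expand.grid(x = kde$x, y = kde$y)
  df$z <- as.vector(kde$z)
  g <- ggplot2::ggplot(df, ggplot2::aes(x, y, z = z)) +
    ggplot2::geom_contour() +
    ggplot2::labs(x = "i", y = "j") +
    ggplot2::theme_classic()
  list(plot = g, layout = list(grid = kde))
}

build_distance_histogram <- function(request) {
  iset <- role_data(request, "interactions")
  tert <- role_data(request, "tertiary")
  dh <- distance_histogram(iset, tert,
                           breaks = request$options$breaks %||%
                             seq(0, 200, 10),
                           gap = request$options$gap %||% 0L)
  mids <- (utils::head(dh$breaks, -1) + utils::tail(dh$breaks, -1)) / 2
  df <- rbind(data.frame(mid = mids, count = dh$counts, what = "records"),
              data.frame(mid = mids,
                         count = dh$background * sum(dh$counts) /
                           base::max(1, sum(dh$background)),
                         what = "background"))
  g <- ggplot2::ggplot(df, ggplot2::aes(mid, count, fill = what)) +
    ggplot2::geom_col(position = "identity", alpha = 0.5) +
    ggplot2::labs(x = "3D distance (Å)", y = "count") +
    ggplot2::theme_classic()
  list(plot = g, layout = list(counts = dh$counts,
                               background = dh$background,
                               breaks = dh$breaks))
}

build_regression_kde <- function(request) {
  pa <- role_data(request, "profile", 1L)
  pb <- if (length(request$samples) > 1L) {
    harmonized_profile(role_data(request, "profile", 2L), pa$sequence)
  } else {
    role_data(request, "profile2", base_role = "profile2")
  }
  fit <- compare_profiles(pa, pb)
  g <- ggplot2::ggplot(fit$pairs, ggplot2::aes(a, b)) +
    ggplot2::stat_density_2d(ggplot2::aes(fill = ggplot2::after_stat(level)),
                             geom = "polygon") +
    ggplot2::geom_abline(slope = fit$slope, intercept = fit$intercept,
                         linetype = 2) +
    ggplot2::labs(x = "profile a", y = "profile b",
                  subtitle = sprintf("r = %.3f, n = %d", fit$r, fit$n)) +
    ggplot2::theme_classic()
  list(plot = g, layout = list(fit = fit[c("slope", "intercept", "r", "n")],
                               points = fit$pairs))
}

build_windowed_auroc <- function(request) {
  profile <- role_data(request, "profile")
  ss <- role_data(request, "structure")
  w <- request$options$window %||% window_params(51L)
  track <- windowed_auroc(profile, ss, w)
  df <- data.frame(pos = seq_len(track$sequence$length),
                   auroc = track$values)
  g <- ggplot2::ggplot(df[!is.na(df$auroc), ], ggplot2::aes(pos, auroc)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_classic()
  list(plot = g, layout = list(track = df))
}

build_deltashape_panel <- function(request) {
  pa <- role_data(request, "profile", 1L)
  pb <- if (length(request$samples) > 1L) {
    harmonized_profile(role_data(request, "profile", 2L), pa$sequence)
  } else {
    role_data(request, "profile2", base_role = "profile2")
  }
  ds <- delta_shape(pa, pb)
  df <- data.frame(pos = ds$positions, d = ds$diff, site = ds$site)
  g <- ggplot2::ggplot(df[!is.na(df$d), ], ggplot2::aes(pos, d)) +
    ggplot2::geom_col(ggplot2::aes(fill = site), width = 1) +
    ggplot2::scale_fill_manual(values = c("grey60", "purple"),
                               guide = "none") +
    ggplot2::labs(x = "nucleotide position", y = "smoothed difference") +
    ggplot2::theme_classic()
  list(plot = g, layout = list(diff = df), result = ds)
}

build_lowss_panel <- function(request) {
  profile <- role_data(request, "profile")
  iset <- role_data(request, "interactions")
  if (!"probability" %in% names(iset$records)) {
    # prefer a pairing-probability set when the sample holds several
    # interaction sets (e.g. RINGs alongside a dotplot)
    cand <- Filter(function(o) inherits(o, "InteractionSet") &&
                     "probability" %in% names(o$records),
                   request$samples[[1]]$store)
    if (length(cand)) iset <- cand[[1]]
  }
  ss <- role_data(request, "structure", required = FALSE)
  params <- request$options$lowss %||% lowss_params()
  entropy <- shannon_entropy(iset)
  regions <- find_lowss(profile, entropy, params)
  med_r <- attr(regions, "med_reactivity")
  med_e <- attr(regions, "med_entropy")
  n <- profile$sequence$length
  arcs <- rbind(
    if (!is.null(ss)) arcs_from_pairs(ss$pairs, "above", "mfe"),
    {
      rec <- iset$records[iset$mask, , drop = FALSE]
      cls <- pairprob_class(rec$probability)
      keep <- cls > 0
      arcs_from_pairs(cbind(rec$i, rec$j)[keep, , drop = FALSE], "below",
                      "pairprob", cls[keep])
    }
  )
  tracks <- data.frame(pos = seq_len(n), med_reactivity = med_r,
                       med_entropy = med_e)
  df <- rbind(data.frame(pos = tracks$pos, value = med_r,
                         what = "median reactivity"),
              data.frame(pos = tracks$pos, value = med_e,
                         what = "median entropy"))
  shade <- if (nrow(regions)) {
    data.frame(xmin = regions$start, xmax = regions$end)
  } else data.frame(xmin = numeric(0), xmax = numeric(0))
  g <- ggplot2::ggplot(df[!is.na(df$value), ]) +
    ggplot2::geom_line(ggplot2::aes(pos, value)) +
    ggplot2::facet_grid(what ~ ., scales = "free_y") +
    ggplot2::theme_classic()
  if (nrow(shade)) {
    g <- g + ggplot2::geom_rect(
      data = shade, ggplot2::aes(xmin = xmin, xmax = xmax, ymin = -Inf,
                                 ymax = Inf),
      fill = "grey50", alpha = 0.3)
  }
  list(plot = g,
       layout = list(regions = regions, tracks = tracks, arcs = arcs))
}

build_alignment_overview <- function(request) {
  if (length(request$samples) < 2L) {
    stop("alignment-overview needs two samples")
  }
  seq_of <- function(k) {
    for (obj in request$samples[[k]]$store) {
      s <- obj$sequence %||% (if (inherits(obj, "SequenceRecord")) obj)
      if (!is.null(s)) return(s)
      if (is.list(obj) && length(obj) && inherits(obj[[1]], "Annotation")) {
        return(obj[[1]]$sequence)
      }
    }
    stop("sample '", request$samples[[k]]$label, "' holds no sequence")
  }
  m <- align_positions(seq_of(1L), seq_of(2L))
  idx <- which(!is.na(m$a_to_b))
  segments <- if (length(idx)) {
    brk <- c(0L, which(diff(m$a_to_b[idx]) != 1L |
                         diff(idx) != 1L), length(idx))
    do.call(rbind, lapply(seq_len(length(brk) - 1L), function(k) {
      block <- idx[(brk[k] + 1L):brk[k + 1L]]
      data.frame(a_start = block[1], a_end = block[length(block)],
                 b_start = m$a_to_b[block[1]],
                 b_end = m$a_to_b[block[length(block)]])
    }))
  } else data.frame(a_start = integer(0))
  g <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = segments,
      ggplot2::aes(x = a_start, xend = a_end, y = b_start, yend = b_end)) +
    ggplot2::labs(x = m$seq_a$id, y = m$seq_b$id) +
    ggplot2::theme_classic()
  list(plot = g, layout = list(segments = segments), mapping = m)
}

build_annotation_track <- function(request) {
  anns <- role_data(request, "annotations")
  if (inherits(anns, "Annotation")) anns <- list(anns)
  spans <- do.call(rbind, lapply(seq_along(anns), function(k) {
    a <- anns[[k]]
    if (!nrow(a$entries)) return(NULL)
    data.frame(name = a$name, category = a$category,
               start = pmin(a$entries$start, a$entries$end),
               end = pmax(a$entries$start, a$entries$end), y = k)
  }))
  if (is.null(spans)) spans <- data.frame(name = character(0))
  g <- ggplot2::ggplot(spans) +
    ggplot2::geom_segment(ggplot2::aes(x = start, xend = end, y = y,
                                       yend = y, color = name),
                          linewidth = 3) +
    ggplot2::labs(x = "nucleotide position", y = NULL) +
    ggplot2::theme_classic()
  list(plot = g, layout = list(spans = spans))
}

build_consensus_summary <- function(request) {
  models <- request$options$models %||% lapply(
    seq_along(request$samples),
    function(k) role_data(request, "structure", k))
  cons <- consensus_pairs(models,
                          request$options$min_support %||% 3L)
  slices <- as.data.frame(table(cons$table$support))
  names(slices) <- c("support", "count")
  slices$fraction <- slices$count / sum(slices$count)
  g <- ggplot2::ggplot(slices, ggplot2::aes(x = "", y = count,
                                            fill = support)) +
    ggplot2::geom_col() +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::theme_void()
  list(plot = g, layout = list(slices = slices), consensus = cons)
}

build_profile_difference <- function(request) {
  pa <- role_data(request, "profile", 1L)
  pb <- if (length(request$samples) > 1L) {
    harmonized_profile(role_data(request, "profile", 2L), pa$sequence)
  } else {
    role_data(request, "profile2", base_role = "profile2")
  }
  d <- pa$values - pb$values
  d[pa$nodata | pb$nodata] <- NA
  bars <- data.frame(pos = seq_len(pa$sequence$length), diff = d)
  g <- ggplot2::ggplot(bars[!is.na(bars$diff), ],
                       ggplot2::aes(pos, diff)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "nucleotide position", y = "difference") +
    ggplot2::theme_classic()
  list(plot = g, layout = list(bars = bars))
}

#' Render a secondary-structure diagram (convenience wrapper)
#'
#' @param sample A `Sample` holding a structure with drawing coordinates
#'   (plus optional profile/interaction overlays).
#' @param ... Options passed into the [plot_request()].
#' @inheritParams render
#' @return See [render()].
#' @export
render_ss_diagram <- function(sample, path = NULL, ...) {
  render(plot_request("ss-diagram", sample, options = list(...)),
         path = path)
}

#' Render a molecular projection with interaction cylinders
#'
#' @inheritParams render_ss_diagram
#' @return See [render()]; additionally `export` holds per-atom
#'   coordinates, per-nucleotide colors and cylinder endpoint coordinates
#'   for external 3D viewers.
#' @export
render_molecule <- function(sample, path = NULL, ...) {
  render(plot_request("molecule", sample, options = list(...)),
         path = path)
}
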