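# Analytic geometry shared by the connectivity-diagram renderers. Tests
# assert on these values (and on the layout reports built from them), not
# on pixels.

#' Arc geometry for a pair (i, j)
#'
#' An interaction between positions i < j is drawn as a semicircle centered
#' at (i+j)/2 with radius (j-i)/2, above the axis for structures and in a
#' below-axis slot for a second track in compare mode.
#'
#' @param i,j Paired positions, `i < j` (vectorized).
#' @return Data frame with columns `center_x` and `radius`.
#' @export
arc_geometry <- function(i, j) {
  if (any(i >= j)) stop("arc requires i < j; got i = ", i[i >= j][1],
                        ", j = ", j[i >= j][1])
  data.frame(center_x = (i + j) / 2, radius = (j - i) / 2)
}

# polyline approximation of one semicircle (sign = +1 above, -1 below)
arc_points <- function(center_x, radius, sign = 1, n = 60) {
  t <- seq(0, pi, length.out = n)
  data.frame(x = center_x + radius * cos(t), y = sign * radius * sin(t))
}

#' Circle-plot placement of nucleotides
#'
#' Nucleotide k of n sits at angle 2*pi*k/n on the unit circle.
#'
#' @param n Sequence length.
#' @return Data frame `pos`, `angle`, `x`, `y`.
#' @export
circle_positions <- function(n) {
  k <- seq_len(n)
  angle <- 2 * pi * k / n
  data.frame(pos = k, angle = angle, x = cos(angle), y = sin(angle))
}

#' Classify values against color-scale breakpoints
#'
#' Pure function of (value, breakpoints): class 1 for v < b1, 2 for
#' b1 <= v < b2, ..., NA for missing values. With the default reactivity
#' breakpoints (0.4, 0.85) the classes are low/mid/high.
#'
#' @param values Numeric vector.
#' @param breakpoints Increasing numeric thresholds.
#' @return Integer class per value.
#' @export
color_class <- function(values, breakpoints = c(0.4, 0.85)) {
  out <- rep(NA_integer_, length(values))
  ok <- !is.na(values)
  out[ok] <- findInterval(values[ok], breakpoints) + 1L
  out
}

# discrete pairing-probability bins used for probability arcs
PAIRPROB_BINS <- c(0.1, 0.3, 0.6, 0.8)

pairprob_class <- function(p) {
  findInterval(p, PAIRPROB_BINS)   # 0: <0.1 (not drawn) .. 4: >=0.8
}
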