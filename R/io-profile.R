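# Per-nucleotide profile readers. The sentinel -999 and non-numeric entries
# become no-data positions. Sequence is reconstructed from the file when it
# carries one (shapemapper-profile, map, rnaframework-xml,
# dance-reactivities), else the caller must supply it.

#' Read a per-nucleotide reactivity/measurement profile
#'
#' @param path Input file.
#' @param tag One of `shapemapper-profile`, `map`, `shape`,
#'   `rnaframework-xml`, `dance-reactivities`, `wig`.
#' @param sequence Optional [sequence_record()]; required for sequence-less
#'   dialects (`shape`, `wig`) and checked against the file's sequence
#'   length otherwise.
#' @param component 1-based ensemble state for `dance-reactivities`.
#' @param metric Metric metadata applied to the result.
#' @return A [nt_profile()].
#' @export
read_profile <- function(path,
                         tag = c("shapemapper-profile", "map", "shape",
                                 "rnaframework-xml", "dance-reactivities",
                                 "wig"),
                         sequence = NULL, component = 1L,
                         metric = list(name = "reactivity",
                                       breakpoints = c(0.4, 0.85))) {
  tag <- match.arg(tag)
  out <- switch(tag,
                "shapemapper-profile" = read_shapemapper_profile(path),
                "map" = read_map_profile(path),
                "shape" = read_shape_profile(path, sequence),
                "rnaframework-xml" = read_rnaframework_xml(path),
                "dance-reactivities" = read_dance_reactivities(path, component),
                "wig" = read_wig_profile(path, sequence))
  if (!is.null(sequence)) {
    if (out$sequence$length != sequence$length) {
      stop("profile '", path, "' has ", out$sequence$length,
           " positions but the supplied sequence has ", sequence$length)
    }
    out$sequence <- sequence
  }
  out$metric <- metric
  out
}

sentinel_to_na <- function(x) {
  x <- suppressWarnings(as.numeric(x))
  x[!is.na(x) & x <= -990] <- NA_real_
  x
}

read_shapemapper_profile <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("Nucleotide", "Sequence", "Norm_profile", "Norm_stderr")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("profile table '", path, "' lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[order(df$Nucleotide), ]
  seq <- sequence_record(basename(path), paste(df$Sequence, collapse = ""))
  values <- sentinel_to_na(df$Norm_profile)
  p <- nt_profile(seq, values,
                  raw = if ("HQ_profile" %in% names(df)) {
                    sentinel_to_na(df$HQ_profile)
                  },
                  stderr = sentinel_to_na(df$Norm_stderr))
  extra <- setdiff(names(df), c(need, "HQ_profile"))
  if (length(extra)) p$aux <- df[extra]
  p
}

read_map_profile <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("pos", "value", "stderr", "base"))
  df <- df[order(df$pos), ]
  seq <- sequence_record(basename(path), paste(df$base, collapse = ""))
  nt_profile(seq, sentinel_to_na(df$value), stderr = sentinel_to_na(df$stderr))
}

read_shape_profile <- function(path, sequence) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  pos <- as.integer(df[[1]])
  n <- if (!is.null(sequence)) sequence$length else max(pos)
  if (is.null(sequence)) {
    sequence <- sequence_record(basename(path),
                                paste(rep("N", n), collapse = ""))
  }
  values <- rep(NA_real_, n)
  values[pos] <- sentinel_to_na(df[[2]])
  nt_profile(sequence, values)
}

read_rnaframework_xml <- function(path) {
  doc <- xml2::read_xml(path)
  tx <- xml2::xml_find_first(doc, ".//transcript")
  if (inherits(tx, "xml_missing")) {
    stop("reactivity XML '", path, "' has no <transcript> element")
  }
  seq_txt <- gsub("[^A-Za-z]", "",
                  xml2::xml_text(xml2::xml_find_first(tx, ".//sequence")))
  seq <- sequence_record(xml2::xml_attr(tx, "id") %||% basename(path), seq_txt)
  react_txt <- xml2::xml_text(xml2::xml_find_first(tx, ".//reactivity"))
  values <- suppressWarnings(
    as.numeric(trimws(strsplit(react_txt, ",")[[1]]))
  )
  if (length(values) != seq$length) {
    stop("reactivity XML '", path, "' has ", length(values),
         " reactivities for a ", seq$length, " nt sequence")
  }
  err_node <- xml2::xml_find_first(tx, ".//stderr")
  stderr <- if (!inherits(err_node, "xml_missing")) {
    suppressWarnings(as.numeric(trimws(strsplit(xml2::xml_text(err_node),
                                                ",")[[1]])))
  }
  nt_profile(seq, values, stderr = stderr)
}

read_dance_reactivities <- function(path, component = 1L) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  cols <- grep("^Norm_profile", names(df), value = TRUE)
  if (!length(cols)) {
    stop("ensemble reactivity table '", path,
         "' has no Norm_profile_<state> columns")
  }
  if (component < 1L || component > length(cols)) {
    stop("component ", component, " requested but '", path, "' has ",
         length(cols), " ensemble states")
  }
  seq <- sequence_record(paste0(basename(path), "_state", component),
                         paste(df$Sequence, collapse = ""))
  nt_profile(seq, sentinel_to_na(df[[cols[component]]]))
}

# wiggle tracks are genomic; here the chrom axis is the transcript itself
# (or is mapped onto it afterwards with extract_transcript()'s map)
read_wig_profile <- function(path, sequence) {
  gr <- rtracklayer::import(path, format = "wig")
  if (is.null(sequence)) {
    sequence <- sequence_record(
      as.character(GenomicRanges::seqnames(gr)[1]),
      paste(rep("N", max(GenomicRanges::end(gr))), collapse = "")
    )
  }
  values <- rep(NA_real_, sequence$length)
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  score <- gr$score
  for (k in seq_along(starts)) {
    span <- starts[k]:ends[k]
    span <- span[span >= 1 & span <= sequence$length]
    values[span] <- score[k]
  }
  nt_profile(sequence, values)
}
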