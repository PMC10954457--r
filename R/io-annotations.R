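# Annotation readers (BED/narrowPeak, GFF3/GTF) and transcript extraction
# from a local genome + annotation pair. BED is 0-based half-open on disk
# and converted to 1-based inclusive on read; everything downstream is
# 1-based inclusive.

#' Read annotations (BED/narrowPeak or GFF/GTF)
#'
#' @param path Input file.
#' @param tag `bed-narrowpeak` or `gff-gtf`.
#' @param sequence Optional [sequence_record()] the annotations index;
#'   inferred as an N-run spanning the records when absent.
#' @return List of [annotation()] objects (one per record). narrowPeak
#'   scores/signal are kept in the annotation's `score` field; strand is
#'   retained (`-` strand encoded via the primers convention only for
#'   primer categories, otherwise kept as a `strand` field).
#' @export
read_annotations <- function(path, tag = c("bed-narrowpeak", "gff-gtf"),
                             sequence = NULL) {
  tag <- match.arg(tag)
  switch(tag,
         "bed-narrowpeak" = read_bed_narrowpeak(path, sequence),
         "gff-gtf" = read_gff_annotations(path, sequence))
}

read_bed_narrowpeak <- function(path, sequence = NULL) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (!length(lines)) return(list())
  df <- utils::read.table(text = lines, header = FALSE,
                          stringsAsFactors = FALSE, fill = TRUE)
  start0 <- as.integer(df[[2]])
  end0 <- as.integer(df[[3]])
  bad <- start0 >= end0
  if (any(bad)) {
    warning(sum(bad), " BED record(s) with start >= end skipped in '",
            path, "'")
    df <- df[!bad, , drop = FALSE]
    start0 <- start0[!bad]; end0 <- end0[!bad]
  }
  if (!nrow(df)) return(list())
  start1 <- start0 + 1L          # half-open -> 1-based inclusive
  end1 <- end0
  if (is.null(sequence)) {
    sequence <- sequence_record(as.character(df[[1]][1]),
                                paste(rep("N", max(end1)), collapse = ""))
  }
  lapply(seq_len(nrow(df)), function(k) {
    a <- annotation(
      name = if (ncol(df) >= 4) as.character(df[[4]][k]) else
        paste0("region_", k),
      category = "spans",
      entries = data.frame(start = start1[k], end = end1[k]),
      sequence = sequence
    )
    if (ncol(df) >= 5) a$score <- as.numeric(df[[5]][k])
    if (ncol(df) >= 7) a$signal <- as.numeric(df[[7]][k])   # narrowPeak
    if (ncol(df) >= 6) a$strand <- as.character(df[[6]][k])
    a
  })
}

read_gff_annotations <- function(path, sequence = NULL) {
  df <- as.data.frame(rtracklayer::readGFF(path))
  if (!nrow(df)) return(list())
  if (is.null(sequence)) {
    sequence <- sequence_record(as.character(df$seqid[1]),
                                paste(rep("N", max(df$end)), collapse = ""))
  }
  lapply(seq_len(nrow(df)), function(k) {
    nm <- df$ID[k] %||% NA
    if (is.na(nm)) nm <- as.character(df$type[k])
    a <- annotation(name = as.character(nm), category = "spans",
                    entries = data.frame(start = df$start[k],
                                         end = df$end[k]),
                    sequence = sequence)
    a$feature_type <- as.character(df$type[k])
    a$strand <- as.character(df$strand[k])
    a
  })
}

#' Extract a transcript from a local genome FASTA + GFF/GTF annotation
#'
#' Splices the transcript's exons 5' to 3' (reverse-complemented for minus
#' strand genes), emits CDS/UTR and exon-junction annotations in transcript
#' coordinates, and returns a genome-to-transcript coordinate map for
#' transferring per-nucleotide genomic tracks (WIG/BED) onto the
#' transcript.
#'
#' @param gff_path GFF3/GTF file containing exon features for the id.
#' @param fasta_path Genome FASTA.
#' @param transcript_id Feature id; matched against `ID`, `Parent` and
#'   `transcript_id` attributes of exon/CDS records.
#' @return List with `sequence` (a [sequence_record()]), `annotations`
#'   (transcript-coordinate [annotation()]s: exon junctions, CDS if
#'   present), and `map` (data frame `genomic`, `transcript`, one row per
#'   exonic nucleotide).
#' @export
extract_transcript <- function(gff_path, fasta_path, transcript_id) {
  df <- as.data.frame(rtracklayer::readGFF(gff_path))
  belongs <- function(rows) {
    hit <- rep(FALSE, nrow(rows))
    for (col in intersect(c("ID", "Parent", "transcript_id"), names(rows))) {
      v <- rows[[col]]
      if (is.list(v)) v <- vapply(v, function(x) {
        if (length(x)) paste(x, collapse = ",") else ""
      }, "")
      hit <- hit | grepl(transcript_id, as.character(v), fixed = TRUE)
    }
    hit
  }
  hits <- df[belongs(df), , drop = FALSE]
  if (!nrow(hits)) {
    stop("transcript id '", transcript_id, "' not found in '", gff_path, "'")
  }
  exons <- hits[hits$type == "exon", , drop = FALSE]
  if (!nrow(exons)) {
    stop("transcript id '", transcript_id, "' has no exon features in '",
         gff_path, "'")
  }
  strand <- as.character(exons$strand[1])
  exons <- exons[order(exons$start), , drop = FALSE]
  genome <- read_sequence(fasta_path, id = as.character(exons$seqid[1]))
  gchars <- seq_chars(genome)
  g_pos <- unlist(lapply(seq_len(nrow(exons)),
                         function(k) exons$start[k]:exons$end[k]))
  spliced <- gchars[g_pos]
  if (strand == "-") {
    spliced <- rev(rna_complement(spliced))
    g_pos <- rev(g_pos)
  }
  seq <- sequence_record(transcript_id, paste(spliced, collapse = ""))
  map <- data.frame(genomic = g_pos, transcript = seq_along(g_pos))
  # junction site after the last base of each exon but the final one
  exon_len <- exons$end - exons$start + 1L
  if (strand == "-") exon_len <- rev(exon_len)
  junctions <- cumsum(exon_len)[-length(exon_len)]
  anns <- list()
  if (length(junctions)) {
    anns$junctions <- annotation(
      "exon_junction", "sites",
      data.frame(start = junctions, end = junctions), seq
    )
  }
  cds <- hits[hits$type == "CDS", , drop = FALSE]
  if (nrow(cds)) {
    g_cds <- unlist(lapply(seq_len(nrow(cds)),
                           function(k) cds$start[k]:cds$end[k]))
    t_cds <- map$transcript[match(g_cds, map$genomic)]
    t_cds <- sort(t_cds[!is.na(t_cds)])
    anns$cds <- annotation("CDS", "spans",
                           data.frame(start = min(t_cds), end = max(t_cds)),
                           seq)
  }
  list(sequence = seq, annotations = anns, map = map)
}

#' Transfer genomic positions to transcript coordinates
#'
#' @param map The `map` component of [extract_transcript()].
#' @param positions Genomic positions.
#' @return Transcript positions (`NA` for intronic/flanking input).
#' @export
genome_to_transcript <- function(map, positions) {
  map$transcript[match(positions, map$genomic)]
}
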