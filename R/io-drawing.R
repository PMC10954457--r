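# Structure-drawing dialects. Each is parsed for sequence, base pairs and
# per-nucleotide (x, y) coordinates only; fonts, colors and viewport
# decorations are ignored (the data classes only need geometry).

# VARNA-style XML: <rna><sequence>..</sequence>
#   <nucleotide index x y/> ... <basepair i j/> ...
read_varna <- function(path) {
  doc <- xml2::read_xml(path)
  seq_node <- xml2::xml_find_first(doc, ".//sequence")
  if (inherits(seq_node, "xml_missing")) {
    stop("VARNA file '", path, "' has no <sequence> element")
  }
  sequence <- sequence_record(basename(path),
                              gsub("[^A-Za-z]", "", xml2::xml_text(seq_node)))
  nts <- xml2::xml_find_all(doc, ".//nucleotide")
  drawing <- NULL
  if (length(nts)) {
    idx <- as.integer(xml2::xml_attr(nts, "index"))
    drawing <- data.frame(x = NA_real_, y = NA_real_)[rep(1, sequence$length), ]
    drawing$x[idx] <- as.numeric(xml2::xml_attr(nts, "x"))
    drawing$y[idx] <- as.numeric(xml2::xml_attr(nts, "y"))
    rownames(drawing) <- NULL
  }
  bps <- xml2::xml_find_all(doc, ".//basepair")
  pairs <- cbind(as.integer(xml2::xml_attr(bps, "i")),
                 as.integer(xml2::xml_attr(bps, "j")))
  secondary_structure(sequence, pairs, drawing)
}

write_varna <- function(ss, path) {
  stopifnot(!is.null(ss$drawing))
  nt <- sprintf('    <nucleotide index="%d" base="%s" x="%.3f" y="%.3f"/>',
                seq_len(ss$sequence$length), seq_chars(ss$sequence),
                ss$drawing$x, ss$drawing$y)
  bp <- if (nrow(ss$pairs)) {
    sprintf('    <basepair i="%d" j="%d"/>', ss$pairs[, 1], ss$pairs[, 2])
  } else character(0)
  writeLines(c("<rna>",
               paste0("  <sequence>", ss$sequence$residues, "</sequence>"),
               nt, bp, "</rna>"), path)
}

# XRNA XML: <NucListData DataType='NucChar.X.Y'> with "base x y" rows, and
# <BasePairs nucID length bpNucID/> helix records meaning
# (nucID+k) pairs (bpNucID-k) for k in 0..length-1.
read_xrna <- function(path) {
  doc <- xml2::read_xml(path)
  nld <- xml2::xml_find_first(doc, ".//NucListData")
  if (inherits(nld, "xml_missing")) {
    stop("XRNA file '", path, "' has no <NucListData> element")
  }
  rows <- strsplit(trimws(xml2::xml_text(nld)), "\n")[[1]]
  rows <- trimws(rows[nzchar(trimws(rows))])
  fields <- do.call(rbind, strsplit(rows, "\\s+"))
  sequence <- sequence_record(basename(path), paste(fields[, 1], collapse = ""))
  drawing <- data.frame(x = as.numeric(fields[, 2]),
                        y = as.numeric(fields[, 3]))
  helices <- xml2::xml_find_all(doc, ".//BasePairs")
  pairs <- matrix(integer(0), ncol = 2)
  for (h in helices) {
    i0 <- as.integer(xml2::xml_attr(h, "nucID"))
    len <- as.integer(xml2::xml_attr(h, "length"))
    j0 <- as.integer(xml2::xml_attr(h, "bpNucID"))
    k <- seq_len(len) - 1L
    pairs <- rbind(pairs, cbind(i0 + k, j0 - k))
  }
  secondary_structure(sequence, pairs, drawing)
}

write_xrna <- function(ss, path) {
  stopifnot(!is.null(ss$drawing))
  rows <- sprintf("%s %.3f %.3f", seq_chars(ss$sequence),
                  ss$drawing$x, ss$drawing$y)
  # emit each pair as a length-1 helix record; compact but valid
  bp <- if (nrow(ss$pairs)) {
    sprintf("<BasePairs nucID='%d' length='1' bpNucID='%d'/>",
            ss$pairs[, 1], ss$pairs[, 2])
  } else character(0)
  writeLines(c("<ComplexDocument>",
               "<Complex><RNAMolecule>",
               "<NucListData StartNucID='1' DataType='NucChar.X.Y'>",
               rows,
               "</NucListData>", bp,
               "</RNAMolecule></Complex>",
               "</ComplexDocument>"), path)
}

# FORNA JSON: {"sequence": str, "structure": dot-bracket, "positions": [[x,y],..]}
read_forna <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$sequence) || is.null(obj$structure)) {
    stop("FORNA file '", path, "' lacks 'sequence'/'structure' keys")
  }
  sequence <- sequence_record(basename(path), obj$sequence)
  drawing <- NULL
  if (!is.null(obj$positions)) {
    pos <- obj$positions
    if (is.list(pos)) pos <- do.call(rbind, pos)
    drawing <- data.frame(x = as.numeric(pos[, 1]), y = as.numeric(pos[, 2]))
  }
  secondary_structure(sequence, decode_dotbracket(obj$structure), drawing)
}

write_forna <- function(ss, path) {
  stopifnot(!is.null(ss$drawing))
  db_path <- tempfile(fileext = ".db")
  on.exit(unlink(db_path))
  write_dotbracket(ss, db_path)
  db <- readLines(db_path)[3]
  jsonlite::write_json(
    list(sequence = ss$sequence$residues, structure = db,
         positions = unname(as.matrix(ss$drawing))),
    path, auto_unbox = TRUE, digits = 6
  )
}

# R2DT JSON, nucleotide-coordinate layout schema:
#   {"rnaComplexes":[{"rnaMolecules":[{"sequence":[{residueName,x,y},...],
#                                      "basePairs":[{residueIndex1,residueIndex2},...]}]}]}
# Other R2DT JSON sub-schemas are rejected with a clear message.
read_r2dt <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$rnaComplexes)) {
    stop("R2DT file '", path, "' does not use the nucleotide-coordinate ",
         "layout schema (no 'rnaComplexes' key); other R2DT JSON ",
         "sub-schemas are not supported")
  }
  mol <- obj$rnaComplexes$rnaMolecules[[1]]
  if (is.data.frame(mol)) mol <- as.list(mol[1, ])
  seq_df <- mol$sequence
  if (is.list(seq_df) && !is.data.frame(seq_df)) seq_df <- seq_df[[1]]
  sequence <- sequence_record(basename(path),
                              paste(seq_df$residueName, collapse = ""))
  drawing <- data.frame(x = as.numeric(seq_df$x), y = as.numeric(seq_df$y))
  bp <- mol$basePairs
  if (is.list(bp) && !is.data.frame(bp)) bp <- bp[[1]]
  pairs <- if (!is.null(bp) && NROW(bp)) {
    cbind(as.integer(bp$residueIndex1), as.integer(bp$residueIndex2))
  } else NULL
  secondary_structure(sequence, pairs, drawing)
}

write_r2dt <- function(ss, path) {
  stopifnot(!is.null(ss$drawing))
  seq_df <- data.frame(residueIndex = seq_len(ss$sequence$length),
                       residueName = seq_chars(ss$sequence),
                       x = ss$drawing$x, y = ss$drawing$y)
  bp <- data.frame(residueIndex1 = ss$pairs[, 1],
                   residueIndex2 = ss$pairs[, 2])
  jsonlite::write_json(
    list(rnaComplexes = list(list(rnaMolecules = list(list(
      sequence = seq_df, basePairs = bp))))),
    path, digits = 6
  )
}

# simplified StructureEditor-style NSD text:
#   #Nucleotides / "<index> <base> <x> <y>" rows, then
#   #Pairs / "<i>:<j>" rows
read_nsd <- function(path) {
  lines <- trimws(read_text_lines(path))
  lines <- lines[nzchar(lines)]
  nt_at <- grep("^#Nucleotides", lines)
  pr_at <- grep("^#Pairs", lines)
  if (!length(nt_at)) {
    stop("NSD file '", path, "' has no '#Nucleotides' section")
  }
  nt_end <- if (length(pr_at)) pr_at - 1L else length(lines)
  nt_rows <- lines[seq(nt_at + 1L, nt_end)]
  fields <- do.call(rbind, strsplit(nt_rows, "\\s+"))
  idx <- as.integer(fields[, 1])
  sequence <- sequence_record(basename(path),
                              paste(fields[order(idx), 2], collapse = ""))
  drawing <- data.frame(x = rep(NA_real_, sequence$length),
                        y = rep(NA_real_, sequence$length))
  drawing$x[idx] <- as.numeric(fields[, 3])
  drawing$y[idx] <- as.numeric(fields[, 4])
  pairs <- NULL
  if (length(pr_at) && pr_at < length(lines)) {
    pr_rows <- lines[seq(pr_at + 1L, length(lines))]
    pr <- do.call(rbind, strsplit(pr_rows, ":"))
    pairs <- cbind(as.integer(pr[, 1]), as.integer(pr[, 2]))
  }
  secondary_structure(sequence, pairs, drawing)
}

write_nsd <- function(ss, path) {
  stopifnot(!is.null(ss$drawing))
  writeLines(c(
    "#Nucleotides",
    sprintf("%d %s %.3f %.3f", seq_len(ss$sequence$length),
            seq_chars(ss$sequence), ss$drawing$x, ss$drawing$y),
    "#Pairs",
    if (nrow(ss$pairs)) sprintf("%d:%d", ss$pairs[, 1], ss$pairs[, 2])
  ), path)
}
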