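# Secondary-structure readers/writers: connectivity tables, dot-bracket
# (multi-layer brackets for pseudoknots), and the drawing dialects.

DB_OPENERS <- c("(", "[", "{", "<", LETTERS)
DB_CLOSERS <- c(")", "]", "}", ">", letters)
DB_UNPAIRED <- c(".", "-", "_", ",", ":")

#' Read a secondary structure
#'
#' @param path Input file.
#' @param tag One of `ct`, `dotbracket`, `varna`, `xrna`, `forna`, `r2dt`,
#'   `nsd`. Drawing dialects also populate per-nucleotide (x, y)
#'   coordinates.
#' @param sequence Optional [sequence_record()] for dot-bracket files that
#'   carry no sequence line.
#' @return A [secondary_structure()].
#' @export
read_secondary_structure <- function(path,
                                     tag = c("ct", "dotbracket", "varna",
                                             "xrna", "forna", "r2dt", "nsd"),
                                     sequence = NULL) {
  tag <- match.arg(tag)
  switch(tag,
         ct = read_ct(path),
         dotbracket = read_dotbracket(path, sequence = sequence),
         varna = read_varna(path),
         xrna = read_xrna(path),
         forna = read_forna(path),
         r2dt = read_r2dt(path),
         nsd = read_nsd(path))
}

#' Write a secondary structure
#'
#' Pseudoknots are emitted on escalating bracket layers chosen by greedy
#' coloring of the pair-crossing graph; more than four mutually crossing
#' layers exceed the bracket alphabet policy and error.
#'
#' @param ss A [secondary_structure()].
#' @param path Output file.
#' @param tag `ct` or `dotbracket`.
#' @return `path`, invisibly.
#' @export
write_secondary_structure <- function(ss, path, tag = c("ct", "dotbracket")) {
  tag <- match.arg(tag)
  switch(tag, ct = write_ct(ss, path), dotbracket = write_dotbracket(ss, path))
  invisible(path)
}

# ---- connectivity table (RNAstructure flavor) -------------------------------

read_ct <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("CT file '", path, "' is empty")
  head_fields <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(head_fields[1]))
  if (is.na(n) || n < 1L) {
    stop("CT parse error in '", path, "' line 1: expected '<count> <title>'")
  }
  title <- if (length(head_fields) > 1) {
    paste(head_fields[-1], collapse = " ")
  } else "structure"
  if (length(lines) < n + 1L) {
    stop("CT file '", path, "' declares ", n, " nucleotides but has ",
         length(lines) - 1L, " rows")
  }
  body <- utils::read.table(text = lines[2:(n + 1L)],
                            col.names = c("i", "base", "prev", "nxt",
                                          "partner", "natural"),
                            colClasses = c("integer", "character", "integer",
                                           "integer", "integer", "integer"))
  if (!identical(body$i, seq_len(n))) {
    stop("CT parse error in '", path, "': index column is not 1..", n)
  }
  partner <- body$partner
  for (i in seq_len(n)) {
    j <- partner[i]
    if (j > 0L) {
      if (j > n || partner[j] != i) {
        stop("CT integrity error in '", path, "': nucleotide ", i,
             " pairs with ", j, " but ", j, " pairs with ",
             if (j > n) "nothing" else partner[j])
      }
    }
  }
  sel <- which(partner > body$i)
  seq <- sequence_record(title, paste(body$base, collapse = ""))
  secondary_structure(seq, cbind(body$i[sel], partner[sel]))
}

write_ct <- function(ss, path) {
  n <- ss$sequence$length
  partner <- partner_vector(ss)
  chars <- seq_chars(ss$sequence)
  lines <- c(
    sprintf("%6d %s", n, ss$sequence$id),
    sprintf("%6d %s %6d %6d %6d %6d", seq_len(n), chars, seq_len(n) - 1L,
            c(seq_len(n - 1L) + 1L, 0L), partner, seq_len(n))
  )
  writeLines(lines, path)
}

# ---- dot-bracket ------------------------------------------------------------

decode_dotbracket <- function(db) {
  chars <- strsplit(db, "", fixed = TRUE)[[1]]
  stacks <- list()
  pairs <- list()
  for (k in seq_along(chars)) {
    ch <- chars[k]
    if (ch %in% DB_UNPAIRED) next
    layer <- match(ch, DB_OPENERS)
    if (!is.na(layer)) {
      stacks[[as.character(layer)]] <- c(stacks[[as.character(layer)]], k)
      next
    }
    layer <- match(ch, DB_CLOSERS)
    if (is.na(layer)) {
      stop("dot-bracket parse error at position ", k,
           ": unexpected character '", ch, "'")
    }
    st <- stacks[[as.character(layer)]]
    if (!length(st)) {
      stop("dot-bracket parse error at position ", k,
           ": unbalanced '", ch, "'")
    }
    pairs[[length(pairs) + 1L]] <- c(st[length(st)], k)
    stacks[[as.character(layer)]] <- st[-length(st)]
  }
  open_left <- unlist(stacks)
  if (length(open_left)) {
    stop("dot-bracket parse error at position ", min(open_left),
         ": unclosed bracket")
  }
  do.call(rbind, c(pairs, list(matrix(integer(0), ncol = 2))))
}

read_dotbracket <- function(path, sequence = NULL) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- trimws(lines[!grepl("^[>#]", lines)])
  is_struct <- vapply(lines, function(l) {
    all(strsplit(l, "")[[1]] %in% c(DB_OPENERS, DB_CLOSERS, DB_UNPAIRED)) &&
      grepl("[]()[{}<>.]", l)
  }, TRUE)
  is_seqline <- grepl("^[ACGUTNacgutn]+$", lines)
  struct_line <- which(is_struct & !is_seqline)
  if (!length(struct_line)) {
    stop("no dot-bracket structure line found in '", path, "'")
  }
  db <- lines[struct_line[1]]
  seq_line <- which(is_seqline)
  seq_line <- seq_line[seq_line < struct_line[1]]
  if (length(seq_line)) {
    sequence <- sequence_record(basename(path), lines[seq_line[length(seq_line)]])
  }
  if (is.null(sequence)) {
    sequence <- sequence_record(basename(path),
                                paste(rep("N", nchar(db)), collapse = ""))
  }
  if (sequence$length != nchar(db)) {
    stop("dot-bracket string length ", nchar(db),
         " does not match sequence length ", sequence$length)
  }
  secondary_structure(sequence, decode_dotbracket(db))
}

# assign each pair a bracket layer by greedy coloring of the crossing graph;
# layers beyond the 4 bracket families are a policy error
bracket_layers <- function(pairs) {
  m <- nrow(pairs)
  layer <- integer(m)
  if (!m) return(layer)
  ord <- order(pairs[, 1], pairs[, 2])
  for (idx in ord) {
    i <- pairs[idx, 1]; j <- pairs[idx, 2]
    conflicting <- layer[(pairs[, 1] < i & i < pairs[, 2] & pairs[, 2] < j) |
                           (i < pairs[, 1] & pairs[, 1] < j & j < pairs[, 2])]
    conflicting <- conflicting[conflicting > 0L]
    layer[idx] <- min(setdiff(seq_len(max(c(conflicting, 0L)) + 1L),
                              conflicting))
  }
  layer
}

write_dotbracket <- function(ss, path) {
  n <- ss$sequence$length
  chars <- rep(".", n)
  layer <- bracket_layers(ss$pairs)
  if (length(layer) && max(layer) > 4L) {
    stop("structure needs ", max(layer), " mutually crossing bracket layers;",
         " at most 4 are supported by the bracket alphabet policy")
  }
  openers <- c("(", "[", "{", "<")
  closers <- c(")", "]", "}", ">")
  if (nrow(ss$pairs)) {
    chars[ss$pairs[, 1]] <- openers[layer]
    chars[ss$pairs[, 2]] <- closers[layer]
  }
  writeLines(c(paste0(">", ss$sequence$id),
               ss$sequence$residues,
               paste(chars, collapse = "")), path)
}
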