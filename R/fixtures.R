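# Deterministic synthetic toy-RNA dataset: a designed secondary structure
# (hairpins plus an H-type pseudoknot), reactivities drawn from separated
# paired/unpaired distributions, pairing probabilities concentrated on the
# true pairs, correlated-probing records near true pairs and a loop-loop
# tertiary contact, idealized helical 3D coordinates, and a 2-exon parent
# gene. One file per supported input format, so every reader is exercised
# with zero downloads. The same seed yields byte-identical files.

#' Fixture specification
#'
#' The generative conditions for the synthetic toy RNA. Reactivities are
#' log-normal: paired positions use `paired_meanlog`, unpaired positions
#' `unpaired_meanlog`, shared `sdlog`; the distributions overlap, so
#' reactivity separates pairing status well but not perfectly.
#'
#' @param seed Integer RNG seed; the same seed gives byte-identical files.
#' @param n Transcript length in nt (>= 20).
#' @param paired_meanlog,unpaired_meanlog,sdlog Log-normal reactivity
#'   parameters (defaults log(0.1), log(0.9), 0.6).
#' @param pseudoknot Include an H-type pseudoknot (loop of the first
#'   hairpin paired with the 3' tail) when the length allows.
#' @return A `FixtureSpec` list.
#' @export
fixture_spec <- function(seed = 1L, n = 120L, paired_meanlog = log(0.1),
                         unpaired_meanlog = log(0.9), sdlog = 0.6,
                         pseudoknot = TRUE) {
  n <- as.integer(n)
  if (n < 20L) stop("fixture transcript must be >= 20 nt")
  list(seed = as.integer(seed), n = n, paired_meanlog = paired_meanlog,
       unpaired_meanlog = unpaired_meanlog, sdlog = sdlog,
       pseudoknot = pseudoknot)
}

# designed structure: hairpins in the 5' ~55%, single-stranded 3' tail
fixture_pairs <- function(spec) {
  n <- spec$n
  helices <- list()
  start <- 6L
  stem <- 6L; loop <- 4L
  limit <- ceiling(0.55 * n)
  while (start + 2L * stem + loop - 1L <= limit) {
    helices[[length(helices) + 1L]] <- list(start = start, stem = stem,
                                            loop = loop)
    start <- start + 2L * stem + loop + 6L
  }
  if (!length(helices)) {
    stem <- max(3L, (n - 10L) %/% 3L)
    helices <- list(list(start = 3L, stem = min(stem, 6L), loop = 4L))
  }
  pairs <- do.call(rbind, lapply(helices, function(h) {
    k <- seq_len(h$stem) - 1L
    cbind(h$start + k, h$start + 2L * h$stem + h$loop - 1L - k)
  }))
  pk <- NULL
  if (spec$pseudoknot && n >= 60L) {
    h1 <- helices[[1]]
    loop_start <- h1$start + h1$stem
    pk_i <- loop_start + 0:2
    pk_j <- (n - 8L):(n - 10L)
    pk <- cbind(pk_i, pk_j)
  }
  list(pairs = rbind(pairs, pk), helices = helices, pk = pk)
}

fixture_truth <- function(spec) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  }
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, .GlobalEnv)
  })
  set.seed(spec$seed)
  design <- fixture_pairs(spec)
  n <- spec$n
  bases <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  for (k in seq_len(nrow(design$pairs))) {
    bases[design$pairs[k, 2]] <- rna_complement(bases[design$pairs[k, 1]])
  }
  seq <- sequence_record("toyRNA", paste(bases, collapse = ""))
  paired <- logical(n)
  paired[c(design$pairs)] <- TRUE
  values <- ifelse(paired,
                   stats::rlnorm(n, spec$paired_meanlog, spec$sdlog),
                   stats::rlnorm(n, spec$unpaired_meanlog, spec$sdlog))
  values[1:3] <- NA   # primer-proximal positions carry no data
  stderr <- 0.05 + 0.1 * ifelse(is.na(values), 0, values)
  # nesting-depth drawing layout (arbitrary units)
  partner <- integer(n)
  partner[design$pairs[, 1]] <- design$pairs[, 2]
  partner[design$pairs[, 2]] <- design$pairs[, 1]
  depth <- 0L
  y <- numeric(n)
  for (i in seq_len(n)) {
    if (partner[i] > i) depth <- depth + 1L
    y[i] <- depth
    if (partner[i] > 0L && partner[i] < i) depth <- depth - 1L
  }
  drawing <- data.frame(x = as.numeric(seq_len(n)), y = y)
  # pairing probabilities: concentrated on true pairs, weak elsewhere
  helix_rank <- function(k) {
    h <- design$pairs[k, ]
    min(vapply(design$helices, function(hh) {
      kk <- seq_len(hh$stem) - 1L
      ii <- hh$start + kk
      if (h[1] %in% ii) min(match(h[1], ii) - 1L, hh$stem - match(h[1], ii))
      else Inf
    }, 0))
  }
  dp <- do.call(rbind, lapply(seq_len(nrow(design$pairs)), function(k) {
    edge <- helix_rank(k) < 1
    is_pk <- !is.null(design$pk) &&
      any(design$pk[, 1] == design$pairs[k, 1])
    p <- if (is_pk) 0.6 else if (edge) 0.65 else 0.95
    rows <- data.frame(i = design$pairs[k, 1], j = design$pairs[k, 2],
                       probability = p)
    if (edge && design$pairs[k, 1] > 1 && design$pairs[k, 2] < n) {
      rows <- rbind(rows, data.frame(i = design$pairs[k, 1] - 1L,
                                     j = design$pairs[k, 2] + 1L,
                                     probability = 0.08))
    }
    rows
  }))
  tail_start <- max(design$pairs) + 1L
  ss_pos <- setdiff(tail_start:n, c(design$pairs))
  if (length(ss_pos) >= 6L) {
    alt <- data.frame(
      i = sample(ss_pos, 3L * length(ss_pos), replace = TRUE),
      j = sample(ss_pos, 3L * length(ss_pos), replace = TRUE),
      probability = round(stats::runif(3L * length(ss_pos), 0.05, 0.15), 4)
    )
    alt <- alt[alt$i != alt$j, ]
    dp <- rbind(dp, alt)
  }
  dp$i2 <- pmin(dp$i, dp$j); dp$j2 <- pmax(dp$i, dp$j)
  dp <- data.frame(i = dp$i2, j = dp$j2, probability = dp$probability)
  dp <- dp[!duplicated(dp[c("i", "j")]), ]
  dp <- dp[order(dp$i, dp$j), ]
  # RINGs: near true pairs plus a loop-loop tertiary contact, few decoys
  jitter_pair <- function(p) {
    i <- p[1] + sample(-2:2, 1); j <- p[2] + sample(-2:2, 1)
    c(max(1L, min(i, j)), min(n, max(i, j)))
  }
  ring_src <- design$pairs[sample(nrow(design$pairs), 12L, replace = TRUE), ,
                           drop = FALSE]
  rings <- t(apply(ring_src, 1, jitter_pair))
  if (length(design$helices) >= 2L) {
    h1 <- design$helices[[1]]; h2 <- design$helices[[length(design$helices)]]
    loop1 <- h1$start + h1$stem + 1L
    loop2 <- h2$start + h2$stem + 1L
    rings <- rbind(rings, cbind(loop1 + 0:2, loop2 + 0:2))
  }
  rings <- rings[rings[, 1] < rings[, 2], , drop = FALSE]
  ring_df <- data.frame(i = rings[, 1], j = rings[, 2],
                        statistic = round(stats::runif(nrow(rings), 2, 8), 3))
  decoys <- data.frame(i = sample(seq_len(n - 10L), 3L))
  decoys$j <- decoys$i + sample(5:9, 3L, replace = TRUE)
  decoys$statistic <- -round(stats::runif(3L, 1, 3), 3)
  ring_df <- rbind(ring_df, decoys)
  ring_df$zscore <- round(abs(ring_df$statistic) / 2, 3)
  # PAIRs: true pairs, primary in helix interiors
  pr <- data.frame(i = design$pairs[, 1], j = design$pairs[, 2])
  pr$statistic <- round(stats::runif(nrow(pr), 1, 5), 3)
  pr$class <- ifelse(vapply(seq_len(nrow(design$pairs)), helix_rank, 0) >= 1,
                     1L, 2L)
  # ensemble state 2: +0.8 reactivity over a 12-nt window in the tail
  v2 <- values
  win <- ss_pos[seq_len(min(12L, length(ss_pos)))]
  v2[win] <- v2[win] + 0.8
  list(spec = spec, sequence = seq, design = design, paired = paired,
       values = values, stderr = stderr, drawing = drawing, dp = dp,
       rings = ring_df, pairs_table = pr, values2 = v2)
}

fmt <- function(x, digits = 4) {
  out <- formatC(x, digits = digits, format = "f")
  out[is.na(x)] <- "-999"
  out
}

#' Generate the synthetic fixture dataset
#'
#' Writes one parseable file per supported input format (plus the genome
#' FASTA backing the GFF) into `outdir` and returns a manifest.
#'
#' @param spec A [fixture_spec()].
#' @param outdir Output directory (created if needed).
#' @return Data frame manifest with columns `tag`, `path`, `md5`;
#'   the generating truth is attached as attribute `truth`.
#' @export
generate_fixture <- function(spec = fixture_spec(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  truth <- fixture_truth(spec)
  seq <- truth$sequence
  n <- spec$n
  ss <- secondary_structure(seq, truth$design$pairs, truth$drawing)
  path <- function(f) file.path(outdir, f)
  files <- c(
    fasta = "toy.fa", ct = "toy.ct", dotbracket = "toy.db",
    varna = "toy.varna", xrna = "toy.xrna", forna = "toy_forna.json",
    r2dt = "toy_r2dt.json", nsd = "toy.nsd", pdb = "toy.pdb",
    cif = "toy.cif", `shapemapper-profile` = "toy_profile.txt",
    map = "toy.map", shape = "toy.shape",
    `rnaframework-xml` = "toy_react.xml",
    `dance-reactivities` = "toy_dance.txt", wig = "toy.wig",
    ring = "toy_rings.txt", pair = "toy_pairs.txt",
    `pairprob-dp` = "toy.dp", `bed-narrowpeak` = "toy.bed",
    `gff-gtf` = "toy.gff"
  )
  write_fasta(seq, path(files["fasta"]))
  write_ct(ss, path(files["ct"]))
  write_dotbracket(ss, path(files["dotbracket"]))
  write_varna(ss, path(files["varna"]))
  write_xrna(ss, path(files["xrna"]))
  write_forna(ss, path(files["forna"]))
  write_r2dt(ss, path(files["r2dt"]))
  write_nsd(ss, path(files["nsd"]))
  write_fixture_pdb(truth, path(files["pdb"]))
  write_fixture_cif(truth, path(files["cif"]))
  chars <- seq_chars(seq)
  writeLines(c(
    paste(c("Nucleotide", "Sequence", "Norm_profile", "Norm_stderr",
            "HQ_profile"), collapse = "\t"),
    paste(seq_len(n), chars, fmt(truth$values), fmt(truth$stderr),
          fmt(truth$values * 1.8), sep = "\t")
  ), path(files["shapemapper-profile"]))
  writeLines(sprintf("%d\t%s\t%s\t%s", seq_len(n), fmt(truth$values),
                     fmt(truth$stderr), chars), path(files["map"]))
  writeLines(sprintf("%d %s", seq_len(n), fmt(truth$values)),
             path(files["shape"]))
  react_csv <- paste(ifelse(is.na(truth$values), "NaN",
                            fmt(truth$values)), collapse = ",")
  writeLines(c('<data tool="synthetic">',
               sprintf('<transcript id="%s" length="%d">', seq$id, n),
               paste0("<sequence>", seq$residues, "</sequence>"),
               paste0("<reactivity>", react_csv, "</reactivity>"),
               "</transcript>", "</data>"),
             path(files["rnaframework-xml"]))
  writeLines(c(
    paste(c("Nucleotide", "Sequence", "Norm_profile_0", "Norm_profile_1"),
          collapse = "\t"),
    paste(seq_len(n), chars, fmt(truth$values), fmt(truth$values2),
          sep = "\t")
  ), path(files["dance-reactivities"]))
  wig_span <- 10:min(n, 60)
  writeLines(c(sprintf("fixedStep chrom=%s start=%d step=1", seq$id,
                       wig_span[1]),
               fmt(ifelse(is.na(truth$values[wig_span]), 0,
                          truth$values[wig_span]))),
             path(files["wig"]))
  writeLines(c("i\tj\tstatistic\tzscore",
               sprintf("%d\t%d\t%s\t%s", truth$rings$i, truth$rings$j,
                       fmt(truth$rings$statistic, 3),
                       fmt(truth$rings$zscore, 3))),
             path(files["ring"]))
  writeLines(c("i\tj\tstatistic\tclass",
               sprintf("%d\t%d\t%s\t%d", truth$pairs_table$i,
                       truth$pairs_table$j,
                       fmt(truth$pairs_table$statistic, 3),
                       truth$pairs_table$class)),
             path(files["pair"]))
  writeLines(c(as.character(n), "i\tj\t-log10(Probability)",
               sprintf("%d %d %s", truth$dp$i, truth$dp$j,
                       fmt(-log10(truth$dp$probability), 6))),
             path(files["pairprob-dp"]))
  write_fixture_gene(truth, path(files["gff-gtf"]), path("toy_genome.fa"),
                     path(files["bed-narrowpeak"]))
  manifest <- data.frame(tag = names(files),
                         path = unname(vapply(files, path, "")),
                         stringsAsFactors = FALSE)
  manifest$md5 <- unname(tools::md5sum(manifest$path))
  attr(manifest, "truth") <- truth
  manifest
}

# idealized A-form-like helical backbone: one ring of atoms per nucleotide
fixture_atom_xyz <- function(n) {
  theta <- (seq_len(n) - 1L) * 32.7 * pi / 180
  rise <- (seq_len(n) - 1L) * 2.81
  list(
    P = cbind(8.7 * cos(theta + 0.2), 8.7 * sin(theta + 0.2), rise),
    `C1'` = cbind(9.4 * cos(theta), 9.4 * sin(theta), rise),
    `O2'` = cbind(10.9 * cos(theta), 10.9 * sin(theta), rise + 0.5),
    N1 = cbind(7.0 * cos(theta - 0.15), 7.0 * sin(theta - 0.15), rise)
  )
}

write_fixture_pdb <- function(truth, path) {
  n <- truth$spec$n
  xyz <- fixture_atom_xyz(n)
  chars <- seq_chars(truth$sequence)
  lines <- character(0)
  serial <- 0L
  for (i in seq_len(n)) {
    for (at in names(xyz)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        serial, at, chars[i], i,
        xyz[[at]][i, 1], xyz[[at]][i, 2], xyz[[at]][i, 3]))
    }
  }
  writeLines(c(lines, "END"), path)
}

write_fixture_cif <- function(truth, path) {
  n <- truth$spec$n
  xyz <- fixture_atom_xyz(n)
  chars <- seq_chars(truth$sequence)
  rows <- character(0)
  serial <- 0L
  for (i in seq_len(n)) {
    for (at in names(xyz)) {
      serial <- serial + 1L
      rows <- c(rows, sprintf(
        "ATOM %d %s \"%s\" . %s A 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s A \"%s\" 1",
        serial, substr(at, 1, 1), at, chars[i], i,
        xyz[[at]][i, 1], xyz[[at]][i, 2], xyz[[at]][i, 3], i, chars[i], at))
    }
  }
  writeLines(c(
    "data_toy",
    "#", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                            "label_atom_id", "label_alt_id",
                            "label_comp_id", "label_asym_id",
                            "label_entity_id", "label_seq_id",
                            "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                            "Cartn_z", "occupancy", "B_iso_or_equiv",
                            "pdbx_formal_charge", "auth_seq_id",
                            "auth_comp_id", "auth_asym_id",
                            "auth_atom_id", "pdbx_PDB_model_num")),
    rows, "#"), path)
}

# 2-exon parent gene: genome = exon1 + 30 nt intron + exon2, plus BED sites
write_fixture_gene <- function(truth, gff_path, genome_path, bed_path) {
  n <- truth$spec$n
  h <- n %/% 2L
  chars <- seq_chars(truth$sequence)
  intron <- c("G", "U", rep(c("A", "U", "C"), length.out = 26L), "A", "G")
  genome_chars <- c(chars[1:h], intron, chars[(h + 1L):n])
  genome <- sequence_record("chrT", paste(genome_chars, collapse = ""))
  write_fasta(genome, genome_path)
  gl <- genome$length
  e2_start <- h + 31L
  cds_t <- c(10L, n - 10L)
  writeLines(c(
    "##gff-version 3",
    sprintf("chrT\tsynthetic\tgene\t1\t%d\t.\t+\t.\tID=gene1", gl),
    sprintf("chrT\tsynthetic\tmRNA\t1\t%d\t.\t+\t.\tID=tx1;Parent=gene1",
            gl),
    sprintf("chrT\tsynthetic\texon\t1\t%d\t.\t+\t.\tID=exon1;Parent=tx1", h),
    sprintf("chrT\tsynthetic\texon\t%d\t%d\t.\t+\t.\tID=exon2;Parent=tx1",
            e2_start, gl),
    sprintf("chrT\tsynthetic\tCDS\t%d\t%d\t.\t+\t0\tID=cds1;Parent=tx1",
            cds_t[1], h),
    sprintf("chrT\tsynthetic\tCDS\t%d\t%d\t.\t+\t0\tID=cds1;Parent=tx1",
            e2_start, e2_start + (cds_t[2] - h) - 1L)
  ), gff_path)
  writeLines(c(
    sprintf("chrT\t%d\t%d\tsite1\t100\t+", 9L, 12L),
    sprintf("chrT\t%d\t%d\tsite2\t80\t+", h + 40L, h + 48L)
  ), bed_path)
}
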