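#' Read a tertiary structure (PDB or mmCIF)
#'
#' Parsing is delegated to bio3d; atoms are grouped by residue, non-nucleic
#' chains are dropped, the first altloc of duplicated atoms is kept, and a
#' residue-number to transcript-position map is built (offset-adjustable).
#'
#' @param path PDB or mmCIF file.
#' @param tag `pdb` or `cif`.
#' @param chain Optional chain id; defaults to all nucleic chains. An error
#'   listing available chains if absent.
#' @param offset Added to the rank-order transcript position of each mapped
#'   residue (default 0).
#' @return A [tertiary_structure()].
#' @export
read_tertiary <- function(path, tag = c("pdb", "cif"), chain = NULL,
                          offset = 0L) {
  tag <- match.arg(tag)
  obj <- if (tag == "pdb") {
    bio3d::read.pdb(path, verbose = FALSE)
  } else {
    suppressWarnings(bio3d::read.cif(path, verbose = FALSE))
  }
  at <- obj$atom
  at$elety <- gsub('"', "", at$elety)   # mmCIF quotes primed atom names
  nucleic <- toupper(at$resid) %in% names(NUCLEIC_RESNAMES)
  if (!any(nucleic)) {
    stop("'", path, "' contains no nucleic-acid residues ",
         "(chains present: ", paste(unique(at$chain), collapse = ", "), ")")
  }
  at <- at[nucleic, , drop = FALSE]
  if (!is.null(chain)) {
    if (!chain %in% at$chain) {
      stop("chain '", chain, "' not found in '", path,
           "'; available nucleic chains: ",
           paste(unique(at$chain), collapse = ", "))
    }
    at <- at[at$chain == chain, , drop = FALSE]
  }
  # first altloc wins: keep the first record of each (chain, residue, atom)
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      resname = toupper(at$resid), atom = at$elety,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  res <- unique(atoms[c("chain", "resno", "resname")])
  seq_map <- data.frame(chain = res$chain, resno = res$resno,
                        resname = res$resname,
                        pos = seq_len(nrow(res)) + as.integer(offset))
  tertiary_structure(atoms, seq_map)
}
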