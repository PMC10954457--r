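# Input-format and plot-kind registries. Both rosters are fixed; readers
# dispatch through the format table so `create_sample()` and the CLI share
# one entry point.

format_registry <- function() {
  df <- rbind(
    c("fasta", "SequenceRecord", "FASTA sequence (wrapped/decorated lines tolerated)"),
    c("ct", "SecondaryStructure", "connectivity table (RNAstructure flavor)"),
    c("dotbracket", "SecondaryStructure", "dot-bracket string, multi-layer brackets for pseudoknots"),
    c("varna", "SecondaryStructure", "VARNA-style XML drawing (sequence, pairs, coordinates)"),
    c("xrna", "SecondaryStructure", "XRNA XML drawing (NucListData/BasePairs)"),
    c("forna", "SecondaryStructure", "FORNA JSON layout"),
    c("r2dt", "SecondaryStructure", "R2DT JSON (nucleotide-coordinate layout schema)"),
    c("nsd", "SecondaryStructure", "StructureEditor-style NSD text drawing"),
    c("pdb", "TertiaryStructure", "Protein Data Bank atomic coordinates"),
    c("cif", "TertiaryStructure", "mmCIF atomic coordinates"),
    c("shapemapper-profile", "Profile", "ShapeMapper-style profile table (Norm_profile column)"),
    c("map", "Profile", "4-column .map reactivity table (pos, value, stderr, base)"),
    c("shape", "Profile", "2-column .shape reactivity table (pos, value)"),
    c("rnaframework-xml", "Profile", "RNA-Framework-style reactivity XML"),
    c("dance-reactivities", "Profile", "ensemble-deconvolution per-state reactivity table"),
    c("wig", "Profile", "wiggle track (fixedStep/variableStep) on transcript coordinates"),
    c("ring", "InteractionSet", "correlated-probing RING table (header-driven columns)"),
    c("pair", "InteractionSet", "correlated-probing PAIR table with primary/secondary classes"),
    c("pairprob-dp", "InteractionSet", "pairing-probability dotplot text (i, j, -log10 p)"),
    c("bed-narrowpeak", "Annotation", "BED / narrowPeak intervals (0-based half-open on disk)"),
    c("gff-gtf", "Annotation", "GFF3 / GTF features")
  )
  data.frame(tag = df[, 1], class = df[, 2], description = df[, 3],
             stringsAsFactors = FALSE)
}

#' List supported input file formats
#'
#' @return Data frame with columns `tag`, `class` (the data class the
#'   reader produces) and `description`, in stable registry order.
#' @examples
#' list_input_formats()$tag
#' @export
list_input_formats <- function() format_registry()

# per-kind data requirements: `needs` are roles that must all be present,
# `any_of` is satisfied by one role from the set
plot_registry <- function() {
  kinds <- list(
    list(kind = "profile-bars", needs = "profile", any_of = NULL,
         description = "colored per-nucleotide bar graph"),
    list(kind = "skyline", needs = "profile", any_of = NULL,
         description = "stepped-line graph comparing profiles"),
    list(kind = "arcs", needs = character(0),
         any_of = c("structure", "interactions"),
         description = "interactions/base pairs as semicircles over the sequence"),
    list(kind = "arcs-compare", needs = "structure", any_of = NULL,
         description = "two structure models classified pair-by-pair on mirrored arcs"),
    list(kind = "circle", needs = character(0),
         any_of = c("structure", "interactions"),
         description = "nucleotides on a circle, interactions as chords"),
    list(kind = "ss-diagram", needs = "structure", any_of = NULL,
         description = "structure diagram at drawing coordinates, with overlays"),
    list(kind = "molecule", needs = "tertiary", any_of = NULL,
         description = "3D projection with interaction cylinders and viewer export"),
    list(kind = "heatmap-density", needs = "interactions", any_of = NULL,
         description = "binned 2D density of interaction endpoints"),
    list(kind = "contour", needs = "interactions", any_of = NULL,
         description = "smoothed 2D density contours of interactions"),
    list(kind = "distance-histogram", needs = c("interactions", "tertiary"),
         any_of = NULL,
         description = "3D contact distances of interactions vs background"),
    list(kind = "regression-kde", needs = "profile", any_of = NULL,
         description = "profile-vs-profile kernel density with regression"),
    list(kind = "windowed-auroc", needs = c("profile", "structure"),
         any_of = NULL,
         description = "windowed paired/unpaired classification AUROC track"),
    list(kind = "deltashape-panel", needs = "profile", any_of = NULL,
         description = "smoothed reactivity difference with detected sites"),
    list(kind = "lowss-panel", needs = c("profile", "interactions"),
         any_of = NULL,
         description = "stacked windowed reactivity/entropy with lowSS shading and arcs"),
    list(kind = "alignment-overview", needs = character(0),
         any_of = c("profile", "structure", "interactions", "tertiary",
                    "annotations"),
         description = "aligned-block overview between two samples' sequences"),
    list(kind = "annotation-track", needs = "annotations", any_of = NULL,
         description = "annotation spans along the sequence"),
    list(kind = "consensus-summary", needs = "structure", any_of = NULL,
         description = "pie summary of base-pair support across models"),
    list(kind = "profile-difference", needs = "profile", any_of = NULL,
         description = "per-nucleotide difference between two profiles")
  )
  kinds
}

#' List supported plot kinds
#'
#' @return Data frame with columns `kind` and `description`, in stable
#'   registry order.
#' @examples
#' nrow(list_plot_kinds())
#' @export
list_plot_kinds <- function() {
  reg <- plot_registry()
  data.frame(kind = vapply(reg, `[[`, "", "kind"),
             description = vapply(reg, `[[`, "", "description"),
             stringsAsFactors = FALSE)
}

data_role <- function(obj) {
  switch(class(obj)[1],
         Profile = "profile",
         SecondaryStructure = "structure",
         InteractionSet = "interactions",
         TertiaryStructure = "tertiary",
         Annotation = "annotations",
         SequenceRecord = "sequence",
         NA_character_)
}

sample_roles <- function(sample) {
  roles <- vapply(sample$store, function(obj) {
    if (is.list(obj) && !inherits(obj, c("Profile", "SecondaryStructure",
                                         "InteractionSet",
                                         "TertiaryStructure", "Annotation",
                                         "SequenceRecord")) &&
        all(vapply(obj, inherits, TRUE, "Annotation"))) {
      return("annotations")
    }
    data_role(obj)
  }, "")
  unique(roles[!is.na(roles)])
}

#' Plot kinds renderable from a sample's data
#'
#' Returns exactly the plot kinds whose declared data requirements are
#' satisfiable from the sample's store (sorted, deduplicated).
#'
#' @param sample A [create_sample()] object.
#' @return Character vector of plot-kind tags.
#' @export
plot_options <- function(sample) {
  roles <- sample_roles(sample)
  ok <- vapply(plot_registry(), function(k) {
    all(k$needs %in% roles) &&
      (is.null(k$any_of) || length(k$any_of) == 0L ||
         any(k$any_of %in% roles))
  }, TRUE)
  sort(unique(vapply(plot_registry()[ok], `[[`, "", "kind")))
}
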