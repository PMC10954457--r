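# rnaprobr

Integrative exploration of RNA chemical probing data in R.

Chemical probing experiments read out by mutational profiling (SHAPE-MaP,
DMS-MaP and relatives) produce several layers of structural information at
once: per-nucleotide reactivities, correlated single-molecule events
(RINGs and PAIRs), partition-function pairing probabilities, and secondary
and tertiary structure models — each arriving in its own file format.
rnaprobr is for RNA structure researchers who need to read those formats,
put the layers on one transcript coordinate system, run the
community-standard analyses, and draw the community-standard pictures,
without writing parsers or plotting code.

## What it does

- **Parses 21 standard input formats** (FASTA; CT and dot-bracket with
  pseudoknot bracket layers; VARNA/XRNA/FORNA/R2DT/NSD drawing files; PDB
  and mmCIF; ShapeMapper-style profiles, `.map`, `.shape`, RNA-Framework
  XML, ensemble reactivity tables, WIG; RING/PAIR correlation tables and
  pairing-probability dotplots; BED/narrowPeak and GFF/GTF) into five
  transcript-centric data classes, grouped per condition in a `Sample`.
- **Aligns data across sequences**: an end-gap-free global pairwise
  alignment (match +1, mismatch −1, gap open −5, gap extend −1; T≡U)
  yields a strictly monotone position map over which profiles, structures,
  annotations and interactions are transferred without inventing values.
- **Automated analyses**: reactivity normalization; centered windowed
  medians; per-nucleotide Shannon entropy
  s_i = −Σ_j p_ij·log10(p_ij) from pairing probabilities; **lowSS
  detection** (regions where the 51-nt windowed median reactivity < 0.4
  and windowed median entropy < 0.15); **deltaSHAPE** (smoothed
  differences with Z-factor 1 − 1.96(e_a+e_b)/|d| and standard-score
  site calling); **windowed AUROC** of reactivity as a paired/unpaired
  classifier; inter-profile regression with Pearson r; pair-by-pair
  structure-model comparison (correct/incorrect/missing, sensitivity,
  PPV); multi-model **consensus base pairs** with per-pair support counts;
  interaction filtering by statistic, sign, class, region, top-k and 3D
  contact distance (O2′ atoms, C1′ fallback).
- **Renders 18 plot kinds** — bar and skyline profiles, arc and circle
  plots, structure diagrams, molecular projections with cylinder exports,
  density heatmaps, contours, distance histograms, regression KDEs, AUROC
  and deltaSHAPE panels, lowSS panels, alignment overviews, annotation
  tracks, consensus summaries — each with a machine-readable layout
  report (arc centers (i+j)/2 and radii (j−i)/2, circle angles 2πk/n, …)
  so analyses built on figures are testable.
- **Generates its own synthetic dataset**: a designed toy RNA (hairpins +
  pseudoknot, separated paired/unpaired reactivity distributions,
  concentrated pairing probabilities, helical 3D coordinates, a 2-exon
  parent gene) written in every supported format, byte-identical per seed.

## Worked example

```r
library(rnaprobr)

dir <- tempfile()
generate_fixture(fixture_spec(seed = 1, n = 120), dir)

s <- create_sample("in_cell", list(
  profile = list(path = file.path(dir, "toy_profile.txt"),
                 format = "shapemapper-profile"),
  ss      = list(path = file.path(dir, "toy.ct"), format = "ct"),
  dp      = list(path = file.path(dir, "toy.dp"), format = "pairprob-dp")))
s
#> <Sample> in_cell - 3 data objects
#>   $profile: Profile
#>   $ss: SecondaryStructure
#>   $dp: InteractionSet

plot_options(s)   # which plot kinds this sample supports
#>  [1] "alignment-overview" "arcs"               "arcs-compare" ...

prof <- get_data(s, "profile")
ent  <- shannon_entropy(get_data(s, "dp"))
find_lowss(prof, ent, lowss_params())
#>   index start end
#> 1     1     1  55
```

The single reported region covers the structured 5' half of the toy RNA:
its paired nucleotides draw low reactivities and its pairing probabilities
are concentrated on the true helices, so both 51-nt windowed medians fall
below the 0.4 / 0.15 thresholds there and nowhere else.

```r
track <- windowed_auroc(prof, get_data(s, "ss"))
mean(track$values, na.rm = TRUE)
#> [1] 0.989      # reactivity separates paired from unpaired nucleotides

out <- render(plot_request("arcs", s), path = file.path(dir, "arcs.svg"))
head(out$layout$arcs[, 1:5], 3)
#>   i  j center_x radius track
#> 1 6 21     13.5    7.5 above
#> 2 7 20     13.5    6.5 above
#> 3 8 19     13.5    5.5 above
```

Every drawn element appears in the layout report in data coordinates —
the first helix pair (6, 21) is the semicircle centered at 13.5 with
radius 7.5.

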