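---
title: "Analyzing RNA chemical probing data with rnaprobr"
author: "rnaprobr maintainers"
output: rmarkdown::html_vignette
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

Chemical probing experiments (SHAPE, DMS, and related reagents read out by
mutational profiling) measure RNA structure at several levels at once:
per-nucleotide adduct rates report local flexibility; correlated
modifications on single molecules (RINGs and PAIRs) report through-space
communication; partition-function pairing probabilities and secondary /
tertiary structure models provide computational context. rnaprobr
organizes all of these into five transcript-centric classes —
`SequenceRecord`, `Annotation`, `SecondaryStructure`,
`TertiaryStructure`, `Profile`, `InteractionSet` — grouped per
experimental condition in a `Sample`. Every coordinate in the package is
1-based and inclusive; BED's 0-based half-open convention is converted at
the file boundary and nowhere else. T and U compare equal everywhere, and
sequence comparison is case-insensitive, because DNA-alphabet inputs are
common upstream.

A deliberate container choice: readers for formats that carry no sequence
(dotplots, `.shape` tables, BED, WIG) synthesize an all-N placeholder
record of the right length. Within a sample, placeholders adopt a sibling
object's real sequence of identical length, and downstream precondition
checks treat an all-N record as matching any equal-length sequence. This
keeps the strict same-sequence precondition for real sequences while not
refusing files that simply cannot state theirs.

# Position mapping

Comparisons across conditions routinely involve slightly different
sequences (primer trimming, construct tags, variants). `align_positions()`
builds a strictly monotone partial map between two sequences from a
pairwise alignment with match +1, mismatch −1, gap open −5, gap extend −1,
and free end gaps in both sequences. The scores are declared rather than
inherited from any particular aligner, and they are overridable; the
defaults favor contiguous near-identity blocks, which is the geometry of
probing comparisons.

Two implementation notes worth recording. First, with end gaps free in
*both* sequences the optimal alignment is exactly the best single
affine-gap local segment: terminal gaps cost nothing, so an optimal
alignment never extends into negative-scoring ends, and Smith–Waterman
(`Biostrings::pairwiseAlignment(type = "local")`) computes the end-gap-free
global optimum. The test suite verifies this equivalence against an
exhaustive alignment enumerator on small random sequences. Second, among
co-optimal alignments the traceback is Biostrings' deterministic choice; we
test determinism (identical inputs give identical maps) rather than a
specific tie-break order. Identical sequences short-circuit to the
identity map without running the aligner.

`map_data()` carries each class across a map: profile values move to their
mapped positions (unmapped targets become no-data, and no value is ever
invented); annotation spans are clipped to their mapped extent; base pairs
and interaction records survive only if both endpoints map. Interaction
records with a lost endpoint are *masked out but retained*, preserving the
invariant that filtering and mapping never delete records.

# Per-nucleotide analyses

**Normalization.** Two community-standard schemes are provided. The
boxplot scheme removes outliers above Q3 + 1.5·IQR (capped at 10% of the
data) and divides by the mean of the top 10% of what remains; the
percentile scheme divides by the mean of values between the 90th and 99th
percentiles. Both require at least 10 valid values — below that the factor
is statistically meaningless and the function refuses.

**Windowed medians.** Centered windows, default 51 nt (odd by
construction). No-data positions are excluded from each window rather than
propagated, and an all-no-data window yields no-data. Two edge policies
exist: `truncate` (default; windows shrink near the ends) and `nodata`.

**Shannon entropy.** From pairing probabilities,
$s_i = -\sum_j p_{ij}\log_{10} p_{ij}$, summed over recorded partners of
$i$ in either orientation; positions with no recorded partner have
$s_i = 0$. Base-10 is used because the conventional 0.15 low-entropy
threshold is defined on that scale. The unpaired-probability term is
excluded: dotplot files record pairs only, so including it would require
inferring $1-\sum_j p_{ij}$ from incomplete content.

**lowSS regions.** A position is "low" when its 51-nt windowed median
reactivity is below 0.4 *and* its windowed median entropy is below 0.15
(both strict, matching "below"). Maximal runs of low positions become
regions numbered 5′→3′. Region boundaries are reported at window centers —
the shaded region is the set of positions whose windows pass, not the
union of window extents; the alternative reading widens every region by
half a window and is less faithful to the per-position definition. By
default no run merging occurs (`merge_gap = 0`); a merge gap is available
because published analyses sometimes bridge 1–2 nt interruptions, but a
default of zero is the least surprising rule.

**deltaSHAPE.** Values and errors of both profiles are smoothed over
centered 5-nt windows (errors combined as $\sqrt{\sum e^2}/n$). The
difference $d_i$ receives a Z-factor $1 - 1.96(e_a + e_b)/|d_i|$ and a
standard score from the distribution of $d$. A site requires Z-factor > 0
and |standard score| ≥ 1 at 3 of 5 consecutive positions; all five
constants are arguments.

**Windowed AUROC.** Within each window, the AUROC of reactivity
classifying unpaired (positive class) versus paired nucleotides, ties
counted ½ (the Mann–Whitney convention, which makes the rank-based
implementation testable against exhaustive pair counting). Windows missing
either class give no-data rather than a fabricated 0.5.

# Internucleotide analyses

Filtering criteria (statistic bounds, sign, PAIR class, region, 3D
distance, top-k) compose conjunctively, and the mask is recomputed from
scratch on each call, which makes filtering idempotent by construction.
3D distances use O2′ atoms with a C1′ fallback — a ribose-centric
convention appropriate for backbone-adduct proximity; both atom names are
parameters.

Structure-model comparison labels each pair correct / incorrect / missing
by exact (i, j) identity; sensitivity = correct/(correct+missing), PPV =
correct/(correct+incorrect), with undefined ratios reported as NA rather
than 0. A ±1 slip mode exists but is off by default and off for every
number the package reports. Consensus across k models counts per-pair
support over the union of all models' pairs; the "fraction shared by all"
uses that union as denominator — the only reading under which a single
percentage is well-defined without privileging one model.

Density heatmaps bin interaction endpoints by integer division of the raw
position (`p %/% bin_size`), so positions 10 and 12 share a bin of width
5; total mass always equals the filter pass count, which the tests assert
on random inputs.

# Rendering

Every plot kind returns, besides the figure, a layout report enumerating
each drawn element in data coordinates: arcs as (i, j, center (i+j)/2,
radius (j−i)/2), circle-plot nucleotides at angle 2πk/n, structure-diagram
glyphs at their drawing coordinates, molecule cylinders at the contact
atoms. Tests assert on these reports, never on pixels. Color assignment is
a pure function of value and breakpoints (reactivity defaults 0.4/0.85).
Pairing-probability arcs use discrete bins (≥0.8, 0.6–0.8, 0.3–0.6,
0.1–0.3; below 0.1 not drawn) — a community-standard quantization chosen
because a continuous ramp is unreadable at arc-plot line widths. The
18-kind roster and the per-kind data requirements live in one registry
that also backs `plot_options()`.

Drawing-file dialects are parsed for sequence, pairs and coordinates only.
For XRNA the public `NucListData`/`BasePairs` XML layout is supported; for
VARNA a minimal XML schema (documented in the reader); for R2DT only the
nucleotide-coordinate JSON layout (other sub-schemas are rejected with an
explicit message); NSD uses a simplified StructureEditor-style text
section format. Dot-bracket output assigns pseudoknot layers by greedy
coloring of the pair-crossing graph and refuses structures needing more
than the four bracket families.

# The synthetic dataset

`generate_fixture()` writes one file per supported input format for a
designed toy RNA, so the whole package exercises with zero downloads. The
generative conditions are fixed as defaults: a 120-nt transcript (300 nt
in the acceptance script, sized to keep the full run in seconds) with
hairpins in the 5′ half, an H-type pseudoknot linking the first hairpin
loop to the 3′ tail, log-normal reactivities with meanlog log(0.1) for
paired and log(0.9) for unpaired positions (sdlog 0.6 — overlapping, so
reactivity separates pairing status well but not perfectly), pairing
probabilities of 0.95 inside helices, 0.65 at helix ends (with 0.08
slipped alternatives) and weak scattered pairs in the tail, RING records
jittered around true pairs plus a loop–loop tertiary contact and a few
negative-correlation decoys, idealized A-form-like helical 3D coordinates,
and a 2-exon parent gene embedding the transcript in a toy genome. The
same seed yields byte-identical files.

What the fixture does *not* emulate: sequence-dependent reactivity biases,
read-depth-dependent error structure, ambiguous or noncanonical pairs,
multi-chain complexes, and real drawing layouts. Green tests therefore
demonstrate correctness of the computations and formats, not robustness to
every pathology of real probing data.

# Numerical and degenerate-input choices

The sentinel −999 and non-numeric entries become no-data on read; no-data
is excluded from every statistic rather than zero-filled. Malformed
trailing lines fail loudly — probing files are machine-generated, so
corruption means upstream failure, and silent truncation would be worse
than an error. CT partner asymmetry is an integrity error naming both
positions. Probabilities outside (0, 1] are errors; dotplot −log10 values
round-trip to 1e−9 over [0, 9]. Empty interaction masks produce empty
histograms, not errors; a predicted structure with no pairs yields PPV =
NA. Windows are required odd so "centered" is exact.

# Testing strategy and problem sizes

Each statistic is verified against an independent naive oracle
(sort-and-middle medians, exhaustive AUROC pair counting, direct entropy
summation, set-enumeration pair classification and consensus, exhaustive
toy alignment) over thousands of randomized small instances under fixed
seeds, plus frozen hand-computed cases. The default suite uses transcripts
of 80–300 nt and oracle instances of 5–60 nt; these sizes were chosen so
the whole suite runs in well under a minute while still crossing every
window-edge and mask-interaction code path.

# Known limitations

Local alignment as a user-facing mode, multiple alignment, partition
function computation, ensemble deconvolution and structure prediction are
out of scope — upstream tools produce those inputs. The WIG reader assumes
the track is on transcript coordinates (or is transferred through
`extract_transcript()`'s genome-to-transcript map). Only the first model
of multi-model coordinate files is used. Figures are static exports; the
molecule renderer emits a viewer-ready export (atoms, per-nucleotide
colors, cylinder endpoints) rather than an interactive widget.
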