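---
title: "Models and methods behind capture3C"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind capture3C}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The assay and what the package computes

Chromosome conformation capture (3C) crosslinks chromatin, digests it with a
restriction enzyme, and religates free ends so that fragments that were
spatially close in the nucleus become covalently joined. The ligation
frequency between two restriction fragments is then a proxy for their
nuclear proximity. Capture-C-family protocols enrich a sequencing-ready 3C
library for molecules containing selected *viewpoint* fragments with
biotinylated oligonucleotide probes, and come in three flavours:

* **Capture-C** — disperse single-fragment viewpoints, pairwise interaction
  profiles;
* **Tri-C** — viewpoints on short (~150–250 bp) fragments with gentler
  sonication (~450 bp fragments), so single reads span multiple ligation
  junctions and witness multi-way contacts at single alleles;
* **Tiled-C** — contiguous probe panels over a region, giving a Hi-C-like
  binned contact matrix at restriction-fragment resolution.

capture3C implements everything computational around these assays: the
restriction map, probe design, digestion QC, the read-to-profile pipeline,
contact matrices, and a generative simulator that makes every stage testable
against ground truth.

# Coordinate and cut-placement conventions

All coordinates are 0-based half-open (BED-compatible). A cut assigns the
intact recognition motif to the *downstream* fragment for DpnII
(`before_site`: every internal fragment begins with `GATC`) and to the
*upstream* fragment for NlaIII (`after_site`: every internal fragment ends
with `CATG`). This mirrors sticky-end religation: a religated junction
between two fragments regenerates exactly one intact motif, so in-silico
digestion of a chimeric read splits it at precisely the positions where
reference fragments abut. Reference map and read digestion share one code
path for motif scanning, which is what makes slice-to-fragment assignment
exact. `N` bases never match a motif; reference assembly gaps therefore stay
inside fragments, a choice the package makes explicitly (no convention
exists in the protocol literature).

# Read processing

The FASTQ-to-slices stage is a composition of three operations.

**Exact duplicate removal.** Deeply sequenced capture libraries are 25–50%
PCR duplicates. At the FASTQ level, duplicates are exact copies, so the
filter keys on the exact `(R1, R2)` sequence pair and keeps first
occurrences. Collision-tolerant hashing is deliberately not used — the
contract is exact identity.

**Overlap merging.** Sonication fragments (~200 bp) are shorter than the
sum of two 150-bp reads, so mates usually overlap. Merging scans every
alignment of the 3' end of R1 against the reverse complement of R2 and
accepts the longest overlap of ≥ 10 bp with ≤ 25% mismatches, resolving
disagreements to the higher-quality base. These defaults follow the
established overlap-merging tools for this read geometry. The stage is
implemented natively (a small C++ kernel) rather than shelled out, so it is
unit-testable against an all-offset brute-force oracle.

**In-silico digestion.** Each merged read (or mate, for unmerged pairs) is
split at every internal motif occurrence under the same convention as the
reference map. A read without a motif yields one slice — legitimate, since a
sonication fragment can lie wholly inside the viewpoint fragment. Slices
shorter than 18 bp are kept (so concatenating slices always reconstructs the
read exactly) but flagged unmappable. Qualities are carried but never used
for filtering; the protocol defines none.

# Alignment, classification, deduplication

The built-in mapper performs unique exact matching: a slice maps only if its
sequence occurs exactly once in the genome over both strands
(seed-and-verify with 20-bp seeds via an Aho–Corasick dictionary).
Multi-hits become unmapped, which is the conservative choice for repeat
loci. Production data can be routed through any external aligner via a
subprocess adapter (FASTQ in, SAM out; only name, flag, position and
CIGAR-derived end are consumed); alignments under MAPQ 30 are treated as
unmapped to guard against mismapping-driven trans inflation.

Each mapped slice is assigned to the restriction fragment with the largest
overlap (ties go to the fragment containing the slice midpoint — slices can
straddle a boundary when a junction motif is disrupted by a sequencing
error), then classified exactly once:

* `capture` — the slice's fragment is a viewpoint fragment (or any
  in-region fragment in tiled mode);
* `exclusion` — within the viewpoint fragment ± 1 kb (default): religation
  back into the original conformation produces capture-adjacent slices that
  would otherwise masquerade as strong proximal signal. The window size is
  configurable; 1 kb follows predecessor pipelines, as the protocol
  describes the artefact but no distance. Tiled mode has no exclusion
  class — contiguous tiling enriches all in-region fragments equally;
* `reporter` — mapped, neither of the above: the informative signal.

A read group (all slices of one molecule) is informative when it has at
least one capture and one reporter slice (tiled: two distinct in-region
fragments). Coordinate-level deduplication then exploits sonication ends:
the key is the sorted tuple of all mapped slice coordinates of the group,
so identical fragment *content* with different shear points survives while
true PCR duplicates (identical molecule boundaries) collapse. The full
tuple is stricter than outer-ends-only; we chose it deliberately. A read
containing capture slices from several viewpoints is reported once per
viewpoint rather than discarded; the count of such reads is retained.

# Quantification

Per viewpoint, every reporter slice of every unique informative group
increments its fragment's count (per slice, not per fragment-per-read: a
molecule ligating the same fragment twice is two observed ligation events).
Counts split into cis (viewpoint contig) and trans. Tracks are normalised
**in cis**: fragment signal = count × 100,000 / total cis reporters.
Normalising to cis rather than to total reporters prevents sample-specific
trans noise from deflating proximal signal in comparisons; the constant
100,000 matches the order of cis reporters in a high-quality library and is
configurable. Replicate means average the *normalised* signal (absent
fragment = 0), and comparative tracks are signed differences of sample
means. Signal lives on whole restriction fragments, emitted as one bedGraph
interval per fragment.

# Contact matrices

Tri-C: per informative group containing the viewpoint, every unordered pair
of in-region reporter slices increments its bin pair once — k reporters
contribute choose(k, 2) increments, and two reporters in one bin land on
the diagonal. Exclusion-class slices are ignored. Tiled-C counts every
unordered pair of *distinct* in-region fragments per group (Hi-C-like
semantics over all pairs, not only adjacent junctions — the tiled map is
the analogue of a Hi-C matrix, and this choice follows that reading).
Default bins: 5 kb for tiled (the resolution the recommended depth
supports), 1 kb for Tri-C over a user region centred on the viewpoint (no
bin size is prescribed for Tri-C anywhere; 1 kb resolves fragment-scale
structure). Bins are half-open, aligned to the region start; the final
partial bin is kept and flagged. Iterative correction (ICE) balances tiled
matrices: bins with zero marginal are masked, then the matrix is scaled by
the outer product of its normalised marginals until every unmasked row sum
is within 1e-5 of the mean (at most 100 iterations). Raw matrices are
always emitted alongside.

# Probe design

Three layouts, probes always on the + strand at 70–120 bp (default 120):
capture viewpoints get a pair flush with the two fragment ends (each
overlapping a digestion site), Tri-C gets one probe centred at
`floor((len − L)/2)`, tiled regions get the capture pair per contained
fragment with sub-probe-length fragments skipped. Candidate filters follow
standard capture-design practice: GC ≤ 60%, genome-wide exact duplicates
≤ 2 (both strands), similarity density ≤ 40, no repeat-masked bases.
"Similarity density" is a package-defined proxy for a BLAT-hit density
score: total bases of all maximal exact matches of the probe's 20-mers
elsewhere in the genome, divided by probe length. It penalises dispersed
homology without an external aligner and is documented as a proxy, with the
same ≤ 40 threshold. Repeats are read from FASTA soft-masking rather than
running RepeatMasker; unmasked genomes give 0 with a logged caveat. Both
probes of a pair are emitted with pass flags — whether one passing probe
suffices (at lower depth) is left to the user. Co-capture checking flags
same-contig viewpoint pairs closer than 5 Mb (the bias is described
qualitatively in the literature; 5 Mb is a deliberately generous default)
so users can split pools.

# Digestion QC

Digestion efficiency comes from qPCR with a primer pair spanning a cut site
and a pair inside a fragment, on undigested (Control 1) and
digested-unligated (Control 2) material:

$$\Delta CT_s = CT_s^{cut} - CT_s^{frag},\qquad
  \Delta\Delta CT = \Delta CT_{C1} - \Delta CT_{C2},\qquad
  E = 100\,(1 - 2^{\Delta\Delta CT})$$

Replicates are averaged as plain means (no outlier rejection — none is
specified anywhere). The pass threshold is strict (> 70%): capture
experiments do not select for digestion-ligation success, so a poorly
digested library wastes reads. Negative efficiencies are reported with a
warning, never clamped — they indicate swapped samples. The low-input
variant (genomic DNA for C1, the 3C library for C2) is accepted with a
caveat that religation depresses the apparent efficiency. The validated
human/mouse/fly primer panel ships as package data.

# The simulator

`simulate_reads()` is generative and fully bookkept. Per molecule it builds
a ligation concatemer: the viewpoint fragment plus K reporters, K shifted
Poisson with mean 1.2 (capture; 2.5 for Tri-C), each reporter trans with
probability 0.2 or drawn in cis with probability ∝ d^(−1) (distance decay;
the exponent is a free parameter — no quantitative polymer model is implied
by the protocols). Units take random orientations and every junction
regenerates the recognition motif per the enzyme convention, so in-silico
digestion splits simulated reads at exactly the constructed positions and
every slice is an exact copy of a genome locus. A sonication window
(Normal, mean 200 bp / sd 50 for capture, 450/80 for Tri-C) covering the
viewpoint junction with ≥ 25 bp margin is drawn, a 150-bp read pair is
emitted from its ends, substitution errors applied (default 0), and PCR
duplicates appended so that the configured rate (default 0.3, matching the
25–50% seen in deep libraries) is the duplicate fraction of the final pool.
`duplicate_mode = "coordinate"` instead re-sequences the same sonication
window with independent errors, producing duplicates only the
coordinate-level filter can catch.

Reporter eligibility excludes (i) terminal contig fragments (no motif
boundary), (ii) fragments within 1 kb of the viewpoint (they would fall in
the pipeline's exclusion window — the simulator does not model religation),
and (iii) fragments shorter than 30 bp, which cannot yield a mappable slice
(20-bp mapper seed) and are therefore unobservable by construction. The
planted truth distribution is defined over this eligible set and sums to 1.

**What the defaults represent.** The synthetic genome is i.i.d. sequence at
GC 0.5 over three contigs (500/300/200 kb), giving 4-cutter sites every
256 bp in expectation — realistic fragment sizes, with the two spare
contigs as the trans pool. A 500-kb viewpoint contig corresponds to the
window over which capture profiles are typically interpreted. Tests and the
acceptance script run 200,000 molecules for the deep recovery check
(~1 minute), 10,000 for duplicate accounting, 1,000–2,000 for structural
checks; these sizes were chosen so each check's sampling noise is well
inside its tolerance.

**What it does not emulate.** No capture-efficiency or hybridisation model
(every molecule is "captured", so simulated capture fractions are ~100%,
versus 80–98% of mapped reads in real libraries); no religation or partial
digestion (real reporter-given-capture is 60–80%, clean simulations sit
near 100%); no indels, adapters or quality decay; no polymer physics beyond
the single decay exponent. Passing tests therefore demonstrate that the
pipeline measures what the generator planted — correctness of the
machinery, not realism of any biological conclusion.

**A sequencing-geometry limitation.** With 450-bp Tri-C sonication
fragments and 150-bp paired-end reads, the middle ~150 bp of each fragment
is never sequenced, which caps the mean number of visible reporter slices
per informative read near 1.9 for any window-placement scheme. The suite
therefore validates Tri-C multi-way yield against the simulator's own
visibility bookkeeping (agreement within ±0.1) rather than against a fixed
absolute yield; longer reads would raise it.

# Numerical and degenerate-input choices

Ties in overlap merging go to the longest, then leftmost overlap. Fragment
assignment ties go to the midpoint fragment. Zero cis reporters yield an
empty track plus a warning rather than an error. An all-zero matrix passes
through ICE unchanged with a warning. Empty FASTQ input produces zeroed
statistics, not failures. All randomness flows from a single integer seed
through a private RNG stream that restores the caller's `.Random.seed`.

# Pipeline orchestration

`run_pipeline()` drives everything from one validated YAML config
(unknown keys rejected, all errors listed together). Replicates are grouped
by the `<sample>_rep<N>` filename convention; per-replicate tracks, per-
sample means, a subtraction track when exactly two sample groups exist,
tri/tiled matrices, QC JSON and relative-path UCSC hub stanzas are written
deterministically — reruns are byte-identical. The
`inst/scripts/capture3C` Rscript exposes the subcommands
(`digest-genome`, `design-probes`, `qc-digestion`, `simulate`, `process`,
`matrix`, `plan-depth`, `report`) as a thin shell over these functions.
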