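---
title: "Models and methods behind plastomeDCAPS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind plastomeDCAPS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastomeDCAPS)
```

# The problem

Chloroplast genomes of closely related cultivars are 99.7–99.99% identical,
circular, ~160 kb, and quadripartite: a large and a small single-copy region
(LSC, SSC) separated by two identical inverted repeats (IRb, IRa). Because
plastomes are maternally inherited, any cultivar-specific variant is a
marker for maternal parentage. This package turns such a variant — typically
a short InDel or SNP found by whole-plastome comparison — into a CAPS/dCAPS
assay: a PCR product whose restriction digest differs between alleles.

This vignette records the models, conventions, parameter defaults, and the
genuinely open design choices, in the package's own words. Every number
shown here is computed by the package's tests or acceptance script; nothing
is asserted that the code does not itself reproduce.

# Coordinates and sequence model

All internal coordinates are 1-based inclusive, the R/Bioconductor and
GenBank convention; `IRanges` arithmetic and GenBank locations are used
as-is with no conversion layer. The one exception is restriction *cut
points*, which are reported as "number of bases 5' of the scission", so a
cut between bases 2 and 3 is position 2 — the natural coordinate for
fragment arithmetic (`diff(c(0, cuts, length))`).

Sequences are uppercase DNA over `{A,C,G,T,N}`; `U` is mapped to `T` on
input so tRNA-derived records and primers share one alphabet, and degenerate
IUPAC codes other than `N` are collapsed to `N` in stored genomes (enzyme
recognition sites, by contrast, keep their full IUPAC alphabet). Circular
records store the sequence linearized at the deposited origin; rotation is
always an explicit operation, never implicit.

# Quadripartite detection

Inverted repeats are detected by exact matching only: 25-mers of the
(doubled, for circular inputs) sequence are hashed against its reverse
complement, consecutive seed matches along anti-diagonals are merged into
maximal runs, and the longest non-overlapping pair on the circle is
returned. Exact matching is the right model here because within-genome IR
copies of the target genomes are literally identical; tolerating mismatched
IRs is deliberately out of scope. Ties are broken by maximizing the shorter
single-copy segment, then by lowest start coordinate, so the output is
deterministic. The default `minLen = 1000` reflects real plastome IRs
(tens of kb); the synthetic toys in the test suite use 50.

The two single-copy segments between the IR copies are labeled SSC
(shorter) and LSC (longer); at exact equality the first-encountered segment
becomes the LSC, with a warning. IRb is defined as the IR copy immediately
downstream of the LSC. Canonical rotation places the LSC start at
position 1; if *rps19* is annotated, the orientation is flipped when needed
so that it sits near the LSC/IRb junction, the conventional plastome
orientation.

Junction–gene distances are signed: 0 means a gene end coincides with a
boundary, positive is the distance from the nearest gene end to the
boundary, and negative means the gene straddles the boundary, extending
|d| bp into the region on its minority side. Because published reports
sometimes measure from the gene's 5' start instead of its nearest end, the
report carries both columns (`distance`, `distance_gene_start`) rather than
guessing which convention a reader expects.

# Pairwise alignment and comparison statistics

The aligner is a global unit-cost alignment: match 0, mismatch 1, gap 1 per
column. Short inputs (≤ 20 kb combined) go straight to the full dynamic
program; long near-identical genomes are anchored on shared *unique* 31-mers
(colinearized by longest-increasing-subsequence, greedily thinned to
non-overlapping anchors) and the full DP runs only between consecutive
anchors. For genomes that are > 99% identical the true differences always
fall between anchors, so the result attains the unrestricted optimum — the
test suite verifies score equality against an independent edit-distance
oracle up to 8 kb. Among equal-cost alignments, a 10⁻³ gap-opening tiebreak
prefers contiguous gap runs, so a planted 3-bp insertion is reported as one
event rather than split fragments; this perturbation is too small to ever
change which alignments are optimal at integer unit costs.

Identity is **gap-excluded**: `100 · match / (match + mismatch)`, rounded
half-up to two decimals. This is the convention that makes a 161-kb pair
with 12 substitutions and 20 gap positions report 99.99% (mismatch-only
error ≈ 0.0075%), where a gap-inclusive ratio would print 99.98. Gap
columns are counted in bp (the primary figure) with gap-opening events
reported alongside, since both conventions appear in the literature.

Specimen-specific variants are extracted from an N ≥ 3 multiple alignment
at assembly level: a column belongs to an event when exactly one row
disagrees with the unanimous consensus of all others; maximal runs of the
same (specimen, kind) merge into single events; one row holding bases
against all-gap rows is an insertion, the converse a deletion. Columns
where two or more rows disagree are *ambiguous*, counted and reported but
never silently dropped. This consensus logic deliberately replaces
read-level evidence thresholds (read depth, base quality), which do not
exist at assembly level; that semantic difference is the main caveat when
comparing counts with read-based callers.

# In-silico PCR

Primer binding is seeded by the 3'-terminal 12-mer (≤ 1 mismatch), then
scored over the full footprint (≤ 3 mismatches by default). The best site
per primer must beat the runner-up by ≥ 2 mismatches, otherwise binding is
reported as ambiguous — a deterministic, explainable failure rather than an
arbitrary choice. Circular templates are searched across the origin. The
amplicon spans the two primer 5' ends and its footprints carry the *primer*
sequences: deliberate primer–template mismatches propagate into the
product. That propagation is the entire dCAPS mechanism, which is why the
simulation models it and nothing thermodynamic (efficiency, dimer dropout
and multiplexing are out of scope).

# Restriction digestion and the overhang question

Fragment lengths are defined by top-strand scissions: k cuts give k + 1
fragments that sum to the amplicon length, and overhang geometry is stored
but does not change duplex lengths — gel mobility tracks duplex length.

MluCI, the enzyme of the bundled assay, recognizes AATT and cuts *before*
the first A on both strands, leaving 4-nt 5' overhangs (it is sometimes
mis-described as blunt-cutting). For the insertion-allele amplicon of the
bundled assay this matters: the single junction site at duplex coordinates
gives fragments 105 + 32, while counting both strand nicks reads the same
molecule as 105 + 28 + 4 — the "4-bp fragment" being the single-stranded
overhang stretch between the two nicks, predicted invisible on a gel. Both
accountings describe one physical digestion; `digestAmplicon()` defaults to
duplex semantics and exposes `bothStrands = TRUE` for the nick-level
accounting, and the bundled marker's genotype matching tolerates either
(the band tolerance of ±10% with a 5-bp floor absorbs the 4-bp difference).

# dCAPS design

The design space is enumerated exhaustively rather than heuristically,
which is feasible because it is small: for each enzyme, each site
orientation, each template strand, each allowed mismatch-primer 3' end
(within `max3PrimeDist = 10` bp of the variant, on the shared flank), and
each placement of the recognition site overlapping both the primer
footprint and the variant, the algorithm asks whether ≤ `maxMismatches`
(default 1) primer base changes make the site match one allele's amplicon
while the other allele's native sequence fails it. Because primer bases are
shared between alleles, discrimination reduces to a clean condition on the
non-primer window positions of each allele. A variant that completes a site
natively needs zero changes — the degenerate design is a plain CAPS marker.

Each hit becomes a concrete primer pair: the mismatch primer's length is
chosen from 18–35 nt to bring its nearest-neighbor Tm closest to the 60 °C
target (within a 50–68 °C window), and a mismatch-free opposite primer is
placed in the shared flank to satisfy the 60–400 bp product range.  Every
candidate is then re-simulated end to end (PCR on both alleles, digestion,
fragment multisets) and rejected unless the allele band sets are separable
by at least the 5-bp gel-resolution floor. Constitutive sites elsewhere in
the amplicon are allowed and simply appear in the predictions. Ranking:
fewest introduced mismatches, then non-terminal mismatch placement
(3'-terminal mismatches destabilize extension, so designs with the edit one
base in are preferred, though terminal edits are permitted — published
assays use them), then largest discriminating fragment difference, then Tm
closeness. Soundness (every emitted marker re-simulates to its own
predictions) and completeness (the search finds a design whenever brute
force over the same space does) are both property-tested against
independent oracles.

For InDels the recognition site may span the inserted bases themselves —
in the bundled assay the insertion contributes the second A of AATT while
the reverse primer's terminal edit contributes the first T. The design
orientation loop handles sites completed on either strand.

# Primer QC

Tm uses the unified nearest-neighbor duplex parameters with terminal
initiation terms, the entropic salt correction 0.368 (N−1) ln[Na⁺], and the
CT/4 symmetry term (CT for self-complementary oligos, which also take the
symmetry entropy). Defaults: 50 mM monovalent cation, 250 nM total oligo —
standard PCR conditions. Frozen reference values in the tests come from an
independent implementation run at identical parameters. Hairpin potential
is summarized as the longest reverse-complementary run between two
non-overlapping primer segments; dimer potential as the longest
complementary run anchored at either 3' terminus against the partner (or
self). These are the secondary-structure screens a designer applies by eye,
made explicit; full folding thermodynamics is out of scope.

# Genotyping

Full-length samples are genotyped by simulation: PCR + digestion, then
fragment-multiset matching against the marker's per-allele predictions
within ±10% (5-bp floor). Short printed windows — the form panel tables
take — are gap-stripped (a gapped window *is* the non-insertion pattern)
and classified by exact containment of either allele context window, with
an edit-distance fallback; equidistant or ambiguous-base windows are called
`uninformative`, never guessed. The context windows stored in a marker
extend 8 bp on each side of the variant, wide enough to be unique in
practice yet short enough to be contained in typical printed windows.

# The synthetic data generators

`makeToyPlastome()` emulates exactly the structural features the
quadripartite code consumes: four regions in canonical order, identical IR
copies, planted genes (including deliberate junction straddlers), GC ≈ 0.37
background matching real plastomes. The four bases flanking the repeat
copies are pinned to `A` so a planted IR can never extend by coincidence —
keeping planted coordinates exact. `makeAlleleLocus()` embeds two allele
windows in shared random flanks; `mutateGenome()` applies well-separated
random substitutions/InDels right-to-left for inject-and-recover tests. All
generators are pure functions of their parameters and seed, and they save
and restore the caller's RNG state.

`hibiscusTrnlLocus()` deserves a note: the real genome accessions are too
large to ship, so the bundled assay runs on a *synthetic* locus pair that
embeds everything the published assay fixes — the two printed primer
binding sites (each with its single documented 3'-terminal primer–template
mismatch), the printed allele windows, and a filler whose length (61 bp) is
forced by the published 134-bp product arithmetic, not tuned. Random flanks
are drawn from the seed and regenerated until the amplicon carries no
accidental AATT. Everything the assay predicts (134/137-bp products,
105 + 32 or 105 + 28 + 4 fragments, 11 of 43 panel carriers) follows from
the printed constants, so passing tests validate the assay logic; what the
synthetic locus cannot validate is the genomic *context* of the real locus
(off-target primer sites, constitutive sites elsewhere in the real
amplicon), which is exactly what the optional accession-dependent checks
cover after a one-time download (`scripts/fetch_accessions.R`).

What the generators do not emulate: sequencing error, assembly artifacts,
heteroplasmy, IR copy divergence, and base-composition structure beyond a
single GC fraction. Results on synthetic data therefore demonstrate
algorithmic correctness, not robustness to dirty assemblies.

# Numerical and degenerate-input choices

* Rounding of reported percentages is half-up (never banker's), to match
  how published tables are printed.
* `findInvertedRepeat()` requires `minLen ≥ 50`; below that, seed-and-extend
  with k = 25 would not be meaningfully constrained.
* Equal-length single-copy segments: first-encountered = LSC, with a
  warning (deterministic, and the caller is told).
* Empty fragment lists, windows of all `N`, and unalignable panel entries
  all resolve to explicit uninformative/empty outputs rather than errors.
* PCR failures carry distinct condition classes (`E_NO_SITE`,
  `E_MULTI_SITE`, `E_PRODUCT_SIZE`, `E_PRIMER_OVERLAP`) so callers and the
  CLI can react specifically; the CLI maps input/validation errors to exit
  code 2 and internal errors to 1.

# Problem sizes used in the shipped tests

The suite runs entirely offline at desk scale: alignment-optimality checks
up to 8 kb against an edit-distance oracle, IR-detection equivalence
against a quadratic oracle up to 3 kb, design soundness/completeness on
~230-bp loci, and variant inject-and-recover across 100 seeded 500-bp loci.
These sizes exercise every code path (including the anchored alignment
path, forced via a reduced `fullLimit`) while keeping the full suite in a
few minutes on one CPU. The accession-dependent checks (full 161-kb
genomes) run unchanged once the three GenBank records are fetched.

# Known limitations

* IR detection is exact-match only; plastomes with diverged IR copies will
  report the longest identical core, not the annotated IR.
* Variant semantics are assembly-level consensus calls; counts are not
  comparable to read-based callers with quality thresholds.
* Gap/SNP counts from other aligners depend on their (often unpublished)
  counting conventions; this package's counts are defined exactly as above
  and agreement with third-party tools is approximate by nature.
* The PCR model is combinatorial, not thermodynamic: it will happily accept
  a primer pair a thermodynamic screen would reject (the QC metrics exist
  precisely to surface that).
* Digestion is assumed complete; partial-digest ladders are not modeled.
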