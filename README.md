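# plastomeDCAPS

Design and validate CAPS/dCAPS genotyping assays from near-identical
chloroplast genomes, in R.

Plastomes of closely related plant cultivars routinely differ by only a
handful of substitutions and short InDels, yet those few variants are
maternally inherited and therefore ideal markers for tracing maternal
parentage in breeding programs. The practical obstacle is turning a single
3-bp InDel buried in a 160-kb genome into a cheap gel-based assay. The
**dCAPS** (derived Cleaved Amplified Polymorphic Sequence) trick solves
this: when the variant does not naturally create or destroy a restriction
site, a deliberate mismatch is placed in one PCR primer so that the
primer-encoded bases *plus* the variant complete a recognition site in
exactly one allele's amplicon. Digestion then yields allele-specific band
patterns readable on a 2% agarose gel.

`plastomeDCAPS` implements that workflow end to end:

* **seqio** — FASTA and GenBank flat-file I/O, allele tables with gapped
  sequence windows, IUPAC-aware reverse complement.
* **quadripartite** — exact inverted-repeat detection, LSC/IRb/SSC/IRa
  partitioning of circular plastomes, canonical rotation, and signed
  junction–gene distance reports (negative = the gene straddles the
  boundary).
* **compare** — anchored global alignment of long near-identical genomes at
  unit costs, gap-excluded identity/gap/SNP statistics, and
  specimen-specific variant extraction from a multiple alignment (a column
  run where exactly one row disagrees with the unanimous consensus of the
  others).
* **dcaps** — the core: enumerate recognition-site placements spanning the
  primer footprint and the variant, find minimal primer edits that complete
  the site in exactly one allele, simulate PCR (primer bases propagate into
  the product) and digestion, rank designs, and predict visible bands.
* **genotype** — call panels of full sequences (simulated digestion) or
  short printed windows (allele-pattern classification) as
  cut/uncut/uninformative.
* **fixtures** — deterministic synthetic plastomes and allele loci so every
  operation is testable offline, plus the bundled *Hibiscus syriacus*
  trnL-UAA intron assay.

## Worked example: the trnL-UAA ATA-insertion marker

The bundled assay genotypes a 3-bp ATA insertion in the P8 stem-loop of the
plastid *trnL-UAA* group I intron of *Hibiscus syriacus* var. *micranthus*.
The forward primer's terminal base is changed A→C to destroy a constitutive
AATT, and the reverse primer's terminal base encodes a T that completes an
MluCI site (AATT) only when the insertion is present:

```r
library(plastomeDCAPS)

marker <- hibiscusDcapsMarker()
marker
#> DcapsMarker [MluCI] on variant insertion (cut allele: insertion)
#> PrimerDesign (+): 5'-ATGCAAAATCTATTTATATGAAAAATAAAAAGC-3' (33 nt), 1 introduced mismatch(es) at 33
#> PrimerDesign (-): 5'-AATCAGTTTTTCAAAAGATTTATCAGACA-3' (29 nt), 1 introduced mismatch(es) at 29
#>   no_insertion: [134] bp
#>   insertion: [105, 32] bp

locus <- hibiscusTrnlLocus()          # synthetic locus pair carrying the assay
amp <- insilicoPcr(locus[["insertion"]], primerSeqs(marker)[1], primerSeqs(marker)[2])
nchar(amp)
#> [1] 137
digestAmplicon(amp, builtinEnzymes()[["MluCI"]], bothStrands = TRUE)
#> [1] 105  28   4
predictGel(c(105, 28, 4))             # the 4-bp overhang sliver is invisible
#> [1] 105  28

calls <- genotypePanel(marker, hibiscusPanel())
table(calls$call)
#>   cut_allele uncut_allele
#>           11           32
```

The non-insertion allele amplifies a single uncut 134-bp product; the
insertion allele's 137-bp product is cleaved. Measured as duplex lengths
(top-strand scissions) the cut fragments are 105 + 32 bp; counting both
strand nicks of the 5'-AATT overhang (`bothStrands = TRUE`) the same single
site reads as 105 + 28 + 4, of which 105 and 28 are visible on the gel.
Across the packaged 43-cultivar panel, exactly 11 entries carry the
insertion allele — the variety itself and the cultivars bred from it as
maternal parent.

Designing a fresh marker from two allele sequences is one call:

```r
designs <- designDcaps(locus[["no_insertion"]], locus[["insertion"]],
                       enzymes = builtinEnzymes()["MluCI"],
                       alleleNames = c("no_insertion", "insertion"))
designs[[1]]   # ranked: fewest primer edits, non-terminal mismatch preferred
```

A command-line wrapper (`inst/scripts/plastomedcaps`) exposes `partition`,
`junctions`, `compare`, `variants`, `dcaps-design`, `pcr-digest`,
`genotype` and `fixtures` subcommands over the same functions.

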