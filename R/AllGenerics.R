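#' @rdname GenomeRecord-class
#' @param object,x a package object.
#' @export
setGeneric("genomeId", function(x) standardGeneric("genomeId"))
#' @rdname GenomeRecord-class
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname GenomeRecord-class
#' @export
setGeneric("isCircular", function(x) standardGeneric("isCircular"))
#' @rdname GenomeRecord-class
#' @export
setGeneric("genomeFeatures", function(x) standardGeneric("genomeFeatures"))
#' @rdname GenomeRecord-class
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname QuadripartitePartition-class
#' @export
setGeneric("regionStarts", function(x) standardGeneric("regionStarts"))
#' @rdname QuadripartitePartition-class
#' @export
setGeneric("regionLengths", function(x) standardGeneric("regionLengths"))

#' @rdname DcapsMarker-class
#' @export
setGeneric("predictedFragments", function(x) standardGeneric("predictedFragments"))
#' @rdname DcapsMarker-class
#' @export
setGeneric("cutAllele", function(x) standardGeneric("cutAllele"))
#' @rdname DcapsMarker-class
#' @export
setGeneric("primerSeqs", function(x) standardGeneric("primerSeqs"))

setMethod("genomeId", "GenomeRecord", function(x) x@id)
setMethod("genomeSeq", "GenomeRecord", function(x) x@sequence)
setMethod("isCircular", "GenomeRecord", function(x) x@circular)
setMethod("genomeFeatures", "GenomeRecord", function(x) x@features)
setMethod("genomeLength", "GenomeRecord", function(x) length(x@sequence))

setMethod("regionStarts", "QuadripartitePartition", function(x) x@starts)
setMethod("regionLengths", "QuadripartitePartition", function(x) x@lengths)

setMethod("predictedFragments", "DcapsMarker", function(x) x@predictedFragments)
setMethod("cutAllele", "DcapsMarker", function(x) x@cutAllele)
setMethod("primerSeqs", "DcapsMarker",
          function(x) c(forward = x@forward@sequence, reverse = x@reverse@sequence))

setMethod("show", "GenomeRecord", function(object) {
  cat(sprintf("GenomeRecord '%s': %d bp, %s, %d feature part(s)\n",
              object@id, length(object@sequence),
              if (object@circular) "circular" else "linear",
              nrow(object@features)))
})

setMethod("show", "QuadripartitePartition", function(object) {
  cat(sprintf("QuadripartitePartition (%d bp): %s\n", object@genomeLength,
              paste(sprintf("%s %d", REGIONS, object@lengths[REGIONS]),
                    collapse = " / ")))
})

setMethod("show", "RestrictionEnzyme", function(object) {
  s <- object@site
  cat(sprintf("RestrictionEnzyme %s: %s^%s (top cut %d, bottom cut %d)\n",
              object@name, substr(s, 1, object@cutOffsetTop),
              substr(s, object@cutOffsetTop + 1L, nchar(s)),
              object@cutOffsetTop, object@cutOffsetBottom))
})

setMethod("show", "PrimerDesign", function(object) {
  mm <- object@introducedMismatches
  cat(sprintf("PrimerDesign (%s): 5'-%s-3' (%d nt)%s\n", object@strand,
              object@sequence, nchar(object@sequence),
              if (nrow(mm)) sprintf(", %d introduced mismatch(es) at %s",
                                    nrow(mm), paste(mm$position, collapse = ","))
              else ""))
})

setMethod("show", "DcapsMarker", function(object) {
  cat(sprintf("DcapsMarker [%s] on variant %s (cut allele: %s)\n",
              object@enzyme@name, object@variant$kind[1], object@cutAllele))
  show(object@forward)
  show(object@reverse)
  for (al in names(object@predictedFragments))
    cat(sprintf("  %s: [%s] bp\n", al,
                paste(object@predictedFragments[[al]], collapse = ", ")))
})

setMethod("show", "AlignedPair", function(object) {
  cat(sprintf("AlignedPair %s vs %s: %d columns, cost %g\n",
              object@ids[1], object@ids[2], nchar(object@a), object@cost))
})
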