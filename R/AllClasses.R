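#' @import methods
#' @importFrom Biostrings DNAString DNAStringSet reverseComplement matchPattern
#'   readDNAStringSet writeXStringSet pairwiseAlignment pattern subject
#'   alignedPattern alignedSubject
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importFrom BiocGenerics score
#' @importFrom IRanges IRanges
NULL

#' GenomeRecord: an annotated (possibly circular) DNA sequence
#'
#' The canonical internal sequence model of the package: an identifier, an
#' uppercase DNA sequence over \{A,C,G,T,N\}, a circularity flag, and a table
#' of gene-level features. Feature coordinates are 1-based inclusive; a
#' feature that wraps the origin of a circular record is split into ordered
#' parts sharing one \code{name} and \code{part} index.
#'
#' @slot id character(1) record identifier.
#' @slot sequence a \link[Biostrings]{DNAString}.
#' @slot circular logical(1).
#' @slot features data.frame with columns \code{name}, \code{kind}
#'   (gene/tRNA/rRNA/other), \code{strand} (+/-), \code{start}, \code{end}
#'   (1-based inclusive), \code{part} (ordered part index within a feature).
#'
#' @exportClass GenomeRecord
setClass("GenomeRecord",
  representation(id = "character", sequence = "DNAString",
                 circular = "logical", features = "data.frame"))

emptyFeatures <- function() {
  data.frame(name = character(), kind = character(), strand = character(),
             start = integer(), end = integer(), part = integer(),
             stringsAsFactors = FALSE)
}

setValidity("GenomeRecord", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@sequence) < 1L)
    msg <- c(msg, "sequence must be non-empty")
  bad <- gsub("[ACGTN]", "", as.character(object@sequence))
  if (nzchar(bad))
    msg <- c(msg, sprintf("sequence contains characters outside {A,C,G,T,N}: '%s'",
                          substr(bad, 1, 10)))
  ft <- object@features
  need <- c("name", "kind", "strand", "start", "end", "part")
  if (!all(need %in% names(ft))) {
    msg <- c(msg, paste("features must have columns", paste(need, collapse = ", ")))
  } else if (nrow(ft)) {
    n <- length(object@sequence)
    if (any(ft$start < 1L) || any(ft$end > n))
      msg <- c(msg, "feature intervals must lie within [1, genome length]")
    if (any(ft$start > ft$end))
      msg <- c(msg, "feature parts must have start <= end (split wrap-around parts)")
    if (!all(ft$strand %in% c("+", "-")))
      msg <- c(msg, "feature strand must be '+' or '-'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeRecord
#'
#' @param id record identifier.
#' @param sequence DNA as character or \code{DNAString}; lowercase accepted,
#'   \code{U} mapped to \code{T}.
#' @param circular logical, is the molecule circular?
#' @param features feature table (see \linkS4class{GenomeRecord}); missing
#'   \code{part} column defaults to 1.
#' @return a \linkS4class{GenomeRecord}.
#' @examples
#' gr <- GenomeRecord("toy", "ACGTACGT")
#' genomeLength(gr)
#' @export
GenomeRecord <- function(id, sequence, circular = FALSE, features = emptyFeatures()) {
  if (is.character(sequence)) {
    sequence <- chartr("uU", "tT", sequence)
    sequence <- DNAString(toupper(sequence))
  }
  if (!nrow(features)) features <- emptyFeatures()
  if (is.null(features$part)) features$part <- 1L
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  features$part <- as.integer(features$part)
  rownames(features) <- NULL
  new("GenomeRecord", id = as.character(id), sequence = sequence,
      circular = isTRUE(circular), features = features)
}

#' QuadripartitePartition: LSC/IRb/SSC/IRa intervals of a plastome
#'
#' Describes the four regions tiling a circular plastome exactly once, stored
#' as 1-based start positions and lengths on the circle in the canonical
#' order LSC, IRb, SSC, IRa (a region may wrap the origin).
#'
#' @slot starts named integer(4), 1-based region starts (LSC, IRb, SSC, IRa).
#' @slot lengths named integer(4), region lengths in bp.
#' @slot genomeLength integer(1).
#' @exportClass QuadripartitePartition
setClass("QuadripartitePartition",
  representation(starts = "integer", lengths = "integer", genomeLength = "integer"))

REGIONS <- c("LSC", "IRb", "SSC", "IRa")

setValidity("QuadripartitePartition", function(object) {
  msg <- character()
  if (!identical(names(object@starts), REGIONS) ||
      !identical(names(object@lengths), REGIONS))
    msg <- c(msg, "starts/lengths must be named LSC, IRb, SSC, IRa in order")
  if (sum(object@lengths) != object@genomeLength)
    msg <- c(msg, "the four regions must tile the genome exactly once")
  if (length(object@lengths) == 4L) {
    if (object@lengths[["IRb"]] != object@lengths[["IRa"]])
      msg <- c(msg, "IRb and IRa must have equal length")
    if (object@lengths[["SSC"]] > object@lengths[["LSC"]])
      msg <- c(msg, "SSC must not be longer than LSC")
  }
  if (length(msg)) msg else TRUE
})

#' RestrictionEnzyme: a recognition site with cut offsets
#'
#' @slot name enzyme name.
#' @slot site IUPAC recognition sequence (length 4-8).
#' @slot cutOffsetTop bases from site start to the top-strand scission.
#' @slot cutOffsetBottom top-strand coordinate offset (from site start) of the
#'   bottom-strand scission; equals \code{nchar(site) - cutOffsetTop} for
#'   palindromic sites.
#' @exportClass RestrictionEnzyme
setClass("RestrictionEnzyme",
  representation(name = "character", site = "character",
                 cutOffsetTop = "integer", cutOffsetBottom = "integer"))

setValidity("RestrictionEnzyme", function(object) {
  msg <- character()
  len <- nchar(object@site)
  if (len < 4L || len > 8L) msg <- c(msg, "site length must be 4-8")
  if (grepl("[^ACGTRYSWKMBDHVN]", object@site))
    msg <- c(msg, "site must be IUPAC DNA")
  if (object@cutOffsetTop < 0L || object@cutOffsetTop > len)
    msg <- c(msg, "cutOffsetTop must lie within [0, site length]")
  if (object@cutOffsetBottom < 0L || object@cutOffsetBottom > len)
    msg <- c(msg, "cutOffsetBottom must lie within [0, site length]")
  if (identical(as.character(revComp(object@site)), object@site) &&
      object@cutOffsetBottom != len - object@cutOffsetTop)
    msg <- c(msg, "palindromic site requires cutOffsetBottom = site length - cutOffsetTop")
  if (length(msg)) msg else TRUE
})

#' Construct a RestrictionEnzyme
#'
#' @param name enzyme name.
#' @param site recognition site; a caret \code{^} may mark the top-strand cut
#'   (e.g. \code{"G^AATTC"} for EcoRI), otherwise give \code{cutOffsetTop}.
#' @param cutOffsetTop,cutOffsetBottom explicit cut offsets (see class docs);
#'   for palindromic sites \code{cutOffsetBottom} defaults to
#'   \code{nchar(site) - cutOffsetTop}.
#' @return a \linkS4class{RestrictionEnzyme}.
#' @examples
#' RestrictionEnzyme("MluCI", "^AATT")
#' @export
RestrictionEnzyme <- function(name, site, cutOffsetTop = NULL, cutOffsetBottom = NULL) {
  site <- toupper(site)
  if (grepl("^", site, fixed = TRUE)) {
    cutOffsetTop <- regexpr("^", site, fixed = TRUE)[1] - 1L
    site <- sub("^", "", site, fixed = TRUE)
  }
  if (is.null(cutOffsetTop))
    stop("cut position unknown: use '^' in the site or give cutOffsetTop")
  if (is.null(cutOffsetBottom)) {
    if (identical(as.character(revComp(site)), site)) {
      cutOffsetBottom <- nchar(site) - cutOffsetTop
    } else {
      cutOffsetBottom <- cutOffsetTop
    }
  }
  new("RestrictionEnzyme", name = name, site = site,
      cutOffsetTop = as.integer(cutOffsetTop),
      cutOffsetBottom = as.integer(cutOffsetBottom))
}

#' PrimerDesign: one primer, possibly carrying deliberate mismatches
#'
#' @slot sequence primer 5'->3'.
#' @slot strand "+" (forward) or "-" (reverse) relative to the locus.
#' @slot templateWindow integer(2), 1-based footprint on the plus strand of
#'   the template the primer anneals over.
#' @slot introducedMismatches data.frame with columns \code{position}
#'   (1-based within the primer, 5'->3'), \code{templateBase},
#'   \code{primerBase}.
#' @exportClass PrimerDesign
setClass("PrimerDesign",
  representation(sequence = "character", strand = "character",
                 templateWindow = "integer", introducedMismatches = "data.frame"))

setValidity("PrimerDesign", function(object) {
  msg <- character()
  if (!object@strand %in% c("+", "-")) msg <- c(msg, "strand must be + or -")
  mm <- object@introducedMismatches
  if (nrow(mm) && (any(mm$position < 1L) || any(mm$position > nchar(object@sequence))))
    msg <- c(msg, "mismatch positions must lie within the primer")
  if (length(msg)) msg else TRUE
})

noMismatches <- function() {
  data.frame(position = integer(), templateBase = character(),
             primerBase = character(), stringsAsFactors = FALSE)
}

PrimerDesign <- function(sequence, strand, templateWindow,
                         introducedMismatches = noMismatches()) {
  new("PrimerDesign", sequence = toupper(sequence), strand = strand,
      templateWindow = as.integer(templateWindow),
      introducedMismatches = introducedMismatches)
}

#' DcapsMarker: a complete CAPS/dCAPS assay
#'
#' A primer pair (one of which may carry deliberate mismatches), the
#' discriminating restriction enzyme, the target variant, per-allele
#' predicted digestion fragments, short per-allele context windows used to
#' classify panel sequence windows, and which allele is cleaved.
#'
#' @slot forward,reverse \linkS4class{PrimerDesign}.
#' @slot enzyme \linkS4class{RestrictionEnzyme}.
#' @slot variant one-row data.frame (kind, refStart, refAllele, altAllele).
#' @slot predictedFragments named list (one element per allele) of integer
#'   fragment lengths sorted descending (top-strand cuts).
#' @slot alleleWindows named character(2): ungapped context windows around
#'   the variant for each allele.
#' @slot cutAllele name of the allele whose amplicon is cleaved.
#' @exportClass DcapsMarker
setClass("DcapsMarker",
  representation(forward = "PrimerDesign", reverse = "PrimerDesign",
                 enzyme = "RestrictionEnzyme", variant = "data.frame",
                 predictedFragments = "list", alleleWindows = "character",
                 cutAllele = "character"))

setValidity("DcapsMarker", function(object) {
  msg <- character()
  fr <- object@predictedFragments
  if (length(fr) != 2L || is.null(names(fr)))
    msg <- c(msg, "predictedFragments must be a named list of two alleles")
  else {
    if (identical(sort(fr[[1]]), sort(fr[[2]])))
      msg <- c(msg, "the two alleles' fragment multisets must differ")
    if (!object@cutAllele %in% names(fr))
      msg <- c(msg, "cutAllele must name one of the alleles")
  }
  if (length(msg)) msg else TRUE
})

#' AlignedPair: a global pairwise alignment as two gapped strings
#'
#' @slot ids character(2) sequence identifiers.
#' @slot a,b gapped aligned strings (equal width, '-' gaps).
#' @slot cost unit-cost alignment cost (mismatch columns + gap columns).
#' @exportClass AlignedPair
setClass("AlignedPair",
  representation(ids = "character", a = "character", b = "character",
                 cost = "numeric"))

setValidity("AlignedPair", function(object) {
  if (nchar(object@a) != nchar(object@b))
    "aligned strings must have equal width" else TRUE
})
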