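# dCAPS/CAPS marker design: enumerate recognition-site placements spanning
# the primer footprint and the variant, find minimal primer base changes that
# complete the site in exactly one allele's amplicon, then validate the
# design end-to-end by simulated PCR + digestion.

#' Design constraints for dCAPS markers
#'
#' @param primerLenRange allowed mismatch-primer length range (nt).
#' @param maxMismatches maximum deliberate base changes per primer.
#' @param max3PrimeDist maximum distance (bp) from the mismatch primer's 3'
#'   end to the variant.
#' @param tmTarget,tmWindow target melting temperature and acceptable window
#'   (degrees C, nearest-neighbor model of \code{\link{primerQc}}).
#' @param productRange allowed amplicon length range (bp).
#' @param gelResolution smallest fragment-size difference (bp) treated as
#'   separable on the gel.
#' @param minVisible smallest visible fragment (bp), see
#'   \code{\link{predictGel}}.
#' @param contextRadius bp of flanking context stored per allele for window
#'   classification.
#' @return list of constraints.
#' @export
dcapsConstraints <- function(primerLenRange = c(18L, 35L), maxMismatches = 1L,
                             max3PrimeDist = 10L, tmTarget = 60,
                             tmWindow = c(50, 68), productRange = c(60L, 400L),
                             gelResolution = 5L, minVisible = 20L,
                             contextRadius = 8L) {
  list(primerLenRange = as.integer(primerLenRange),
       maxMismatches = as.integer(maxMismatches),
       max3PrimeDist = as.integer(max3PrimeDist),
       tmTarget = tmTarget, tmWindow = tmWindow,
       productRange = as.integer(productRange),
       gelResolution = as.integer(gelResolution),
       minVisible = as.integer(minVisible),
       contextRadius = as.integer(contextRadius))
}

#' Locate the single difference between two allele sequences
#'
#' Computes the maximal common prefix/suffix and normalizes the enclosed
#' difference (left-aligned for shift-ambiguous InDels).
#'
#' @param ref,alt allele sequences (text).
#' @return one-row data.frame: \code{kind}, \code{refStart}, \code{refEnd},
#'   \code{refAllele}, \code{altAllele} (1-based; for an insertion
#'   \code{refEnd = refStart - 1} and \code{refAllele = ""}).
#' @export
locateAlleleDifference <- function(ref, alt) {
  a <- asDnaChar(ref); b <- asDnaChar(alt)
  na <- nchar(a); nb <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  nmin <- min(na, nb)
  neq <- which(av[seq_len(nmin)] != bv[seq_len(nmin)])
  cp <- if (length(neq)) neq[1] - 1L else nmin
  neqs <- which(rev(av)[seq_len(nmin)] != rev(bv)[seq_len(nmin)])
  cs <- if (length(neqs)) neqs[1] - 1L else nmin
  cs <- min(cs, nmin - cp)
  refAllele <- if (na - cs >= cp + 1L) substr(a, cp + 1L, na - cs) else ""
  altAllele <- if (nb - cs >= cp + 1L) substr(b, cp + 1L, nb - cs) else ""
  if (!nzchar(refAllele) && !nzchar(altAllele))
    toolError("E_INPUT", "allele sequences are identical")
  kind <- if (!nzchar(refAllele)) "insertion"
          else if (!nzchar(altAllele)) "deletion"
          else if (nchar(refAllele) == nchar(altAllele)) "substitution"
          else "complex"
  data.frame(kind = kind, refStart = cp + 1L,
             refEnd = cp + nchar(refAllele),
             refAllele = refAllele, altAllele = altAllele,
             stringsAsFactors = FALSE)
}

# Do two fragment multisets differ by at least `floor` bp somewhere?
# Returns the largest discriminating size difference (0 when equivalent).
.bandsetDifference <- function(fx, fy, floor) {
  fx <- sort(fx); fy <- sort(fy)
  used <- logical(length(fy))
  unmatched <- integer()
  for (b in fx) {
    cand <- which(!used & abs(fy - b) < floor)
    if (length(cand)) used[cand[1]] <- TRUE else unmatched <- c(unmatched, b)
  }
  unmatchedY <- fy[!used]
  if (!length(unmatched) && !length(unmatchedY)) return(0)
  dmax <- 0
  for (b in unmatched)
    dmax <- max(dmax, if (length(fy)) min(abs(fy - b)) else b)
  for (b in unmatchedY)
    dmax <- max(dmax, if (length(fx)) min(abs(fx - b)) else b)
  dmax
}

# Pick the best primer length for a 3'-end position: Tm closest to target.
.pickPrimer <- function(s, e, changes, constraints) {
  lmin <- max(constraints$primerLenRange[1],
              if (nrow(changes)) e - min(changes$tpos) + 1L else 1L)
  lmax <- min(constraints$primerLenRange[2], e)
  if (lmin > lmax) return(NULL)
  best <- NULL
  for (len in lmin:lmax) {
    start <- e - len + 1L
    pv <- strsplit(substr(s, start, e), "")[[1]]
    if (nrow(changes)) pv[changes$tpos - start + 1L] <- changes$base
    pseq <- paste(pv, collapse = "")
    tm <- primerTm(pseq)
    d <- abs(tm - constraints$tmTarget)
    inWin <- tm >= constraints$tmWindow[1] && tm <= constraints$tmWindow[2]
    key <- c(!inWin, d)
    if (is.null(best) || key[1] < best$key[1] ||
        (key[1] == best$key[1] && key[2] < best$key[2]))
      best <- list(seq = pseq, start = start, len = len, tm = tm, key = key)
  }
  best
}

# Choose a mismatch-free opposite primer in the shared suffix; `sx`, `sy` are
# the two allele sequences in design orientation, `pstart` the mismatch
# primer's footprint start. Returns NULL or list(seq, t, len, tm).
.pickOpposite <- function(sx, sy, cs, pstart, constraints) {
  nx <- nchar(sx); ny <- nchar(sy)
  best <- NULL
  lmin <- constraints$primerLenRange[1]; lmax <- constraints$primerLenRange[2]
  tMax <- min(cs - lmin, 400L)
  if (tMax < 0L) return(NULL)
  for (t in 0:tMax) {
    prodX <- (nx - t) - pstart + 1L
    prodY <- (ny - t) - pstart + 1L
    if (max(prodX, prodY) > constraints$productRange[2]) next
    if (min(prodX, prodY) < constraints$productRange[1]) break  # only shrinks
    for (len in lmin:min(lmax, cs - t)) {
      b <- nx - t; a <- b - len + 1L
      if (a < 1L) next
      pseq <- as.character(revComp(substr(sx, a, b)))
      tm <- primerTm(pseq)
      d <- abs(tm - constraints$tmTarget)
      inWin <- tm >= constraints$tmWindow[1] && tm <= constraints$tmWindow[2]
      key <- c(!inWin, d)
      if (is.null(best) || key[1] < best$key[1] ||
          (key[1] == best$key[1] && key[2] < best$key[2]))
        best <- list(seq = pseq, t = t, len = len, tm = tm, key = key)
    }
  }
  best
}

#' Design dCAPS/CAPS markers around a variant
#'
#' Enumerates, for each enzyme, each strand, and each placement of the
#' recognition site overlapping both the mismatch-primer footprint and the
#' variant locus, whether a set of at most \code{maxMismatches} primer base
#' changes completes the site in exactly one allele's amplicon. Each hit is
#' turned into a primer pair (mismatch primer adjacent to the variant, the
#' opposite primer mismatch-free in the shared flank), simulated end-to-end
#' (\code{\link{insilicoPcr}} then \code{\link{digestAmplicon}}) on both
#' alleles, and kept only if the two fragment multisets differ by at least
#' the gel-resolution floor. Constitutive sites elsewhere in the amplicon are
#' allowed and appear in the predicted fragments. A variant that natively
#' creates a site needs zero changes: the degenerate design is a plain CAPS
#' marker. Designs are ranked by fewest introduced mismatches, then
#' non-terminal mismatch placement, then largest discriminating
#' fragment-size difference, then Tm closeness to target.
#'
#' @param ref,alt the two allele sequences (>= 60 bp flanks recommended).
#' @param variant optional variant table from
#'   \code{\link{locateAlleleDifference}} (computed when missing).
#' @param enzymes named list of \linkS4class{RestrictionEnzyme}.
#' @param constraints see \code{\link{dcapsConstraints}}.
#' @param alleleNames names for the two alleles (default ref/alt).
#' @return list of \linkS4class{DcapsMarker}, ranked best first; when empty,
#'   attribute \code{rejectionReasons} gives a per-enzyme explanation.
#' @export
designDcaps <- function(ref, alt, variant = NULL, enzymes = builtinEnzymes(),
                        constraints = dcapsConstraints(),
                        alleleNames = c("ref", "alt")) {
  sref <- asDnaChar(ref); salt <- asDnaChar(alt)
  if (is.null(variant)) variant <- locateAlleleDifference(sref, salt)
  if (is.null(names(enzymes)))
    names(enzymes) <- vapply1c(enzymes, function(e) e@name)
  reasons <- setNames(rep("no site placement completes the recognition site in exactly one allele",
                          length(enzymes)), names(enzymes))
  markers <- list()
  keys <- character()

  for (orient in c("+", "-")) {
    if (orient == "+") {
      sx <- sref; sy <- salt
    } else {
      sx <- as.character(revComp(sref)); sy <- as.character(revComp(salt))
    }
    # shared prefix/suffix in this orientation
    vloc <- tryCatch(locateAlleleDifference(sx, sy), error = function(e) NULL)
    if (is.null(vloc)) next
    cp <- vloc$refStart - 1L
    cs <- min(nchar(sx) - vloc$refEnd,
              nchar(sy) - (vloc$refStart - 1L + nchar(vloc$altAllele)))
    xv <- strsplit(sx, "")[[1]]; yv <- strsplit(sy, "")[[1]]

    for (ei in seq_along(enzymes)) {
      enz <- enzymes[[ei]]
      for (siteStr in unique(c(enz@site, as.character(revComp(enz@site))))) {
      site <- strsplit(siteStr, "")[[1]]
      L <- length(site)
      eLo <- max(constraints$primerLenRange[1], cp - constraints$max3PrimeDist)
      if (eLo > cp) { reasons[ei] <- "flank too short for a primer next to the variant"; next }
      for (e in eLo:cp) {
        for (p in max(1L, e - L + 2L):e) {
          if (p + L - 1L <= cp) next        # site must reach the variant side
          if (p + L - 1L <= e) next         # need >= 1 non-primer position
          qs <- p:(p + L - 1L)
          inPrimer <- qs <= e
          # primer-covered positions: cost of forcing a match
          tpl <- xv[qs[inPrimer]]
          want <- site[inPrimer]
          needChange <- !mapply(iupacMatches, tpl, want)
          cost <- sum(needChange)
          if (cost > constraints$maxMismatches) next
          chosen <- ifelse(needChange,
                           vapply1c(IUPAC_SETS[want], function(st) st[1]),
                           tpl)
          # non-primer window per allele
          okAllele <- function(v) {
            q2 <- qs[!inPrimer]
            if (any(q2 > length(v))) return(FALSE)
            all(mapply(iupacMatches, v[q2], site[!inPrimer]))
          }
          okX <- okAllele(xv); okY <- okAllele(yv)
          if (okX == okY) next   # cuts both or neither: not discriminating
          changes <- data.frame(tpos = qs[inPrimer][needChange],
                                base = chosen[needChange],
                                stringsAsFactors = FALSE)
          mp <- .pickPrimer(sx, e, changes, constraints)
          if (is.null(mp)) { reasons[ei] <- "no primer length satisfies the constraints"; next }
          op <- .pickOpposite(sx, sy, cs, mp$start, constraints)
          if (is.null(op)) { reasons[ei] <- "no mismatch-free opposite primer placement fits the product-size constraints"; next }
          # simulate end-to-end on both alleles, in the orientation the
          # user will run (forward primer of the original locus first) so
          # predicted fragments match re-simulation exactly even for
          # asymmetric cutters
          fwdSeq <- if (orient == "+") mp$seq else op$seq
          revSeq <- if (orient == "+") op$seq else mp$seq
          sim <- tryCatch({
            ampX <- insilicoPcr(sref, fwdSeq, revSeq)
            ampY <- insilicoPcr(salt, fwdSeq, revSeq)
            list(fx = digestAmplicon(ampX, enz), fy = digestAmplicon(ampY, enz))
          }, condition = function(c) c)
          if (inherits(sim, "condition")) {
            reasons[ei] <- conditionMessage(sim); next
          }
          dmax <- .bandsetDifference(sim$fx, sim$fy, constraints$gelResolution)
          if (dmax < constraints$gelResolution) {
            reasons[ei] <- "allele fragment multisets are not separable on the gel"
            next
          }
          cutX <- okX  # the allele whose window completes the site
          marker <- .assembleMarker(orient, sref, salt, variant, enz,
                                    mp, op, changes, sim,
                                    cutAllele = if (cutX) alleleNames[1] else alleleNames[2],
                                    alleleNames = alleleNames,
                                    constraints = constraints)
          key <- paste(enz@name, marker@forward@sequence, marker@reverse@sequence)
          if (key %in% keys) next
          keys <- c(keys, key)
          terminalMM <- nrow(changes) > 0L && any(changes$tpos == e)
          attr(marker, "rank") <- c(cost = cost, terminal = as.integer(terminalMM),
                                    negDiff = -dmax,
                                    tmDist = abs(mp$tm - constraints$tmTarget))
          markers[[length(markers) + 1L]] <- marker
        }
      }
      }
    }
  }
  if (!length(markers)) {
    out <- list()
    attr(out, "rejectionReasons") <- reasons
    return(out)
  }
  ranks <- t(vapply(markers, function(m) attr(m, "rank"), numeric(4)))
  markers[order(ranks[, 1], ranks[, 2], ranks[, 3], ranks[, 4])]
}

# Build a DcapsMarker, mapping design-orientation primers back to the
# original locus orientation.
.assembleMarker <- function(orient, sref, salt, variant, enz, mp, op, changes,
                            sim, cutAllele, alleleNames, constraints) {
  n <- nchar(sref)
  mmTab <- if (nrow(changes)) {
    data.frame(position = changes$tpos - mp$start + 1L,
               templateBase = substring(if (orient == "+") sref else
                 as.character(revComp(sref)), changes$tpos, changes$tpos),
               primerBase = changes$base, stringsAsFactors = FALSE)
  } else noMismatches()
  if (orient == "+") {
    fwd <- PrimerDesign(mp$seq, "+", c(mp$start, mp$start + mp$len - 1L), mmTab)
    rstartRef <- nchar(sref) - op$t - op$len + 1L
    rev <- PrimerDesign(op$seq, "-", c(rstartRef, rstartRef + op$len - 1L))
  } else {
    # design ran on the reverse complement: the opposite primer is the
    # forward primer of the original locus (its design-orientation footprint
    # [n-t-len+1, n-t] maps to original [t+1, t+len]) and the mismatch
    # primer is the reverse primer
    fstart <- op$t + 1L
    fwd <- PrimerDesign(op$seq, "+", c(fstart, fstart + op$len - 1L))
    mstart <- n - (mp$start + mp$len - 1L) + 1L
    rev <- PrimerDesign(mp$seq, "-", c(mstart, mstart + mp$len - 1L), mmTab)
  }
  frags <- setNames(list(as.integer(sim$fx), as.integer(sim$fy)), alleleNames)
  r <- constraints$contextRadius
  cp <- variant$refStart - 1L
  refWin <- substr(sref, max(1L, cp - r + 1L),
                   min(nchar(sref), variant$refEnd + r))
  altEnd <- cp + nchar(variant$altAllele)
  altWin <- substr(salt, max(1L, cp - r + 1L), min(nchar(salt), altEnd + r))
  new("DcapsMarker", forward = fwd, reverse = rev, enzyme = enz,
      variant = variant, predictedFragments = frags,
      alleleWindows = setNames(c(refWin, altWin), alleleNames),
      cutAllele = cutAllele)
}
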