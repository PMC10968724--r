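# Quadripartite structure: IR detection, LSC/IRb/SSC/IRa partitioning,
# canonical rotation, junction-gene distance reports.

#' Find the longest inverted-repeat pair of a genome
#'
#' Detects the longest pair of exact, non-overlapping, oppositely oriented
#' repeats on the (circular) sequence by seeding 25-mers against the reverse
#' complement and extending maximal runs. Ties are broken by preferring the
#' pair that maximizes the shorter single-copy segment between the copies,
#' then the lowest start coordinate, so output is deterministic.
#'
#' @param record a \linkS4class{GenomeRecord} (or DNA text).
#' @param minLen minimum repeat length to report (default 1000 bp, the scale
#'   of real plastome IRs; use smaller values for toy sequences).
#' @return data.frame with columns \code{start} (1-based, on the input
#'   rotation) and \code{length}, one row per repeat copy (0 rows when no
#'   repeat of at least \code{minLen} exists).
#' @export
findInvertedRepeat <- function(record, minLen = 1000L) {
  s <- asDnaChar(record)
  n <- nchar(s)
  circular <- if (is(record, "GenomeRecord")) isCircular(record) else TRUE
  if (minLen < 50L) toolError("E_INPUT", "minLen must be >= 50")
  if (n < 2L * minLen)
    toolError("E_INPUT", "sequence shorter than twice minLen")
  k <- min(25L, as.integer(minLen))

  s2 <- if (circular) paste0(s, s) else s
  m <- nchar(s2)
  rc <- as.character(revComp(s2))
  starts2 <- seq_len(m - k + 1L)
  kS <- substring(s2, starts2, starts2 + k - 1L)
  kR <- substring(rc, starts2, starts2 + k - 1L)
  idxR <- split(starts2, kR)
  # seeds only need to start within the first copy of the doubled sequence
  iMax <- min(n, length(kS))
  hits <- idxR[kS[seq_len(iMax)]]
  lens <- lengths(hits)
  if (!sum(lens)) return(data.frame(start = integer(), length = integer()))
  i <- rep.int(seq_len(iMax), lens)
  p <- unlist(hits, use.names = FALSE)
  d <- p - i
  ord <- order(d, i)
  dd <- d[ord]; ii <- i[ord]
  nh <- length(ii)
  newrun <- c(TRUE, dd[-1L] != dd[-nh] | ii[-1L] != ii[-nh] + 1L)
  runid <- cumsum(newrun)
  i0 <- ii[newrun]
  r <- tabulate(runid)
  L <- r + k - 1L
  p0 <- i0 + dd[newrun]
  keep <- L >= minLen & 2L * L <= n
  if (!any(keep)) return(data.frame(start = integer(), length = integer()))
  i0 <- i0[keep]; p0 <- p0[keep]; L <- L[keep]
  # second copy in s2 coordinates: rc position j <-> s2 position m - j + 1
  bStart <- m - (p0 + L - 1L) + 1L
  aC <- circIndex(i0, n)
  bC <- circIndex(bStart, n)
  # drop overlapping / self pairs on the circle
  off <- (bC - aC) %% n
  ok <- off >= L & off <= n - L & !(off == 0L)
  aC <- aC[ok]; bC <- bC[ok]; L <- L[ok]
  if (!length(L)) return(data.frame(start = integer(), length = integer()))
  lo <- pmin(aC, bC); hi <- pmax(aC, bC)
  key <- paste(lo, hi, L)
  first <- !duplicated(key)
  lo <- lo[first]; hi <- hi[first]; L <- L[first]
  gap1 <- (hi - (lo + L)) %% n
  gap2 <- (lo - (hi + L)) %% n
  minGap <- pmin(gap1, gap2)
  best <- order(-L, -minGap, lo, hi)[1]
  data.frame(start = c(lo[best], hi[best]), length = c(L[best], L[best]))
}

# Circular single-copy gap following interval (start, len): start + len .. next
.gapAfter <- function(start, len, nextStart, n) {
  gstart <- circIndex(start + len, n)
  glen <- (nextStart - (start + len)) %% n
  c(start = gstart, length = glen)
}

#' Partition a plastome into LSC / IRb / SSC / IRa
#'
#' Labels the two single-copy segments between an inverted-repeat pair as
#' SSC (shorter) and LSC (longer); IRb is the IR copy immediately downstream
#' of the LSC in the forward orientation. When the two single-copy segments
#' have equal length the first-encountered segment (lower start coordinate)
#' is labeled LSC, with a warning.
#'
#' @param record a \linkS4class{GenomeRecord}.
#' @param irPair repeat pair as returned by \code{\link{findInvertedRepeat}}.
#' @return a \linkS4class{QuadripartitePartition}.
#' @export
partitionGenome <- function(record, irPair) {
  s <- asDnaChar(record)
  n <- nchar(s)
  if (!is.data.frame(irPair) || nrow(irPair) != 2L)
    toolError("E_INPUT", "irPair must be a two-row data.frame (start, length)")
  s1 <- irPair$start[1]; l1 <- irPair$length[1]
  s2 <- irPair$start[2]; l2 <- irPair$length[2]
  if (l1 != l2) toolError("E_PARTITION", "IR copies must have equal length")
  off <- (s2 - s1) %% n
  if (off < l1 || off > n - l1)
    toolError("E_PARTITION", "IR intervals overlap on the circle")
  ir1seq <- circSubstr(s, s1, l1)
  ir2seq <- circSubstr(s, s2, l2)
  if (!identical(ir1seq, as.character(revComp(ir2seq))))
    toolError("E_PARTITION", "intervals are not exact inverted copies")
  g1 <- .gapAfter(s1, l1, s2, n)  # segment between IR1 and IR2
  g2 <- .gapAfter(s2, l2, s1, n)  # segment between IR2 and IR1
  if (g1["length"] == 0L || g2["length"] == 0L)
    toolError("E_PARTITION", "IR copies are adjacent; no single-copy segments")
  if (g1["length"] == g2["length"]) {
    warning("single-copy segments have equal length; labeling the ",
            "first-encountered segment as LSC")
    lscIsG1 <- g1["start"] <= g2["start"]
  } else {
    lscIsG1 <- g1["length"] > g2["length"]
  }
  if (lscIsG1) {
    lsc <- g1; ssc <- g2
    irb <- c(start = s2, length = l2)  # follows LSC
    ira <- c(start = s1, length = l1)
  } else {
    lsc <- g2; ssc <- g1
    irb <- c(start = s1, length = l1)
    ira <- c(start = s2, length = l2)
  }
  starts <- c(LSC = unname(lsc["start"]), IRb = unname(irb["start"]),
              SSC = unname(ssc["start"]), IRa = unname(ira["start"]))
  lengths <- c(LSC = unname(lsc["length"]), IRb = unname(irb["length"]),
               SSC = unname(ssc["length"]), IRa = unname(ira["length"]))
  new("QuadripartitePartition", starts = as.integer(starts) |> setNames(REGIONS),
      lengths = as.integer(lengths) |> setNames(REGIONS),
      genomeLength = as.integer(n))
}

#' Detect and partition in one call
#'
#' @inheritParams findInvertedRepeat
#' @return a \linkS4class{QuadripartitePartition}.
#' @export
quadripartitePartition <- function(record, minLen = 1000L) {
  ir <- findInvertedRepeat(record, minLen)
  if (!nrow(ir)) toolError("E_PARTITION", "no inverted repeat found")
  partitionGenome(record, ir)
}

# Rotate a circular record so that (1-based) position `newStart` becomes 1.
rotateRecord <- function(record, newStart) {
  n <- genomeLength(record)
  newStart <- circIndex(newStart, n)
  if (newStart == 1L) return(record)
  s <- asDnaChar(record)
  rs <- paste0(substr(s, newStart, n), substr(s, 1L, newStart - 1L))
  ft <- record@features
  if (nrow(ft)) {
    rows <- list()
    for (j in seq_len(nrow(ft))) {
      ns <- circIndex(ft$start[j] - newStart + 1L, n)
      ne <- circIndex(ft$end[j] - newStart + 1L, n)
      if (ns <= ne) {
        rows[[length(rows) + 1L]] <- transform(ft[j, ], start = ns, end = ne)
      } else {  # part now wraps the new origin: split
        rows[[length(rows) + 1L]] <- transform(ft[j, ], start = ns, end = n)
        rows[[length(rows) + 1L]] <- transform(ft[j, ], start = 1L, end = ne)
      }
    }
    ft <- do.call(rbind, rows)
    ft$part <- stats::ave(ft$part, ft$name, FUN = seq_along)
  }
  GenomeRecord(record@id, rs, circular = record@circular, features = ft)
}

# Reverse-complement a record, flipping feature coordinates and strands.
revCompRecord <- function(record) {
  n <- genomeLength(record)
  ft <- record@features
  if (nrow(ft)) {
    ns <- n - ft$end + 1L
    ne <- n - ft$start + 1L
    ft$start <- ns; ft$end <- ne
    ft$strand <- ifelse(ft$strand == "+", "-", "+")
    ft <- ft[order(ft$name, ft$start), , drop = FALSE]
    ft$part <- stats::ave(ft$part, ft$name, FUN = seq_along)
  }
  GenomeRecord(record@id, as.character(revComp(record@sequence)),
               circular = record@circular, features = ft)
}

#' Rotate a plastome to its canonical form
#'
#' Rotates the circular sequence so that position 1 is the LSC start, in the
#' orientation LSC-IRb-SSC-IRa. If a \emph{rps19} gene is annotated, the
#' orientation is chosen so that it lies near the LSC/IRb junction (the
#' standard plastome convention); otherwise the current orientation is kept.
#' Features are remapped. Idempotent, and invariant to the input rotation.
#'
#' @param record a \linkS4class{GenomeRecord}.
#' @param partition optional precomputed \linkS4class{QuadripartitePartition}.
#' @param minLen passed to \code{\link{findInvertedRepeat}} when
#'   \code{partition} is missing.
#' @return the canonicalized \linkS4class{GenomeRecord}.
#' @export
canonicalRotation <- function(record, partition = NULL, minLen = 1000L) {
  if (is.null(partition)) partition <- quadripartitePartition(record, minLen)
  n <- genomeLength(record)
  out <- rotateRecord(record, partition@starts[["LSC"]])
  lscLen <- partition@lengths[["LSC"]]
  ft <- out@features
  rps19 <- ft[ft$name == "rps19", , drop = FALSE]
  if (nrow(rps19)) {
    center <- mean(c(min(rps19$start), max(rps19$end)))
    # near LSC/IRb junction (position lscLen) vs IRa/LSC junction (origin)
    if (min(center, n - center) < abs(center - lscLen)) {
      out <- revCompRecord(out)
      ir <- findInvertedRepeat(out, min(minLen, partition@lengths[["IRb"]]))
      out <- rotateRecord(out, partitionGenome(out, ir)@starts[["LSC"]])
    }
  }
  out
}

# Cluster same-name feature parts into gene copies (IR genes occur twice);
# parts separated by more than `gapMax` are treated as separate copies.
.geneCopies <- function(features, n, gapMax = 10000L) {
  out <- list()
  for (nm in unique(features$name)) {
    parts <- features[features$name == nm, , drop = FALSE]
    parts <- parts[order(parts$start), , drop = FALSE]
    copy <- cumsum(c(1L, diff(parts$start) > gapMax))
    # wrap-around: first and last cluster may be one copy split at the origin
    for (cp in unique(copy)) {
      p <- parts[copy == cp, , drop = FALSE]
      out[[length(out) + 1L]] <- list(name = nm, strand = p$strand[1],
                                      start = min(p$start), end = max(p$end))
    }
  }
  # merge a cluster ending at n with one starting at 1 (origin-split copy)
  if (length(out) > 1L) {
    atEnd <- vapply1i(out, function(g) as.integer(g$end == n))
    atStart <- vapply1i(out, function(g) as.integer(g$start == 1L))
    for (iEnd in which(atEnd == 1L)) {
      j <- which(atStart == 1L &
                 vapply1c(out, function(g) g$name) == out[[iEnd]]$name)
      j <- setdiff(j, iEnd)
      if (length(j)) {
        out[[iEnd]]$end <- out[[j[1]]]$end + n  # wrapped span
        out[[j[1]]] <- NULL
        break
      }
    }
  }
  out
}

#' Junction-gene distance report
#'
#' For each of the four junctions (LSC/IRb, IRb/SSC, SSC/IRa, IRa/LSC),
#' reports the signed distance of flanking genes: negative means the gene
#' straddles the junction, extending \code{|distance|} bp into the region on
#' the minority side; positive means the gene's nearest end is
#' \code{distance} bp away from the junction; 0 means a gene end coincides
#' with the junction. A second column gives the distance measured from the
#' gene's strand-aware 5' start, since published reports sometimes use that
#' convention.
#'
#' @param record an annotated \linkS4class{GenomeRecord}.
#' @param partition a \linkS4class{QuadripartitePartition}.
#' @param genesOfInterest optional character vector of gene names; by default
#'   the nearest gene on each side of each junction is reported. A requested
#'   gene missing from the annotation yields an \code{NA} distance row.
#' @return data.frame with columns \code{junction}, \code{junction_position}
#'   (1-based position of the last base before the boundary), \code{gene},
#'   \code{strand}, \code{region} (majority side), \code{distance},
#'   \code{distance_gene_start}.
#' @export
junctionReport <- function(record, partition, genesOfInterest = NULL) {
  n <- genomeLength(record)
  ft <- record@features
  stopifnot(partition@genomeLength == n)
  jnames <- c("LSC/IRb", "IRb/SSC", "SSC/IRa", "IRa/LSC")
  jpos <- vapply1i(REGIONS, function(rg)
    circIndex(partition@starts[[rg]] + partition@lengths[[rg]] - 1L, n))
  names(jpos) <- jnames
  copies <- if (nrow(ft)) .geneCopies(ft, n) else list()
  if (!length(copies))
    return(data.frame(junction = character(), junction_position = integer(),
                      gene = character(), strand = character(),
                      region = character(), distance = integer(),
                      distance_gene_start = integer()))
  regionOf <- function(pos) {
    pos <- circIndex(pos, n)
    for (rg in REGIONS) {
      offp <- (pos - partition@starts[[rg]]) %% n
      if (offp < partition@lengths[[rg]]) return(rg)
    }
    REGIONS[1]
  }
  measure <- function(g, j) {
    relS <- circOffset(circIndex(g$start, n), j, n)
    relE <- relS + (g$end - g$start)
    if (relE <= 0) {                       # wholly upstream of the boundary
      d <- -relE; side <- "X"
    } else if (relS >= 1) {                # wholly downstream
      d <- relS - 1; side <- "Y"
    } else {                               # straddles
      inX <- -relS + 1L; inY <- relE
      d <- -min(inX, inY)
      side <- if (inX >= inY) "X" else "Y"
    }
    fivePrime <- if (g$strand == "+") relS else relE
    dStart <- if (fivePrime <= 0) -fivePrime else fivePrime - 1L
    list(distance = as.integer(d), side = side,
         distance_gene_start = as.integer(dStart))
  }
  rows <- list()
  for (ji in seq_along(jpos)) {
    j <- jpos[[ji]]
    xRegion <- strsplit(jnames[ji], "/")[[1]][1]
    yRegion <- strsplit(jnames[ji], "/")[[1]][2]
    ms <- lapply(copies, measure, j = j)
    dists <- vapply(ms, function(m) m$distance, numeric(1))
    if (is.null(genesOfInterest)) {
      sideX <- which(vapply1c(ms, function(m) m$side) == "X")
      sideY <- which(vapply1c(ms, function(m) m$side) == "Y")
      pick <- c(if (length(sideX)) sideX[which.min(abs(dists[sideX]))],
                if (length(sideY)) sideY[which.min(abs(dists[sideY]))])
    } else {
      nms <- vapply1c(copies, function(g) g$name)
      pick <- integer()
      for (gn in genesOfInterest) {
        cand <- which(nms == gn)
        if (!length(cand)) {
          rows[[length(rows) + 1L]] <- data.frame(
            junction = jnames[ji], junction_position = j, gene = gn,
            strand = NA_character_, region = NA_character_,
            distance = NA_integer_, distance_gene_start = NA_integer_,
            stringsAsFactors = FALSE)
        } else {
          pick <- c(pick, cand[which.min(abs(dists[cand]))])
        }
      }
    }
    for (ci in pick) {
      g <- copies[[ci]]; m <- ms[[ci]]
      region <- if (m$side == "X") xRegion else yRegion
      rows[[length(rows) + 1L]] <- data.frame(
        junction = jnames[ji], junction_position = j, gene = g$name,
        strand = g$strand, region = region, distance = m$distance,
        distance_gene_start = m$distance_gene_start, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
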