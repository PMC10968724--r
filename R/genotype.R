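# Genotyping sequence panels against a dCAPS marker.

# Do observed fragments match predicted ones within +/- tol (5 bp floor)?
.fragmentsMatch <- function(obs, pred, tol = 0.1, floor = 5L) {
  if (length(obs) != length(pred)) return(FALSE)
  obs <- sort(obs); pred <- sort(pred)
  all(abs(obs - pred) <= pmax(floor, tol * pred))
}

#' Classify a short allele window against a marker
#'
#' Gap characters are stripped first (a window printed with \code{-} gaps is
#' the non-insertion pattern). Classification is by ungapped exact
#' containment of either allele context window (in either direction), with a
#' fallback to nearest edit distance; a tie or an unalignable window (e.g.
#' all N) is uninformative.
#'
#' @param window short sequence window, possibly gapped.
#' @param marker a \linkS4class{DcapsMarker}.
#' @return list with \code{allele} (name or NA), \code{call}
#'   (cut_allele/uncut_allele/uninformative) and \code{reason}.
#' @export
classifyAlleleWindow <- function(window, marker) {
  w <- gsub("-", "", toupper(gsub("[*[:space:]]", "", as.character(window))))
  wins <- marker@alleleWindows
  toCall <- function(allele)
    list(allele = allele,
         call = if (identical(allele, marker@cutAllele)) "cut_allele"
                else "uncut_allele",
         reason = "")
  if (!nzchar(w) || grepl("[^ACGT]", w))
    return(list(allele = NA_character_, call = "uninformative",
                reason = "window empty or contains ambiguous bases"))
  contains <- vapply(wins, function(aw)
    grepl(aw, w, fixed = TRUE) || grepl(w, aw, fixed = TRUE), logical(1))
  if (sum(contains) == 1L) return(toCall(names(wins)[contains]))
  d <- as.vector(utils::adist(w, wins))
  if (d[1] == d[2])
    return(list(allele = NA_character_, call = "uninformative",
                reason = "window equidistant from both allele patterns"))
  toCall(names(wins)[which.min(d)])
}

#' Genotype a panel of samples with a dCAPS marker
#'
#' Panel entries that are full-length sequences are genotyped by simulating
#' PCR and digestion and matching the fragment multiset to the marker's
#' per-allele predictions within a size tolerance (default +/-10\% with a
#' 5-bp floor); short allele windows (such as printed panel tables, possibly
#' gapped) are classified against the marker's allele context windows via
#' \code{\link{classifyAlleleWindow}}. A sample matching neither or both
#' allele patterns is called uninformative, never guessed.
#'
#' @param marker a \linkS4class{DcapsMarker}.
#' @param panel a data.frame from \code{\link{readAlleleTable}} (columns
#'   \code{name}, \code{sequence_window}), a named character vector of
#'   sequences, or a list of \linkS4class{GenomeRecord}.
#' @param tol relative band-size tolerance.
#' @param floor absolute band-size tolerance floor (bp).
#' @param bothStrands passed to \code{\link{digestAmplicon}}.
#' @return data.frame with columns \code{sample}, \code{call},
#'   \code{allele}, \code{observed_fragments}, \code{reason}.
#' @export
genotypePanel <- function(marker, panel, tol = 0.1, floor = 5L,
                          bothStrands = FALSE) {
  if (is.data.frame(panel)) {
    entries <- setNames(as.list(panel$sequence_window), panel$name)
  } else if (is.list(panel)) {
    entries <- panel
    if (is.null(names(entries)))
      names(entries) <- vapply1c(entries, function(r)
        if (is(r, "GenomeRecord")) genomeId(r) else "sample")
  } else {
    entries <- as.list(panel)
    if (is.null(names(entries)))
      names(entries) <- paste0("sample", seq_along(entries))
  }
  minFullLen <- nchar(marker@forward@sequence) + nchar(marker@reverse@sequence) + 10L
  rows <- lapply(seq_along(entries), function(i) {
    x <- entries[[i]]
    s <- if (is(x, "GenomeRecord")) x else toupper(as.character(x))
    schr <- asDnaChar(s)
    isWindow <- grepl("-", schr, fixed = TRUE) || nchar(schr) < minFullLen
    if (!isWindow) {
      res <- tryCatch({
        amp <- insilicoPcr(s, marker@forward@sequence, marker@reverse@sequence)
        frags <- digestAmplicon(amp, marker@enzyme, bothStrands = bothStrands)
        matches <- vapply(marker@predictedFragments, function(pred)
          .fragmentsMatch(frags, pred, tol, floor), logical(1))
        if (sum(matches) == 1L) {
          allele <- names(matches)[matches]
          list(call = if (identical(allele, marker@cutAllele)) "cut_allele"
                      else "uncut_allele",
               allele = allele, obs = frags, reason = "")
        } else {
          list(call = "uninformative", allele = NA_character_, obs = frags,
               reason = if (sum(matches) == 2L)
                 "fragments match both allele predictions"
               else "fragments match neither allele prediction")
        }
      }, condition = function(c)
        list(call = "uninformative", allele = NA_character_, obs = integer(),
             reason = conditionMessage(c)))
    } else {
      cl <- classifyAlleleWindow(schr, marker)
      pred <- if (!is.na(cl$allele)) marker@predictedFragments[[cl$allele]]
              else integer()
      res <- list(call = cl$call, allele = cl$allele, obs = pred,
                  reason = cl$reason)
    }
    data.frame(sample = names(entries)[i], call = res$call,
               allele = ifelse(is.na(res$allele), NA_character_, res$allele),
               observed_fragments = paste(res$obs, collapse = ","),
               reason = res$reason, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---- marker serialization ---------------------------------------------------

#' Write a DcapsMarker to JSON
#'
#' @param marker a \linkS4class{DcapsMarker}.
#' @param path output file.
#' @export
writeDcapsMarker <- function(marker, path) {
  primerList <- function(p) list(
    sequence = p@sequence, strand = p@strand,
    template_window = as.integer(p@templateWindow),
    introduced_mismatches = p@introducedMismatches)
  obj <- list(
    forward = primerList(marker@forward),
    reverse = primerList(marker@reverse),
    enzyme = list(name = marker@enzyme@name, site = marker@enzyme@site,
                  cut_offset_top = marker@enzyme@cutOffsetTop,
                  cut_offset_bottom = marker@enzyme@cutOffsetBottom),
    variant = marker@variant,
    predicted_fragments = marker@predictedFragments,
    allele_windows = as.list(marker@alleleWindows),
    cut_allele = marker@cutAllele)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read a DcapsMarker from JSON
#'
#' @param path JSON file written by \code{\link{writeDcapsMarker}}.
#' @return a \linkS4class{DcapsMarker}.
#' @export
readDcapsMarker <- function(path) {
  if (!file.exists(path)) toolError("E_INPUT", paste("no such file:", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  asPrimer <- function(p) {
    mm <- p$introduced_mismatches
    mm <- if (is.data.frame(mm) && nrow(mm)) mm else noMismatches()
    PrimerDesign(p$sequence, p$strand, p$template_window, mm)
  }
  frags <- lapply(obj$predicted_fragments, as.integer)
  new("DcapsMarker",
      forward = asPrimer(obj$forward), reverse = asPrimer(obj$reverse),
      enzyme = RestrictionEnzyme(obj$enzyme$name, obj$enzyme$site,
                                 obj$enzyme$cut_offset_top,
                                 obj$enzyme$cut_offset_bottom),
      variant = as.data.frame(obj$variant, stringsAsFactors = FALSE),
      predictedFragments = frags,
      alleleWindows = unlist(obj$allele_windows),
      cutAllele = obj$cut_allele)
}
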