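#' Reverse complement with full IUPAC support
#'
#' @param seq DNA text (character) or \code{DNAString}; degenerate IUPAC
#'   codes are complemented (R<->Y, W<->W, ...).
#' @return reverse complement, same type as the input.
#' @examples
#' revComp("ACGTN")  # "NACGT"
#' @export
revComp <- function(seq) {
  if (is(seq, "DNAString") || is(seq, "DNAStringSet"))
    return(Biostrings::reverseComplement(seq))
  s <- toupper(chartr("uU", "tT", as.character(seq)))
  if (any(grepl("[^ACGTRYSWKMBDHVN-]", s)))
    toolError("E_ALPHABET", "non-IUPAC character in sequence")
  out <- vapply1c(s, function(x) {
    if (!nzchar(x)) return(x)
    # '-' kept as '-' so gapped windows can be flipped too
    comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  })
  out
}

#' Read genomes from a FASTA file
#'
#' Sequences are uppercased, \code{U} is mapped to \code{T}, and a record is
#' flagged circular when its header contains the token given by
#' \code{circularToken} (case-insensitive), as GenBank-derived FASTA headers
#' commonly do.
#'
#' @param path FASTA file (multi-entry, wrapped or unwrapped).
#' @param circularToken header word marking circular molecules.
#' @return list of \linkS4class{GenomeRecord}, input order preserved.
#' @export
readFastaGenomes <- function(path, circularToken = "circular") {
  if (!file.exists(path)) toolError("E_INPUT", paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(startsWith(lines, ">")))
    toolError("E_PARSE", paste("not a FASTA file (no '>' header):", path))
  hdr <- startsWith(lines, ">")
  idx <- cumsum(hdr)
  if (idx[1] == 0) toolError("E_PARSE", "sequence data before first FASTA header")
  headers <- sub("^>", "", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  # split() drops headers with empty bodies; re-align by header index
  full <- setNames(rep("", length(headers)), seq_along(headers))
  full[names(seqs)] <- seqs
  lapply(seq_along(headers), function(i) {
    s <- toupper(chartr("uU", "tT", gsub("[ \t]", "", full[[i]])))
    if (!nzchar(s))
      toolError("E_PARSE", sprintf("empty sequence for entry '%s'", headers[i]))
    bad <- regmatches(s, regexpr("[^ACGTRYSWKMBDHVN]", s))
    if (length(bad) && nzchar(bad))
      toolError("E_PARSE", sprintf("entry '%s' contains non-IUPAC character '%s'",
                                   headers[i], bad))
    # degenerate codes other than N are collapsed to N in the internal model
    s <- gsub("[RYSWKMBDHV]", "N", s)
    id <- strsplit(headers[i], "[ \t]+")[[1]][1]
    circ <- grepl(circularToken, headers[i], ignore.case = TRUE)
    GenomeRecord(id, s, circular = circ)
  })
}

#' Write GenomeRecords to FASTA
#'
#' @param records list of \linkS4class{GenomeRecord} (or a single one).
#' @param path output file.
#' @param width line wrap width.
#' @export
writeFastaGenomes <- function(records, path, width = 70L) {
  if (is(records, "GenomeRecord")) records <- list(records)
  dss <- DNAStringSet(vapply1c(records, function(r) as.character(r@sequence)))
  names(dss) <- vapply1c(records, function(r)
    paste0(r@id, if (r@circular) " circular" else ""))
  writeXStringSet(dss, path, width = width)
  invisible(path)
}

# ---- GenBank flat file ------------------------------------------------------

# Parse a GenBank location string into a part table (1-based inclusive).
parseGenbankLocation <- function(loc) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (startsWith(loc, "complement(")) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (startsWith(loc, "join(") || startsWith(loc, "order(")) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",")[[1]]
  tab <- lapply(parts, function(p) {
    pstrand <- strand
    if (startsWith(p, "complement(")) {
      pstrand <- if (strand == "+") "-" else "+"
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      se <- as.integer(strsplit(p, "\\.\\.")[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      se <- c(as.integer(p), as.integer(p))
    } else {
      toolError("E_PARSE", sprintf("unparseable location part '%s'", p))
    }
    data.frame(start = se[1], end = se[2], strand = pstrand,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tab)
  if (strand == "-") out <- out[rev(seq_len(nrow(out))), , drop = FALSE]
  out$part <- seq_len(nrow(out))
  out
}

# Render a feature part table back to a GenBank location string.
formatGenbankLocation <- function(parts) {
  strand <- parts$strand[1]
  p <- parts[order(parts$part), , drop = FALSE]
  if (strand == "-") p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  spans <- ifelse(p$start == p$end, as.character(p$start),
                  paste0(p$start, "..", p$end))
  loc <- if (length(spans) > 1L) paste0("join(", paste(spans, collapse = ","), ")")
         else spans
  if (strand == "-") paste0("complement(", loc, ")") else loc
}

#' Read a GenBank flat file
#'
#' Minimal reader for annotated (possibly circular) genome records: the
#' sequence is taken from the ORIGIN block and \code{gene}, \code{tRNA} and
#' \code{rRNA} features (with \code{join}/\code{complement} locations) are
#' mapped into the \linkS4class{GenomeRecord} feature table. GenBank 1-based
#' inclusive coordinates are kept as-is (the package-wide convention). LOCUS
#' line dialects of DDBJ/ENA are tolerated.
#'
#' @param path GenBank flat file.
#' @return a \linkS4class{GenomeRecord}.
#' @export
readGenBank <- function(path) {
  if (!file.exists(path)) toolError("E_INPUT", paste("no such file:", path))
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- "unknown"
  circular <- FALSE
  if (length(locus)) {
    toks <- strsplit(trimws(locus[1]), "[ \t]+")[[1]]
    if (length(toks) >= 2) id <- toks[2]
    circular <- any(tolower(toks) == "circular")
  }
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc)) {
    a <- strsplit(trimws(acc[1]), "[ \t]+")[[1]]
    if (length(a) >= 2 && nzchar(a[2])) id <- a[2]
  }
  oi <- grep("^ORIGIN", lines)
  if (!length(oi)) toolError("E_PARSE", "GenBank record has no ORIGIN block")
  seqLines <- lines[(oi[1] + 1L):length(lines)]
  endi <- grep("^//", seqLines)
  if (length(endi)) seqLines <- seqLines[seq_len(endi[1] - 1L)]
  s <- toupper(gsub("[0-9 /\t]", "", paste(seqLines, collapse = "")))
  s <- chartr("U", "T", s)
  if (!nzchar(s)) toolError("E_PARSE", "empty ORIGIN block")

  fi <- grep("^FEATURES", lines)
  feats <- emptyFeatures()
  if (length(fi)) {
    block <- lines[(fi[1] + 1L):(oi[1] - 1L)]
    keyLine <- grepl("^ {5}\\S", block)
    idx <- cumsum(keyLine)
    rows <- list()
    for (g in split(block, idx)) {
      if (!grepl("^ {5}\\S", g[1])) next
      key <- sub("^ {5}(\\S+).*", "\\1", g[1])
      if (!key %in% c("gene", "tRNA", "rRNA", "CDS")) next
      # location may continue over lines until the first qualifier
      qual <- grep("^ {10,}/", g)
      locEnd <- if (length(qual)) qual[1] - 1L else length(g)
      loc <- paste(trimws(c(sub("^ {5}\\S+\\s*", "", g[1]),
                            if (locEnd >= 2) g[2:locEnd] else character())),
                   collapse = "")
      name <- NA_character_
      gq <- grep('^\\s*/gene="', g, value = TRUE)
      if (length(gq)) name <- sub('.*?/gene="([^"]*)".*', "\\1", gq[1])
      if (is.na(name)) {
        pq <- grep('^\\s*/(product|label)="', g, value = TRUE)
        if (length(pq)) name <- sub('.*?="([^"]*)".*', "\\1", pq[1])
      }
      if (is.na(name)) name <- key
      parts <- parseGenbankLocation(loc)
      kind <- switch(key, gene = "gene", tRNA = "tRNA", rRNA = "rRNA", "other")
      if (key == "CDS") next  # gene-level features suffice for junction work
      rows[[length(rows) + 1L]] <- data.frame(
        name = name, kind = kind, strand = parts$strand,
        start = parts$start, end = parts$end, part = parts$part,
        stringsAsFactors = FALSE)
    }
    if (length(rows)) feats <- do.call(rbind, rows)
  }
  GenomeRecord(id, s, circular = circular, features = feats)
}

#' Write a GenomeRecord as a minimal GenBank flat file
#'
#' @param record a \linkS4class{GenomeRecord}.
#' @param path output file.
#' @export
writeGenBank <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- genomeLength(record)
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN %s",
                     record@id, n,
                     if (record@circular) "circular" else "linear",
                     format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s.", record@id), con)
  writeLines(sprintf("ACCESSION   %s", record@id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  ft <- record@features
  if (nrow(ft)) {
    for (nm in unique(ft$name)) {
      parts <- ft[ft$name == nm, , drop = FALSE]
      key <- parts$kind[1]
      if (key == "other") key <- "misc_feature"
      writeLines(sprintf("     %-15s %s", key, formatGenbankLocation(parts)), con)
      writeLines(sprintf('                     /gene="%s"', nm), con)
    }
  }
  writeLines("ORIGIN", con)
  s <- tolower(as.character(record@sequence))
  starts <- seq(1L, n, by = 60L)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59L, n))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a cultivar allele table
#'
#' Reads a TSV with a header whose sequence column holds short allele windows
#' possibly containing \code{-} gap characters. Markup characters
#' (\code{*}, whitespace) inside sequences are stripped; gaps are kept.
#'
#' @param path TSV file.
#' @param seqColumn name of the sequence column; by default the first column
#'   whose name contains "seq" (case-insensitive).
#' @return data.frame with columns \code{index}, \code{name},
#'   \code{sequence_window} plus any further metadata columns, one row per
#'   panel entry, input order preserved.
#' @export
readAlleleTable <- function(path, seqColumn = NULL) {
  if (!file.exists(path)) toolError("E_INPUT", paste("no such file:", path))
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "#", quote = "")
  if (is.null(seqColumn)) {
    hit <- grep("seq", names(tab), ignore.case = TRUE, value = TRUE)
    if (!length(hit)) toolError("E_PARSE", "allele table has no sequence column")
    seqColumn <- hit[1]
  } else if (!seqColumn %in% names(tab)) {
    toolError("E_PARSE", sprintf("no column '%s' in allele table", seqColumn))
  }
  win <- toupper(gsub("[*[:space:]]", "", tab[[seqColumn]]))
  if (any(!nzchar(win))) toolError("E_PARSE", "empty sequence window in allele table")
  if (any(grepl("[^ACGTN-]", win)))
    toolError("E_PARSE", "allele window contains characters outside {A,C,G,T,N,-}")
  nameCol <- grep("^name$", names(tab), ignore.case = TRUE, value = TRUE)
  nm <- if (length(nameCol)) as.character(tab[[nameCol[1]]]) else
    paste0("entry", seq_len(nrow(tab)))
  if (anyDuplicated(nm))
    warning("duplicate cultivar names in allele table: ",
            paste(unique(nm[duplicated(nm)]), collapse = ", "))
  idxCol <- grep("^(no\\.?|index)$", names(tab), ignore.case = TRUE, value = TRUE)
  idx <- if (length(idxCol)) suppressWarnings(as.integer(gsub("[^0-9]", "", tab[[idxCol[1]]])))
         else seq_len(nrow(tab))
  meta <- tab[, setdiff(names(tab), c(seqColumn, nameCol, idxCol)), drop = FALSE]
  out <- data.frame(index = idx, name = nm, sequence_window = win,
                    stringsAsFactors = FALSE)
  cbind(out, meta)
}
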