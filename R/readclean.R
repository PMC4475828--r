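#' Alignment scoring parameters for read cleaning
#'
#' Global alignment scores used against the in-frame consensus reference.
#' Defaults: match +2, mismatch -3, and linear gap costs of 7 per gapped
#' base (gap opening 0). Linear rather than affine gap costs matter here:
#' homopolymer indels are independent scattered events, and an affine
#' opening penalty would merge clustered single-base insertions into one
#' gap block at the price of spurious mismatches.
#'
#' @param match match score.
#' @param mismatch mismatch score.
#' @param gapOpening gap opening penalty (positive cost; default 0).
#' @param gapExtension per-base gap penalty (positive cost).
#' @return list of scoring parameters.
#' @export
alignmentScoring <- function(match = 2, mismatch = -3,
                             gapOpening = 0, gapExtension = 7) {
  list(match = match, mismatch = mismatch,
       gapOpening = gapOpening, gapExtension = gapExtension)
}

# fixed tie-break priority among orientation candidates
ORIENTATIONS <- c("forward", "reverse-complement", "complement", "reverse")

orientRead <- function(x, orientation) {
  switch(orientation,
    "forward" = x,
    "complement" = Biostrings::complement(x),
    "reverse" = Biostrings::reverse(x),
    "reverse-complement" = Biostrings::reverseComplement(x))
}

#' Best-orientation global alignment of a read against the reference
#'
#' Aligns the read, its complement, reverse, and reverse complement
#' globally (affine gaps) against the in-frame consensus reference and
#' returns the highest-scoring candidate. Ties are broken by the fixed
#' priority forward > reverse-complement > complement > reverse.
#'
#' @param read nucleotide string (IUPAC letters).
#' @param reference reference nucleotide string (no gaps).
#' @param scoring list from [alignmentScoring()].
#' @return list with `alignedRead` and `alignedRef` (equal-length gapped
#'   strings), `orientation`, and `score`.
#' @examples
#' ref <- "ATGGCAAGTTGG"
#' bestOrientationAlignment(ref, ref)$orientation             # "forward"
#' @export
bestOrientationAlignment <- function(read, reference,
                                     scoring = alignmentScoring()) {
  if (nchar(read) == 0) stop("read must be non-empty")
  res <- cleanReads(setNames(read, "read"), reference, scoring = scoring,
                    .keepAlignments = TRUE)
  al <- res$alignments[[1]]
  if (is.null(al)) stop("read rejected before alignment: ",
                        res$details$reason[1])
  al
}

# among equal-score gap placements, prefer excising read bases that are
# plausible homopolymer copies: a true inserted copy always has a retained
# identical neighbour in the read. An insertion next to a true polymorphism
# (or inside a locally periodic context) admits several optimal alignments,
# most of which erase the polymorphism; those leave some excised base
# without a retained identical neighbour, which flags the read for a
# bounded repair search over nearby excision sets at equal alignment score.
canonicalizeExcision <- function(readChars, excised, refChars) {
  S <- sort(unique(excised))
  n <- length(readChars)
  mism <- function(S) sum((if (length(S)) readChars[-S] else readChars) != refChars)
  # an excised base is a plausible homopolymer copy iff its maximal run in
  # the raw read retains at least one identical base after all excisions
  runId <- rep.int(seq_along(rle(readChars)$lengths), rle(readChars)$lengths)
  runLen <- rle(readChars)$lengths
  nConf <- function(S) {
    exPerRun <- tabulate(runId[S], nbins = length(runLen))
    sum((runLen[runId[S]] - exPerRun[runId[S]]) >= 1L)
  }
  confOf <- function(q, S) {
    exPerRun <- sum(runId[S] == runId[q])
    (runLen[runId[q]] - exPerRun) >= 1L
  }
  if (length(S) && nConf(S) < length(S)) {
    baseM <- mism(S)
    for (pass in 1:2) {
      moved <- FALSE
      for (i in seq_along(S)) {
        q <- S[i]
        if (confOf(q, S)) next
        for (d in c(-1L, 1L, -2L, 2L)) {
          q2 <- q + d
          if (q2 < 1L || q2 > n || q2 %in% S) next
          S2 <- sort(c(S[-i], q2))
          if (mism(S2) > baseM) next
          if (!confOf(q2, S2)) next
          S <- S2; baseM <- mism(S2); moved <- TRUE
          break
        }
      }
      if (!moved) break
    }
  }
  list(positions = S,
       sequence = paste(if (length(S)) readChars[-S] else readChars,
                        collapse = ""))
}

#' Excise frameshift bases from a read/reference alignment
#'
#' Every read base aligned to a reference gap (an insertion in the read,
#' assumed to be an erroneous homopolymer) is excised, and the read is
#' trimmed to the reference span. If the trimmed read still contains gaps
#' relative to the reference (a deletion, or incomplete coverage of the
#' reference) it is rejected with reason "gap". Where an equally scoring
#' gap placement exists, the excised base is canonicalized to a
#' homopolymer duplicate (see Details).
#'
#' @details Alignment ties are real: an inserted copy of a base next to a
#' true polymorphism admits two optimal alignments, one of which erases
#' the polymorphism. Excisions are therefore canonicalized: an excised
#' base that does not duplicate an adjacent read base is exchanged for an
#' adjacent one that does, provided the positional mismatch count against
#' the reference (hence the alignment score) is unchanged.
#'
#' @param alignment list from [bestOrientationAlignment()].
#' @return list with `status` ("passed"/"rejected"), `sequence` (reference
#'   length, no gaps) and `nExcised` when passed, `reason` when rejected.
#' @examples
#' ref <- "ATGGCAAGTTGG"
#' al <- bestOrientationAlignment("ATGGCAAAGTTGG", ref)  # one extra A
#' exciseFrameshiftBases(al)$sequence                    # equals ref
#' @export
exciseFrameshiftBases <- function(alignment) {
  readChars <- strsplit(alignment$alignedRead, "", fixed = TRUE)[[1]]
  refChars <- strsplit(alignment$alignedRef, "", fixed = TRUE)[[1]]
  insCols <- refChars == "-"
  if (any(readChars[!insCols] == "-"))
    return(list(status = "rejected", reason = "gap"))
  raw <- readChars[readChars != "-"]
  excised <- cumsum(readChars != "-")[insCols]
  can <- canonicalizeExcision(raw, excised, refChars[!insCols])
  list(status = "passed", sequence = can$sequence,
       nExcised = length(can$positions), orientation = alignment$orientation)
}

#' Clean a batch of raw reads against the consensus reference
#'
#' Removes homopolymer frameshift artifacts: each read is aligned in four
#' orientations to the in-frame consensus reference
#' ([bestOrientationAlignment()]); bases gapping the reference frame are
#' excised and the read trimmed to reference length
#' ([exciseFrameshiftBases()]). Reads with residual gaps are rejected
#' ("gap"); reads with non-IUPAC characters or shorter than half the
#' reference are rejected ("quality"). Deterministic given inputs.
#'
#' @param reads named character vector, or a `DNAStringSet`, of raw reads.
#' @param reference reference nucleotide string (or length-1 DNAStringSet).
#' @param scoring list from [alignmentScoring()].
#' @param cdnaWindow optional c(start, end): trim passed reads to this
#'   1-based reference window (cDNA mode, default the 247-bp segment used
#'   for transcript matching is up to the caller).
#' @param .keepAlignments internal: retain per-read alignments.
#' @return list with `cleaned` (named character vector, all of reference —
#'   or window — length), `report` (n_input, n_passed, n_rejected_gap,
#'   n_rejected_quality; counts conserved) and `details` (per-read
#'   data.frame: id, status, reason, orientation, n_excised).
#' @examples
#' ref <- "ATGGCAAGTTGGACCT"
#' out <- cleanReads(c(a = ref, b = "ATGGCAAAGTTGGACCT"), ref)
#' out$report$n_passed   # 2
#' @export
cleanReads <- function(reads, reference, scoring = alignmentScoring(),
                       cdnaWindow = NULL, .keepAlignments = FALSE) {
  if (is(reads, "XStringSet")) reads <- setNames(as.character(reads), names(reads))
  if (is(reference, "XStringSet")) reference <- as.character(reference[[1]])
  if (grepl("-", reference, fixed = TRUE)) stop("reference must contain no gaps")
  n <- length(reads)
  ids <- names(reads)
  if (is.null(ids)) ids <- sprintf("read%d", seq_len(n))
  empty <- list(
    cleaned = setNames(character(0), character(0)),
    report = list(n_input = 0L, n_passed = 0L, n_rejected_gap = 0L,
                  n_rejected_quality = 0L),
    details = data.frame(id = character(), status = character(),
                         reason = character(), orientation = character(),
                         n_excised = integer(), stringsAsFactors = FALSE))
  if (n == 0L) return(empty)

  status <- character(n); reason <- rep(NA_character_, n)
  orientation <- rep(NA_character_, n); nExc <- rep(NA_integer_, n)
  cleaned <- rep(NA_character_, n)
  alignments <- if (.keepAlignments) vector("list", n) else NULL

  okChars <- grepl("^[ACGTRYSWKMBDHVNacgtryswkmbdhvn]+$", reads)
  longEnough <- nchar(reads) >= 0.5 * nchar(reference)
  quality <- !(okChars & longEnough)
  status[quality] <- "rejected"; reason[quality] <- "quality"

  idx <- which(!quality)
  if (length(idx)) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
    ref <- Biostrings::DNAString(reference)
    refLen <- nchar(reference)
    rset <- Biostrings::DNAStringSet(toupper(reads[idx]))
    scores <- matrix(-Inf, length(idx), length(ORIENTATIONS))
    pas <- vector("list", length(ORIENTATIONS))
    oriented <- vector("list", length(ORIENTATIONS))
    for (k in seq_along(ORIENTATIONS)) {
      oriented[[k]] <- orientRead(rset, ORIENTATIONS[k])
      pas[[k]] <- Biostrings::pairwiseAlignment(
        oriented[[k]], ref, type = "global",
        substitutionMatrix = mat, gapOpening = scoring$gapOpening,
        gapExtension = scoring$gapExtension)
      scores[, k] <- Biostrings::score(pas[[k]])
    }
    # ties resolved by column order = fixed orientation priority
    best <- apply(scores, 1, which.max)
    for (k in seq_along(ORIENTATIONS)) {
      sel <- which(best == k)
      if (!length(sel)) next
      pa <- pas[[k]]
      # read bases gapping the reference frame, and reference positions
      # unmatched by the read; insertion() anchors each range after the
      # removal of preceding insertions, so shift back to read coordinates
      nDel <- lengths(Biostrings::deletion(pa))[sel]
      insRanges <- IRanges::IRangesList(lapply(
        seq_along(sel), function(j) {
          # reads with deletions are rejected below; their subject-anchored
          # coordinates cannot be mapped back onto the read
          if (nDel[j] > 0L) return(IRanges::IRanges())
          ir <- Biostrings::insertion(pa)[[sel[j]]]
          if (length(ir) > 1L) {
            w <- IRanges::width(ir)
            ir <- IRanges::shift(ir, cumsum(c(0L, w[-length(w)])))
          }
          ir
        }))
      exSeq <- rep(NA_character_, length(sel))
      noDel <- nDel == 0L
      exSeq[noDel] <- as.character(Biostrings::replaceAt(
        oriented[[k]][sel[noDel]], insRanges[noDel], ""))
      ok <- noDel & !is.na(exSeq) & nchar(exSeq) == refLen
      nExcised <- sum(IRanges::width(insRanges))
      # terminal read overhangs are end gaps in the subject and are not
      # reported by insertion(); resolve those few via the gapped strings
      slow <- which(nDel == 0L & nchar(exSeq) > refLen)
      for (j in slow) {
        ex <- exciseFrameshiftBases(list(
          alignedRead = as.character(Biostrings::alignedPattern(pa[sel[j]])),
          alignedRef = as.character(Biostrings::alignedSubject(pa[sel[j]])),
          orientation = ORIENTATIONS[k]))
        if (ex$status == "passed") {
          ok[j] <- TRUE
          exSeq[j] <- ex$sequence
          nExcised[j] <- ex$nExcised
        }
      }
      refChars <- strsplit(reference, "", fixed = TRUE)[[1]]
      orientedChar <- as.character(oriented[[k]][sel])
      for (j in setdiff(which(ok & nExcised > 0L), slow)) {
        ir <- insRanges[[j]]
        pos <- unlist(mapply(seq.int, IRanges::start(ir), IRanges::end(ir),
                             SIMPLIFY = FALSE))
        can <- canonicalizeExcision(
          strsplit(orientedChar[j], "", fixed = TRUE)[[1]], pos, refChars)
        exSeq[j] <- can$sequence
      }
      i <- idx[sel]
      status[i] <- ifelse(ok, "passed", "rejected")
      reason[i[!ok]] <- "gap"
      cleaned[i[ok]] <- exSeq[ok]
      nExc[i[ok]] <- nExcised[ok]
      orientation[i[ok]] <- ORIENTATIONS[k]
      if (.keepAlignments) {
        for (j in seq_along(sel)) {
          alignments[[idx[sel[j]]]] <- list(
            alignedRead = as.character(Biostrings::alignedPattern(pa[sel[j]])),
            alignedRef = as.character(Biostrings::alignedSubject(pa[sel[j]])),
            orientation = ORIENTATIONS[k], score = scores[sel[j], k])
        }
      }
    }
  }

  passed <- status == "passed"
  out <- setNames(cleaned[passed], ids[passed])
  if (!is.null(cdnaWindow)) {
    stopifnot(length(cdnaWindow) == 2, cdnaWindow[1] >= 1,
              cdnaWindow[2] <= nchar(reference))
    out <- setNames(substr(out, cdnaWindow[1], cdnaWindow[2]), names(out))
  }
  res <- list(
    cleaned = out,
    report = list(
      n_input = n, n_passed = sum(passed),
      n_rejected_gap = sum(reason == "gap", na.rm = TRUE),
      n_rejected_quality = sum(reason == "quality", na.rm = TRUE)),
    details = data.frame(id = ids, status = status, reason = reason,
                         orientation = orientation, n_excised = nExc,
                         stringsAsFactors = FALSE))
  if (.keepAlignments) res$alignments <- alignments
  res
}

#' Write a cleaning report as TSV
#'
#' @param result result of [cleanReads()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeCleaningReport <- function(result, path) {
  utils::write.table(result$details, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
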