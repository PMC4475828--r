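#' Dereplicate cleaned reads and count variants per sample
#'
#' Collapses cleaned, reference-framed reads into unique sequence variants
#' and counts exact occurrences per sample. Variant ordering is
#' deterministic: descending total count across samples, ties broken
#' lexicographically by sequence. Samples with no reads are retained as
#' zero columns.
#'
#' @param readsBySample named list: sample id -> character vector of
#'   cleaned reads (all the same length).
#' @return a [VariantTable-class].
#' @examples
#' vt <- dereplicateAndCount(list(s1 = c("AAA", "AAA", "AAT")))
#' variantTotals(vt)
#' @export
dereplicateAndCount <- function(readsBySample) {
  stopifnot(is.list(readsBySample), !is.null(names(readsBySample)))
  all <- unlist(readsBySample, use.names = FALSE)
  if (length(all) && length(unique(nchar(all))) != 1L)
    stop("cleaned reads must all share the reference length")
  uniq <- unique(all)
  counts <- vapply(readsBySample, function(r) {
    tabulate(match(r, uniq), nbins = length(uniq))
  }, integer(length(uniq)))
  counts <- matrix(as.integer(counts), nrow = length(uniq),
                   dimnames = list(NULL, names(readsBySample)))
  ord <- order(-rowSums(counts), uniq)
  uniq <- uniq[ord]
  counts <- counts[ord, , drop = FALSE]
  ids <- sprintf("v%03d", seq_along(uniq))
  rownames(counts) <- ids
  new("VariantTable", sequences = setNames(uniq, ids), counts = counts)
}

#' Select high-frequency sequences (HFS)
#'
#' A variant is an HFS when its total count across ALL samples is strictly
#' greater than the threshold (default 50, the definition used for putative
#' ecotype demarcation; 10 is a common alternate for broader surveys).
#'
#' @param table a [VariantTable-class].
#' @param threshold integer >= 0.
#' @return list with `threshold`, `members` (named character vector of HFS
#'   sequences) and `totals` (their total counts).
#' @examples
#' vt <- dereplicateAndCount(list(s = rep(c("AA", "AT"), c(51, 50))))
#' names(selectHFS(vt, 50)$members)   # only the first variant
#' @export
selectHFS <- function(table, threshold = 50L) {
  stopifnot(is(table, "VariantTable"), threshold >= 0)
  tot <- variantTotals(table)
  keep <- tot > threshold
  list(threshold = as.integer(threshold),
       members = variantSequences(table)[keep],
       totals = tot[keep])
}

# percent positional identity between equal-length reference-framed strings
percentIdentity <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(x) != length(y)) stop("sequences must share the reference frame")
  100 * sum(x == y) / length(x)
}

#' Assign variants to Synechococcus lineages
#'
#' Labels each reference-framed variant by positional identity (no
#' realignment) to lineage reference homologs: `A` or `Bprime` when the
#' variant is >= `identityFloor` percent identical to that genomic homolog
#' and it is the best match; `Aprime` when the best match overall lies in
#' the A-prime reference set (sequences from high-temperature metagenomic
#' libraries; no identity floor by default); otherwise `unclassified`.
#'
#' @param variants character vector of variant sequences.
#' @param refs list with elements `A` (single sequence), `Bprime` (single
#'   sequence) and optionally `Aprime` (character vector of sequences).
#' @param identityFloor percent identity floor for A/Bprime calls
#'   (default 95).
#' @param aprimeFloor optional identity floor for Aprime calls (default 0).
#' @return data.frame with columns `lineage` (A, Bprime, Aprime,
#'   unclassified) and `identity` (percent identity to the best reference).
#' @export
assignLineage <- function(variants, refs, identityFloor = 95,
                          aprimeFloor = 0) {
  if (is.null(refs$A) || is.null(refs$Bprime))
    stop("refs must provide 'A' and 'Bprime' homolog sequences")
  aprime <- refs$Aprime
  out <- lapply(variants, function(v) {
    cand <- c(A = percentIdentity(v, refs$A),
              Bprime = percentIdentity(v, refs$Bprime))
    if (length(aprime))
      cand <- c(cand, Aprime = max(vapply(aprime, percentIdentity, 0, a = v)))
    best <- names(cand)[which.max(cand)]   # ties: A > Bprime > Aprime
    id <- max(cand)
    label <- if (best == "Aprime" && id >= aprimeFloor) "Aprime"
      else if (best %in% c("A", "Bprime") && id >= identityFloor) best
      else "unclassified"
    list(label = label, id = id)
  })
  data.frame(lineage = vapply(out, `[[`, "", "label"),
             identity = vapply(out, `[[`, 0, "id"),
             row.names = names(variants), stringsAsFactors = FALSE)
}

#' Write a VariantTable as TSV
#'
#' Long header: variant id, sequence, then one count column per sample.
#'
#' @param table a [VariantTable-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeVariantTable <- function(table, path) {
  df <- data.frame(variant = names(variantSequences(table)),
                   sequence = unname(variantSequences(table)),
                   variantCounts(table), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export HFS as FASTA
#'
#' @param hfs result of [selectHFS()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeHFSFasta <- function(hfs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(hfs$members), path)
  invisible(path)
}
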