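#' Assign low-frequency sequences to putative ecotypes
#'
#' Each LFS variant is placed by reference-framed Hamming distance to the
#' HFS variants carrying the PE demarcation. When the nearest and
#' second-nearest HFS belong to the same PE the LFS falls within that PE's
#' clade (basis "LFS-within-clade"); otherwise it is tentatively assigned
#' to the PE of its nearest HFS (basis "LFS-nearest-PE"). Distance ties
#' are broken toward the PE whose tied nearest HFS has the larger total
#' count across all samples. HFS variants themselves are carried through
#' with basis "HFS-member".
#'
#' @param table a [VariantTable-class] covering all variants (HFS + LFS).
#' @param hfs result of [selectHFS()] used for demarcation.
#' @param partition a [PEPartition-class] over the HFS variant ids.
#' @return data.frame with columns `variant`, `pe`, `basis`.
#' @export
assignLFS <- function(table, hfs, partition) {
  seqs <- variantSequences(table)
  totals <- variantTotals(table)
  hfsIds <- names(hfs$members)
  stopifnot(all(hfsIds %in% names(seqs)),
            all(names(peAssignments(partition)) %in% hfsIds))
  pe <- peAssignments(partition)
  lfsIds <- setdiff(names(seqs), hfsIds)
  hfsChars <- do.call(rbind, strsplit(seqs[hfsIds], "", fixed = TRUE))
  out <- data.frame(variant = names(seqs), pe = NA_character_,
                    basis = NA_character_, stringsAsFactors = FALSE)
  rownames(out) <- out$variant
  out[hfsIds, "pe"] <- pe[hfsIds]
  out[hfsIds, "basis"] <- "HFS-member"
  for (v in lfsIds) {
    d <- colSums(t(hfsChars) != strsplit(seqs[[v]], "", fixed = TRUE)[[1]])
    ord <- order(d, -totals[hfsIds], hfsIds)
    nearest <- hfsIds[ord[1]]
    second <- if (length(hfsIds) > 1) hfsIds[ord[2]] else nearest
    within <- pe[nearest] == pe[second]
    out[v, "pe"] <- pe[[nearest]]
    out[v, "basis"] <- if (within) "LFS-within-clade" else "LFS-nearest-PE"
  }
  out
}

#' Per-sample putative-ecotype abundance profile
#'
#' The percentage contribution of each PE in each sample:
#' (PE sequences in sample / all assigned sequences in sample) x 100,
#' decomposed into the dominant variant, other HFS, and pooled LFS
#' components. Samples with zero assigned reads yield missing percentages
#' with a warning. Replicate samples (same temperature, depth, timepoint
#' and condition) can be summarized with [summarizeReplicates()].
#'
#' @param table a [VariantTable-class].
#' @param assignment data.frame from [assignLFS()].
#' @return list with `percent` (PE x sample matrix), and `components`
#'   (long data.frame: pe, sample, total_pct, dominant_pct, hfs_pct,
#'   lfs_pct).
#' @export
peAbundance <- function(table, assignment) {
  counts <- variantCounts(table)
  stopifnot(setequal(rownames(counts), assignment$variant))
  assignment <- assignment[rownames(counts), ]
  pes <- sort(unique(assignment$pe))
  totals <- colSums(counts)
  if (any(totals == 0))
    warning("samples with zero assigned reads: ",
            paste(colnames(counts)[totals == 0], collapse = ", "))
  agg <- function(rows) {
    m <- counts[rows, , drop = FALSE]
    100 * colSums(m) / ifelse(totals == 0, NA_real_, totals)
  }
  percent <- t(vapply(pes, function(p) agg(assignment$pe == p),
                      numeric(ncol(counts))))
  dimnames(percent) <- list(pes, colnames(counts))
  comp <- do.call(rbind, lapply(pes, function(p) {
    rows <- which(assignment$pe == p)
    isHfs <- assignment$basis[rows] == "HFS-member"
    # dominant variant: the PE's HFS with the largest total count
    rowTot <- rowSums(counts[rows, , drop = FALSE])
    dom <- rows[isHfs][which.max(rowTot[isHfs])]
    data.frame(
      pe = p, sample = colnames(counts),
      total_pct = percent[p, ],
      dominant_pct = agg(seq_len(nrow(counts)) %in% dom),
      hfs_pct = agg(seq_len(nrow(counts)) %in% setdiff(rows[isHfs], dom)),
      lfs_pct = agg(seq_len(nrow(counts)) %in% rows[!isHfs]),
      row.names = NULL, stringsAsFactors = FALSE)
  }))
  list(percent = percent, components = comp)
}

#' Mean and range of PE percentages over replicate samples
#'
#' @param profile result of [peAbundance()].
#' @param samples sample metadata (as from [sampleMetadata()]); replicates
#'   share temperature, depth, timepoint and condition.
#' @return data.frame: pe, temperature_C, depth_um, timepoint, condition,
#'   mean_pct, min_pct, max_pct, n_replicates.
#' @export
summarizeReplicates <- function(profile, samples) {
  key <- interaction(samples$temperature_C, samples$depth_um,
                     samples$timepoint, samples$condition, drop = TRUE)
  out <- do.call(rbind, lapply(rownames(profile$percent), function(p) {
    do.call(rbind, lapply(levels(key), function(k) {
      idx <- which(key == k)
      v <- profile$percent[p, samples$sample_id[idx]]
      data.frame(pe = p,
                 temperature_C = samples$temperature_C[idx[1]],
                 depth_um = samples$depth_um[idx[1]],
                 timepoint = samples$timepoint[idx[1]],
                 condition = samples$condition[idx[1]],
                 mean_pct = mean(v), min_pct = min(v), max_pct = max(v),
                 n_replicates = length(idx), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Write an abundance profile as long-format TSV
#'
#' @param profile result of [peAbundance()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeAbundanceProfile <- function(profile, path) {
  utils::write.table(profile$components, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
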