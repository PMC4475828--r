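#' Generate the haplotypes of one ecotype
#'
#' Builds the dominant variant plus high-frequency (HFS) and low-frequency
#' (LFS) haplotypes of a single ecotype by planting substitutions at
#' uniformly random, mutually disjoint positions of the reference frame.
#' Substitutions only: all haplotypes share the reference length, so
#' frame-based read cleaning has unambiguous ground truth. Each
#' non-dominant HFS differs from the dominant by exactly `withinDistance`
#' substitutions at its own positions (hence pairwise HFS distances are
#' `withinDistance` or `2 * withinDistance`); each LFS differs from a
#' randomly chosen HFS parent by one further substitution.
#'
#' @param spec an [EcotypeSpec-class]. If its `dominant` slot is empty the
#'   reference itself (or a mutated copy, see `dominantDistance`) is used.
#' @param reference nucleotide string defining length and frame.
#' @param withinDistance substitutions separating each HFS from the
#'   dominant variant (default 2).
#' @param dominantDistance substitutions separating the dominant from the
#'   reference (default 0); used by [communityHaplotypes()] to separate
#'   ecotypes.
#' @param reservedPositions positions of the reference that must not be
#'   mutated (used to keep ecotypes disjoint).
#' @param seed optional integer seed.
#' @return data.frame with columns `ecotype`, `haplotype_id`, `class`
#'   (dominant/HFS/LFS) and `sequence`; attribute `"positions"` records the
#'   reference positions touched.
#' @examples
#' sp <- ecotypeSpec("E1", c(60, 400), nHfs = 3, nLfs = 1)
#' h <- generateHaplotypes(sp, strrep("ACGT", 20), seed = 1)
#' table(h$class)
#' @export
generateHaplotypes <- function(spec, reference, withinDistance = 2L,
                               dominantDistance = 0L,
                               reservedPositions = integer(), seed = NULL) {
  stopifnot(is(spec, "EcotypeSpec"))
  L <- nchar(reference)
  if (L < 1) stop("reference must be non-empty")
  withSeed(seed, {
    refChars <- strsplit(reference, "", fixed = TRUE)[[1]]
    # substitutions go only to homopolymer-free, mutually non-adjacent
    # sites so that frameshift excision has provably unambiguous output
    free <- setdiff(eligibleMutationSites(refChars), reservedPositions)
    needed <- dominantDistance + (spec@nHfs - 1L) * withinDistance + spec@nLfs
    if (length(free) < needed)
      stop("reference shorter than requested number of distinct mutation sites")
    takePos <- function(k) {
      pos <- integer(k)
      for (i in seq_len(k)) {
        if (length(free) < 1L)
          stop("reference shorter than requested number of distinct mutation sites")
        p <- if (length(free) == 1L) free else sample(free, 1L)
        # enforce pairwise spacing: adjacent substitutions would let the
        # excision alignment trade one polymorphism against another
        free <<- setdiff(free, c(p - 1L, p, p + 1L))
        pos[i] <- p
      }
      pos
    }
    if (nzchar(spec@dominant)) {
      if (nchar(spec@dominant) != L)
        stop("dominant haplotype length must equal reference length")
      domChars <- strsplit(spec@dominant, "", fixed = TRUE)[[1]]
    } else {
      domChars <- refChars
      for (p in takePos(dominantDistance)) domChars <- substituteBase(domChars, p, refChars)
    }
    haps <- list(list(id = paste0(spec@id, ".d"), class = "dominant",
                      chars = domChars))
    if (spec@nHfs > 1L) {
      for (i in seq_len(spec@nHfs - 1L)) {
        ch <- domChars
        for (p in takePos(withinDistance)) ch <- substituteBase(ch, p, refChars)
        haps[[length(haps) + 1L]] <-
          list(id = sprintf("%s.h%d", spec@id, i), class = "HFS", chars = ch)
      }
    }
    if (spec@nLfs > 0L) {
      for (j in seq_len(spec@nLfs)) {
        parent <- haps[[sample.int(spec@nHfs, 1L)]]
        ch <- substituteBase(parent$chars, takePos(1L), refChars)
        haps[[length(haps) + 1L]] <-
          list(id = sprintf("%s.l%d", spec@id, j), class = "LFS", chars = ch)
      }
    }
    out <- data.frame(
      ecotype = spec@id,
      haplotype_id = vapply(haps, `[[`, "", "id"),
      class = vapply(haps, `[[`, "", "class"),
      sequence = vapply(haps, function(h) paste(h$chars, collapse = ""), ""),
      stringsAsFactors = FALSE)
    attr(out, "positions") <- setdiff(eligibleMutationSites(refChars),
                                      c(free, reservedPositions))
    out
  })
}

#' Generate haplotypes for a whole multi-ecotype community
#'
#' Applies [generateHaplotypes()] to each ecotype with mutually disjoint
#' mutation positions: each dominant variant carries
#' `ceiling(separation * withinDistance / 2)` private substitutions from
#' the reference, so any two ecotypes' haplotypes differ by at least
#' `separation * withinDistance` sites and the minimum between-ecotype
#' Hamming distance exceeds the maximum within-ecotype distance (verified
#' after generation).
#'
#' @param specs list of [EcotypeSpec-class] objects.
#' @param reference nucleotide string.
#' @param withinDistance within-ecotype HFS distance (default 2).
#' @param separation separation factor (default 5): minimum
#'   between-ecotype distance is `separation * withinDistance`.
#' @param seed optional integer seed.
#' @return data.frame as in [generateHaplotypes()], rows for all ecotypes.
#' @export
communityHaplotypes <- function(specs, reference, withinDistance = 2L,
                                separation = 5L, seed = NULL) {
  stopifnot(length(specs) >= 1)
  withSeed(seed, {
    used <- integer()
    out <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      h <- generateHaplotypes(specs[[i]], reference,
        withinDistance = withinDistance,
        dominantDistance = if (nzchar(specs[[i]]@dominant)) 0L else
          as.integer(ceiling(separation * withinDistance / 2)),
        reservedPositions = used)
      used <- union(used, attr(h, "positions"))
      out[[i]] <- h
    }
    haps <- do.call(rbind, out)
    if (length(specs) > 1L) {
      d <- hammingMatrix(setNames(haps$sequence, haps$haplotype_id))
      same <- outer(haps$ecotype, haps$ecotype, `==`)
      diag(same) <- NA
      within <- max(d[which(same)], 0)
      between <- min(d[which(!same)])
      if (between <= within)
        stop("ecotype separation violated: increase 'separation'")
    }
    haps
  })
}

#' Build a temperature x depth sampling design
#'
#' Convenience constructor for the sample metadata table consumed by
#' [simulateCommunity()]: the full factorial of temperature sites and depth
#' intervals, optionally replicated over timepoints/conditions.
#'
#' @param temperatures numeric vector of site temperatures (degC).
#' @param depths numeric vector of depth interval midpoints (um).
#' @param timepoints vector of timepoints (default 0).
#' @param condition single condition label (default "baseline").
#' @return data.frame with columns sample_id, temperature_C, depth_um,
#'   timepoint, condition.
#' @export
habitatGrid <- function(temperatures, depths, timepoints = 0,
                        condition = "baseline") {
  g <- expand.grid(temperature_C = temperatures, depth_um = depths,
                   timepoint = timepoints, KEEP.OUT.ATTRS = FALSE,
                   stringsAsFactors = FALSE)
  data.frame(
    sample_id = sprintf("S%02d_T%g_z%g", seq_len(nrow(g)),
                        g$temperature_C, g$depth_um),
    g, condition = rep(condition, length.out = nrow(g)),
    stringsAsFactors = FALSE)
}

#' Simulate true ecotype abundances over a habitat grid
#'
#' Gaussian product niche model: the relative abundance of ecotype i in a
#' sample at temperature T and depth z is proportional to
#' `weight_i * exp(-(T - T_i)^2 / (2 sigma_T^2) - (z - z_i)^2 / (2 sigma_z^2))`,
#' normalized per sample. Deterministic given specs and grid.
#'
#' @param specs list of [EcotypeSpec-class] objects.
#' @param samples sample table as from [habitatGrid()].
#' @return a [CommunityGrid-class].
#' @examples
#' specs <- list(ecotypeSpec("A", c(60, 300)), ecotypeSpec("B", c(65, 600)))
#' cg <- simulateCommunity(specs, habitatGrid(c(60, 63, 65), c(200, 600)))
#' colSums(trueAbundance(cg))   # all 1
#' @export
simulateCommunity <- function(specs, samples) {
  if (length(specs) < 1) stop("need at least one ecotype spec")
  if (nrow(samples) < 1) stop("empty habitat grid")
  need <- c("temperature_C", "depth_um")
  if (!all(need %in% names(samples)))
    stop("samples must have temperature_C and depth_um columns")
  if (is.null(samples$sample_id))
    samples$sample_id <- sprintf("S%02d", seq_len(nrow(samples)))
  if (is.null(samples$timepoint)) samples$timepoint <- 0
  if (is.null(samples$condition)) samples$condition <- "baseline"
  ab <- vapply(specs, function(sp) {
    sp@weight * exp(
      -(samples$temperature_C - sp@nicheCenter[1])^2 / (2 * sp@nicheBreadth[1]^2) -
       (samples$depth_um    - sp@nicheCenter[2])^2 / (2 * sp@nicheBreadth[2]^2))
  }, numeric(nrow(samples)))
  ab <- matrix(ab, nrow = nrow(samples))
  ab <- t(ab / rowSums(ab))
  dimnames(ab) <- list(vapply(specs, function(s) s@id, ""), samples$sample_id)
  new("CommunityGrid", samples = samples[, c("sample_id", "temperature_C",
      "depth_um", "timepoint", "condition")], abundance = ab)
}

# apply the homopolymer error model to one read (character scalar).
# At most one indel per maximal run of identical bases.
corruptRead <- function(seq, model) {
  if (model@pIns == 0 && model@pDel == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  r <- rle(chars)
  scale <- r$lengths^model@runLengthExponent
  pi <- pmin(model@pIns * scale, 1)
  pd <- pmin(model@pDel * scale, 1)
  u <- runif(length(r$lengths))
  ins <- u < pi
  del <- !ins & u < (pi + pd)
  if (!any(ins | del)) return(seq)
  lens <- r$lengths + ins - del
  paste(rep.int(r$values, pmax(lens, 0L)), collapse = "")
}

#' Simulate amplicon reads with homopolymer errors
#'
#' Draws reads per sample multinomially over (ecotype, haplotype): ecotype
#' probabilities come from the community's true abundances, within-ecotype
#' haplotype frequencies from `freqSplit` (dominant share, total HFS share
#' split equally over non-dominant HFS, total LFS share split equally over
#' LFS; absent classes fold into the dominant). Each read is then corrupted
#' by the homopolymer [ErrorModel-class]: per maximal run of identical
#' bases of length L, one extra copy of the run base is inserted with
#' probability `pIns * L^runLengthExponent`, or one base deleted with
#' probability `pDel * L^runLengthExponent` (at most one event per run).
#'
#' @param community a [CommunityGrid-class].
#' @param haplotypes data.frame from [communityHaplotypes()].
#' @param depthPerSample integer >= 1 reads per sample.
#' @param error an [ErrorModel-class] (default: error-free).
#' @param freqSplit numeric length 3 (dominant, HFS, LFS shares; sums to 1).
#' @param seed optional integer seed.
#' @return list with elements `reads` (named list: sample id -> named
#'   character vector of read sequences; read names encode sample, source
#'   ecotype and haplotype) and `truth` (data.frame read_id, sample_id,
#'   ecotype, haplotype_id, class, sequence_true).
#' @export
simulateReads <- function(community, haplotypes, depthPerSample,
                          error = errorModel(0, 0),
                          freqSplit = c(dominant = 0.70, hfs = 0.25, lfs = 0.05),
                          seed = NULL) {
  stopifnot_scalar_count(depthPerSample, "depthPerSample", 1L)
  stopifnot(is(error, "ErrorModel"))
  if (abs(sum(freqSplit) - 1) > 1e-9) stop("freqSplit must sum to 1")
  ab <- trueAbundance(community)
  withSeed(seed, {
    # per-haplotype probability within its ecotype
    hw <- numeric(nrow(haplotypes))
    for (e in rownames(ab)) {
      idx <- which(haplotypes$ecotype == e)
      cls <- haplotypes$class[idx]
      w <- numeric(length(idx))
      nh <- sum(cls == "HFS"); nl <- sum(cls == "LFS")
      w[cls == "dominant"] <- freqSplit[1] +
        (if (nh == 0) freqSplit[2] else 0) + (if (nl == 0) freqSplit[3] else 0)
      if (nh > 0) w[cls == "HFS"] <- freqSplit[2] / nh
      if (nl > 0) w[cls == "LFS"] <- freqSplit[3] / nl
      hw[idx] <- w / sum(w)
    }
    reads <- vector("list", ncol(ab))
    names(reads) <- colnames(ab)
    truth <- vector("list", ncol(ab))
    for (s in colnames(ab)) {
      p <- hw * ab[haplotypes$ecotype, s]
      n <- as.vector(rmultinom(1, depthPerSample, p))
      src <- rep.int(seq_len(nrow(haplotypes)), n)
      ids <- sprintf("%s|r%04d|%s", s, seq_along(src),
                     haplotypes$haplotype_id[src])
      seqs <- vapply(haplotypes$sequence[src], corruptRead, "",
                     model = error, USE.NAMES = FALSE)
      reads[[s]] <- setNames(seqs, ids)
      truth[[s]] <- data.frame(
        read_id = ids, sample_id = s,
        ecotype = haplotypes$ecotype[src],
        haplotype_id = haplotypes$haplotype_id[src],
        class = haplotypes$class[src],
        sequence_true = haplotypes$sequence[src],
        stringsAsFactors = FALSE)
    }
    list(reads = reads, truth = do.call(rbind, c(truth, make.row.names = FALSE)))
  })
}

#' Simulate a diel transcript count series
#'
#' Each PE follows a cosine diel activity curve
#' `baseline * (1 + amplitude * cos(2 pi (t - peakHour) / 24))` (clamped at
#' zero); counts at each retained timepoint are multinomial over PEs with
#' total `depth`. Timepoints listed in `missing` emulate failed sequencing
#' reactions and are omitted from the output; timepoints where all PEs have
#' zero activity yield zero counts and are flagged.
#'
#' @param profiles data.frame with columns `pe`, `peakHour` (0-24),
#'   `amplitude` (0-1), and optionally `baseline` (default 1).
#' @param timepoints numeric vector of hours.
#' @param depth total transcripts per timepoint.
#' @param missing optional subset of `timepoints` to drop.
#' @param seed optional integer seed.
#' @return a [DielSeries-class].
#' @export
simulateDielTranscripts <- function(profiles, timepoints, depth,
                                    missing = NULL, seed = NULL) {
  stopifnot(all(c("pe", "peakHour", "amplitude") %in% names(profiles)))
  if (is.null(profiles$baseline)) profiles$baseline <- 1
  keep <- setdiff(timepoints, missing)
  if (length(keep) == 0) stop("all timepoints missing")
  act <- vapply(keep, function(t) {
    pmax(profiles$baseline *
           (1 + profiles$amplitude * cos(2 * pi * (t - profiles$peakHour) / 24)), 0)
  }, numeric(nrow(profiles)))
  act <- matrix(act, nrow = nrow(profiles),
                dimnames = list(profiles$pe, as.character(keep)))
  withSeed(seed, {
    counts <- matrix(0L, nrow(act), ncol(act), dimnames = dimnames(act))
    flagged <- character()
    for (j in seq_len(ncol(act))) {
      tot <- sum(act[, j])
      if (tot == 0) { flagged <- c(flagged, colnames(act)[j]); next }
      counts[, j] <- rmultinom(1, depth, act[, j] / tot)[, 1]
    }
    new("DielSeries", counts = counts,
        missing = as.character(intersect(timepoints, missing)),
        flagged = flagged, ambiguous = 0L)
  })
}

#' Write simulated reads, metadata and truth tables to disk
#'
#' One FASTA file per sample (read ids encode sample and true haplotype),
#' a tab-separated sample metadata table, and a truth table for recovery
#' tests.
#'
#' @param sim result of [simulateReads()].
#' @param community the [CommunityGrid-class] that produced it.
#' @param outdir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
writeSimulatedReads <- function(sim, community, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  for (s in names(sim$reads)) {
    p <- file.path(outdir, paste0(s, ".fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(sim$reads[[s]]), p)
    paths <- c(paths, p)
  }
  mp <- file.path(outdir, "samples.tsv")
  utils::write.table(sampleMetadata(community), mp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tp <- file.path(outdir, "truth.tsv")
  utils::write.table(sim$truth, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, mp, tp))
}
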