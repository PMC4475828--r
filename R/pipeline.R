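#' Default pipeline configuration
#'
#' Returns the demonstration configuration: a three-ecotype synthetic
#' community over a 60-65 degC x 200-600 um grid, sequenced at moderate
#' depth with nominal homopolymer error rates, cleaned, dereplicated,
#' demarcated and tested. Every knob can be overridden; a YAML file with
#' the same structure can be loaded with [readPipelineConfig()].
#'
#' @param ... named overrides merged over the defaults (top-level keys).
#' @return nested list of configuration values.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    reference = list(length = 324L),
    ecotypes = list(
      list(id = "E1", niche_center = c(60, 250), niche_breadth = c(2.5, 220),
           weight = 1, n_hfs = 3L, n_lfs = 2L),
      list(id = "E2", niche_center = c(63, 400), niche_breadth = c(2.5, 220),
           weight = 1, n_hfs = 3L, n_lfs = 2L),
      list(id = "E3", niche_center = c(65, 600), niche_breadth = c(2.5, 220),
           weight = 1, n_hfs = 3L, n_lfs = 2L)),
    haplotypes = list(within_distance = 2L, separation = 5L),
    grid = list(temperatures = c(60, 63, 65), depths = c(200, 400, 600)),
    reads = list(depth_per_sample = 600L, p_ins = 0.01, p_del = 0.005,
                 run_length_exponent = 0),
    hfs_threshold = 50L,
    demarc = list(n_replicates = 150L, slack = 0L, npop_max = 6L),
    ordtest = list(n_perm = 999L),
    modes = c("conservative", "fine"))
  over <- list(...)
  for (k in names(over)) cfg[[k]] <- over[[k]]
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file mirroring the structure of [pipelineConfig()].
#' @return configuration list (defaults filled for absent keys).
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipelineConfig, yaml::read_yaml(path))
}

# deterministic random reference without homopolymer scarcity artifacts
makeReference <- function(length, seed) {
  withSeed(seed, paste(sample(DNA_BASES4, length, replace = TRUE),
                       collapse = ""))
}

#' Run the full demarcation pipeline on synthetic data
#'
#' Executes, from one master seed: community simulation, read simulation
#' with homopolymer errors, frameshift cleaning, dereplication and HFS
#' selection, Stable Ecotype Model demarcation (conservative and
#' fine-scale), LFS assignment with per-sample PE abundance profiles, and
#' the ecological statistics (CCA, ordination cluster tests, G-test).
#' All per-stage seeds are derived deterministically from the master
#' seed; outputs are written as TSV/FASTA under `outdir` together with a
#' JSON manifest of parameters, seeds and per-file checksums. Re-running
#' with the same config and seed reproduces identical checksums.
#'
#' @param config list from [pipelineConfig()] or [readPipelineConfig()].
#' @param seed master integer seed.
#' @param outdir output directory, created if needed (NULL: no files
#'   written, results returned only).
#' @return list with per-stage results and `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig(), seed = 1L,
                        outdir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  stages <- character()
  if (!is.null(outdir)) dir.create(outdir, recursive = TRUE,
                                   showWarnings = FALSE)

  # synthio
  reference <- if (!is.null(config$reference$sequence))
    config$reference$sequence
  else makeReference(config$reference$length, deriveSeed(seed, 1))
  specs <- lapply(config$ecotypes, function(e)
    ecotypeSpec(e$id, e$niche_center, e$niche_breadth, e$weight,
                e$n_hfs, e$n_lfs))
  haps <- communityHaplotypes(specs, reference,
    withinDistance = config$haplotypes$within_distance,
    separation = config$haplotypes$separation, seed = deriveSeed(seed, 2))
  community <- simulateCommunity(specs,
    habitatGrid(config$grid$temperatures, config$grid$depths))
  err <- errorModel(config$reads$p_ins, config$reads$p_del,
                    config$reads$run_length_exponent)
  sim <- simulateReads(community, haps, config$reads$depth_per_sample,
                       error = err, seed = deriveSeed(seed, 3))
  stages <- c(stages, "synthio")

  # readclean
  cleaned <- lapply(sim$reads, cleanReads, reference = reference)
  report <- Reduce(function(a, b) Map(`+`, a, b),
                   lapply(cleaned, `[[`, "report"))
  stages <- c(stages, "readclean")

  # hfscount
  vt <- dereplicateAndCount(lapply(cleaned, `[[`, "cleaned"))
  hfs <- selectHFS(vt, config$hfs_threshold)
  if (length(hfs$members) < 2)
    stop("pipeline_cli stage hfscount: fewer than 2 high-frequency sequences")
  stages <- c(stages, "hfscount")

  # demarc
  dm <- correctedDistances(hfs$members)
  tree <- njTree(dm)
  dcfg <- demarcConfig(npopMax = config$demarc$npop_max,
                       nReplicates = config$demarc$n_replicates,
                       slack = config$demarc$slack)
  partitions <- lapply(setNames(config$modes, config$modes), function(m)
    demarcate(tree, hfs$members, mode = m, config = dcfg,
              seed = deriveSeed(seed, 4)))
  stages <- c(stages, "demarc")

  # abundance (on the fine partition when present)
  part <- partitions[[length(partitions)]]
  assignment <- assignLFS(vt, hfs, part)
  profile <- peAbundance(vt, assignment)
  stages <- c(stages, "abundance")

  # ecostats
  env <- sampleMetadata(community)
  hfsCounts <- variantCounts(vt)[names(hfs$members), , drop = FALSE]
  # constrain on the gradients that actually vary in this design
  preds <- c("temperature_C", "depth_um")
  preds <- preds[vapply(preds, function(p) stats::sd(env[[p]]) > 0,
                        logical(1))]
  if (!length(preds)) stop("no varying environmental predictor")
  ord <- ccaOrdination(hfsCounts, env, predictors = preds)
  axes <- seq_len(min(2L, ncol(ord$speciesScores)))
  clusterTests <- lapply(names(part@clades), function(p) {
    ordtestCluster(ord$speciesScores[, axes, drop = FALSE],
                   intersect(part@clades[[p]], rownames(ord$speciesScores)),
                   nPerm = config$ordtest$n_perm,
                   seed = deriveSeed(seed, 5))
  })
  names(clusterTests) <- names(part@clades)
  peByTemp <- do.call(rbind, lapply(rownames(profile$percent), function(p) {
    tapply(colSums(variantCounts(vt)[assignment$variant[assignment$pe == p],
                                     , drop = FALSE]),
           env$temperature_C, sum)
  }))
  rownames(peByTemp) <- rownames(profile$percent)
  gt <- gTest(peByTemp)
  stages <- c(stages, "ecostats")

  res <- list(reference = reference, haplotypes = haps,
              community = community, truth = sim$truth,
              cleaningReport = report, variants = vt, hfs = hfs,
              tree = tree, partitions = partitions,
              assignment = assignment, profile = profile,
              ordination = ord, clusterTests = clusterTests, gTest = gt)

  files <- character()
  if (!is.null(outdir)) {
    wp <- function(x, name) {
      p <- file.path(outdir, name)
      utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
      files <<- c(files, p)
      p
    }
    writeLines(c(">consensus_reference", reference),
               rp <- file.path(outdir, "reference.fasta"))
    files <- c(files, rp)
    wp(haps, "haplotypes.tsv")
    wp(sampleMetadata(community), "samples.tsv")
    wp(sim$truth, "truth.tsv")
    wp(data.frame(metric = names(report), value = unlist(report)),
       "cleaning_report.tsv")
    writeVariantTable(vt, file.path(outdir, "variants.tsv"))
    files <- c(files, file.path(outdir, "variants.tsv"))
    for (m in names(partitions)) {
      wp(data.frame(variant = names(peAssignments(partitions[[m]])),
                    pe = unname(peAssignments(partitions[[m]]))),
         paste0("partition_", m, ".tsv"))
    }
    wp(assignment, "lfs_assignment.tsv")
    writeAbundanceProfile(profile, file.path(outdir, "pe_abundance.tsv"))
    files <- c(files, file.path(outdir, "pe_abundance.tsv"))
    wp(data.frame(pe = names(clusterTests),
                  statistic = vapply(clusterTests, `[[`, 0, "statistic"),
                  p = vapply(clusterTests, `[[`, 0, "p")),
       "ordtest.tsv")
    ape::write.tree(tree, tp <- file.path(outdir, "hfs_nj.nwk"))
    files <- c(files, tp)
  }

  manifest <- list(
    seed = seed,
    stages = stages,
    parameters = config,
    n_reads = report$n_input,
    n_passed = report$n_passed,
    n_variants = nrow(variantCounts(vt)),
    n_hfs = length(hfs$members),
    n_pe = lapply(partitions, nPE),
    g_test = gt[c("G", "df", "p")],
    cca_explained = ord$explainedFraction,
    checksums = if (length(files))
      as.list(tools::md5sum(sort(files))) else list(),
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
  if (!is.null(outdir)) {
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res$manifest <- manifest
  res
}
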