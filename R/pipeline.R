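#' Build a validated run configuration
#'
#' Orchestration settings for the end-to-end pipeline (simulate ->
#' standardize -> distances -> network -> PCA -> exports). Either construct
#' directly or load from a YAML file with [readRunConfig()].
#'
#' @param outputDir Directory for all outputs (created if absent).
#' @param samplesFile CSV sample table (the [writeSampleTable()] dialect).
#' @param specimensFile Optional CSV specimen table; specimens are
#'   aggregated into single-cranium samples and projected/standardized like
#'   other focal samples.
#' @param referenceId `sample_id` of the SD-donor sample inside
#'   `samplesFile` (default `"Reference"`).
#' @param battery Measurement battery (default [martinBattery()]).
#' @param projectTags Group tags treated as held-out/focal: excluded from
#'   the grand mean and from the PCA fit set, standardized and projected
#'   afterwards (default `c("focal", "ancient")`).
#' @param nonneg Enforce non-negative split weights (default `TRUE`).
#' @param retentionRule `"eigenvalue"` or `"contribution"` (logged by
#'   [cmdPCA()], both are reported).
#' @param includeEstimated Include estimated measurement values when
#'   aggregating specimens (default `TRUE`, mirroring the source tables).
#' @param seed Seed for [cmdSimulate()].
#' @param verbose Emit progress messages (default `TRUE`).
#' @return A validated list of class `"cranioRunConfig"`.
#' @export
runConfig <- function(outputDir,
                      samplesFile = NULL,
                      specimensFile = NULL,
                      referenceId = "Reference",
                      battery = martinBattery(),
                      projectTags = c("focal", "ancient"),
                      nonneg = TRUE,
                      retentionRule = c("eigenvalue", "contribution"),
                      includeEstimated = TRUE,
                      seed = 1L,
                      verbose = TRUE) {
  cfg <- list(outputDir = outputDir, samplesFile = samplesFile,
              specimensFile = specimensFile, referenceId = referenceId,
              battery = battery, projectTags = projectTags, nonneg = nonneg,
              retentionRule = match.arg(retentionRule),
              includeEstimated = includeEstimated, seed = as.integer(seed),
              verbose = verbose)
  class(cfg) <- "cranioRunConfig"
  cfg
}

#' Load a run configuration from YAML
#'
#' @param path YAML file whose keys are the arguments of [runConfig()].
#' @return A validated `"cranioRunConfig"`.
#' @export
readRunConfig <- function(path) {
  stopifnot(file.exists(path))
  do.call(runConfig, yaml::read_yaml(path))
}

logMsg <- function(config, ...) if (isTRUE(config$verbose)) message(sprintf(...))

loadPipelineSamples <- function(config) {
  stopifnot(!is.null(config$samplesFile), file.exists(config$samplesFile))
  samples <- readSampleTable(config$samplesFile)
  if (!is.null(config$specimensFile)) {
    specs <- readSpecimenTable(config$specimensFile)
    singles <- lapply(specs, function(s)
      aggregateSpecimens(list(s), sampleId = s@specimenId,
                         groupTag = "focal",
                         includeEstimated = config$includeEstimated))
    samples <- c(samples, singles)
  }
  ids <- vapply(samples, sampleId, character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample ids: ", paste(ids[duplicated(ids)], collapse = ", "))
  if (!config$referenceId %in% ids)
    stop("reference sample id '", config$referenceId, "' not present in inputs")
  samples
}

pipelineProfiles <- function(config) {
  samples <- loadPipelineSamples(config)
  ids <- vapply(samples, sampleId, character(1))
  tags <- vapply(samples, groupTag, character(1))
  refSample <- samples[[which(ids == config$referenceId)]]
  comparative <- samples[!(tags %in% config$projectTags)]
  held <- ids[tags %in% config$projectTags]
  if (length(held))
    logMsg(config, "excluded from grand mean (%s): %s",
           paste(config$projectTags, collapse = "/"), paste(held, collapse = ", "))
  ref <- buildReference(comparative, refSample, battery = config$battery)
  profiles <- lapply(samples, standardize, ref = ref)
  list(samples = samples, reference = ref, profiles = profiles,
       fitIds = ids[!(tags %in% config$projectTags)])
}

#' Simulate a dataset to disk
#'
#' Wraps [generatePanel()] and [generateAncientSingletons()]; writes
#' `specimens.csv`, `samples.csv` (panel + ancient singleton samples +
#' reference), and `ground_truth.csv` into `outputDir`.
#'
#' @param config A `"cranioRunConfig"`.
#' @param genConfig A [GeneratorConfig-class]; defaults to
#'   `generatorConfig(seed = config$seed)`.
#' @param nAncients Number of ancient singletons drawn from `layer1`.
#' @return Named character vector of the files written, invisibly.
#' @export
cmdSimulate <- function(config, genConfig = generatorConfig(seed = config$seed),
                        nAncients = 7L) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  panel <- generatePanel(genConfig)
  ancients <- generateAncientSingletons(genConfig, "layer1", nAncients)
  ancientSamples <- lapply(ancients, function(s)
    aggregateSpecimens(list(s), s@specimenId, "ancient"))
  files <- c(
    specimens = file.path(config$outputDir, "specimens.csv"),
    samples = file.path(config$outputDir, "samples.csv"),
    truth = file.path(config$outputDir, "ground_truth.csv"))
  writeSpecimenTable(c(panel$specimens, ancients), files["specimens"])
  writeSampleTable(c(panel$samples, ancientSamples, list(panel$reference)),
                   files["samples"])
  writeGroundTruth(panel$truth, files["truth"])
  logMsg(config, "simulated %d populations + %d ancients + reference -> %s",
         length(panel$samples), nAncients, config$outputDir)
  invisible(files)
}

#' Standardize and compute the 1 - r distance matrix
#'
#' Runs [buildReference()], [standardize()] and [distanceMatrix()] over the
#' configured inputs; writes `profiles.csv`, `distances.csv` and
#' `distances.phy` (PHYLIP square format).
#'
#' @param config A `"cranioRunConfig"`.
#' @return The [DistanceMatrix-class], invisibly.
#' @export
cmdDistances <- function(config) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  pp <- pipelineProfiles(config)
  dm <- distanceMatrix(pp$profiles)
  writeProfileTable(pp$profiles, file.path(config$outputDir, "profiles.csv"))
  utils::write.csv(as.data.frame(as.matrix(dm)),
                   file.path(config$outputDir, "distances.csv"))
  writeDistancePhylip(dm, file.path(config$outputDir, "distances.phy"))
  logMsg(config, "distance matrix over %d samples written", length(labels(dm)))
  invisible(dm)
}

#' NeighborNet network stage
#'
#' Distances -> [neighborNetOrder()] -> [estimateSplitWeights()] ->
#' [writeNexusSplits()]; writes `network.nex`.
#'
#' @param config A `"cranioRunConfig"`.
#' @return The [CircularSplitSystem-class], invisibly.
#' @export
cmdNetwork <- function(config) {
  dm <- cmdDistances(config)
  if (length(labels(dm)) < 4L)
    stop("network construction needs at least 4 samples")
  css <- neighborNet(dm, nonneg = config$nonneg)
  writeNexusSplits(css, file.path(config$outputDir, "network.nex"))
  logMsg(config, "network: %d splits retained, residual norm %.3g",
         length(splitSides(css)), sqrt(css@rss))
  invisible(css)
}

#' PCA stage
#'
#' Fits the PCA on the comparative (non-held-out) samples, projects the
#' held-out ones, and writes `pca_model.csv` (eigenvalues, contributions,
#' loadings), `pca_scores.csv` and `pca_scatter_pc2_pc3.csv`.
#'
#' @param config A `"cranioRunConfig"`.
#' @return A list with the [PCAModel-class] and the score table, invisibly.
#' @export
cmdPCA <- function(config) {
  dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
  pp <- pipelineProfiles(config)
  if (length(pp$fitIds) < 3L) stop("PCA fit set must have at least 3 samples")
  model <- fitPCA(pp$profiles, fitIds = pp$fitIds)
  scores <- scoreTable(model, pp$profiles)
  modelTab <- data.frame(component = paste0("PC", seq_along(eigenvalues(model))),
                         eigenvalue = eigenvalues(model),
                         contribution_pct = contributions(model),
                         t(pcaLoadings(model)), check.names = FALSE)
  utils::write.csv(modelTab, file.path(config$outputDir, "pca_model.csv"),
                   row.names = FALSE)
  utils::write.csv(scores, file.path(config$outputDir, "pca_scores.csv"),
                   row.names = FALSE)
  exportScatter(scores, "PC2", "PC3",
                file.path(config$outputDir, "pca_scatter_pc2_pc3.csv"))
  logMsg(config, "retained components: %s (eigenvalue > 1); %s (contribution > 10%%)",
         paste(retainedComponents(model, "eigenvalue"), collapse = ","),
         paste(retainedComponents(model, "contribution"), collapse = ","))
  invisible(list(model = model, scores = scores))
}

#' Run the whole pipeline
#'
#' [cmdSimulate()] (only when no `samplesFile` is configured), then
#' [cmdDistances()], [cmdNetwork()] and [cmdPCA()].
#'
#' @param config A `"cranioRunConfig"`.
#' @param ... Passed to [cmdSimulate()] when simulation is needed.
#' @return Invisible list with the network and PCA results.
#' @export
cmdAll <- function(config, ...) {
  if (is.null(config$samplesFile)) {
    files <- cmdSimulate(config, ...)
    config$samplesFile <- unname(files["samples"])
  }
  css <- cmdNetwork(config)
  pca <- cmdPCA(config)
  invisible(list(network = css, pca = pca))
}
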