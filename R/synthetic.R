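defaultBaseMean <- function() {
  c(M1 = 180, M8 = 135, M9 = 95, M10 = 112, M17 = 135, M43 = 110,
    M45 = 135, M46 = 100, M48 = 65, M51 = 42, M52 = 33, M54 = 26, M55 = 50)
}

defaultWithinPopSd <- function() {
  c(M1 = 5, M8 = 5, M9 = 4, M10 = 4, M17 = 5, M43 = 4,
    M45 = 5, M46 = 4, M48 = 3.5, M51 = 2, M52 = 2, M54 = 1.5, M55 = 2.5)
}

defaultClusterContrast <- function() {
  c(M1 = 1, M8 = 0, M9 = 0, M10 = 0, M17 = 0, M43 = 0,
    M45 = 1, M46 = 1, M48 = -1, M51 = 0, M52 = 0, M54 = 0, M55 = -1)
}

#' Construct a generator configuration
#'
#' Defaults emulate the study conditions of the female craniometric
#' analysis: base means and within-population SDs at the magnitudes of the
#' published focal-crania table, a two-cluster ("two-layer") contrast that
#' gives cluster `layer1` a broader face and longer, lower vault (positive on
#' M1/M45/M46, negative on M48/M55) at 1.0 within-SD units, per-population
#' multiplicative size factors on 0.88-1.05, no missingness, and a
#' 50-individual contrast-free reference population that donates the
#' standardization SDs (the Jomon role).
#'
#' @param seed Integer RNG seed.
#' @param nPopulationsPerCluster Populations per cluster (default 8).
#' @param individualsPerPopulation Individuals per population (default 30).
#' @param baseMean,withinPopSd Named numeric vectors over the battery (mm).
#' @param clusterContrast Named numeric contrast signs over the battery.
#' @param contrastScale Contrast magnitude in within-SD units (default 1.0).
#' @param sizeFactorRange Length-2 multiplicative interval within (0.5, 1.5).
#' @param missingRate Per-cell missingness probability (default 0).
#' @param referencePopulationSize Individuals in the reference sample.
#' @return A [GeneratorConfig-class].
#' @export
generatorConfig <- function(seed = 1L,
                            nPopulationsPerCluster = 8L,
                            individualsPerPopulation = 30L,
                            baseMean = defaultBaseMean(),
                            withinPopSd = defaultWithinPopSd(),
                            clusterContrast = defaultClusterContrast(),
                            contrastScale = 1,
                            sizeFactorRange = c(0.88, 1.05),
                            missingRate = 0,
                            referencePopulationSize = 50L) {
  new("GeneratorConfig", seed = as.integer(seed),
      nPopulationsPerCluster = as.integer(nPopulationsPerCluster),
      individualsPerPopulation = as.integer(individualsPerPopulation),
      baseMean = baseMean, withinPopSd = withinPopSd,
      clusterContrast = clusterContrast, contrastScale = contrastScale,
      sizeFactorRange = as.numeric(sizeFactorRange),
      missingRate = missingRate,
      referencePopulationSize = as.integer(referencePopulationSize))
}

clusterSign <- function(label) {
  switch(label, layer1 = 1, layer2 = -1,
         stop("unknown cluster label: ", label))
}

drawPopulationSpecimens <- function(config, mu, idPrefix, nInd) {
  codes <- names(config@baseMean)
  lapply(seq_len(nInd), function(i) {
    vals <- stats::rnorm(length(codes), mu, config@withinPopSd)
    names(vals) <- codes
    if (config@missingRate > 0) {
      drop <- stats::runif(length(codes)) < config@missingRate
      vals <- vals[!drop]
    }
    cranialSpecimen(sprintf("%s_i%02d", idPrefix, i), site = idPrefix,
                    values = vals)
  })
}

#' Generate a synthetic two-cluster craniometric panel
#'
#' Each population's true mean vector is
#' `sizeFactor * (baseMean + sign * contrastScale * withinPopSd * clusterContrast)`
#' with `sign = +1` for cluster `layer1` and `-1` for `layer2`; individuals
#' are drawn independently per measurement from normals with those means and
#' the within-population SDs, and aggregated with [aggregateSpecimens()].
#' The reference sample is aggregated from its own contrast-free draws
#' (size factor 1). Fully reproducible from `config@seed`.
#'
#' @param config A [GeneratorConfig-class].
#' @return A list with `specimens` (all individuals), `samples` (one
#'   [PopulationSample-class] per population), `reference` (the SD-donor
#'   sample, group tag `"reference"`), and `truth` (data.frame `sample_id`,
#'   `cluster`, `size_factor`, plus the true mean matrix as attribute
#'   `"trueMeans"`).
#' @export
generatePanel <- function(config) {
  validObject(config)
  set.seed(config@seed)
  codes <- names(config@baseMean)
  refSpec <- drawPopulationSpecimens(config, config@baseMean, "REF",
                                     config@referencePopulationSize)
  reference <- aggregateSpecimens(refSpec, "Reference", "reference")

  specimens <- list()
  samples <- list()
  truth <- data.frame(sample_id = character(0), cluster = character(0),
                      size_factor = numeric(0))
  trueMeans <- NULL
  for (cluster in c("layer1", "layer2")) {
    sgn <- clusterSign(cluster)
    for (i in seq_len(config@nPopulationsPerCluster)) {
      id <- sprintf("%s_p%02d", toupper(sub("layer", "L", cluster)), i)
      sf <- stats::runif(1, config@sizeFactorRange[1], config@sizeFactorRange[2])
      mu <- sf * (config@baseMean +
                    sgn * config@contrastScale * config@withinPopSd *
                    config@clusterContrast)
      spec <- drawPopulationSpecimens(config, mu, id,
                                      config@individualsPerPopulation)
      specimens <- c(specimens, spec)
      samples <- c(samples, list(aggregateSpecimens(spec, id, cluster)))
      truth <- rbind(truth, data.frame(sample_id = id, cluster = cluster,
                                       size_factor = sf))
      trueMeans <- rbind(trueMeans, mu)
    }
  }
  rownames(trueMeans) <- truth$sample_id
  colnames(trueMeans) <- codes
  attr(truth, "trueMeans") <- trueMeans
  list(specimens = specimens, samples = samples, reference = reference,
       truth = truth)
}

#' Generate single-cranium "ancient" samples from one cluster
#'
#' Emulates the focal single crania: `k` individuals drawn from the named
#' cluster's distribution (each with its own size factor), returned as
#' [CranialSpecimen-class] objects. With `dropM17 = TRUE` the basion-bregma
#' height is removed and an auricular-basion height (`ABH`) consistent with
#' the packaged regression is emitted instead, so the pipeline must pass
#' through [imputeM17()] to complete the battery.
#'
#' @param config A [GeneratorConfig-class].
#' @param clusterLabel `"layer1"` or `"layer2"`.
#' @param k Number of singletons (0 allowed).
#' @param dropM17 Replace M17 by an ABH predictor value.
#' @param seed RNG seed; defaults to `config@seed + 1` so the singletons are
#'   independent of the panel draws.
#' @return List of `k` [CranialSpecimen-class] objects.
#' @export
generateAncientSingletons <- function(config, clusterLabel = "layer1", k,
                                      dropM17 = FALSE,
                                      seed = config@seed + 1L) {
  validObject(config)
  sgn <- clusterSign(clusterLabel)
  set.seed(seed)
  codes <- names(config@baseMean)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    sf <- stats::runif(1, config@sizeFactorRange[1], config@sizeFactorRange[2])
    mu <- sf * (config@baseMean +
                  sgn * config@contrastScale * config@withinPopSd *
                  config@clusterContrast)
    vals <- stats::rnorm(length(codes), mu, config@withinPopSd)
    names(vals) <- codes
    if (dropM17) {
      imp <- regressionImputer()
      vals["ABH"] <- (vals[["M17"]] - imp@intercept) / imp@slope
      vals <- vals[names(vals) != "M17"]
    }
    out[[i]] <- cranialSpecimen(sprintf("ANC_%s_%02d", clusterLabel, i),
                                site = "synthetic", values = vals)
  }
  out
}

#' Write ground truth as CSV
#'
#' @param truth The `truth` element of [generatePanel()] output.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeGroundTruth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
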