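#' @import methods
NULL

#' Canonical 13-measurement Martin battery
#'
#' The thirteen Martin-system cranial measurements used throughout the
#' affinity analysis: maximum cranial length (M1), maximum cranial breadth
#' (M8), minimum and maximum frontal breadth (M9, M10), basion-bregma height
#' (M17), upper facial breadth (M43), bizygomatic breadth (M45), bimaxillary
#' breadth (M46), upper facial height (M48), orbital breadth and height
#' (M51, M52), and nasal breadth and height (M54, M55). All values are in
#' millimetres.
#'
#' @return Character vector of the 13 Martin codes, in canonical order.
#' @export
#' @examples
#' martinBattery()
martinBattery <- function() {
  c("M1", "M8", "M9", "M10", "M17", "M43", "M45",
    "M46", "M48", "M51", "M52", "M54", "M55")
}

#' Martin measurement definitions
#'
#' @return A data.frame with columns `code`, `label` and `units` describing
#'   the Martin measurements the package knows about (the 13-measurement
#'   battery plus the additional vault/face chords that occur in the packaged
#'   focal-crania table).
#' @export
martinMeasurements <- function() {
  data.frame(
    code = c("M1", "M5", "M8", "M9", "M10", "M12", "M17", "M29", "M30",
             "M31", "M40", "M43", "M45", "M46", "M48", "M51", "M52",
             "M54", "M55"),
    label = c("Maximum cranial length", "Basion-nasion length",
              "Maximum cranial breadth", "Minimum frontal breadth",
              "Maximum frontal breadth", "Maximum occipital breadth",
              "Basion-bregma height", "Frontal chord", "Parietal chord",
              "Occipital chord", "Basion-prosthion breadth",
              "Upper facial breadth", "Bizygomatic breadth",
              "Bimaxillary breadth", "Upper facial height",
              "Orbital breadth", "Orbital height", "Nasal breadth",
              "Nasal height"),
    units = "mm",
    stringsAsFactors = FALSE
  )
}

MEASUREMENT_FLAGS <- c("observed", "estimated")

## Stable measurement ordering: battery codes first, extras lexicographic.
## Keeps round-tripped objects field-identical regardless of input order.
canonicalCodeOrder <- function(codes) {
  c(intersect(martinBattery(), codes), sort(setdiff(codes, martinBattery())))
}

#' CranialSpecimen: one individual's Martin measurements
#'
#' Holds the measurements (mm) of a single cranium together with a per-value
#' flag distinguishing directly observed values from estimated ones
#' (reconstructions or regression estimates, printed in parentheses in the
#' source tables). Measurements that could not be taken are simply absent
#' from `values`.
#'
#' @slot specimenId character, unique specimen identifier.
#' @slot site character, site or series name.
#' @slot sexLabel character, sex as recorded (e.g. "F").
#' @slot values named numeric, measurement values in mm keyed by Martin code.
#' @slot flags named character, "observed" or "estimated", same names as
#'   `values`.
#' @export
setClass("CranialSpecimen",
  representation(specimenId = "character", site = "character",
                 sexLabel = "character", values = "numeric",
                 flags = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@specimenId) != 1L || !nzchar(object@specimenId))
      msg <- c(msg, "specimenId must be a single non-empty string")
    if (length(object@values) &&
        (is.null(names(object@values)) || anyDuplicated(names(object@values))))
      msg <- c(msg, "values must be uniquely named by Martin code")
    if (any(!is.finite(object@values)) ||
        any(object@values <= 0) || any(object@values >= 300))
      msg <- c(msg, "all measurement values must be finite, > 0 and < 300 mm")
    if (!identical(names(object@values), names(object@flags)))
      msg <- c(msg, "flags must carry exactly the names of values")
    if (length(object@flags) && !all(object@flags %in% MEASUREMENT_FLAGS))
      msg <- c(msg, "flags must be 'observed' or 'estimated'")
    if (length(msg)) msg else TRUE
  })

#' Construct a CranialSpecimen
#'
#' @param specimenId Specimen identifier (unique within a table).
#' @param site Site or series name.
#' @param values Named numeric vector of measurements in mm (Martin codes as
#'   names). Values must be positive and below 300 mm.
#' @param flags Named character vector parallel to `values`; each element is
#'   `"observed"` or `"estimated"`. Defaults to all observed.
#' @param sexLabel Sex label as recorded; defaults to `"F"`.
#' @return A [CranialSpecimen-class] object.
#' @export
cranialSpecimen <- function(specimenId, site = specimenId, values,
                            flags = NULL, sexLabel = "F") {
  values <- values[!is.na(values)]
  values <- values[canonicalCodeOrder(names(values))]
  if (is.null(flags)) {
    flags <- rep("observed", length(values))
    names(flags) <- names(values)
  } else {
    flags <- flags[names(values)]
  }
  new("CranialSpecimen", specimenId = as.character(specimenId),
      site = as.character(site), sexLabel = as.character(sexLabel),
      values = values, flags = flags)
}

#' PopulationSample: per-measurement summary of a named group
#'
#' Summarises a population sample by measurement: the number of individuals
#' measured, the mean (mm) and, when at least two individuals were measured,
#' the sample standard deviation (mm, n - 1 denominator). A sample of one
#' individual carries no SD.
#'
#' @slot sampleId character, unique sample identifier.
#' @slot groupTag character, group label (e.g. "NEA", "SEA", "MEL", "AF",
#'   "focal", "reference").
#' @slot n named integer, per-code count of measured individuals.
#' @slot means named numeric, per-code mean in mm.
#' @slot sds named numeric, per-code sample SD in mm; `NA` when `n == 1`.
#' @export
setClass("PopulationSample",
  representation(sampleId = "character", groupTag = "character",
                 n = "integer", means = "numeric", sds = "numeric"),
  validity = function(object) {
    msg <- character()
    nm <- names(object@means)
    if (length(object@means) && (is.null(nm) || anyDuplicated(nm)))
      msg <- c(msg, "means must be uniquely named by Martin code")
    if (!identical(nm, names(object@n)) || !identical(nm, names(object@sds)))
      msg <- c(msg, "n, means and sds must carry identical names")
    if (any(object@n < 1L))
      msg <- c(msg, "per-measurement n must be >= 1")
    if (any(!is.na(object@sds) & object@sds < 0))
      msg <- c(msg, "sds must be >= 0 where present")
    if (any(object@n == 1L & !is.na(object@sds)))
      msg <- c(msg, "a measurement with n = 1 cannot carry an SD")
    if (length(msg)) msg else TRUE
  })

#' Construct a PopulationSample
#'
#' @param sampleId Sample identifier.
#' @param groupTag Group label (free text; used to partition comparative vs
#'   focal samples downstream).
#' @param n Named integer vector of per-measurement counts.
#' @param means Named numeric vector of per-measurement means (mm).
#' @param sds Named numeric vector of per-measurement sample SDs (mm); use
#'   `NA` where `n == 1`. Defaults to all `NA`.
#' @return A [PopulationSample-class] object.
#' @export
populationSample <- function(sampleId, groupTag, n, means, sds = NULL) {
  means <- means[canonicalCodeOrder(names(means))]
  codes <- names(means)
  if (is.null(sds)) sds <- setNames(rep(NA_real_, length(codes)), codes)
  n <- setNames(as.integer(n[codes]), codes)
  sds <- setNames(as.numeric(sds[codes]), codes)
  new("PopulationSample", sampleId = as.character(sampleId),
      groupTag = as.character(groupTag), n = n,
      means = setNames(as.numeric(means), codes), sds = sds)
}

#' RegressionImputer: linear fill-in for a missing measurement
#'
#' Affine regression used to estimate a missing measurement from an auxiliary
#' one. The packaged default estimates basion-bregma height (M17) from
#' auricular-basion height (ABH) as `M17 = 1.05 * ABH + 14.26` (mm), a
#' regression fitted on 24 female crania in the source material.
#'
#' @slot slope numeric, dimensionless.
#' @slot intercept numeric, mm.
#' @slot predictorCode character, code of the predictor measurement.
#' @slot targetCode character, code of the imputed measurement.
#' @export
setClass("RegressionImputer",
  representation(slope = "numeric", intercept = "numeric",
                 predictorCode = "character", targetCode = "character"),
  validity = function(object) {
    if (!identical(object@targetCode, "M17"))
      return("this imputer is defined for target M17 only")
    TRUE
  })

#' Default basion-bregma height imputer
#'
#' @param slope Regression slope (default 1.05).
#' @param intercept Regression intercept in mm (default 14.26).
#' @return A [RegressionImputer-class] with predictor `ABH`, target `M17`.
#' @export
regressionImputer <- function(slope = 1.05, intercept = 14.26) {
  new("RegressionImputer", slope = slope, intercept = intercept,
      predictorCode = "ABH", targetCode = "M17")
}

#' StandardizationReference: grand means and reference SDs
#'
#' Per-measurement grand means (unweighted means over the comparative
#' population samples' means) and reference standard deviations (donated by a
#' single reference sample, the Jomon role) used to z-score population mean
#' profiles before Q-mode correlation.
#'
#' @slot battery character, ordered Martin codes.
#' @slot grandMean named numeric, mm.
#' @slot refSd named numeric, mm, strictly positive.
#' @export
setClass("StandardizationReference",
  representation(battery = "character", grandMean = "numeric",
                 refSd = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(object@battery %in% names(object@grandMean)) ||
        !all(object@battery %in% names(object@refSd)))
      msg <- c(msg, "every battery code needs a grand mean and a reference SD")
    sd <- object@refSd[object@battery]
    if (any(!is.finite(sd)) || any(sd <= 0))
      msg <- c(msg, "reference SDs must be finite and strictly positive")
    if (any(!is.finite(object@grandMean[object@battery])))
      msg <- c(msg, "grand means must be finite")
    if (length(msg)) msg else TRUE
  })

#' StandardizedProfile: z-scored population mean vector
#'
#' @slot sampleId character.
#' @slot groupTag character.
#' @slot battery character, ordered codes.
#' @slot z numeric, dimensionless z-scores in battery order.
#' @export
setClass("StandardizedProfile",
  representation(sampleId = "character", groupTag = "character",
                 battery = "character", z = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@z) != length(object@battery))
      msg <- c(msg, "z must have one value per battery code")
    if (any(!is.finite(object@z)))
      msg <- c(msg, "z values must be finite")
    if (length(msg)) msg else TRUE
  })

#' DistanceMatrix: labelled symmetric distance matrix
#'
#' A symmetric, zero-diagonal, non-negative distance matrix with unique
#' sample labels. Used both for the 1 - r Q-mode distances (entries then lie
#' in [0, 2]) and for general dissimilarities fed to NeighborNet.
#'
#' @slot labels character, ordered sample ids.
#' @slot d numeric matrix.
#' @export
setClass("DistanceMatrix",
  representation(labels = "character", d = "matrix"),
  validity = function(object) {
    msg <- character()
    d <- object@d
    if (nrow(d) != ncol(d) || nrow(d) != length(object@labels))
      msg <- c(msg, "d must be square with one row per label")
    if (anyDuplicated(object@labels))
      msg <- c(msg, "labels must be unique")
    if (any(!is.finite(d)))
      msg <- c(msg, "distances must be finite (no NA/NaN)")
    else {
      if (max(abs(d - t(d))) > 1e-9)
        msg <- c(msg, "d must be symmetric")
      if (any(abs(diag(d)) > 1e-12))
        msg <- c(msg, "diagonal must be zero")
      if (any(d < -1e-12))
        msg <- c(msg, "distances must be non-negative")
    }
    if (length(msg)) msg else TRUE
  })

#' Construct a DistanceMatrix from a labelled square matrix
#'
#' @param d Square numeric matrix (symmetrised to machine precision).
#' @param labels Sample labels; defaults to `rownames(d)`.
#' @return A [DistanceMatrix-class] object.
#' @export
asDistanceMatrix <- function(d, labels = rownames(d)) {
  d <- as.matrix(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(d)))
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(labels, labels)
  new("DistanceMatrix", labels = as.character(labels), d = d)
}

#' CircularSplitSystem: circular taxon ordering plus weighted splits
#'
#' The output of NeighborNet: a circular ordering of the taxa and a set of
#' weighted splits, each of which is an interval (arc) of that ordering.
#' Splits are stored as sorted integer index vectors giving the side that
#' does NOT contain taxon 1.
#'
#' @slot taxa character, taxon labels in input order.
#' @slot cycle integer, circular ordering as indices into `taxa`, rotated to
#'   start at taxon 1.
#' @slot splits list of sorted integer vectors (the side without taxon 1).
#' @slot weights numeric, non-negative split weights (when non-negativity is
#'   enforced at estimation).
#' @slot rss numeric, residual sum of squares of the least-squares fit.
#' @export
setClass("CircularSplitSystem",
  representation(taxa = "character", cycle = "integer", splits = "list",
                 weights = "numeric", rss = "numeric"),
  validity = function(object) {
    msg <- character()
    ntax <- length(object@taxa)
    if (length(object@cycle) != ntax ||
        !identical(sort(object@cycle), seq_len(ntax)))
      msg <- c(msg, "cycle must be a permutation of the taxa")
    if (length(object@splits) != length(object@weights))
      msg <- c(msg, "one weight per split required")
    ok <- vapply(object@splits, function(s) {
      length(s) >= 1L && length(s) < ntax && !1L %in% s &&
        !is.unsorted(s) && all(s >= 1L & s <= ntax)
    }, logical(1))
    if (length(ok) && !all(ok))
      msg <- c(msg, "splits must be sorted, proper, and exclude taxon 1")
    if (length(msg)) msg else TRUE
  })

#' PCAModel: eigenstructure of the fitted standardized profiles
#'
#' @slot battery character, ordered codes.
#' @slot center named numeric, per-code mean of the fit-set profiles.
#' @slot loadings numeric matrix (p x k), unit-norm orthogonal columns; each
#'   column's sign is fixed so its loading sum is positive.
#' @slot eigenvalues numeric, non-increasing.
#' @slot contribution numeric, percentage of total variance per component
#'   (sums to 100 over all components).
#' @slot fittedIds character, sample ids used in fitting.
#' @export
setClass("PCAModel",
  representation(battery = "character", center = "numeric",
                 loadings = "matrix", eigenvalues = "numeric",
                 contribution = "numeric", fittedIds = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@loadings) != length(object@battery))
      msg <- c(msg, "loadings must have one row per battery code")
    if (ncol(object@loadings) != length(object@eigenvalues))
      msg <- c(msg, "one eigenvalue per loading column required")
    if (is.unsorted(rev(object@eigenvalues)))
      msg <- c(msg, "eigenvalues must be non-increasing")
    if (length(msg)) msg else TRUE
  })

#' GeneratorConfig: parameters of the synthetic population generator
#'
#' Defines the statistical structure the synthetic craniometric panel
#' emulates: two clusters of populations ("layer1", "layer2") whose mean
#' vectors differ by a face/vault contrast, a multiplicative per-population
#' size factor, within-population measurement SDs at the magnitude of real
#' female cranial series, and a contrast-free reference population that
#' donates standardization SDs.
#'
#' @slot seed integer RNG seed.
#' @slot nPopulationsPerCluster integer.
#' @slot individualsPerPopulation integer.
#' @slot baseMean named numeric, mm.
#' @slot withinPopSd named numeric, mm.
#' @slot clusterContrast named numeric, dimensionless signs/weights.
#' @slot contrastScale numeric, in multiples of the within-population SD.
#' @slot sizeFactorRange numeric length 2 within (0.5, 1.5).
#' @slot missingRate numeric in [0, 1).
#' @slot referencePopulationSize integer.
#' @export
setClass("GeneratorConfig",
  representation(seed = "integer", nPopulationsPerCluster = "integer",
                 individualsPerPopulation = "integer", baseMean = "numeric",
                 withinPopSd = "numeric", clusterContrast = "numeric",
                 contrastScale = "numeric", sizeFactorRange = "numeric",
                 missingRate = "numeric",
                 referencePopulationSize = "integer"),
  validity = function(object) {
    msg <- character()
    codes <- names(object@baseMean)
    if (!identical(codes, names(object@withinPopSd)) ||
        !identical(codes, names(object@clusterContrast)))
      msg <- c(msg, "baseMean, withinPopSd and clusterContrast need identical names")
    if (any(object@withinPopSd <= 0))
      msg <- c(msg, "all within-population SDs must be > 0")
    if (object@contrastScale < 0)
      msg <- c(msg, "contrastScale must be >= 0")
    if (length(object@sizeFactorRange) != 2L ||
        object@sizeFactorRange[1] > object@sizeFactorRange[2] ||
        object@sizeFactorRange[1] <= 0.5 || object@sizeFactorRange[2] >= 1.5)
      msg <- c(msg, "sizeFactorRange must be an interval within (0.5, 1.5)")
    if (object@missingRate < 0 || object@missingRate >= 1)
      msg <- c(msg, "missingRate must lie in [0, 1)")
    if (object@individualsPerPopulation < 2L)
      msg <- c(msg, "individualsPerPopulation must be >= 2 (SDs are required)")
    if (object@referencePopulationSize < 2L)
      msg <- c(msg, "referencePopulationSize must be >= 2 (its SDs are donated)")
    if (length(msg)) msg else TRUE
  })
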