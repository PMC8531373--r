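#' Accessors
#'
#' Small accessor generics for the package's value classes: `sampleId()` and
#' `groupTag()` for samples and profiles, `measurementValues()` and
#' `measurementFlags()` for specimens, `circularOrder()`, `splitSides()` and
#' `splitWeights()` for split systems, and `eigenvalues()`, `contributions()`
#' and `pcaLoadings()` for PCA models.
#'
#' @param x An object of the corresponding class.
#' @return The slot content; see the class documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("groupTag", function(x) standardGeneric("groupTag"))
#' @rdname accessors
#' @export
setGeneric("measurementValues", function(x) standardGeneric("measurementValues"))
#' @rdname accessors
#' @export
setGeneric("measurementFlags", function(x) standardGeneric("measurementFlags"))
#' @rdname accessors
#' @export
setGeneric("circularOrder", function(x) standardGeneric("circularOrder"))
#' @rdname accessors
#' @export
setGeneric("splitSides", function(x) standardGeneric("splitSides"))
#' @rdname accessors
#' @export
setGeneric("splitWeights", function(x) standardGeneric("splitWeights"))
#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setGeneric("contributions", function(x) standardGeneric("contributions"))
#' @rdname accessors
#' @export
setGeneric("pcaLoadings", function(x) standardGeneric("pcaLoadings"))

#' Standardize a population sample against a reference
#'
#' @param sample A [PopulationSample-class].
#' @param ref A [StandardizationReference-class].
#' @return A [StandardizedProfile-class].
#' @export
setGeneric("standardize", function(sample, ref) standardGeneric("standardize"))

#' @rdname accessors
setMethod("sampleId", "PopulationSample", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "StandardizedProfile", function(x) x@sampleId)
#' @rdname accessors
setMethod("sampleId", "CranialSpecimen", function(x) x@specimenId)
#' @rdname accessors
setMethod("groupTag", "PopulationSample", function(x) x@groupTag)
#' @rdname accessors
setMethod("groupTag", "StandardizedProfile", function(x) x@groupTag)
#' @rdname accessors
setMethod("measurementValues", "CranialSpecimen", function(x) x@values)
#' @rdname accessors
setMethod("measurementFlags", "CranialSpecimen", function(x) x@flags)
#' @rdname accessors
setMethod("circularOrder", "CircularSplitSystem", function(x) x@cycle)
#' @rdname accessors
setMethod("splitSides", "CircularSplitSystem", function(x) x@splits)
#' @rdname accessors
setMethod("splitWeights", "CircularSplitSystem", function(x) x@weights)
#' @rdname accessors
setMethod("eigenvalues", "PCAModel", function(x) x@eigenvalues)
#' @rdname accessors
setMethod("contributions", "PCAModel", function(x) x@contribution)
#' @rdname accessors
setMethod("pcaLoadings", "PCAModel", function(x) x@loadings)

#' @describeIn DistanceMatrix-class extract the labelled numeric matrix.
#' @param x A `DistanceMatrix`.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "DistanceMatrix", function(x, ...) x@d)

#' @describeIn DistanceMatrix-class sample labels.
#' @param object A `DistanceMatrix`.
#' @export
setMethod("labels", "DistanceMatrix", function(object, ...) object@labels)

setMethod("show", "CranialSpecimen", function(object) {
  est <- sum(object@flags == "estimated")
  cat(sprintf("CranialSpecimen '%s' (site %s, sex %s): %d measurements (%d estimated)\n",
              object@specimenId, object@site, object@sexLabel,
              length(object@values), est))
})

setMethod("show", "PopulationSample", function(object) {
  cat(sprintf("PopulationSample '%s' [%s]: %d measurements, n = %s\n",
              object@sampleId, object@groupTag, length(object@means),
              paste(range(object@n), collapse = "-")))
})

setMethod("show", "StandardizationReference", function(object) {
  cat(sprintf("StandardizationReference over %d measurements (%s ...)\n",
              length(object@battery), paste(head(object@battery, 4), collapse = ", ")))
})

setMethod("show", "StandardizedProfile", function(object) {
  cat(sprintf("StandardizedProfile '%s' [%s]: %d z-values in [%.2f, %.2f]\n",
              object@sampleId, object@groupTag, length(object@z),
              min(object@z), max(object@z)))
})

setMethod("show", "DistanceMatrix", function(object) {
  d <- object@d[upper.tri(object@d)]
  cat(sprintf("DistanceMatrix over %d samples; off-diagonal range [%.4g, %.4g]\n",
              length(object@labels), if (length(d)) min(d) else 0,
              if (length(d)) max(d) else 0))
})

setMethod("show", "CircularSplitSystem", function(object) {
  triv <- sum(lengths(object@splits) == 1L |
                lengths(object@splits) == length(object@taxa) - 1L)
  cat(sprintf("CircularSplitSystem: %d taxa, %d splits (%d trivial), RSS %.3g\n",
              length(object@taxa), length(object@splits), triv, object@rss))
  cat("  cycle:", paste(object@taxa[object@cycle], collapse = " "), "\n")
})

setMethod("show", "PCAModel", function(object) {
  k <- length(object@eigenvalues)
  cat(sprintf("PCAModel on %d measurements, %d components; eigenvalues %s ...\n",
              length(object@battery), k,
              paste(sprintf("%.3g", head(object@eigenvalues, 4)), collapse = ", ")))
  cat(sprintf("  fitted on %d samples; first %d contributions (%%): %s\n",
              length(object@fittedIds), min(4L, k),
              paste(sprintf("%.1f", head(object@contribution, 4)), collapse = ", ")))
})

setMethod("show", "GeneratorConfig", function(object) {
  cat(sprintf(paste0("GeneratorConfig: seed %d, 2 x %d populations x %d individuals,\n",
                     "  contrast %.2f SD units, size factors [%.2f, %.2f], missing %.2f\n"),
              object@seed, object@nPopulationsPerCluster,
              object@individualsPerPopulation, object@contrastScale,
              object@sizeFactorRange[1], object@sizeFactorRange[2],
              object@missingRate))
})
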