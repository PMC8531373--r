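#' Build a standardization reference
#'
#' Computes per-measurement grand means as the unweighted mean over the
#' comparative samples' means (each sample counts once, regardless of its n),
#' and takes the reference standard deviations from a single SD-donor sample
#' (the Jomon role). Focal/held-out samples are standardized against this
#' reference but must not be passed in `comparative`.
#'
#' @param comparative List of [PopulationSample-class] objects; each must
#'   carry a mean for every battery code.
#' @param refSample A [PopulationSample-class] with a strictly positive SD
#'   for every battery code.
#' @param battery Ordered Martin codes; defaults to [martinBattery()].
#' @return A [StandardizationReference-class].
#' @export
buildReference <- function(comparative, refSample, battery = martinBattery()) {
  stopifnot(length(comparative) >= 1L)
  for (s in comparative) {
    miss <- setdiff(battery, names(s@means))
    if (length(miss))
      stop(sprintf("sample '%s' lacks a mean for %s", s@sampleId,
                   paste(miss, collapse = ", ")))
  }
  missr <- setdiff(battery, names(refSample@sds))
  if (length(missr) || any(is.na(refSample@sds[battery])))
    stop(sprintf("reference sample '%s' lacks an SD for some battery codes",
                 refSample@sampleId))
  if (any(refSample@sds[battery] <= 0))
    stop(sprintf("reference sample '%s' has a non-positive SD", refSample@sampleId))
  M <- vapply(comparative, function(s) s@means[battery], numeric(length(battery)))
  gm <- rowMeans(M)
  names(gm) <- battery
  new("StandardizationReference", battery = battery, grandMean = gm,
      refSd = refSample@sds[battery])
}

#' @describeIn standardize z-score a sample's battery means:
#'   `z[c] = (mean[c] - grandMean[c]) / refSd[c]`, in battery order. A sample
#'   missing any battery code is rejected (no silent pairwise deletion);
#'   [imputeM17()] is the sanctioned fill-in path.
#' @export
setMethod("standardize", signature("PopulationSample", "StandardizationReference"),
  function(sample, ref) {
    miss <- setdiff(ref@battery, names(sample@means))
    if (length(miss))
      stop(sprintf("sample '%s' lacks battery code(s) %s", sample@sampleId,
                   paste(miss, collapse = ", ")))
    z <- (sample@means[ref@battery] - ref@grandMean[ref@battery]) /
      ref@refSd[ref@battery]
    new("StandardizedProfile", sampleId = sample@sampleId,
        groupTag = sample@groupTag, battery = ref@battery,
        z = unname(z))
  })

#' Q-mode correlation between two standardized profiles
#'
#' Pearson product-moment correlation computed across the battery values of
#' the two profiles (objects correlated over variables, hence "Q-mode").
#'
#' @param a,b [StandardizedProfile-class] objects on the same battery.
#' @return Correlation coefficient in [-1, 1].
#' @export
qmodeCorrelation <- function(a, b) {
  if (!identical(a@battery, b@battery))
    stop("profiles must share the same battery")
  if (stats::sd(a@z) == 0 || stats::sd(b@z) == 0)
    stop(sprintf("degenerate profile (zero variance across measurements): '%s'",
                 if (stats::sd(a@z) == 0) a@sampleId else b@sampleId))
  stats::cor(a@z, b@z)
}

#' Q-mode correlation distance matrix
#'
#' Builds the symmetric matrix of `1 - r` over all profile pairs, where `r`
#' is the Q-mode correlation. Entries lie in [0, 2] (values above 1 arise
#' from negative correlations and are deliberately not clipped).
#'
#' @param profiles List of at least three [StandardizedProfile-class]
#'   objects with unique sample ids.
#' @return A [DistanceMatrix-class].
#' @export
distanceMatrix <- function(profiles) {
  stopifnot(length(profiles) >= 3L)
  ids <- vapply(profiles, sampleId, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample ids among profiles")
  degen <- vapply(profiles, function(p) stats::sd(p@z) == 0, logical(1))
  if (any(degen))
    stop("degenerate profile (zero variance across measurements): ",
         paste(sQuote(ids[degen]), collapse = ", "))
  Z <- vapply(profiles, function(p) p@z, numeric(length(profiles[[1]]@z)))
  d <- 1 - stats::cor(Z)
  dimnames(d) <- list(ids, ids)
  asDistanceMatrix(d, ids)
}

sanitizePhylipLabels <- function(labels, suffix = TRUE) {
  lab <- gsub("[^A-Za-z0-9_.]", "_", labels)
  lab <- substr(lab, 1L, 10L)
  if (anyDuplicated(lab)) {
    if (!suffix)
      stop("PHYLIP label collision after sanitizing: ",
           paste(unique(lab[duplicated(lab)]), collapse = ", "))
    seen <- character(0)
    for (i in seq_along(lab)) {
      if (lab[i] %in% seen) {
        k <- 2L
        repeat {
          cand <- paste0(substr(lab[i], 1L, 10L - nchar(k) - 1L), "_", k)
          if (!cand %in% seen) break
          k <- k + 1L
        }
        lab[i] <- cand
      }
      seen <- c(seen, lab[i])
    }
  }
  lab
}

#' Write a PHYLIP square distance matrix
#'
#' Labels are sanitized to at most 10 characters; collisions get numeric
#' suffixes unless `suffix = FALSE`, in which case a collision is an error.
#'
#' @param dm A [DistanceMatrix-class].
#' @param path Output path.
#' @param suffix Resolve sanitized-label collisions by suffixing.
#' @return `path`, invisibly.
#' @export
writeDistancePhylip <- function(dm, path, suffix = TRUE) {
  lab <- sanitizePhylipLabels(dm@labels, suffix = suffix)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", length(lab)), con)
  for (i in seq_along(lab)) {
    writeLines(paste0(formatC(lab[i], width = -10),
                      paste(sprintf("%12.6f", dm@d[i, ]), collapse = "")), con)
  }
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' @param path File written in PHYLIP square format.
#' @return A [DistanceMatrix-class].
#' @export
readDistancePhylip <- function(path) {
  lines <- readLines(path)
  n <- as.integer(trimws(lines[1]))
  lab <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    parts <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1]]
    lab[i] <- parts[1]
    d[i, ] <- as.numeric(parts[-1])
  }
  asDistanceMatrix(d, lab)
}

#' Export standardized profiles as CSV
#'
#' One row per profile: `sample_id`, `group_tag`, then one column per
#' battery code.
#'
#' @param profiles List of [StandardizedProfile-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeProfileTable <- function(profiles, path) {
  battery <- profiles[[1]]@battery
  tab <- data.frame(
    sample_id = vapply(profiles, sampleId, character(1)),
    group_tag = vapply(profiles, groupTag, character(1)),
    check.names = FALSE)
  Z <- t(vapply(profiles, function(p) p@z, numeric(length(battery))))
  colnames(Z) <- battery
  utils::write.csv(cbind(tab, Z), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
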