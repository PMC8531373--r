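## Tabular dialects
##
## Specimen tables: CSV, one row per specimen, columns specimen_id, site,
## sex, then Martin codes. A cell is a plain number (observed), a number in
## parentheses (estimated), or empty (missing).
##
## Sample tables: CSV, one row per population sample, columns sample_id,
## group_tag, then for each code the triple <code>_n, <code>_mean, <code>_sd.
## An empty n/mean pair means the measurement is absent; an empty sd with
## n = 1 encodes an absent SD.

parseMeasurementCell <- function(cell, row, column) {
  cell <- trimws(cell)
  if (is.na(cell) || !nzchar(cell))
    return(list(value = NA_real_, flag = NA_character_))
  est <- grepl("^\\(.*\\)$", cell)
  body <- if (est) sub("^\\((.*)\\)$", "\\1", cell) else cell
  if (!grepl("^[0-9]+(\\.[0-9]+)?$", trimws(body)))
    stop(sprintf("malformed measurement cell '%s' in row %s, column %s",
                 cell, row, column), call. = FALSE)
  list(value = as.numeric(body), flag = if (est) "estimated" else "observed")
}

#' Read a specimen table
#'
#' Reads a CSV of individual crania (see the dialect described in
#' [writeSpecimenTable()]): parenthesised cells become estimated values,
#' empty cells missing values.
#'
#' @param path CSV file path.
#' @return A list of [CranialSpecimen-class] objects.
#' @export
readSpecimenTable <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  fixed <- c("specimen_id", "site", "sex")
  if (!all(fixed %in% names(tab)))
    stop("specimen table must have columns specimen_id, site, sex")
  if (anyDuplicated(tab$specimen_id))
    stop("duplicate specimen_id in ", path)
  codes <- setdiff(names(tab), fixed)
  lapply(seq_len(nrow(tab)), function(i) {
    vals <- numeric(0); flags <- character(0)
    for (code in codes) {
      cell <- parseMeasurementCell(tab[[code]][i], tab$specimen_id[i], code)
      if (!is.na(cell$value)) {
        vals[code] <- cell$value
        flags[code] <- cell$flag
      }
    }
    cranialSpecimen(tab$specimen_id[i], site = tab$site[i], values = vals,
                    flags = flags, sexLabel = tab$sex[i])
  })
}

#' Write a specimen table
#'
#' Inverse of [readSpecimenTable()]; estimated values are written in
#' parentheses, missing measurements as empty cells.
#'
#' @param specimens List of [CranialSpecimen-class] objects.
#' @param path Output CSV path.
#' @param codes Measurement columns to write; defaults to the union of codes
#'   present, battery codes first.
#' @return `path`, invisibly.
#' @export
writeSpecimenTable <- function(specimens, path, codes = NULL) {
  if (is.null(codes)) {
    all_codes <- unique(unlist(lapply(specimens, function(s) names(s@values))))
    codes <- c(intersect(martinBattery(), all_codes),
               sort(setdiff(all_codes, martinBattery())))
  }
  rows <- lapply(specimens, function(s) {
    cells <- vapply(codes, function(code) {
      if (!code %in% names(s@values)) return("")
      v <- formatC(s@values[[code]], format = "g", digits = 15)
      if (s@flags[[code]] == "estimated") paste0("(", v, ")") else v
    }, character(1))
    c(specimen_id = s@specimenId, site = s@site, sex = s@sexLabel, cells)
  })
  tab <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Impute basion-bregma height from auricular-basion height
#'
#' Applies the affine regression `M17 = slope * ABH + intercept` (defaults
#' 1.05 and 14.26 mm, fitted on 24 female crania in the source material).
#' Full precision is returned; round to integer mm for reporting, as in the
#' source tables (ABH = 112 mm gives 131.86, reported as 132).
#'
#' @param abh Auricular-basion height in mm (> 0); vectorised.
#' @param imputer A [RegressionImputer-class]; defaults to the packaged one.
#' @return Imputed M17 in mm, full precision.
#' @export
#' @examples
#' imputeM17(112)        # 131.86
#' round(imputeM17(112)) # 132
imputeM17 <- function(abh, imputer = regressionImputer()) {
  if (any(!is.finite(abh)) || any(abh <= 0))
    stop("ABH must be finite and > 0 mm")
  imputer@slope * abh + imputer@intercept
}

#' Aggregate specimens into a population sample
#'
#' Per measurement, `n` counts the non-missing values, the mean is the
#' arithmetic mean and the SD the sample standard deviation (n - 1
#' denominator), absent when n = 1. Estimated values participate by default,
#' mirroring the source tables' use of parenthesised values.
#'
#' @param specimens Non-empty list of [CranialSpecimen-class] objects.
#' @param sampleId Identifier for the aggregate sample.
#' @param groupTag Group label for the aggregate sample.
#' @param includeEstimated If `FALSE`, estimated values are excluded from
#'   aggregation.
#' @return A [PopulationSample-class].
#' @export
aggregateSpecimens <- function(specimens, sampleId, groupTag = "focal",
                               includeEstimated = TRUE) {
  stopifnot(length(specimens) >= 1L)
  pull <- function(s) {
    v <- s@values
    if (!includeEstimated) v <- v[s@flags[names(v)] != "estimated"]
    v
  }
  codes <- unique(unlist(lapply(specimens, function(s) names(pull(s)))))
  n <- integer(0); mu <- numeric(0); sd_ <- numeric(0)
  for (code in codes) {
    vals <- unlist(lapply(specimens, function(s) pull(s)[code]))
    vals <- vals[!is.na(vals)]
    n[code] <- length(vals)
    mu[code] <- mean(vals)
    sd_[code] <- if (length(vals) >= 2L) stats::sd(vals) else NA_real_
  }
  populationSample(sampleId, groupTag, n = n, means = mu, sds = sd_)
}

#' Read a sample table
#'
#' @param path CSV file path in the sample-table dialect (see [writeSampleTable()]).
#' @return A list of [PopulationSample-class] objects.
#' @export
readSampleTable <- function(path) {
  stopifnot(file.exists(path))
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("sample_id", "group_tag") %in% names(tab)))
    stop("sample table must have columns sample_id, group_tag")
  if (anyDuplicated(tab$sample_id))
    stop("duplicate sample_id in ", path)
  codes <- unique(sub("_n$", "", grep("_n$", names(tab), value = TRUE)))
  lapply(seq_len(nrow(tab)), function(i) {
    n <- integer(0); mu <- numeric(0); sd_ <- numeric(0)
    for (code in codes) {
      ni <- tab[[paste0(code, "_n")]][i]
      mi <- tab[[paste0(code, "_mean")]][i]
      if (is.na(ni) || is.na(mi)) next
      n[code] <- as.integer(ni)
      mu[code] <- as.numeric(mi)
      si <- tab[[paste0(code, "_sd")]][i]
      sd_[code] <- if (is.null(si) || is.na(si)) NA_real_ else as.numeric(si)
    }
    populationSample(tab$sample_id[i], tab$group_tag[i],
                     n = n, means = mu, sds = sd_)
  })
}

#' Write a sample table
#'
#' One row per sample; for each measurement code the columns `<code>_n`,
#' `<code>_mean`, `<code>_sd`. Round-trips losslessly through
#' [readSampleTable()].
#'
#' @param samples List of [PopulationSample-class] objects.
#' @param path Output CSV path.
#' @param codes Measurement columns to write; defaults to the union present.
#' @return `path`, invisibly.
#' @export
writeSampleTable <- function(samples, path, codes = NULL) {
  if (is.null(codes)) {
    all_codes <- unique(unlist(lapply(samples, function(s) names(s@means))))
    codes <- c(intersect(martinBattery(), all_codes),
               sort(setdiff(all_codes, martinBattery())))
  }
  header <- c("sample_id", "group_tag",
              unlist(lapply(codes, function(code)
                paste0(code, c("_n", "_mean", "_sd")))))
  rows <- lapply(samples, function(s) {
    row <- setNames(rep(NA_real_, length(header)), header)
    row <- as.list(row)
    row$sample_id <- s@sampleId
    row$group_tag <- s@groupTag
    for (code in intersect(codes, names(s@means))) {
      row[[paste0(code, "_n")]] <- s@n[[code]]
      row[[paste0(code, "_mean")]] <- s@means[[code]]
      row[[paste0(code, "_sd")]] <- s@sds[[code]]
    }
    as.data.frame(row, check.names = FALSE)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(logical(0)), length(header)), header),
                  check.names = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Load the packaged focal-crania fixture
#'
#' Returns the transcription of the published female cranial measurement
#' table for the seven focal sites: five single crania (Yahuai, Hang Cho,
#' Mai Da Dieu, Bau Du, Xiaoma) and two summary samples (Huiyaotian,
#' Liyupo). Estimated values (parenthesised in the source) carry the
#' `"estimated"` flag; the Xiaoma basion-bregma height is the regression
#' estimate reproduced by [imputeM17()].
#'
#' @return A list with elements `specimens` (list of
#'   [CranialSpecimen-class]) and `samples` (list of
#'   [PopulationSample-class]).
#' @export
#' @examples
#' fx <- loadFocalCrania()
#' measurementValues(fx$specimens[[1]])["M45"]  # Yahuai bizygomatic breadth
loadFocalCrania <- function() {
  spath <- system.file("extdata", "focal_crania_specimens.csv",
                       package = "CranioNet", mustWork = TRUE)
  ppath <- system.file("extdata", "focal_crania_samples.csv",
                       package = "CranioNet", mustWork = TRUE)
  list(specimens = readSpecimenTable(spath), samples = readSampleTable(ppath))
}
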