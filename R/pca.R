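profilesToMatrix <- function(profiles) {
  battery <- profiles[[1]]@battery
  for (p in profiles) if (!identical(p@battery, battery))
    stop("profiles must share the same battery")
  Z <- t(vapply(profiles, function(p) p@z, numeric(length(battery))))
  rownames(Z) <- vapply(profiles, sampleId, character(1))
  colnames(Z) <- battery
  Z
}

#' Fit a PCA on standardized population profiles
#'
#' Eigen-decomposition of the covariance matrix of the fit-set profiles,
#' centred on the fit-set means. No further per-variable rescaling is
#' applied: the inputs are already standardized against the reference SDs,
#' and a second (correlation-matrix) standardization would erase that
#' choice. Components are ordered by eigenvalue; each loading column is
#' sign-flipped if its sum is negative, so a shared size axis appears with
#' positive loadings.
#'
#' @param profiles List of [StandardizedProfile-class] objects.
#' @param fitIds Sample ids to fit on; defaults to all profiles. Held-out
#'   (e.g. ancient) samples should be excluded here and projected afterwards
#'   with [projectProfiles()].
#' @return A [PCAModel-class]. If the fit set is rank deficient the trailing
#'   eigenvalues are zero (a warning is emitted); if the fit set is not
#'   larger than the battery a warning is emitted as well.
#' @export
fitPCA <- function(profiles, fitIds = NULL) {
  Z <- profilesToMatrix(profiles)
  if (is.null(fitIds)) fitIds <- rownames(Z)
  miss <- setdiff(fitIds, rownames(Z))
  if (length(miss)) stop("fitIds not among profiles: ",
                         paste(miss, collapse = ", "))
  Zf <- Z[fitIds, , drop = FALSE]
  p <- ncol(Zf)
  if (nrow(Zf) <= p)
    warning(sprintf("fit set of %d samples is not larger than the %d-measurement battery",
                    nrow(Zf), p))
  ctr <- colMeans(Zf)
  S <- stats::cov(Zf)
  eig <- eigen(S, symmetric = TRUE)
  ev <- pmax(eig$values, 0)
  if (min(eig$values) < -1e-8 || sum(ev > 1e-10 * max(ev)) < p)
    warning("fit data are rank deficient; trailing components have zero variance")
  L <- eig$vectors
  flip <- colSums(L) < 0
  L[, flip] <- -L[, flip]
  dimnames(L) <- list(colnames(Zf), paste0("PC", seq_len(p)))
  new("PCAModel", battery = colnames(Zf), center = ctr, loadings = L,
      eigenvalues = ev, contribution = 100 * ev / sum(ev),
      fittedIds = fitIds)
}

#' Retained components under the published rules
#'
#' @param model A [PCAModel-class].
#' @param rule `"eigenvalue"` retains components with eigenvalue strictly
#'   greater than `threshold` (default 1, the Kaiser rule); `"contribution"`
#'   retains components whose contribution percentage is strictly greater
#'   than `threshold` (default 10).
#' @param threshold Strict cut-off; defaults to 1 or 10 according to `rule`.
#' @return Integer indices of the retained components, in order.
#' @export
retainedComponents <- function(model, rule = c("eigenvalue", "contribution"),
                               threshold = NULL) {
  rule <- match.arg(rule)
  if (is.null(threshold)) threshold <- if (rule == "eigenvalue") 1 else 10
  x <- if (rule == "eigenvalue") model@eigenvalues else model@contribution
  which(x > threshold)
}

#' Project profiles onto a fitted PCA
#'
#' `scores = t(loadings) %*% (z - center)`; the model is not altered.
#' Projecting a fitted sample reproduces its fitted score exactly.
#'
#' @param model A [PCAModel-class].
#' @param profiles List of [StandardizedProfile-class] objects on the
#'   model's battery.
#' @return Numeric matrix of scores (samples x components).
#' @export
projectProfiles <- function(model, profiles) {
  Z <- profilesToMatrix(profiles)
  if (!identical(colnames(Z), model@battery))
    stop("profiles do not match the model battery")
  sweep(Z, 2L, model@center) %*% model@loadings
}

#' Score table for fitted and projected samples
#'
#' @param model A [PCAModel-class].
#' @param profiles List of [StandardizedProfile-class]; samples whose id is
#'   in `model@fittedIds` are flagged `fitted`, the rest `projected`.
#' @return A data.frame with columns `sample_id`, `group_tag`, `role`, and
#'   one column per component.
#' @export
scoreTable <- function(model, profiles) {
  sc <- projectProfiles(model, profiles)
  data.frame(
    sample_id = rownames(sc),
    group_tag = vapply(profiles, groupTag, character(1)),
    role = ifelse(rownames(sc) %in% model@fittedIds, "fitted", "projected"),
    sc, check.names = FALSE, row.names = NULL)
}

#' Rank samples by a component score
#'
#' @param scores A score table from [scoreTable()].
#' @param component Component name (e.g. `"PC1"`).
#' @param direction `"negative"` ranks most-negative first, `"positive"`
#'   most-positive first.
#' @param k Return at most the first `k` ids (the full ordering if `k`
#'   exceeds the number of samples).
#' @return Character vector of sample ids; ties broken by id.
#' @export
rankByComponent <- function(scores, component = "PC1",
                            direction = c("negative", "positive"), k = Inf) {
  direction <- match.arg(direction)
  if (!component %in% names(scores)) stop("unknown component: ", component)
  s <- scores[[component]]
  ord <- order(if (direction == "negative") s else -s, scores$sample_id)
  utils::head(scores$sample_id[ord], k)
}

#' Export a two-component scatter as CSV
#'
#' @param scores A score table from [scoreTable()].
#' @param cx,cy Component names for the x and y coordinates (default PC2,
#'   PC3).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
exportScatter <- function(scores, cx = "PC2", cy = "PC3", path) {
  for (cc in c(cx, cy)) if (!cc %in% names(scores))
    stop("unknown component: ", cc)
  out <- data.frame(sample_id = scores$sample_id,
                    group_tag = scores$group_tag,
                    score_x = scores[[cx]], score_y = scores[[cy]],
                    role = scores$role)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
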