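# Shared helpers: independent oracles and small constructors used across the
# suite. Oracles are deliberately naive (explicit sums/loops) so they cannot
# share code paths with the implementation they check.

# Textbook Pearson correlation via explicit sums.
bruteForcePearson <- function(x, y) {
  n <- length(x)
  sx <- 0; sy <- 0; sxx <- 0; syy <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx <- sx + x[i]; sy <- sy + y[i]
    sxx <- sxx + x[i]^2; syy <- syy + y[i]^2
    sxy <- sxy + x[i] * y[i]
  }
  (n * sxy - sx * sy) / sqrt((n * sxx - sx^2) * (n * syy - sy^2))
}

# Quick standardized profile with an arbitrary battery.
makeProfile <- function(id, z, battery = paste0("V", seq_along(z)),
                        group = "") {
  new("StandardizedProfile", sampleId = id, groupTag = group,
      battery = battery, z = as.numeric(z))
}

# Distance matrix forward-generated from planted splits (index-vector sides)
# on n taxa: d[i, j] = sum of weights of splits separating i and j.
plantedSplitMetric <- function(splits, weights, n,
                               labels = paste0("t", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (k in seq_along(splits)) {
    s <- splits[[k]]
    d[s, -s] <- d[s, -s] + weights[k]
    d[-s, s] <- d[-s, s] + weights[k]
  }
  asDistanceMatrix(d)
}

# Non-trivial bipartitions of a phylo tree, as sorted label vectors of the
# side not containing the alphabetically first label.
treeBipartitions <- function(tree, labs) {
  spl <- phangorn::as.splits(ape::unroot(tree))
  m <- as.matrix(spl)
  sides <- apply(m, 1, function(r) sort(colnames(m)[r == 1]),
                 simplify = FALSE)
  sides <- lapply(sides, function(x)
    if (labs[1] %in% x) sort(setdiff(labs, x)) else x)
  sides <- Filter(function(x) length(x) > 1 && length(x) < length(labs) - 1,
                  sides)
  unique(sides)
}

# Canonical string form of a list of label-vector splits, for set comparison.
splitKey <- function(sides) sort(vapply(sides, paste, "", collapse = "|"))

# Non-trivial positive-weight splits of a CircularSplitSystem as label sides
# (side not containing the first label).
cssNontrivialSplits <- function(css, minWeight = 1e-8) {
  labs <- css@taxa
  n <- length(labs)
  keep <- splitWeights(css) > minWeight &
    lengths(splitSides(css)) > 1L & lengths(splitSides(css)) < n - 1L
  unique(lapply(splitSides(css)[keep], function(s) sort(labs[s])))
}

# Random additive (tree) metric with comfortably positive branch lengths.
randomTreeMetric <- function(n) {
  tree <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
  D <- ape::cophenetic.phylo(tree)
  labs <- sort(rownames(D))
  list(tree = tree, labs = labs, dm = asDistanceMatrix(D[labs, labs]))
}

# Standardize a whole generated panel against its own reference sample.
panelProfiles <- function(panel, includeReference = FALSE) {
  ref <- buildReference(panel$samples, panel$reference)
  samples <- if (includeReference) c(panel$samples, list(panel$reference))
             else panel$samples
  lapply(samples, standardize, ref = ref)
}

# TRUE when some positive-weight split places every L1_* population on one
# side and every L2_* population on the other (additional taxa such as the
# reference or projected ancients may fall on either side).
separatesClusters <- function(css, minWeight = 1e-8) {
  ids <- css@taxa
  l1 <- which(startsWith(ids, "L1_"))
  l2 <- which(startsWith(ids, "L2_"))
  any(vapply(seq_along(splitSides(css)), function(k) {
    s <- splitSides(css)[[k]]
    splitWeights(css)[k] > minWeight &&
      ((all(l1 %in% s) && !any(l2 %in% s)) ||
         (all(l2 %in% s) && !any(l1 %in% s)))
  }, logical(1)))
}

# TRUE when the split system contains the bipartition separating the two
# generated clusters (L1_* vs the rest).
hasClusterSplit <- function(css, minWeight = 1e-8) {
  ids <- css@taxa
  l1 <- sort(which(startsWith(ids, "L1_")))
  other <- sort(setdiff(seq_along(ids), l1))
  any(vapply(seq_along(splitSides(css)), function(k) {
    s <- splitSides(css)[[k]]
    splitWeights(css)[k] > minWeight &&
      (identical(sort(s), l1) || identical(sort(s), other))
  }, logical(1)))
}
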