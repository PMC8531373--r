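## NeighborNet: agglomerative construction of a circular split system.
##
## The circular ordering is found by the published two-stage agglomeration:
## (1) a neighbour-joining-style selection over clusters using average
## cluster distances, (2) a node-level selection between the two chosen
## clusters' endpoint nodes, followed by reduction of each three-node path
## to two nodes with the equal-thirds distance formulas. Split weights are
## then estimated by (non-negative) least squares over all n(n-1)/2 interval
## splits of the ordering.

## Replace the consecutive path nodes (x, y, z) by two nodes stored in the
## slots of x and z; y is retired. Equal-thirds reduction:
##   d(u, a) = 2/3 d(x, a) + 1/3 d(y, a)
##   d(v, a) = 2/3 d(z, a) + 1/3 d(y, a)
##   d(u, v) = (d(x, y) + d(x, z) + d(y, z)) / 3
reduceTriple <- function(d, x, y, z) {
  u <- 2 / 3 * d[x, ] + d[y, ] / 3
  v <- 2 / 3 * d[z, ] + d[y, ] / 3
  uv <- (d[x, y] + d[x, z] + d[y, z]) / 3
  d[x, ] <- u; d[, x] <- u
  d[z, ] <- v; d[, z] <- v
  d[y, ] <- 0; d[, y] <- 0
  d[x, z] <- d[z, x] <- uv
  d[x, x] <- d[z, z] <- 0
  d
}

#' NeighborNet circular ordering
#'
#' Computes a circular ordering of the taxa such that the split system
#' estimated from it is circular. Ties in both selection criteria are broken
#' by the lowest index pair in a fixed column-major scan, making the result
#' deterministic. The returned ordering is rotated to start at taxon 1 and
#' reflected so that its second element is smaller than its last.
#'
#' @param dm A [DistanceMatrix-class] (or square numeric matrix) over at
#'   least 4 taxa with finite entries.
#' @return Integer vector: circular ordering as indices into the taxa.
#' @references Bryant, D. and Moulton, V. (2004) Neighbor-Net: an
#'   agglomerative method for the construction of phylogenetic networks.
#'   Molecular Biology and Evolution 21(2), 255-265.
#' @export
neighborNetOrder <- function(dm) {
  d <- if (is(dm, "DistanceMatrix")) dm@d else as.matrix(dm)
  n <- nrow(d)
  if (n < 4L) stop("NeighborNet needs at least 4 taxa")
  if (any(!is.finite(d))) stop("distances must be finite (no NA/NaN)")

  CL <- as.list(seq_len(n))   # active endpoint nodes per cluster (1 or 2)
  ORD <- as.list(seq_len(n))  # full taxon path per cluster
  DM <- d                     # cluster-average distance matrix
  m <- n
  while (m > 1L) {
    if (m > 2L) {
      r <- rowSums(DM) / (m - 2)
      Q <- DM - outer(r, r, "+")
      diag(Q) <- Inf
      sel <- arrayInd(which.min(Q), dim(Q))
      e1 <- min(sel); e2 <- max(sel)
    } else {
      e1 <- 1L; e2 <- 2L
    }
    n1 <- length(CL[[e1]]); n2 <- length(CL[[e2]])
    if (n1 == 1L && n2 == 1L) {
      CL[[e1]] <- c(CL[[e1]], CL[[e2]])
      ORD[[e1]] <- c(ORD[[e1]], ORD[[e2]])
    } else {
      # node-level selection among the endpoints of the two chosen clusters,
      # treating those endpoints as singletons next to the remaining clusters
      nodes <- c(CL[[e1]], CL[[e2]])
      others <- CL[-c(e1, e2)]
      mm <- length(nodes) + length(others)
      R <- vapply(seq_along(nodes), function(i) {
        xi <- nodes[i]
        s <- sum(d[xi, nodes[-i]])
        if (length(others))
          s <- s + sum(vapply(others, function(cl) mean(d[xi, cl]), 0))
        s
      }, 0)
      if (mm > 2L) R <- R / (mm - 2)
      Qh <- matrix(Inf, n1, n2)
      for (i in seq_len(n1)) for (j in seq_len(n2))
        Qh[i, j] <- d[nodes[i], nodes[n1 + j]] - R[i] - R[n1 + j]
      sel <- arrayInd(which.min(Qh), dim(Qh))
      x <- CL[[e1]][sel[1]]; y <- CL[[e2]][sel[2]]
      p1 <- CL[[e1]]; o1 <- ORD[[e1]]
      p2 <- CL[[e2]]; o2 <- ORD[[e2]]
      if (n1 == 2L && x == p1[1]) { p1 <- rev(p1); o1 <- rev(o1) }
      if (n2 == 2L && y == p2[2]) { p2 <- rev(p2); o2 <- rev(o2) }
      path <- c(p1, p2)           # x and y are now adjacent in the middle
      while (length(path) > 2L) {
        d <- reduceTriple(d, path[1], path[2], path[3])
        path <- path[-2]
      }
      CL[[e1]] <- path
      ORD[[e1]] <- c(o1, o2)
    }
    CL <- CL[-e2]
    ORD <- ORD[-e2]
    m <- m - 1L
    DM <- matrix(0, m, m)
    for (i in seq_len(m)) for (j in seq_len(m)) if (i < j)
      DM[i, j] <- DM[j, i] <- mean(d[CL[[i]], CL[[j]]])
  }
  cyc <- ORD[[1]]
  start <- which(cyc == 1L)
  cyc <- c(cyc[start:length(cyc)], cyc[seq_len(start - 1L)])
  if (length(cyc) > 2L && cyc[2] > cyc[length(cyc)])
    cyc <- c(cyc[1], rev(cyc[-1]))
  as.integer(cyc)
}

## All interval splits of a circular ordering, as sorted index vectors of the
## side not containing taxon 1 (the ordering starts at taxon 1).
circularSplits <- function(cycle) {
  n <- length(cycle)
  out <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (p in 2:n) for (q in p:n) {
    k <- k + 1L
    out[[k]] <- sort.int(cycle[p:q])
  }
  out
}

## Pair-by-split 0/1 design matrix; pairs in lower.tri(d) column-major order.
splitDesignMatrix <- function(splits, n) {
  B <- matrix(FALSE, length(splits), n)
  for (s in seq_along(splits)) B[s, splits[[s]]] <- TRUE
  ii <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  A <- matrix(0, nrow(ii), length(splits))
  for (k in seq_len(nrow(ii)))
    A[k, ] <- as.numeric(xor(B[, ii[k, 1]], B[, ii[k, 2]]))
  A
}

#' Estimate split weights on a circular ordering
#'
#' Solves `min || d_observed - sum_s w_s delta_s ||^2` over all n(n-1)/2
#' interval splits of the ordering, with `w_s >= 0` enforced by an active-set
#' non-negative least-squares solver when `nonneg = TRUE` (the default).
#' Splits with weight at or below `dropThreshold` are removed; trivial
#' (singleton) splits are kept regardless when `keepTrivial = TRUE`, since
#' they carry the terminal edge lengths of the drawn network.
#'
#' @param dm A [DistanceMatrix-class] or square numeric matrix.
#' @param order Circular ordering (indices into the taxa), e.g. from
#'   [neighborNetOrder()].
#' @param nonneg Enforce non-negative weights (default `TRUE`).
#' @param dropThreshold Weight below/at which a non-trivial split is dropped.
#' @param keepTrivial Keep singleton splits regardless of weight.
#' @return A [CircularSplitSystem-class].
#' @export
estimateSplitWeights <- function(dm, order, nonneg = TRUE,
                                 dropThreshold = 1e-8, keepTrivial = TRUE) {
  d <- if (is(dm, "DistanceMatrix")) dm@d else as.matrix(dm)
  labels <- if (is(dm, "DistanceMatrix")) dm@labels else
    (if (!is.null(rownames(d))) rownames(d) else paste0("t", seq_len(nrow(d))))
  n <- nrow(d)
  order <- as.integer(order)
  if (!identical(sort.int(order), seq_len(n)))
    stop("order must be a permutation covering all taxa")
  if (anyDuplicated(labels)) stop("duplicate taxa labels")
  splits <- circularSplits(order)
  A <- splitDesignMatrix(splits, n)
  y <- d[lower.tri(d)]
  w <- tryCatch(qr.solve(A, y), error = function(e) rep(-1, ncol(A)))
  if (nonneg && any(w < -1e-12)) {
    w <- pracma::lsqnonneg(A, y)$x
  } else if (nonneg) {
    w[w < 0] <- 0
  }
  rss <- sum((y - A %*% w)^2)
  trivial <- lengths(splits) == 1L | lengths(splits) == n - 1L
  keep <- w > dropThreshold | (keepTrivial & trivial)
  new("CircularSplitSystem", taxa = as.character(labels), cycle = order,
      splits = splits[keep], weights = unname(w[keep]), rss = rss)
}

#' Run NeighborNet end to end
#'
#' Convenience wrapper: [neighborNetOrder()] followed by
#' [estimateSplitWeights()].
#'
#' @inheritParams estimateSplitWeights
#' @return A [CircularSplitSystem-class].
#' @export
neighborNet <- function(dm, nonneg = TRUE, dropThreshold = 1e-8,
                        keepTrivial = TRUE) {
  estimateSplitWeights(dm, neighborNetOrder(dm), nonneg = nonneg,
                       dropThreshold = dropThreshold,
                       keepTrivial = keepTrivial)
}

#' Metric induced by a split system
#'
#' `d[i, j]` is the sum of the weights of the splits separating taxa i and
#' j. For a system estimated from forward-generated circular-split distances
#' this reconstructs the generating matrix exactly.
#'
#' @param css A [CircularSplitSystem-class].
#' @return A [DistanceMatrix-class].
#' @export
splitDecompositionDistance <- function(css) {
  n <- length(css@taxa)
  d <- matrix(0, n, n)
  for (s in seq_along(css@splits)) {
    side <- css@splits[[s]]
    d[side, -side] <- d[side, -side] + css@weights[s]
    d[-side, side] <- d[-side, side] + css@weights[s]
  }
  asDistanceMatrix(d, css@taxa)
}

#' Neighbor-joining tree (oracle for tree-like inputs)
#'
#' Standard neighbor joining via [ape::nj()], returned as newick text. Used
#' as an independent check that NeighborNet generalises NJ on additive
#' distance matrices.
#'
#' @param dm A [DistanceMatrix-class] or square numeric matrix, n >= 3.
#' @return Newick string.
#' @export
njTree <- function(dm) {
  d <- if (is(dm, "DistanceMatrix")) dm@d else as.matrix(dm)
  if (nrow(d) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(d))) stop("distances must be finite (no NA/NaN)")
  lab <- if (is(dm, "DistanceMatrix")) dm@labels else rownames(d)
  dimnames(d) <- list(lab, lab)
  ape::write.tree(ape::nj(stats::as.dist(d)))
}
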