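test_that("a 4-taxon additive tree yields a compatible ordering and weights", {
  # ((A,B),(C,D)) with unit terminal branches and unit internal branch
  labs <- LETTERS[1:4]
  d <- matrix(3, 4, 4, dimnames = list(labs, labs))
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 2
  diag(d) <- 0
  dm <- asDistanceMatrix(d)
  ord <- neighborNetOrder(dm)
  pos <- match(1:4, ord)  # positions of A,B,C,D on the cycle
  onCycle <- labs[ord]
  ab <- sort(match(c("A", "B"), onCycle))
  expect_true(diff(ab) == 1 || diff(ab) == 3)  # A,B contiguous on the cycle
  css <- estimateSplitWeights(dm, ord)
  sides <- lapply(splitSides(css), function(s) sort(labs[s]))
  w <- setNames(splitWeights(css), vapply(sides, paste, "", collapse = ","))
  expect_equal(unname(w["C,D"]), 1)               # the internal AB|CD split
  expect_equal(unname(w[c("B", "C", "D", "B,C,D")]), rep(1, 4)) # terminals
  expect_equal(css@rss, 0, tolerance = 1e-20)
  rec <- as.matrix(splitDecompositionDistance(css))
  expect_equal(rec, d, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("ordering is deterministic on an all-equal (fully tied) matrix", {
  d <- matrix(1, 5, 5); diag(d) <- 0
  dm <- asDistanceMatrix(d)
  o1 <- neighborNetOrder(dm)
  o2 <- neighborNetOrder(dm)
  expect_identical(o1, o2)
  expect_setequal(o1, 1:5)
  expect_equal(o1[1], 1L)
})

test_that("tiny matrices and non-finite distances are rejected", {
  d <- matrix(1, 3, 3); diag(d) <- 0
  expect_error(neighborNetOrder(asDistanceMatrix(d)), "at least 4")
  d4 <- matrix(1, 4, 4); diag(d4) <- 0
  d4[1, 2] <- d4[2, 1] <- NaN
  expect_error(neighborNetOrder(d4), "finite")
})

test_that("planted circular split systems are inverted exactly", {
  set.seed(3)
  for (rep in 1:5) {
    n <- 6
    splits <- c(lapply(2:n, identity),
                list(c(2L, 3L), c(4L, 5L, 6L)))
    w <- c(runif(n - 1, 0.2, 1), runif(2, 0.3, 0.9))
    dm <- plantedSplitMetric(splits, w, n)
    ord <- neighborNetOrder(dm)
    # every planted split must be an interval of the recovered ordering
    pos <- match(seq_len(n), ord)
    for (s in splits) {
      p <- sort(pos[s])
      isInterval <- all(diff(p) == 1) ||
        identical(sort(setdiff(seq_len(n), p)),
                  seq(min(setdiff(seq_len(n), p)),
                      max(setdiff(seq_len(n), p))))
      expect_true(isInterval)
    }
    css <- estimateSplitWeights(dm, ord)
    expect_lte(css@rss, 1e-8)
    key <- function(s) paste(sort(s), collapse = ",")
    est <- setNames(splitWeights(css), vapply(splitSides(css), key, ""))
    planted <- vapply(splits, key, "")
    expect_true(all(planted %in% names(est)))
    expect_lt(max(abs(w - est[planted])), 1e-6)
    # nothing else carries weight
    expect_lt(sum(est[setdiff(names(est), planted)]), 1e-6)
    # reconstruction returns the generating matrix
    expect_equal(as.matrix(splitDecompositionDistance(css)),
                 as.matrix(dm), tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("the zero matrix gives an all-zero-weight split system", {
  dm <- asDistanceMatrix(matrix(0, 5, 5))
  css <- CranioNet::neighborNet(dm)
  expect_true(all(splitWeights(css) == 0))
  expect_equal(max(as.matrix(splitDecompositionDistance(css))), 0)
})

test_that("single planted split induces the expected two-point metric", {
  css <- new("CircularSplitSystem", taxa = LETTERS[1:4], cycle = 1:4,
             splits = list(3:4), weights = 1, rss = 0)
  d <- as.matrix(splitDecompositionDistance(css))
  expect_equal(d["A", "C"], 1)
  expect_equal(d["A", "B"], 0)
  expect_equal(d["C", "D"], 0)
  empty <- new("CircularSplitSystem", taxa = LETTERS[1:4], cycle = 1:4,
               splits = list(), weights = numeric(0), rss = 0)
  expect_equal(max(as.matrix(splitDecompositionDistance(empty))), 0)
})

test_that("NeighborNet generalizes NJ on 50 random additive tree metrics", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  for (rep in 1:50) {
    n <- sample(5:8, 1)
    tm <- randomTreeMetric(n)
    css <- CranioNet::neighborNet(tm$dm)
    mySplits <- cssNontrivialSplits(css)
    trSplits <- treeBipartitions(tm$tree, tm$labs)
    njSplits <- treeBipartitions(ape::read.tree(text = njTree(tm$dm)),
                                 tm$labs)
    expect_identical(splitKey(mySplits), splitKey(trSplits))
    expect_identical(splitKey(njSplits), splitKey(trSplits))
    # weights on tree splits equal branch lengths: reconstruction is exact
    expect_equal(as.matrix(splitDecompositionDistance(css)),
                 as.matrix(tm$dm), tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("circular orderings agree with an independent implementation", {
  skip_if_not_installed("phangorn")
  # compare against phangorn's NeighborNet ordering on generic (tie-free)
  # matrices, up to rotation/reflection of the cycle
  canonCycle <- function(o) {
    o <- as.integer(o)
    s <- which(o == 1L)
    o <- c(o[s:length(o)], o[seq_len(s - 1L)])
    if (length(o) > 2L && o[2] > o[length(o)]) o <- c(o[1], rev(o[-1]))
    o
  }
  set.seed(21)
  for (rep in 1:10) {
    n <- sample(5:7, 1)
    m <- matrix(runif(n * n, 0.5, 2), n, n)
    d <- (m + t(m)) / 2; diag(d) <- 0
    labs <- paste0("t", seq_len(n))
    dimnames(d) <- list(labs, labs)
    mine <- canonCycle(neighborNetOrder(asDistanceMatrix(d)))
    theirs <- canonCycle(phangorn:::getOrderingNN(d))
    expect_identical(mine, theirs)
  }
})

test_that("relabelling taxa permutes the split system identically", {
  set.seed(31)
  n <- 6
  m <- matrix(runif(n * n, 0.5, 2), n, n)
  d <- (m + t(m)) / 2; diag(d) <- 0
  labs <- paste0("t", 1:n)
  dimnames(d) <- list(labs, labs)
  css1 <- CranioNet::neighborNet(asDistanceMatrix(d))
  perm <- c(4, 2, 6, 1, 3, 5)
  dp <- d[perm, perm]
  css2 <- CranioNet::neighborNet(asDistanceMatrix(dp))
  key <- function(css) {
    keep <- splitWeights(css) > 1e-8
    sides <- lapply(splitSides(css)[keep], function(s) {
      side <- sort(css@taxa[s])
      if ("t1" %in% side) side <- sort(setdiff(css@taxa, side))
      paste(side, collapse = ",")
    })
    o <- order(unlist(sides))
    data.frame(side = unlist(sides)[o],
               w = round(splitWeights(css)[keep][o], 9))
  }
  expect_equal(key(css1), key(css2))
})

test_that("NJ oracle behaves on tiny and permuted inputs", {
  # brute force over the 3 quartet topologies by least-squares fit
  labs <- LETTERS[1:4]
  d <- matrix(3, 4, 4, dimnames = list(labs, labs))
  d["A", "B"] <- d["B", "A"] <- 2
  d["C", "D"] <- d["D", "C"] <- 2
  diag(d) <- 0
  fitQuartet <- function(d, pair) {
    # design for splits: 4 terminals + internal separating `pair`
    pairs <- t(combn(4, 2))
    X <- matrix(0, 6, 5)
    for (k in 1:6) {
      X[k, pairs[k, 1]] <- 1; X[k, pairs[k, 2]] <- 1
      sep <- xor(pairs[k, 1] %in% pair, pairs[k, 2] %in% pair)
      if (sep) X[k, 5] <- 1
    }
    y <- apply(pairs, 1, function(p) d[p[1], p[2]])
    sum(stats::lsfit(X, y, intercept = FALSE)$residuals^2)
  }
  rss <- vapply(list(c(1, 2), c(1, 3), c(1, 4)), fitQuartet, 0, d = d)
  expect_equal(which.min(rss), 1L)  # AB|CD wins the brute-force LS fit
  nj <- ape::read.tree(text = njTree(asDistanceMatrix(d)))
  expect_identical(splitKey(treeBipartitions(nj, labs)),
                   splitKey(list(c("C", "D"))))
  # label-permutation equivariance of the topology
  perm <- c(3, 1, 4, 2)
  nj2 <- ape::read.tree(text = njTree(asDistanceMatrix(d[perm, perm])))
  expect_identical(splitKey(treeBipartitions(nj2, labs)),
                   splitKey(list(c("C", "D"))))
  # 3-taxon input resolves as a star consistent with the distances
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(LETTERS[1:3], LETTERS[1:3]))
  tr3 <- ape::read.tree(text = njTree(asDistanceMatrix(d3)))
  expect_equal(ape::Ntip(tr3), 3L)
  cd <- ape::cophenetic.phylo(tr3)[LETTERS[1:3], LETTERS[1:3]]
  expect_equal(cd, d3, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("NEXUS splits output round-trips and matches the system", {
  set.seed(41)
  n <- 6
  splits <- c(lapply(2:n, identity), list(c(2L, 3L), c(4L, 5L, 6L)))
  w <- c(runif(n - 1, 0.2, 1), 0.8, 0.5)
  dm <- plantedSplitMetric(splits, w, n)
  css <- CranioNet::neighborNet(dm)
  path <- withr::local_tempfile(fileext = ".nex")
  writeNexusSplits(css, path)
  lines <- readLines(path)
  expect_equal(lines[1], "#nexus")
  expect_true(any(grepl(sprintf("DIMENSIONS ntax=%d nsplits=%d;", n,
                                length(splitSides(css))), lines)))
  cyc <- grep("^CYCLE ", lines, value = TRUE)
  expect_equal(as.integer(strsplit(sub("^CYCLE (.*);$", "\\1", cyc),
                                   " ")[[1]]),
               circularOrder(css))
  back <- readNexusSplits(path)
  expect_identical(back@taxa, css@taxa)
  expect_identical(back@cycle, css@cycle)
  key <- function(x) paste(vapply(x, paste, "", collapse = ","))
  o1 <- order(key(splitSides(css))); o2 <- order(key(splitSides(back)))
  expect_identical(splitSides(css)[o1], splitSides(back)[o2])
  expect_equal(splitWeights(css)[o1], splitWeights(back)[o2],
               tolerance = 1e-9)
  # deterministic bytes on rewrite
  path2 <- withr::local_tempfile(fileext = ".nex")
  writeNexusSplits(css, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("retained splits are intervals of the cycle, non-negative weights", {
  set.seed(51)
  cfg <- generatorConfig(seed = 99)
  panel <- generatePanel(cfg)
  dm <- distanceMatrix(panelProfiles(panel))
  css <- CranioNet::neighborNet(dm)
  expect_true(all(splitWeights(css) >= 0))
  pos <- match(seq_along(css@taxa), circularOrder(css))
  for (s in splitSides(css)) {
    p <- sort(pos[s])
    comp <- sort(pos[setdiff(seq_along(css@taxa), s)])
    expect_true(all(diff(p) == 1) || all(diff(comp) == 1))
  }
})
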