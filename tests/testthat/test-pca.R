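battery13 <- martinBattery()

randomProfiles <- function(n, p = 13, sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(n), function(i)
    makeProfile(paste0("s", i), rnorm(p, 0, sd), battery = battery13[1:p]))
}

test_that("PCA eigenstructure invariants hold", {
  profiles <- randomProfiles(40, seed = 1)
  model <- fitPCA(profiles)
  L <- pcaLoadings(model)
  # orthonormal loadings
  expect_equal(t(L) %*% L, diag(13), tolerance = 1e-8, ignore_attr = TRUE)
  # trace identity: sum of eigenvalues == total variance of centred data
  Z <- t(vapply(profiles, function(p) p@z, numeric(13)))
  expect_equal(sum(eigenvalues(model)), sum(diag(cov(Z))), tolerance = 1e-8)
  # contributions sum to 100 over all 13 components
  expect_equal(sum(contributions(model)), 100, tolerance = 1e-10)
  # eigenvalues non-increasing, loading sums non-negative (sign convention)
  expect_false(is.unsorted(rev(eigenvalues(model))))
  expect_true(all(colSums(L) >= -1e-12))
  # fitted scores: zero mean, uncorrelated across components
  sc <- projectProfiles(model, profiles)
  expect_lt(max(abs(colMeans(sc))), 1e-8)
  cc <- crossprod(sweep(sc, 2, colMeans(sc)))
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-6)
})

test_that("isotropic data give near-equal eigenvalues and contributions", {
  profiles <- randomProfiles(4000, seed = 2)
  model <- fitPCA(profiles)
  expect_true(all(abs(eigenvalues(model) - 1) < 0.15))
  expect_true(all(abs(contributions(model) - 100 / 13) < 1.2))
})

test_that("a planted common size factor produces an all-positive PC1", {
  set.seed(3)
  u <- rep(1, 13) / sqrt(13)
  profiles <- lapply(1:60, function(i)
    makeProfile(paste0("s", i), rnorm(1, 0, 3) * u + rnorm(13, 0, 0.2),
                battery = battery13))
  model <- fitPCA(profiles)
  pc1 <- pcaLoadings(model)[, 1]
  expect_true(all(pc1 > 0))
  expect_lt(max(pc1) / min(pc1), 1.6)  # near-equal loadings
})

test_that("retention rules use strict inequalities", {
  model <- new("PCAModel", battery = paste0("V", 1:4),
               center = rep(0, 4), loadings = diag(4),
               eigenvalues = c(5, 2, 1.2, 0.9),
               contribution = c(40, 25, 15, 9) / 89 * 100 * 0.89,
               fittedIds = "x")
  expect_equal(retainedComponents(model, "eigenvalue"), 1:3)
  model@contribution <- c(40, 25, 15, 9)
  expect_equal(retainedComponents(model, "contribution"), 1:3)
  # boundary: eigenvalues exactly 1 are NOT retained under strict ">"
  model@eigenvalues <- rep(1, 4)
  expect_length(retainedComponents(model, "eigenvalue"), 0)
})

test_that("projection is consistent and does not alter the model", {
  profiles <- randomProfiles(30, seed = 4)
  fitIds <- paste0("s", 1:25)
  model <- fitPCA(profiles, fitIds = fitIds)
  before <- pcaLoadings(model)
  # projecting a fitted sample reproduces its fitted score
  scAll <- projectProfiles(model, profiles)
  scOne <- projectProfiles(model, profiles[3])
  expect_equal(scAll[3, ], scOne[1, ])
  # projecting the fit-set centroid gives the zero score
  Z <- t(vapply(profiles[match(fitIds, paste0("s", 1:30))],
                function(p) p@z, numeric(13)))
  centroid <- makeProfile("ctr", colMeans(Z), battery = battery13)
  expect_lt(max(abs(projectProfiles(model, list(centroid)))), 1e-10)
  expect_identical(pcaLoadings(model), before)
  # incomplete profiles are rejected
  short <- makeProfile("bad", rnorm(12), battery = battery13[1:12])
  expect_error(projectProfiles(model, list(short)), "battery")
})

test_that("score tables flag roles and rank components correctly", {
  profiles <- randomProfiles(20, seed = 5)
  model <- fitPCA(profiles, fitIds = paste0("s", 1:15))
  scores <- scoreTable(model, profiles)
  expect_equal(sum(scores$role == "projected"), 5L)
  expect_equal(sum(scores$role == "fitted"), 15L)

  toy <- data.frame(sample_id = c("a", "b", "c"), group_tag = "g",
                    role = "fitted", PC1 = c(-2, 1, -3))
  expect_equal(rankByComponent(toy, "PC1", "negative"), c("c", "a", "b"))
  expect_equal(rankByComponent(toy, "PC1", "positive"), c("b", "a", "c"))
  expect_equal(rankByComponent(toy, "PC1", "negative", k = 10),
               c("c", "a", "b"))  # k > n returns the full ordering
  expect_error(rankByComponent(toy, "PC9"), "unknown component")
  # ties broken by id
  toy$PC1 <- c(1, 1, 1)
  expect_equal(rankByComponent(toy, "PC1", "negative"), c("a", "b", "c"))
})

test_that("scatter export writes one row per sample and round-trips", {
  profiles <- randomProfiles(10, seed = 6)
  model <- suppressWarnings(fitPCA(profiles, fitIds = paste0("s", 1:8)))
  scores <- scoreTable(model, profiles)
  path <- withr::local_tempfile(fileext = ".csv")
  exportScatter(scores, "PC2", "PC3", path)
  back <- read.csv(path)
  expect_equal(nrow(back), 10L)
  expect_equal(back$score_x, scores$PC2)
  expect_equal(back$score_y, scores$PC3)
  expect_setequal(unique(back$role), c("fitted", "projected"))
  expect_error(exportScatter(scores, "PC2", "PC99", path), "unknown")
})

test_that("small fit sets warn; rank-deficient data warn and stay valid", {
  profiles <- randomProfiles(10, seed = 7)
  w <- capture_warnings(fitPCA(profiles))
  expect_match(w, "not larger", all = FALSE)
  # rank-deficient: 20 samples living in a 3-dimensional subspace
  set.seed(8)
  B <- matrix(rnorm(13 * 3), 13, 3)
  flat <- lapply(1:20, function(i)
    makeProfile(paste0("f", i), as.numeric(B %*% rnorm(3)),
                battery = battery13))
  model <- suppressWarnings(fitPCA(flat))
  expect_warning(fitPCA(flat), "rank deficient")
  expect_true(all(eigenvalues(model)[4:13] < 1e-8))
  expect_equal(sum(contributions(model)), 100)
})

test_that("planted size factors and clusters are recovered by the PCA", {
  nrep <- 100
  rOk <- logical(nrep); accOk <- logical(nrep); ancOk <- numeric(nrep)
  for (k in seq_len(nrep)) {
    cfg <- generatorConfig(seed = 2000 + k)
    panel <- generatePanel(cfg)
    profs <- panelProfiles(panel)
    model <- fitPCA(profs)
    scores <- scoreTable(model, profs)
    m <- match(panel$truth$sample_id, scores$sample_id)
    rOk[k] <- abs(cor(scores$PC1[m], panel$truth$size_factor)) > 0.9
    isL1 <- panel$truth$cluster == "layer1"
    accByPC <- vapply(c("PC2", "PC3"), function(pc)
      max(mean((scores[[pc]][m] > 0) == isL1),
          mean((scores[[pc]][m] < 0) == isL1)), 0)
    accOk[k] <- max(accByPC) >= 0.9
    # a projected ancient population lands with its planted cluster
    # (nearest PC2/PC3 centroid)
    anc <- generateAncientSingletons(cfg, "layer1", 1)
    ancSample <- aggregateSpecimens(anc, "ANC", "ancient")
    ref <- buildReference(panel$samples, panel$reference)
    ancScore <- projectProfiles(model, list(standardize(ancSample, ref)))
    best <- names(which.max(accByPC))
    cen1 <- colMeans(as.matrix(scores[m, c("PC2", "PC3")])[isL1, ])
    cen2 <- colMeans(as.matrix(scores[m, c("PC2", "PC3")])[!isL1, ])
    a23 <- ancScore[1, c("PC2", "PC3")]
    ancOk[k] <- sum((a23 - cen1)^2) < sum((a23 - cen2)^2)
  }
  expect_gte(mean(rOk), 0.9)
  expect_gte(mean(accOk), 0.9)
  expect_gte(mean(ancOk), 0.95)
})

test_that("small-size populations take the most negative PC1 ranks", {
  set.seed(9)
  cfg <- generatorConfig(seed = 77, contrastScale = 0)
  panel <- generatePanel(cfg)
  profs <- panelProfiles(panel)
  model <- fitPCA(profs)
  scores <- scoreTable(model, profs)
  bottom <- rankByComponent(scores, "PC1", "negative", k = 4)
  smallest <- panel$truth$sample_id[order(panel$truth$size_factor)][1:4]
  expect_gte(length(intersect(bottom, smallest)), 3L)
})
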