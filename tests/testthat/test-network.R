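test_that("initialization is seeded, shaped and bounded by fan-in", {
  cfg <- networkConfig(720)
  p1 <- initNetwork(cfg); p2 <- initNetwork(cfg)
  expect_identical(p1, p2)
  expect_equal(dim(p1$W[[1]]), c(30L, 720L))
  expect_equal(dim(p1$W[[2]]), c(5L, 30L))
  expect_equal(dim(p1$W[[3]]), c(1L, 5L))
  for (l in 1:3) {
    fanIn <- ncol(p1$W[[l]])
    expect_lte(max(abs(p1$W[[l]])), 1 / sqrt(fanIn))
    expect_equal(p1$b[[l]], numeric(nrow(p1$W[[l]])))
  }
})

test_that("forward pass composes tanh and log-sigmoid correctly", {
  cfg <- networkConfig(4)
  p <- initNetwork(cfg)
  for (l in 1:3) p$W[[l]] <- p$W[[l]] * 0
  expect_equal(forwardNetwork(p, matrix(rnorm(8), 2, 4)), c(0.5, 0.5))
  set.seed(19)
  pr <- initNetwork(cfg)
  out <- forwardNetwork(pr, matrix(rnorm(1000 * 4), 1000, 4))
  expect_true(all(out > 0 & out < 1))
  # hand-built single-feature chain: logsig(w3 tanh(w2 tanh(w1 x)))
  toy <- list(W = list(matrix(2), matrix(-1.5), matrix(0.7)),
              b = list(0.1, -0.2, 0.3), center = NULL, scale = NULL)
  x <- 0.37
  manual <- 1 / (1 + exp(-(0.7 * tanh(-1.5 * tanh(2 * x + 0.1) - 0.2) + 0.3)))
  expect_equal(forwardNetwork(toy, matrix(x, 1, 1)), manual,
               tolerance = 1e-12)
})

test_that("cross-entropy matches hand computation", {
  expect_equal(crossEntropy(0.5, 1), log(2), tolerance = 1e-4)
  expect_lt(crossEntropy(1 - 1e-9, 1), 1e-6)
  p <- c(0.9, 0.2, 0.6); y <- c(1, 0, 1)
  manual <- -(log(0.9) + log(0.8) + log(0.6)) / 3
  expect_equal(crossEntropy(p, y), manual)
})

test_that("training separates separable clusters and descends the loss", {
  set.seed(31)
  n <- 100; d <- 10
  y <- rep(c(1, 0), each = n / 2)
  X <- matrix(rnorm(n * d), n, d)
  X[y == 1, 1:2] <- X[y == 1, 1:2] + 4
  cfg <- networkConfig(d, seed = 2)
  params <- trainNetwork(X, y, cfg)
  acc <- mean((forwardNetwork(params, X) > 0.5) == (y == 1))
  expect_gte(acc, 0.99)
  expect_lte(params$losses[cfg$epochs], params$losses[1])
  # label flip symmetry: decision function flips
  paramsF <- trainNetwork(X, 1 - y, cfg)
  sc <- forwardNetwork(params, X); scF <- forwardNetwork(paramsF, X)
  expect_equal(aucRank(sc, y) + aucRank(sc, 1 - y), 1)
  expect_gt(aucRank(scF, 1 - y), 0.95)
  expect_error(trainNetwork(X, rep(1, n), cfg), "single class")
})

test_that("classification threshold is strict at 0.5", {
  cfg <- networkConfig(3)
  p <- initNetwork(cfg)
  for (l in 1:3) p$W[[l]] <- p$W[[l]] * 0   # output exactly 0.5
  expect_equal(unname(classifyHCM(p, matrix(0, 1, 3))), "non-HCM")
  p$b[[3]] <- 0.1                           # output just above 0.5
  expect_equal(unname(classifyHCM(p, matrix(0, 1, 3))), "HCM")
})

test_that("stratified folds balance classes and partition subjects", {
  labels <- rep(c("HCM", "CA", "AFD", "HTNcm"), c(85, 18, 30, 30))
  fold <- stratifiedKFold(labels, k = 5, seed = 3)
  expect_equal(sort(unique(fold)), 1:5)
  expect_equal(as.vector(table(fold[labels == "HCM"])), rep(17L, 5))
  negPerFold <- table(fold[labels != "HCM"])
  expect_true(all(negPerFold %in% c(15L, 16L)))
  expect_equal(sort(unlist(lapply(1:5, function(f) which(fold == f)))),
               seq_along(labels))
  expect_error(stratifiedKFold(labels, k = 1), "at least 2")
  expect_error(stratifiedKFold(rep(c("A", "B"), c(3, 50)), k = 5),
               "fewer subjects")
})

test_that("cross-validation is deterministic and perfect on separable data", {
  sep <- separableFeatures(n = 60, d = 10, gap = 6)
  cfg <- networkConfig(10, seed = 5)
  cv1 <- crossValidate(sep, cfg)
  cv2 <- crossValidate(sep, cfg)
  expect_identical(cvMetrics(cv1), cvMetrics(cv2))
  expect_identical(medianROC(cv1), medianROC(cv2))
  s <- cvSummary(cv1)
  expect_equal(s$mean[s$metric == "auc"], 1.0)
  expect_equal(s$mean[s$metric == "accuracy"], 1.0)
  # every subject is tested exactly once
  idx <- sort(unlist(lapply(cvFolds(cv1), `[[`, "testIndex")))
  expect_equal(idx, 1:60)
  # median ROC starts at (0,*) and ends at (1,1)
  mr <- medianROC(cv1)
  expect_equal(mr$fpr[1], 0)
  expect_equal(mr$tpr[nrow(mr)], 1)
})

test_that("standardization statistics come from the training portion only", {
  set.seed(41)
  X <- matrix(rnorm(40 * 4), 40, 4)
  y <- rep(c(1, 0), 20)
  Xtr <- X[1:30, ]; ytr <- y[1:30]
  params <- trainNetwork(Xtr, ytr, networkConfig(4, seed = 1))
  expect_equal(params$center, colMeans(Xtr))
  expect_equal(params$scale, apply(Xtr, 2, sd))
  # a wild outlier outside the training rows cannot move the stored stats
  X2 <- X; X2[31, 1] <- 1e6
  params2 <- trainNetwork(X2[1:30, ], ytr, networkConfig(4, seed = 1))
  expect_identical(params$center, params2$center)
})
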