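test_that("rbfKernel and the kernel matrix agree", {
  u <- c(1, 2, 3); v <- c(0, 2, 5)
  expect_equal(rbfKernel(u, v, 0.5), exp(-0.5 * (1 + 0 + 4)))
  expect_equal(rbfKernel(u, u, 2), 1)
  expect_error(rbfKernel(u, v, 0), "positive")
  expect_error(rbfKernel(u, c(1, 2), 1), "dimension")
})

test_that("the RBF kernel matrix is positive semi-definite", {
  set.seed(41)
  x <- matrix(rnorm(30 * 5), ncol = 5L)
  K <- mirpos:::rbfKernelMatrix(x, x, gamma = 0.3)
  expect_equal(K, t(K))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  ## diagonal is 1 up to the cancellation error of the distance formula
  expect_equal(unname(diag(K)), rep(1, nrow(K)), tolerance = 1e-12)
})

test_that("svmTrain decision values reproduce libSVM and orient 'real' positive", {
  set.seed(42)
  x <- rbind(matrix(rnorm(40, mean = 3), ncol = 2L),
             matrix(rnorm(40, mean = -3), ncol = 2L))
  labels <- rep(c("real", "pseudo"), each = 20L)
  model <- svmTrain(x, labels, cost = 2, gamma = 0.7)
  mine <- decisionValues(model, x)
  fit <- e1071::svm(x, factor(labels, levels = c("real", "pseudo")),
                    type = "C-classification", kernel = "radial",
                    cost = 2, gamma = 0.7, scale = FALSE)
  ref <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
  sgn <- if (grepl("^real", colnames(ref)[1L])) 1 else -1
  expect_equal(mine, sgn * as.numeric(ref), tolerance = 1e-10)
  ## real samples score positive on separable data
  expect_true(all(mine[1:20] > 0))
  expect_true(all(mine[21:40] < 0))
  ## orientation is invariant to the label order of the input; values
  ## agree up to the solver's convergence tolerance
  model2 <- svmTrain(x[40:1, ], labels[40:1], cost = 2, gamma = 0.7)
  expect_equal(decisionValues(model2, x), mine, tolerance = 1e-3)
})

test_that("svmTrain matches an independent QP solve of the dual", {
  ## solve the soft-margin dual with kernlab::ipop on 20 points:
  ## min 1/2 a' Q a - 1' a  s.t.  y' a = 0, 0 <= a <= C
  set.seed(43)
  x <- rbind(matrix(rnorm(20, mean = 1), ncol = 2L),
             matrix(rnorm(20, mean = -1), ncol = 2L))
  y <- rep(c(1, -1), each = 10L)
  C <- 5; gamma <- 0.5
  K <- mirpos:::rbfKernelMatrix(x, x, gamma)
  Q <- (y %*% t(y)) * K
  qp <- kernlab::ipop(c = rep(-1, 20L), H = Q,
                      A = matrix(y, nrow = 1L), b = 0, r = 0,
                      l = rep(0, 20L), u = rep(C, 20L))
  a <- kernlab::primal(qp)
  ## bias from the KKT conditions on free support vectors
  free <- which(a > 1e-5 & a < C - 1e-5)
  b <- mean(y[free] - colSums(a * y * K[, free, drop = FALSE]))
  oracleScores <- as.numeric(K %*% (a * y) + b)

  model <- svmTrain(x, ifelse(y > 0, "real", "pseudo"),
                    cost = C, gamma = gamma)
  got <- decisionValues(model, x)
  expect_equal(got, oracleScores, tolerance = 1e-2)
  ## the two solvers agree on every confident classification
  sure <- abs(oracleScores) > 0.05
  expect_identical(sign(got[sure]), sign(oracleScores[sure]))
})

test_that("saved models reload with bit-identical decision values", {
  set.seed(44)
  x <- rbind(matrix(rnorm(30, 1), ncol = 3L),
             matrix(rnorm(30, -1), ncol = 3L))
  labels <- rep(c("real", "pseudo"), each = 10L)
  model <- svmTrain(x, labels, cost = 3, gamma = 0.2,
                    subset = list(features = c("f1", "f2"),
                                  scaling = list(dis = c(min = 0, max = 7))),
                    config = unclass(featureConfig()))
  path <- withr::local_tempfile(fileext = ".json")
  saveModel(model, path)
  back <- loadModel(path)
  xt <- matrix(rnorm(15), ncol = 3L)
  expect_identical(decisionValues(back, xt), decisionValues(model, xt))
  expect_identical(back@sv, model@sv)
  expect_identical(back@coefs, model@coefs)
  expect_identical(back@b, model@b)
  expect_identical(back@subset$scaling$dis, model@subset$scaling$dis)
  expect_error(loadModel(withr::local_tempfile(lines = "{}",
                                               fileext = ".json")),
               "not a recognised")
})

test_that("groupFolds keeps all candidates of a hairpin together", {
  groups <- rep(letters[1:10], times = sample(3:8, 10, replace = TRUE))
  f <- mirpos:::groupFolds(groups, folds = 5L, seed = 7L)
  expect_length(f, length(groups))
  for (g in letters[1:10])
    expect_length(unique(f[groups == g]), 1L)
  expect_error(mirpos:::groupFolds(letters[1:3], folds = 5L, seed = 1L),
               "exceeds")
})

test_that("gridSearch is deterministic and prefers smaller C then gamma", {
  set.seed(45)
  ## groups of 4 candidates, one real each, trivially separable so all
  ## grid points tie at accuracy 1
  n <- 10L
  x <- NULL; labels <- c(); groups <- c()
  for (g in seq_len(n)) {
    x <- rbind(x, c(5, 5), matrix(rnorm(6, -2), ncol = 2L))
    labels <- c(labels, "real", rep("pseudo", 3L))
    groups <- c(groups, rep(paste0("g", g), 4L))
  }
  r1 <- gridSearch(x, labels, groups, costGrid = c(1, 4),
                   gammaGrid = c(0.1, 1), folds = 2L, seed = 1L,
                   refine = FALSE)
  r2 <- gridSearch(x, labels, groups, costGrid = c(4, 1),
                   gammaGrid = c(1, 0.1), folds = 2L, seed = 1L,
                   refine = FALSE)
  expect_identical(r1[c("cost", "gamma", "accuracy")],
                   r2[c("cost", "gamma", "accuracy")])
  expect_identical(r1$cost, 1)
  expect_identical(r1$gamma, 0.1)
  expect_equal(r1$accuracy, 1)
})

test_that("predictHairpin ranks candidates and reports per arm", {
  set.seed(46)
  ds <- sampleDataset(synthParams(n_hairpins = 6L, seed = 91L))
  ids <- names(ds$hairpins)
  fit <- runTrain(ds$hairpins[ids[1:5]], ds$annotations,
                  runConfig(tune = FALSE, use_mfe = FALSE))
  res <- predictHairpin(ds$hairpins[[ids[6L]]], fit$model)
  expect_s3_class(res, "predictionResult")
  expect_identical(res$ranked$rank, seq_len(nrow(res$ranked)))
  expect_true(all(diff(res$ranked$score) <= 0))
  expect_identical(res$top1$mirna_start, res$ranked$mirna_start[1L])
  expect_lte(nrow(res$perArm), 2L)
  expect_lte(nrow(res$topk), 10L)
})
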