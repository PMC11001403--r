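synthDir <- withr::local_tempdir(.local_envir = teardown_env())
synthCfg <- smallConfig(nFrames = 30L, seed = 202L)
synth <- generateStack(synthCfg, synthDir)
geom <- synth$geometry
roiPanel <- frameRoi(panel = "p1")

test_that("feature rows are the row-major ROI pixels of each frame", {
  refs <- data.frame(path = synth$files[1L], event = 0:2)
  roi <- frameRoi(ss = c(1L, 5L), fs = c(2L, 7L))   # 4 x 5 ROI
  X <- buildFeatures(refs, roi, geom)
  expect_identical(dim(X), c(3L, 20L))
  raw <- rhdf5::h5read(synth$files[1L], "/data/data")
  for (i in 1:3) {
    brute <- numeric(0)
    for (r in 2:5) for (cc in 3:7) brute <- c(brute, raw[r, cc, i])
    expect_equal(unname(X[i, ]), brute)
  }
  expect_identical(attr(X, "roiFingerprint"), "ss[1,5)fs[2,7)")
})

test_that("constant frames give constant features", {
  f <- withr::local_tempfile(fileext = ".h5")
  rhdf5::h5createFile(f)
  rhdf5::h5write(array(3.5, c(16, 10, 2)), f, "data")
  g <- makeGeometry(smallConfig())$geometry
  X <- buildFeatures(data.frame(path = f, event = 0:1),
                     frameRoi(panel = "p0"), g, dataPath = "/data")
  expect_true(all(X == 3.5))
})

test_that("unreadable refs and oversized ROIs are errors", {
  refs <- data.frame(path = file.path(synthDir, "ghost.h5"), event = 0L)
  expect_error(buildFeatures(refs, roiPanel, geom), "ghost\\.h5")
  big <- frameRoi(ss = c(0L, 999L), fs = c(0L, 5L))
  expect_error(buildFeatures(data.frame(path = synth$files[1L], event = 0L),
                             big, geom), "outside")
})

test_that("the 70/30 split of 10 frames is a disjoint 7/3 partition", {
  refs <- data.frame(path = "x.h5", event = 0:9,
                     label = rep(c("good", "bad"), 5L))
  sp <- splitDataset(labelSet(refs), 0.7, 0.3, seed = 4L)
  expect_identical(nrow(sp$train), 7L)
  expect_identical(nrow(sp$test), 3L)
  key <- function(d) paste(d$path, d$event)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  expect_setequal(c(key(sp$train), key(sp$test)), key(refs))
})

test_that("fractions that do not sum to one are rejected quoting both", {
  refs <- labelSet(data.frame(path = "x.h5", event = 0:9,
                              label = rep(c("good", "bad"), 5L)))
  expect_error(splitDataset(refs, 0.7, 0.2), "100%.*0\\.7.*0\\.2")
  expect_error(splitDataset(refs, 1, 0), "> 0")
})

test_that("the split is seed-deterministic and seed-sensitive", {
  refs <- labelSet(data.frame(path = "x.h5", event = 0:99,
                              label = rep(c("good", "bad"), 50L)))
  a <- splitDataset(refs, seed = 11L)
  b <- splitDataset(refs, seed = 11L)
  expect_identical(a, b)
  differs <- vapply(1:100, function(s)
    !identical(splitDataset(refs, seed = s)$train, a$train), logical(1))
  expect_true(mean(differs) > 0.9)
})

test_that("stratified splits preserve class proportions", {
  refs <- labelSet(data.frame(path = "x.h5", event = 0:99,
                              label = rep(c("good", "bad"), c(30L, 70L))))
  sp <- splitDataset(refs, seed = 2L, stratify = TRUE)
  expect_identical(sum(sp$train$label == "good"), 21L)  # floor(0.7 * 30)
  expect_identical(sum(sp$train$label == "bad"), 49L)
})

test_that("degenerate label sets cannot be split", {
  oneClass <- labelSet(data.frame(path = "x.h5", event = 0:5, label = "good"))
  expect_error(splitDataset(oneClass), "both classes")
  tiny <- labelSet(data.frame(path = "x.h5", event = 0L, label = "good"))
  expect_error(splitDataset(tiny), "at least 2")
})

sepToy <- local({
  set.seed(33)
  n <- 20L
  X <- rbind(matrix(rnorm(n * 5, 10), n),
             matrix(rnorm(n * 5, -10), n))
  list(X = X, y = rep(c("good", "bad"), each = n))
})

test_that("all four algorithms memorize linearly separable toys", {
  for (alg in c("logreg", "knn", "dtree", "rforest")) {
    m <- trainModel(sepToy$X, sepToy$y, algorithm = alg, seed = 1L)
    expect_identical(as.character(predictLabels(m, sepToy$X)), sepToy$y,
                     label = alg)
  }
})

test_that("degenerate training inputs are rejected", {
  expect_error(trainModel(sepToy$X, rep("good", nrow(sepToy$X))),
               "both classes")
  expect_error(trainModel(sepToy$X, sepToy$y, algorithm = "svm"),
               "logreg, knn, dtree, rforest")
  expect_error(trainModel(sepToy$X, sepToy$y[-1L]), "one label per")
})

test_that("KNN with K = 1 returns a training row's own label", {
  m <- trainModel(sepToy$X, sepToy$y, algorithm = "knn",
                  hyperparams = list(k = 1L))
  for (i in c(1L, 25L, 40L))
    expect_identical(as.character(predictLabels(m, sepToy$X[i, , drop = FALSE])),
                     sepToy$y[i])
})

test_that("feature-width and ROI-fingerprint mismatches are predict-time errors", {
  m <- trainModel(sepToy$X, sepToy$y, algorithm = "dtree")
  expect_error(predictLabels(m, sepToy$X[, 1:3]), "3 does not match.*5")
  refs <- data.frame(path = synth$files[1L], event = 0:9)
  XA <- buildFeatures(refs, frameRoi(ss = c(0L, 4L), fs = c(0L, 5L)), geom)
  XB <- buildFeatures(refs, frameRoi(ss = c(4L, 8L), fs = c(0L, 5L)), geom)
  labs <- labelRefs(synth$truth)$label[1:10]
  if (length(unique(labs)) < 2L) labs <- rep(c("good", "bad"), 5L)
  mA <- trainModel(XA, labs, algorithm = "dtree")
  expect_error(predictLabels(mA, XB), "fingerprint mismatch")
})

test_that("training is reproducible under a fixed seed", {
  refs <- labelRefs(synth$truth)
  X <- buildFeatures(refs, roiPanel, geom)
  hold <- X[1:10, , drop = FALSE]
  m1 <- trainModel(X, refs$label, algorithm = "rforest", seed = 7L)
  m2 <- trainModel(X, refs$label, algorithm = "rforest", seed = 7L)
  expect_identical(predictLabels(m1, hold), predictLabels(m2, hold))
  expect_identical(attr(predictLabels(m1, hold), "scores"),
                   attr(predictLabels(m2, hold), "scores"))
})

test_that("persisted models restore and predict identically", {
  m <- trainModel(sepToy$X, sepToy$y, algorithm = "rforest", seed = 3L)
  f <- withr::local_tempfile(fileext = ".rds")
  persistModel(m, f)
  r <- restoreModel(f)
  set.seed(8)
  probe <- matrix(rnorm(50 * 5, 0, 20), 50L)
  expect_identical(predictLabels(r, probe), predictLabels(m, probe))
  expect_identical(r@algorithm, m@algorithm)
  expect_identical(r@hyperparams, m@hyperparams)
})

test_that("corrupt or foreign model files fail to restore", {
  f <- withr::local_tempfile(fileext = ".rds")
  writeLines("not a model", f)
  expect_error(restoreModel(f), "cannot read|not a frameTriage")
  saveRDS(list(format = "something-else"), f)
  expect_error(restoreModel(f), "not a frameTriage model")
})

test_that("optional standardization fits on the training data only", {
  m <- trainModel(sepToy$X, sepToy$y, algorithm = "logreg",
                  standardize = TRUE)
  expect_length(m@center, 5L)
  expect_identical(as.character(predictLabels(m, sepToy$X)), sepToy$y)
})
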