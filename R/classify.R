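#' Build the ROI-pixel feature matrix
#'
#' The feature vector of a frame is the raw pixel intensity of every ROI
#' pixel: row i of the returned matrix is the row-major flattening (ROI
#' rows concatenated) of frame i's ROI slab, sanitized to finite values.
#' The matrix carries the ROI fingerprint and the frame references as
#' attributes so that models refuse features from a different ROI.
#'
#' @param refs data.frame with columns `path` and `event` (0-based; `NA`
#'   event rows are expanded to all events of the file).
#' @param roi a [FrameRoi-class].
#' @param geom a [DetectorGeometry-class].
#' @param dataPath HDF5 dataset path passed to [openStack()].
#' @return numeric matrix (frames x ROI pixels) with attributes
#'   `roiFingerprint` and `refs`.
#' @export
buildFeatures <- function(refs, roi, geom, dataPath = NULL) {
  refs <- .expandRefs(refs[, c("path", "event"), drop = FALSE], dataPath)
  rect <- roiRect(roi, geom)
  stacks <- new.env(parent = emptyenv())
  rows <- lapply(seq_len(nrow(refs)), function(i) {
    p <- refs$path[i]
    st <- if (!is.null(stacks[[p]])) stacks[[p]] else {
      s <- tryCatch(openStack(p, dataPath), error = function(e)
        stop(sprintf("cannot read %s //%d: %s", p, refs$event[i],
                     conditionMessage(e)), call. = FALSE))
      stacks[[p]] <- s
      s
    }
    frame <- readFrame(st, refs$event[i], quiet = TRUE)
    if (rect$ss[2L] > nrow(frame) || rect$fs[2L] > ncol(frame))
      stop(sprintf("ROI %s outside frame shape (%d, %d) of %s",
                   rect$fingerprint, nrow(frame), ncol(frame), p))
    as.vector(t(.roiSlab(frame, rect)))
  })
  X <- do.call(rbind, rows)
  X[!is.finite(X)] <- 0
  attr(X, "roiFingerprint") <- rect$fingerprint
  attr(X, "refs") <- refs
  X
}

#' Random train/test split of an annotated dataset
#'
#' Splits the good/bad-labelled frames uniformly at random (under `seed`)
#' into a training and a testing subset; the test subset is excluded from
#' model training to avoid bias. The two fractions must sum to 1 — a
#' mismatch is an error quoting both values, the same guard the
#' interactive workflow enforces. The training side takes
#' `floor(trainFrac * N)` frames.
#'
#' @param labels a [LabelSet-class]; only `good`/`bad` rows are used.
#' @param trainFrac,testFrac split fractions (default 0.7 / 0.3).
#' @param seed integer RNG seed; the same seed reproduces the partition
#'   exactly.
#' @param stratify if `TRUE`, split each class separately so class
#'   proportions are preserved (default `FALSE`: plain random split).
#' @return list with data.frames `train` and `test` (columns `path`,
#'   `event`, `label`), disjoint and jointly covering all labelled
#'   frames.
#' @export
splitDataset <- function(labels, trainFrac = 0.7, testFrac = 0.3, seed = 1L,
                         stratify = FALSE) {
  if (abs(trainFrac + testFrac - 1) > 1e-8)
    stop(sprintf("train/test split must equate to 100%%: got %g + %g = %g",
                 trainFrac, testFrac, trainFrac + testFrac))
  if (trainFrac <= 0 || testFrac <= 0)
    stop("both split fractions must be > 0")
  r <- labelRefs(labels)
  r <- r[r$label %in% c("good", "bad"), , drop = FALSE]
  if (nrow(r) < 2L) stop("need at least 2 good/bad-labelled frames")
  if (length(unique(r$label)) < 2L)
    stop("both classes (good and bad) must be present to split")
  # hash the seed into a different RNG stream: a caller reusing one seed for
  # data generation and splitting must not end up with the split permutation
  # equal to the generator's class shuffle
  set.seed(as.integer((as.numeric(seed) * 2654435761) %% 2147483647))
  pick <- function(idx) {
    perm <- idx[sample.int(length(idx))]
    nTrain <- floor(trainFrac * length(idx))
    list(train = perm[seq_len(nTrain)],
         test = perm[setdiff(seq_along(perm), seq_len(nTrain))])
  }
  if (stratify) {
    parts <- lapply(split(seq_len(nrow(r)), r$label), pick)
    iTrain <- sort(unlist(lapply(parts, `[[`, "train"), use.names = FALSE))
    iTest <- sort(unlist(lapply(parts, `[[`, "test"), use.names = FALSE))
  } else {
    p <- pick(seq_len(nrow(r)))
    iTrain <- sort(p$train); iTest <- sort(p$test)
  }
  if (!length(iTrain) || !length(iTest))
    stop(sprintf("split leaves an empty side (N = %d, trainFrac = %g)",
                 nrow(r), trainFrac))
  list(train = r[iTrain, , drop = FALSE], test = r[iTest, , drop = FALSE])
}

.algorithms <- c("logreg", "knn", "dtree", "rforest")

#' Train a good/bad frame classifier
#'
#' Fits one of the four supported classical algorithms on ROI pixel
#' features with known good/bad labels. `good` is the positive class.
#' Defaults: KNN K = 5 (odd, avoiding binary vote ties), random forest
#' 100 trees, decision tree grown without depth limit, logistic
#' regression with L2 (ridge) regularization at `lambda = 1/n`.
#' Stochastic algorithms are seeded, so training is reproducible.
#'
#' @param features matrix from [buildFeatures()] (frames x ROI pixels).
#' @param labels character vector (`good`/`bad`), one per feature row.
#' @param algorithm `"logreg"`, `"knn"`, `"dtree"` or `"rforest"`.
#' @param hyperparams optional list: `k` (knn), `ntree` (rforest),
#'   `cp`/`minsplit` (dtree), `lambda` (logreg).
#' @param seed integer RNG seed.
#' @param standardize standardize features to zero mean / unit variance
#'   (parameters fitted on this training set only). Off by default: the
#'   trees are scale-invariant and raw ROI pixels mirror the intended
#'   feature definition.
#' @return A [FrameModel-class].
#' @seealso [predictLabels()], [persistModel()]
#' @export
trainModel <- function(features, labels, algorithm = "rforest",
                       hyperparams = list(), seed = 1L,
                       standardize = FALSE) {
  if (!algorithm %in% .algorithms)
    stop(sprintf("unknown algorithm '%s'; supported: %s", algorithm,
                 paste(.algorithms, collapse = ", ")))
  labels <- as.character(labels)
  if (length(labels) != nrow(features))
    stop("one label per feature row required")
  if (!all(labels %in% c("good", "bad")))
    stop("labels must be 'good' or 'bad'")
  if (length(unique(labels)) < 2L)
    stop("training requires both classes; got only '", labels[1L], "'")
  y <- factor(labels, levels = c("bad", "good"))
  X <- unname(as.matrix(features))
  storage.mode(X) <- "double"

  center <- numeric(0); scale <- numeric(0)
  if (standardize) {
    center <- colMeans(X)
    scale <- apply(X, 2L, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
    X <- sweep(sweep(X, 2L, center), 2L, scale, `/`)
  }

  seed <- as.integer(seed)
  set.seed(seed)
  hp <- hyperparams
  fit <- switch(algorithm,
    rforest = {
      hp$ntree <- hp$ntree %||% 100L
      randomForest::randomForest(x = X, y = y, ntree = hp$ntree)
    },
    dtree = {
      hp$cp <- hp$cp %||% 0
      hp$minsplit <- hp$minsplit %||% 2L
      df <- data.frame(.y = y, X)
      rpart::rpart(.y ~ ., data = df, method = "class",
                   control = rpart::rpart.control(cp = hp$cp,
                                                  minsplit = hp$minsplit,
                                                  xval = 0L))
    },
    logreg = {
      hp$lambda <- hp$lambda %||% 1 / nrow(X)
      glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                     lambda = hp$lambda, standardize = FALSE)
    },
    knn = {
      hp$k <- hp$k %||% 5L
      list(x = X, y = y)        # knn is lazy: training = storing the data
    })

  counts <- table(y)
  new("FrameModel", algorithm = algorithm, fit = fit, hyperparams = hp,
      roiFingerprint = attr(features, "roiFingerprint") %||% "",
      nFeatures = ncol(X), seed = seed,
      classCounts = stats::setNames(as.integer(counts), names(counts)),
      standardize = standardize, center = center, scale = scale)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict good/bad labels for frames
#'
#' Applies a trained model to a feature matrix. The feature width and the
#' ROI fingerprint must match the ones the model was trained with;
#' mismatches are errors, never silent.
#'
#' @param model a [FrameModel-class].
#' @param features matrix from [buildFeatures()].
#' @return character vector of `good`/`bad`, one per row, with attribute
#'   `scores` = estimated P(good) where the algorithm provides it.
#' @export
predictLabels <- function(model, features) {
  stopifnot(is(model, "FrameModel"))
  X <- unname(as.matrix(features))
  storage.mode(X) <- "double"
  if (ncol(X) != model@nFeatures)
    stop(sprintf(
      "feature length %d does not match model's %d (feature ROI '%s', model ROI '%s')",
      ncol(X), model@nFeatures, attr(features, "roiFingerprint") %||% "?",
      model@roiFingerprint))
  fpIn <- attr(features, "roiFingerprint")
  if (!is.null(fpIn) && nzchar(model@roiFingerprint) && fpIn != model@roiFingerprint)
    stop(sprintf("ROI fingerprint mismatch: features from %s, model trained on %s",
                 fpIn, model@roiFingerprint))
  if (model@standardize)
    X <- sweep(sweep(X, 2L, model@center), 2L, model@scale, `/`)

  scores <- switch(model@algorithm,
    rforest = stats::predict(model@fit, X, type = "prob")[, "good"],
    dtree = stats::predict(model@fit, data.frame(X), type = "prob")[, "good"],
    logreg = as.numeric(stats::predict(model@fit, X, type = "response")),
    knn = {
      # seed the neighbour vote's tie-breaks without disturbing the
      # caller's RNG stream
      rng <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(rng)) assign(".Random.seed", rng, .GlobalEnv))
      set.seed(model@seed)
      pred <- class::knn(model@fit$x, X, model@fit$y,
                         k = model@hyperparams$k, prob = TRUE)
      p <- attr(pred, "prob")
      ifelse(pred == "good", p, 1 - p)
    })
  # ties at exactly 0.5 resolve to "bad": deterministic, errs conservative
  labels <- ifelse(scores > 0.5, "good", "bad")
  attr(labels, "scores") <- unname(scores)
  labels
}

#' Save a trained model for future use
#'
#' The file is a self-describing container recording the algorithm,
#' hyperparameters, ROI fingerprint and seed next to the fitted state;
#' [restoreModel()] refuses files written by an incompatible version.
#'
#' @param model a [FrameModel-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
persistModel <- function(model, path) {
  stopifnot(is(model, "FrameModel"))
  saveRDS(list(format = "frameTriage-model", version = 1L, model = model),
          path)
  invisible(path)
}

#' Restore a saved model
#'
#' @param path file written by [persistModel()].
#' @return A [FrameModel-class].
#' @export
restoreModel <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("cannot read model file %s: %s", path, conditionMessage(e)),
         call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "frameTriage-model"))
    stop(sprintf("%s is not a frameTriage model file", path))
  if (!identical(obj$version, 1L))
    stop(sprintf("unsupported model file version %s", obj$version))
  model <- obj$model
  if (!is(model, "FrameModel")) stop("corrupt model file: payload missing")
  validObject(model)
  model
}
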