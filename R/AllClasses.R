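#' @import methods
NULL

#' Detector geometry: panel slabs and their lab-frame placement
#'
#' A `DetectorGeometry` describes how the rectangular panel slabs of a
#' segmented detector, stored contiguously in a single raw 2D data array,
#' are placed in the laboratory coordinate frame. Each panel carries its
#' data-space rectangle (`min_fs`/`max_fs`/`min_ss`/`max_ss`, 0-based
#' inclusive as in CrystFEL geometry files), the lab-frame direction
#' vectors of its fast- and slow-scan axes, and the lab-frame position of
#' its first pixel relative to the beam centre (pixel units).
#'
#' @slot panels data.frame with one row per panel and columns `name`,
#'   `min_fs`, `max_fs`, `min_ss`, `max_ss`, `fsx`, `fsy`, `ssx`, `ssy`,
#'   `cnx`, `cny`.
#' @slot dataShape integer(2); (rows, cols) of the raw per-event array,
#'   rows indexed by slow scan (ss) and columns by fast scan (fs).
#'
#' @seealso [parseGeometry()], [assembleImage()], [panelSlice()]
#' @export
setClass("DetectorGeometry",
  representation(panels = "data.frame", dataShape = "integer"))

.geomCols <- c("name", "min_fs", "max_fs", "min_ss", "max_ss",
               "fsx", "fsy", "ssx", "ssy", "cnx", "cny")

setValidity("DetectorGeometry", function(object) {
  p <- object@panels
  if (!all(.geomCols %in% names(p)))
    return(paste("panels must have columns:", paste(.geomCols, collapse = ", ")))
  if (nrow(p) < 1L) return("geometry must contain at least one panel")
  if (anyDuplicated(p$name)) return("duplicate panel names")
  if (any(p$max_fs < p$min_fs) || any(p$max_ss < p$min_ss))
    return("panel with max_fs < min_fs or max_ss < min_ss")
  if (length(object@dataShape) != 2L || any(object@dataShape < 1L))
    return("dataShape must be two positive integers (rows, cols)")
  if (any(p$min_fs < 0L) || any(p$min_ss < 0L) ||
      any(p$max_ss >= object@dataShape[1L]) || any(p$max_fs >= object@dataShape[2L]))
    return("panel data rectangle outside dataShape")
  # fs and ss must span the plane
  det <- p$fsx * p$ssy - p$fsy * p$ssx
  if (any(abs(det) < 1e-12))
    return(paste("fs and ss vectors are collinear for panel",
                 p$name[which(abs(det) < 1e-12)[1L]]))
  # pairwise disjoint data rectangles
  n <- nrow(p)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      fsOverlap <- p$min_fs[i] <= p$max_fs[j] && p$min_fs[j] <= p$max_fs[i]
      ssOverlap <- p$min_ss[i] <= p$max_ss[j] && p$min_ss[j] <= p$max_ss[i]
      if (fsOverlap && ssOverlap)
        return(sprintf("panels '%s' and '%s' overlap in the raw data array",
                       p$name[i], p$name[j]))
    }
  }
  TRUE
})

setMethod("show", "DetectorGeometry", function(object) {
  cat(sprintf("DetectorGeometry: %d panel(s), raw data shape %d x %d (ss x fs)\n",
              nrow(object@panels), object@dataShape[1L], object@dataShape[2L]))
  for (i in seq_len(nrow(object@panels))) {
    p <- object@panels[i, ]
    cat(sprintf("  %s: fs [%d,%d] ss [%d,%d]  corner (%.1f, %.1f)\n",
                p$name, p$min_fs, p$max_fs, p$min_ss, p$max_ss, p$cnx, p$cny))
  }
})

#' Handle to one multi-event HDF5 frame stack
#'
#' Addresses a 2D (single event) or 3D dataset of detector frames inside an
#' HDF5 file. Events are the slowest-varying dimension in the file; each
#' event is one (rows x cols) frame in the raw panel-slab layout.
#'
#' @slot path HDF5 file path.
#' @slot dataPath HDF5 dataset path inside the file.
#' @slot nEvents number of events (frames).
#' @slot frameShape integer(2); (rows, cols) of one frame.
#' @seealso [openStack()], [readFrame()]
#' @export
setClass("FrameStack",
  representation(path = "character", dataPath = "character",
                 nEvents = "integer", frameShape = "integer",
                 rank = "integer"))

setValidity("FrameStack", function(object) {
  if (object@nEvents < 1L) return("nEvents must be >= 1")
  if (length(object@frameShape) != 2L || any(object@frameShape < 1L))
    return("frameShape must be two positive integers")
  TRUE
})

setMethod("show", "FrameStack", function(object) {
  cat(sprintf("FrameStack: %s[%s]  %d event(s) of %d x %d\n",
              object@path, object@dataPath, object@nEvents,
              object@frameShape[1L], object@frameShape[2L]))
})

#' Region of interest on the raw detector array
#'
#' Either a named detector panel (resolved against a [DetectorGeometry]) or
#' an explicit data-space rectangle. Rectangles are half-open 0-based
#' `[ss0, ss1) x [fs0, fs1)` ranges into the raw array.
#'
#' @slot panel character; panel name, or empty when a rectangle is given.
#' @slot ss integer(2) half-open slow-scan (row) range, or empty.
#' @slot fs integer(2) half-open fast-scan (column) range, or empty.
#' @seealso [frameRoi()], [roiRect()]
#' @export
setClass("FrameRoi",
  representation(panel = "character", ss = "integer", fs = "integer"))

setValidity("FrameRoi", function(object) {
  hasPanel <- length(object@panel) == 1L && nzchar(object@panel)
  hasRect <- length(object@ss) == 2L && length(object@fs) == 2L
  if (!hasPanel && !hasRect)
    return("ROI needs either a panel name or both ss and fs ranges")
  if (hasRect && (object@ss[2L] <= object@ss[1L] || object@fs[2L] <= object@fs[1L]))
    return("ROI rectangle is empty (half-open ranges must satisfy hi > lo)")
  TRUE
})

setMethod("show", "FrameRoi", function(object) {
  if (length(object@panel) == 1L && nzchar(object@panel)) {
    cat(sprintf("FrameRoi: panel '%s'\n", object@panel))
  } else {
    cat(sprintf("FrameRoi: ss [%d,%d) fs [%d,%d)\n",
                object@ss[1L], object@ss[2L], object@fs[1L], object@fs[2L]))
  }
})

#' 1D vertical intensity projection of an ROI
#'
#' Mean pixel intensity of each slow-scan row of the ROI slab, averaged
#' across the fast-scan extent; position r is the 0-based row index within
#' the ROI.
#'
#' @slot values numeric; mean intensity per ROI row.
#' @slot sourcePath,sourceEvent provenance of the frame (may be empty).
#' @slot roiFingerprint character id of the ROI rectangle used.
#' @seealso [verticalProjection()], [fitProfilePolynomial()]
#' @export
setClass("IntensityProfile",
  representation(values = "numeric", sourcePath = "character",
                 sourceEvent = "integer", roiFingerprint = "character"))

setValidity("IntensityProfile", function(object) {
  if (length(object@values) < 1L) return("profile must have at least one row")
  if (!all(is.finite(object@values))) return("profile values must be finite")
  TRUE
})

setMethod("show", "IntensityProfile", function(object) {
  cat(sprintf("IntensityProfile: %d rows, range [%.4g, %.4g]\n",
              length(object@values), min(object@values), max(object@values)))
})

#' Polynomial fit to an intensity profile and its inflection points
#'
#' Least-squares polynomial of a chosen degree fitted to an
#' [IntensityProfile]; the inflection points are the real roots of the
#' second derivative that fall inside the profile domain, in ascending
#' order. Coefficients are reported in original row units (ascending
#' powers), although the fit itself runs on an abscissa rescaled to
#' \[-1, 1\] for numerical conditioning.
#'
#' @slot order polynomial degree.
#' @slot coefficients numeric(order + 1); ascending powers of the row index.
#' @slot domain numeric(2); \[0, L-1\] in row units.
#' @slot inflections ascending in-domain real roots of the 2nd derivative.
#' @seealso [fitProfilePolynomial()], [polyValues()], [inflections()]
#' @export
setClass("PolyFit",
  representation(order = "integer", coefficients = "numeric",
                 domain = "numeric", inflections = "numeric"))

setValidity("PolyFit", function(object) {
  if (length(object@coefficients) != object@order + 1L)
    return("coefficient count must equal order + 1")
  if (length(object@inflections) > max(0L, object@order - 2L))
    return("more inflections than order - 2")
  if (length(object@inflections) &&
      (any(object@inflections < object@domain[1L] - 1e-6) ||
       any(object@inflections > object@domain[2L] + 1e-6)))
    return("inflection outside domain")
  TRUE
})

setMethod("show", "PolyFit", function(object) {
  cat(sprintf("PolyFit: degree %d on [%g, %g]; %d inflection(s)%s\n",
              object@order, object@domain[1L], object@domain[2L],
              length(object@inflections),
              if (length(object@inflections))
                paste0(" at ", paste(signif(object@inflections, 6), collapse = ", "))
              else ""))
})

#' Good/bad/skip frame annotations
#'
#' Maps frame references (file path + 0-based event index) to one of the
#' labels `good`, `bad` or `skip`. One label per frame; conflicting labels
#' are a hard error at merge/load time, never silently resolved.
#'
#' @slot refs data.frame with columns `path` (character), `event`
#'   (integer; `NA` means the whole file) and `label`.
#' @seealso [labelSet()], [mergeLabelSets()], [saveLabelSet()],
#'   [loadLabelSet()]
#' @export
setClass("LabelSet", representation(refs = "data.frame"))

setValidity("LabelSet", function(object) {
  r <- object@refs
  if (!all(c("path", "event", "label") %in% names(r)))
    return("refs needs columns path, event, label")
  if (!all(r$label %in% c("good", "bad", "skip")))
    return("labels must be good, bad or skip")
  key <- paste(r$path, r$event, sep = "\r")
  if (anyDuplicated(key)) {
    d <- r[duplicated(key) | duplicated(key, fromLast = TRUE), ]
    return(sprintf("duplicate frame reference: %s //%s", d$path[1L], d$event[1L]))
  }
  TRUE
})

setMethod("show", "LabelSet", function(object) {
  n <- labelCounts(object)
  cat(sprintf("LabelSet: %d good, %d bad, %d skip (%d frames)\n",
              n[["good"]], n[["bad"]], n[["skip"]], sum(n)))
})

#' A trained good/bad frame classifier
#'
#' Wraps the fitted state of one of the four supported algorithms together
#' with the metadata needed to apply it safely: the ROI fingerprint and
#' feature count it was trained with (prediction refuses mismatching
#' features), the RNG seed, the per-class training counts and any
#' standardization parameters.
#'
#' @slot algorithm one of `"logreg"`, `"knn"`, `"dtree"`, `"rforest"`.
#' @slot fit fitted model object (algorithm dependent; for knn, the stored
#'   training set).
#' @slot hyperparams list of hyperparameters actually used.
#' @slot roiFingerprint ROI id the features came from.
#' @slot nFeatures expected feature-vector length (ROI pixel count).
#' @slot seed integer RNG seed used for training.
#' @slot classCounts named integer; training frames per class.
#' @slot standardize logical; whether features are standardized.
#' @slot center,scale per-feature standardization parameters (empty when
#'   `standardize` is `FALSE`).
#' @seealso [trainModel()], [predictLabels()], [persistModel()]
#' @export
setClass("FrameModel",
  representation(algorithm = "character", fit = "ANY", hyperparams = "list",
                 roiFingerprint = "character", nFeatures = "integer",
                 seed = "integer", classCounts = "integer",
                 standardize = "logical", center = "numeric", scale = "numeric"))

setValidity("FrameModel", function(object) {
  if (!object@algorithm %in% c("logreg", "knn", "dtree", "rforest"))
    return("algorithm must be one of logreg, knn, dtree, rforest")
  if (object@nFeatures < 1L) return("nFeatures must be positive")
  TRUE
})

setMethod("show", "FrameModel", function(object) {
  cat(sprintf("FrameModel: %s, %d features, ROI %s\n  trained on %s (seed %d)\n",
              object@algorithm, object@nFeatures, object@roiFingerprint,
              paste(sprintf("%d %s", object@classCounts, names(object@classCounts)),
                    collapse = " + "),
              object@seed))
})

#' Binary confusion matrix (positive class = good)
#'
#' @slot tp,tn,fp,fn non-negative counts; `tp + tn + fp + fn` equals the
#'   number of evaluated frames.
#' @seealso [confusionMatrix()], [classificationReport()]
#' @export
setClass("ConfusionMatrix",
  representation(tp = "integer", tn = "integer", fp = "integer", fn = "integer"))

setValidity("ConfusionMatrix", function(object) {
  if (any(c(object@tp, object@tn, object@fp, object@fn) < 0L))
    return("counts must be non-negative")
  TRUE
})

setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2L, 2L,
              dimnames = list(actual = c("good", "bad"),
                              predicted = c("good", "bad")))
  cat("ConfusionMatrix (positive = good):\n")
  print(m)
})

#' Per-class classification report
#'
#' Accuracy, misclassification rate and per-class precision, recall, F1
#' and support for a binary good/bad evaluation. All rates are stored as
#' fractions in \[0, 1\]; `show()` renders percentages. Ratios with a zero
#' denominator are `NA` and flagged in `undefined` rather than silently 0.
#'
#' @slot accuracy (TP + TN) / total.
#' @slot misclassification (FP + FN) / total; complement of accuracy.
#' @slot perClass data.frame with one row per class (`good`, `bad`) and
#'   columns `precision`, `recall`, `f1`, `support`, `misclassification`
#'   (per-class rate, 1 - recall).
#' @slot undefined character; names of fields with zero-denominator ratios.
#' @slot cm the underlying [ConfusionMatrix-class].
#' @seealso [classificationReport()]
#' @export
setClass("ClassificationReport",
  representation(accuracy = "numeric", misclassification = "numeric",
                 perClass = "data.frame", undefined = "character",
                 cm = "ConfusionMatrix"))

setMethod("show", "ClassificationReport", function(object) {
  cat("ClassificationReport (positive = good)\n")
  cat(sprintf("  accuracy          %6.1f%%\n", 100 * object@accuracy))
  cat(sprintf("  misclassification %6.1f%%\n", 100 * object@misclassification))
  pc <- object@perClass
  cat("  class  precision  recall      f1  support  misclassified\n")
  for (i in seq_len(nrow(pc))) {
    fmt <- function(x) if (is.na(x)) "   n/a" else sprintf("%5.1f%%", 100 * x)
    cat(sprintf("  %-5s  %9s  %6s  %6s  %7d  %13s\n", pc$class[i],
                fmt(pc$precision[i]), fmt(pc$recall[i]), fmt(pc$f1[i]),
                pc$support[i], fmt(pc$misclassification[i])))
  }
  if (length(object@undefined))
    cat("  undefined (zero denominator):",
        paste(object@undefined, collapse = ", "), "\n")
})
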