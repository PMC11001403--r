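#' Construct a region of interest
#'
#' An ROI is either a detector panel name (resolved through the geometry;
#' clicking a panel in the original viewer workflow corresponds to
#' `frameRoi(panel = ...)`) or an explicit half-open 0-based data-space
#' rectangle.
#'
#' @param panel panel name, or `NULL`.
#' @param ss,fs integer(2) half-open `[lo, hi)` row/column ranges, or
#'   `NULL` when `panel` is given.
#' @return A [FrameRoi-class].
#' @export
frameRoi <- function(panel = NULL, ss = NULL, fs = NULL) {
  new("FrameRoi",
      panel = if (is.null(panel)) character(0) else as.character(panel),
      ss = if (is.null(ss)) integer(0) else as.integer(ss),
      fs = if (is.null(fs)) integer(0) else as.integer(fs))
}

#' Resolve an ROI to its data-space rectangle
#'
#' @param roi a [FrameRoi-class].
#' @param geom a [DetectorGeometry-class]; required for panel ROIs and for
#'   bounds checking.
#' @return list with `ss`, `fs` (half-open integer(2) ranges) and
#'   `fingerprint` (a character id of the rectangle).
#' @export
roiRect <- function(roi, geom = NULL) {
  stopifnot(is(roi, "FrameRoi"))
  if (length(roi@panel) == 1L && nzchar(roi@panel)) {
    if (is.null(geom)) stop("panel ROI needs a DetectorGeometry to resolve")
    rect <- panelSlice(geom, roi@panel)
  } else {
    rect <- list(ss = roi@ss, fs = roi@fs)
  }
  if (!is.null(geom)) {
    shp <- geom@dataShape
    if (rect$ss[1L] < 0L || rect$ss[2L] > shp[1L] ||
        rect$fs[1L] < 0L || rect$fs[2L] > shp[2L])
      stop(sprintf("ROI ss [%d,%d) fs [%d,%d) outside frame shape (%d, %d)",
                   rect$ss[1L], rect$ss[2L], rect$fs[1L], rect$fs[2L],
                   shp[1L], shp[2L]))
  }
  rect$fingerprint <- sprintf("ss[%d,%d)fs[%d,%d)", rect$ss[1L], rect$ss[2L],
                              rect$fs[1L], rect$fs[2L])
  rect
}

# extract the ROI slab (rows = ss, cols = fs) from a raw frame
.roiSlab <- function(frame, rect) {
  frame[seq.int(rect$ss[1L] + 1L, rect$ss[2L]),
        seq.int(rect$fs[1L] + 1L, rect$fs[2L]), drop = FALSE]
}

#' 1D vertical projection of an ROI
#'
#' Projects the ROI slab onto its slow-scan (row) axis: value r is the
#' mean intensity of ROI row r across the full fast-scan extent. The mean
#' (rather than the sum) makes profiles comparable across ROI widths.
#'
#' @param frame raw 2D frame.
#' @param roi a [FrameRoi-class].
#' @param geom a [DetectorGeometry-class] (needed for panel ROIs).
#' @param sourcePath,sourceEvent optional provenance recorded on the
#'   profile.
#' @return An [IntensityProfile-class].
#' @export
verticalProjection <- function(frame, roi, geom = NULL,
                               sourcePath = character(0),
                               sourceEvent = integer(0)) {
  rect <- roiRect(roi, geom)
  if (rect$ss[2L] > nrow(frame) || rect$fs[2L] > ncol(frame))
    stop("ROI rectangle outside the frame")
  slab <- .roiSlab(frame, rect)
  if (!length(slab)) stop("empty ROI")
  new("IntensityProfile", values = rowMeans(slab),
      sourcePath = sourcePath, sourceEvent = as.integer(sourceEvent),
      roiFingerprint = rect$fingerprint)
}

#' Profiles for every event of a stack
#'
#' Convenience wrapper producing one [IntensityProfile-class] per event,
#' ready for [autoLabelByInflection()].
#'
#' @param stack a [FrameStack-class].
#' @param roi,geom as in [verticalProjection()].
#' @param events 0-based event indices (default: all).
#' @return list of [IntensityProfile-class] objects.
#' @export
profileStack <- function(stack, roi, geom = NULL, events = NULL) {
  if (is.null(events)) events <- seq_len(stack@nEvents) - 1L
  lapply(events, function(ev)
    verticalProjection(readFrame(stack, ev, quiet = TRUE), roi, geom,
                       sourcePath = stack@path, sourceEvent = ev))
}

#' Fit a polynomial to an intensity profile and locate its inflections
#'
#' Least-squares fit of a degree-`order` polynomial (default 4) to the
#' profile values against the 0-based row index. For conditioning the fit
#' runs on an abscissa rescaled to \[-1, 1\]; coefficients are converted
#' back to row units. Inflection points are the real roots of the second
#' derivative inside `[0, L-1]`, ascending. Second-derivative
#' coefficients that are negligible relative to the fit (|c| below
#' `1e-8` of the largest fitted coefficient) are treated as zero, so a
#' profile with no genuine curvature change yields an empty inflection
#' list instead of noise roots.
#'
#' @param profile an [IntensityProfile-class] or numeric vector of row
#'   means.
#' @param order polynomial degree (n >= 1); the profile must have at
#'   least `order + 1` rows.
#' @return A [PolyFit-class].
#' @examples
#' v <- (0:100 - 50)^3
#' inflections(fitProfilePolynomial(v, order = 3))  # 50
#' @export
fitProfilePolynomial <- function(profile, order = 4L) {
  values <- if (is(profile, "IntensityProfile")) profile@values else
    as.numeric(profile)
  order <- as.integer(order)
  if (order < 1L) stop("order must be >= 1")
  L <- length(values)
  if (L <= order)
    stop(sprintf("profile length %d too short for degree %d (need >= %d points)",
                 L, order, order + 1L))
  m <- (L - 1) / 2
  h <- max((L - 1) / 2, 1)
  xs <- (seq_len(L) - 1 - m) / h
  X <- outer(xs, 0:order, `^`)
  qrX <- qr(X)
  if (qrX$rank < order + 1L)
    stop("rank-deficient polynomial fit")
  aScaled <- qr.coef(qrX, values)

  # convert to coefficients in row units: p(i) = sum_k a_k ((i - m)/h)^k
  q <- c(-m / h, 1 / h)
  coefRow <- aScaled[order + 1L]
  if (order >= 1L) for (k in order:1) {
    coefRow <- .polyMul(coefRow, q)
    coefRow[1L] <- coefRow[1L] + aScaled[k]
  }
  coefRow <- c(coefRow, numeric(order + 1L - length(coefRow)))

  infl <- .inflectionPoints(aScaled, m, h, c(0, L - 1))
  new("PolyFit", order = order, coefficients = unname(coefRow),
      domain = c(0, L - 1), inflections = infl)
}

.polyMul <- function(a, b) {
  res <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a))
    res[i + seq_along(b) - 1L] <- res[i + seq_along(b) - 1L] + a[i] * b
  res
}

# real in-domain roots of the 2nd derivative, from scaled-abscissa coefs
.inflectionPoints <- function(aScaled, m, h, domain) {
  n <- length(aScaled) - 1L
  if (n < 2L) return(numeric(0))
  k <- 2:n
  c2 <- aScaled[k + 1L] * k * (k - 1L)        # coefs of x^(k-2), scaled space
  tol <- 1e-8 * max(abs(aScaled))
  c2[abs(c2) <= tol] <- 0
  while (length(c2) > 1L && c2[length(c2)] == 0) c2 <- c2[-length(c2)]
  if (length(c2) < 2L || all(c2 == 0)) return(numeric(0))
  roots <- polyroot(c2)
  re <- Re(roots)[abs(Im(roots)) <= 1e-6 * (1 + abs(Re(roots)))]
  pos <- m + h * re
  pos <- pos[pos >= domain[1L] - 1e-6 & pos <= domain[2L] + 1e-6]
  sort(pmin(pmax(pos, domain[1L]), domain[2L]))
}

#' Evaluate a fitted profile polynomial
#'
#' @param fit a [PolyFit-class].
#' @param x row positions at which to evaluate.
#' @return numeric; polynomial values.
#' @export
polyValues <- function(fit, x) {
  stopifnot(is(fit, "PolyFit"))
  co <- fit@coefficients
  out <- numeric(length(x)) + co[length(co)]
  if (length(co) > 1L) for (k in (length(co) - 1L):1L) out <- out * x + co[k]
  out
}

#' Auto-label frames from the inflection points of their profile fits
#'
#' Implements the dominant-histogram rule for automatic annotation: each
#' frame's profile is fitted with a polynomial and the frame's signature
#' is the first (lowest-position) in-domain inflection point. Signatures
#' are histogrammed with bins of width `binWidth`; frames whose signature
#' falls in the most populated bin are labelled `good`, all others `bad`.
#' This assumes that the majority of frames constitute good data — when
#' the dominant bin holds less than `minDominantFrac` of the signatures a
#' warning flag is raised in the diagnostics, because the majority
#' assumption is then questionable. Frames whose fit has no in-domain
#' inflection are labelled `skip` and excluded from the histogram.
#'
#' @param profiles list of [IntensityProfile-class] objects (>= 2).
#' @param order polynomial degree for the fits (default 4).
#' @param binWidth histogram bin width in row units; default `L / 20`
#'   where `L` is the profile length.
#' @param minDominantFrac dominant-bin fraction below which the warning
#'   flag is set (default 0.5).
#' @return list with elements `labels` (a [LabelSet-class]) and
#'   `diagnostics` (list: `signatures`, `binWidth`, `dominantBin`,
#'   `dominantFraction`, `warning`, `nSkipped`).
#' @export
autoLabelByInflection <- function(profiles, order = 4L, binWidth = NULL,
                                  minDominantFrac = 0.5) {
  if (length(profiles) < 2L) stop("need at least 2 profiles")
  L <- length(profiles[[1L]]@values)
  if (is.null(binWidth)) binWidth <- L / 20
  if (binWidth <= 0) stop("binWidth must be > 0")

  sig <- vapply(profiles, function(p) {
    fit <- fitProfilePolynomial(p, order = order)
    if (length(fit@inflections)) fit@inflections[1L] else NA_real_
  }, numeric(1))
  if (all(is.na(sig)))
    stop("no profile has an in-domain inflection point; cannot auto-label")

  ok <- which(!is.na(sig))
  bins <- floor((sig[ok] - min(sig[ok])) / binWidth)
  counts <- table(bins)
  top <- max(counts)
  dominantBin <- min(as.numeric(names(counts)[counts == top]))  # tie -> lower
  isGood <- bins == dominantBin
  dominantFraction <- sum(isGood) / length(ok)

  label <- rep("skip", length(profiles))
  label[ok[isGood]] <- "good"
  label[ok[!isGood]] <- "bad"
  refs <- data.frame(
    path = vapply(profiles, function(p)
      if (length(p@sourcePath)) p@sourcePath else "", character(1)),
    event = vapply(profiles, function(p)
      if (length(p@sourceEvent)) p@sourceEvent else NA_integer_, integer(1)),
    label = label, stringsAsFactors = FALSE)
  # anonymous profiles get synthetic refs so the LabelSet stays keyed
  anon <- !nzchar(refs$path)
  refs$path[anon] <- "<profile>"
  refs$event[anon & is.na(refs$event)] <- which(anon & is.na(refs$event)) - 1L

  list(labels = labelSet(refs),
       diagnostics = list(signatures = sig, binWidth = binWidth,
                          dominantBin = dominantBin,
                          dominantFraction = dominantFraction,
                          warning = dominantFraction < minDominantFrac,
                          nSkipped = sum(is.na(sig))))
}
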