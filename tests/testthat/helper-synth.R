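# shared fixtures: all synthetic data is generated in code at test time

smallConfig <- function(nFrames = 20L, seed = 101L, ...) {
  args <- list(nFrames = nFrames, nPanels = 2L, slabRows = 8L, slabCols = 10L,
               gap = 2L, ringRadius = 6, ringWidth = 2, ringAmplitude = 10,
               nSpots = 3L, spotAmplitude = 15, spotSigma = 1,
               noiseSigma = 1, artefactPanel = 1L, artefactRows = c(2L, 6L),
               artefactOffset = 5, seed = seed)
  do.call(synthConfig, utils::modifyList(args, list(...)))
}

# config realizing a clean two-cluster inflection scenario: a central
# diffuse blob gives good frames a profile bump (inflection ~10.5), the
# artefact step on the lower half of panel p1 moves it to ~16.2
autoLabelConfig <- function(nFrames = 40L, seed = 5L, artefactOffset = 30) {
  synthConfig(nFrames = nFrames, fracBad = 0.3, nSpots = 0L,
              noiseSigma = 0.3, ringRadius = 12, ringWidth = 4,
              ringAmplitude = 20, artefactRows = c(16L, 32L),
              artefactOffset = artefactOffset, seed = seed)
}

makeProfile <- function(values, path = "<profile>", event = 0L) {
  new("IntensityProfile", values = as.numeric(values),
      sourcePath = path, sourceEvent = as.integer(event),
      roiFingerprint = "test")
}

# independent brute-force oracle for the confusion matrix / report
bruteConfusion <- function(yt, yp) {
  tp <- 0L; tn <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_along(yt)) {
    if (yt[i] == "good" && yp[i] == "good") tp <- tp + 1L
    else if (yt[i] == "bad" && yp[i] == "bad") tn <- tn + 1L
    else if (yt[i] == "bad" && yp[i] == "good") fp <- fp + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, tn = tn, fp = fp, fn = fn)
}

randomLabelPair <- function(n) {
  list(yt = sample(c("good", "bad"), n, replace = TRUE),
       yp = sample(c("good", "bad"), n, replace = TRUE))
}

# quartic with second-derivative roots at r1 < r2 (both analytic):
# p''(x) = s (x - r1)(x - r2) integrated twice
quarticWithInflections <- function(r1, r2, s = 1) {
  c(0, 0, s * r1 * r2 / 2, -s * (r1 + r2) / 6, s / 12)
}

evalPolyCoefs <- function(co, x) {
  out <- numeric(length(x)) + co[length(co)]
  for (k in (length(co) - 1L):1L) out <- out * x + co[k]
  out
}

# bump-like quartic profile family on 0..100: inflections in [20, 80],
# separation >= 20, linear trend removed so the range reflects the
# curvature feature rather than the edge growth
noisyQuarticCase <- function() {
  repeat {
    r <- sort(stats::runif(2, 20, 80))
    if (diff(r) >= 20) break
  }
  x <- 0:100
  v <- evalPolyCoefs(quarticWithInflections(r[1L], r[2L]), x)
  v <- v - stats::lm(v ~ x)$fitted.values
  list(r = r, x = x, values = unname(v))
}
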