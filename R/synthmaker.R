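#' Configuration for the synthetic SFX frame generator
#'
#' Describes a small segmented detector and the image model used to
#' emulate serial-crystallography frames: a diffuse water-ring background
#' (Gaussian radial shell around the beam centre), Bragg-like Gaussian
#' spots scattered along the ring, i.i.d. Gaussian pixel noise, and — on
#' the "bad" fraction of frames — a miscalibration artefact: a constant
#' intensity offset on a row band of one panel, emulating a detector
#' whose gain-switching calibration fails over a q range when the water
#' ring drives it into a critical intensity regime.
#'
#' @param nFrames total frame count.
#' @param fracBad fraction of frames carrying the artefact; the bad set
#'   is the first `ceiling(fracBad * nFrames)` indices of a seeded
#'   shuffle, so class counts are exact and reproducible.
#' @param nPanels,slabRows,slabCols panel layout: `nPanels` slabs of
#'   `slabRows x slabCols` pixels, stacked along the slow-scan axis in
#'   the raw array and placed side by side (gap `gap` pixels) in the lab
#'   frame, centred on the beam.
#' @param gap lab-frame gap between adjacent panels (pixels; must be
#'   >= 0, otherwise panels would overlap).
#' @param ringRadius,ringWidth,ringAmplitude water-ring shell: radius and
#'   Gaussian width (pixels from beam centre) and peak intensity (ADU).
#' @param nSpots,spotAmplitude,spotSigma Bragg-like spots per frame:
#'   count, peak intensity and Gaussian radius; spots sit at random
#'   azimuths near the ring.
#' @param noiseSigma standard deviation of the Gaussian pixel noise (ADU).
#' @param artefactPanel 0-based index of the panel carrying the artefact.
#' @param artefactRows half-open `[lo, hi)` row band within that panel.
#' @param artefactOffset additive intensity offset (ADU) applied to the
#'   band on bad frames; 0 makes good and bad indistinguishable.
#' @param seed RNG seed; every random draw derives from it.
#' @return A validated `SynthConfig` (named list).
#' @seealso [makeGeometry()], [generateStack()]
#' @export
synthConfig <- function(nFrames = 600L, fracBad = 0.3,
                        nPanels = 2L, slabRows = 32L, slabCols = 64L,
                        gap = 2L,
                        ringRadius = 40, ringWidth = 6, ringAmplitude = 10,
                        nSpots = 15L, spotAmplitude = 20, spotSigma = 1.5,
                        noiseSigma = 1,
                        artefactPanel = 1L, artefactRows = c(8L, 24L),
                        artefactOffset = 5, seed = 42L) {
  cfg <- list(nFrames = as.integer(nFrames), fracBad = fracBad,
              nPanels = as.integer(nPanels), slabRows = as.integer(slabRows),
              slabCols = as.integer(slabCols), gap = as.integer(gap),
              ringRadius = ringRadius, ringWidth = ringWidth,
              ringAmplitude = ringAmplitude, nSpots = as.integer(nSpots),
              spotAmplitude = spotAmplitude, spotSigma = spotSigma,
              noiseSigma = noiseSigma,
              artefactPanel = as.integer(artefactPanel),
              artefactRows = as.integer(artefactRows),
              artefactOffset = artefactOffset, seed = as.integer(seed))
  if (cfg$nFrames < 1L) stop("nFrames must be >= 1")
  if (cfg$fracBad < 0 || cfg$fracBad > 1) stop("fracBad must be in [0, 1]")
  if (cfg$nPanels < 1L || cfg$slabRows < 1L || cfg$slabCols < 1L)
    stop("panel layout must be positive")
  if (cfg$gap < 0L) stop("panel layout overlaps: gap must be >= 0")
  if (any(c(cfg$ringAmplitude, cfg$spotAmplitude, cfg$noiseSigma) < 0))
    stop("amplitudes and noiseSigma must be >= 0")
  if (cfg$artefactPanel < 0L || cfg$artefactPanel >= cfg$nPanels)
    stop("artefactPanel out of range")
  if (cfg$artefactRows[1L] < 0L || cfg$artefactRows[2L] > cfg$slabRows ||
      cfg$artefactRows[2L] <= cfg$artefactRows[1L])
    stop("artefactRows must be a non-empty half-open band within the panel")
  class(cfg) <- "SynthConfig"
  cfg
}

#' Geometry for the synthetic detector
#'
#' Emits the CrystFEL-format text, its parsed [DetectorGeometry-class]
#' and a parameter dump (one row per panel, used as the oracle in
#' geometry tests) for a [synthConfig()] layout: panels stacked along ss
#' in the raw array, side by side along x in the lab frame, centred on
#' the beam.
#'
#' @param config a [synthConfig()].
#' @return list with `text` (character lines), `geometry`
#'   ([DetectorGeometry-class]) and `dump` (data.frame of panel
#'   parameters).
#' @export
makeGeometry <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  n <- config$nPanels
  width <- n * config$slabCols + (n - 1L) * config$gap
  dump <- do.call(rbind, lapply(seq_len(n) - 1L, function(j) {
    data.frame(name = sprintf("p%d", j),
               min_fs = 0L, max_fs = config$slabCols - 1L,
               min_ss = j * config$slabRows,
               max_ss = (j + 1L) * config$slabRows - 1L,
               fsx = 1, fsy = 0, ssx = 0, ssy = 1,
               cnx = j * (config$slabCols + config$gap) - width / 2,
               cny = -config$slabRows / 2,
               stringsAsFactors = FALSE)
  }))
  geom <- new("DetectorGeometry", panels = dump,
              dataShape = c(n * config$slabRows, config$slabCols))
  list(text = serializeGeometry(geom), geometry = geom, dump = dump)
}

# lab-frame x/y coordinate of every raw pixel (matrices rows x cols)
.labCoords <- function(geom) {
  shp <- geom@dataShape
  X <- matrix(NA_real_, shp[1L], shp[2L])
  Y <- matrix(NA_real_, shp[1L], shp[2L])
  for (i in seq_len(nrow(geom@panels))) {
    p <- geom@panels[i, ]
    ifs <- seq.int(0L, p$max_fs - p$min_fs)
    iss <- seq.int(0L, p$max_ss - p$min_ss)
    rows <- p$min_ss + iss + 1L
    cols <- p$min_fs + ifs + 1L
    X[rows, cols] <- outer(iss * p$ssx, ifs * p$fsx, `+`) + p$cnx
    Y[rows, cols] <- outer(iss * p$ssy, ifs * p$fsy, `+`) + p$cny
  }
  list(x = X, y = Y)
}

#' Generate synthetic multi-event HDF5 frame stacks with ground truth
#'
#' Writes `nFiles` multi-event HDF5 files (dataset `/data/data`, events
#' slowest-varying), a CrystFEL geometry file, ground-truth
#' `truth_good.lst`/`truth_bad.lst` event lists and a JSON parameter
#' dump. Frames follow the [synthConfig()] image model; bad frames
#' additionally carry the constant-offset artefact on the configured
#' panel row band. Fully reproducible: the same config (including seed)
#' produces identical pixel data and truth labels.
#'
#' @param config a [synthConfig()].
#' @param outDir output directory (created if needed).
#' @param nFiles number of HDF5 files to split the frames across.
#' @param filePrefix file name prefix.
#' @return list with `files` (HDF5 paths), `truth` ([LabelSet-class]),
#'   `geometry` ([DetectorGeometry-class]), `geometryFile`, `dump`
#'   (parameter record incl. per-panel rectangles) and `dumpFile`.
#' @export
generateStack <- function(config, outDir, nFiles = 1L,
                          filePrefix = "synth") {
  stopifnot(inherits(config, "SynthConfig"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop(sprintf("cannot create directory %s", outDir))
  gm <- makeGeometry(config)
  geom <- gm$geometry
  geometryFile <- file.path(outDir, "geometry.geom")
  writeLines(gm$text, geometryFile)

  lab <- .labCoords(geom)
  R <- sqrt(lab$x^2 + lab$y^2)
  ringImg <- config$ringAmplitude *
    exp(-(R - config$ringRadius)^2 / (2 * config$ringWidth^2))

  set.seed(config$seed)
  nBad <- as.integer(ceiling(config$fracBad * config$nFrames))
  shuffle <- sample.int(config$nFrames)
  isBad <- logical(config$nFrames)
  isBad[shuffle[seq_len(nBad)]] <- TRUE

  bandRows <- config$artefactPanel * config$slabRows +
    seq.int(config$artefactRows[1L] + 1L, config$artefactRows[2L])
  shp <- geom@dataShape

  nFiles <- as.integer(nFiles)
  perFile <- rep(config$nFrames %/% nFiles, nFiles) +
    (seq_len(nFiles) <= config$nFrames %% nFiles)
  if (any(perFile < 1L)) stop("more files than frames")
  files <- file.path(outDir, sprintf("%s_%03d.h5", filePrefix,
                                     seq_len(nFiles) - 1L))

  frameIdx <- 0L
  truthRows <- vector("list", nFiles)
  for (f in seq_len(nFiles)) {
    arr <- array(0, dim = c(shp[1L], shp[2L], perFile[f]))
    for (e in seq_len(perFile[f])) {
      frameIdx <- frameIdx + 1L
      frame <- ringImg
      if (config$nSpots > 0L) {
        theta <- stats::runif(config$nSpots, 0, 2 * pi)
        rad <- stats::rnorm(config$nSpots, config$ringRadius,
                            config$ringWidth)
        for (s in seq_len(config$nSpots)) {
          sx <- rad[s] * cos(theta[s]); sy <- rad[s] * sin(theta[s])
          frame <- frame + config$spotAmplitude *
            exp(-((lab$x - sx)^2 + (lab$y - sy)^2) / (2 * config$spotSigma^2))
        }
      }
      if (config$noiseSigma > 0)
        frame <- frame + matrix(stats::rnorm(length(frame), 0,
                                             config$noiseSigma),
                                shp[1L], shp[2L])
      if (isBad[frameIdx])
        frame[bandRows, ] <- frame[bandRows, ] + config$artefactOffset
      arr[, , e] <- frame
    }
    if (file.exists(files[f])) unlink(files[f])
    rhdf5::h5createFile(files[f])
    rhdf5::h5createGroup(files[f], "data")
    # one chunk per frame so single-event reads stay cheap
    rhdf5::h5createDataset(files[f], "/data/data", dims = dim(arr),
                           storage.mode = "double",
                           chunk = c(shp[1L], shp[2L], 1L), level = 1L)
    rhdf5::h5write(arr, files[f], "/data/data")
    first <- frameIdx - perFile[f]
    truthRows[[f]] <- data.frame(
      path = files[f], event = seq_len(perFile[f]) - 1L,
      label = ifelse(isBad[first + seq_len(perFile[f])], "bad", "good"),
      stringsAsFactors = FALSE)
  }
  truth <- labelSet(do.call(rbind, truthRows))
  r <- labelRefs(truth)
  .writeEventList(r[r$label == "good", ], file.path(outDir, "truth_good.lst"))
  .writeEventList(r[r$label == "bad", ], file.path(outDir, "truth_bad.lst"))

  dump <- list(config = unclass(config), panels = gm$dump,
               files = basename(files), perFile = perFile,
               bandRows0 = bandRows - 1L)
  dumpFile <- file.path(outDir, "synth_params.json")
  writeLines(jsonlite::toJSON(dump, auto_unbox = TRUE, digits = NA,
                              dataframe = "columns"), dumpFile)
  list(files = files, truth = truth, geometry = geom,
       geometryFile = geometryFile, dump = dump, dumpFile = dumpFile)
}
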