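#' Sort a folder of multi-event files with a trained model
#'
#' Applies a [FrameModel-class] to every event of every file matching
#' `glob` under `folder`, writes `good.lst`/`bad.lst` event lists and
#' returns a per-file summary. Output ordering is canonical (path, then
#' event) and identical for any worker count: workers only partition the
#' file list, and results are merged back in order. A file that cannot
#' be read is skipped with a logged error and marked failed in the
#' summary; the run continues.
#'
#' Execution tiers: with `workers > 1` on a unix platform, a forked
#' process pool (`parallel::mclapply`) is used; otherwise the run is
#' serial. The chosen tier is logged and has no effect on the output.
#'
#' @param folder directory containing the files.
#' @param model a [FrameModel-class].
#' @param roi a [FrameRoi-class]; must match the model's ROI fingerprint.
#' @param geom a [DetectorGeometry-class].
#' @param glob filename pattern (default `"*.h5"`).
#' @param dataPath HDF5 dataset path (default: candidate search).
#' @param workers process count (default 1).
#' @param outDir directory for `good.lst`/`bad.lst`; `NULL` writes no
#'   files.
#' @param quiet suppress progress messages.
#' @return list with `good` and `bad` (data.frames of `path`, `event`),
#'   `summary` (data.frame: `path`, `nEvents`, `nGood`, `nBad`,
#'   `failed`), and `files` (the written list paths, if any).
#' @export
sortDataset <- function(folder, model, roi, geom, glob = "*.h5",
                        dataPath = NULL, workers = 1L, outDir = NULL,
                        quiet = FALSE) {
  stopifnot(is(model, "FrameModel"))
  files <- sort(Sys.glob(file.path(folder, glob)))
  if (!length(files))
    stop(sprintf("no files matching '%s' in %s", glob, folder))
  rect <- roiRect(roi, geom)
  if (nzchar(model@roiFingerprint) && rect$fingerprint != model@roiFingerprint)
    stop(sprintf("ROI fingerprint mismatch: sort ROI %s, model trained on %s",
                 rect$fingerprint, model@roiFingerprint))

  sortOne <- function(path) {
    tryCatch({
      st <- openStack(path, dataPath)
      refs <- data.frame(path = path, event = seq_len(st@nEvents) - 1L,
                         stringsAsFactors = FALSE)
      X <- buildFeatures(refs, roi, geom, dataPath = dataPath)
      labels <- predictLabels(model, X)
      list(path = path, refs = refs, labels = as.character(labels),
           failed = FALSE)
    }, error = function(e) {
      if (!quiet)
        message(sprintf("sortDataset: skipping %s: %s", path,
                        conditionMessage(e)))
      list(path = path, refs = NULL, labels = character(0), failed = TRUE)
    })
  }

  parallelOk <- workers > 1L && .Platform$OS.type == "unix"
  if (!quiet)
    message(sprintf("sortDataset: %d file(s), tier = %s", length(files),
                    if (parallelOk) sprintf("process pool (%d workers)", workers)
                    else "serial"))
  results <- if (parallelOk) {
    parallel::mclapply(files, sortOne, mc.cores = workers)
  } else {
    lapply(files, sortOne)
  }
  # canonical order regardless of scheduling
  results <- results[order(vapply(results, `[[`, character(1), "path"))]

  summary <- do.call(rbind, lapply(results, function(r) {
    data.frame(path = r$path,
               nEvents = if (r$failed) 0L else nrow(r$refs),
               nGood = sum(r$labels == "good"),
               nBad = sum(r$labels == "bad"),
               failed = r$failed, stringsAsFactors = FALSE)
  }))
  ok <- results[!vapply(results, `[[`, logical(1), "failed")]
  if (!length(ok)) stop("every file failed to sort")
  refs <- do.call(rbind, lapply(ok, `[[`, "refs"))
  labels <- unlist(lapply(ok, `[[`, "labels"), use.names = FALSE)
  good <- refs[labels == "good", , drop = FALSE]
  bad <- refs[labels == "bad", , drop = FALSE]
  rownames(good) <- rownames(bad) <- NULL

  outFiles <- character(0)
  if (!is.null(outDir))
    outFiles <- writeEventLists(good, bad, outDir)
  if (!quiet)
    message(sprintf("sortDataset: %d good, %d bad of %d event(s) in %d file(s)%s",
                    nrow(good), nrow(bad), nrow(good) + nrow(bad),
                    sum(!summary$failed),
                    if (any(summary$failed))
                      sprintf(" (%d failed)", sum(summary$failed)) else ""))
  list(good = good, bad = bad, summary = summary, files = outFiles)
}
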