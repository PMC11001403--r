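#' Create a label set
#'
#' @param refs data.frame with columns `path`, `event` (0-based integer;
#'   `NA` = whole file) and `label` (`good`, `bad` or `skip`). Rows with
#'   duplicate identical entries are deduplicated; the same frame with
#'   two different labels is an error.
#' @return A [LabelSet-class].
#' @export
labelSet <- function(refs = data.frame(path = character(0),
                                       event = integer(0),
                                       label = character(0))) {
  refs <- data.frame(path = as.character(refs$path),
                     event = as.integer(refs$event),
                     label = as.character(refs$label),
                     stringsAsFactors = FALSE)
  refs <- unique(refs)
  key <- paste(refs$path, refs$event, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    j <- which(key == key[i])
    stop(sprintf("conflicting labels for %s //%s: %s vs %s",
                 refs$path[i], refs$event[i],
                 refs$label[j[1L]], refs$label[j[2L]]))
  }
  refs <- refs[order(refs$path, refs$event), , drop = FALSE]
  rownames(refs) <- NULL
  new("LabelSet", refs = refs)
}

#' Merge label sets from several annotation sessions
#'
#' Supports the resume / multi-annotator workflow: annotations collected
#' in interrupted sessions or by different people are concatenated into
#' one training set. Identical duplicates deduplicate; the same frame
#' labelled differently in two sets is a hard error (silent label
#' corruption would poison training).
#'
#' @param ... [LabelSet-class] objects, or a single list of them.
#' @return The merged [LabelSet-class].
#' @export
mergeLabelSets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !is(sets[[1L]], "LabelSet"))
    sets <- sets[[1L]]
  if (!length(sets)) stop("need at least one LabelSet")
  stopifnot(all(vapply(sets, is, logical(1), "LabelSet")))
  labelSet(do.call(rbind, lapply(sets, labelRefs)))
}

#' Save a label set as event-list files
#'
#' Writes `good.lst` and `bad.lst` (the two sorted outputs consumed by
#' downstream tools) plus `skip.lst`, which makes an annotation session
#' losslessly resumable.
#'
#' @param labels a [LabelSet-class].
#' @param outDir output directory (created if needed).
#' @param quiet suppress the count message.
#' @return character(3); the written file paths.
#' @seealso [loadLabelSet()]
#' @export
saveLabelSet <- function(labels, outDir, quiet = FALSE) {
  stopifnot(is(labels, "LabelSet"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop(sprintf("cannot create directory %s", outDir))
  r <- labelRefs(labels)
  paths <- file.path(outDir, c("good.lst", "bad.lst", "skip.lst"))
  for (i in seq_along(paths))
    .writeEventList(r[r$label == c("good", "bad", "skip")[i], , drop = FALSE],
                    paths[i])
  if (!quiet) {
    n <- labelCounts(labels)
    message(sprintf("saved %d good, %d bad, %d skip to %s",
                    n[["good"]], n[["bad"]], n[["skip"]], outDir))
  }
  invisible(paths)
}

#' Load a label set from event-list files
#'
#' Reconstructs a [LabelSet-class] from the `good.lst` / `bad.lst` /
#' `skip.lst` files of a previous session; missing files are treated as
#' empty, so a directory holding only partial state still resumes. A
#' frame appearing in two files is a conflict error.
#'
#' @param dir directory containing the list files.
#' @return A [LabelSet-class].
#' @export
loadLabelSet <- function(dir) {
  files <- file.path(dir, c("good.lst", "bad.lst", "skip.lst"))
  present <- file.exists(files)
  if (!any(present))
    stop(sprintf("no good.lst, bad.lst or skip.lst in %s", dir))
  parts <- lapply(which(present), function(i) {
    refs <- readEventList(files[i])
    if (!nrow(refs)) return(NULL)
    refs$label <- c("good", "bad", "skip")[i]
    refs
  })
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return(labelSet())
  labelSet(do.call(rbind, parts))
}
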