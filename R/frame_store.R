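.defaultDataPaths <- c("/data/data", "/entry_1/data_1/data")

#' Open a multi-event HDF5 frame stack
#'
#' Locates the image dataset inside an HDF5 file and returns a lightweight
#' [FrameStack-class] handle. The dataset must be rank 3 (rows x cols x
#' events, events slowest-varying in the file) or rank 2 (a single
#' event). When `dataPath` is `NULL` a small list of common facility
#' layouts is tried (`/data/data`, `/entry_1/data_1/data`).
#'
#' @param path HDF5 file.
#' @param dataPath dataset path, or `NULL` to search the candidate list.
#' @return A [FrameStack-class].
#' @seealso [readFrame()]
#' @export
openStack <- function(path, dataPath = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  contents <- rhdf5::h5ls(path)
  dsets <- paste0(sub("^/$", "", contents$group), "/", contents$name)[
    contents$otype == "H5I_DATASET"]
  if (is.null(dataPath)) {
    hit <- .defaultDataPaths[.defaultDataPaths %in% dsets]
    if (!length(hit))
      stop(sprintf("no dataset found at any default path (%s); file contains: %s",
                   paste(.defaultDataPaths, collapse = ", "),
                   paste(dsets, collapse = ", ")))
    dataPath <- hit[1L]
  } else if (!dataPath %in% dsets) {
    stop(sprintf("no dataset at '%s'; file contains: %s", dataPath,
                 paste(dsets, collapse = ", ")))
  }
  dims <- .h5dims(path, dataPath)
  if (length(dims) == 2L) {
    new("FrameStack", path = path, dataPath = dataPath, nEvents = 1L,
        frameShape = as.integer(dims), rank = 2L)
  } else if (length(dims) == 3L) {
    new("FrameStack", path = path, dataPath = dataPath,
        nEvents = as.integer(dims[3L]), frameShape = as.integer(dims[1:2]),
        rank = 3L)
  } else {
    stop(sprintf("dataset '%s' has rank %d; expected 2 or 3", dataPath,
                 length(dims)))
  }
}

.h5dims <- function(path, dataPath) {
  fid <- rhdf5::H5Fopen(path, flags = "H5F_ACC_RDONLY")
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  did <- rhdf5::H5Dopen(fid, dataPath)
  on.exit(rhdf5::H5Dclose(did), add = TRUE, after = FALSE)
  sid <- rhdf5::H5Dget_space(did)
  on.exit(rhdf5::H5Sclose(sid), add = TRUE, after = FALSE)
  rhdf5::H5Sget_simple_extent_dims(sid)$size
}

#' Read one event's frame from a stack
#'
#' Returns the raw (rows x cols) frame of one event. Non-finite pixels
#' (NaN/Inf, typically masked or saturated) are replaced by 0 so that
#' downstream features are finite; the replacement count is reported with
#' a message.
#'
#' @param stack a [FrameStack-class].
#' @param event 0-based event index.
#' @param quiet suppress the non-finite replacement message.
#' @return numeric matrix (rows x cols).
#' @export
readFrame <- function(stack, event, quiet = FALSE) {
  stopifnot(is(stack, "FrameStack"))
  if (event < 0L || event >= stack@nEvents)
    stop(sprintf("event %d out of range [0, %d) for %s", event,
                 stack@nEvents, stack@path))
  raw <- if (stack@rank == 2L) {
    rhdf5::h5read(stack@path, stack@dataPath)
  } else {
    rhdf5::h5read(stack@path, stack@dataPath,
                  index = list(NULL, NULL, event + 1L))
  }
  frame <- matrix(as.numeric(raw), nrow = stack@frameShape[1L],
                  ncol = stack@frameShape[2L])
  bad <- !is.finite(frame)
  if (any(bad)) {
    frame[bad] <- 0
    if (!quiet)
      message(sprintf("readFrame: replaced %d non-finite pixel(s) with 0 (%s //%d)",
                      sum(bad), stack@path, event))
  }
  frame
}

#' Write good/bad event lists
#'
#' Writes the two sorted-output text files, one event per line in the
#' `<path> //<event>` dialect understood by downstream serial
#' crystallography tools. Lines are ordered deterministically by path,
#' then event. The two lists must be disjoint.
#'
#' @param good,bad data.frames with columns `path` and `event` (0-based;
#'   `NA` event means the whole file).
#' @param outDir output directory (created if needed).
#' @param fileNames names of the two files.
#' @return character(2); paths of the written files.
#' @seealso [readEventList()]
#' @export
writeEventLists <- function(good, bad, outDir,
                            fileNames = c("good.lst", "bad.lst")) {
  keyG <- paste(good$path, good$event, sep = "\r")
  keyB <- paste(bad$path, bad$event, sep = "\r")
  clash <- intersect(keyG, keyB)
  if (length(clash)) {
    i <- match(clash[1L], keyG)
    stop(sprintf("event present in both lists: %s //%s",
                 good$path[i], good$event[i]))
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(outDir, fileNames)
  .writeEventList(good, paths[1L])
  .writeEventList(bad, paths[2L])
  paths
}

.writeEventList <- function(refs, path) {
  refs <- refs[order(refs$path, refs$event), , drop = FALSE]
  lines <- if (nrow(refs)) {
    ifelse(is.na(refs$event), refs$path,
           sprintf("%s //%d", refs$path, refs$event))
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Read an event-list text file
#'
#' Parses `<path> //<event>` lines; a line without `//` is a whole-file
#' reference (expanded to all of its events at use time) and is returned
#' with `event = NA`. Blank lines are ignored.
#'
#' @param path list file.
#' @return data.frame with columns `path` and `event` (integer, 0-based).
#' @export
readEventList <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  out <- lapply(keep, function(i) {
    ln <- trimws(lines[i])
    if (grepl("//", ln, fixed = TRUE)) {
      m <- regmatches(ln, regexec("^(.*\\S)\\s+//([0-9]+)$", ln))[[1L]]
      if (length(m) != 3L)
        stop(sprintf("%s: malformed event-list line %d: '%s'", path, i, ln))
      data.frame(path = m[2L], event = as.integer(m[3L]),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(path = ln, event = NA_integer_, stringsAsFactors = FALSE)
    }
  })
  if (!length(out))
    return(data.frame(path = character(0), event = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# expand whole-file refs (event NA) to every event of the file
.expandRefs <- function(refs, dataPath = NULL) {
  if (!anyNA(refs$event)) return(refs)
  out <- lapply(seq_len(nrow(refs)), function(i) {
    if (!is.na(refs$event[i])) return(refs[i, , drop = FALSE])
    st <- openStack(refs$path[i], dataPath)
    data.frame(path = refs$path[i], event = seq_len(st@nEvents) - 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
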