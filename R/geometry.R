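#' Parse a CrystFEL-format detector geometry description
#'
#' Reads the plain-text `panel/key = value` geometry dialect used by
#' CrystFEL and returns the panel layout needed to locate panel slabs in
#' the raw data array and place them in the laboratory frame. Only the
#' keys required for that purpose are interpreted: `min_fs`, `max_fs`,
#' `min_ss`, `max_ss` (0-based inclusive pixel indices into the raw
#' array), `fs` and `ss` (lab-frame direction vectors, e.g. `+1.0x
#' -0.002y`), and `corner_x`/`corner_y` (lab-frame position of the
#' panel's first pixel, pixel units relative to the beam centre). All
#' other keys (`res`, `clen`, `adu_per_photon`, masks, ...) are ignored
#' with a notice.
#'
#' @param text character; geometry file content (single string or vector
#'   of lines) or a file path to read.
#' @param dataShape optional integer(2) (rows, cols) of the raw per-event
#'   array; when `NULL` it is inferred as `(max(max_ss) + 1, max(max_fs)
#'   + 1)`.
#' @param quiet suppress the ignored-key notice.
#' @return A [DetectorGeometry-class].
#' @examples
#' txt <- c("p0/min_fs = 0", "p0/max_fs = 9", "p0/min_ss = 0",
#'          "p0/max_ss = 9", "p0/fs = +1.0x", "p0/ss = +1.0y",
#'          "p0/corner_x = 0", "p0/corner_y = 0")
#' parseGeometry(txt)
#' @export
parseGeometry <- function(text, dataShape = NULL, quiet = FALSE) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub(";.*$", "", lines)            # comments
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]

  panelKeys <- list()
  ignored <- character(0)
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=/\\s]+)/([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln,
                                perl = TRUE))[[1L]]
    if (length(m) == 4L) {
      panel <- m[2L]; key <- m[3L]; val <- trimws(m[4L])
      if (key %in% c("min_fs", "max_fs", "min_ss", "max_ss",
                     "fs", "ss", "corner_x", "corner_y")) {
        if (is.null(panelKeys[[panel]])) panelKeys[[panel]] <- list()
        panelKeys[[panel]][[key]] <- val
      } else {
        ignored <- c(ignored, paste0(panel, "/", key))
      }
    } else if (grepl("=", ln, fixed = TRUE)) {
      ignored <- c(ignored, trimws(sub("=.*$", "", ln)))   # global key
    }
  }
  if (length(ignored) && !quiet)
    message("parseGeometry: ignoring unrecognized key(s): ",
            paste(unique(ignored), collapse = ", "))
  if (!length(panelKeys))
    stop("no panel blocks found in geometry text")

  need <- c("min_fs", "max_fs", "min_ss", "max_ss", "fs", "ss",
            "corner_x", "corner_y")
  rows <- lapply(names(panelKeys), function(nm) {
    kv <- panelKeys[[nm]]
    missing <- setdiff(need, names(kv))
    if (length(missing))
      stop(sprintf("panel '%s' is missing mandatory key(s): %s",
                   nm, paste(missing, collapse = ", ")))
    fs <- .parseAxisVector(kv$fs, nm, "fs")
    ss <- .parseAxisVector(kv$ss, nm, "ss")
    data.frame(name = nm,
               min_fs = .parseGeomInt(kv$min_fs, nm, "min_fs"),
               max_fs = .parseGeomInt(kv$max_fs, nm, "max_fs"),
               min_ss = .parseGeomInt(kv$min_ss, nm, "min_ss"),
               max_ss = .parseGeomInt(kv$max_ss, nm, "max_ss"),
               fsx = fs[1L], fsy = fs[2L], ssx = ss[1L], ssy = ss[2L],
               cnx = .parseGeomNum(kv$corner_x, nm, "corner_x"),
               cny = .parseGeomNum(kv$corner_y, nm, "corner_y"),
               stringsAsFactors = FALSE)
  })
  panels <- do.call(rbind, rows)
  if (is.null(dataShape))
    dataShape <- c(max(panels$max_ss) + 1L, max(panels$max_fs) + 1L)
  new("DetectorGeometry", panels = panels,
      dataShape = as.integer(dataShape))
}

.parseGeomInt <- function(v, panel, key) {
  x <- suppressWarnings(as.integer(v))
  if (is.na(x)) stop(sprintf("panel '%s': key %s has non-integer value '%s'",
                             panel, key, v))
  x
}

.parseGeomNum <- function(v, panel, key) {
  x <- suppressWarnings(as.numeric(v))
  if (is.na(x)) stop(sprintf("panel '%s': key %s has non-numeric value '%s'",
                             panel, key, v))
  x
}

# "+1.0x -0.002y" / "x" / "-y" -> c(x, y)
.parseAxisVector <- function(v, panel, key) {
  toks <- regmatches(v, gregexpr("[+-]?[0-9]*\\.?[0-9]*(?:[eE][+-]?[0-9]+)?[xy]",
                                 v))[[1L]]
  if (!length(toks))
    stop(sprintf("panel '%s': cannot parse %s vector '%s'", panel, key, v))
  out <- c(x = 0, y = 0)
  for (tk in toks) {
    axis <- substring(tk, nchar(tk))
    num <- substring(tk, 1L, nchar(tk) - 1L)
    val <- if (num %in% c("", "+")) 1 else if (num == "-") -1 else
      suppressWarnings(as.numeric(num))
    if (is.na(val))
      stop(sprintf("panel '%s': cannot parse %s component '%s'", panel, key, tk))
    out[[axis]] <- out[[axis]] + val
  }
  unname(out)
}

#' Serialize a DetectorGeometry back to CrystFEL-format text
#'
#' Writes the supported key subset; `parseGeometry(serializeGeometry(g))`
#' reproduces `g`.
#'
#' @param geom a [DetectorGeometry-class].
#' @return character vector of geometry lines.
#' @export
serializeGeometry <- function(geom) {
  stopifnot(is(geom, "DetectorGeometry"))
  fmtAxis <- function(x, y) {
    trimws(paste0(ifelse(x != 0 | y == 0, sprintf("%+gx", x), ""),
                  ifelse(y != 0, sprintf(" %+gy", y), "")))
  }
  unlist(lapply(seq_len(nrow(geom@panels)), function(i) {
    p <- geom@panels[i, ]
    c(sprintf("%s/min_fs = %d", p$name, p$min_fs),
      sprintf("%s/max_fs = %d", p$name, p$max_fs),
      sprintf("%s/min_ss = %d", p$name, p$min_ss),
      sprintf("%s/max_ss = %d", p$name, p$max_ss),
      sprintf("%s/fs = %s", p$name, fmtAxis(p$fsx, p$fsy)),
      sprintf("%s/ss = %s", p$name, fmtAxis(p$ssx, p$ssy)),
      sprintf("%s/corner_x = %g", p$name, p$cnx),
      sprintf("%s/corner_y = %g", p$name, p$cny),
      "")
  }))
}

#' Assemble a raw frame into the laboratory coordinate frame
#'
#' Places every panel pixel at `round(corner + i_fs * fs + i_ss * ss)`
#' relative to the beam centre and returns the canvas covering the
#' bounding box of all placed pixels. Canvas cells not covered by any
#' panel are `NA` (and must be excluded from statistics); two panels
#' mapping to the same cell is a validation error.
#'
#' @param frame raw 2D array of shape `dataShape(geom)`.
#' @param geom a [DetectorGeometry-class].
#' @return numeric matrix; assembled image with `NA` gaps. Attribute
#'   `origin` gives the lab-frame coordinate of cell (1, 1).
#' @export
assembleImage <- function(frame, geom) {
  stopifnot(is(geom, "DetectorGeometry"))
  if (!all(dim(frame) == geom@dataShape))
    stop(sprintf("frame shape (%d, %d) does not match geometry dataShape (%d, %d)",
                 nrow(frame), ncol(frame), geom@dataShape[1L], geom@dataShape[2L]))
  place <- .panelPlacements(geom)
  xr <- range(place$x); yr <- range(place$y)
  canvas <- matrix(NA_real_, nrow = yr[2L] - yr[1L] + 1L,
                   ncol = xr[2L] - xr[1L] + 1L)
  idx <- cbind(place$y - yr[1L] + 1L, place$x - xr[1L] + 1L)
  lin <- (idx[, 2L] - 1L) * nrow(canvas) + idx[, 1L]
  if (anyDuplicated(lin)) {
    d <- which(duplicated(lin))[1L]
    stop(sprintf("panel placement collision at lab cell (x=%d, y=%d)",
                 place$x[d], place$y[d]))
  }
  canvas[idx] <- frame[cbind(place$ss + 1L, place$fs + 1L)]
  attr(canvas, "origin") <- c(x = xr[1L], y = yr[1L])
  canvas
}

# rounded integer lab positions for every panel pixel, with the data-space
# (ss, fs) it came from
.panelPlacements <- function(geom) {
  out <- lapply(seq_len(nrow(geom@panels)), function(i) {
    p <- geom@panels[i, ]
    ifs <- seq.int(0L, p$max_fs - p$min_fs)
    iss <- seq.int(0L, p$max_ss - p$min_ss)
    grid <- expand.grid(ifs = ifs, iss = iss)
    x <- .roundHalfUp(p$cnx + grid$ifs * p$fsx + grid$iss * p$ssx)
    y <- .roundHalfUp(p$cny + grid$ifs * p$fsy + grid$iss * p$ssy)
    data.frame(panel = p$name, ss = p$min_ss + grid$iss,
               fs = p$min_fs + grid$ifs, x = x, y = y)
  })
  do.call(rbind, out)
}

.roundHalfUp <- function(x) as.integer(floor(x + 0.5))

#' Data-space rectangle of one detector panel
#'
#' Converts a panel's inclusive CrystFEL bounds into the half-open 0-based
#' `[ss0, ss1) x [fs0, fs1)` rectangle used internally; this rectangle is
#' the default ROI when a panel is selected.
#'
#' @param geom a [DetectorGeometry-class].
#' @param panelName panel to look up.
#' @return list with integer(2) elements `ss` and `fs` (half-open ranges).
#' @export
panelSlice <- function(geom, panelName) {
  stopifnot(is(geom, "DetectorGeometry"))
  i <- match(panelName, geom@panels$name)
  if (is.na(i))
    stop(sprintf("unknown panel '%s'; valid panels: %s", panelName,
                 paste(geom@panels$name, collapse = ", ")))
  p <- geom@panels[i, ]
  list(ss = c(p$min_ss, p$max_ss + 1L), fs = c(p$min_fs, p$max_fs + 1L))
}
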