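onePanelText <- c(
  "p0/min_fs = 0", "p0/max_fs = 9", "p0/min_ss = 0", "p0/max_ss = 9",
  "p0/fs = +1.0x", "p0/ss = +1.0y", "p0/corner_x = 0", "p0/corner_y = 0")

test_that("a single panel block parses to the expected geometry", {
  g <- parseGeometry(onePanelText)
  expect_s4_class(g, "DetectorGeometry")
  expect_identical(nrow(g@panels), 1L)
  expect_identical(dataShape(g), c(10L, 10L))
  p <- g@panels
  expect_identical(p$name, "p0")
  expect_equal(c(p$fsx, p$fsy, p$ssx, p$ssy), c(1, 0, 0, 1))
  expect_equal(c(p$cnx, p$cny), c(0, 0))
})

test_that("generated two-panel geometry text parses back to the generator's record", {
  gm <- makeGeometry(smallConfig())
  g <- parseGeometry(gm$text)
  expect_equal(g@panels, gm$dump)
  expect_identical(dataShape(g), dataShape(gm$geometry))
})

test_that("missing mandatory keys and unknown panels are clear errors", {
  broken <- onePanelText[-8L]   # drop corner_y
  expect_error(parseGeometry(broken), "p0.*corner_y")
  expect_error(parseGeometry("no keys here at all"), "no panel blocks")
  g <- parseGeometry(onePanelText)
  expect_error(panelSlice(g, "nope"), "unknown panel 'nope'.*p0")
})

test_that("unrecognized keys are ignored with a notice, not fatal", {
  txt <- c(onePanelText, "p0/res = 10000", "clen = 0.12",
           "p0/adu_per_photon = 1.0")
  expect_message(g <- parseGeometry(txt), "ignoring unrecognized")
  expect_equal(g@panels, parseGeometry(onePanelText)@panels)
})

test_that("parse-serialize-parse is idempotent on the supported keys", {
  gm <- makeGeometry(smallConfig())
  g1 <- parseGeometry(gm$text)
  g2 <- parseGeometry(serializeGeometry(g1))
  expect_equal(g1@panels, g2@panels)
  expect_identical(dataShape(g1), dataShape(g2))
})

test_that("identity geometry assembles to the input frame", {
  g <- parseGeometry(onePanelText)
  frame <- matrix(runif(100), 10, 10)
  img <- assembleImage(frame, g)
  expect_equal(unname(img[1:10, 1:10]), frame)
})

test_that("side-by-side panels assemble with the hand-computed bounding box", {
  txt <- c(
    "a/min_fs = 0", "a/max_fs = 9", "a/min_ss = 0", "a/max_ss = 9",
    "a/fs = +1x", "a/ss = +1y", "a/corner_x = 0", "a/corner_y = 0",
    "b/min_fs = 10", "b/max_fs = 19", "b/min_ss = 0", "b/max_ss = 9",
    "b/fs = +1x", "b/ss = +1y", "b/corner_x = 12", "b/corner_y = 0")
  g <- parseGeometry(txt)
  frame <- matrix(1, 10, 20)
  img <- assembleImage(frame, g)
  expect_identical(ncol(img), 22L)   # 10 + 2 gap + 10
  expect_identical(nrow(img), 10L)
  expect_identical(sum(is.na(img)), 2L * 10L)
})

test_that("assembly conserves total intensity, also for rotated panels", {
  set.seed(3)
  for (cfg in list(smallConfig(), smallConfig(nFrames = 5L, seed = 9L))) {
    g <- makeGeometry(cfg)$geometry
    frame <- matrix(rnorm(prod(dataShape(g))), dataShape(g)[1L])
    img <- assembleImage(frame, g)
    expect_equal(sum(img, na.rm = TRUE), sum(frame))
  }
  # a 90-degree rotated panel next to an unrotated one
  txt <- c(
    "a/min_fs = 0", "a/max_fs = 7", "a/min_ss = 0", "a/max_ss = 3",
    "a/fs = +1x", "a/ss = +1y", "a/corner_x = 0", "a/corner_y = 0",
    "b/min_fs = 0", "b/max_fs = 7", "b/min_ss = 4", "b/max_ss = 7",
    "b/fs = +1y", "b/ss = -1x", "b/corner_x = 20", "b/corner_y = 0")
  g <- parseGeometry(txt)
  frame <- matrix(rnorm(8 * 8), 8, 8)
  img <- assembleImage(frame, g)
  expect_equal(sum(img, na.rm = TRUE), sum(frame))
  expect_identical(sum(!is.na(img)), 64L)
})

test_that("every raw pixel is recoverable from its assembled location", {
  for (seed in c(1L, 2L)) {
    g <- makeGeometry(smallConfig(seed = seed))$geometry
    shp <- dataShape(g)
    frame <- matrix(as.numeric(seq_len(prod(shp))), shp[1L], shp[2L])
    img <- assembleImage(frame, g)
    origin <- attr(img, "origin")
    for (i in seq_len(nrow(g@panels))) {
      p <- g@panels[i, ]
      for (ifs in c(0L, p$max_fs - p$min_fs)) for (iss in c(0L, p$max_ss - p$min_ss)) {
        x <- as.integer(floor(p$cnx + ifs * p$fsx + iss * p$ssx + 0.5))
        y <- as.integer(floor(p$cny + ifs * p$fsy + iss * p$ssy + 0.5))
        expect_identical(img[y - origin[["y"]] + 1L, x - origin[["x"]] + 1L],
                         frame[p$min_ss + iss + 1L, p$min_fs + ifs + 1L])
      }
    }
    expect_setequal(as.vector(img)[!is.na(img)], as.vector(frame))
  }
})

test_that("overlapping lab placements are a collision error", {
  txt <- c(
    "a/min_fs = 0", "a/max_fs = 9", "a/min_ss = 0", "a/max_ss = 9",
    "a/fs = +1x", "a/ss = +1y", "a/corner_x = 0", "a/corner_y = 0",
    "b/min_fs = 10", "b/max_fs = 19", "b/min_ss = 0", "b/max_ss = 9",
    "b/fs = +1x", "b/ss = +1y", "b/corner_x = 5", "b/corner_y = 0")
  g <- parseGeometry(txt)
  expect_error(assembleImage(matrix(0, 10, 20), g), "collision")
})

test_that("frame/geometry shape mismatch is an error", {
  g <- parseGeometry(onePanelText)
  expect_error(assembleImage(matrix(0, 5, 5), g), "does not match")
})

test_that("panelSlice converts inclusive bounds to half-open rectangles", {
  g <- parseGeometry(onePanelText)
  expect_identical(panelSlice(g, "p0"), list(ss = c(0L, 10L), fs = c(0L, 10L)))
  gm <- makeGeometry(smallConfig())
  sl <- panelSlice(gm$geometry, "p1")
  d <- gm$dump[gm$dump$name == "p1", ]
  expect_identical(sl$ss, c(d$min_ss, d$max_ss + 1L))
  expect_identical(sl$fs, c(d$min_fs, d$max_fs + 1L))
})

test_that("overlapping panel data rectangles fail geometry validation", {
  txt <- c(
    "a/min_fs = 0", "a/max_fs = 9", "a/min_ss = 0", "a/max_ss = 9",
    "a/fs = +1x", "a/ss = +1y", "a/corner_x = 0", "a/corner_y = 0",
    "b/min_fs = 5", "b/max_fs = 14", "b/min_ss = 5", "b/max_ss = 14",
    "b/fs = +1x", "b/ss = +1y", "b/corner_x = 30", "b/corner_y = 0")
  expect_error(parseGeometry(txt), "overlap")
})
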