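test_that("vertical projection is the per-row ROI mean", {
  frame <- matrix(7, 12, 9)
  roi <- frameRoi(ss = c(2L, 10L), fs = c(1L, 8L))
  expect_equal(verticalProjection(frame, roi)@values, rep(7, 8))

  # row-indicator field: row r (0-based within ROI) holds value r
  frame2 <- matrix(rep(0:11, 9), 12, 9)
  prof <- verticalProjection(frame2, frameRoi(ss = c(3L, 9L), fs = c(0L, 9L)))
  expect_equal(prof@values, 3:8)

  set.seed(42)
  frame3 <- matrix(rnorm(10 * 8), 10, 8)
  roi3 <- frameRoi(ss = c(0L, 10L), fs = c(0L, 8L))
  brute <- vapply(1:10, function(r) {
    s <- 0
    for (cc in 1:8) s <- s + frame3[r, cc]
    s / 8
  }, numeric(1))
  expect_equal(verticalProjection(frame3, roi3)@values, brute)
})

test_that("panel ROI and its explicit rectangle project identically", {
  gm <- makeGeometry(smallConfig())
  g <- gm$geometry
  frame <- matrix(rnorm(prod(dataShape(g))), dataShape(g)[1L])
  byPanel <- verticalProjection(frame, frameRoi(panel = "p1"), g)
  sl <- panelSlice(g, "p1")
  byRect <- verticalProjection(frame, frameRoi(ss = sl$ss, fs = sl$fs), g)
  expect_equal(byPanel@values, byRect@values)
})

test_that("empty or out-of-bounds ROIs are errors", {
  g <- makeGeometry(smallConfig())$geometry
  frame <- matrix(0, dataShape(g)[1L], dataShape(g)[2L])
  expect_error(frameRoi(ss = c(3L, 3L), fs = c(0L, 5L)), "empty")
  expect_error(verticalProjection(frame, frameRoi(ss = c(0L, 99L), fs = c(0L, 5L)), g),
               "outside")
})

test_that("an odd-symmetric cubic has its single inflection at the centre", {
  v <- (0:100 - 50)^3
  fit <- fitProfilePolynomial(v, order = 3L)
  expect_identical(length(inflections(fit)), 1L)
  expect_equal(inflections(fit), 50, tolerance = 1e-6)
})

test_that("noiseless quartics are recovered along with their analytic inflections", {
  x <- 0:100
  for (r in list(c(30, 70), c(20, 55), c(45, 80))) {
    co <- quarticWithInflections(r[1L], r[2L])
    v <- evalPolyCoefs(co, x)
    fit <- fitProfilePolynomial(v, order = 4L)
    scale <- diff(range(v))
    expect_lt(max(abs(polyValues(fit, x) - v)), 1e-8 * scale)
    expect_equal(inflections(fit), r, tolerance = 1e-6)
    expect_equal(coef(fit), co, tolerance = 1e-6 * max(abs(co)))
  }
})

test_that("polynomials of degree below the fit order are recovered exactly", {
  x <- 0:60
  set.seed(1)
  for (deg in 0:4) {
    co <- c(rnorm(deg + 1L), numeric(4L - deg))
    v <- evalPolyCoefs(co, x)
    fit <- fitProfilePolynomial(v, order = 4L)
    scale <- max(diff(range(v)), 1)
    expect_lt(max(abs(polyValues(fit, x) - v)), 1e-8 * scale)
  }
})

test_that("a strictly linear profile has no in-domain inflections at order 4", {
  fit <- fitProfilePolynomial(0.5 * (0:80) + 3, order = 4L)
  expect_identical(inflections(fit), numeric(0))
})

test_that("profiles shorter than order + 1 are rejected", {
  expect_error(fitProfilePolynomial(c(1, 2, 3), order = 3L), "too short")
  expect_error(fitProfilePolynomial(c(1, 2, 3, 4), order = 4L), "too short")
})

test_that("inflections survive 1%-of-range noise to within one row", {
  set.seed(7)
  for (trial in 1:10) {
    case <- noisyQuarticCase()
    noisy <- case$values +
      stats::rnorm(length(case$values), 0, 0.01 * diff(range(case$values)))
    got <- inflections(fitProfilePolynomial(noisy, order = 4L))
    expect_identical(length(got), 2L)
    expect_lt(max(abs(got - case$r)), 1)
  }
})

test_that("well-separated signature clusters auto-label by dominance", {
  x <- 0:100
  t <- c(20 + seq(0, 1.4, 0.2), 70, 70.5)
  profiles <- lapply(seq_along(t), function(i)
    makeProfile((x - t[i])^3, event = i))
  res <- autoLabelByInflection(profiles, order = 3L, binWidth = 5)
  refs <- labelRefs(res$labels)
  expect_identical(refs$label[order(refs$event)],
                   c(rep("good", 8L), rep("bad", 2L)))
  expect_equal(res$diagnostics$dominantFraction, 0.8)
  expect_false(res$diagnostics$warning)
})

test_that("a sub-majority dominant bin raises the warning flag", {
  x <- 0:100
  mk <- function(t, ev) makeProfile((x - t)^3, event = ev)
  profiles <- c(lapply(1:4, function(i) mk(20 + 0.1 * i, i)),
                lapply(5:7, function(i) mk(50 + 0.1 * i, i)),
                lapply(8:10, function(i) mk(80 + 0.1 * i, i)))
  res <- autoLabelByInflection(profiles, order = 3L, binWidth = 5)
  expect_equal(res$diagnostics$dominantFraction, 0.4)
  expect_true(res$diagnostics$warning)
  expect_identical(sum(labelRefs(res$labels)$label == "good"), 4L)
})

test_that("auto-labelling is invariant to input ordering", {
  x <- 0:100
  profiles <- lapply(1:10, function(i)
    makeProfile((x - c(rep(25, 7), rep(75, 3))[i] - 0.05 * i)^3, event = i))
  res1 <- autoLabelByInflection(profiles, order = 3L, binWidth = 5)
  set.seed(9)
  res2 <- autoLabelByInflection(sample(profiles), order = 3L, binWidth = 5)
  expect_identical(labelRefs(res1$labels), labelRefs(res2$labels))
})

test_that("inflection-free inputs are skipped, or fatal when universal", {
  lin <- lapply(1:3, function(i) makeProfile(1:50 * i, event = i))
  expect_error(autoLabelByInflection(lin, order = 4L), "no profile has")
  x <- 0:100
  mixed <- c(lin, lapply(4:9, function(i) makeProfile((x - 40 - 0.1 * i)^3, event = i)))
  res <- autoLabelByInflection(mixed, order = 3L, binWidth = 5)
  expect_identical(res$diagnostics$nSkipped, 3L)
  expect_identical(sum(labelRefs(res$labels)$label == "skip"), 3L)
})

test_that("generator-truth frames auto-label exactly when the artefact shift spans many bins", {
  d <- withr::local_tempdir()
  res <- generateStack(autoLabelConfig(), d)
  st <- openStack(res$files[1L])
  profiles <- profileStack(st, frameRoi(panel = "p1"), res$geometry)
  binWidth <- 0.5
  auto <- autoLabelByInflection(profiles, order = 4L, binWidth = binWidth)
  truth <- labelRefs(res$truth)
  sig <- auto$diagnostics$signatures
  shift <- abs(mean(sig[truth$label == "bad"]) - mean(sig[truth$label == "good"]))
  expect_gte(shift, 10 * binWidth)   # the scenario's separation precondition
  got <- labelRefs(auto$labels)
  expect_identical(got$label[order(got$event)], truth$label[order(truth$event)])
})
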