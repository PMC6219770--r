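hline <- function(lc, bmo = rbind(c(0, 0), c(1000, 0)))
  bscan_annotation(0, bmo, lc)

test_that("the BMO reference line angle is the signed slope angle", {
  expect_equal(bmo_reference_line(hline(rbind(c(1, 1))))$alpha_deg, 0)
  a <- bscan_annotation(0, rbind(c(0, 0), c(800, 600)), rbind(c(1, 1)))
  expect_equal(bmo_reference_line(a)$alpha_deg, 36.8699, tolerance = 1e-6)
  v <- bscan_annotation(0, rbind(c(0, 0), c(0, 500)), rbind(c(1, 1)))
  expect_equal(bmo_reference_line(v)$alpha_deg, 90)
  # undirected: swapping the BMO points leaves alpha in (-90, 90]
  b <- bscan_annotation(0, rbind(c(800, 600), c(0, 0)), rbind(c(1, 1)))
  expect_equal(bmo_reference_line(b)$alpha_deg, 36.8699, tolerance = 1e-6)
})

test_that("scan LCD is the maximum signed perpendicular distance", {
  a <- hline(rbind(c(200, 300), c(500, 400), c(800, 350)))
  expect_equal(as.numeric(scan_lcd(a)), 400)
  expect_identical(attr(scan_lcd(a), "which_point"), 2L)
  # all LC points on the BMO line
  expect_equal(as.numeric(scan_lcd(hline(rbind(c(100, 0), c(900, 0))))), 0)
  # LC entirely anterior to the line: negative depth, not an error
  expect_lt(as.numeric(scan_lcd(hline(rbind(c(300, -120))))), 0)
  # flipping the axial convention flips the sign
  flipped <- bscan_annotation(0, rbind(c(0, 0), c(1000, 0)),
                              rbind(c(300, -120)),
                              axial_positive_is_posterior = FALSE)
  expect_equal(as.numeric(scan_lcd(flipped)), 120)
})

test_that("scan LCD agrees with the implicit point-line distance oracle", {
  set.seed(101)
  for (i in 1:300) {
    ann <- random_annotation()
    expect_lt(abs(as.numeric(scan_lcd(ann)) - oracle_scan_lcd(ann)), 1e-9)
  }
})

test_that("scan LCD is rigid-motion invariant, scale-linear and monotone", {
  # tilts bounded so the posterior half-plane keeps its meaning: the sign
  # convention references the image axial axis
  set.seed(202)
  for (i in 1:100) {
    ann <- random_plausible_annotation()
    lcd0 <- as.numeric(scan_lcd(ann))
    theta <- runif(1, -pi / 6, pi / 6); shift <- runif(2, -5000, 5000)
    moved <- bscan_annotation(ann$scan_index,
                              rotate_translate(ann$bmo, theta, shift),
                              rotate_translate(ann$lc, theta, shift),
                              ann$axial_positive_is_posterior)
    expect_lt(abs(as.numeric(scan_lcd(moved)) - lcd0), 1e-9)
    s <- runif(1, 0.1, 10)
    scaled <- bscan_annotation(ann$scan_index, ann$bmo * s, ann$lc * s,
                               ann$axial_positive_is_posterior)
    expect_equal(as.numeric(scan_lcd(scaled)), s * lcd0, tolerance = 1e-9)
  }
  # moving one LC point deeper (perpendicular, posterior) never lowers LCD
  set.seed(303)
  for (i in 1:50) {
    ann <- random_annotation()
    lcd0 <- as.numeric(scan_lcd(ann))
    d <- ann$bmo[2, ] - ann$bmo[1, ]
    n <- c(-d[2], d[1]) / sqrt(sum(d^2))
    post <- if (ann$axial_positive_is_posterior) 1 else -1
    if (n[2] * post < 0) n <- -n
    j <- sample(nrow(ann$lc), 1)
    ann$lc[j, ] <- ann$lc[j, ] + runif(1, 0, 500) * n
    expect_gte(as.numeric(scan_lcd(ann)) - lcd0, -1e-9)
  }
})

test_that("mean LCD averages the selected scans and stays within bounds", {
  mk <- function(i, depth) bscan_annotation(i, rbind(c(0, 0), c(1000, 0)),
                                            rbind(c(500, depth)))
  eye14 <- eye_annotations(lapply(1:14, function(i) mk(i - 1, 400)))
  res <- mean_lcd(eye14)
  expect_equal(res$mean_lcd, 400)
  expect_identical(res$n_scans_used, 14L)

  eye3 <- eye_annotations(lapply(1:3, function(i)
    mk(i - 1, c(300, 400, 500)[i])))
  expect_warning(res3 <- mean_lcd(eye3), "12-16")
  expect_equal(res3$mean_lcd, 400)
  expect_gte(res3$mean_lcd, min(res3$per_scan$lcd_um))
  expect_lte(res3$mean_lcd, max(res3$per_scan$lcd_um))

  # explicit index selection and the empty-selection error
  expect_warning(sub <- mean_lcd(eye14, scan_indices = c(2, 5, 9)), "12-16")
  expect_identical(sub$n_scans_used, 3L)
  expect_error(mean_lcd(eye14, scan_indices = 99), "empty")
})

test_that("central-scan selection is symmetric, equidistant and banded", {
  expect_identical(select_central_scans(75, 1, 0.75), 37L)
  expect_identical(select_central_scans(9, 3, 1.0), c(0L, 4L, 8L))
  sel <- select_central_scans(75, 13, 0.75)
  expect_length(sel, 13L)
  expect_true(all(sel >= 10 & sel <= 64))
  expect_lte(diff(range(diff(sel))), 1)          # near-equidistant
  expect_equal(sel + rev(sel), rep(74L, 13L))    # symmetric about centre
  expect_error(select_central_scans(10, 9, 0.5), "exceeds")
})
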