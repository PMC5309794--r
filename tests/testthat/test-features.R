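test_that("elongation of canonical shapes", {
  expect_equal(elongation(disk_mask(20))$elongation, 1, tolerance = 0.05)
  expect_equal(elongation(rasterize_ellipse(20, 10))$elongation, 0.5,
               tolerance = 0.05)
  expect_equal(elongation(rasterize_ellipse(20, 10, pi / 3))$elongation,
               0.5, tolerance = 0.05)
  expect_error(elongation(matrix(FALSE, 5, 5)), "empty")
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_equal(elongation(one)$elongation, 1)
})

test_that("fast chord path equals the exhaustive boundary-pair oracle", {
  shapes <- c(list(disk_mask(12), rasterize_ellipse(15, 6, 0.4),
                   rasterize_ellipse(18, 14, 2.1)),
              lapply(1:12, random_blob, size = 36L))
  for (m in shapes) {
    fast <- elongation(m)
    slow <- oracle_chords(m)
    expect_lte(abs(fast$major - slow$major), 1)
    expect_lte(abs(fast$minor - slow$minor), 1)
  }
})

test_that("elongation is invariant to rotation and scale (up to discretization)", {
  for (s in 1:5) {
    b <- random_blob(s + 100, size = 30L)
    e0 <- elongation(b)$elongation
    e90 <- elongation(t(b)[ncol(b):1, , drop = FALSE])$elongation
    expect_lte(abs(e0 - e90), 0.02)
  }
  # doubling an ellipse's dimensions
  e1 <- elongation(rasterize_ellipse(14, 7, 0.7))$elongation
  e2 <- elongation(rasterize_ellipse(28, 14, 0.7))$elongation
  expect_lte(abs(e1 - e2), 0.02)
})

test_that("moment-based elongation agrees with chords on ellipses", {
  for (ab in list(c(20, 10), c(15, 15), c(18, 6))) {
    m <- rasterize_ellipse(ab[1], ab[2], 0.9)
    expect_equal(elongation(m, method = "moment")$elongation,
                 elongation(m, method = "chord")$elongation,
                 tolerance = 0.06)
  }
})

test_that("measure_cells averages reporters over the nucleus mask only", {
  nuc <- matrix(0L, 60, 60); bod <- matrix(0L, 60, 60)
  bod[phenoscreen:::ellipse_pixels(60, 60, 30, 30, 15, 10, 0)] <- 1L
  nuc[phenoscreen:::ellipse_pixels(60, 60, 30, 30, 5, 5, 0)] <- 1L
  green <- matrix(100, 60, 60)
  green[nuc == 1L] <- 600                      # uniform inside the nucleus
  red <- matrix(700, 60, 60)
  red[nuc == 1L] <- 50                         # body bright, nucleus dim
  rec <- measure_cells(label_mask(nuc, "nuclei"),
                       label_mask(bod, "cell_bodies"),
                       list(green = green, red = red))
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$mean_green, 600)
  expect_equal(rec$mean_red, 50)               # not contaminated by the body
  expect_equal(rec$elongation, 10 / 15, tolerance = 0.05)
  expect_equal(rec$area, sum(bod > 0))
  expect_error(
    measure_cells(label_mask(nuc, "nuclei"), label_mask(bod, "cell_bodies"),
                  list(green = matrix(0, 10, 10))), "aligned")
})

test_that("classification applies strict printed thresholds per profile", {
  df <- data.frame(mean_green = c(600, 500, 400, 0),
                   mean_red = c(360, 400, 283, 0))
  fish <- classify_cells(df, profile = "fish")
  expect_equal(fish$green_pos, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(fish$red_pos, c(FALSE, TRUE, FALSE, FALSE))
  human <- classify_cells(df, profile = "human")
  expect_false(any(human$green_pos))           # no green reporter threshold
  expect_equal(human$red_pos, c(TRUE, TRUE, FALSE, FALSE))
  expect_error(classify_cells(df, profile = "mouse"))
  expect_error(classify_cells(df, thresholds = list(green = -1, red = 360)),
               "positive")
})

test_that("cells rendered far from thresholds are classified without error", {
  cfg <- small_cfg()
  r <- render_field(60, cfg = cfg, seed = 31)
  rec <- process_field(r$images, well_id = "B02")
  obj <- data.frame(x = rec$centroid_x, y = rec$centroid_y)
  d <- sqrt(outer(r$truth$cx, obj$x, "-")^2 + outer(r$truth$cy, obj$y, "-")^2)
  mi <- apply(d, 1, which.min)
  clear_g <- abs(r$truth$green_intensity - 500) >= 100
  expect_true(all((r$truth$green_intensity > 500)[clear_g] ==
                    rec$green_pos[mi][clear_g]))
  clear_r <- abs(r$truth$red_intensity - 360) >= 72
  expect_true(all((r$truth$red_intensity > 360)[clear_r] ==
                    rec$red_pos[mi][clear_r]))
})

test_that("well summaries add across fields and respect the border policy", {
  mk <- function(field, n, elong = 0.5, border = FALSE) {
    data.frame(cell_id = seq_len(n), well_id = "C03", field_index = field,
               centroid_x = 1, centroid_y = 1, area = 100,
               major_axis = 10, minor_axis = 5, elongation = elong,
               border_touch = border, mean_green = 600, mean_red = 100)
  }
  rec <- classify_cells(rbind(mk(1, 100), mk(2, 100)))
  sm <- summarize_well(rec)
  expect_equal(sm$n_cells, 200L)
  expect_equal(sm$n_fields, 2L)
  expect_equal(sm$mean_elong, 0.5)
  expect_equal(sm$n_green, 200L)
  # border cells count for proliferation but not for shape means
  rec2 <- classify_cells(rbind(mk(1, 50, elong = 0.5),
                               mk(1, 50, elong = 0.9, border = TRUE)))
  sm2 <- summarize_well(rec2)
  expect_equal(sm2$n_cells, 100L)
  expect_equal(sm2$mean_elong, 0.5)
  sm3 <- summarize_well(rec2, border_policy = "include")
  expect_equal(sm3$mean_elong, 0.7)
  # known class mixture
  mix <- classify_cells(rbind(mk(1, 70), within(mk(1, 30), mean_green <- 100)))
  smx <- summarize_well(mix)
  expect_equal(smx$n_green, 70L)
  expect_equal(smx$n_cells, 100L)
  # empty record set
  sme <- summarize_well(mix[0, ])
  expect_equal(sme$n_cells, 0L)
  expect_true(is.nan(sme$mean_elong))
})
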