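nuclear_pair_image <- function(dist_px, r = 6, seed = 5, size = 300L,
                               amp = 2000, noise = 200) {
  scene <- matrix(0, size, size)
  for (cx in c(size / 2 - dist_px / 2, size / 2 + dist_px / 2)) {
    p <- phenoscreen:::ellipse_pixels(size, size, cx, size / 2, r, r, 0)
    scene[p] <- scene[p] + amp
  }
  set.seed(seed)
  field_image(pmax(pmin(round(100 + scene + rnorm(size^2, 0, noise)),
                        65535), 0), "nuclear_short")
}

test_that("well-separated synthetic nuclei are all recovered", {
  r <- render_field(50, cfg = small_cfg(), seed = 13)
  nuc <- segment_nuclei(r$images$nuclear_short)
  expect_equal(n_objects(nuc), 50L)
  obj <- mask_objects(nuc)
  d <- sqrt(outer(r$truth$cx, obj$centroid_x, "-")^2 +
              outer(r$truth$cy, obj$centroid_y, "-")^2)
  expect_true(all(apply(d, 1, min) <= 3))
})

test_that("signal-free images yield zero nuclei", {
  const <- field_image(matrix(500, 256, 256), "nuclear_short")
  expect_equal(n_objects(segment_nuclei(const)), 0L)
  set.seed(2)
  noise <- field_image(pmax(round(100 + matrix(rnorm(256^2, 0, 200),
                                               256, 256)), 0),
                       "nuclear_short")
  expect_equal(n_objects(segment_nuclei(noise)), 0L)
})

test_that("nucleus merging follows distance and the splitting switch", {
  far <- nuclear_pair_image(40)
  expect_equal(n_objects(segment_nuclei(far)), 2L)
  close <- nuclear_pair_image(5)
  expect_equal(
    n_objects(segment_nuclei(close, seg_params(split_touching = FALSE))),
    1L)
})

test_that("segment_nuclei validates inputs", {
  expect_error(seg_params(tophat_radius = 0), "tophat_radius")
  img <- field_image(matrix(1, 256, 256), "nuclear_long")
  expect_error(segment_nuclei(img), "nuclear_short")
})

test_that("cell bodies contain their seeds, partition the field, and track truth", {
  r <- render_field(40, cfg = small_cfg(), seed = 17)
  nuc <- segment_nuclei(r$images$nuclear_short)
  bod <- segment_cell_bodies(r$images$nuclear_long, nuc)
  expect_equal(n_objects(bod), n_objects(nuc))
  # seed containment: every nucleus pixel carries its body's label
  nz <- unclass(nuc) > 0
  expect_true(all(unclass(bod)[nz] == unclass(nuc)[nz]))
  # bodies recover the rendered ellipse areas
  obj <- mask_objects(bod)
  d <- sqrt(outer(r$truth$cx, obj$centroid_x, "-")^2 +
              outer(r$truth$cy, obj$centroid_y, "-")^2)
  match_idx <- apply(d, 1, which.min)
  truth_area <- pi * r$truth$a * r$truth$b
  expect_true(all(abs(obj$area[match_idx] - truth_area) / truth_area < 0.1))
})

test_that("empty nuclei mask gives an empty body mask", {
  img <- field_image(matrix(300, 256, 256), "nuclear_long")
  empty <- label_mask(matrix(0L, 256, 256), "nuclei")
  expect_equal(n_objects(segment_cell_bodies(img, empty)), 0L)
})

test_that("touching cells with one seed each become two disjoint bodies", {
  size <- 256L
  scene <- matrix(0, size, size)
  centers <- cbind(x = c(108, 148), y = c(128, 128))  # 20 px apart, r = 14
  for (i in 1:2) {
    p <- phenoscreen:::ellipse_pixels(size, size, centers[i, 1],
                                      centers[i, 2], 14, 14, 0)
    scene[p] <- scene[p] + 400
    np <- phenoscreen:::ellipse_pixels(size, size, centers[i, 1],
                                       centers[i, 2], 5, 5, 0)
    scene[np] <- scene[np] + 2000
  }
  set.seed(8)
  short <- field_image(pmax(round(100 + scene + rnorm(size^2, 0, 150)), 0),
                       "nuclear_short")
  long <- field_image(pmax(round(3 * (100 + scene) + rnorm(size^2, 0, 150)),
                           0), "nuclear_long")
  nuc <- segment_nuclei(short)
  expect_equal(n_objects(nuc), 2L)
  bod <- segment_cell_bodies(long, nuc)
  expect_equal(n_objects(bod), 2L)
  # each body contains exactly its own seed
  for (k in 1:2) {
    labs <- unique(unclass(bod)[unclass(nuc) == k])
    expect_equal(labs, k)
  }
  # centroids of the two bodies straddle the touch line
  obj <- mask_objects(bod)
  expect_equal(sort(round(obj$centroid_x, -1)), c(110, 150), tolerance = 0.1)
})

test_that("detected count is stable under added noise", {
  r <- render_field(60, cfg = small_cfg(), seed = 19)
  base <- n_objects(segment_nuclei(r$images$nuclear_short))
  img <- unclass(r$images$nuclear_short)
  fg_level <- stats::quantile(img, 0.999)            # ~ nucleus intensity
  set.seed(4)
  noisy <- field_image(
    pmax(pmin(round(img + rnorm(length(img), 0, 0.05 * fg_level)),
              65535), 0), "nuclear_short")
  pert <- n_objects(segment_nuclei(noisy))
  expect_lte(abs(pert - base) / base, 0.05)
})

test_that("label masks round-trip through TIFF and report objects", {
  r <- render_field(10, cfg = image_config(width = 300L, height = 300L),
                    seed = 23)
  nuc <- segment_nuclei(r$images$nuclear_short)
  tf <- tempfile(fileext = ".tif"); cf <- tempfile(fileext = ".csv")
  write_label_mask(nuc, tf, cf)
  back <- read_label_mask(tf, "nuclei")
  expect_equal(unclass(back), unclass(nuc), ignore_attr = TRUE)
  tab <- utils::read.csv(cf)
  expect_equal(nrow(tab), 10L)
  expect_true(all(c("label", "centroid_x", "centroid_y", "area",
                    "border_touch") %in% names(tab)))
})
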