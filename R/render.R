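#' Construct a field image
#'
#' A single-channel, single-plane intensity image from one imaged field of a
#' well, stored as a numeric matrix (rows = y, columns = x) in raw camera
#' counts.
#'
#' @param pixels numeric matrix of nonnegative intensities.
#' @param channel one of \code{"nuclear_short"}, \code{"nuclear_long"},
#'   \code{"green"}, \code{"red"} (or \code{"brightfield"} for the companion
#'   assays).
#' @param well_id,field_index identifiers.
#' @param bit_depth camera bit depth; intensities must be <=
#'   \code{2^bit_depth - 1}.
#' @return A \code{field_image} object.
#' @export
field_image <- function(pixels, channel, well_id = NA_character_,
                        field_index = 1L, bit_depth = 16L) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (any(pixels < 0) || any(pixels > 2^bit_depth - 1))
    stop("intensities must lie in [0, 2^bit_depth - 1]")
  structure(pixels, channel = channel, well_id = well_id,
            field_index = as.integer(field_index),
            bit_depth = as.integer(bit_depth),
            class = c("field_image", "matrix", "array"))
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("field_image %dx%d  channel=%s  well=%s  field=%d  %d-bit\n",
              nrow(x), ncol(x), attr(x, "channel"), attr(x, "well_id"),
              attr(x, "field_index"), attr(x, "bit_depth")))
  invisible(x)
}

#' Imaging configuration for the synthetic renderer
#'
#' Defaults put the fish-profile classification thresholds (green 500, red
#' 360) in the middle of the generated positive/negative intensity mixtures
#' and give the nuclear channel a signal-to-noise ratio of about 10
#' (nucleus amplitude / read-noise sd).
#'
#' @param width,height field dimensions in pixels (>= 256).
#' @param bit_depth camera bit depth.
#' @param background nuclear-channel background level (counts).
#' @param body_amp added intensity of the cell body over background in the
#'   nuclear scene.
#' @param nucleus_amp added intensity of the nucleus over the body.
#' @param gain multiplicative long/short exposure gain (> 1); the
#'   long-exposure image is the gain-scaled clean scene plus fresh noise.
#' @param noise_sd Gaussian read-noise standard deviation (counts).
#' @param shot_noise logical; add Poisson shot noise to the clean scene.
#' @param reporter_background,reporter_noise_sd background and noise for the
#'   green/red reporter channels.
#' @param green_pos,green_neg,red_pos,red_neg \code{c(mean, sd)} of the
#'   per-cell nuclear reporter intensity for positive/negative cells.
#' @param a_range semi-major axis range of cells (pixels).
#' @param elong_conc concentration of the Beta distribution from which
#'   per-cell elongation is drawn around the well mean.
#' @param nucleus_radius_frac nucleus radius as a fraction of the cell's
#'   semi-minor axis (clamped to [4, 8] px).
#' @param allow_overlap logical; if FALSE (default) cells are placed without
#'   overlap (bounded rejection sampling).
#' @param cell_gap minimum gap between bounding circles of neighbouring
#'   cells when non-overlapping (pixels).
#' @return A list of class \code{image_config}.
#' @export
image_config <- function(width = 1000L, height = 1000L, bit_depth = 16L,
                         background = 100, body_amp = 400, nucleus_amp = 2000,
                         gain = 3, noise_sd = 200, shot_noise = FALSE,
                         reporter_background = 50, reporter_noise_sd = 20,
                         green_pos = c(800, 80), green_neg = c(200, 50),
                         red_pos = c(600, 60), red_neg = c(150, 40),
                         a_range = c(12, 20), elong_conc = 25,
                         nucleus_radius_frac = 0.5,
                         allow_overlap = FALSE, cell_gap = 2) {
  stopifnot(width >= 256, height >= 256, gain > 1, noise_sd >= 0)
  structure(as.list(environment()), class = "image_config")
}

# pixel index set of a rotated filled ellipse, clipped to the canvas
ellipse_pixels <- function(width, height, cx, cy, a, b, theta) {
  x0 <- max(1L, floor(cx - a - 1)); x1 <- min(width, ceiling(cx + a + 1))
  y0 <- max(1L, floor(cy - a - 1)); y1 <- min(height, ceiling(cy + a + 1))
  if (x0 > x1 || y0 > y1) return(cbind(row = integer(0), col = integer(0)))
  xs <- x0:x1; ys <- y0:y1
  dx <- matrix(xs - cx, nrow = length(ys), ncol = length(xs), byrow = TRUE)
  dy <- matrix(ys - cy, nrow = length(ys), ncol = length(xs))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  idx <- which(inside, arr.ind = TRUE)
  cbind(row = ys[idx[, 1]], col = xs[idx[, 2]])
}

#' Rasterize a filled ellipse as a logical mask
#'
#' @param a,b semi-axes in pixels (a >= b).
#' @param theta orientation in radians.
#' @param pad margin of background pixels around the ellipse.
#' @return Logical matrix with the ellipse centred.
#' @export
rasterize_ellipse <- function(a, b, theta = 0, pad = 3L) {
  n <- ceiling(2 * a) + 2L * pad + 1L
  cx <- (n + 1) / 2
  m <- matrix(FALSE, n, n)
  px <- ellipse_pixels(n, n, cx, cx, a, b, theta)
  m[px] <- TRUE
  m
}

place_cells <- function(n, cfg, a, rng_tries = 500L) {
  w <- cfg$width; h <- cfg$height
  cx <- numeric(n); cy <- numeric(n)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(rng_tries)) {
      x <- runif(1, a[i] + 2, w - a[i] - 2)
      y <- runif(1, a[i] + 2, h - a[i] - 2)
      if (cfg$allow_overlap || i == 1L) { ok <- TRUE }
      else {
        j <- seq_len(i - 1L)
        ok <- all((cx[j] - x)^2 + (cy[j] - y)^2 >
                    (a[j] + a[i] + cfg$cell_gap)^2)
      }
      if (ok) { cx[i] <- x; cy[i] <- y; break }
    }
    if (!ok) stop("could not place ", n, " non-overlapping cells after ",
                  rng_tries, " retries each; lower the density or set ",
                  "allow_overlap = TRUE")
  }
  cbind(cx = cx, cy = cy)
}

rtrunc_norm <- function(n, mean, sd, lo = 0) pmax(lo, rnorm(n, mean, sd))

#' Render one synthetic multi-channel field with ground truth
#'
#' Draws \code{n_cells} ellipse-shaped cells with per-cell elongation around
#' the requested well mean, renders the four screen channels (short- and
#' long-exposure nuclear, green and red reporters) and returns the exact
#' per-cell generative parameters as the ground-truth record. The
#' long-exposure nuclear image is the gain-scaled clean scene plus fresh
#' noise, so nuclei dominate the short exposure while cell bodies become
#' segmentable in the long one.
#'
#' @param n_cells number of cells to draw (may be 0).
#' @param mean_elong target mean elongation (minor/major, in (0, 1]).
#' @param green_frac,red_frac fraction of cells drawn from the
#'   reporter-positive intensity component.
#' @param cfg an \code{\link{image_config}}.
#' @param seed integer seed; identical arguments and seed give identical
#'   images and truth.
#' @param well_id,field_index identifiers stamped on the images.
#' @return List with \code{images} (named list of \code{\link{field_image}}:
#'   nuclear_short, nuclear_long, green, red) and \code{truth} (data.frame:
#'   cell, cx, cy, a, b, theta, elongation, nucleus_r, green_intensity,
#'   red_intensity, green_pos_true, red_pos_true).
#' @export
render_field <- function(n_cells, mean_elong = 0.6, green_frac = 0.6,
                         red_frac = 0.4, cfg = image_config(), seed = 1L,
                         well_id = "A01", field_index = 1L) {
  stopifnot(inherits(cfg, "image_config"), n_cells >= 0,
            mean_elong > 0, mean_elong <= 1)
  set.seed(as.integer(seed))
  w <- cfg$width; h <- cfg$height
  maxv <- 2^cfg$bit_depth - 1

  if (n_cells > 0) {
    a <- runif(n_cells, cfg$a_range[1], cfg$a_range[2])
    m <- min(max(mean_elong, 0.05), 0.98)
    el <- rbeta(n_cells, m * cfg$elong_conc, (1 - m) * cfg$elong_conc)
    el <- pmin(pmax(el, 0.15), 1)
    b <- a * el
    theta <- runif(n_cells, 0, pi)
    pos <- place_cells(n_cells, cfg, a)
    nr <- pmin(pmax(cfg$nucleus_radius_frac * b, 4), 8)
    g_pos <- runif(n_cells) < green_frac
    r_pos <- runif(n_cells) < red_frac
    g_int <- ifelse(g_pos,
                    rtrunc_norm(n_cells, cfg$green_pos[1], cfg$green_pos[2]),
                    rtrunc_norm(n_cells, cfg$green_neg[1], cfg$green_neg[2]))
    r_int <- ifelse(r_pos,
                    rtrunc_norm(n_cells, cfg$red_pos[1], cfg$red_pos[2]),
                    rtrunc_norm(n_cells, cfg$red_neg[1], cfg$red_neg[2]))
    truth <- data.frame(cell = seq_len(n_cells), cx = pos[, "cx"],
                        cy = pos[, "cy"], a = a, b = b, theta = theta,
                        elongation = b / a, nucleus_r = nr,
                        green_intensity = g_int, red_intensity = r_int)
  } else {
    truth <- data.frame(cell = integer(0), cx = numeric(0), cy = numeric(0),
                        a = numeric(0), b = numeric(0), theta = numeric(0),
                        elongation = numeric(0), nucleus_r = numeric(0),
                        green_intensity = numeric(0), red_intensity = numeric(0))
  }

  scene <- matrix(0, h, w)        # nuclear clean scene over background
  green <- matrix(cfg$reporter_background, h, w)
  red <- matrix(cfg$reporter_background, h, w)
  for (i in seq_len(n_cells)) {
    body <- ellipse_pixels(w, h, truth$cx[i], truth$cy[i],
                           truth$a[i], truth$b[i], truth$theta[i])
    nuc <- ellipse_pixels(w, h, truth$cx[i], truth$cy[i],
                          truth$nucleus_r[i], truth$nucleus_r[i], 0)
    scene[body] <- scene[body] + cfg$body_amp
    scene[nuc] <- scene[nuc] + cfg$nucleus_amp
    green[body] <- truth$green_intensity[i]
    red[body] <- truth$red_intensity[i]
  }

  short_clean <- cfg$background + scene
  long_clean <- cfg$gain * short_clean
  if (cfg$shot_noise) {
    short_clean <- matrix(rpois(length(short_clean), short_clean), h, w)
    long_clean <- matrix(rpois(length(long_clean), long_clean), h, w)
  }
  clampi <- function(m) matrix(pmin(pmax(round(m), 0), maxv), nrow(m), ncol(m))
  mk <- function(m, ch) field_image(clampi(m), ch, well_id, field_index,
                                    cfg$bit_depth)
  images <- list(
    nuclear_short = mk(short_clean + rnorm(h * w, 0, cfg$noise_sd),
                       "nuclear_short"),
    nuclear_long = mk(long_clean + rnorm(h * w, 0, cfg$noise_sd),
                      "nuclear_long"),
    green = mk(green + rnorm(h * w, 0, cfg$reporter_noise_sd), "green"),
    red = mk(red + rnorm(h * w, 0, cfg$reporter_noise_sd), "red")
  )
  list(images = images, truth = truth)
}

#' Ground-truth label masks for a rendered field
#'
#' Rasterizes the generator's own cell-body and nucleus ellipses as label
#' masks, bypassing segmentation; used to validate feature extraction
#' independently of the segmentation stage.
#'
#' @param truth the \code{truth} data.frame from \code{\link{render_field}}.
#' @param cfg the \code{\link{image_config}} used for rendering.
#' @return List with \code{nuclei} and \code{bodies}
#'   \code{\link{label_mask}} objects.
#' @export
truth_masks <- function(truth, cfg) {
  w <- cfg$width; h <- cfg$height
  nuc <- matrix(0L, h, w); bod <- matrix(0L, h, w)
  for (i in seq_len(nrow(truth))) {
    bp <- ellipse_pixels(w, h, truth$cx[i], truth$cy[i], truth$a[i],
                         truth$b[i], truth$theta[i])
    np <- ellipse_pixels(w, h, truth$cx[i], truth$cy[i], truth$nucleus_r[i],
                         truth$nucleus_r[i], 0)
    bod[bp] <- i; nuc[np] <- i
  }
  list(nuclei = label_mask(nuc, "nuclei"),
       bodies = label_mask(bod, "cell_bodies"))
}

#' Write / read a field image as a single-plane grayscale TIFF
#'
#' Files follow the \code{{plate}_{well}_f{field}_{channel}.tif} naming
#' pattern when written through \code{\link{write_well_images}}.
#'
#' @param img a \code{\link{field_image}}.
#' @param path TIFF path.
#' @export
write_field_tiff <- function(img, path) {
  maxv <- 2^attr(img, "bit_depth") - 1
  tiff::writeTIFF(unclass(img) / maxv, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_field_tiff
#' @param channel,well_id,field_index,bit_depth metadata restored on read.
#' @export
read_field_tiff <- function(path, channel, well_id = NA_character_,
                            field_index = 1L, bit_depth = 16L) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  field_image(round(m * (2^bit_depth - 1)), channel, well_id, field_index,
              bit_depth)
}

#' Write a rendered field set to disk (TIFFs + ground-truth JSON)
#'
#' @param rendered result of \code{\link{render_field}}.
#' @param plate_id,well_id,field_index identifiers for the filename pattern.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_well_images <- function(rendered, plate_id, well_id, field_index,
                              out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in names(rendered$images)) {
    p <- file.path(out_dir, sprintf("%s_%s_f%d_%s.tif", plate_id, well_id,
                                    field_index, ch))
    write_field_tiff(rendered$images[[ch]], p)
    paths <- c(paths, p)
  }
  gt <- file.path(out_dir, sprintf("%s_%s_f%d_truth.json", plate_id, well_id,
                                   field_index))
  jsonlite::write_json(rendered$truth, gt, digits = NA)
  invisible(c(paths, gt))
}
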