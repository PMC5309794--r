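#' Rasterize a region of interest
#'
#' Supports axis-aligned rectangles (\code{list(xmin, xmax, ymin, ymax)}) and
#' polygons (\code{list(x = ..., y = ...)} vertex vectors, ray-casting
#' even-odd rule over pixel centres). ROIs may be read from simple JSON via
#' \code{\link{read_roi}}.
#'
#' @param roi ROI description.
#' @param width,height image dimensions.
#' @return Logical matrix (rows = y, cols = x).
#' @export
roi_mask <- function(roi, width, height) {
  if (all(c("xmin", "xmax", "ymin", "ymax") %in% names(roi))) {
    m <- matrix(FALSE, height, width)
    x0 <- max(1, ceiling(roi$xmin)); x1 <- min(width, floor(roi$xmax))
    y0 <- max(1, ceiling(roi$ymin)); y1 <- min(height, floor(roi$ymax))
    if (x0 <= x1 && y0 <= y1) m[y0:y1, x0:x1] <- TRUE
    return(m)
  }
  if (all(c("x", "y") %in% names(roi))) {
    vx <- as.numeric(roi$x); vy <- as.numeric(roi$y)
    if (length(vx) < 3) stop("polygon ROI needs >= 3 vertices")
    px <- rep(seq_len(width), each = height)
    py <- rep(seq_len(height), times = width)
    nv <- length(vx)
    inside <- rep(FALSE, width * height)
    j <- nv
    for (i in seq_len(nv)) {
      cross <- ((vy[i] > py) != (vy[j] > py)) &
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
      inside <- xor(inside, cross)
      j <- i
    }
    return(matrix(inside, height, width))
  }
  stop("roi must be a rectangle (xmin/xmax/ymin/ymax) or polygon (x/y)")
}

#' @rdname roi_mask
#' @param path JSON file holding the ROI (optionally with a \code{label}).
#' @export
read_roi <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Pigment-area fraction of a region of interest
#'
#' Fraction of ROI pixels at or below an intensity threshold — the
#' percentage of a larval tail occupied by black pigmented cells after
#' thresholding brightfield images into black versus white. The threshold
#' is user-supplied by default (fractions are comparable only within a
#' fixed-threshold batch); \code{threshold = "isodata"} selects it
#' automatically from the ROI histogram.
#'
#' @param img brightfield intensity matrix (dark = pigment).
#' @param roi ROI description (see \code{\link{roi_mask}}); NULL for the
#'   whole image.
#' @param threshold numeric cutoff, or \code{"isodata"}.
#' @return Fraction in [0, 1].
#' @export
pigment_area_fraction <- function(img, roi = NULL, threshold) {
  m <- unclass(img)
  sel <- if (is.null(roi)) matrix(TRUE, nrow(m), ncol(m))
  else roi_mask(roi, ncol(m), nrow(m))
  if (!any(sel)) stop("empty ROI")
  v <- m[sel]
  if (identical(threshold, "isodata")) threshold <- isodata_threshold(v)
  mean(v <= threshold)
}

#' Tumour area and perimeter by uniform automatic thresholding
#'
#' Segments bright objects with the isodata (iterative intermeans)
#' automatic threshold — the documented "default" algorithm of common image
#' software — applied identically across a batch, labels connected
#' components and reports per-object and total area and perimeter.
#'
#' @param img single-channel intensity matrix (e.g. a GFP tumour image).
#' @param method \code{"isodata"} (default), \code{"otsu"}, or a fixed
#'   numeric threshold (so one threshold can be applied uniformly across
#'   groups).
#' @param min_area discard objects smaller than this (pixels).
#' @return List: \code{objects} (data.frame label, area, perimeter),
#'   \code{total_area}, \code{total_perimeter}, \code{threshold}. A blank
#'   image yields zero objects.
#' @export
tumour_area <- function(img, method = "isodata", min_area = 9L) {
  m <- unclass(img)
  tv <- if (is.numeric(method)) method
  else if (identical(method, "isodata")) isodata_threshold(m)
  else if (identical(method, "otsu"))
    EBImage::otsu(as_ebimage(m / max(m)), range = c(0, 1)) * max(m)
  else stop("unknown method: ", method)
  empty <- data.frame(label = integer(0), area = numeric(0),
                      perimeter = numeric(0))
  if (is.na(tv) || diff(range(m)) == 0)
    return(list(objects = empty, total_area = 0, total_perimeter = 0,
                threshold = tv))
  fg <- m > tv
  lab <- EBImage::bwlabel(as_ebimage(fg))
  feats <- EBImage::computeFeatures.shape(lab)
  if (is.null(feats) || nrow(feats) == 0)
    return(list(objects = empty, total_area = 0, total_perimeter = 0,
                threshold = tv))
  obj <- data.frame(label = seq_len(nrow(feats)),
                    area = feats[, "s.area"],
                    perimeter = feats[, "s.perimeter"])
  obj <- obj[obj$area >= min_area, , drop = FALSE]
  list(objects = obj, total_area = sum(obj$area),
       total_perimeter = sum(obj$perimeter), threshold = tv)
}

#' Fit a melanin standard curve
#'
#' Ordinary least-squares line through (known melanin concentration, A405
#' absorbance) calibration points from commercially purified melanin.
#'
#' @param concentration known concentrations (>= 3 distinct values, >= 0).
#' @param absorbance matched A405 readings.
#' @return Object of class \code{standard_curve}: slope, intercept,
#'   residual standard error, the points.
#' @export
fit_standard_curve <- function(concentration, absorbance) {
  stopifnot(length(concentration) == length(absorbance))
  if (length(unique(concentration)) < 3)
    stop("standard curve needs >= 3 distinct concentrations")
  if (any(concentration < 0)) stop("concentrations must be >= 0")
  fit <- lm(absorbance ~ concentration)
  co <- coef(fit)
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 residual = sqrt(mean(fit$residuals^2)),
                 points = data.frame(concentration, absorbance)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: A405 = %.4g + %.4g x conc (rms resid %.3g, %d points)\n",
              x$intercept, x$slope, x$residual, nrow(x$points)))
  invisible(x)
}

#' Melanin content relative to the vehicle control
#'
#' Maps A405 absorbances to melanin concentrations through the inverted
#' linear standard curve and reports mean sample concentration over mean
#' vehicle concentration (the equal-cell-number protocol makes this a
#' per-cell relative content). Without a curve, the raw absorbance ratio is
#' returned.
#'
#' @param sample_a405 absorbance readings of the treated condition.
#' @param vehicle_a405 absorbance readings of the vehicle (DMSO) control.
#' @param curve optional \code{\link{fit_standard_curve}} result.
#' @return Relative melanin content (1 = vehicle level).
#' @export
#' @examples
#' cv <- fit_standard_curve(c(0, 1, 2), c(0, 0.5, 1.0))
#' melanin_relative(0.75, 0.25, cv)   # 3
melanin_relative <- function(sample_a405, vehicle_a405, curve = NULL) {
  if (!is.null(curve)) {
    stopifnot(inherits(curve, "standard_curve"))
    if (curve$slope <= 0) stop("standard curve slope must be positive")
    conc <- function(a) (a - curve$intercept) / curve$slope
    s <- mean(conc(sample_a405)); v <- mean(conc(vehicle_a405))
  } else {
    s <- mean(sample_a405); v <- mean(vehicle_a405)
  }
  if (isTRUE(all.equal(v, 0)) || v == 0)
    stop("vehicle-control mean is zero")
  s / v
}
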