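#' Construct a label mask
#'
#' Integer matrix where 0 is background and k > 0 marks object k; labels are
#' relabelled to contiguous 1..K on construction.
#'
#' @param labels integer matrix of nonnegative labels.
#' @param kind \code{"nuclei"} or \code{"cell_bodies"}.
#' @return A \code{label_mask} object.
#' @export
label_mask <- function(labels, kind = c("nuclei", "cell_bodies")) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(labels))
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  if (any(labels < 0)) stop("labels must be nonnegative")
  u <- sort(unique(labels[labels > 0L]))
  if (length(u) && !identical(u, seq_along(u))) {
    remap <- integer(max(u)); remap[u] <- seq_along(u)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
  }
  structure(labels, kind = kind, class = c("label_mask", "matrix", "array"))
}

#' @export
print.label_mask <- function(x, ...) {
  cat(sprintf("label_mask %dx%d  kind=%s  objects=%d\n", nrow(x), ncol(x),
              attr(x, "kind"), n_objects(x)))
  invisible(x)
}

#' Number of objects in a label mask
#' @param mask a \code{\link{label_mask}}.
#' @export
n_objects <- function(mask) {
  m <- max(mask)
  if (is.na(m)) 0L else as.integer(m)
}

#' Object centroids and areas of a label mask
#'
#' @param mask a \code{\link{label_mask}}.
#' @return data.frame with label, centroid_x, centroid_y (pixel coordinates,
#'   x = column, y = row), area and border_touch flag.
#' @export
mask_objects <- function(mask) {
  k <- n_objects(mask)
  if (k == 0L) {
    return(data.frame(label = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), area = integer(0),
                      border_touch = logical(0)))
  }
  idx <- which(mask > 0L)
  lab <- as.integer(mask)[idx]
  rows <- (idx - 1L) %% nrow(mask) + 1L
  cols <- (idx - 1L) %/% nrow(mask) + 1L
  area <- tabulate(lab, k)
  cx <- as.numeric(rowsum(as.numeric(cols), lab)) / area
  cy <- as.numeric(rowsum(as.numeric(rows), lab)) / area
  on_border <- rows == 1L | rows == nrow(mask) | cols == 1L | cols == ncol(mask)
  bt <- as.logical(tabulate(lab[on_border], k) > 0L)
  data.frame(label = seq_len(k), centroid_x = cx, centroid_y = cy,
             area = area, border_touch = bt)
}

#' Isodata (iterative intermeans) automatic threshold
#'
#' The classic two-class automatic threshold: starting from the global mean,
#' iterate t <- (mean below t + mean above t) / 2 until convergence. This is
#' the documented "default" auto-threshold of common image-analysis software.
#'
#' @param x numeric vector or matrix of intensities.
#' @param tol convergence tolerance on the threshold.
#' @param max_iter iteration cap.
#' @return The threshold value; pixels with intensity > threshold are
#'   foreground. NA for constant input.
#' @export
#' @examples
#' isodata_threshold(c(rnorm(500, 10), rnorm(500, 100)))
isodata_threshold <- function(x, tol = 0.5, max_iter = 100L) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (!length(v) || diff(range(v)) == 0) return(NA_real_)
  # midrange initialization keeps the iteration out of the dominant mode
  # when the two classes are heavily unbalanced (few bright objects on a
  # large background)
  t <- (min(v) + max(v)) / 2
  for (i in seq_len(max_iter)) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t) < tol) { t <- t_new; break }
    t <- t_new
  }
  t
}

as_ebimage <- function(m) EBImage::Image(t(unclass(m)))
from_ebimage <- function(img) t(EBImage::imageData(img))

#' Segmentation parameters
#'
#' @param tophat_radius disk radius of the top-hat structuring element
#'   (pixels); about 1.5x the expected nucleus radius.
#' @param nucleus_threshold \code{"isodata"} or a fixed numeric value applied
#'   to the top-hat image.
#' @param min_area minimum object area (pixels) kept after nucleus detection.
#' @param split_touching logical; split merged nuclei by distance-transform
#'   watershed.
#' @param body_threshold \code{"isodata"} or a fixed numeric value applied to
#'   the long-exposure image.
#' @param noise_floor_k with the automatic nucleus threshold, the threshold
#'   is floored at median + k * MAD of the top-hat image so that read noise
#'   alone (a signal-free field) produces no objects; set to 0 to disable.
#' @return List of class \code{seg_params}.
#' @export
seg_params <- function(tophat_radius = 15L, nucleus_threshold = "isodata",
                       min_area = 30L, split_touching = TRUE,
                       body_threshold = "isodata", noise_floor_k = 5) {
  if (tophat_radius < 1) stop("tophat_radius must be >= 1")
  structure(list(tophat_radius = as.integer(tophat_radius),
                 nucleus_threshold = nucleus_threshold,
                 min_area = as.integer(min_area),
                 split_touching = split_touching,
                 body_threshold = body_threshold,
                 noise_floor_k = noise_floor_k),
            class = "seg_params")
}

resolve_threshold <- function(spec, x) {
  if (is.numeric(spec)) return(spec)
  if (identical(spec, "isodata")) return(isodata_threshold(x))
  stop("unknown threshold rule: ", spec)
}

#' Detect nuclei on the short-exposure nuclear image
#'
#' White top-hat transform with a disk structuring element isolates bright
#' features smaller than the element (nuclei); an automatic isodata threshold
#' of the top-hat image, connected-component labelling, a minimum-area filter
#' and an optional distance-transform watershed split of touching pairs give
#' the nucleus label mask.
#'
#' @param img a \code{\link{field_image}} with channel
#'   \code{"nuclear_short"}.
#' @param params a \code{\link{seg_params}}.
#' @return A \code{\link{label_mask}} of kind \code{"nuclei"}. A constant or
#'   empty image yields zero objects.
#' @export
segment_nuclei <- function(img, params = seg_params()) {
  stopifnot(inherits(params, "seg_params"))
  if (inherits(img, "field_image") &&
      !identical(attr(img, "channel"), "nuclear_short"))
    stop("segment_nuclei expects the nuclear_short channel, got ",
         attr(img, "channel"))
  m <- unclass(img)
  if (diff(range(m)) == 0)
    return(label_mask(matrix(0L, nrow(m), ncol(m)), "nuclei"))
  e <- as_ebimage(m)
  brush <- EBImage::makeBrush(2L * params$tophat_radius + 1L, shape = "disc")
  th <- EBImage::whiteTopHat(e, brush)
  tv <- resolve_threshold(params$nucleus_threshold, EBImage::imageData(th))
  if (!is.numeric(params$nucleus_threshold) && params$noise_floor_k > 0) {
    v <- as.numeric(EBImage::imageData(th))
    tv <- max(tv, stats::median(v) + params$noise_floor_k * stats::mad(v))
  }
  fg <- th > tv
  lab <- EBImage::bwlabel(fg)
  if (params$split_touching) {
    dm <- EBImage::distmap(fg)
    lab <- EBImage::watershed(dm, tolerance = 1, ext = 1)
  }
  lm <- from_ebimage(lab)
  # minimum-area filter
  k <- max(lm)
  if (k > 0) {
    areas <- tabulate(lm[lm > 0L], k)
    drop <- which(areas < params$min_area)
    if (length(drop)) lm[lm %in% drop] <- 0L
  }
  label_mask(lm, "nuclei")
}

#' Segment cell bodies on the long-exposure image using nuclei as seeds
#'
#' A single global threshold (isodata by default) defines the foreground of
#' the long-exposure nuclear image; the foreground is partitioned among the
#' nucleus seeds by seeded region growing, foreground components containing
#' no seed are discarded, and each body inherits its seed's label. Nucleus
#' pixels are always included in their body, so a seed falling outside the
#' thresholded foreground reduces to its nucleus mask (with a warning).
#'
#' @param img a \code{\link{field_image}} with channel \code{"nuclear_long"}.
#' @param nuclei the nucleus \code{\link{label_mask}} (aligned with
#'   \code{img}).
#' @param params a \code{\link{seg_params}}.
#' @return A \code{\link{label_mask}} of kind \code{"cell_bodies"} whose
#'   labels match the nucleus labels.
#' @export
segment_cell_bodies <- function(img, nuclei, params = seg_params()) {
  stopifnot(inherits(params, "seg_params"))
  if (inherits(img, "field_image") &&
      !identical(attr(img, "channel"), "nuclear_long"))
    stop("segment_cell_bodies expects the nuclear_long channel, got ",
         attr(img, "channel"))
  m <- unclass(img)
  if (!all(dim(m) == dim(nuclei))) stop("nuclei mask not aligned with image")
  if (n_objects(nuclei) == 0L)
    return(label_mask(matrix(0L, nrow(m), ncol(m)), "cell_bodies"))
  # the automatic threshold is computed over non-nucleus pixels: nuclei are
  # known foreground (they seed the bodies), and excluding their much
  # brighter mode leaves a bimodal background/body histogram for the
  # intermeans rule; the resulting single global threshold is applied to the
  # whole image
  tv <- resolve_threshold(params$body_threshold, m[unclass(nuclei) == 0L])
  fg <- m > tv
  seeds <- unclass(nuclei)
  fg_s <- fg | seeds > 0L               # seeds always foreground
  seeded <- EBImage::propagate(as_ebimage(m), as_ebimage(seeds),
                               mask = as_ebimage(fg_s))
  bodies <- from_ebimage(seeded)
  mode(bodies) <- "integer"
  # discard foreground components with no seed (propagate cannot reach them)
  bodies[!fg_s] <- 0L
  bodies[seeds > 0L] <- seeds[seeds > 0L]
  # warn about seeds whose body is just the nucleus
  k <- max(seeds)
  b_area <- tabulate(bodies[bodies > 0L], k)
  s_area <- tabulate(seeds[seeds > 0L], k)
  stranded <- which(b_area > 0 & b_area <= s_area)
  if (length(stranded))
    warning(length(stranded), " seed(s) outside the thresholded foreground; ",
            "reduced to their nucleus masks")
  out <- label_mask(bodies, "cell_bodies")
  attr(out, "threshold") <- tv
  out
}

#' Write a label mask and its per-object table
#'
#' Writes the mask as a 16-bit label TIFF and a CSV of per-object label,
#' centroid, area and border-touch flag.
#'
#' @param mask a \code{\link{label_mask}}.
#' @param tiff_path,csv_path output paths.
#' @export
write_label_mask <- function(mask, tiff_path, csv_path = NULL) {
  tiff::writeTIFF(unclass(mask) / 65535, tiff_path, bits.per.sample = 16L)
  if (!is.null(csv_path)) write.csv(mask_objects(mask), csv_path,
                                    row.names = FALSE)
  invisible(tiff_path)
}

#' @rdname write_label_mask
#' @param kind mask kind restored on read.
#' @export
read_label_mask <- function(tiff_path, kind = "nuclei") {
  m <- tiff::readTIFF(tiff_path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  label_mask(round(m * 65535), kind)
}
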