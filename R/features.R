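#' Boundary pixels of a binary mask
#'
#' A mask pixel is a boundary pixel if any of its 4-neighbours is background
#' or lies outside the image.
#'
#' @param mask logical matrix.
#' @return Two-column matrix of (row, col) boundary pixel coordinates.
#' @keywords internal
boundary_pixels <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  core <- pad[2:(h + 1L), 2:(w + 1L)]
  interior <- core &
    pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  which(core & !interior, arr.ind = TRUE)
}

# TRUE for each pair whose connecting segment stays inside the mask,
# sampled at sub-pixel steps and rounded to the nearest pixel
segments_inside <- function(mask, p1, p2) {
  n <- nrow(p1)
  if (n == 0L) return(logical(0))
  d <- sqrt(rowSums((p1 - p2)^2))
  steps <- max(2L, ceiling(max(d) * 2) + 1L)
  tt <- seq(0, 1, length.out = steps)
  ok <- rep(TRUE, n)
  for (t in tt) {
    r <- round(p1[, 1] + t * (p2[, 1] - p1[, 1]))
    c <- round(p1[, 2] + t * (p2[, 2] - p1[, 2]))
    ok <- ok & mask[cbind(r, c)]
    if (!any(ok)) break
  }
  ok
}

longest_inside_pair <- function(mask, pairs, d, block = 256L) {
  ord <- order(d, decreasing = TRUE)
  i <- 1L
  while (i <= length(ord)) {
    j <- ord[i:min(i + block - 1L, length(ord))]
    ok <- segments_inside(mask, pairs[j, 1:2, drop = FALSE],
                          pairs[j, 3:4, drop = FALSE])
    if (any(ok)) return(j[which(ok)[1L]])
    i <- i + block
  }
  NA_integer_
}

#' Cell elongation: ratio of minor to major axis of a mask
#'
#' The major axis is the longest straight-line chord that can be drawn
#' within the mask (between boundary pixel centres, with the whole segment
#' inside the mask); the minor axis is the longest in-mask chord
#' perpendicular to the major axis (within an angular tolerance, since exact
#' perpendicularity is measure-zero on a pixel grid). Elongation is
#' minor/major: 1 for a disk, approaching 0 for needle-like cells.
#'
#' \code{method = "chord"} (default) computes the literal chord definition;
#' \code{method = "moment"} uses the equivalent-ellipse axes from the second
#' central moments of the pixel coordinates, which is faster but only an
#' approximation for non-elliptical masks.
#'
#' @param mask logical (or 0/1) matrix; must contain at least one TRUE pixel.
#' @param method \code{"chord"} or \code{"moment"}.
#' @param angle_tol angular tolerance (degrees) for the perpendicular minor
#'   chord.
#' @return List with \code{major}, \code{minor} (chord lengths in pixels, as
#'   distances between pixel centres) and \code{elongation} = minor/major in
#'   (0, 1]. A single-pixel mask has elongation 1 by convention; a chord
#'   direction along which the mask is one pixel wide contributes length 1.
#' @export
#' @examples
#' elongation(rasterize_ellipse(20, 10))$elongation   # ~0.5
elongation <- function(mask, method = c("chord", "moment"), angle_tol = 2) {
  method <- match.arg(method)
  mask <- unclass(mask) > 0
  npx <- sum(mask)
  if (npx == 0L) stop("empty mask")
  if (npx == 1L) return(list(major = 1, minor = 1, elongation = 1))
  if (method == "moment") return(elongation_moment(mask))

  bp <- boundary_pixels(mask)
  n <- nrow(bp)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- cbind(bp[ij[, 1], , drop = FALSE], bp[ij[, 2], , drop = FALSE])
  dr <- pairs[, 3] - pairs[, 1]
  dc <- pairs[, 4] - pairs[, 2]
  d <- sqrt(dr^2 + dc^2)

  imax <- longest_inside_pair(mask, pairs, d)
  if (is.na(imax)) {                       # no multi-pixel in-mask chord
    return(list(major = 1, minor = 1, elongation = 1))
  }
  major <- d[imax]
  ang_major <- atan2(dr[imax], dc[imax])

  ang <- atan2(dr, dc)
  dev <- abs(((ang - ang_major) * 180 / pi) %% 180 - 90)  # 0 = perpendicular
  perp <- which(dev <= angle_tol & d > 0)
  minor <- 1
  if (length(perp)) {
    k <- longest_inside_pair(mask, pairs[perp, , drop = FALSE], d[perp])
    if (!is.na(k)) minor <- max(d[perp][k], 1)
  }
  minor <- min(minor, major)
  list(major = major, minor = minor, elongation = minor / major)
}

elongation_moment <- function(mask) {
  px <- which(mask, arr.ind = TRUE)
  cc <- sweep(px, 2, colMeans(px))
  cv <- crossprod(cc) / nrow(px)
  ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  major <- 4 * sqrt(max(ev[1], 1 / 12))
  minor <- 4 * sqrt(max(ev[2], 1 / 12))
  list(major = major, minor = minor, elongation = minor / major)
}

#' Measure per-cell intensity and shape features
#'
#' For each nucleus, reporter intensities are averaged over the nucleus mask
#' (not the body), and shape features (area, major/minor chord, elongation,
#' border contact) are computed over the matching cell-body mask.
#'
#' @param nuclei nucleus \code{\link{label_mask}}.
#' @param bodies cell-body \code{\link{label_mask}} sharing the nucleus
#'   labels.
#' @param channels named list of \code{\link{field_image}}/matrices; nuclear
#'   mean intensity is reported for each (typically \code{green} and
#'   \code{red}).
#' @param well_id,field_index identifiers copied into the records.
#' @param method elongation method, see \code{\link{elongation}}.
#' @return data.frame with one row per nucleus: cell_id, well_id,
#'   field_index, centroid_x/y, area, major_axis, minor_axis, elongation,
#'   border_touch and \code{mean_<channel>} columns.
#' @export
measure_cells <- function(nuclei, bodies, channels, well_id = NA_character_,
                          field_index = 1L, method = "chord") {
  stopifnot(is.list(channels))
  for (ch in names(channels)) {
    if (!all(dim(channels[[ch]]) == dim(nuclei)))
      stop("channel not aligned with masks: ", ch)
  }
  k <- n_objects(nuclei)
  nuc_obj <- mask_objects(nuclei)
  bod <- unclass(bodies)
  recs <- vector("list", k)
  h <- nrow(bod); w <- ncol(bod)
  idx_all <- which(bod > 0L)
  lab_all <- bod[idx_all]
  by_lab <- split(idx_all, lab_all)
  nuc_idx <- split(which(unclass(nuclei) > 0L),
                   unclass(nuclei)[unclass(nuclei) > 0L])
  for (i in seq_len(k)) {
    bi <- by_lab[[as.character(i)]]
    ni <- nuc_idx[[as.character(i)]]
    if (is.null(ni) || !length(ni)) next   # mask invariant: no empty nucleus
    if (is.null(bi)) bi <- ni
    rows <- (bi - 1L) %% h + 1L
    cols <- (bi - 1L) %/% h + 1L
    r0 <- min(rows); c0 <- min(cols)
    sub <- matrix(FALSE, max(rows) - r0 + 1L, max(cols) - c0 + 1L)
    sub[cbind(rows - r0 + 1L, cols - c0 + 1L)] <- TRUE
    el <- elongation(sub, method = method)
    means <- vapply(channels, function(chm) mean(unclass(chm)[ni]), 0)
    recs[[i]] <- data.frame(
      cell_id = i, well_id = well_id, field_index = as.integer(field_index),
      centroid_x = nuc_obj$centroid_x[i], centroid_y = nuc_obj$centroid_y[i],
      area = length(bi), major_axis = el$major, minor_axis = el$minor,
      elongation = el$elongation,
      border_touch = any(rows == 1L | rows == h | cols == 1L | cols == w),
      stringsAsFactors = FALSE)
    for (ch in names(means)) recs[[i]][[paste0("mean_", ch)]] <- means[[ch]]
  }
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(cell_id = integer(0), well_id = character(0),
                      field_index = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), area = integer(0),
                      major_axis = numeric(0), minor_axis = numeric(0),
                      elongation = numeric(0), border_touch = logical(0))
    for (ch in names(channels)) out[[paste0("mean_", ch)]] <- numeric(0)
  }
  rownames(out) <- NULL
  out
}
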