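#' Control-well statistics for one stratum
#'
#' Mean and sample standard deviation of a measurement over the vehicle
#' wells of one stratum (same plate, same vehicle, same serum, same cell
#' reservoir) — the mock-treatment distribution that treated wells are
#' scored against.
#'
#' @param x numeric vector of the measurement in the stratum's control wells
#'   (length >= 2).
#' @param stratum optional label (e.g. "P01/low") carried in errors and
#'   output.
#' @return List of class \code{control_stats}: \code{mu}, \code{sigma}
#'   (n - 1 denominator), \code{n_controls}, \code{degenerate} flag
#'   (\code{sigma == 0}), \code{stratum}.
#' @export
#' @examples
#' control_stats(c(10, 12, 14))   # mu 12, sigma 2
control_stats <- function(x, stratum = NA_character_) {
  x <- x[is.finite(x)]
  if (length(x) < 2)
    stop("need >= 2 control wells in stratum ", stratum)
  s <- sd(x)
  structure(list(mu = mean(x), sigma = s, n_controls = length(x),
                 degenerate = s == 0, stratum = stratum),
            class = "control_stats")
}

#' Signed per-well Z-score against the control distribution
#'
#' Z = (x - mu) / sigma: the number of control standard deviations a
#' replicate well falls above or below the mean of its matched vehicle
#' controls.
#'
#' @param x measurement in one (or several) treated replicate wells.
#' @param stats a \code{\link{control_stats}} object with \code{sigma > 0}.
#' @return Numeric Z-score(s), signed.
#' @export
zscore <- function(x, stats) {
  stopifnot(inherits(stats, "control_stats"))
  if (stats$degenerate || stats$sigma <= 0)
    stop("degenerate control stratum (sigma = 0): ", stats$stratum)
  (x - stats$mu) / stats$sigma
}

#' Composite Z-score across replicate wells
#'
#' The replicate Z-scores form a vector z in R^n; the composite statistic is
#' the signed scalar projection of z onto the unit diagonal
#' v = (1/sqrt(n), ..., 1/sqrt(n)) — the direction of perfect
#' reproducibility: z_hat = sum(z) / sqrt(n). If all replicates share the
#' same Z-score z, the composite is sqrt(n) * z; under a standard-normal
#' null it is again standard normal for any n.
#'
#' @param z numeric vector of replicate Z-scores (finite, length >= 1).
#' @param absolute if TRUE return |z_hat| (the unsigned projection length).
#' @return List of class \code{composite_z}: \code{z_hat}, \code{n}.
#' @export
#' @examples
#' composite_z(c(1, 2, 3))$z_hat    # 6 / sqrt(3)
composite_z <- function(z, absolute = FALSE) {
  if (!length(z)) stop("empty replicate Z-score vector")
  if (!all(is.finite(z))) stop("non-finite replicate Z-score")
  zh <- sum(z) / sqrt(length(z))
  if (absolute) zh <- abs(zh)
  structure(list(z_hat = zh, n = length(z)), class = "composite_z")
}

#' Null calibration of the composite Z-score
#'
#' Simulates null conditions whose replicate Z-scores are independent
#' standard normals and reports the fraction whose |z_hat| exceeds the
#' cutoff. Because the projection of an i.i.d. standard-normal vector onto a
#' unit vector is standard normal, the rate at cutoff 1.96 converges to
#' about 0.05 for any replicate count; the screen applies no
#' multiple-testing correction, so this is the raw per-condition
#' false-positive rate.
#'
#' @param n_reps replicate wells per simulated condition.
#' @param n_sims number of simulated null conditions (>= 1000).
#' @param cutoff two-sided cutoff on |z_hat|.
#' @param seed integer seed.
#' @return List: \code{rate} (empirical false-positive fraction),
#'   \code{cutoff}, \code{n_reps}, \code{n_sims}.
#' @export
null_calibration <- function(n_reps = 4L, n_sims = 100000L, cutoff = 1.96,
                             seed = 1L) {
  stopifnot(n_reps >= 1, n_sims >= 1000)
  set.seed(as.integer(seed))
  z <- matrix(rnorm(n_sims * n_reps), n_sims, n_reps)
  zh <- rowSums(z) / sqrt(n_reps)
  list(rate = mean(abs(zh) > cutoff), cutoff = cutoff,
       n_reps = as.integer(n_reps), n_sims = as.integer(n_sims))
}

#' Score a screen: composite Z per (agent, dose, serum, measurement)
#'
#' Joins well summaries to the plate map, computes per-stratum control
#' statistics (controls on the same plate and serum level), Z-scores every
#' treated replicate well and projects each replicate group onto the
#' perfect-reproducibility diagonal.
#'
#' @param summaries data.frame of well summaries (one row per well) carrying
#'   \code{plate_id}, \code{well_id} and the measurement columns.
#' @param plate_map plate map data.frame (see \code{\link{generate_plate}}).
#' @param measurements named character vector mapping measurement names to
#'   summary columns; default scores proliferation as the total cell count
#'   and differentiation as the mean elongation of the green-reporter
#'   population.
#' @param absolute report |z_hat| instead of the signed projection.
#' @return Long-format data.frame: agent, dose, dose_unit, serum,
#'   measurement, n, z_hat.
#' @export
score_screen <- function(summaries, plate_map,
                         measurements = c(count = "n_cells",
                                          elongation = "mean_elong_green"),
                         absolute = FALSE) {
  need <- unname(measurements)
  miss <- setdiff(need, names(summaries))
  if (length(miss)) stop("summaries missing columns: ",
                         paste(miss, collapse = ", "))
  key <- c("plate_id", "well_id")
  if (!all(key %in% names(summaries)))
    stop("summaries must carry plate_id and well_id")
  df <- merge(plate_map, summaries[, unique(c(key, need)), drop = FALSE],
              by = key)
  if (nrow(df) < nrow(plate_map))
    warning(nrow(plate_map) - nrow(df), " plate-map wells without summaries")
  out <- list()
  for (m in names(measurements)) {
    col <- measurements[[m]]
    for (pid in unique(df$plate_id)) {
      for (s in unique(df$serum[df$plate_id == pid])) {
        stratum <- df$plate_id == pid & df$serum == s
        ctrl <- df[stratum & df$is_control, col]
        cs <- control_stats(ctrl, paste(pid, s, sep = "/"))
        trt <- df[stratum & !df$is_control, , drop = FALSE]
        if (!nrow(trt)) next
        trt$z <- zscore(trt[[col]], cs)
        grp <- split(trt, list(trt$agent, signif(trt$dose, 8)), drop = TRUE)
        for (g in grp) {
          out[[length(out) + 1L]] <- data.frame(
            agent = g$agent[1], dose = g$dose[1], dose_unit = g$dose_unit[1],
            serum = s, measurement = m, n = nrow(g),
            z_hat = composite_z(g$z, absolute = absolute)$z_hat,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$agent, res$dose, res$serum, res$measurement), ]
  rownames(res) <- NULL
  res
}
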