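#' Simulate measured well summaries without rendering images
#'
#' Draws the well summaries the imaging pipeline would produce, directly
#' from each well's generative parameters: the measured count is the well's
#' realized cell count and the measured mean elongations are the truth plus
#' sampling error of a mean (between-cell elongation sd divided by
#' sqrt(n)). This is the fast path for statistics that only depend on well
#' summaries (null calibration of hit calling, power sweeps); the image
#' path (\code{\link{simulate_screen_images}}) exercises the same contract
#' through rendering and segmentation.
#'
#' @param plate result of \code{\link{generate_plate}}.
#' @param seed integer seed for the measurement draws.
#' @param elong_sd between-cell elongation standard deviation.
#' @return data.frame of well summaries (plate_id, well_id, n_cells,
#'   n_green, n_red, mean_elong, mean_elong_green, mean_elong_red).
#' @export
simulate_well_summaries <- function(plate, seed = 1L, elong_sd = 0.1) {
  wp <- plate$well_params
  set.seed(as.integer(seed))
  n <- nrow(wp)
  n_cells <- wp$n_cells
  n_green <- rbinom(n, n_cells, wp$green_frac)
  n_red <- rbinom(n, n_cells, wp$red_frac)
  se <- function(k) ifelse(k > 0, elong_sd / sqrt(pmax(k, 1)), NA_real_)
  clip01 <- function(x) pmin(pmax(x, .Machine$double.eps), 1)
  data.frame(
    plate_id = wp$plate_id, well_id = wp$well_id,
    n_fields = 1L, n_cells = n_cells, n_green = n_green, n_red = n_red,
    mean_elong = clip01(rnorm(n, wp$mean_elong, se(n_cells))),
    mean_elong_green = clip01(rnorm(n, wp$mean_elong, se(n_green))),
    mean_elong_red = clip01(rnorm(n, wp$mean_elong, se(n_red))),
    stringsAsFactors = FALSE)
}

#' Process one rendered field through the full image pipeline
#'
#' Segments nuclei and cell bodies, measures per-cell features, and
#' classifies reporter positivity.
#'
#' @param images named list of \code{\link{field_image}}s
#'   (nuclear_short, nuclear_long, green, red).
#' @param params \code{\link{seg_params}}.
#' @param profile classification profile, see \code{\link{classify_cells}}.
#' @param well_id,field_index identifiers.
#' @return Classified per-cell records (see \code{\link{measure_cells}}).
#' @export
process_field <- function(images, params = seg_params(), profile = "fish",
                          well_id = NA_character_, field_index = 1L) {
  need <- c("nuclear_short", "nuclear_long", "green", "red")
  miss <- setdiff(need, names(images))
  if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))
  nuc <- segment_nuclei(images$nuclear_short, params)
  bod <- segment_cell_bodies(images$nuclear_long, nuc, params)
  rec <- measure_cells(nuc, bod,
                       list(green = images$green, red = images$red),
                       well_id = well_id, field_index = field_index)
  classify_cells(rec, profile = profile)
}

#' Simulate a screen end-to-end through rendered images
#'
#' For every well of a generated plate, renders \code{n_fields}
#' multi-channel fields from the well's generative parameters, runs
#' segmentation, feature extraction and classification, and summarizes each
#' well. Cell counts are split evenly across fields.
#'
#' @param plate result of \code{\link{generate_plate}}.
#' @param cfg \code{\link{image_config}} for rendering.
#' @param params \code{\link{seg_params}} for segmentation.
#' @param profile classification profile.
#' @param n_fields fields per well.
#' @param seed integer seed; per-well render seeds are derived from it.
#' @param verbose print progress.
#' @return data.frame of well summaries joined to plate_id/well_id.
#' @export
simulate_screen_images <- function(plate, cfg = image_config(),
                                   params = seg_params(), profile = "fish",
                                   n_fields = 1L, seed = 1L,
                                   verbose = FALSE) {
  wp <- plate$well_params
  out <- vector("list", nrow(wp))
  for (i in seq_len(nrow(wp))) {
    recs <- vector("list", n_fields)
    per_field <- diff(round(seq(0, wp$n_cells[i], length.out = n_fields + 1)))
    for (f in seq_len(n_fields)) {
      rf <- render_field(per_field[f], mean_elong = wp$mean_elong[i],
                         green_frac = wp$green_frac[i],
                         red_frac = wp$red_frac[i], cfg = cfg,
                         seed = (seed * 10007L + i * 131L + f) %% 2147483647L,
                         well_id = wp$well_id[i], field_index = f)
      recs[[f]] <- process_field(rf$images, params, profile,
                                 well_id = wp$well_id[i], field_index = f)
    }
    sm <- summarize_well(do.call(rbind, recs))
    sm$plate_id <- wp$plate_id[i]
    out[[i]] <- sm
    if (verbose) message(sprintf("well %s/%s: %d cells", wp$plate_id[i],
                                 wp$well_id[i], sm$n_cells))
  }
  do.call(rbind, out)
}

#' @importFrom stats rbinom
NULL
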