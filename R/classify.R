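#' Reporter classification thresholds
#'
#' The screen's printed nuclear-intensity cutoffs: the fish (ZMEL) profile
#' calls GFP-positive cells at a nuclear green mean > 500 and
#' tdTomato-positive cells at a nuclear red mean > 360; the human profile
#' calls RFP-positive cells at a nuclear red mean > 283. All comparisons are
#' strict.
#'
#' @param profile \code{"fish"} or \code{"human"}.
#' @return Named list with \code{green} and \code{red} thresholds (\code{NA}
#'   when the profile has no reporter on that channel).
#' @export
classification_thresholds <- function(profile = c("fish", "human")) {
  profile <- match.arg(profile)
  switch(profile,
         fish = list(green = 500, red = 360),
         human = list(green = NA_real_, red = 283))
}

#' Classify cells as reporter-positive at the printed thresholds
#'
#' Adds \code{green_pos} / \code{red_pos} flags to per-cell records using
#' strict-inequality comparisons of the nuclear mean intensities
#' (\code{mean_green} / \code{mean_red} columns) against the profile's
#' thresholds.
#'
#' @param records data.frame from \code{\link{measure_cells}}.
#' @param profile \code{"fish"} (green > 500, red > 360) or \code{"human"}
#'   (red > 283).
#' @param thresholds optional named list overriding the profile thresholds.
#' @return \code{records} with logical \code{green_pos} and \code{red_pos}
#'   columns (FALSE where the profile defines no threshold).
#' @export
#' @examples
#' df <- data.frame(mean_green = c(600, 500), mean_red = c(360, 400))
#' classify_cells(df)[, c("green_pos", "red_pos")]
classify_cells <- function(records, profile = "fish", thresholds = NULL) {
  th <- thresholds %||% classification_thresholds(profile)
  if (any(vapply(th, function(v) !is.na(v) && v <= 0, TRUE)))
    stop("thresholds must be strictly positive")
  flag <- function(col, cut) {
    if (is.na(cut) || is.null(records[[col]])) rep(FALSE, nrow(records))
    else records[[col]] > cut
  }
  records$green_pos <- flag("mean_green", th$green)
  records$red_pos <- flag("mean_red", th$red)
  records
}

#' Summarize the cells of one well
#'
#' Aggregates per-cell records into the well-level readouts the screen
#' scores: total cell count, reporter-class counts, and mean elongation
#' overall and per class. Border-touching cells count toward proliferation
#' but are excluded from shape means under the default policy (clipped masks
#' bias elongation).
#'
#' @param records classified per-cell records for one well (possibly several
#'   fields).
#' @param condition optional row of the plate map describing the well.
#' @param border_policy \code{"exclude_from_shape"} (default) or
#'   \code{"include"}.
#' @return One-row data.frame: well_id, n_fields, n_cells, n_green, n_red,
#'   mean_elong, mean_elong_green, mean_elong_red (NaN when a class is
#'   empty), plus any condition columns.
#' @export
summarize_well <- function(records, condition = NULL,
                           border_policy = c("exclude_from_shape",
                                             "include")) {
  border_policy <- match.arg(border_policy)
  if (nrow(records) > 1 && length(unique(records$well_id)) > 1)
    stop("records span multiple wells")
  shape <- if (border_policy == "exclude_from_shape")
    records[!records$border_touch, , drop = FALSE] else records
  mean_or_nan <- function(x) if (length(x)) mean(x) else NaN
  out <- data.frame(
    well_id = if (nrow(records)) records$well_id[1] else NA_character_,
    n_fields = length(unique(records$field_index)),
    n_cells = nrow(records),
    n_green = sum(records$green_pos %||% logical(0)),
    n_red = sum(records$red_pos %||% logical(0)),
    mean_elong = mean_or_nan(shape$elongation),
    mean_elong_green = mean_or_nan(shape$elongation[shape$green_pos]),
    mean_elong_red = mean_or_nan(shape$elongation[shape$red_pos]),
    stringsAsFactors = FALSE)
  if (!is.null(condition)) {
    for (cn in setdiff(names(condition), names(out)))
      out[[cn]] <- condition[[cn]]
  }
  out
}
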