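#' Assemble the screen's composite-Z matrix
#'
#' Arranges composite Z-scores as the heatmap structure of the screen: rows
#' are (agent, dose) pairs ordered by agent then ascending dose, columns are
#' (serum, measurement) pairs; conditions never scored are explicit NA cells.
#'
#' @param composites long-format data.frame from \code{\link{score_screen}}
#'   (agent, dose, serum, measurement, n, z_hat).
#' @return Object of class \code{screen_matrix}: list with \code{values}
#'   (numeric matrix), \code{rows} (data.frame agent, dose), \code{cols}
#'   (data.frame serum, measurement).
#' @export
build_matrix <- function(composites) {
  need <- c("agent", "dose", "serum", "measurement", "z_hat")
  miss <- setdiff(need, names(composites))
  if (length(miss)) stop("composites missing columns: ",
                         paste(miss, collapse = ", "))
  if (!nrow(composites)) stop("no composite Z-scores supplied")
  keys <- composites[c("agent", "dose", "serum", "measurement")]
  if (anyDuplicated(keys))
    stop("duplicate (agent, dose, serum, measurement) entries")
  rows <- unique(composites[c("agent", "dose")])
  rows <- rows[order(rows$agent, rows$dose), , drop = FALSE]
  cols <- unique(composites[c("serum", "measurement")])
  cols <- cols[order(cols$serum, cols$measurement), , drop = FALSE]
  rownames(rows) <- rownames(cols) <- NULL
  v <- matrix(NA_real_, nrow(rows), nrow(cols),
              dimnames = list(paste(rows$agent, signif(rows$dose, 6),
                                    sep = " @ "),
                              paste(cols$serum, cols$measurement,
                                    sep = ".")))
  ri <- match(paste(composites$agent, signif(composites$dose, 8)),
              paste(rows$agent, signif(rows$dose, 8)))
  ci <- match(paste(composites$serum, composites$measurement),
              paste(cols$serum, cols$measurement))
  v[cbind(ri, ci)] <- composites$z_hat
  structure(list(values = v, rows = rows, cols = cols),
            class = "screen_matrix")
}

#' @export
print.screen_matrix <- function(x, ...) {
  cat(sprintf("screen_matrix: %d (agent, dose) rows x %d (serum, measurement) columns\n",
              nrow(x$values), ncol(x$values)))
  print(round(x$values, 2))
  invisible(x)
}

#' Call per-agent hits from a composite-Z matrix
#'
#' An agent is a proliferation hit when its count composite Z reaches the
#' cutoff at \code{min_doses} or more doses (anti-proliferative when it
#' falls below -cutoff), and a differentiation hit when its elongation
#' composite Z departs from 0 past the cutoff in the configured direction.
#' Serum conditions are evaluated separately and a hit in either suffices.
#' The call classes are: \code{dual_phenotype} (proliferation up and
#' differentiation together in the same serum condition),
#' \code{anti_proliferative_differentiation} (proliferation down with
#' differentiation), \code{proliferation_only}, \code{differentiation_only},
#' \code{none}.
#'
#' By this package's convention the synthetic differentiation signature is a
#' RISE of the elongation composite (direction \code{"increase"}, the
#' default); \code{"decrease"} and \code{"either"} are available since the
#' minor/major ratio itself falls as cells become needle-like.
#'
#' @param mat a \code{\link{screen_matrix}} containing \code{count} and
#'   \code{elongation} measurements.
#' @param cutoff composite-Z magnitude required for significance (> 0).
#' @param min_doses number of doses that must pass the cutoff (>= 1).
#' @param elong_direction \code{"increase"}, \code{"decrease"} or
#'   \code{"either"}.
#' @return Object of class \code{hit_table}: data.frame with one row per
#'   agent (agent, call, max_z_count, max_z_elong, direction_count,
#'   direction_elong, n_doses_prolif, n_doses_diff), with the cutoff and
#'   rule recorded as attributes.
#' @export
call_hits <- function(mat, cutoff = 1.96, min_doses = 2L,
                      elong_direction = c("increase", "decrease", "either")) {
  stopifnot(inherits(mat, "screen_matrix"), cutoff > 0, min_doses >= 1)
  elong_direction <- match.arg(elong_direction)
  if (all(is.na(mat$values))) stop("empty screen matrix")
  agents <- unique(mat$rows$agent)
  serum_levels <- unique(mat$cols$serum)
  res <- vector("list", length(agents))
  for (ai in seq_along(agents)) {
    ag <- agents[ai]
    ri <- which(mat$rows$agent == ag)
    prolif_up <- prolif_down <- diff_hit <- FALSE
    np_best <- nd_best <- 0L
    for (s in serum_levels) {
      zc <- mat$values[ri, which(mat$cols$serum == s &
                                   mat$cols$measurement == "count")]
      ze <- mat$values[ri, which(mat$cols$serum == s &
                                   mat$cols$measurement == "elongation")]
      n_up <- sum(zc >= cutoff, na.rm = TRUE)
      n_dn <- sum(zc <= -cutoff, na.rm = TRUE)
      n_di <- switch(elong_direction,
                     increase = sum(ze >= cutoff, na.rm = TRUE),
                     decrease = sum(ze <= -cutoff, na.rm = TRUE),
                     either = sum(abs(ze) >= cutoff, na.rm = TRUE))
      # dual calls require both phenotypes in the same serum condition
      if (n_up >= min_doses && n_di >= min_doses) {
        prolif_up <- diff_hit <- TRUE
      }
      if (n_dn >= min_doses && n_di >= min_doses) {
        prolif_down <- diff_hit <- TRUE
      }
      if (n_up >= min_doses) prolif_up <- TRUE
      if (n_dn >= min_doses) prolif_down <- TRUE
      if (n_di >= min_doses) diff_hit <- TRUE
      np_best <- max(np_best, n_up, n_dn)
      nd_best <- max(nd_best, n_di)
    }
    # re-evaluate same-serum conjunctions for the dual classes
    dual <- anti <- FALSE
    for (s in serum_levels) {
      zc <- mat$values[ri, which(mat$cols$serum == s &
                                   mat$cols$measurement == "count")]
      ze <- mat$values[ri, which(mat$cols$serum == s &
                                   mat$cols$measurement == "elongation")]
      n_di <- switch(elong_direction,
                     increase = sum(ze >= cutoff, na.rm = TRUE),
                     decrease = sum(ze <= -cutoff, na.rm = TRUE),
                     either = sum(abs(ze) >= cutoff, na.rm = TRUE))
      if (sum(zc >= cutoff, na.rm = TRUE) >= min_doses && n_di >= min_doses)
        dual <- TRUE
      if (sum(zc <= -cutoff, na.rm = TRUE) >= min_doses && n_di >= min_doses)
        anti <- TRUE
    }
    call <- if (dual) "dual_phenotype"
    else if (anti) "anti_proliferative_differentiation"
    else if (diff_hit) "differentiation_only"
    else if (prolif_up || prolif_down) "proliferation_only"
    else "none"
    zc_all <- mat$values[ri, mat$cols$measurement == "count", drop = FALSE]
    ze_all <- mat$values[ri, mat$cols$measurement == "elongation",
                         drop = FALSE]
    maxabs <- function(v) if (all(is.na(v))) NA_real_ else
      v[which.max(abs(v))]
    mc <- maxabs(as.numeric(zc_all)); me <- maxabs(as.numeric(ze_all))
    res[[ai]] <- data.frame(
      agent = ag, call = call,
      max_z_count = mc, max_z_elong = me,
      direction_count = if (is.na(mc)) NA_character_ else
        if (mc >= 0) "up" else "down",
      direction_elong = if (is.na(me)) NA_character_ else
        if (me >= 0) "up" else "down",
      n_doses_prolif = np_best, n_doses_diff = nd_best,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, cutoff = cutoff, min_doses = as.integer(min_doses),
            elong_direction = elong_direction,
            class = c("hit_table", "data.frame"))
}

screen_matrix_df <- function(mat) {
  data.frame(agent = rep(mat$rows$agent, ncol(mat$values)),
             dose = rep(mat$rows$dose, ncol(mat$values)),
             serum = rep(mat$cols$serum, each = nrow(mat$values)),
             measurement = rep(mat$cols$measurement, each = nrow(mat$values)),
             z_hat = as.numeric(mat$values),
             stringsAsFactors = FALSE)
}

#' Write the screen report: matrices, hit table, heatmaps, manifest
#'
#' Writes the composite-Z matrix as CSV (long and wide), the hit table as
#' CSV, one heatmap PNG per measurement (red/blue diverging for
#' proliferation-style signed scores), and a JSON run manifest recording the
#' seed, a hash of the inputs and package/R versions.
#'
#' @param mat a \code{\link{screen_matrix}}.
#' @param hits a \code{\link{call_hits}} table.
#' @param out_dir output directory (created if needed).
#' @param seed the seed used to produce the inputs (recorded in the
#'   manifest).
#' @return Invisibly, the written paths.
#' @export
write_report <- function(mat, hits, out_dir, seed = NA_integer_) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p_long <- file.path(out_dir, "composite_z_long.csv")
  p_wide <- file.path(out_dir, "composite_z_matrix.csv")
  p_hits <- file.path(out_dir, "hit_table.csv")
  p_man <- file.path(out_dir, "manifest.json")
  long <- screen_matrix_df(mat)
  write.csv(long, p_long, row.names = FALSE)
  wide <- data.frame(mat$rows, mat$values, check.names = FALSE)
  write.csv(wide, p_wide, row.names = FALSE)
  write.csv(as.data.frame(hits), p_hits, row.names = FALSE)
  paths <- c(p_long, p_wide, p_hits, p_man)
  for (m in unique(mat$cols$measurement)) {
    sel <- mat$cols$measurement == m
    p <- file.path(out_dir, sprintf("heatmap_%s.png", m))
    v <- mat$values[, sel, drop = FALSE]
    png(p, width = 480 + 60 * ncol(v), height = 200 + 18 * nrow(v))
    pal <- colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
    lim <- max(abs(v), na.rm = TRUE); if (!is.finite(lim) || lim == 0) lim <- 1
    image(t(v[nrow(v):1, , drop = FALSE]), col = pal, zlim = c(-lim, lim),
          axes = FALSE, main = sprintf("composite Z (%s)", m))
    axis(2, at = seq(0, 1, length.out = nrow(v)),
         labels = rev(rownames(v)), las = 2, cex.axis = 0.6)
    axis(1, at = seq(0, 1, length.out = ncol(v)),
         labels = colnames(v)[] , las = 2, cex.axis = 0.7)
    dev.off()
    paths <- c(paths, p)
  }
  manifest <- list(
    seed = seed,
    input_hash = rlang::hash(list(mat$values, mat$rows, mat$cols)),
    cutoff = attr(hits, "cutoff"),
    min_doses = attr(hits, "min_doses"),
    elong_direction = attr(hits, "elong_direction"),
    package = as.character(packageVersion("phenoscreen")),
    r_version = R.version.string,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, p_man, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Null specificity of dual-phenotype hit calling
#'
#' Simulates whole screens of a single effect-free agent (summary level:
#' well counts and elongations drawn from the baseline distributions, then
#' scored and called exactly as a real screen) and reports how often the
#' null agent is called in each class. The dual-phenotype false-call rate is
#' the screen's key specificity figure; it depends strongly on the number of
#' vehicle-control wells per stratum, because the control SD is shared by
#' every dose-level composite on the plate.
#'
#' @param design screen design as in \code{\link{generate_plate}}; defaults
#'   to one null agent at the standard 7-dose series with the default
#'   control count.
#' @param n_screens number of simulated screens.
#' @param cutoff,min_doses,elong_direction hit-calling rule, see
#'   \code{\link{call_hits}}.
#' @param seed integer seed.
#' @return List: \code{dual_rate} (fraction of screens whose null agent is
#'   called dual_phenotype), \code{calls} (table of all calls),
#'   \code{n_screens}.
#' @export
screen_null_rate <- function(design = NULL, n_screens = 1000L,
                             cutoff = 1.96, min_doses = 2L,
                             elong_direction = "increase", seed = 1L) {
  design <- design %||% list(
    agents = data.frame(agent = "null_agent", dose_max = 100,
                        dose_unit = "nM"),
    n_replicates = 4L, serum = "low")
  seed <- as.integer(seed)
  calls <- vapply(seq_len(n_screens), function(i) {
    pl <- generate_plate(design, seed = (seed + i) %% 2147483647L)
    sm <- simulate_well_summaries(pl, seed = (seed + i + 777779L) %% 2147483647L)
    h <- call_hits(build_matrix(score_screen(sm, pl$plate_map)),
                   cutoff = cutoff, min_doses = min_doses,
                   elong_direction = elong_direction)
    h$call[1]
  }, "")
  list(dual_rate = mean(calls == "dual_phenotype"), calls = table(calls),
       n_screens = as.integer(n_screens))
}
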