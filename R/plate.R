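#' Agonists of the reference screen with their printed dose ranges
#'
#' The seven microenvironmental agonists screened against phenotype switching,
#' each with a 7-point 2-fold dilution series anchored at the top
#' concentration (e.g. EDN3 at 1.56--100 nM, SCF at 3.125--200 nM).
#'
#' @return A data.frame with columns \code{agent}, \code{dose_max},
#'   \code{dose_unit}, \code{n_doses}, \code{fold}.
#' @export
#' @examples
#' screen_agents()
screen_agents <- function() {
  data.frame(
    agent     = c("EDN1", "EDN3", "IGF1", "SCF", "LDL", "Dopamine", "L-DOPA"),
    dose_max  = c(100, 100, 50, 200, 40, 300, 300),
    dose_unit = c("nM", "nM", "uM", "nM", "uM", "uM", "uM"),
    n_doses   = 7L,
    fold      = 2,
    stringsAsFactors = FALSE
  )
}

#' Geometric dose series anchored at the top dose
#'
#' @param dose_max top concentration of the series.
#' @param n number of doses.
#' @param fold dilution factor between consecutive doses.
#' @return Increasing numeric vector of length \code{n} ending at
#'   \code{dose_max}.
#' @export
#' @examples
#' dose_series(100)     # 1.5625 ... 100 (a 1.56-100 range)
dose_series <- function(dose_max, n = 7L, fold = 2) {
  stopifnot(dose_max > 0, n >= 1, fold > 1)
  dose_max / fold^((n - 1):0)
}

#' Hill-type dose-response effect model for the synthetic generator
#'
#' Describes how an agent perturbs the two screen readouts. At dose d the
#' fractional occupancy is \code{d^hill / (d^hill + ec50^hill)}; expected cell
#' count is scaled by \code{1 + emax_count * occupancy} and mean elongation is
#' shifted additively by \code{emax_elong * occupancy} (clipped to (0, 1]).
#'
#' @param ec50 half-maximal concentration (> 0), in the agent's dose unit.
#' @param hill Hill exponent (> 0).
#' @param emax_count maximal fractional change in expected cell count
#'   (e.g. 1 doubles the count, -0.5 halves it; must be > -1).
#' @param emax_elong maximal additive change in mean elongation (ratio units).
#' @param noise_cv coefficient of variation of realized well-level counts.
#' @return An object of class \code{effect_model}.
#' @export
effect_model <- function(ec50, hill = 1, emax_count = 0, emax_elong = 0,
                         noise_cv = 0.1) {
  stopifnot(ec50 > 0, hill > 0, emax_count > -1, noise_cv >= 0)
  structure(list(ec50 = ec50, hill = hill, emax_count = emax_count,
                 emax_elong = emax_elong, noise_cv = noise_cv),
            class = "effect_model")
}

#' Null effect model (vehicle-like agent)
#' @param noise_cv coefficient of variation of well counts.
#' @export
null_effect_model <- function(noise_cv = 0.1) {
  effect_model(ec50 = 1, hill = 1, emax_count = 0, emax_elong = 0,
               noise_cv = noise_cv)
}

#' Apply an effect model to baseline well parameters
#'
#' @param dose concentration (same unit as the model's ec50); 0 for vehicle.
#' @param baseline list with \code{count} (> 0) and \code{mean_elong}
#'   in (0, 1].
#' @param model an \code{\link{effect_model}}.
#' @return List with \code{count} (expected cell count) and
#'   \code{mean_elong}; vehicle (dose 0) returns the baseline exactly.
#' @export
#' @examples
#' m <- effect_model(ec50 = 10, hill = 1, emax_count = 1, emax_elong = 0.2)
#' apply_effect_model(10, list(count = 100, mean_elong = 0.6), m)
apply_effect_model <- function(dose, baseline, model) {
  stopifnot(inherits(model, "effect_model"),
            baseline$count > 0,
            baseline$mean_elong > 0, baseline$mean_elong <= 1,
            dose >= 0)
  if (dose == 0) {
    return(list(count = baseline$count, mean_elong = baseline$mean_elong))
  }
  occ <- dose^model$hill / (dose^model$hill + model$ec50^model$hill)
  el_raw <- baseline$mean_elong + model$emax_elong * occ
  el <- min(max(el_raw, .Machine$double.eps), 1)
  if (el != el_raw) {
    warning("mean elongation clipped to (0, 1]: requested ",
            signif(el_raw, 4))
  }
  list(count = baseline$count * (1 + model$emax_count * occ),
       mean_elong = el)
}

well_ids_96 <- function() {
  paste0(rep(LETTERS[1:8], each = 12L),
         sprintf("%02d", rep(1:12, times = 8L)))
}

#' Design and lay out a synthetic screening plate set
#'
#' Builds a plate map (agents x dose series x serum levels x replicates, plus
#' same-plate vehicle-control wells in every (plate, serum) stratum) and draws
#' per-well generative parameters: the expected cell count and mean elongation
#' after applying each agent's dose-response effect model to the baseline.
#' Wells whose serum stratum would exceed the 96-well capacity are laid out on
#' additional plates, each receiving its own control wells so every treated
#' well has matched same-plate controls.
#'
#' @param design list describing the screen:
#'   \describe{
#'     \item{agents}{data.frame with columns \code{agent}, \code{dose_max},
#'       \code{dose_unit} and optionally \code{n_doses}, \code{fold}
#'       (see \code{\link{screen_agents}}).}
#'     \item{effects}{named list of \code{\link{effect_model}} objects, one
#'       per agent; missing agents get the null model.}
#'     \item{n_replicates}{replicate wells per (agent, dose, serum); >= 2.}
#'     \item{serum}{character vector of serum levels, default
#'       \code{c("low", "high")}.}
#'     \item{controls_per_stratum}{vehicle wells per (plate, serum) stratum;
#'       >= 2, default 24. The default is sized so the per-stratum control
#'       mean and SD are stable enough that dual-phenotype hit calling at
#'       the default cutoff keeps its false-call rate below 1\% (see
#'       \code{\link{screen_null_rate}}); with fewer controls the noisy
#'       shared SD correlates all dose-level composites of a plate.}
#'     \item{baseline_count}{expected vehicle-well cell count per field
#'       (default 120).}
#'     \item{baseline_elong}{vehicle mean elongation (default 0.60).}
#'     \item{noise_cv}{CV of realized well counts (default 0.1).}
#'   }
#' @param seed integer seed; the same (design, seed) reproduces the plate map
#'   and parameters exactly.
#' @return List with \code{plate_map} (data.frame: plate_id, well_id, agent,
#'   dose, dose_unit, serum, replicate_group, is_control) and
#'   \code{well_params} (data.frame keyed by plate_id/well_id with expected
#'   \code{count}, \code{mean_elong}, realized \code{n_cells},
#'   \code{green_frac}, \code{red_frac}).
#' @export
generate_plate <- function(design, seed = 1L) {
  stopifnot(is.list(design), is.data.frame(design$agents))
  agents <- design$agents
  if (is.null(agents$n_doses)) agents$n_doses <- 7L
  if (is.null(agents$fold)) agents$fold <- 2
  n_rep <- design$n_replicates %||% 4L
  serum <- design$serum %||% c("low", "high")
  n_ctrl <- design$controls_per_stratum %||% 24L
  if (n_rep < 2) stop("need n_replicates >= 2")
  if (n_ctrl < 2) stop("need >= 2 control wells per (plate, serum) stratum")
  base_count <- design$baseline_count %||% 120
  base_elong <- design$baseline_elong %||% 0.60
  noise_cv <- design$noise_cv %||% 0.1
  effects <- design$effects %||% list()

  treated <- do.call(rbind, lapply(seq_len(nrow(agents)), function(i) {
    doses <- dose_series(agents$dose_max[i], agents$n_doses[i], agents$fold[i])
    expand.grid(agent = agents$agent[i], dose = doses,
                dose_unit = agents$dose_unit[i], serum = serum,
                replicate = seq_len(n_rep),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  }))

  # lay out plates: one serum stratum never splits a (agent, dose) replicate
  # block across plates; each plate gets its own fresh controls per stratum
  capacity <- 96L
  plates <- list()
  plate_no <- 0L
  for (s in serum) {
    ts <- treated[treated$serum == s, , drop = FALSE]
    per_plate <- capacity - n_ctrl
    if (per_plate < n_rep) stop("controls_per_stratum leaves no room for wells")
    idx <- seq_len(nrow(ts))
    chunks <- split(idx, ceiling(idx / per_plate))
    for (ch in chunks) {
      plate_no <- plate_no + 1L
      pid <- sprintf("P%02d", plate_no)
      blk <- ts[ch, , drop = FALSE]
      ctrl <- data.frame(agent = "vehicle", dose = 0, dose_unit = blk$dose_unit[1],
                         serum = s, replicate = seq_len(n_ctrl),
                         stringsAsFactors = FALSE)
      pm <- rbind(blk, ctrl)
      pm$plate_id <- pid
      pm$well_id <- well_ids_96()[seq_len(nrow(pm))]
      plates[[pid]] <- pm
    }
  }
  pm <- do.call(rbind, plates)
  rownames(pm) <- NULL
  pm$is_control <- pm$agent == "vehicle"
  pm$replicate_group <- paste(pm$agent, signif(pm$dose, 6), pm$serum, sep = "|")
  if (anyDuplicated(pm[c("plate_id", "well_id")]))
    stop("duplicate well assignment")
  pm <- pm[c("plate_id", "well_id", "agent", "dose", "dose_unit", "serum",
             "replicate_group", "is_control")]

  # every treated stratum must have matched same-plate controls
  for (pid in unique(pm$plate_id)) {
    p <- pm[pm$plate_id == pid, ]
    for (s in unique(p$serum)) {
      if (sum(p$is_control & p$serum == s) < 2 && any(!p$is_control & p$serum == s))
        stop("stratum (", pid, ", ", s, ") has no controls")
    }
  }

  set.seed(as.integer(seed))
  baseline <- list(count = base_count, mean_elong = base_elong)
  wp <- lapply(seq_len(nrow(pm)), function(i) {
    ag <- pm$agent[i]
    em <- if (pm$is_control[i]) NULL else effects[[ag]]
    exp_par <- if (is.null(em)) baseline else
      apply_effect_model(pm$dose[i], baseline, em)
    cv <- if (is.null(em)) noise_cv else em$noise_cv
    n_cells <- max(0L, round(rnorm(1, exp_par$count, cv * exp_par$count)))
    data.frame(plate_id = pm$plate_id[i], well_id = pm$well_id[i],
               count = exp_par$count, mean_elong = exp_par$mean_elong,
               n_cells = n_cells,
               green_frac = design$green_frac %||% 0.6,
               red_frac = design$red_frac %||% 0.4,
               stringsAsFactors = FALSE)
  })
  list(plate_map = pm, well_params = do.call(rbind, wp))
}

#' Write / read a plate map CSV
#'
#' Columns: plate_id, well_id, agent, dose, dose_unit, serum,
#' replicate_group, is_control.
#'
#' @param plate_map data.frame as returned in \code{generate_plate()$plate_map}.
#' @param path CSV file path.
#' @export
write_plate_map <- function(plate_map, path) {
  write.csv(plate_map, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_map
#' @export
read_plate_map <- function(path) {
  pm <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("plate_id", "well_id", "agent", "dose", "dose_unit", "serum",
            "replicate_group", "is_control")
  miss <- setdiff(need, names(pm))
  if (length(miss)) stop("plate map missing columns: ", paste(miss, collapse = ", "))
  pm$is_control <- as.logical(pm$is_control)
  pm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
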