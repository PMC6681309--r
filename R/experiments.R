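# In-silico experiment drivers: each "animal" is a synthetic head phantom
# whose mucosa thickness follows the swelling model; the mucosa index is
# measured through the full imaging pipeline (generate volume -> landmark
# plan -> reslice -> ROI -> bi-threshold -> index).

#' Configuration for the in-silico experiments
#'
#' Defaults mirror the experimental designs being emulated: methacholine
#' doses PBS/0.5/1.0/2.0 mg/mL, observation times 0/15/60/120 min, and
#' group sizes in the 3-6 animals/group range.
#'
#' @param doses Dose levels, mg/mL (0 = PBS).
#' @param times Observation times for the kinetics driver, minutes.
#' @param groups Group names for the dose-response driver (must be names of
#'   the model's multipliers); the first is the reference.
#' @param n_per_group Animals per cell (>= 2 so groups can be tested).
#' @param dose Single dose used by the kinetics and treatment drivers,
#'   mg/mL.
#' @param time_min Observation time for dose-response and treatment
#'   drivers, minutes.
#' @param model A [swelling_model()].
#' @param phantom A [phantom_spec()] template; experiment phantoms default
#'   to 40 um voxels and 20 HU noise to keep simulated cohorts fast.
#' @param axis `"axial"` or `"coronal"` measurement plan.
#' @param seed Integer seed; every driver is reproducible given the config.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(doses = c(0, 0.5, 1, 2),
                              times = c(0, 15, 60, 120),
                              groups = c("control", "AR"),
                              n_per_group = 5L,
                              dose = 1,
                              time_min = 15,
                              model = swelling_model(),
                              phantom = phantom_spec(spacing = 0.04,
                                                     noise_sd = 20),
                              axis = c("axial", "coronal"),
                              seed = 1L) {
  axis <- match.arg(axis)
  if (n_per_group < 1L) stop("n_per_group must be >= 1", call. = FALSE)
  if (any(doses < 0) || any(times < 0))
    stop("doses and times must be non-negative", call. = FALSE)
  if (!all(groups %in% names(model$multipliers)))
    stop("unknown group(s): ",
         paste(setdiff(groups, names(model$multipliers)), collapse = ", "),
         call. = FALSE)
  structure(list(doses = doses, times = times, groups = groups,
                 n_per_group = as.integer(n_per_group), dose = dose,
                 time_min = time_min, model = model, phantom = phantom,
                 axis = axis, seed = as.integer(seed)),
            class = "experiment_config")
}

# Measure one simulated animal through the full pipeline.
.simulate_animal <- function(config, dose, time_min, group, t0, noise_seed) {
  spec <- config$phantom
  spec$seed <- noise_seed
  spec <- swell(spec, dose = dose, time_min = time_min,
                model = config$model, group = group, t0 = t0)
  ph <- generate_phantom(spec)
  plan <- if (config$axis == "axial")
    build_axial_plan(ph$truth$landmarks) else
      build_coronal_plan(ph$truth$landmarks)
  rois <- phantom_rois(ph$truth, plan)
  measure_volume(ph$volume, plan, rois)$value
}

# Simulate all cells of a factorial design; cells is a data.frame with
# columns group, dose, time. Returns the tidy per-animal table.
.simulate_cells <- function(config, cells) {
  n <- config$n_per_group
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  total <- nrow(cells) * n
  t0s <- config$model$t0 +
    stats::rnorm(total, 0, config$model$t0_sd)
  t0s <- pmax(t0s, 0.02)  # keep a physical, positive baseline
  noise_seeds <- sample.int(.Machine$integer.max - 1L, total)
  rows <- vector("list", total)
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (a in seq_len(n)) {
      k <- k + 1L
      idx <- .simulate_animal(config, dose = cells$dose[ci],
                              time_min = cells$time[ci],
                              group = cells$group[ci],
                              t0 = t0s[k], noise_seed = noise_seeds[k])
      rows[[k]] <- data.frame(group = cells$group[ci],
                              dose = cells$dose[ci],
                              time_min = cells$time[ci],
                              animal_id = sprintf("%s_d%g_t%g_%02d",
                                                  cells$group[ci],
                                                  cells$dose[ci],
                                                  cells$time[ci], a),
                              index = idx,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

.cell_values <- function(samples, group, dose, time_min)
  samples$index[samples$group == group & samples$dose == dose &
                  samples$time_min == time_min]

.summ_row <- function(values, test = NULL) {
  s <- summarize_group(values)
  data.frame(n = s$n, mean = s$mean, sem = s$sem,
             U = if (is.null(test)) NA_real_ else test$U,
             p = if (is.null(test)) NA_real_ else test$p_value,
             significant = if (is.null(test)) NA else test$significant)
}

.check_testable <- function(config) {
  if (config$n_per_group < 2L)
    stop("group comparisons need at least 2 animals per group (got n = ",
         config$n_per_group, ")", call. = FALSE)
}

#' Simulated dose-response experiment
#'
#' For every (group, dose) cell, simulates `n_per_group` phantom animals at
#' `time_min` and measures their mucosa indices through the imaging
#' pipeline. Each cell is summarized (mean, SEM) and tested two ways: within
#' group against its dose-0 (PBS) cell, and against the reference (first)
#' group at the same dose.
#'
#' @param config An [experiment_config()].
#' @return List with `samples` (tidy per-animal data.frame) and `summary`
#'   (one row per cell with mean, sem, and `p_vs_dose0`, `p_vs_ref`
#'   Mann-Whitney results).
#' @export
run_dose_response <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  .check_testable(config)
  cells <- expand.grid(group = config$groups, dose = config$doses,
                       stringsAsFactors = FALSE)
  cells$time <- config$time_min
  samples <- .simulate_cells(config, cells)
  ref_group <- config$groups[1]
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    g <- cells$group[ci]; d <- cells$dose[ci]
    vals <- .cell_values(samples, g, d, config$time_min)
    base <- .cell_values(samples, g, config$doses[1], config$time_min)
    t0 <- if (d != config$doses[1]) mann_whitney_u(vals, base) else NULL
    refv <- .cell_values(samples, ref_group, d, config$time_min)
    tr <- if (g != ref_group) mann_whitney_u(vals, refv) else NULL
    s <- summarize_group(vals)
    out[[ci]] <- data.frame(
      group = g, dose = d, n = s$n, mean = s$mean, sem = s$sem,
      U_vs_dose0 = if (is.null(t0)) NA_real_ else t0$U,
      p_vs_dose0 = if (is.null(t0)) NA_real_ else t0$p_value,
      sig_vs_dose0 = if (is.null(t0)) NA else t0$significant,
      U_vs_ref = if (is.null(tr)) NA_real_ else tr$U,
      p_vs_ref = if (is.null(tr)) NA_real_ else tr$p_value,
      sig_vs_ref = if (is.null(tr)) NA else tr$significant,
      stringsAsFactors = FALSE)
  }
  list(samples = samples, summary = do.call(rbind, out))
}

#' Simulated kinetics experiment
#'
#' Simulates cohorts observed at each time point after one dose and tests
#' every later time point against the time-0 (baseline) cohort.
#'
#' @param config An [experiment_config()]; uses `times`, `dose`, and the
#'   first entry of `groups`.
#' @return List with `samples` and `summary` (per time point: mean, sem,
#'   U, p, significant vs time 0).
#' @export
run_kinetics <- function(config = experiment_config()) {
  stopifnot(inherits(config, "experiment_config"))
  .check_testable(config)
  g <- config$groups[1]
  cells <- data.frame(group = g, dose = config$dose, time = config$times,
                      stringsAsFactors = FALSE)
  samples <- .simulate_cells(config, cells)
  base <- samples$index[samples$time_min == config$times[1]]
  out <- list()
  for (ti in seq_along(config$times)) {
    tm <- config$times[ti]
    vals <- samples$index[samples$time_min == tm]
    tst <- if (ti > 1L) mann_whitney_u(vals, base) else NULL
    s <- summarize_group(vals)
    out[[ti]] <- data.frame(
      group = g, dose = config$dose, time_min = tm, n = s$n,
      mean = s$mean, sem = s$sem,
      U = if (is.null(tst)) NA_real_ else tst$U,
      p = if (is.null(tst)) NA_real_ else tst$p_value,
      significant = if (is.null(tst)) NA else tst$significant,
      stringsAsFactors = FALSE)
  }
  list(samples = samples, summary = do.call(rbind, out))
}

#' Simulated treatment-comparison experiment
#'
#' Three groups at one dose and time: healthy controls (PBS-pretreated),
#' allergic-rhinitis animals (PBS-pretreated), and allergic-rhinitis animals
#' pretreated with dexamethasone. Pairwise Mann-Whitney tests: AR vs
#' control, AR+dex vs AR, and AR+dex vs control.
#'
#' @param config An [experiment_config()]; group multipliers `control`,
#'   `AR`, `AR_dex` must exist in the model.
#' @return List with `samples`, `summary` (per group mean/sem), and
#'   `tests` (one row per pairwise comparison).
#' @export
run_treatment <- function(config = experiment_config(n_per_group = 6L)) {
  stopifnot(inherits(config, "experiment_config"))
  .check_testable(config)
  groups <- c("control", "AR", "AR_dex")
  if (!all(groups %in% names(config$model$multipliers)))
    stop("model must define multipliers control, AR, AR_dex", call. = FALSE)
  cells <- data.frame(group = groups, dose = config$dose,
                      time = config$time_min, stringsAsFactors = FALSE)
  samples <- .simulate_cells(config, cells)
  val <- function(g) .cell_values(samples, g, config$dose, config$time_min)
  summ <- do.call(rbind, lapply(groups, function(g) {
    s <- summarize_group(val(g))
    data.frame(group = g, n = s$n, mean = s$mean, sem = s$sem,
               stringsAsFactors = FALSE)
  }))
  pairs <- list(c("AR", "control"), c("AR_dex", "AR"), c("AR_dex", "control"))
  tests <- do.call(rbind, lapply(pairs, function(p) {
    tst <- mann_whitney_u(val(p[1]), val(p[2]))
    data.frame(comparison = paste(p[1], "vs", p[2]), U = tst$U,
               p = tst$p_value, significant = tst$significant,
               stringsAsFactors = FALSE)
  }))
  list(samples = samples, summary = summ, tests = tests)
}
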