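#' Measurement-noise model for synthetic traces
#'
#' Additive white Gaussian noise with standard deviation expressed as a
#' fraction of the clean trace's dynamic range.
#'
#' @param additive_sd Noise SD as a fraction of dynamic range (default
#'   0.01).
#' @param seed Integer RNG seed.
#' @return An object of class `"noise_model"`.
#' @export
noise_model <- function(additive_sd = 0.01, seed = 1L) {
  .check_nonneg(additive_sd, "additive_sd")
  structure(list(additive_sd = additive_sd, seed = as.integer(seed)),
            class = "noise_model")
}

#' Synthetic plate-reader experiment template
#'
#' Describes one simulated well or cell: the receptor population and its
#' ligand, the gating and store parameters, and the experimental timeline
#' (ATP starts SERCA loading from a partially filled store; the SERCA
#' inhibitor starts the leak-only decay; ligand additions follow; an
#' antagonist optionally stops IP3R release).
#'
#' @param id Template label.
#' @param receptors_total Total receptors in the simulated unit.
#' @param kd Ligand K_D, nM.
#' @param rates A [gating_rates()].
#' @param er An [er_params()]; its `C_ER_init` is the store content at the
#'   start of the record (before loading).
#' @param schedule data.frame with columns `time_s` and `concentration_nM`
#'   (cumulative final concentrations); may have zero rows.
#' @param sampling_interval Plate-reader sampling interval, s (default
#'   1.44).
#' @param duration Record length, s.
#' @param cells Cells sharing the receptor population (1 for a single
#'   cell).
#' @param atp_time SERCA loading start, s (`NULL` for no loading phase).
#' @param serca_inhibitor_time SERCA inhibition time, s (`NULL` keeps SERCA
#'   active to the end of the record).
#' @param antagonist_time Optional antagonist addition, s.
#' @param calibration Linear fluorescence map `c(a = , b = )` with
#'   fluorescence = a * content + b (default identity, i.e. calibrated
#'   traces in uM).
#' @return An object of class `"experiment_template"`.
#' @export
experiment_template <- function(id, receptors_total, kd = 794,
                                rates = gating_rates(),
                                er = er_params(C_ER_init = 250),
                                schedule = data.frame(time_s = numeric(),
                                                      concentration_nM = numeric()),
                                sampling_interval = 1.44, duration,
                                cells = 1, atp_time = 50,
                                serca_inhibitor_time = 450,
                                antagonist_time = NULL,
                                calibration = c(a = 1, b = 0)) {
  stopifnot(inherits(rates, "gating_rates"), inherits(er, "er_params"),
            is.data.frame(schedule))
  .check_pos(sampling_interval, "sampling_interval")
  .check_pos(duration, "duration")
  .check_pos(cells, "cells")
  if (nrow(schedule) > 0) {
    if (!all(c("time_s", "concentration_nM") %in% names(schedule))) {
      stop("'schedule' needs columns 'time_s' and 'concentration_nM'")
    }
    if (any(schedule$time_s < 0) || any(schedule$time_s > duration)) {
      stop("schedule events must lie within [0, duration]")
    }
  }
  for (tv in c(atp_time, serca_inhibitor_time, antagonist_time)) {
    if (!is.null(tv) && (tv < 0 || tv > duration)) {
      stop("event times must lie within [0, duration]")
    }
  }
  structure(list(id = id, receptors_total = receptors_total, kd = kd,
                 rates = rates, er = er, schedule = schedule,
                 sampling_interval = sampling_interval, duration = duration,
                 cells = cells, atp_time = atp_time,
                 serca_inhibitor_time = serca_inhibitor_time,
                 antagonist_time = antagonist_time,
                 calibration = calibration),
            class = "experiment_template")
}

#' @export
print.experiment_template <- function(x, ...) {
  cat(sprintf(
    "Template '%s': %s receptors (%g cells), K_D %g nM, %g s at %g s\n",
    x$id, format(x$receptors_total, big.mark = ","), x$cells, x$kd,
    x$duration, x$sampling_interval))
  if (nrow(x$schedule)) {
    cat("  additions:",
        paste(sprintf("%g nM @ %g s", x$schedule$concentration_nM,
                      x$schedule$time_s), collapse = ", "), "\n")
  } else cat("  additions: none (leak only)\n")
  invisible(x)
}

#' Ready-made experiment templates
#'
#' The standard study conditions: 96-well HEK-IP3R1 populations
#' (4e5 cells/well, ~2e10 receptors/well, sequential 60/90/120 nM
#' additions), a single wild-type HEK cell (9,101 receptors, 143/177/219 nM
#' giving 5/10/20 tetra-liganded receptors), a direct single addition of
#' the incremental protocol's final concentration, a strong direct release
#' (300 nM), an antagonist run with SERCA kept active, and a leak-only
#' control. Additions are spaced 150 s apart; loading runs from 50 s to
#' SERCA inhibition at 450 s, stimulation from 950 s.
#'
#' @return Named list of [experiment_template()] objects:
#'   `population_96well`, `incremental`, `direct`, `direct_release`,
#'   `single_cell`, `antagonist`, `leak_only`.
#' @examples
#' names(template_library())
#' @export
template_library <- function() {
  pop <- experiment_template(
    id = "population_96well", receptors_total = 2e10, cells = 4e5,
    schedule = data.frame(time_s = c(950, 1100, 1250),
                          concentration_nM = c(60, 90, 120)),
    duration = 1400)
  inc <- pop
  inc$id <- "incremental"
  direct <- experiment_template(
    id = "direct", receptors_total = 2e10, cells = 4e5,
    schedule = data.frame(time_s = 1250, concentration_nM = 120),
    duration = 1400)
  strong <- experiment_template(
    id = "direct_release", receptors_total = 2e10, cells = 4e5,
    schedule = data.frame(time_s = 950, concentration_nM = 300),
    duration = 1200)
  single <- experiment_template(
    id = "single_cell", receptors_total = 9101, cells = 1,
    schedule = data.frame(time_s = c(950, 1100, 1250),
                          concentration_nM = c(143, 177, 219)),
    duration = 1400)
  antag <- experiment_template(
    id = "antagonist", receptors_total = 2e10, cells = 4e5,
    er = er_params(C_ER_init = 250, serca_active = TRUE),
    schedule = data.frame(time_s = 600, concentration_nM = 1000),
    duration = 1100, serca_inhibitor_time = NULL, antagonist_time = 800)
  leak <- experiment_template(
    id = "leak_only", receptors_total = 2e10, cells = 4e5,
    duration = 1400)
  list(population_96well = pop, incremental = inc, direct = direct,
       direct_release = strong, single_cell = single, antagonist = antag,
       leak_only = leak)
}

#' Generate a synthetic luminal fluorescence trace
#'
#' Runs the forward model (stochastic gating + ER store integration) over a
#' template's timeline, maps the store content to fluorescence through the
#' template's linear calibration, samples at the plate-reader interval and
#' adds white measurement noise. The returned trace carries a ground-truth
#' bundle (true open-receptor and store trajectories at the sampling grid,
#' all parameters, the seed) in `attr(, "ground_truth")` for recovery
#' scoring. Identical `(template, noise, seed)` regenerate the trace
#' bitwise.
#'
#' @param template An [experiment_template()].
#' @param noise A [noise_model()].
#' @param seed Integer RNG seed (defaults to the noise model's seed).
#' @return A [fluorescence_trace()] with annotations set from the template
#'   and a `ground_truth` attribute.
#' @examples
#' \donttest{
#' tpl <- template_library()$single_cell
#' tr <- generate_trace(tpl, noise_model(0.01, seed = 7))
#' }
#' @export
generate_trace <- function(template, noise = noise_model(),
                           seed = noise$seed) {
  stopifnot(inherits(template, "experiment_template"),
            inherits(noise, "noise_model"))
  fwd <- .simulate_template(template, seed)
  full_t <- fwd$time
  o4 <- fwd$o4
  cer <- fwd$C_ER

  tg <- seq(0, template$duration, by = template$sampling_interval)
  cer_g <- stats::approx(full_t, cer, xout = tg)$y
  o4_g <- stats::approx(full_t, o4, xout = tg)$y
  a <- template$calibration[["a"]]
  b <- template$calibration[["b"]]
  clean <- a * cer_g + b
  rng <- diff(range(clean))
  sd_abs <- noise$additive_sd * (if (rng > 0) rng else abs(mean(clean)))
  values <- clean + stats::rnorm(length(clean), 0, sd_abs)

  ann <- list()
  if (!is.null(template$atp_time)) ann$atp <- template$atp_time
  if (!is.null(template$serca_inhibitor_time)) {
    ann$serca_inhibitor <- template$serca_inhibitor_time
  }
  if (nrow(template$schedule)) ann$stimulus <- template$schedule$time_s[1]
  if (!is.null(template$antagonist_time)) {
    ann$antagonist <- template$antagonist_time
  }

  out <- fluorescence_trace(tg, values, annotations = ann,
                            calibration = template$calibration)
  r <- template$rates
  e <- template$er
  attr(out, "ground_truth") <- list(
    truth = data.frame(time_s = tg, O4_true = o4_g, C_ER_true_uM = cer_g),
    template_id = template$id, seed = as.integer(seed),
    noise_sd = sd_abs,
    er_params = list(k_leak = e$k_leak, k_rel = e$k_rel, C_cyt = e$C_cyt,
                     C_ER_init = e$C_ER_init, tau_SERCA = e$tau_SERCA,
                     releasable_fraction = e$releasable_fraction),
    rates = list(k1 = r$k1, k2 = r$k2, k3 = r$k3,
                 reverse_factor = r$reverse_factor, dt = r$dt),
    occupancy = list(kd = template$kd,
                     receptors_total = template$receptors_total,
                     cells = template$cells))
  out
}

# forward model over a template timeline: stochastic gating at the
# template schedule, ER pools with the SERCA window (atp ->
# serca_inhibitor) and optional antagonist cut-off of k_rel
.simulate_template <- function(template, seed) {
  dt <- template$rates$dt
  n_steps <- ceiling(template$duration / dt)
  full_t <- seq(0, by = dt, length.out = n_steps + 1L)
  if (nrow(template$schedule) > 0) {
    protocol <- addition_protocol(template$schedule$time_s,
                                  template$schedule$concentration_nM,
                                  kd = template$kd,
                                  receptors_total = template$receptors_total)
    gtraj <- simulate_protocol(protocol, template$rates, seed = seed,
                               duration = template$duration)
    o4 <- gtraj$O4
  } else {
    set.seed(seed, kind = "Mersenne-Twister")
    gtraj <- NULL
    o4 <- rep(0, n_steps + 1L)
  }
  serca_on <- if (is.null(template$atp_time)) rep(FALSE, length(full_t))
    else if (is.null(template$serca_inhibitor_time)) {
      full_t >= template$atp_time
    } else {
      full_t >= template$atp_time & full_t < template$serca_inhibitor_time
    }
  krel_on <- if (is.null(template$antagonist_time)) rep(TRUE, length(full_t))
    else full_t < template$antagonist_time
  pools <- .integrate_er_core(o4 / template$cells, dt, template$er,
                              serca_on = serca_on, krel_on = krel_on)
  list(time = full_t, o4 = o4, gating = gtraj,
       releasable = pools$releasable,
       C_ER = pools$releasable + pools$nonreleasable)
}

#' Generate a synthetic dose-response dataset
#'
#' Hill-curve responses plus additive Gaussian noise, for fit-recovery
#' testing. The generating parameters travel with the result.
#'
#' @param midpoint Generating EC50/IC50, nM.
#' @param hill Generating Hill coefficient.
#' @param top,bottom Generating plateaus.
#' @param concentrations Concentration grid, nM (should span the midpoint).
#' @param noise_sd Noise SD as a fraction of the top-bottom span.
#' @param seed Integer RNG seed.
#' @return data.frame with `concentration_nM`, `response`; the generating
#'   parameters in `attr(, "ground_truth")`.
#' @export
generate_binding_dataset <- function(midpoint, hill = 1, top = 100,
                                     bottom = 0,
                                     concentrations =
                                       10^seq(0, 4, length.out = 12),
                                     noise_sd = 0, seed = 1L) {
  .check_nonneg(concentrations, "concentrations")
  if (min(concentrations[concentrations > 0]) > midpoint ||
      max(concentrations) < midpoint) {
    stop("'concentrations' must span the midpoint")
  }
  set.seed(seed, kind = "Mersenne-Twister")
  y <- hill_response(concentrations, midpoint, hill, top, bottom) +
    stats::rnorm(length(concentrations), 0, noise_sd * (top - bottom))
  out <- data.frame(concentration_nM = concentrations, response = y)
  attr(out, "ground_truth") <- list(midpoint = midpoint, hill = hill,
                                    top = top, bottom = bottom,
                                    noise_sd = noise_sd,
                                    seed = as.integer(seed))
  out
}
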