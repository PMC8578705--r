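#' ER store parameters
#'
#' Parameters of the luminal Ca2+ balance
#' `dC_ER/dt = -(k_leak + k_rel * O4) * (C_ER - C) [+ (500 - C_ER)/tau]`:
#' a first-order IP3-independent leak, release through open IP3Rs, a
#' clamped cytosolic free Ca2+, and optional SERCA refill toward the
#' 500 uM loading plateau. The store is partitioned at the start of each
#' integration into a releasable pool (`releasable_fraction` of the
#' content, the only pool the `k_rel * O4` term can drain) and a
#' non-releasable remainder; the leak acts on the total.
#'
#' @param k_leak Leak rate constant, 1/s (default 1.8e-4).
#' @param k_rel Release rate constant per open receptor, 1/s (default
#'   8e-4).
#' @param C_cyt Clamped cytosolic free Ca2+, uM (default 0.22).
#' @param C_ER_init Initial luminal free Ca2+, uM (default 500).
#' @param tau_SERCA SERCA refill time constant, s (default 100).
#' @param releasable_fraction Fraction of the store available to IP3R
#'   release (default 0.8).
#' @param serca_active Whether refill is on (default FALSE, as after SERCA
#'   inhibition).
#' @return An object of class `"er_params"`. The refill target is the
#'   500 uM plateau, a fixed constant of the refill term, not a parameter.
#' @export
er_params <- function(k_leak = 1.8e-4, k_rel = 8e-4, C_cyt = 0.22,
                      C_ER_init = 500, tau_SERCA = 100,
                      releasable_fraction = 0.8, serca_active = FALSE) {
  .check_nonneg(k_leak, "k_leak")
  .check_nonneg(k_rel, "k_rel")
  .check_nonneg(C_cyt, "C_cyt")
  .check_pos(C_ER_init, "C_ER_init")
  .check_pos(tau_SERCA, "tau_SERCA")
  if (!is.numeric(releasable_fraction) || releasable_fraction <= 0 ||
      releasable_fraction > 1) {
    stop("'releasable_fraction' must be in (0, 1]")
  }
  if (C_ER_init <= C_cyt) stop("'C_ER_init' must exceed 'C_cyt'")
  structure(list(k_leak = k_leak, k_rel = k_rel, C_cyt = C_cyt,
                 C_ER_init = C_ER_init, tau_SERCA = tau_SERCA,
                 releasable_fraction = releasable_fraction,
                 serca_active = isTRUE(serca_active),
                 refill_target = 500), class = "er_params")
}

#' @export
print.er_params <- function(x, ...) {
  cat(sprintf(
    "ER params: k_leak %g /s, k_rel %g /s, C_cyt %g uM, C_ER(0) %g uM,\n",
    x$k_leak, x$k_rel, x$C_cyt, x$C_ER_init))
  cat(sprintf("  tau_SERCA %g s (%s), releasable %g%%\n", x$tau_SERCA,
              if (x$serca_active) "active" else "inhibited",
              100 * x$releasable_fraction))
  invisible(x)
}

#' HEK-cell geometry for ER Ca2+ accounting
#'
#' @param cell_volume Whole-cell volume, L (default 1.1e-12).
#' @param nuclear_fraction Fraction of the cell occupied by the nucleus
#'   (default 0.10).
#' @param er_fraction Fraction of the remaining cytoplasm occupied by ER
#'   (default 0.35).
#' @param buffer_ratio Total/free luminal Ca2+ ratio (default 5).
#' @param free_luminal_Ca Free luminal Ca2+, uM (default 500).
#' @param channel_flux Ca2+ flux through one open receptor, ions/s
#'   (default 5e5).
#' @return An object of class `"cell_geometry"` with the derived
#'   `er_volume` (L).
#' @export
cell_geometry <- function(cell_volume = 1.1e-12, nuclear_fraction = 0.10,
                          er_fraction = 0.35, buffer_ratio = 5,
                          free_luminal_Ca = 500, channel_flux = 5e5) {
  .check_pos(cell_volume, "cell_volume")
  for (nm in c("nuclear_fraction", "er_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      stop("'", nm, "' must be in (0, 1)")
    }
  }
  .check_pos(buffer_ratio, "buffer_ratio")
  .check_pos(free_luminal_Ca, "free_luminal_Ca")
  .check_pos(channel_flux, "channel_flux")
  structure(list(cell_volume = cell_volume,
                 nuclear_fraction = nuclear_fraction,
                 er_fraction = er_fraction, buffer_ratio = buffer_ratio,
                 free_luminal_Ca = free_luminal_Ca,
                 channel_flux = channel_flux,
                 er_volume = cell_volume * (1 - nuclear_fraction) *
                   er_fraction),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(
    "Cell geometry: cell %.3g L, ER %.3g L, buffer ratio %g, free %g uM,\n",
    x$cell_volume, x$er_volume, x$buffer_ratio, x$free_luminal_Ca))
  cat(sprintf("  single-channel flux %g ions/s\n", x$channel_flux))
  invisible(x)
}

.AVOGADRO <- 6.02214076e23

#' Total ER Ca2+ content of a single cell
#'
#' content (mol) = free luminal Ca2+ x buffer ratio x ER volume, with ER
#' volume = cell volume x (1 - nuclear fraction) x ER fraction of the
#' remaining cytoplasm. Defaults give ~9e-16 mol for a HEK cell.
#'
#' @param geometry A [cell_geometry()].
#' @return Total ER Ca2+, mol.
#' @export
er_calcium_content <- function(geometry = cell_geometry()) {
  stopifnot(inherits(geometry, "cell_geometry"))
  geometry$free_luminal_Ca * 1e-6 * geometry$buffer_ratio *
    geometry$er_volume
}

#' Fraction of ER Ca2+ lost through one continuously open channel
#'
#' @param geometry A [cell_geometry()].
#' @param open_duration Open time, s (>= 0).
#' @return Dimensionless fraction of the total ER content. With the
#'   defaults, 20 s of opening loses just under 2%.
#' @export
single_channel_depletion <- function(geometry = cell_geometry(),
                                     open_duration) {
  stopifnot(inherits(geometry, "cell_geometry"))
  .check_nonneg(open_duration, "open_duration")
  (geometry$channel_flux * open_duration / .AVOGADRO) /
    er_calcium_content(geometry)
}

#' Per-open-channel release rate constant implied by the geometry
#'
#' The single-channel flux expressed as a first-order rate on the buffered
#' free luminal pool:
#' `k_rel = (channel_flux / N_A / buffer_ratio) / (free_luminal_Ca * ER volume)`.
#' Reproduces the working value 8e-4 1/s only to within ~20%: the exact
#' volume normalisation behind that constant is not recoverable, so the
#' store model keeps 8e-4 as its default rather than this derivation.
#'
#' @param geometry A [cell_geometry()].
#' @return Rate constant, 1/s (~9e-4 with the defaults).
#' @export
estimate_k_rel <- function(geometry = cell_geometry()) {
  stopifnot(inherits(geometry, "cell_geometry"))
  (geometry$channel_flux / .AVOGADRO / geometry$buffer_ratio) /
    (geometry$free_luminal_Ca * 1e-6 * geometry$er_volume)
}

# core fixed-step integrator; o4, serca_on and krel_on are per-step vectors
.integrate_er_core <- function(o4, dt, params, serca_on = NULL,
                               krel_on = NULL) {
  n <- length(o4)
  if (is.null(serca_on)) serca_on <- rep(params$serca_active, n)
  if (is.null(krel_on)) krel_on <- rep(TRUE, n)
  cc <- params$C_cyt
  rel <- params$releasable_fraction * params$C_ER_init
  nonrel <- params$C_ER_init - rel
  out_rel <- numeric(n)
  out_non <- numeric(n)
  out_rel[1] <- rel
  out_non[1] <- nonrel
  for (i in seq_len(n - 1L)) {
    cer <- rel + nonrel
    grad <- cer - cc
    leak <- if (grad > 0) params$k_leak * grad else 0
    release <- if (grad > 0 && krel_on[i]) params$k_rel * o4[i] * grad else 0
    frac_rel <- if (cer > 0) rel / cer else 0
    refill <- if (serca_on[i]) (params$refill_target - cer) /
      params$tau_SERCA else 0
    # leak split pro rata across pools; release and refill hit the
    # releasable pool only
    rel <- rel + dt * (-leak * frac_rel - release + refill)
    nonrel <- nonrel + dt * (-leak * (1 - frac_rel))
    if (rel < 0) rel <- 0
    if (nonrel < 0) nonrel <- 0
    out_rel[i + 1L] <- rel
    out_non[i + 1L] <- nonrel
  }
  list(releasable = out_rel, nonreleasable = out_non)
}

# accept a gating_trajectory, data.frame(time_s, O4) or bare vector + dt
.as_o4_trace <- function(o4_trace, dt = NULL) {
  if (inherits(o4_trace, "gating_trajectory") || is.data.frame(o4_trace)) {
    tm <- o4_trace$time_s
    o4 <- o4_trace$O4
    if (is.null(tm) || is.null(o4)) {
      stop("O4 trace data.frame needs columns 'time_s' and 'O4'")
    }
    if (length(tm) < 2L) stop("O4 trace needs at least 2 samples")
    steps <- diff(tm)
    if (max(steps) - min(steps) > 1e-9 * max(steps)) {
      stop("O4 trace must be uniformly sampled")
    }
    dt <- steps[1]
  } else {
    o4 <- as.numeric(o4_trace)
    if (is.null(dt)) stop("'dt' is required with a bare O4 vector")
    tm <- seq(0, by = dt, length.out = length(o4))
  }
  if (any(!is.finite(o4)) || any(o4 < 0)) stop("O4 counts must be >= 0")
  list(time = tm, o4 = o4, dt = dt)
}

#' Integrate ER luminal Ca2+ driven by an open-receptor trace
#'
#' Explicit Euler integration of the store balance, locked to the sampling
#' step of the open-receptor trace. With `O4 = 0` and SERCA off the result
#' is the closed-form leak exponential
#' `C + (C_ER_init - C) * exp(-k_leak * t)`.
#'
#' @param o4_trace Open receptor counts: a [simulate_protocol()] result, a
#'   data.frame with `time_s` and `O4`, or a numeric vector with `dt`.
#' @param params An [er_params()].
#' @param dt Sampling step, s (only with a bare numeric `o4_trace`).
#' @param cells Number of cells sharing the receptor population: `O4` is
#'   divided by `cells` so that `k_rel` stays a per-cell, per-open-channel
#'   constant in population-well simulations (default 1).
#' @return A data.frame of class `"er_trajectory"` with columns `time_s`,
#'   `C_ER_uM`, `releasable_uM`, `percent_of_initial`, and a `params`
#'   attribute.
#' @examples
#' p <- er_params()
#' tr <- integrate_er(rep(0, 801), params = p, dt = 1.25)
#' @export
integrate_er <- function(o4_trace, params = er_params(), dt = NULL,
                         cells = 1) {
  stopifnot(inherits(params, "er_params"))
  .check_pos(cells, "cells")
  tr <- .as_o4_trace(o4_trace, dt)
  pools <- .integrate_er_core(tr$o4 / cells, tr$dt, params)
  .er_trajectory(tr$time, pools, params)
}

#' ER trajectory with an IP3R antagonist added mid-run
#'
#' Identical to [integrate_er()] up to `antagonist_time`; afterwards the
#' release term is removed (`k_rel` effectively 0) while leak and any
#' SERCA refill continue, so with SERCA active the store recovers toward
#' its ~500 uM steady state.
#'
#' @inheritParams integrate_er
#' @param antagonist_time Time of antagonist addition, s (within the trace
#'   span).
#' @return An `"er_trajectory"` data.frame; the antagonist time is kept in
#'   the `annotations` attribute.
#' @export
simulate_antagonist <- function(o4_trace, params = er_params(),
                                antagonist_time, dt = NULL, cells = 1) {
  stopifnot(inherits(params, "er_params"))
  .check_pos(cells, "cells")
  tr <- .as_o4_trace(o4_trace, dt)
  if (antagonist_time < tr$time[1] || antagonist_time > tr$time[length(tr$time)]) {
    stop("'antagonist_time' must lie within the trace span")
  }
  krel_on <- tr$time < antagonist_time
  pools <- .integrate_er_core(tr$o4 / cells, tr$dt, params,
                              krel_on = krel_on)
  out <- .er_trajectory(tr$time, pools, params)
  attr(out, "annotations") <- list(antagonist = antagonist_time)
  out
}

.er_trajectory <- function(time, pools, params) {
  cer <- pools$releasable + pools$nonreleasable
  res <- data.frame(time_s = time, C_ER_uM = cer,
                    releasable_uM = pools$releasable,
                    percent_of_initial = 100 * cer / params$C_ER_init)
  structure(res, params = params,
            class = c("er_trajectory", "data.frame"))
}

#' @export
print.er_trajectory <- function(x, ...) {
  cat(sprintf("ER trajectory: %d samples over %g s; C_ER %g -> %.4g uM\n",
              nrow(x), x$time_s[nrow(x)] - x$time_s[1], x$C_ER_uM[1],
              x$C_ER_uM[nrow(x)]))
  invisible(x)
}

#' @export
plot.er_trajectory <- function(x, ...) {
  graphics::plot(x$time_s, x$C_ER_uM, type = "l", xlab = "time (s)",
                 ylab = expression("[Ca"^"2+"*"]"[ER]*" ("*mu*"M)"), ...)
  ann <- attr(x, "annotations")
  if (!is.null(ann)) graphics::abline(v = unlist(ann), lty = 3)
  invisible(x)
}

#' Write an ER trajectory as delimited text
#'
#' @param trajectory An `er_trajectory`.
#' @param path Output path.
#' @param overwrite Allow overwriting an existing file.
#' @return `path`, invisibly.
#' @export
write_er_trajectory <- function(trajectory, path, overwrite = FALSE) {
  stopifnot(inherits(trajectory, "er_trajectory"))
  if (file.exists(path) && !overwrite) {
    stop("'", path, "' exists; use overwrite = TRUE")
  }
  p <- attr(trajectory, "params")
  meta <- c(
    sprintf("# quantalCa ER trajectory v%s",
            as.character(utils::packageVersion("quantalCa"))),
    sprintf(paste0("# params: k_leak=%g k_rel=%g C_cyt=%g C_ER_init=%g ",
                   "tau_SERCA=%g releasable=%g serca_active=%s"),
            p$k_leak, p$k_rel, p$C_cyt, p$C_ER_init, p$tau_SERCA,
            p$releasable_fraction, p$serca_active))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(as.data.frame(trajectory), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
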