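# shared fixtures and independent oracles

# closed-form pure-leak store decay (analytic limit of the store ODE)
leak_closed_form <- function(t, C0 = 500, C_cyt = 0.22, k = 1.8e-4) {
  C_cyt + (C0 - C_cyt) * exp(-k * t)
}

# analytic steady state of the refill equation with O4 = 0:
# 0 = -k_leak (C - C_cyt) + (target - C)/tau
serca_steady_state <- function(k_leak = 1.8e-4, tau = 100, C_cyt = 0.22,
                               target = 500) {
  (target / tau + k_leak * C_cyt) / (1 / tau + k_leak)
}

# independent fine-step master-equation oracle (lsoda), for cross-checking
# the matrix-exponential route
ode_occupancies <- function(initial, rates, t) {
  q <- rate_matrix(rates)
  f <- function(t, y, parms) list(as.numeric(y %*% q))
  out <- deSolve::lsoda(initial, c(0, t), f, NULL,
                        rtol = 1e-10, atol = 1e-12)
  unname(out[nrow(out), -1])
}

# a noiseless calibrated leak-only trace built directly from the closed
# form (independent of the package's generator)
make_leak_trace <- function(k = 1.8e-4, C0 = 480, C_cyt = 0.22,
                            interval = 1.44, duration = 500,
                            t_offset = 0, stimulus = NULL) {
  tm <- seq(0, duration, by = interval) + t_offset
  ann <- list(serca_inhibitor = tm[1])
  if (!is.null(stimulus)) ann$stimulus <- stimulus
  fluorescence_trace(tm, C_cyt + (C0 - C_cyt) * exp(-k * (tm - tm[1])),
                     annotations = ann, calibration = c(a = 1, b = 0))
}

# small single-cell template used where full study-scale runs would be
# wasteful
small_single_cell <- function(schedule, duration = 1400, ...) {
  experiment_template("single_cell_small", receptors_total = 9101,
                      schedule = schedule, duration = duration, ...)
}
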