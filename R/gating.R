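#' Gating rate constants for tetra-liganded receptors
#'
#' The tetra-liganded receptor moves among closed (C4), open (O4) and
#' inactivated (I4) states on a triangular scheme with one forbidden edge:
#' C4 -> O4 at `k1`, O4 -> C4 at `k1/reverse_factor`, O4 -> I4 at `k2`,
#' I4 -> O4 at `k2/reverse_factor`, I4 -> C4 at `k3`, and C4 -> I4 never
#' (the irreversible step). Reverse rates are 100-fold slower than forward
#' rates by default. The fixed simulation step `dt` must keep every
#' per-step transition probability small (max rate x dt < 0.1).
#'
#' @param k1 C4 -> O4 rate, 1/s (default 0.4).
#' @param k2 O4 -> I4 rate, 1/s (default 0.2).
#' @param k3 I4 -> C4 rate, 1/s (default 0.004).
#' @param reverse_factor Forward/reverse rate ratio (default 100); `Inf`
#'   disables the reverse transitions entirely.
#' @param dt Simulation time step, s (default 0.0125).
#' @return An object of class `"gating_rates"`.
#' @examples
#' gating_rates()          # the default scheme
#' rate_matrix(gating_rates())
#' @export
gating_rates <- function(k1 = 0.4, k2 = 0.2, k3 = 0.004,
                         reverse_factor = 100, dt = 0.0125) {
  for (nm in c("k1", "k2", "k3")) .check_nonneg(get(nm), nm)
  if (!is.numeric(reverse_factor) || reverse_factor <= 0) {
    stop("'reverse_factor' must be > 0 (use Inf to disable reverse rates)")
  }
  .check_pos(dt, "dt")
  km1 <- if (is.infinite(reverse_factor)) 0 else k1 / reverse_factor
  km2 <- if (is.infinite(reverse_factor)) 0 else k2 / reverse_factor
  if (max(k1, k2, k3, km1, km2) * dt >= 0.1) {
    stop("max(rate) * dt must be < 0.1 for the fixed-step scheme")
  }
  structure(list(k1 = k1, k2 = k2, k3 = k3, km1 = km1, km2 = km2,
                 reverse_factor = reverse_factor, dt = dt),
            class = "gating_rates")
}

#' @export
print.gating_rates <- function(x, ...) {
  cat(sprintf(
    "Gating rates (1/s): C4->O4 %g, O4->C4 %g, O4->I4 %g, I4->O4 %g, I4->C4 %g; dt = %g s\n",
    x$k1, x$km1, x$k2, x$km2, x$k3, x$dt))
  invisible(x)
}

#' Infinitesimal generator of the three-state scheme
#'
#' @param rates A [gating_rates()] object.
#' @return A 3x3 matrix Q (rows/cols C4, O4, I4) with `Q[i, j]` the rate
#'   from state i to state j and rows summing to zero.
#' @export
rate_matrix <- function(rates) {
  stopifnot(inherits(rates, "gating_rates"))
  q <- matrix(0, 3, 3, dimnames = list(c("C4", "O4", "I4"),
                                       c("C4", "O4", "I4")))
  q["C4", "O4"] <- rates$k1
  q["O4", "C4"] <- rates$km1
  q["O4", "I4"] <- rates$k2
  q["I4", "C4"] <- rates$k3
  q["I4", "O4"] <- rates$km2
  diag(q) <- -rowSums(q)
  q
}

# per-step exit probabilities k_i * dt, rows = origin, cols = destination
.step_probs <- function(rates) {
  p <- rate_matrix(rates) * rates$dt
  diag(p) <- 0
  p
}

#' Receptor ensemble state
#'
#' Integer counts of tetra-liganded receptors in each gating state at one
#' time point. Counts are stored as doubles so that well-scale totals
#' (>2^31) remain exact integers in double precision.
#'
#' @param C4,O4,I4 Non-negative integer-valued counts.
#' @param time Time stamp, s.
#' @return An object of class `"receptor_ensemble"`.
#' @export
receptor_ensemble <- function(C4 = 0, O4 = 0, I4 = 0, time = 0) {
  counts <- c(C4 = C4, O4 = O4, I4 = I4)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != round(counts))) {
    stop("state counts must be non-negative integers")
  }
  structure(list(C4 = C4, O4 = O4, I4 = I4, time = time),
            class = "receptor_ensemble")
}

#' @export
print.receptor_ensemble <- function(x, ...) {
  cat(sprintf("t = %g s: C4 = %g, O4 = %g, I4 = %g (total %g)\n",
              x$time, x$C4, x$O4, x$I4, x$C4 + x$O4 + x$I4))
  invisible(x)
}

# multinomial draw that chunks sizes above .Machine$integer.max
.rmultinom_large <- function(n, prob) {
  if (n == 0) return(numeric(length(prob)))
  cap <- 2^31 - 2
  if (n <= cap) return(as.numeric(stats::rmultinom(1, n, prob)[, 1]))
  out <- numeric(length(prob))
  remaining <- n
  while (remaining > 0) {
    take <- min(remaining, cap)
    out <- out + as.numeric(stats::rmultinom(1, take, prob)[, 1])
    remaining <- remaining - take
  }
  out
}

# advance counts (C4, O4, I4) by one step
.step_counts <- function(counts, pexit, engine = "multinomial") {
  moved <- matrix(0, 3, 3)
  for (i in 1:3) {
    n_i <- counts[i]
    if (n_i == 0) next
    probs <- pexit[i, ]
    stay <- 1 - sum(probs)
    if (engine == "multinomial") {
      draw <- .rmultinom_large(n_i, c(probs, stay))
      moved[i, ] <- draw[1:3]
    } else {
      # literal per-receptor mechanics: one uniform per receptor, the unit
      # interval partitioned into disjoint exit sub-intervals of length k*dt
      u <- stats::runif(n_i)
      edges <- cumsum(probs)
      dest <- findInterval(u, c(0, edges), rightmost.closed = FALSE)
      dest[dest > 3] <- 0  # u beyond all exits: stay
      tab <- tabulate(dest, nbins = 3)
      moved[i, ] <- tab
    }
  }
  counts - rowSums(moved) + colSums(moved)
}

#' Advance a receptor ensemble by one time step
#'
#' Each receptor makes at most one transition per step; the probability of
#' taking allowed exit i from its current state is `k_i * dt`.
#'
#' @param ensemble A [receptor_ensemble()].
#' @param rates A [gating_rates()].
#' @param engine `"multinomial"` (exact-distribution ensemble update,
#'   default) or `"per_receptor"` (literal one-uniform-per-receptor draws,
#'   for validation).
#' @return The ensemble advanced by `rates$dt`.
#' @export
step_ensemble <- function(ensemble, rates, engine = c("multinomial",
                                                      "per_receptor")) {
  stopifnot(inherits(ensemble, "receptor_ensemble"),
            inherits(rates, "gating_rates"))
  engine <- match.arg(engine)
  counts <- .step_counts(c(ensemble$C4, ensemble$O4, ensemble$I4),
                         .step_probs(rates), engine)
  receptor_ensemble(counts[1], counts[2], counts[3],
                    time = ensemble$time + rates$dt)
}

#' Inject newly tetra-liganded receptors into the closed state
#'
#' A ligand addition is modelled as an immediate increase of the closed
#' (C4) pool to bring the cumulative tetra-liganded total to `new_total`;
#' O4 and I4 are untouched. Concentration decreases are unsupported.
#'
#' @param ensemble A [receptor_ensemble()].
#' @param new_total New cumulative tetra-liganded total (>= current total).
#' @return The updated ensemble.
#' @export
inject_tetraliganded <- function(ensemble, new_total) {
  stopifnot(inherits(ensemble, "receptor_ensemble"))
  total <- ensemble$C4 + ensemble$O4 + ensemble$I4
  if (!is.numeric(new_total) || !is.finite(new_total) ||
      new_total != round(new_total)) {
    stop("'new_total' must be an integer-valued count")
  }
  if (new_total < total) {
    stop("'new_total' below the current total: concentration decreases ",
         "are unsupported")
  }
  receptor_ensemble(ensemble$C4 + (new_total - total), ensemble$O4,
                    ensemble$I4, time = ensemble$time)
}

#' Ligand-addition protocol
#'
#' An ordered schedule of ligand additions. At each event the cumulative
#' tetra-liganded receptor total jumps to
#' `round(receptors_total * alpha(conc)^4)` and the increment enters C4.
#'
#' @param times Event times, s (strictly increasing, >= 0).
#' @param concentrations Ligand concentrations, nM. Cumulative final
#'   concentrations when `cumulative = TRUE` (must be non-decreasing);
#'   per-addition increments otherwise.
#' @param kd Ligand K_D, nM.
#' @param receptors_total Total receptors in the simulated unit (cell or
#'   well).
#' @param cumulative Whether `concentrations` are cumulative totals.
#' @return An object of class `"addition_protocol"`.
#' @examples
#' addition_protocol(c(0, 200, 400), c(60, 90, 120), kd = 794,
#'                   receptors_total = 2e10)
#' @export
addition_protocol <- function(times, concentrations, kd, receptors_total,
                              cumulative = TRUE) {
  .check_nonneg(times, "times")
  .check_nonneg(concentrations, "concentrations")
  if (length(times) != length(concentrations)) {
    stop("'times' and 'concentrations' must have equal length")
  }
  if (any(diff(times) <= 0)) {
    stop("event times must be strictly increasing (no overlapping events)")
  }
  conc <- if (cumulative) concentrations else cumsum(concentrations)
  if (any(diff(conc) < 0)) {
    stop("cumulative concentrations must be non-decreasing")
  }
  .check_pos(kd, "kd")
  .check_nonneg(receptors_total, "receptors_total")
  structure(list(times = times, concentrations = conc, kd = kd,
                 receptors_total = receptors_total), class = "addition_protocol")
}

#' @export
print.addition_protocol <- function(x, ...) {
  cat(sprintf("Addition protocol: K_D = %g nM, %s receptors\n", x$kd,
              format(x$receptors_total, big.mark = ",")))
  print(data.frame(time_s = x$times, concentration_nM = x$concentrations))
  invisible(x)
}

#' Stochastic simulation of a ligand-addition protocol
#'
#' Runs the fixed-step three-state gating scheme over the protocol. At each
#' event time the tetra-liganded total jumps to the occupancy-model value
#' for the new concentration (rounded to the nearest integer, entering C4);
#' between events every receptor is updated independently each `dt`.
#' Identical `(protocol, rates, seed)` give bitwise-identical trajectories.
#'
#' @param protocol An [addition_protocol()].
#' @param rates A [gating_rates()].
#' @param seed Integer RNG seed (required; recorded in the result).
#' @param duration Total simulated time, s (default: last event + 100 s).
#' @param record_every Record every this many steps (default 1).
#' @param engine See [step_ensemble()].
#' @return A data.frame of class `"gating_trajectory"` with columns
#'   `time_s`, `C4`, `O4`, `I4` and attributes `protocol`, `rates`, `seed`,
#'   `engine`.
#' @examples
#' pr <- addition_protocol(0, 143, kd = 794, receptors_total = 9101)
#' tr <- simulate_protocol(pr, gating_rates(), seed = 1, duration = 30)
#' @export
simulate_protocol <- function(protocol, rates = gating_rates(), seed,
                              duration = NULL, record_every = 1L,
                              engine = c("multinomial", "per_receptor")) {
  stopifnot(inherits(protocol, "addition_protocol"),
            inherits(rates, "gating_rates"))
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  engine <- match.arg(engine)
  if (is.null(duration)) duration <- max(protocol$times) + 100
  dt <- rates$dt
  n_steps <- ceiling(duration / dt)
  record_every <- as.integer(record_every)
  stopifnot(record_every >= 1L)

  model <- occupancy_model(protocol$kd, protocol$receptors_total)
  totals <- round(tetra_count(protocol$concentrations, model))
  event_step <- pmin(round(protocol$times / dt), n_steps)

  set.seed(seed, kind = "Mersenne-Twister")
  pexit <- .step_probs(rates)
  counts <- c(0, 0, 0)
  n_rec <- n_steps %/% record_every + 1L
  out <- matrix(0, n_rec, 3)
  rec_row <- 1L
  ev <- 1L
  for (s in 0:n_steps) {
    while (ev <= length(event_step) && event_step[ev] == s) {
      inc <- totals[ev] - sum(counts)
      if (inc > 0) counts[1] <- counts[1] + inc
      ev <- ev + 1L
    }
    if (s %% record_every == 0L) {
      out[rec_row, ] <- counts
      rec_row <- rec_row + 1L
    }
    if (s < n_steps) counts <- .step_counts(counts, pexit, engine)
  }
  res <- data.frame(time_s = seq(0, by = dt * record_every,
                                 length.out = n_rec),
                    C4 = out[, 1], O4 = out[, 2], I4 = out[, 3])
  structure(res, protocol = protocol, rates = rates, seed = seed,
            engine = engine,
            class = c("gating_trajectory", "data.frame"))
}

#' @export
print.gating_trajectory <- function(x, ...) {
  r <- attr(x, "rates")
  cat(sprintf(
    "Gating trajectory: %d samples, dt-record %g s, seed %s, engine %s\n",
    nrow(x), if (nrow(x) > 1) x$time_s[2] - x$time_s[1] else r$dt,
    attr(x, "seed"), attr(x, "engine")))
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
plot.gating_trajectory <- function(x, states = c("O4", "I4", "C4"), ...) {
  graphics::matplot(x$time_s, as.matrix(as.data.frame(x)[states]),
                    type = "l", lty = 1, xlab = "time (s)",
                    ylab = "receptors", ...)
  graphics::legend("topright", legend = states, lty = 1,
                   col = seq_along(states), bty = "n")
  invisible(x)
}

#' Deterministic state probabilities (master equation)
#'
#' Solves the three-state master equation exactly via the matrix
#' exponential: p(t) = p(0) expm(Q t). Used as the deterministic oracle for
#' the stochastic simulator. `method = "discrete"` instead iterates the
#' one-step matrix of the fixed-step chain, `M = I + Q dt`, giving the
#' exact mean of the simulated process (the two differ by the O(k dt)
#' discretisation bias; `t` is then rounded to whole steps).
#'
#' @param initial Initial state probabilities (C4, O4, I4), summing to 1.
#' @param rates A [gating_rates()].
#' @param t Time(s), s.
#' @param method `"exponential"` (continuous-time master equation,
#'   default) or `"discrete"` (exact fixed-step chain mean).
#' @return For scalar `t` a named probability vector; for vector `t` a
#'   matrix with one row per time.
#' @export
meanfield_occupancies <- function(initial, rates, t,
                                  method = c("exponential", "discrete")) {
  stopifnot(inherits(rates, "gating_rates"))
  method <- match.arg(method)
  if (length(initial) != 3 || any(!is.finite(initial)) || any(initial < 0)) {
    stop("'initial' must be 3 non-negative probabilities")
  }
  if (abs(sum(initial) - 1) > 1e-8) stop("'initial' must sum to 1")
  .check_nonneg(t, "t")
  q <- rate_matrix(rates)
  propagate <- if (method == "exponential") {
    function(tt) as.numeric(initial %*% as.matrix(Matrix::expm(q * tt)))
  } else {
    m <- diag(3) + q * rates$dt
    function(tt) {
      n <- round(tt / rates$dt)
      p <- initial
      mk <- m
      # fast exponentiation by squaring over the step count
      while (n > 0) {
        if (n %% 2 == 1) p <- as.numeric(p %*% mk)
        mk <- mk %*% mk
        n <- n %/% 2
      }
      p
    }
  }
  res <- t(vapply(t, function(tt) {
    p <- propagate(tt)
    p <- pmin(pmax(p, 0), 1)
    p / sum(p)
  }, numeric(3)))
  colnames(res) <- c("C4", "O4", "I4")
  if (length(t) == 1L) res[1, ] else res
}

#' Stationary state distribution
#'
#' The long-run distribution of the single-receptor chain: the null space
#' of the transposed generator, normalised to sum to 1.
#'
#' @param rates A [gating_rates()].
#' @return Named probability vector (C4, O4, I4).
#' @export
stationary_distribution <- function(rates) {
  q <- rate_matrix(rates)
  ns <- pracma::nullspace(t(q))
  if (is.null(ns)) stop("no stationary distribution (degenerate rates)")
  v <- abs(ns[, 1])
  stats::setNames(v / sum(v), c("C4", "O4", "I4"))
}

#' Sample single-state residence times
#'
#' Residence (dwell) times in one state under the fixed-step scheme: the
#' number of steps before any exit is geometric with per-step exit
#' probability `sum(exit rates) * dt`, so the mean dwell converges to
#' 1/(sum of exit rates).
#'
#' @param state One of `"C4"`, `"O4"`, `"I4"`.
#' @param rates A [gating_rates()].
#' @param n Number of dwells to sample.
#' @param seed Integer RNG seed.
#' @return Numeric vector of dwell times, s. All `Inf` if the state has no
#'   exit.
#' @examples
#' mean(dwell_time_sample("O4", gating_rates(), 1e4, seed = 1))  # ~4.9 s
#' @export
dwell_time_sample <- function(state = c("C4", "O4", "I4"),
                              rates = gating_rates(), n, seed) {
  state <- match.arg(state)
  stopifnot(inherits(rates, "gating_rates"), n >= 1)
  if (missing(seed)) stop("an explicit integer 'seed' is required")
  exit_rate <- sum(.step_probs(rates)[state, ]) / rates$dt
  if (exit_rate == 0) return(rep(Inf, n))
  set.seed(seed, kind = "Mersenne-Twister")
  steps <- stats::rgeom(n, prob = exit_rate * rates$dt) + 1
  steps * rates$dt
}

#' Write a gating trajectory as delimited text
#'
#' Comma-separated columns `time_s, C4, O4, I4` preceded by `#` metadata
#' lines carrying the rates, protocol and seed.
#'
#' @param trajectory A `gating_trajectory`.
#' @param path Output path.
#' @param overwrite Allow overwriting an existing file.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path, overwrite = FALSE) {
  stopifnot(inherits(trajectory, "gating_trajectory"))
  if (file.exists(path) && !overwrite) {
    stop("'", path, "' exists; use overwrite = TRUE")
  }
  r <- attr(trajectory, "rates")
  p <- attr(trajectory, "protocol")
  meta <- c(
    sprintf("# quantalCa gating trajectory v%s",
            as.character(utils::packageVersion("quantalCa"))),
    sprintf("# rates: k1=%g k2=%g k3=%g reverse_factor=%g dt=%g",
            r$k1, r$k2, r$k3, r$reverse_factor, r$dt),
    sprintf("# protocol: times=%s conc_nM=%s kd=%g receptors_total=%g",
            paste(p$times, collapse = ";"),
            paste(p$concentrations, collapse = ";"), p$kd,
            p$receptors_total),
    sprintf("# seed: %d engine: %s", attr(trajectory, "seed"),
            attr(trajectory, "engine")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.table(as.data.frame(trajectory), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
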