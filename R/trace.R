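#' Luminal Ca2+ fluorescence trace
#'
#' A uniformly sampled low-affinity-indicator fluorescence record from one
#' well or cell, assumed approximately linear in ER free Ca2+. Annotations
#' mark the addition times that structure the analysis: ATP (SERCA loading
#' starts), the SERCA inhibitor (leak-only decay starts), the stimulus, and
#' optionally an antagonist.
#'
#' @param times Sample times, s (strictly increasing, uniform within 1%).
#' @param values Fluorescence values, arbitrary units.
#' @param annotations Named list of event times (s), e.g.
#'   `list(atp = 0, serca_inhibitor = 400, stimulus = 900)`. All must lie
#'   within the record.
#' @param calibration Optional linear map to uM: a named vector
#'   `c(a = , b = )` with fluorescence = a * content + b. `NULL` keeps the
#'   analysis in raw units.
#' @return An object of class `"fluor_trace"`.
#' @export
fluorescence_trace <- function(times, values, annotations = list(),
                               calibration = NULL) {
  if (!is.numeric(times) || length(times) < 3L || any(diff(times) <= 0)) {
    stop("'times' must be strictly increasing with >= 3 samples")
  }
  steps <- diff(times)
  if ((max(steps) - min(steps)) / stats::median(steps) > 0.01) {
    stop("'times' must be uniformly spaced within 1%")
  }
  if (!is.numeric(values) || length(values) != length(times) ||
      any(!is.finite(values))) {
    stop("'values' must be finite and match 'times' in length")
  }
  ann <- lapply(annotations, as.numeric)
  for (nm in names(ann)) {
    if (ann[[nm]] < times[1] || ann[[nm]] > times[length(times)]) {
      stop("annotation '", nm, "' lies outside the record")
    }
  }
  if (!is.null(calibration)) {
    if (!all(c("a", "b") %in% names(calibration)) || calibration[["a"]] == 0) {
      stop("'calibration' must be c(a = , b = ) with a != 0")
    }
  }
  structure(list(times = times, values = values, annotations = ann,
                 calibration = calibration), class = "fluor_trace")
}

#' @export
print.fluor_trace <- function(x, ...) {
  cat(sprintf("Fluorescence trace: %d samples at %.3g s, %s\n",
              length(x$times), stats::median(diff(x$times)),
              if (is.null(x$calibration)) "uncalibrated (a.u.)"
              else "calibrated to uM"))
  if (length(x$annotations)) {
    cat("  annotations:",
        paste(sprintf("%s = %g s", names(x$annotations),
                      unlist(x$annotations)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.fluor_trace <- function(x, ...) {
  graphics::plot(x$times, x$values, type = "l", xlab = "time (s)",
                 ylab = "fluorescence (a.u.)", ...)
  if (length(x$annotations)) {
    graphics::abline(v = unlist(x$annotations), lty = 3)
  }
  invisible(x)
}

# content in uM if calibrated, raw units otherwise
trace_content <- function(trace) {
  if (is.null(trace$calibration)) return(trace$values)
  (trace$values - trace$calibration[["b"]]) / trace$calibration[["a"]]
}

#' Fit the IP3-independent leak from a post-inhibition window
#'
#' Fits a mono-exponential `content(t) = C_cyt + A * exp(-k * (t - t0))` to
#' the ER content between SERCA inhibition and the stimulus. The asymptote
#' is fixed at the clamped cytosolic Ca2+ by default: over a few hundred
#' seconds `k * t << 1`, so a free offset is barely identifiable, while the
#' physical asymptote of a pure leak is the (known) clamped cytosolic
#' concentration. The analytic derivative of the fit gives the leak flux
#' `J_leak(t)`, which is then paired with the time-matched content and
#' fitted by a second-degree polynomial (default) or an exponential, giving
#' the `J_leak`-vs-content relationship used for subtraction.
#'
#' @param trace A [fluorescence_trace()].
#' @param window Optional `c(start, end)` in s; defaults to the
#'   `serca_inhibitor` annotation up to the `stimulus` annotation (or the
#'   end of the record). Needs >= 10 samples.
#' @param family `"poly2"` or `"exponential"` for the J_leak-vs-content
#'   relationship.
#' @param C_cyt Clamped cytosolic Ca2+ in content units (default 0.22, uM
#'   for calibrated traces).
#' @param fix_offset Fix the exponential's asymptote at `C_cyt` (default
#'   TRUE); otherwise the offset is a free parameter.
#' @return An object of class `"leak_model"`: `rate` (1/s), `amplitude`,
#'   `offset`, `t0`, the `jleak_vs_content` fit, the fitted `window`, and
#'   the content range used.
#' @examples
#' tm <- seq(0, 500, by = 1.44)
#' tr <- fluorescence_trace(tm, 0.22 + 480 * exp(-1.8e-4 * tm),
#'                          annotations = list(serca_inhibitor = 0),
#'                          calibration = c(a = 1, b = 0))
#' fit_leak(tr)$rate   # 1.8e-4
#' @export
fit_leak <- function(trace, window = NULL,
                     family = c("poly2", "exponential"), C_cyt = 0.22,
                     fix_offset = TRUE) {
  stopifnot(inherits(trace, "fluor_trace"))
  family <- match.arg(family)
  ann <- trace$annotations
  if (is.null(window)) {
    start <- ann$serca_inhibitor
    if (is.null(start)) stop("no 'serca_inhibitor' annotation and no window")
    end <- if (!is.null(ann$stimulus)) ann$stimulus
           else trace$times[length(trace$times)]
    window <- c(start, end)
  }
  sel <- trace$times >= window[1] & trace$times <= window[2]
  if (sum(sel) < 10L) stop("leak window must contain at least 10 samples")
  tt <- trace$times[sel]
  yy <- trace_content(trace)[sel]
  t0 <- tt[1]

  if (diff(range(yy)) < 1e-12 * max(abs(yy), 1)) {
    stop("leak fit failure: window is constant (zero rate)")
  }
  above <- yy - C_cyt
  if (any(above <= 0)) above <- pmax(above, 1e-12 * max(abs(yy)))
  k0 <- -stats::coef(stats::lm(log(above) ~ I(tt - t0)))[[2]]
  if (!is.finite(k0) || k0 <= 0) {
    stop("leak fit failure: window does not decay (rate <= 0)")
  }
  dat <- data.frame(t = tt - t0, y = yy)
  fit <- tryCatch({
    if (fix_offset) {
      minpack.lm::nlsLM(y ~ OFF + A * exp(-k * t),
                        data = cbind(dat, OFF = C_cyt),
                        start = list(A = yy[1] - C_cyt, k = k0),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500))
    } else {
      minpack.lm::nlsLM(y ~ off + A * exp(-k * t), data = dat,
                        start = list(off = C_cyt, A = yy[1] - C_cyt,
                                     k = k0),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500))
    }
  }, error = function(e) stop("leak fit failure: ", conditionMessage(e)))
  cf <- stats::coef(fit)
  rate <- unname(cf[["k"]])
  amp <- unname(cf[["A"]])
  off <- if (fix_offset) C_cyt else unname(cf[["off"]])
  if (rate <= 0) stop("leak fit failure: fitted rate <= 0")

  content_fit <- off + amp * exp(-rate * (tt - t0))
  jleak <- amp * rate * exp(-rate * (tt - t0))  # -d(content)/dt of the fit
  jfit <- if (family == "poly2") {
    stats::lm(jleak ~ stats::poly(content_fit, 2, raw = TRUE))
  } else {
    minpack.lm::nlsLM(jleak ~ a * exp(b * content_fit),
                      start = list(a = max(jleak[1], 1e-12),
                                   b = 1e-4),
                      control = minpack.lm::nls.lm.control(maxiter = 500))
  }
  structure(list(rate = rate, amplitude = amp, offset = off, t0 = t0,
                 C_cyt = C_cyt, family = family, jleak_fit = jfit,
                 window = window, content_range = range(content_fit),
                 n = length(tt)), class = "leak_model")
}

#' @export
print.leak_model <- function(x, ...) {
  cat(sprintf(
    "Leak model: rate %.4g /s, amplitude %.4g, offset %.4g (%d samples)\n",
    x$rate, x$amplitude, x$offset, x$n))
  cat(sprintf("  J_leak vs content: %s over [%.4g, %.4g]\n", x$family,
              x$content_range[1], x$content_range[2]))
  invisible(x)
}

#' @export
coef.leak_model <- function(object, ...) {
  c(rate = object$rate, amplitude = object$amplitude,
    offset = object$offset)
}

#' Leak flux at given store content
#'
#' Evaluates the fitted J_leak-vs-content relationship. Contents outside
#' the fitted range are extrapolated; the result then carries
#' `attr(, "extrapolated") = TRUE`. Negative predictions are clipped to 0
#' (a leak cannot refill the store).
#'
#' @param object A `leak_model`.
#' @param content Store content values (same units as the fitted trace).
#' @param ... Unused.
#' @return J_leak values, content-units/s.
#' @export
predict.leak_model <- function(object, content, ...) {
  if (missing(content)) stop("'content' is required")
  j <- if (object$family == "poly2") {
    cf <- stats::coef(object$jleak_fit)
    cf[[1]] + cf[[2]] * content + cf[[3]] * content^2
  } else {
    cf <- stats::coef(object$jleak_fit)
    cf[["a"]] * exp(cf[["b"]] * content)
  }
  j <- pmax(j, 0)
  extra <- any(content < object$content_range[1] - 1e-9) ||
    any(content > object$content_range[2] + 1e-9)
  if (extra) attr(j, "extrapolated") <- TRUE
  j
}

# derivative of a uniformly sampled series: optional Savitzky-Golay
# smoothing, then central differences (one-sided at the ends)
.smoothed_derivative <- function(y, times, smooth_window = 7L,
                                 smooth_order = 2L) {
  if (!is.null(smooth_window) && smooth_window >= 3L) {
    if (smooth_window %% 2L == 0L) smooth_window <- smooth_window + 1L
    if (smooth_window > length(y)) {
      smooth_window <- length(y) - (1 - length(y) %% 2)
    }
    if (smooth_window > smooth_order + 1) {
      y <- signal::sgolayfilt(y, p = smooth_order, n = smooth_window)
    }
  }
  pracma::gradient(y, times)
}

#' Subtract the fitted leak to isolate stimulus-evoked flux
#'
#' Computes `evoked_flux(t) = -d(content)/dt - J_leak(content(t))`. Inside
#' the fitted leak window the derivative is the analytic derivative of the
#' mono-exponential fit (so a leak-only trace subtracts to ~0 exactly);
#' elsewhere it is a central finite difference after optional
#' Savitzky-Golay smoothing.
#'
#' @param trace A [fluorescence_trace()].
#' @param leak A [fit_leak()] result for the same trace.
#' @param smooth_window Smoothing filter length in samples (default 7;
#'   `NULL` or < 3 disables smoothing).
#' @param smooth_order Smoothing polynomial order (default 2).
#' @return A data.frame with `time_s` and `evoked_flux` (content-units/s);
#'   attribute `extrapolated` flags contents outside the leak fit's range.
#' @export
subtract_leak <- function(trace, leak, smooth_window = 7L,
                          smooth_order = 2L) {
  stopifnot(inherits(trace, "fluor_trace"), inherits(leak, "leak_model"))
  content <- trace_content(trace)
  dcdt <- .smoothed_derivative(content, trace$times, smooth_window,
                               smooth_order)
  inwin <- trace$times >= leak$window[1] & trace$times <= leak$window[2]
  dcdt[inwin] <- -leak$amplitude * leak$rate *
    exp(-leak$rate * (trace$times[inwin] - leak$t0))
  jl <- predict(leak, content)
  evoked <- -dcdt - jl
  out <- data.frame(time_s = trace$times, evoked_flux = evoked)
  attr(out, "extrapolated") <- isTRUE(attr(jl, "extrapolated"))
  out
}

#' Reconstruct luminal Ca2+ content from evoked flux
#'
#' Cumulative trapezoidal integration of the evoked flux, subtracted from
#' the initial content: the time evolution of the store due to the
#' stimulus alone.
#'
#' @param evoked_flux Flux values (content-units/s), or the data.frame from
#'   [subtract_leak()].
#' @param times Sample times, s (ignored when a data.frame is given).
#' @param initial_content Content at `times[1]`.
#' @return Numeric vector of reconstructed content; attribute
#'   `below_zero = TRUE` if the reconstruction crosses zero.
#' @export
reconstruct_caer <- function(evoked_flux, times = NULL, initial_content) {
  if (is.data.frame(evoked_flux)) {
    times <- evoked_flux$time_s
    evoked_flux <- evoked_flux$evoked_flux
  }
  if (is.null(times) || length(times) != length(evoked_flux)) {
    stop("'times' must match 'evoked_flux' in length")
  }
  rec <- initial_content - pracma::cumtrapz(times, evoked_flux)[, 1]
  if (any(rec < 0)) attr(rec, "below_zero") <- TRUE
  rec
}

#' Open-receptor time course in arbitrary units
#'
#' Divides the stimulus-evoked flux by the instantaneous luminal-cytosolic
#' Ca2+ gradient. The result is proportional to the true number of open
#' receptors with (unknown) proportionality constant `k_rel`. Negative
#' fluxes (noise) are clipped to 0 here; samples whose gradient falls below
#' the floor are masked (`NA`) rather than divided.
#'
#' @param evoked_flux Flux values, content-units/s.
#' @param reconstructed_C_ER Reconstructed content, same length.
#' @param C_cyt Cytosolic Ca2+ in content units (default 0.22).
#' @param gradient_floor Minimum gradient for division, content units.
#'   Default 2% of the initial reconstructed content.
#' @return Open receptors in arbitrary units (>= 0, `NA` where masked).
#' @export
open_receptors <- function(evoked_flux, reconstructed_C_ER, C_cyt = 0.22,
                           gradient_floor = NULL) {
  if (length(evoked_flux) != length(reconstructed_C_ER)) {
    stop("'evoked_flux' and 'reconstructed_C_ER' must match in length")
  }
  if (is.null(gradient_floor)) {
    gradient_floor <- 0.02 * reconstructed_C_ER[1]
  }
  grad <- reconstructed_C_ER - C_cyt
  au <- pmax(evoked_flux, 0) / grad
  au[grad < gradient_floor] <- NA_real_
  au
}

#' Leak rate constant at a reference content
#'
#' `k_leak = J_leak(reference) / (reference - C_cyt)`: the first-order rate
#' constant implied by the fitted leak flux at a reference store content
#' (the 500 uM loading plateau for calibrated traces).
#'
#' @param leak A `leak_model`.
#' @param reference_content Reference content (same units as the fit).
#' @param C_cyt Cytosolic Ca2+ in content units (default the value used in
#'   the leak fit).
#' @return Rate constant, 1/s; `attr(, "extrapolated")` is set when the
#'   reference lies outside the fitted content range.
#' @export
estimate_k_leak <- function(leak, reference_content,
                            C_cyt = leak$C_cyt) {
  stopifnot(inherits(leak, "leak_model"))
  .check_pos(reference_content, "reference_content")
  if (reference_content <= C_cyt) {
    stop("'reference_content' must exceed 'C_cyt' (zero gradient)")
  }
  j <- predict(leak, reference_content)
  k <- as.numeric(j) / (reference_content - C_cyt)
  if (isTRUE(attr(j, "extrapolated"))) attr(k, "extrapolated") <- TRUE
  k
}

#' Full inverse analysis of a luminal fluorescence trace
#'
#' Runs the pipeline: leak fit on the post-inhibition window, leak
#' subtraction, reconstruction of the stimulus-evoked store depletion from
#' the stimulus time, division by the gradient to obtain the open-receptor
#' time course, and a leak rate-constant estimate.
#'
#' @param trace A [fluorescence_trace()] with at least a `serca_inhibitor`
#'   annotation; the `stimulus` annotation marks the start of the
#'   reconstruction span (default: end of the leak window).
#' @param family J_leak-vs-content family, see [fit_leak()].
#' @param C_cyt Cytosolic Ca2+ in content units.
#' @param smooth_window,smooth_order Derivative smoothing, see
#'   [subtract_leak()].
#' @param gradient_floor See [open_receptors()].
#' @param reference_content Content for the k_leak estimate (default: the
#'   content at the start of the leak window).
#' @return An object of class `"trace_reconstruction"`: the `leak` model,
#'   `k_leak` estimate, and a `result` data.frame with `time_s`,
#'   `evoked_flux`, `reconstructed_content`, `open_receptors_au` over the
#'   analysis span.
#' @export
analyze_trace <- function(trace, family = c("poly2", "exponential"),
                          C_cyt = 0.22, smooth_window = 7L,
                          smooth_order = 2L, gradient_floor = NULL,
                          reference_content = NULL) {
  stopifnot(inherits(trace, "fluor_trace"))
  family <- match.arg(family)
  leak <- fit_leak(trace, family = family, C_cyt = C_cyt)
  flux <- subtract_leak(trace, leak, smooth_window, smooth_order)

  # analysis span: from the stimulus; for stimulus-free (leak-only) records,
  # the leak window itself, where the evoked flux should be ~0
  start <- trace$annotations$stimulus
  if (is.null(start)) start <- leak$window[1]
  sel <- trace$times >= start
  if (sum(sel) < 2L) stop("analysis span has fewer than 2 samples")
  content <- trace_content(trace)
  initial <- content[which(sel)[1]]
  # exact telescoping of the evoked-flux integral: integral(-dC/dt) is
  # C(t0) - C(t), so the reconstruction is the measured content with the
  # integrated leak restored; this avoids re-integrating the finite-
  # difference derivative, which loses mass at the stimulus-onset kink
  content_s <- content
  if (!is.null(smooth_window) && smooth_window >= 3L) {
    sw <- smooth_window + (1L - smooth_window %% 2L)
    if (sw <= length(content) && sw > smooth_order + 1) {
      content_s <- signal::sgolayfilt(content, p = smooth_order, n = sw)
    }
  }
  jl_span <- predict(leak, content_s[sel])
  rec <- content_s[sel] +
    pracma::cumtrapz(trace$times[sel], as.numeric(jl_span))[, 1]
  rec <- rec - rec[1] + initial
  if (any(rec < 0)) attr(rec, "below_zero") <- TRUE
  au <- open_receptors(flux$evoked_flux[sel], rec, C_cyt, gradient_floor)
  if (is.null(reference_content)) {
    reference_content <- content[trace$times >= leak$window[1]][1]
  }
  k_leak <- estimate_k_leak(leak, reference_content, C_cyt)
  res <- data.frame(time_s = trace$times[sel],
                    evoked_flux = flux$evoked_flux[sel],
                    reconstructed_content = as.numeric(rec),
                    open_receptors_au = au)
  structure(list(leak = leak, k_leak = k_leak, result = res,
                 trace = trace,
                 extrapolated = isTRUE(attr(flux, "extrapolated"))),
            class = "trace_reconstruction")
}

#' @export
print.trace_reconstruction <- function(x, ...) {
  cat("Trace reconstruction\n")
  cat(sprintf("  leak rate (mono-exp fit): %.4g /s\n", x$leak$rate))
  cat(sprintf("  k_leak at reference     : %.4g /s\n", as.numeric(x$k_leak)))
  cat(sprintf("  analysis span           : %g to %g s (%d samples)\n",
              x$result$time_s[1], x$result$time_s[nrow(x$result)],
              nrow(x$result)))
  invisible(x)
}

#' @export
summary.trace_reconstruction <- function(object, ...) {
  print(object)
  r <- object$result
  cat(sprintf("  peak open receptors (a.u.): %.4g at t = %g s\n",
              max(r$open_receptors_au, na.rm = TRUE),
              r$time_s[which.max(r$open_receptors_au)]))
  cat(sprintf("  content %g -> %.4g (%.1f%% of initial)\n",
              r$reconstructed_content[1],
              r$reconstructed_content[nrow(r)],
              100 * r$reconstructed_content[nrow(r)] /
                r$reconstructed_content[1]))
  invisible(object)
}

#' @export
plot.trace_reconstruction <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  r <- x$result
  graphics::plot(r$time_s, r$reconstructed_content, type = "l",
                 xlab = "time (s)", ylab = "content", ...)
  graphics::plot(r$time_s, r$open_receptors_au, type = "l",
                 xlab = "time (s)", ylab = "open receptors (a.u.)", ...)
  invisible(x)
}
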