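#' Hill (four-parameter logistic) response
#'
#' response = bottom + (top - bottom) * L^h / (L^h + midpoint^h).
#' At L = midpoint the response is halfway between bottom and top.
#'
#' @param L Ligand concentration, nM (>= 0). Vectorised.
#' @param midpoint EC50 or IC50, nM (> 0).
#' @param hill Hill coefficient h (!= 0). Negative h gives a descending
#'   curve (inhibition).
#' @param top,bottom Response plateaus (top >= bottom).
#' @return Response values.
#' @examples
#' hill_response(166, midpoint = 166, hill = 1, top = 86, bottom = 0)  # 43
#' @export
hill_response <- function(L, midpoint, hill = 1, top = 1, bottom = 0) {
  .check_nonneg(L, "L")
  .check_pos(midpoint, "midpoint")
  if (!is.numeric(hill) || length(hill) != 1L || !is.finite(hill) ||
      hill == 0) {
    stop("'hill' must be a single nonzero finite number")
  }
  if (top < bottom) stop("'top' must be >= 'bottom'")
  # L^h/(L^h + m^h) written on the log scale to stay finite for h < 0, L = 0
  frac <- 1 / (1 + exp(hill * (log(midpoint) - log(L))))
  frac[L == 0] <- if (hill > 0) 0 else 1
  bottom + (top - bottom) * frac
}

#' Fit a Hill equation to dose-response data
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of the four-parameter
#' logistic, initialised from the data: bottom = min response, top = max
#' response, midpoint = concentration whose response is nearest half-range,
#' h = 1. Degenerate data (constant response, too few concentrations) and
#' non-convergence are reported as errors, never silently clamped.
#'
#' @param concentrations Concentrations in nM (>= 4 distinct values).
#' @param responses Responses, same length.
#' @param fix_bottom,fix_top Optionally fix a plateau at a known value.
#' @return An object of class `"hill_fit"`: a list with `midpoint` (nM),
#'   `p_midpoint` (-log10 molar), `hill`, `top`, `bottom`, `rss`, `fitted`,
#'   `data`, and the underlying `nls` object.
#' @seealso [hill_response()], [coef.hill_fit()], [predict.hill_fit()]
#' @examples
#' L <- c(10, 30, 100, 300, 1000, 3000)
#' y <- hill_response(L, midpoint = 186, hill = 1, top = 100, bottom = 0)
#' fit <- fit_hill(L, y)
#' coef(fit)
#' @export
fit_hill <- function(concentrations, responses,
                     fix_bottom = NULL, fix_top = NULL) {
  .check_nonneg(concentrations, "concentrations")
  if (!is.numeric(responses) || length(responses) != length(concentrations) ||
      any(!is.finite(responses))) {
    stop("'responses' must be finite and match 'concentrations' in length")
  }
  if (length(unique(concentrations)) < 4L) {
    stop("need at least 4 distinct concentrations to fit a Hill equation")
  }
  if (diff(range(responses)) <= 0 ||
      diff(range(responses)) < 1e-12 * max(abs(responses), 1)) {
    stop("Hill fit failure: responses are constant")
  }

  dat <- data.frame(L = as.numeric(concentrations),
                    y = as.numeric(responses))
  b0 <- if (is.null(fix_bottom)) min(dat$y) else fix_bottom
  t0 <- if (is.null(fix_top)) max(dat$y) else fix_top
  half <- (b0 + t0) / 2
  pos <- dat$L > 0
  m0 <- dat$L[pos][which.min(abs(dat$y[pos] - half))]
  if (length(m0) == 0L || !is.finite(m0) || m0 <= 0) m0 <- stats::median(dat$L[pos])

  # fit log(midpoint) so the optimizer cannot wander non-positive
  start <- list(lm0 = log(m0), h = 1)
  form <- if (is.null(fix_bottom) && is.null(fix_top)) {
    start <- c(start, list(top = t0, bottom = b0))
    y ~ bottom + (top - bottom) / (1 + exp(h * (lm0 - log(L))))
  } else if (is.null(fix_top)) {
    start <- c(start, list(top = t0))
    substitute(y ~ BOT + (top - BOT) / (1 + exp(h * (lm0 - log(L)))),
               list(BOT = fix_bottom))
  } else if (is.null(fix_bottom)) {
    start <- c(start, list(bottom = b0))
    substitute(y ~ bottom + (TOP - bottom) / (1 + exp(h * (lm0 - log(L)))),
               list(TOP = fix_top))
  } else {
    substitute(y ~ BOT + (TOP - BOT) / (1 + exp(h * (lm0 - log(L)))),
               list(BOT = fix_bottom, TOP = fix_top))
  }

  dat_fit <- dat[dat$L > 0, , drop = FALSE]  # logistic form needs log(L)
  fit <- tryCatch(
    minpack.lm::nlsLM(stats::as.formula(form), data = dat_fit, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("Hill fit failure: ", conditionMessage(e)))

  cf <- stats::coef(fit)
  midpoint <- exp(unname(cf[["lm0"]]))
  top <- if (is.null(fix_top)) unname(cf[["top"]]) else fix_top
  bottom <- if (is.null(fix_bottom)) unname(cf[["bottom"]]) else fix_bottom
  hill <- unname(cf[["h"]])
  if (top < bottom) {  # normalise orientation: keep top >= bottom
    tmp <- top; top <- bottom; bottom <- tmp; hill <- -hill
  }
  fitted_all <- hill_response(dat$L, midpoint, hill, top, bottom)
  structure(list(
    midpoint = midpoint,
    p_midpoint = pkd(midpoint),
    hill = hill,
    top = top,
    bottom = bottom,
    rss = sum((dat$y - fitted_all)^2),
    fitted = fitted_all,
    data = dat,
    nls = fit), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat("Hill fit\n")
  cat(sprintf("  midpoint : %.4g nM (p = %.3f)\n", x$midpoint, x$p_midpoint))
  cat(sprintf("  hill     : %.4g\n", x$hill))
  cat(sprintf("  top      : %.4g   bottom: %.4g\n", x$top, x$bottom))
  cat(sprintf("  RSS      : %.4g on %d points\n", x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(midpoint = object$midpoint, hill = object$hill,
    top = object$top, bottom = object$bottom)
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) object$data$L
       else if (is.numeric(newdata)) newdata
       else newdata$L
  hill_response(L, object$midpoint, object$hill, object$top, object$bottom)
}

#' @export
plot.hill_fit <- function(x, n = 200, ...) {
  pos <- x$data$L > 0
  grid <- exp(seq(log(min(x$data$L[pos])), log(max(x$data$L)), length.out = n))
  graphics::plot(x$data$L, x$data$y, log = "x",
                 xlab = "concentration (nM)", ylab = "response", ...)
  graphics::lines(grid, predict(x, grid))
  graphics::abline(v = x$midpoint, lty = 3)
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  cat(sprintf(
    "Hill fit: midpoint %.4g nM (p%s = %.3f), h = %.3g, span %.4g to %.4g\n",
    object$midpoint, "X50", object$p_midpoint, object$hill,
    object$bottom, object$top))
  print(summary(object$nls))
  invisible(object)
}

#' Competition-binding K_D from an IC50 (Cheng-Prusoff)
#'
#' Corrects a half-maximal inhibitory concentration measured against a
#' radioligand for the radioligand's own occupancy:
#' K_D = IC50 / (1 + \[L*\]/K_D*).
#'
#' @param ic50 Measured IC50 of the competing ligand, nM.
#' @param radioligand_conc Free radioligand concentration \[L*\], nM.
#' @param radioligand_kd Radioligand K_D*, nM.
#' @return The competitor's K_D in nM (always <= IC50).
#' @export
kd_from_ic50 <- function(ic50, radioligand_conc, radioligand_kd) {
  .check_pos(ic50, "ic50")
  .check_pos(radioligand_conc, "radioligand_conc")
  .check_pos(radioligand_kd, "radioligand_kd")
  ic50 / (1 + radioligand_conc / radioligand_kd)
}

#' Antagonist K_D from a dose ratio (Schild)
#'
#' K_D = \[antagonist\] / (DR - 1), where DR is the fold-increase in agonist
#' concentration needed for an equal response in the antagonist's presence.
#'
#' @param antagonist_conc Antagonist concentration, nM.
#' @param dose_ratio Dose ratio DR (> 1).
#' @return Antagonist K_D, nM.
#' @export
kd_from_dose_ratio <- function(antagonist_conc, dose_ratio) {
  .check_pos(antagonist_conc, "antagonist_conc")
  if (!is.numeric(dose_ratio) || any(!is.finite(dose_ratio)) ||
      any(dose_ratio <= 1)) {
    stop("'dose_ratio' must be > 1 (no rightward shift, no estimate)")
  }
  antagonist_conc / (dose_ratio - 1)
}

#' Binding free-energy difference between two receptor constructs
#'
#' Computes dG = -RT ln K_D (K_D in molar) for a ligand binding to the
#' isolated binding core (IBC) and to the longer N-terminal construct (NT),
#' and their difference ddG = dG_IBC - dG_NT, the binding energy diverted
#' into conformational change of the N-terminal suppressor domain.
#'
#' @param kd_ibc,kd_nt K_D values in nM.
#' @param temperature Absolute temperature, K (default 277, i.e. 4 C
#'   binding-assay conditions).
#' @return A list of class `"energetics_result"` with `delta_G_IBC`,
#'   `delta_G_NT`, `delta_delta_G` (all J/mol) and `temperature`.
#' @export
delta_delta_G <- function(kd_ibc, kd_nt, temperature = 277) {
  .check_pos(kd_ibc, "kd_ibc")
  .check_pos(kd_nt, "kd_nt")
  .check_pos(temperature, "temperature")
  R <- 8.31446261815324  # J/mol/K
  dg <- function(kd_nM) -R * temperature * log(kd_nM * 1e-9)
  g_ibc <- dg(kd_ibc)
  g_nt <- dg(kd_nt)
  structure(list(delta_G_IBC = g_ibc, delta_G_NT = g_nt,
                 delta_delta_G = g_ibc - g_nt, temperature = temperature),
            class = "energetics_result")
}

#' @export
print.energetics_result <- function(x, ...) {
  cat(sprintf("dG_IBC = %.3f kJ/mol, dG_NT = %.3f kJ/mol at %g K\n",
              x$delta_G_IBC / 1000, x$delta_G_NT / 1000, x$temperature))
  cat(sprintf("ddG (IBC - NT) = %.3f kJ/mol\n", x$delta_delta_G / 1000))
  invisible(x)
}

#' Read a two-column dose-response table
#'
#' Expects a delimited text file with a header row and columns
#' `concentration_nM` and `response`; lines starting with `#` are metadata.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return A data.frame with columns `concentration_nM`, `response`.
#' @export
read_dose_response <- function(path, sep = ",") {
  d <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                         strip.white = TRUE)
  need <- c("concentration_nM", "response")
  if (!all(need %in% names(d))) {
    stop("dose-response file must have columns: ",
         paste(need, collapse = ", "))
  }
  d[need]
}

#' Write a Hill fit as a delimited summary
#'
#' @param fit A `hill_fit`.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_hill_fit <- function(fit, path, sep = ",") {
  stopifnot(inherits(fit, "hill_fit"))
  d <- data.frame(midpoint_nM = fit$midpoint, p_midpoint = fit$p_midpoint,
                  hill = fit$hill, top = fit$top, bottom = fit$bottom,
                  rss = fit$rss)
  utils::write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
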