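#' Ligand binding parameters
#'
#' Bundle a ligand's equilibrium dissociation constant with a label and the
#' assay context in which it was measured. Concentrations are in nM
#' throughout; log-molar quantities (pKD) are derived on demand.
#'
#' @param name Ligand label.
#' @param kd Equilibrium dissociation constant, nM (> 0).
#' @param assay_context Optional free-text context, e.g. `"CLM 22C"`.
#' @return An object of class `"ligand_params"` with fields `name`, `kd`
#'   (nM) and `assay_context`.
#' @examples
#' ip3 <- ligand_params("IP3", kd = 794)
#' pkd(ip3)
#' @export
ligand_params <- function(name, kd, assay_context = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  .check_pos(kd, "kd")
  structure(list(name = name, kd = kd, assay_context = assay_context),
            class = "ligand_params")
}

#' @export
print.ligand_params <- function(x, ...) {
  cat(sprintf("Ligand '%s': K_D = %g nM (pK_D = %.3f)%s\n", x$name, x$kd,
              pkd(x), if (is.null(x$assay_context)) "" else
                paste0(" [", x$assay_context, "]")))
  invisible(x)
}

#' Negative log10 molar dissociation constant
#'
#' @param x A `ligand_params` object or a K_D in nM.
#' @return pK_D = -log10(K_D in molar).
#' @export
pkd <- function(x) {
  kd <- if (inherits(x, "ligand_params")) x$kd else x
  .check_pos(kd, "kd")
  -log10(kd * 1e-9)
}

#' Tetrameric receptor occupancy model
#'
#' A receptor population with four independent, identical ligand-binding
#' sites per tetramer and a known number of receptors per cell. Only
#' receptors with all four sites occupied are eligible to gate.
#'
#' @param ligand A [ligand_params()] object, or a K_D in nM.
#' @param receptors_per_cell Number of receptors per cell (>= 0).
#' @return An object of class `"occupancy_model"`.
#' @examples
#' m <- occupancy_model(794, receptors_per_cell = 49146)
#' tetra_count(186, m)   # about 60 tetra-liganded receptors per cell
#' @export
occupancy_model <- function(ligand, receptors_per_cell) {
  if (!inherits(ligand, "ligand_params")) {
    ligand <- ligand_params("ligand", kd = ligand)
  }
  if (!is.numeric(receptors_per_cell) || length(receptors_per_cell) != 1L ||
      !is.finite(receptors_per_cell) || receptors_per_cell < 0) {
    stop("'receptors_per_cell' must be a single non-negative finite number")
  }
  structure(list(ligand = ligand, receptors_per_cell = receptors_per_cell),
            class = "occupancy_model")
}

#' @export
print.occupancy_model <- function(x, ...) {
  cat(sprintf("Occupancy model: %s, K_D = %g nM, %s receptors/cell\n",
              x$ligand$name, x$ligand$kd,
              format(x$receptors_per_cell, big.mark = ",")))
  invisible(x)
}

#' Fractional occupancy of a single binding site
#'
#' One-site binding isotherm alpha = L/(L + K_D), the probability that any
#' one of the four identical, independent IP3-binding sites of a tetramer
#' is occupied at ligand concentration L.
#'
#' @param L Free ligand concentration, nM (>= 0). Vectorised.
#' @param kd Equilibrium dissociation constant, nM (> 0).
#' @return alpha in [0, 1).
#' @examples
#' fractional_occupancy(794, 794)  # 0.5 at L = K_D
#' @export
fractional_occupancy <- function(L, kd) {
  .check_nonneg(L, "L")
  .check_pos(kd, "kd")
  L / (L + kd)
}

#' Fraction of receptors with all four sites occupied
#'
#' With four independent identical sites, the tetra-liganded fraction is
#' alpha^4.
#'
#' @param alpha Per-site fractional occupancy in [0, 1]. Vectorised.
#' @return alpha^4.
#' @export
tetra_fraction <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) ||
      any(alpha < 0) || any(alpha > 1)) {
    stop("'alpha' must be finite and within [0, 1]")
  }
  alpha^4
}

#' Expected number of tetra-liganded receptors per cell
#'
#' @param L Free ligand concentration, nM. Vectorised.
#' @param model An [occupancy_model()].
#' @return `receptors_per_cell * alpha(L)^4` (real, not rounded).
#' @examples
#' m <- occupancy_model(794, 9101)
#' tetra_count(143, m)  # ~5
#' @export
tetra_count <- function(L, model) {
  stopifnot(inherits(model, "occupancy_model"))
  model$receptors_per_cell *
    tetra_fraction(fractional_occupancy(L, model$ligand$kd))
}

#' Fold-change in tetra-liganded receptors between two concentrations
#'
#' Ratio alpha^4(L2)/alpha^4(L1); independent of the receptor count.
#'
#' @param L1,L2 Ligand concentrations, nM (both > 0).
#' @param kd K_D, nM.
#' @return The fold-change (> 1 when L2 > L1).
#' @examples
#' tetra_fold_change(60, 90, 794)  # 4.41
#' @export
tetra_fold_change <- function(L1, L2, kd) {
  .check_pos(L1, "L1")
  .check_pos(L2, "L2")
  .check_pos(kd, "kd")
  tetra_fraction(fractional_occupancy(L2, kd)) /
    tetra_fraction(fractional_occupancy(L1, kd))
}

#' Ligand concentration yielding a target tetra-liganded count
#'
#' Inverts the alpha^4 relation: alpha = (count/N)^(1/4), then
#' L = K_D * alpha / (1 - alpha).
#'
#' @param target_count Desired expected tetra-liganded receptors per cell,
#'   with 0 < target_count < receptors_per_cell. Vectorised.
#' @param model An [occupancy_model()].
#' @return Ligand concentration in nM.
#' @examples
#' m <- occupancy_model(794, 9101)
#' concentration_for_count(c(5, 10, 20), m)  # ~143, 177, 219 nM
#' @export
concentration_for_count <- function(target_count, model) {
  stopifnot(inherits(model, "occupancy_model"))
  n <- model$receptors_per_cell
  if (!is.numeric(target_count) || any(!is.finite(target_count)) ||
      any(target_count <= 0)) {
    stop("'target_count' must be finite and > 0")
  }
  if (any(target_count >= n)) {
    stop("'target_count' must be below 'receptors_per_cell' (alpha < 1)")
  }
  alpha <- (target_count / n)^(1 / 4)
  model$ligand$kd * alpha / (1 - alpha)
}

#' Receptors per cell from a Bmax-calibrated standard
#'
#' Scale a lysate's immunoblot signal against a standard whose receptor
#' density is known from saturation binding (Bmax), then divide by the cell
#' density of the lysate.
#'
#' @param bmax_per_volume Receptor density of the standard, receptors/uL.
#' @param cells_per_volume Cell density of the lysate, cells/uL.
#' @param signal_ratio (lysate band intensity per uL) / (standard band
#'   intensity per uL); >= 0.
#' @return Receptors per cell.
#' @export
receptors_per_cell_from_bmax <- function(bmax_per_volume, cells_per_volume,
                                         signal_ratio) {
  .check_pos(bmax_per_volume, "bmax_per_volume")
  .check_pos(cells_per_volume, "cells_per_volume")
  .check_nonneg(signal_ratio, "signal_ratio")
  signal_ratio * bmax_per_volume / cells_per_volume
}

# shared argument checks: scalar-or-vector numeric domain guards
.check_pos <- function(x, nm) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("'%s' must be finite and > 0", nm))
  }
  invisible(x)
}

.check_nonneg <- function(x, nm) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("'%s' must be finite and >= 0", nm))
  }
  invisible(x)
}
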