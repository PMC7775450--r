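## CODATA 2018 physical constants (SI), stored once.
.const <- list(
  e    = 1.602176634e-19,   # elementary charge [C]
  eps0 = 8.8541878128e-12,  # vacuum permittivity [F m^-1]
  kB   = 1.380649e-23       # Boltzmann constant [J K^-1]
)

#' Polyelectrolyte chain geometry
#'
#' Describes a linear charged glycan chain (e.g. heparan sulphate) by its
#' contour length and the number of charged groups it carries.  The mean
#' distance between charges along the chain, `b = L/P`, is the quantity
#' that enters the Manning line charge density.
#'
#' @param contour_length Contour length `L` of the chain, in nm. Must be
#'   positive.
#' @param n_charges Number of charged groups `P` on the chain
#'   (dimensionless count, >= 1).
#' @param label Optional text label for the chain.
#'
#' @return An object of class `polyelectrolyte_chain`.
#' @examples
#' hs <- polyelectrolyte_chain(contour_length = 1, n_charges = 4,
#'                             label = "heparan sulphate")
#' charge_spacing(hs)  # 0.25 nm
#' @export
polyelectrolyte_chain <- function(contour_length, n_charges, label = "") {
  if (!is.numeric(contour_length) || length(contour_length) != 1L ||
      !is.finite(contour_length) || contour_length <= 0)
    stop("'contour_length' must be a single positive number (nm)")
  if (!is.numeric(n_charges) || length(n_charges) != 1L ||
      !is.finite(n_charges) || n_charges < 1)
    stop("'n_charges' must be a single number >= 1")
  structure(list(contour_length = contour_length,
                 n_charges = n_charges,
                 label = as.character(label)),
            class = "polyelectrolyte_chain")
}

#' Solvent conditions for electrostatics
#'
#' Temperature and relative permittivity of the solvent, used to compute
#' the Bjerrum length.  Defaults are water at 25 degrees C with a
#' dielectric constant of 78.5.
#'
#' @param temperature Absolute temperature in K (default 298.15).
#'   Alternatively supply `temperature_C` in degrees Celsius.
#' @param dielectric_constant Relative permittivity of the solvent
#'   (dimensionless, > 1; default 78.5).
#' @param temperature_C Temperature in degrees Celsius; if given it
#'   overrides `temperature`.
#'
#' @return An object of class `solvent_conditions`.
#' @export
solvent_conditions <- function(temperature = 298.15,
                               dielectric_constant = 78.5,
                               temperature_C = NULL) {
  if (!is.null(temperature_C)) temperature <- temperature_C + 273.15
  if (!is.numeric(temperature) || length(temperature) != 1L ||
      !is.finite(temperature) || temperature <= 0)
    stop("'temperature' must be a single positive number (K)")
  if (!is.numeric(dielectric_constant) || length(dielectric_constant) != 1L ||
      !is.finite(dielectric_constant) || dielectric_constant <= 1)
    stop("'dielectric_constant' must be a single number > 1")
  structure(list(temperature = temperature,
                 dielectric_constant = dielectric_constant),
            class = "solvent_conditions")
}

#' Mean charge spacing along a chain
#'
#' `b = L/P`: contour length divided by the number of charged groups.
#'
#' @param chain A [polyelectrolyte_chain()].
#' @return Charge spacing in nm.
#' @examples
#' charge_spacing(polyelectrolyte_chain(1, 4))  # heparan sulphate, 0.25 nm
#' @export
charge_spacing <- function(chain) {
  if (!inherits(chain, "polyelectrolyte_chain"))
    stop("'chain' must be a polyelectrolyte_chain")
  chain$contour_length / chain$n_charges
}

#' Bjerrum length
#'
#' Distance at which the electrostatic energy between two elementary
#' charges equals the thermal energy kT: `e^2 / (4 pi eps0 eps k T)`.
#' About 0.714 nm in water at 25 degrees C.
#'
#' @param conditions A [solvent_conditions()] object.
#' @return Bjerrum length in nm.
#' @examples
#' bjerrum_length(solvent_conditions())  # ~0.714 nm
#' @export
bjerrum_length <- function(conditions = solvent_conditions()) {
  if (!inherits(conditions, "solvent_conditions"))
    stop("'conditions' must be a solvent_conditions object")
  lb_m <- .const$e^2 /
    (4 * pi * .const$eps0 * conditions$dielectric_constant *
       .const$kB * conditions$temperature)
  lb_m * 1e9
}

#' Dimensionless line charge density and condensation state
#'
#' Computes the Manning parameter `xi` = Bjerrum length / charge spacing.
#' Counterion condensation occurs when `xi > 1`; in that regime mobile
#' counterions condense onto the chain until the effective charge density
#' is renormalized to the critical value, leaving an effective charge
#' fraction `1/xi` (condensed fraction `1 - 1/xi`, the standard Manning
#' closure for monovalent counterions).
#'
#' @param b Charge spacing in nm (> 0), e.g. from [charge_spacing()].
#' @param conditions A [solvent_conditions()] object.
#' @return An object of class `condensation_state`: a list with `xi`,
#'   `is_condensed`, `condensed_fraction`, `effective_charge_fraction`,
#'   `b` and `bjerrum_length`.
#' @examples
#' line_charge_density(0.25)  # heparan sulphate in water: xi ~ 2.9
#' @export
line_charge_density <- function(b, conditions = solvent_conditions()) {
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b) || b <= 0)
    stop("'b' must be a single positive number (nm)")
  lb <- bjerrum_length(conditions)
  xi <- lb / b
  structure(list(
    xi = xi,
    is_condensed = xi > 1,
    condensed_fraction = condensation_fraction(xi),
    effective_charge_fraction = if (xi > 1) 1 / xi else 1,
    b = b,
    bjerrum_length = lb
  ), class = "condensation_state")
}

#' Condensed-counterion charge fraction
#'
#' Fraction of the chain's charge neutralized by condensed counterions:
#' `max(0, 1 - 1/xi)` (Manning closure, monovalent counterions).  Zero at
#' or below the condensation threshold `xi = 1`, approaching 1 as
#' `xi -> Inf`.
#'
#' @param xi Dimensionless line charge density (> 0); vectorized.
#' @return Condensed fraction in `[0, 1)`.
#' @examples
#' condensation_fraction(2.9)  # ~0.655
#' @export
condensation_fraction <- function(xi) {
  if (!is.numeric(xi) || any(!is.finite(xi)) || any(xi <= 0))
    stop("'xi' must be positive and finite")
  pmax(0, 1 - 1 / xi)
}

#' @export
print.condensation_state <- function(x, ...) {
  cat("Manning condensation state\n")
  cat(sprintf("  charge spacing b:       %.4g nm\n", x$b))
  cat(sprintf("  Bjerrum length:         %.4g nm\n", x$bjerrum_length))
  cat(sprintf("  line charge density xi: %.4g\n", x$xi))
  cat(sprintf("  condensed:              %s\n",
              if (x$is_condensed) "yes (xi > 1)" else "no (xi <= 1)"))
  cat(sprintf("  condensed fraction:     %.4g\n", x$condensed_fraction))
  cat(sprintf("  effective charge frac.: %.4g\n",
              x$effective_charge_fraction))
  invisible(x)
}

#' @export
print.polyelectrolyte_chain <- function(x, ...) {
  cat(sprintf("Polyelectrolyte chain%s: L = %g nm, P = %g charges, b = %g nm\n",
              if (nzchar(x$label)) paste0(" (", x$label, ")") else "",
              x$contour_length, x$n_charges, charge_spacing(x)))
  invisible(x)
}

#' @export
print.solvent_conditions <- function(x, ...) {
  cat(sprintf("Solvent: T = %g K, epsilon = %g (Bjerrum length %.4g nm)\n",
              x$temperature, x$dielectric_constant, bjerrum_length(x)))
  invisible(x)
}
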