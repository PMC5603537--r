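#' @keywords internal
"_PACKAGE"

# IUPAC 2021 conventional atomic masses, 3 d.p.
.atomic_mass <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)

# Built-in registry of C_n H_a O_b N_c formulas used in the microcosm study.
.substrate_registry <- list(
  glucose     = c(n = 6,  a = 12, b = 6,  c = 0),
  galactose   = c(n = 6,  a = 12, b = 6,  c = 0),
  mannose     = c(n = 6,  a = 12, b = 6,  c = 0),
  xylose      = c(n = 5,  a = 10, b = 5,  c = 0),
  arabinose   = c(n = 5,  a = 10, b = 5,  c = 0),
  cellobiose  = c(n = 12, a = 22, b = 11, c = 0),
  `acetic acid` = c(n = 2, a = 4, b = 2, c = 0),
  acetate     = c(n = 2,  a = 4,  b = 2,  c = 0),
  biomass     = c(n = 5,  a = 7,  b = 2,  c = 1)
)

#' Define an organic electron-donor substrate C_n H_a O_b N_c
#'
#' A substrate is an empirical formula \eqn{C_nH_aO_bN_c} together with its
#' molar mass and carbon mass fraction. Named sugars and acids from the
#' built-in registry (glucose, galactose, mannose, xylose, arabinose,
#' cellobiose, acetic acid/acetate, and the standard cell-biomass formula
#' C5H7O2N under the name `"biomass"`) can be requested by name alone;
#' arbitrary formulas are given via `n`, `a`, `b`, `c`.
#'
#' @param name Substrate name. If `n` is missing the name is looked up in the
#'   registry (case-insensitive).
#' @param n,a,b,c Atoms of carbon, hydrogen, oxygen and nitrogen per formula
#'   unit. `n` must be at least 1; all must be non-negative integers.
#' @param molar_mass Optional molar mass (g/mol). Must agree with the mass
#'   computed from the formula within 0.1%; computed from IUPAC atomic masses
#'   when omitted.
#' @return An object of class `"substrate"` with fields `name`, `n`, `a`,
#'   `b`, `c`, `molar_mass` and `carbon_mass_fraction`.
#' @examples
#' substrate("glucose")
#' substrate("lactic acid", n = 3, a = 6, b = 3, c = 0)
#' @export
substrate <- function(name, n, a = 0, b = 0, c = 0, molar_mass = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (missing(n)) {
    key <- tolower(name)
    if (!key %in% names(.substrate_registry))
      stop("unknown substrate '", name, "'; supply n, a, b, c explicitly. ",
           "Registry: ", paste(names(.substrate_registry), collapse = ", "))
    f <- .substrate_registry[[key]]
    n <- f[["n"]]; a <- f[["a"]]; b <- f[["b"]]; c <- f[["c"]]
  }
  for (x in list(n = n, a = a, b = b, c = c)) {
    if (!is.numeric(x) || length(x) != 1L || x < 0 || x != round(x))
      stop("n, a, b, c must be single non-negative integers")
  }
  if (n < 1) stop("substrate must contain at least one carbon atom (n >= 1)")
  computed <- n * .atomic_mass[["C"]] + a * .atomic_mass[["H"]] +
    b * .atomic_mass[["O"]] + c * .atomic_mass[["N"]]
  if (is.null(molar_mass)) {
    molar_mass <- computed
  } else if (abs(molar_mass - computed) / computed > 0.001) {
    stop(sprintf("supplied molar mass %.3f differs from formula mass %.3f by more than 0.1%%",
                 molar_mass, computed))
  }
  structure(
    list(name = name, n = as.integer(n), a = as.integer(a),
         b = as.integer(b), c = as.integer(c),
         molar_mass = molar_mass,
         carbon_mass_fraction = n * .atomic_mass[["C"]] / molar_mass),
    class = "substrate"
  )
}

#' @export
print.substrate <- function(x, ...) {
  cat(sprintf("Substrate: %s (%s), M = %.3f g/mol, %.1f%% C by mass\n",
              x$name, formula_string(x), x$molar_mass,
              100 * x$carbon_mass_fraction))
  invisible(x)
}

#' Empirical formula as text, e.g. "C6H12O6"
#'
#' @param substrate A [substrate()] object.
#' @return A character string.
#' @export
formula_string <- function(substrate) {
  stopifnot(inherits(substrate, "substrate"))
  part <- function(sym, k) if (k == 0) "" else if (k == 1) sym else paste0(sym, k)
  paste0(part("C", substrate$n), part("H", substrate$a),
         part("O", substrate$b), part("N", substrate$c))
}

#' Electron equivalents per mole of donor
#'
#' The number of oxidizable electron equivalents of a donor
#' \eqn{C_nH_aO_bN_c} is \eqn{d = 4n + a - 2b - 3c}, the electrons released
#' on complete oxidation to CO2 with ammonium as the nitrogen end product.
#' For the standard cell formula C5H7O2N this gives the textbook
#' 20 e-eq per mole of cells.
#'
#' @param substrate A [substrate()] object.
#' @return Integer count of electron equivalents per mole.
#' @examples
#' electron_equivalents(substrate("glucose")) # 24
#' electron_equivalents(substrate("biomass")) # 20
#' @export
electron_equivalents <- function(substrate) {
  stopifnot(inherits(substrate, "substrate"))
  d <- 4L * substrate$n + substrate$a - 2L * substrate$b - 3L * substrate$c
  if (d <= 0)
    stop("formula ", formula_string(substrate),
         " has no oxidizable electron equivalents (d = ", d, ")")
  d
}

#' Chemical oxygen demand of a substrate
#'
#' COD equivalent of one mole of donor: 8 g COD per electron equivalent,
#' hence \eqn{8d} g COD per mole.
#'
#' @inheritParams electron_equivalents
#' @return g COD per mole of substrate.
#' @examples
#' substrate_cod(substrate("glucose")) # 192
#' @export
substrate_cod <- function(substrate) {
  8 * electron_equivalents(substrate)
}
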