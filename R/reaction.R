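#' Electron partition factors fs / fe
#'
#' Fraction of donor electron equivalents routed to cell synthesis (`fs`)
#' versus energy generation, i.e. methane (`fe`). The two must sum to 1;
#' `fe` defaults to `1 - fs`.
#'
#' @param fs Fraction to synthesis, in \[0, 1\].
#' @param fe Fraction to energy, in \[0, 1\]; defaults to `1 - fs`.
#' @return An object of class `"partition_factors"`.
#' @examples
#' partition_factors(0.2)
#' @export
partition_factors <- function(fs = 0.2, fe = 1 - fs) {
  stopifnot(is.numeric(fs), length(fs) == 1L, is.numeric(fe), length(fe) == 1L)
  if (fs < 0 || fs > 1) stop("fs must lie in [0, 1]")
  if (fe < 0 || fe > 1) stop("fe must lie in [0, 1]")
  if (abs(fs + fe - 1) > 1e-12) stop("fs + fe must sum to 1")
  structure(list(fs = fs, fe = fe), class = "partition_factors")
}

#' @export
print.partition_factors <- function(x, ...) {
  cat(sprintf("Electron partition: fs = %g (synthesis), fe = %g (energy)\n",
              x$fs, x$fe))
  invisible(x)
}

# atoms (C, H, O, N) and charge per formula unit of each reaction species
.species_matrix <- rbind(
  water = c(C = 0, H = 2, O = 1, N = 0, q = 0),
  ch4   = c(C = 1, H = 4, O = 0, N = 0, q = 0),
  co2   = c(C = 1, H = 0, O = 2, N = 0, q = 0),
  cells = c(C = 5, H = 7, O = 2, N = 1, q = 0),
  nh4   = c(C = 0, H = 4, O = 0, N = 1, q = 1),
  hco3  = c(C = 1, H = 1, O = 3, N = 0, q = -1)
)

#' Build the balanced methanogenic cell-synthesis reaction for a donor
#'
#' Constructs the generalized methanogenesis reaction for an organic donor
#' \eqn{C_nH_aO_bN_c} with CO2 as the electron acceptor and C5H7O2N as the
#' cell formula, splitting the donor's \eqn{d = 4n + a - 2b - 3c} electron
#' equivalents between energy (methane, fraction `fe`) and cell synthesis
#' (fraction `fs`):
#' \deqn{CH_4: d f_e / 8, \quad cells: d f_s / 20,
#'       \quad CO_2: n - c - d f_s/5 - d f_e/8,}
#' with water, ammonium and bicarbonate coefficients fixed by the element
#' and charge balance. Coefficients are stored signed on the product side
#' (positive = produced, negative = consumed); for nitrogen-free donors the
#' NH4+/HCO3- coefficients are negative, i.e. the synthesis of cells draws
#' ammonium and bicarbonate from the medium.
#'
#' @param substrate A [substrate()] object (must have d > 0).
#' @param factors A [partition_factors()] object.
#' @return An object of class `"methanogenesis_reaction"`: fields
#'   `substrate`, `factors`, `d` and a named numeric vector `coefficients`
#'   with elements `water`, `ch4`, `co2`, `cells`, `nh4`, `hco3`.
#' @examples
#' build_reaction(substrate("glucose"), partition_factors(0.2))
#' @export
build_reaction <- function(substrate, factors = partition_factors(0.2)) {
  stopifnot(inherits(substrate, "substrate"))
  if (!inherits(factors, "partition_factors"))
    factors <- partition_factors(factors)
  d <- electron_equivalents(substrate)
  n <- substrate$n; a <- substrate$a; b <- substrate$b; c <- substrate$c
  fs <- factors$fs; fe <- factors$fe
  coef <- c(
    water = -(2 * n + c - b - 9 * d * fs / 20 - d * fe / 4),
    ch4   = d * fe / 8,
    co2   = n - c - d * fs / 5 - d * fe / 8,
    cells = d * fs / 20,
    nh4   = c - d * fs / 20,
    hco3  = c - d * fs / 20
  )
  rxn <- structure(
    list(substrate = substrate, factors = factors, d = d, coefficients = coef),
    class = "methanogenesis_reaction"
  )
  resid <- reaction_balance(rxn)
  if (max(abs(resid)) > 1e-9)
    stop("internal error: reaction does not balance (max residual ",
         format(max(abs(resid))), ")")
  rxn
}

#' Element and charge balance residuals of a reaction
#'
#' Counts C, H, O, N atoms and charge on the product side (signed
#' coefficients) minus the donor on the reactant side. A correctly built
#' reaction returns residuals that are zero to numerical precision.
#'
#' @param reaction A [build_reaction()] object.
#' @return Named numeric vector of residuals for `C`, `H`, `O`, `N`, `q`.
#' @export
reaction_balance <- function(reaction) {
  stopifnot(inherits(reaction, "methanogenesis_reaction"))
  s <- reaction$substrate
  donor <- c(C = s$n, H = s$a, O = s$b, N = s$c, q = 0)
  drop(reaction$coefficients %*% .species_matrix) - donor
}

#' Coefficient table for a reaction
#'
#' @param reaction A [build_reaction()] object.
#' @return A data frame with columns `species`, `formula`, `coefficient`
#'   (signed, product-side convention) and `side` (`"product"` or
#'   `"reactant"` after moving negative coefficients across). Suitable for
#'   `write.csv()`.
#' @export
reaction_coefficients <- function(reaction) {
  stopifnot(inherits(reaction, "methanogenesis_reaction"))
  co <- reaction$coefficients
  labels <- c(water = "H2O", ch4 = "CH4", co2 = "CO2",
              cells = "C5H7O2N", nh4 = "NH4+", hco3 = "HCO3-")
  out <- data.frame(
    species = c("donor", names(co)),
    formula = c(formula_string(reaction$substrate), unname(labels[names(co)])),
    coefficient = c(-1, unname(co)),
    stringsAsFactors = FALSE
  )
  out$side <- ifelse(out$coefficient < 0, "reactant", "product")
  out
}

#' @export
format.methanogenesis_reaction <- function(x, digits = 4, ...) {
  tab <- reaction_coefficients(x)
  tab <- tab[abs(tab$coefficient) > 1e-12, ]
  term <- function(row) {
    k <- abs(row$coefficient)
    if (abs(k - 1) < 1e-12) row$formula
    else paste0(format(k, digits = digits), " ", row$formula)
  }
  lhs <- vapply(which(tab$side == "reactant"),
                function(i) term(tab[i, ]), character(1))
  rhs <- vapply(which(tab$side == "product"),
                function(i) term(tab[i, ]), character(1))
  paste(paste(lhs, collapse = " + "), "->", paste(rhs, collapse = " + "))
}

#' @export
print.methanogenesis_reaction <- function(x, ...) {
  cat(sprintf("Methanogenesis reaction for %s (d = %d e-eq/mol, fs = %g):\n",
              x$substrate$name, x$d, x$factors$fs))
  cat("  ", format(x), "\n")
  invisible(x)
}

#' Theoretical methane yield of a substrate
#'
#' Moles of CH4 produced per mole of donor under the partitioned reaction:
#' \eqn{d f_e / 8}. With `fs = 0` this is the complete-conversion (Buswell)
#' limit \eqn{d/8}.
#'
#' @inheritParams build_reaction
#' @return mol CH4 per mol substrate.
#' @examples
#' theoretical_ch4_yield(substrate("glucose"), partition_factors(0.2)) # 2.4
#' theoretical_ch4_yield(substrate("xylose"),  partition_factors(0.2)) # 2.0
#' @export
theoretical_ch4_yield <- function(substrate, factors = partition_factors(0.2)) {
  unname(build_reaction(substrate, factors)$coefficients["ch4"])
}

#' Theoretical methane yield per gram of substrate carbon
#'
#' Converts the molar yield to micromoles of CH4 per gram of elemental
#' substrate carbon, the unit in which cumulative microcosm methane curves
#' are usually reported.
#'
#' @inheritParams build_reaction
#' @return µmol CH4 per g substrate carbon.
#' @export
theoretical_ch4_per_gC <- function(substrate, factors = partition_factors(0.2)) {
  theoretical_ch4_yield(substrate, factors) /
    (.atomic_mass[["C"]] * substrate$n) * 1e6
}

#' Net biomass yield from the electron partition
#'
#' \deqn{Y = \frac{f_s M_c}{n_e \cdot 8} \;\mathrm{g\ cells\ (g\ COD)^{-1}},}
#' with \eqn{M_c = 113} g cells per mol cells (C5H7O2N) and
#' \eqn{n_e = 20} e-eq per mol cells, so \eqn{Y = 0.706 f_s} to three
#' significant figures. Decay is neglected.
#'
#' @param factors A [partition_factors()] object (or a plain `fs` value).
#' @param cell_mass Molar mass of cells, g/mol (default 113).
#' @param cell_electrons Electron equivalents per mol cells (default 20).
#' @return g cells per g COD of donor.
#' @examples
#' biomass_yield(partition_factors(0.2)) # 0.14125
#' @export
biomass_yield <- function(factors = partition_factors(0.2),
                          cell_mass = 113, cell_electrons = 20) {
  if (!inherits(factors, "partition_factors"))
    factors <- partition_factors(factors)
  factors$fs * cell_mass / (cell_electrons * 8)
}

#' Conversion efficiency of observed methane against the theoretical yield
#'
#' Owen-style efficiency: observed peak methane divided by the theoretical
#' methane for the dosed substrate, as a percentage. The `"partitioned"`
#' basis uses the fs/fe reaction (default fs = 0.2); the `"complete"` basis
#' sets fs = 0, i.e. every electron equivalent to methane.
#'
#' @param observed_peak_ch4 Observed peak methane, mol per mol substrate.
#' @param substrate A [substrate()] object.
#' @param factors A [partition_factors()] object (ignored for
#'   `basis = "complete"`).
#' @param basis `"partitioned"` (default) or `"complete"`.
#' @return Efficiency in percent.
#' @examples
#' conversion_efficiency(2.13, substrate("glucose")) # 88.75
#' @export
conversion_efficiency <- function(observed_peak_ch4, substrate,
                                  factors = partition_factors(0.2),
                                  basis = c("partitioned", "complete")) {
  basis <- match.arg(basis)
  stopifnot(is.numeric(observed_peak_ch4), all(observed_peak_ch4 >= 0))
  if (basis == "complete") factors <- partition_factors(0)
  theo <- theoretical_ch4_yield(substrate, factors)
  if (theo <= 0)
    stop("theoretical methane yield is zero for ",
         formula_string(substrate), " at fs = ", factors$fs)
  100 * observed_peak_ch4 / theo
}
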