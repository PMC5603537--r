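# gas constant, L atm / (mol K)
.R_gas <- 0.0820574

#' Carbonate equilibrium constants
#'
#' Holds the first and second carbonic-acid dissociation constants (as pK)
#' and the Henry's-law constant for CO2. Defaults are the standard values
#' at 25 °C (pK1 = 6.35, pK2 = 10.33, KH = 0.0339 mol/L/atm). For other
#' temperatures an optional van't Hoff correction is applied using standard
#' reaction enthalpies (K1: +7.7, K2: +14.9, CO2 dissolution: -19.4 kJ/mol).
#'
#' @param temperature Temperature in °C.
#' @param pK1,pK2 Dissociation constants at 25 °C (-log10 scale).
#' @param henry_kh Henry constant for CO2 at 25 °C, mol/L/atm.
#' @param vant_hoff Apply the van't Hoff temperature correction when
#'   `temperature` differs from 25 °C (default `FALSE`, matching gas
#'   measurements converted to a 25 °C standard state).
#' @return An object of class `"carbonate_system"`.
#' @examples
#' carbonate_system()
#' carbonate_system(temperature = 30, vant_hoff = TRUE)
#' @export
carbonate_system <- function(temperature = 25, pK1 = 6.35, pK2 = 10.33,
                             henry_kh = 0.0339, vant_hoff = FALSE) {
  stopifnot(pK1 < pK2, henry_kh > 0)
  if (vant_hoff && temperature != 25) {
    Tk <- temperature + 273.15
    T0 <- 298.15
    shift <- function(dH) dH * 1000 / (log(10) * 8.314) * (1 / Tk - 1 / T0)
    # ln K2/K1 = -dH/R (1/T2 - 1/T1); pK shifts by +dH/(R ln10) (1/T2 - 1/T1)
    pK1 <- pK1 + shift(7.7)
    pK2 <- pK2 + shift(14.9)
    henry_kh <- henry_kh * exp(-(-19.4) * 1000 / 8.314 * (1 / Tk - 1 / T0))
  }
  structure(list(temperature = temperature, pK1 = pK1, pK2 = pK2,
                 henry_kh = henry_kh),
            class = "carbonate_system")
}

#' @export
print.carbonate_system <- function(x, ...) {
  cat(sprintf("Carbonate system at %g degC: pK1 = %.3f, pK2 = %.3f, KH = %.4g mol/L/atm\n",
              x$temperature, x$pK1, x$pK2, x$henry_kh))
  invisible(x)
}

#' Ionization fractions of dissolved inorganic carbon
#'
#' Closed-form fractions of H2CO3* (alpha0), HCO3- (alpha1) and CO3^2-
#' (alpha2) at a given pH:
#' \deqn{\alpha_1 = \left(1 + 10^{pK_1 - pH} + 10^{pH - pK_2}\right)^{-1}}
#' and analogously for the others; the three always sum to 1.
#'
#' @param pH Solution pH, strictly between 0 and 14; vectorized.
#' @param system A [carbonate_system()].
#' @return For scalar `pH`, a named numeric vector `c(alpha0, alpha1,
#'   alpha2)`; for vector `pH`, a matrix with one row per pH.
#' @examples
#' speciate_dic(7) # alpha1 ~ 0.817 with default constants
#' @export
speciate_dic <- function(pH, system = carbonate_system()) {
  stopifnot(inherits(system, "carbonate_system"))
  if (any(pH <= 0 | pH >= 14)) stop("pH must lie strictly between 0 and 14")
  a0 <- 1 / (1 + 10^(pH - system$pK1) + 10^(2 * pH - system$pK1 - system$pK2))
  a1 <- 1 / (1 + 10^(system$pK1 - pH) + 10^(pH - system$pK2))
  a2 <- 1 / (1 + 10^(system$pK2 - pH) + 10^(system$pK1 + system$pK2 - 2 * pH))
  out <- cbind(alpha0 = a0, alpha1 = a1, alpha2 = a2)
  if (length(pH) == 1L) out[1L, ] else out
}

#' Configuration of a sealed microcosm bottle
#'
#' Volumes, headspace pressure, substrate dose and bicarbonate buffer of
#' one incubation bottle. The default buffer is the nominal
#' 1 mg/L NaHCO3 of the microcosm recipe; that concentration provides
#' almost no buffering capacity (1 g/L is the usual choice), so a warning
#' is emitted when the default is used.
#'
#' @param substrate A [substrate()] object.
#' @param liquid_volume Liquid volume, L.
#' @param headspace_volume Headspace volume, L.
#' @param headspace_pressure Headspace pressure, atm.
#' @param dose_mol Substrate dose, mol per bottle (default: 10 mM in the
#'   liquid volume).
#' @param buffer_mg_per_l NaHCO3 concentration in the liquid, mg/L.
#' @param temperature Temperature (°C) used for gas-law conversions
#'   (default 25, the standard reporting state).
#' @return An object of class `"bottle_config"`; includes the derived
#'   `buffer_carbon_mol`, the moles of inorganic buffer carbon per bottle.
#' @export
bottle_config <- function(substrate,
                          liquid_volume = 0.1,
                          headspace_volume = 0.06,
                          headspace_pressure = 1,
                          dose_mol = 0.010 * liquid_volume,
                          buffer_mg_per_l = 1,
                          temperature = 25) {
  stopifnot(inherits(substrate, "substrate"),
            liquid_volume > 0, headspace_volume > 0,
            headspace_pressure > 0, dose_mol >= 0, buffer_mg_per_l >= 0)
  if (missing(buffer_mg_per_l))
    warning("using the nominal 1 mg/L NaHCO3 buffer, which has negligible ",
            "buffering capacity; pass buffer_mg_per_l explicitly to silence")
  nahco3_molar_mass <- 22.990 + 1.008 + 12.011 + 3 * 15.999 # 84.006 g/mol
  structure(
    list(substrate = substrate,
         liquid_volume = liquid_volume,
         headspace_volume = headspace_volume,
         headspace_pressure = headspace_pressure,
         dose_mol = dose_mol,
         buffer_mg_per_l = buffer_mg_per_l,
         buffer_carbon_mol = buffer_mg_per_l * liquid_volume / 1000 /
           nahco3_molar_mass,
         temperature = temperature),
    class = "bottle_config"
  )
}

#' @export
print.bottle_config <- function(x, ...) {
  cat(sprintf("Bottle: %s, %.0f mL liquid / %.0f mL headspace at %g atm, %.4g mmol dose, %g mg/L NaHCO3\n",
              x$substrate$name, 1000 * x$liquid_volume,
              1000 * x$headspace_volume, x$headspace_pressure,
              1000 * x$dose_mol, x$buffer_mg_per_l))
  invisible(x)
}

#' Convert a headspace mole fraction to micromoles of gas
#'
#' Ideal-gas conversion \eqn{n = x P V_{head} / (R T)} at the bottle's
#' reporting temperature (25 °C standard state by default).
#'
#' @param mole_fraction Headspace mole fraction in \[0, 1\]; vectorized.
#' @param bottle A [bottle_config()].
#' @return µmol of the gas in the headspace.
#' @export
gas_to_moles <- function(mole_fraction, bottle) {
  stopifnot(inherits(bottle, "bottle_config"))
  if (any(mole_fraction < 0 | mole_fraction > 1))
    stop("mole fractions must lie in [0, 1]")
  Tk <- bottle$temperature + 273.15
  mole_fraction * bottle$headspace_pressure * bottle$headspace_volume /
    (.R_gas * Tk) * 1e6
}

# inverse of gas_to_moles for a given amount in µmol
.moles_to_fraction <- function(umol, bottle) {
  Tk <- bottle$temperature + 273.15
  umol * 1e-6 * .R_gas * Tk / (bottle$headspace_pressure * bottle$headspace_volume)
}

#' Dissolved inorganic carbon in equilibrium with a CO2 headspace
#'
#' Henry's law fixes \eqn{[H_2CO_3^*] = K_H\, p_{CO_2}}; dividing by the
#' ionization fraction \eqn{\alpha_0(pH)} gives total DIC per litre, scaled
#' to the bottle's liquid volume.
#'
#' @param p_co2 CO2 partial pressure, atm.
#' @param pH Liquid pH.
#' @param bottle A [bottle_config()].
#' @param system A [carbonate_system()].
#' @return mol DIC in the liquid phase of the bottle.
#' @export
dissolved_co2 <- function(p_co2, pH, bottle, system = carbonate_system()) {
  stopifnot(inherits(bottle, "bottle_config"), p_co2 >= 0)
  a0 <- if (length(pH) == 1L) speciate_dic(pH, system)[["alpha0"]]
  else speciate_dic(pH, system)[, "alpha0"]
  system$henry_kh * p_co2 / a0 * bottle$liquid_volume
}

#' Partition inorganic carbon between headspace and liquid
#'
#' Given a total amount of inorganic carbon in a closed bottle at a fixed
#' pH, solves the Henry/speciation equilibrium for the CO2 partial pressure
#' and the gas/liquid split. Used by the synthetic-data generator so that
#' generated headspace CO2 and the ledger's speciation are mutually
#' consistent.
#'
#' @param total_mol Total inorganic carbon, mol per bottle.
#' @param pH Liquid pH.
#' @param bottle A [bottle_config()].
#' @param system A [carbonate_system()].
#' @return A list with `p_co2` (atm), `gas_mol` and `dic_mol`.
#' @export
partition_inorganic_carbon <- function(total_mol, pH, bottle,
                                       system = carbonate_system()) {
  stopifnot(total_mol >= 0)
  Tk <- bottle$temperature + 273.15
  a0 <- speciate_dic(pH, system)[["alpha0"]]
  # total = p * Vh/(RT) + KH p / a0 * Vl
  denom <- bottle$headspace_volume / (.R_gas * Tk) +
    system$henry_kh / a0 * bottle$liquid_volume
  p <- total_mol / denom
  list(p_co2 = p,
       gas_mol = p * bottle$headspace_volume / (.R_gas * Tk),
       dic_mol = system$henry_kh * p / a0 * bottle$liquid_volume)
}

# carbon atoms per molecule of each measured organic acid
.acid_carbons <- c(acetic = 2, formic = 1, lactic = 3)

#' Carbon mass balance of one bottle on one sampling day
#'
#' Partitions the carbon added to a microcosm (substrate dose plus
#' bicarbonate buffer) into measured pools — CH4 carbon, biogenic gaseous
#' CO2, biogenic dissolved inorganic carbon, the buffer's own inorganic
#' carbon, acetic/formic/lactic acid carbon, and residual substrate — and
#' assigns whatever is left to biomass. Buffer-derived inorganic carbon is
#' subtracted from the measured DIC (then, if needed, from gaseous CO2)
#' before biogenic CO2 is assigned. Biomass is a residual by construction,
#' so the ledger always closes exactly; a negative residual is retained and
#' flagged rather than corrected. Because every unmeasured sink lands in
#' the residual, the biomass pool is an upper bound.
#'
#' @param day_record A list or one-row data frame with elements `day`,
#'   `ch4_frac`, `co2_frac` (headspace mole fractions), `acetic_mM`,
#'   `formic_mM`, `lactic_mM`, `pH`, `substrate_mM`.
#' @param bottle A [bottle_config()].
#' @param system A [carbonate_system()].
#' @return A one-row data frame of class `"carbon_ledger"` with g C per
#'   bottle in columns `ch4_c`, `co2_gas_c`, `dic_c`, `buffer_c`,
#'   `acetic_c`, `formic_c`, `lactic_c`, `substrate_c`, `biomass_c`, plus
#'   `added_c` and logical flags `closed` (biomass residual non-negative)
#'   and `inorganic_deficit` (measured inorganic carbon below the buffer
#'   carbon).
#' @export
carbon_ledger <- function(day_record, bottle, system = carbonate_system()) {
  stopifnot(inherits(bottle, "bottle_config"))
  r <- as.list(day_record)
  need <- c("day", "ch4_frac", "co2_frac", "acetic_mM", "formic_mM",
            "lactic_mM", "pH", "substrate_mM")
  miss <- setdiff(need, names(r))
  if (length(miss) > 0)
    stop("day record is missing: ", paste(miss, collapse = ", "))
  if (is.null(r$pH) || is.na(r$pH))
    stop("pH missing on day ", r$day, ": carbonate speciation is impossible")
  mC <- .atomic_mass[["C"]]
  s <- bottle$substrate

  ch4_mol <- gas_to_moles(r$ch4_frac, bottle) * 1e-6
  co2_gas_mol <- gas_to_moles(r$co2_frac, bottle) * 1e-6
  dic_mol <- dissolved_co2(r$co2_frac * bottle$headspace_pressure, r$pH,
                           bottle, system)
  buffer_mol <- bottle$buffer_carbon_mol

  # buffer carbon is assumed to remain inorganic: remove it from DIC first,
  # then from gaseous CO2, before counting biogenic inorganic carbon
  dic_biogenic <- dic_mol - buffer_mol
  co2_biogenic <- co2_gas_mol
  if (dic_biogenic < 0) {
    co2_biogenic <- co2_gas_mol + dic_biogenic
    dic_biogenic <- 0
  }
  deficit <- co2_biogenic < 0
  if (deficit) co2_biogenic <- 0

  acid_mol <- function(conc_mM) conc_mM / 1000 * bottle$liquid_volume
  pools <- c(
    ch4_c = ch4_mol * mC,
    co2_gas_c = co2_biogenic * mC,
    dic_c = dic_biogenic * mC,
    buffer_c = buffer_mol * mC,
    acetic_c = acid_mol(r$acetic_mM) * .acid_carbons[["acetic"]] * mC,
    formic_c = acid_mol(r$formic_mM) * .acid_carbons[["formic"]] * mC,
    lactic_c = acid_mol(r$lactic_mM) * .acid_carbons[["lactic"]] * mC,
    substrate_c = r$substrate_mM / 1000 * bottle$liquid_volume * s$n * mC
  )
  added_c <- (bottle$dose_mol * s$n + buffer_mol) * mC
  biomass_c <- added_c - sum(pools)
  out <- data.frame(day = r$day, t(pools), biomass_c = biomass_c,
                    added_c = added_c,
                    closed = biomass_c >= -1e-12,
                    inorganic_deficit = deficit)
  class(out) <- c("carbon_ledger", "data.frame")
  out
}

#' Carbon ledger across all sampling days of a bottle
#'
#' @param records A data frame of day records (see [carbon_ledger()]), one
#'   row per sampling day.
#' @param bottle A [bottle_config()].
#' @param system A [carbonate_system()].
#' @return A `"carbon_ledger"` data frame with one row per day.
#' @export
carbon_ledger_table <- function(records, bottle, system = carbonate_system()) {
  stopifnot(is.data.frame(records), nrow(records) > 0)
  out <- do.call(rbind, lapply(seq_len(nrow(records)), function(i)
    carbon_ledger(records[i, ], bottle, system)))
  class(out) <- c("carbon_ledger", "data.frame")
  out
}

#' Stack a carbon ledger into long (one row per day per pool) format
#'
#' The long format mirrors the stacked-column presentation of microcosm
#' carbon balances and is convenient for plotting and CSV export.
#'
#' @param ledger A `"carbon_ledger"` data frame.
#' @return A data frame with columns `day`, `pool`, `carbon_g`.
#' @export
ledger_long <- function(ledger) {
  stopifnot(inherits(ledger, "carbon_ledger"))
  pools <- c("ch4_c", "co2_gas_c", "dic_c", "buffer_c", "acetic_c",
             "formic_c", "lactic_c", "substrate_c", "biomass_c")
  out <- do.call(rbind, lapply(pools, function(p)
    data.frame(day = ledger$day, pool = sub("_c$", "", p),
               carbon_g = ledger[[p]])))
  out[order(out$day, out$pool), , drop = FALSE]
}
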