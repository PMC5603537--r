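# Random C_n H_a O_b N_c formulas with at least one oxidizable electron
random_substrate <- function() {
  repeat {
    n <- sample(1:12, 1)
    a <- sample(0:24, 1)
    b <- sample(0:12, 1)
    c <- sample(0:2, 1)
    if (4 * n + a - 2 * b - 3 * c > 0)
      return(substrate(sprintf("C%dH%dO%dN%d", n, a, b, c),
                       n = n, a = a, b = b, c = c))
  }
}

# Brute-force SSR landscape search for the Gompertz least-squares problem,
# independent of the package's optimizer
gompertz_ssr <- function(par, t, y) {
  sum((y - par[1] * exp(-exp((par[2] * exp(1) / par[1]) * (par[3] - t) + 1)))^2)
}

grid_search_gompertz <- function(t, y, centre, span = 0.05, res = 1e-3) {
  grid_A <- centre[1] * seq(1 - span, 1 + span, by = res)
  grid_mu <- centre[2] * seq(1 - span, 1 + span, by = res)
  grid_lam <- centre[3] * seq(1 - span, 1 + span, by = res)
  best <- c(ssr = Inf, A = NA, mu = NA, lam = NA)
  for (A in grid_A) for (mu in grid_mu) for (lam in grid_lam) {
    s <- gompertz_ssr(c(A, mu, lam), t, y)
    if (s < best[["ssr"]]) best <- c(ssr = s, A = A, mu = mu, lam = lam)
  }
  best
}

# Hand ANOVA decomposition used as the oracle against stats::aov
hand_anova <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g)
  N <- length(values)
  gm <- mean(values)
  mi <- tapply(values, g, mean)
  ni <- as.integer(table(g))
  ssb <- sum(ni * (mi - gm)^2)
  ssw <- sum((values - mi[g])^2)
  F <- (ssb / (k - 1)) / (ssw / (N - k))
  list(F = F, df = c(k - 1, N - k),
       p = stats::pf(F, k - 1, N - k, lower.tail = FALSE),
       msw = ssw / (N - k))
}

# Build the day record of a bottle in which the dosed substrate has been
# fully converted through the fs/fe reaction: methane and net inorganic
# carbon in stoichiometric proportion, no residual acids or substrate.
stoichiometric_endpoint_record <- function(bottle, fs = 0.2, pH = 6.5,
                                           system = carbonate_system()) {
  rxn <- build_reaction(bottle$substrate, partition_factors(fs))
  co <- rxn$coefficients
  ch4_mol <- co[["ch4"]] * bottle$dose_mol
  inorg_mol <- bottle$buffer_carbon_mol +
    (co[["co2"]] + co[["hco3"]]) * bottle$dose_mol
  part <- partition_inorganic_carbon(inorg_mol, pH, bottle, system)
  Tk <- bottle$temperature + 273.15
  ch4_frac <- ch4_mol * 0.0820574 * Tk /
    (bottle$headspace_pressure * bottle$headspace_volume)
  list(day = 128, ch4_frac = ch4_frac,
       co2_frac = part$p_co2 / bottle$headspace_pressure,
       acetic_mM = 0, formic_mM = 0, lactic_mM = 0,
       pH = pH, substrate_mM = 0)
}
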