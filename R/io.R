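#' Write a microcosm dataset to a directory of CSV files
#'
#' Writes `gas.csv`, `liquids.csv` and `config.yaml` (RFC 4180 CSV, UTF-8,
#' '.' decimal separator), the on-disk format [read_microcosm()] consumes.
#'
#' @param dataset A `"microcosm_dataset"` (see [generate_microcosm()]).
#' @param dir Output directory; created if absent.
#' @return `dir`, invisibly.
#' @export
write_microcosm <- function(dataset, dir) {
  stopifnot(inherits(dataset, "microcosm_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(dataset$gas, file.path(dir, "gas.csv"), row.names = FALSE)
  utils::write.csv(dataset$liquids, file.path(dir, "liquids.csv"),
                   row.names = FALSE)
  cfg <- unclass(dataset$config)
  cfg$treatments <- lapply(seq_len(nrow(cfg$treatments)), function(i)
    as.list(cfg$treatments[i, ]))
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

.required_gas_cols <- c("treatment", "replicate", "day", "ch4_umol_per_gC",
                        "ch4_frac", "co2_frac")
.required_liquid_cols <- c("treatment", "replicate", "day", "acetic_mM",
                           "formic_mM", "lactic_mM", "pH", "substrate_mM")

.validate_table <- function(df, required, what) {
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  day <- suppressWarnings(as.numeric(df$day))
  bad <- which(is.na(day) | day < 0)
  if (length(bad) > 0)
    stop(what, ": invalid day value at row ", bad[1L],
         " ('", df$day[bad[1L]], "')")
  df$day <- day
  for (b in split(seq_len(nrow(df)),
                  interaction(df$treatment, df$replicate, drop = TRUE))) {
    d <- df$day[b]
    if (is.unsorted(d, strictly = TRUE))
      stop(what, ": days not strictly increasing for treatment '",
           df$treatment[b[1L]], "' replicate ", df$replicate[b[1L]],
           " (first offence at row ",
           b[which(diff(d) <= 0)[1L] + 1L], ")")
  }
  df
}

#' Read a microcosm dataset from a directory of CSV files
#'
#' Expects `gas.csv`, `liquids.csv` and `config.yaml` as written by
#' [write_microcosm()]. Validates the schema — required columns, numeric
#' non-negative strictly increasing days per bottle, and that every
#' treatment in the tables is declared in the config with a known or fully
#' specified substrate — reporting the offending row on failure.
#'
#' @param dir Directory containing the three files.
#' @return A `"microcosm_dataset"`.
#' @export
read_microcosm <- function(dir) {
  for (f in c("gas.csv", "liquids.csv", "config.yaml"))
    if (!file.exists(file.path(dir, f)))
      stop("missing file: ", file.path(dir, f))
  gas <- utils::read.csv(file.path(dir, "gas.csv"), stringsAsFactors = FALSE)
  liquids <- utils::read.csv(file.path(dir, "liquids.csv"),
                             stringsAsFactors = FALSE)
  gas <- .validate_table(gas, .required_gas_cols, "gas.csv")
  liquids <- .validate_table(liquids, .required_liquid_cols, "liquids.csv")
  raw <- yaml::read_yaml(file.path(dir, "config.yaml"))
  treatments <- do.call(rbind, lapply(raw$treatments, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  config <- scenario_config(
    treatments = treatments,
    replicates = raw$replicates,
    gas_days = raw$gas_days,
    liquid_days = raw$liquid_days,
    noise_sd = raw$noise_sd,
    noise_decay = raw$noise_decay,
    lag_jitter = raw$lag_jitter,
    dose_mM = raw$dose_mM,
    liquid_volume = raw$liquid_volume,
    headspace_volume = raw$headspace_volume,
    buffer_mg_per_l = raw$buffer_mg_per_l,
    seed = raw$seed)
  known <- unique(c(gas$treatment, liquids$treatment))
  undeclared <- setdiff(known, treatments$treatment)
  if (length(undeclared) > 0)
    stop("treatment(s) not declared in config.yaml: ",
         paste(undeclared, collapse = ", "))
  bottles <- list()
  for (i in seq_len(nrow(treatments))) {
    sub <- substrate(treatments$substrate[i])
    bottles[[treatments$treatment[i]]] <- bottle_config(
      sub,
      liquid_volume = config$liquid_volume,
      headspace_volume = config$headspace_volume,
      dose_mol = config$dose_mM / 1000 * config$liquid_volume,
      buffer_mg_per_l = config$buffer_mg_per_l)
  }
  structure(list(config = config, bottles = bottles, gas = gas,
                 liquids = liquids),
            class = "microcosm_dataset")
}

#' Kinetic summary table for every treatment in a dataset
#'
#' Pools the replicate bottles of each treatment and fits the methane
#' curve with [fit_methane()]; the spread of the asymptote across
#' replicates is reported as `sd_A` from separate per-replicate fits.
#' Treatments that fall back to (or are forced to) the linear model report
#' their slope, with `A` taken as the final replicate-mean cumulative
#' methane.
#'
#' @param dataset A `"microcosm_dataset"`.
#' @param model Passed to [fit_methane()].
#' @return A data frame with columns `treatment`, `model`, `A`, `sd_A`,
#'   `mu_m`, `lambda`, `slope`, `r_squared`.
#' @export
kinetics_table <- function(dataset, model = "auto") {
  stopifnot(inherits(dataset, "microcosm_dataset"))
  gas <- dataset$gas
  rows <- lapply(unique(gas$treatment), function(tr) {
    g <- gas[gas$treatment == tr, ]
    d <- data.frame(day = g$day, ch4 = g$ch4_umol_per_gC)
    if (max(d$ch4) <= 0)
      return(data.frame(treatment = tr, model = "none", A = 0, sd_A = 0,
                        mu_m = NA_real_, lambda = NA_real_,
                        slope = NA_real_, r_squared = NA_real_))
    fit <- fit_methane(ch4 ~ day, d, model = model)
    used <- attr(fit, "model")
    rep_A <- vapply(unique(g$replicate), function(r) {
      gr <- g[g$replicate == r, ]
      if (used == "gompertz") {
        f <- fit_gompertz(ch4 ~ day, data.frame(day = gr$day,
                                                ch4 = gr$ch4_umol_per_gC))
        if (f$converged) f$coefficients[["A"]] else max(gr$ch4_umol_per_gC)
      } else max(gr$ch4_umol_per_gC)
    }, numeric(1))
    if (used == "gompertz") {
      data.frame(treatment = tr, model = "gompertz",
                 A = fit$coefficients[["A"]],
                 sd_A = stats::sd(rep_A),
                 mu_m = fit$coefficients[["mu_m"]],
                 lambda = fit$coefficients[["lambda"]],
                 slope = NA_real_, r_squared = fit$r_squared)
    } else {
      ybar <- tapply(d$ch4, d$day, mean)
      data.frame(treatment = tr, model = "linear",
                 A = max(ybar), sd_A = stats::sd(rep_A),
                 mu_m = NA_real_, lambda = NA_real_,
                 slope = fit$coefficients[["slope"]],
                 r_squared = fit$r_squared)
    }
  })
  do.call(rbind, rows)
}

#' Conversion-efficiency table for every treatment in a dataset
#'
#' The observed peak methane of each treatment (maximum of the
#' replicate-mean cumulative series, µmol per g substrate carbon) is
#' converted to mol CH4 per mol substrate and compared to the theoretical
#' yield of the fs/fe reaction. Because cumulative methane normalised "per
#' gram carbon" can mean per gram of elemental substrate carbon or per
#' gram of substrate, both unit readings are reported: columns suffixed
#' `_gC` treat the series as µmol per g elemental carbon, `_gsub` as µmol
#' per g substrate.
#'
#' @param dataset A `"microcosm_dataset"`.
#' @param factors A [partition_factors()] for the partitioned basis.
#' @return A data frame with per-treatment observed yields and
#'   partitioned- and complete-basis efficiencies (percent) under both
#'   unit readings.
#' @export
efficiency_table <- function(dataset, factors = partition_factors(0.2)) {
  stopifnot(inherits(dataset, "microcosm_dataset"))
  gas <- dataset$gas
  rows <- lapply(unique(gas$treatment), function(tr) {
    g <- gas[gas$treatment == tr, ]
    sub <- dataset$bottles[[tr]]$substrate
    peak <- max(tapply(g$ch4_umol_per_gC, g$day, mean))
    obs_gC <- peak * 1e-6 * .atomic_mass[["C"]] * sub$n
    obs_gsub <- peak * 1e-6 * sub$molar_mass
    data.frame(
      treatment = tr,
      peak_umol_per_gC = peak,
      observed_mol_per_mol_gC = obs_gC,
      observed_mol_per_mol_gsub = obs_gsub,
      eff_partitioned_gC = conversion_efficiency(obs_gC, sub, factors),
      eff_complete_gC = conversion_efficiency(obs_gC, sub, basis = "complete"),
      eff_partitioned_gsub = conversion_efficiency(obs_gsub, sub, factors),
      eff_complete_gsub = conversion_efficiency(obs_gsub, sub,
                                                basis = "complete"))
  })
  do.call(rbind, rows)
}

#' Carbon ledgers for every bottle and liquid sampling day
#'
#' Joins each bottle's liquid measurements with its headspace gas record
#' (gas fractions linearly interpolated onto the liquid sampling days) and
#' runs [carbon_ledger()] per day.
#'
#' @param dataset A `"microcosm_dataset"`.
#' @param system A [carbonate_system()].
#' @return A data frame: one row per treatment, replicate and sampling
#'   day with the ledger pools in g C per bottle.
#' @export
ledger_table <- function(dataset, system = carbonate_system()) {
  stopifnot(inherits(dataset, "microcosm_dataset"))
  out <- list()
  for (tr in unique(dataset$liquids$treatment)) {
    bottle <- dataset$bottles[[tr]]
    for (r in unique(dataset$liquids$replicate[dataset$liquids$treatment == tr])) {
      liq <- dataset$liquids[dataset$liquids$treatment == tr &
                               dataset$liquids$replicate == r, ]
      g <- dataset$gas[dataset$gas$treatment == tr &
                         dataset$gas$replicate == r, ]
      recs <- data.frame(
        day = liq$day,
        ch4_frac = stats::approx(g$day, g$ch4_frac, xout = liq$day,
                                 rule = 2)$y,
        co2_frac = stats::approx(g$day, g$co2_frac, xout = liq$day,
                                 rule = 2)$y,
        acetic_mM = liq$acetic_mM, formic_mM = liq$formic_mM,
        lactic_mM = liq$lactic_mM, pH = liq$pH,
        substrate_mM = liq$substrate_mM)
      led <- carbon_ledger_table(recs, bottle, system)
      led <- cbind(treatment = tr, replicate = r, led)
      out[[length(out) + 1L]] <- led
    }
  }
  do.call(rbind, out)
}

#' Run the full microcosm analysis pipeline
#'
#' From a dataset to a report: kinetic fits per treatment
#' ([kinetics_table()]), conversion efficiencies ([efficiency_table()]),
#' per-bottle carbon ledgers ([ledger_table()]), consolidated group rate
#' comparisons (mean series per `group` in the config's treatment table,
#' rise-phase linear rates via [rise_rate()]), and a plain-text summary.
#' Deterministic given the dataset and options.
#'
#' @param dataset A `"microcosm_dataset"`.
#' @param factors A [partition_factors()].
#' @param model Kinetic model selection, passed to [kinetics_table()].
#' @return A list of class `"microcosm_report"` with elements `kinetics`,
#'   `efficiency`, `ledgers`, `groups`, `summary` (character lines).
#' @export
run_pipeline <- function(dataset, factors = partition_factors(0.2),
                         model = "auto") {
  stopifnot(inherits(dataset, "microcosm_dataset"))
  kin <- kinetics_table(dataset, model = model)
  eff <- efficiency_table(dataset, factors)
  led <- ledger_table(dataset)

  groups <- NULL
  trt <- dataset$config$treatments
  if ("group" %in% names(trt)) {
    grp_rows <- lapply(unique(trt$group), function(gp) {
      members <- trt$treatment[trt$group == gp]
      series <- lapply(members, function(tr) {
        g <- dataset$gas[dataset$gas$treatment == tr, ]
        ybar <- tapply(g$ch4_umol_per_gC, g$day, mean)
        data.frame(day = as.numeric(names(ybar)), ch4 = as.numeric(ybar))
      })
      cons <- consolidate_group(series)
      if (max(cons$ch4) <= 0)
        return(data.frame(group = gp, n_treatments = length(members),
                          rate = 0, r_squared = NA_real_,
                          plateau = 0))
      rr <- rise_rate(cons)
      data.frame(group = gp, n_treatments = length(members),
                 rate = rr$coefficients[["slope"]],
                 r_squared = rr$r_squared,
                 plateau = max(cons$ch4))
    })
    groups <- do.call(rbind, grp_rows)
  }

  summary_lines <- c(
    sprintf("microcosm pipeline report (seed %s)",
            format(dataset$config$seed)),
    sprintf("treatments: %d; replicates: %d",
            nrow(trt), dataset$config$replicates),
    sprintf("kinetics: %d gompertz, %d linear",
            sum(kin$model == "gompertz"), sum(kin$model == "linear")),
    if (!is.null(groups))
      apply(groups, 1L, function(r)
        sprintf("group %s: rise rate %.1f umol/gC/day (R2 %.2f)",
                r[["group"]], as.numeric(r[["rate"]]),
                as.numeric(r[["r_squared"]]))),
    sprintf("ledger closure: %d of %d bottle-days non-negative",
            sum(led$closed), nrow(led)))

  structure(list(kinetics = kin, efficiency = eff, ledgers = led,
                 groups = groups, summary = summary_lines),
            class = "microcosm_report")
}

#' @export
print.microcosm_report <- function(x, ...) {
  cat(paste(x$summary, collapse = "\n"), "\n")
  invisible(x)
}

#' Write the report tables of a pipeline run to CSV files
#'
#' @param report A `"microcosm_report"` from [run_pipeline()].
#' @param dir Output directory; created if absent.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "microcosm_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$kinetics, file.path(dir, "kinetics.csv"),
                   row.names = FALSE)
  utils::write.csv(report$efficiency, file.path(dir, "efficiency.csv"),
                   row.names = FALSE)
  utils::write.csv(report$ledgers, file.path(dir, "ledgers.csv"),
                   row.names = FALSE)
  if (!is.null(report$groups))
    utils::write.csv(report$groups, file.path(dir, "groups.csv"),
                     row.names = FALSE)
  writeLines(report$summary, file.path(dir, "summary.txt"))
  invisible(dir)
}
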