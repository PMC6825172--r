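# Upscaling sponge standing biomass to daily ecosystem function.
#
# All quantities are linear in biomass. Filtration carries the 0.70
# activity factor (the underlying rate is a maximum pumping rate);
# respiration does not. SDs of filtration, respiration and carbon
# propagate the single rate SD linearly; nitrogen fluxes combine the
# filtration SD and the concentration SD in quadrature of relative errors
# (each bound alone is available via `sd_mode`).

#' Daily seawater filtration of a sponge stock
#'
#' @param biomass_t Sponge wet weight, tonnes.
#' @param rates A [geodia_rates()] list.
#' @return List with `mean` and `sd` in 10^6 L day^-1.
#' @export
filtration <- function(biomass_t, rates = geodia_rates()) {
  stopifnot(all(biomass_t >= 0))
  kg <- biomass_t * 1000
  list(mean = kg * rates$filtration_l_per_kg_day * rates$activity_factor / 1e6,
       sd   = kg * rates$filtration_sd           * rates$activity_factor / 1e6,
       units = "1e6 L day-1")
}

#' Daily oxygen consumption of a sponge stock
#'
#' No activity factor is applied: the respiration rate is a routine
#' metabolic rate, not a maximum pumping rate.
#'
#' @inheritParams filtration
#' @return List with `mean` and `sd` in t O2 day^-1.
#' @export
respiration <- function(biomass_t, rates = geodia_rates()) {
  stopifnot(all(biomass_t >= 0))
  # t O2/day = g WW * umol/g/day * 1e-6 mol/umol * M g/mol * 1e-6 t/g
  k <- rates$respiration_umol_per_g_day * rates$molar_mass_g[["O2"]] * 1e-6
  ks <- rates$respiration_sd * rates$molar_mass_g[["O2"]] * 1e-6
  list(mean = biomass_t * k, sd = biomass_t * ks, units = "t O2 day-1")
}

#' Daily organic carbon consumption from respiration
#'
#' Applies the 0.9:1.0 carbon-to-oxygen mass conversion: C tonnage equals
#' the O2 tonnage divided by 0.9. The SD is divided likewise.
#'
#' @param respiration_estimate Result of [respiration()] (or any list with
#'   `mean` and `sd` in t O2 day^-1).
#' @param rates A [geodia_rates()] list.
#' @return List with `mean` and `sd` in t C day^-1.
#' @export
carbon_consumption <- function(respiration_estimate, rates = geodia_rates()) {
  list(mean = respiration_estimate$mean / rates$c_to_o_mass_ratio,
       sd   = respiration_estimate$sd   / rates$c_to_o_mass_ratio,
       units = "t C day-1")
}

#' Daily nitrogen flux mediated by sponge filtration
#'
#' Uptake of ammonium or nitrite, or release of nitrate, per litre of
#' seawater filtered.
#'
#' @param filtration_estimate Result of [filtration()].
#' @param species One of `"NH4"`, `"NO2"`, `"NO3"`.
#' @param rates A [geodia_rates()] list.
#' @param sd_mode How to propagate uncertainty: `"quadrature"` (default)
#'   combines the relative SDs of filtration and concentration;
#'   `"concentration"` and `"filtration"` report each bound alone.
#' @return List with `mean` and `sd` in t day^-1.
#' @export
nitrogen_flux <- function(filtration_estimate, species = c("NH4", "NO2", "NO3"),
                          rates = geodia_rates(),
                          sd_mode = c("quadrature", "concentration", "filtration")) {
  species <- match.arg(species)
  sd_mode <- match.arg(sd_mode)
  conc <- switch(species, NH4 = rates$nh4_umol_per_l,
                 NO2 = rates$no2_umol_per_l, NO3 = rates$no3_umol_per_l)
  conc_sd <- switch(species, NH4 = rates$nh4_sd, NO2 = rates$no2_sd, NO3 = rates$no3_sd)
  mm <- rates$molar_mass_g[[species]]
  litres <- filtration_estimate$mean * 1e6
  # t/day = L * umol/L * 1e-6 mol/umol * M g/mol * 1e-6 t/g
  mean_t <- litres * conc * 1e-6 * mm * 1e-6
  rel_f <- if (filtration_estimate$mean > 0) filtration_estimate$sd / filtration_estimate$mean else 0
  rel_c <- conc_sd / conc
  rel <- switch(sd_mode,
                quadrature = sqrt(rel_f^2 + rel_c^2),
                concentration = rel_c,
                filtration = rel_f)
  list(mean = mean_t, sd = mean_t * rel, units = "t day-1")
}

#' All ecosystem functions for one biomass figure
#'
#' @inheritParams filtration
#' @return One-row data frame with mean and SD columns for filtration
#'   (10^6 L day^-1), respiration (t O2 day^-1), carbon (t C day^-1) and
#'   the three nitrogen fluxes (t day^-1).
#' @export
function_estimate <- function(biomass_t, rates = geodia_rates()) {
  f <- filtration(biomass_t, rates)
  r <- respiration(biomass_t, rates)
  cc <- carbon_consumption(r, rates)
  nh4 <- nitrogen_flux(f, "NH4", rates)
  no2 <- nitrogen_flux(f, "NO2", rates)
  no3 <- nitrogen_flux(f, "NO3", rates)
  data.frame(
    biomass_t = biomass_t,
    filtration_ML = f$mean, filtration_ML_sd = f$sd,
    respiration_t_O2 = r$mean, respiration_t_O2_sd = r$sd,
    carbon_t_C = cc$mean, carbon_t_C_sd = cc$sd,
    nh4_t = nh4$mean, nh4_t_sd = nh4$sd,
    no2_t = no2$mean, no2_t_sd = no2$sd,
    no3_t = no3$mean, no3_t_sd = no3$sd)
}

#' Ecosystem-function table by region
#'
#' One row per region plus a `Total` row computed directly from the summed
#' biomass (every mean is linear in biomass, so the direct total equals the
#' sum of unrounded region rows). A second total, the sum of region values
#' after rounding to `rounded_digits` decimals, is attached as attribute
#' `"rounded_total"` because published tables are often assembled that way.
#'
#' @param biomass_by_region Named numeric vector of biomass, tonnes.
#' @param rates A [geodia_rates()] list.
#' @param rounded_digits Decimals used for the rounded-sum total (default 2).
#' @return Data frame with a `region` column; see [function_estimate()].
#' @export
function_table <- function(biomass_by_region, rates = geodia_rates(),
                           rounded_digits = 2) {
  stopifnot(!is.null(names(biomass_by_region)))
  rows <- do.call(rbind, lapply(seq_along(biomass_by_region), function(i)
    cbind(region = names(biomass_by_region)[i],
          function_estimate(biomass_by_region[[i]], rates))))
  total <- cbind(region = "Total",
                 function_estimate(sum(biomass_by_region), rates))
  out <- rbind(rows, total)
  rownames(out) <- NULL
  num <- vapply(rows, is.numeric, TRUE)
  attr(out, "rounded_total") <- colSums(round(rows[, num], rounded_digits))
  out
}

#' Ecosystem-function loss from removed biomass
#'
#' The same upscaling applied to the biomass removed by trawling.
#'
#' @param removal_t Removed sponge wet weight, tonnes.
#' @param rates A [geodia_rates()] list.
#' @return See [function_estimate()].
#' @export
function_loss <- function(removal_t, rates = geodia_rates()) {
  stopifnot(all(removal_t >= 0))
  function_estimate(removal_t, rates)
}
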