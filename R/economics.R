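# Economic valuation: ex-vessel catch value with inflation adjustment, and
# replacement-cost valuation of the lost filtration service against a
# wastewater-treatment plant of comparable daily flow.

#' Ashbridges Bay Treatment Plant specification
#'
#' Reference engineered system for the replacement-cost valuation of
#' filtration: nominal capacity 818 x 10^6 L day^-1, average daily flow
#' 598 x 10^6 L day^-1, capital cost of the UV disinfection facility
#' USD 182 million, operating cost USD 5.4 million over a 3-year horizon
#' (2015 costs carried to 2018).
#'
#' @param ... Named overrides of any field.
#' @return A `plant_spec` list.
#' @export
abtp_plant <- function(...) {
  plant <- list(
    name = "Ashbridges Bay Treatment Plant",
    nominal_capacity_ML_day = 818,
    average_daily_flow_ML_day = 598,
    capital_cost_musd = 182,
    operating_cost_3yr_musd = 5.4)
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(plant)) stop("unknown plant field: ", nm)
    plant[[nm]] <- dots[[nm]]
  }
  stopifnot(plant$average_daily_flow_ML_day <= plant$nominal_capacity_ML_day)
  structure(plant, class = "plant_spec")
}

#' Value of reported catch, by year and total
#'
#' Rows with a `value_usd` are passed through; otherwise value is
#' `catch_t * unit_price_usd_per_t`. Rows with neither are excluded with a
#' message.
#'
#' @param catch_table Data frame with columns `species`, `year`, `catch_t`
#'   and either `value_usd` or `unit_price_usd_per_t`.
#' @return List with `by_year` (data frame `year`, `catch_t`, `value_usd`),
#'   `total_usd` and `total_catch_t`.
#' @export
catch_value <- function(catch_table) {
  tb <- catch_table
  empty <- function()
    list(by_year = data.frame(year = integer(), catch_t = numeric(),
                              value_usd = numeric()),
         total_usd = 0, total_catch_t = 0)
  if (nrow(tb) == 0) return(empty())
  val <- if ("value_usd" %in% names(tb)) tb$value_usd else rep(NA_real_, nrow(tb))
  price <- if ("unit_price_usd_per_t" %in% names(tb)) tb$unit_price_usd_per_t else rep(NA_real_, nrow(tb))
  val[is.na(val)] <- (tb$catch_t * price)[is.na(val)]
  drop <- is.na(val)
  if (any(drop)) {
    message(sum(drop), " row(s) without price or value excluded from valuation")
    tb <- tb[!drop, , drop = FALSE]; val <- val[!drop]
  }
  if (nrow(tb) == 0) return(empty())
  by_year <- aggregate(cbind(catch_t = tb$catch_t, value_usd = val),
                       by = list(year = tb$year), FUN = sum)
  list(by_year = by_year, total_usd = sum(val), total_catch_t = sum(tb$catch_t))
}

#' Compound inflation adjustment
#'
#' @param value_usd Nominal value.
#' @param annual_rate Average annual inflation rate (e.g. 0.0178).
#' @param n_years Number of years of compounding.
#' @return Adjusted value: `value * (1 + rate)^n_years`.
#' @export
inflation_adjust <- function(value_usd, annual_rate, n_years) {
  stopifnot(annual_rate >= 0, n_years >= 0)
  value_usd * (1 + annual_rate)^n_years
}

#' Inflation-adjust a catch valuation to a reference year
#'
#' @param valuation Result of [catch_value()].
#' @param rates_by_year Named numeric vector of average annual inflation
#'   rates, names = catch year.
#' @param reference_year Year values are carried to (default 2018).
#' @return The valuation with columns `adjusted_usd` added and totals.
#' @export
adjust_catch_value <- function(valuation, rates_by_year, reference_year = 2018) {
  by <- valuation$by_year
  r <- rates_by_year[as.character(by$year)]
  if (anyNA(r)) stop("missing inflation rate for year(s): ",
                     paste(by$year[is.na(r)], collapse = ", "))
  by$adjusted_usd <- inflation_adjust(by$value_usd, unname(r), reference_year - by$year)
  valuation$by_year <- by
  valuation$total_adjusted_usd <- sum(by$adjusted_usd)
  valuation$reference_year <- reference_year
  valuation
}

#' Replacement cost of lost filtration capacity
#'
#' Monetizes a daily filtration loss as the cost of wastewater-treatment
#' plants delivering an equivalent average daily flow. The plant-equivalence
#' ratio is `loss / average_daily_flow`; a ratio in (0.5, 1.5] counts as one
#' substantially equivalent plant, and in general the plant count is the
#' nearest integer to the ratio (halves rounding down, consistent with the
#' one-plant band). Cost per plant is capital plus 3-year operating cost.
#'
#' @param filtration_loss_ML_day Lost pumping capacity, 10^6 L day^-1.
#' @param plant A [abtp_plant()] specification.
#' @return List with `ratio`, `n_plants`, `cost_musd` (rounded to the
#'   nearest million) and `cost_musd_exact`.
#' @export
replacement_cost <- function(filtration_loss_ML_day, plant = abtp_plant()) {
  stopifnot(filtration_loss_ML_day >= 0)
  ratio <- filtration_loss_ML_day / plant$average_daily_flow_ML_day
  n_plants <- max(0, ceiling(ratio - 0.5))
  if (filtration_loss_ML_day > 0) n_plants <- max(1, n_plants)
  per_plant <- plant$capital_cost_musd + plant$operating_cost_3yr_musd
  exact <- n_plants * per_plant
  list(ratio = ratio, n_plants = n_plants,
       cost_musd = round(exact), cost_musd_exact = exact,
       plant = plant$name)
}

#' Compare catch value with the replacement cost of lost filtration
#'
#' @param catch_total_adjusted_usd Inflation-adjusted catch value, USD.
#' @param replacement_cost_usd Replacement cost, USD (same units as catch).
#' @return List with `catch_to_replacement` and `replacement_to_catch`.
#' @export
compare_values <- function(catch_total_adjusted_usd, replacement_cost_usd) {
  stopifnot(catch_total_adjusted_usd > 0)
  if (replacement_cost_usd <= 0) stop("replacement cost must be positive")
  list(catch_to_replacement = catch_total_adjusted_usd / replacement_cost_usd,
       replacement_to_catch = replacement_cost_usd / catch_total_adjusted_usd)
}
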