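# Catch-statistics tables for the economic valuation.

#' Reported fish catch and ex-vessel value, Division 3M, 2010-2012
#'
#' The packaged reference table of catch (tonnes) and ex-vessel value (USD)
#' by species and year for the trawl fleet in Division 3M: Atlantic cod,
#' groundfish (NS), Atlantic redfishes, mixed marine fish (nei), Greenland
#' halibut and shrimps. Yearly catch totals are 23,817 / 24,879 / 18,919 t
#' and value totals 35,121,904 / 46,062,863 / 31,034,532 USD.
#'
#' @return Data frame: `species`, `year`, `catch_t`, `value_usd`.
#' @export
nafo_3m_catch <- function() {
  data.frame(
    species = c(rep("Atlantic cod", 3), rep("Groundfish (NS)", 3),
                rep("Atlantic redfishes", 3), "Mixed species (marine fish nei)",
                "Greenland halibut", "Greenland halibut",
                "Shrimps (Pandalus borealis)"),
    year = c(2010, 2011, 2012, 2010, 2011, 2012, 2010, 2011, 2012,
             2010, 2010, 2012, 2010),
    catch_t = c(9564, 15960, 14500, 4658, 3786, 3838, 4233, 5133, 338,
                3783, 795, 243, 784),
    value_usd = c(18735451, 33102275, 24822180, 5181757, 4291103, 4894955,
                  5436154, 8669485, 534995, 2033120, 2322683, 782402, 1412739))
}

#' Average inflation rates to 2018 by catch year
#'
#' @return Named vector of compound annual rates for 2010, 2011, 2012.
#' @export
inflation_rates_2018 <- function() {
  c("2010" = 0.0178, "2011" = 0.0158, "2012" = 0.0150)
}

#' Make a catch table (fixture or seeded random)
#'
#' With `config$fixture = "table_3m"` (alias `"table4"`) returns the
#' packaged reference table [nafo_3m_catch()]. Otherwise draws a random
#' table over `config$species` and `config$years` with log-normal catches
#' and unit prices.
#'
#' @param config List: `fixture`, or `species` (character), `years`
#'   (integer), `mean_catch_t`, `mean_price_usd_t`.
#' @param seed Integer seed for the random mode.
#' @return Data frame: `species`, `year`, `catch_t` and either `value_usd`
#'   (fixture) or `unit_price_usd_per_t` (random).
#' @export
make_catch_table <- function(config = list(), seed = 1L) {
  if (!is.null(config$fixture)) {
    if (config$fixture %in% c("table_3m", "table4")) return(nafo_3m_catch())
    stop("unknown fixture: ", config$fixture)
  }
  species <- config$species %||% c("Atlantic cod", "Atlantic redfishes",
                                   "Greenland halibut", "Shrimps")
  years <- config$years %||% 2010:2012
  if (length(species) == 0 || length(years) == 0)
    return(data.frame(species = character(), year = integer(),
                      catch_t = numeric(), unit_price_usd_per_t = numeric()))
  set.seed(seed)
  gr <- expand.grid(species = species, year = years,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mean_catch <- config$mean_catch_t %||% 5000
  mean_price <- config$mean_price_usd_t %||% 1500
  gr$catch_t <- round(stats::rlnorm(nrow(gr), log(mean_catch), 0.6))
  gr$unit_price_usd_per_t <- round(stats::rlnorm(nrow(gr), log(mean_price), 0.3), 2)
  gr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
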