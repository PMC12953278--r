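#' Default registry of Finnish wellbeing service counties
#'
#' The 23 wellbeing service counties with the minimum-mortality temperature
#' (MMT) used as the relative-risk reference. Published per-county MMT values
#' range from 16 degrees C on the southern coast to 14 degrees C in the north;
#' here they are assigned by approximate latitude band (southern 16, central
#' 15, northern 14) and can be overridden. `missing_fraction` starts as `NA`
#' and is filled from data; `included` defaults to `TRUE` for the 19 counties
#' retained in regional analyses and `FALSE` for the four lowest-population
#' counties whose daily counts are mostly suppressed.
#'
#' @return data frame with columns `region_id`, `mmt`, `missing_fraction`,
#'   `included`.
#' @export
finland_registry <- function() {
  south <- c("Helsinki", "West Uusimaa", "Central Uusimaa", "East Uusimaa",
             "Vantaa & Kerava", "Kymenlaakso", "South Karelia",
             "Southwest Finland", "Satakunta", "Kanta-Hame", "Paijat-Hame",
             "Aland")
  central <- c("Pirkanmaa", "Central Finland", "South Savo", "North Savo",
               "North Karelia", "South Ostrobothnia", "Ostrobothnia",
               "Central Ostrobothnia")
  north <- c("North Ostrobothnia", "Kainuu", "Lapland")
  excluded <- c("Aland", "Kainuu", "Central Ostrobothnia", "East Uusimaa")
  region_id <- c(south, central, north)
  data.frame(
    region_id = region_id,
    mmt = c(rep(16, length(south)), rep(15, length(central)),
            rep(14, length(north))),
    missing_fraction = NA_real_,
    included = !(region_id %in% excluded)
  )
}

#' Published county heat-attributable death estimates
#'
#' Reference point estimates of all-age heat-attributable deaths (AN) for the
#' 19 analysed counties in the baseline decade (2010-2019), mid-century
#' (2050-2059) and end of century (2090-2099) under the SSP2-4.5 and SSP5-8.5
#' scenarios (fixed-knots model), together with the published end-of-century /
#' baseline change ratio (`NA` where the baseline AN is negative and the ratio
#' is undefined). Used as worked-example inputs for [change_ratio()].
#'
#' @return data frame with columns `region_id`, `scenario`, `an_2010_2019`,
#'   `an_2050_2059`, `an_2090_2099`, `ratio_printed`.
#' @export
reference_heat_an <- function() {
  path <- system.file("extdata", "fi_county_heat_an.csv", package = "tempmort")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
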