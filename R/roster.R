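#' County demographic and socioeconomic variable roster
#'
#' The 30 county-level covariates considered as candidate heat-vulnerability
#' predictors: age structure, sex, race/ethnicity, employment and occupation,
#' wealth, education, housing, family structure, and urbanicity. Units are
#' percent of population unless noted (median age and median year built are
#' in years; income, rent, and house value in dollars or $1000s).
#'
#' @return data.frame with columns `variable`, `group`, `unit`.
#' @export
sdoh_roster <- function() {
  data.frame(
    variable = c(
      "median_age", "pct_under_5", "pct_over_65", "pct_over_65_nursing",
      "pct_female",
      "pct_nh_white", "pct_nh_black", "pct_nh_other", "pct_hispanic",
      "pct_labor_force", "unemployment_rate", "pct_farm_fish_mine_forest",
      "pct_construction_extraction", "pct_install_maint_repair", "pct_services",
      "per_capita_income", "median_household_income", "median_gross_rent",
      "median_house_value", "pct_hh_income_under_10k", "pct_hh_income_over_200k",
      "pct_food_stamps", "pct_below_poverty", "pct_no_automobile",
      "pct_less_than_hs", "pct_limited_english",
      "median_year_built", "pct_mobile_homes",
      "pct_one_parent",
      "pct_rural"
    ),
    group = c(
      rep("age", 4), "sex", rep("race_ethnicity", 4), rep("employment", 6),
      rep("wealth", 9), rep("education", 2), rep("housing", 2), "one_parent",
      "urbanicity"
    ),
    unit = c(
      "year", "percent", "percent", "percent", "percent",
      rep("percent", 4), rep("percent", 6),
      "1000_dollar", "1000_dollar", "1000_dollar", "1000_dollar",
      rep("percent", 5),
      "percent", "percent", "year", "percent", "percent", "percent"
    ),
    stringsAsFactors = FALSE
  )
}

#' Variables removed for multicollinearity in the reference analysis
#'
#' Twelve roster variables that typically correlate above 0.7 with other
#' candidates in US county data (wealth, education, and housing measures
#' track each other closely), supplied as a ready-made override for
#' [correlation_prune()].
#' Removing them from the 30-variable roster leaves 18 predictors for
#' stepwise selection.
#'
#' @return character vector of 12 variable names.
#' @export
default_pruned_variables <- function() {
  c(
    "median_age", "pct_nh_white", "median_household_income",
    "median_gross_rent", "median_house_value", "pct_hh_income_over_200k",
    "pct_food_stamps", "pct_below_poverty", "pct_less_than_hs",
    "pct_limited_english", "pct_mobile_homes", "pct_rural"
  )
}
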