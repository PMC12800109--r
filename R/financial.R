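# Provider-perspective net financial impact analysis (NFIA) and
# payer-perspective budget impact analysis (BIA).  Under the Medicare ESRD
# bundled payment, ESA savings accrue to the dialysis provider; avoiding the
# Quality Incentive Program payment reduction adds revenue; implementation
# costs (AMT fee, monitoring consumables, device depreciation) are netted off.

#' Annual provider savings from reduced ESA use
#'
#' `dose_reduction (ug/kg per 30 days) * weight (kg) * 365/30 * price
#' (USD/ug)`.  The annualization factor is 365/30 (not 12 calendar months).
#'
#' @param dose_reduction Reduction in mean ESA dose, micrograms per kg per 30
#'   days (may be negative: a dose increase costs money).
#' @param weight Patient weight, kg (> 0).
#' @param price ESA price, USD per microgram (>= 0).
#' @return USD per patient-year.
#' @examples
#' esa_annual_savings(0.4, 81.4, 1.3)  # 515.05
#' @export
esa_annual_savings <- function(dose_reduction, weight, price) {
  if (any(weight <= 0)) stop("esa_annual_savings: weight must be positive", call. = FALSE)
  if (any(price < 0)) stop("esa_annual_savings: price must be non-negative", call. = FALSE)
  dose_reduction * weight * (365 / 30) * price
}

#' Annual revenue from avoiding the QIP payment reduction
#'
#' `session_cost * sessions_per_year * reduction_fraction`: the Medicare
#' payment a facility retains by avoiding the ESRD Quality Incentive Program
#' penalty.
#'
#' @param session_cost Bundled payment per dialysis session, USD.
#' @param sessions_per_year Sessions per patient-year (156 for thrice-weekly).
#' @param reduction_fraction QIP payment reduction avoided (e.g. 0.0012).
#' @return USD per patient-year.
#' @examples
#' qip_avoided_reduction(265.57, 156, 0.0012)  # 49.71
#' @export
qip_avoided_reduction <- function(session_cost, sessions_per_year, reduction_fraction) {
  if (any(c(session_cost, sessions_per_year, reduction_fraction) < 0)) {
    stop("qip_avoided_reduction: inputs must be non-negative", call. = FALSE)
  }
  session_cost * sessions_per_year * reduction_fraction
}

#' Annual implementation cost per patient
#'
#' Three cost scenarios for a facility adopting the tool:
#' * `"full"` - device, consumables and software fee.  When
#'   `use_aggregate = TRUE` (default from the parameter set) the published
#'   combined figure (`combined_cost_per_patient_year`, $347) is used;
#'   otherwise the per-session components are summed.
#' * `"consumables_amt"` - facility already owns the monitoring device;
#'   consumables + software fee only.
#' * `"amt_only"` - device and consumables already in routine use; software
#'   fee only.
#'
#' @param scenario One of `"full"`, `"consumables_amt"`, `"amt_only"`.
#' @param provider The `provider` section of an `amt_parameters` object (or
#'   any list with the same fields).
#' @param use_aggregate Use the published aggregate for the full scenario?
#'   Defaults to `provider$use_aggregate_cost`.
#' @return USD per patient-year.
#' @export
implementation_cost_per_patient_year <- function(scenario, provider,
                                                 use_aggregate = provider$use_aggregate_cost) {
  sessions <- provider$sessions_per_week * 52
  per_session <- switch(scenario,
    full = provider$amt_fee_per_treatment + provider$consumable_cost_per_session +
      provider$device_cost_per_session,
    consumables_amt = provider$amt_fee_per_treatment + provider$consumable_cost_per_session,
    amt_only = provider$amt_fee_per_treatment,
    stop(sprintf("configuration error: unknown cost scenario '%s'", scenario),
         call. = FALSE)
  )
  if (scenario == "full" && isTRUE(use_aggregate)) {
    provider$combined_cost_per_patient_year
  } else {
    per_session * sessions
  }
}

#' Net financial impact analysis (provider perspective)
#'
#' Composes ESA savings, QIP avoided-penalty revenue and implementation costs
#' into a per-patient annual net figure and scales it (unrounded) to the
#' facility level.
#'
#' @param params An `amt_parameters` object.
#' @param scenario Cost scenario; see
#'   [implementation_cost_per_patient_year()].
#' @return An object of class `amt_nfia`: `esa_savings`, `qip_revenue`,
#'   `implementation_cost`, `net_per_patient`, `facility_profit`,
#'   `facility_patient_count`, `scenario`.
#' @examples
#' nfia(load_parameters())$net_per_patient  # ~217.8, rounds to $218
#' @export
nfia <- function(params, scenario = "full") {
  stopifnot(inherits(params, "amt_parameters"))
  pr <- params$provider
  esa <- esa_annual_savings(pr$esa_dose_reduction, pr$patient_weight_kg,
                            pr$esa_price_per_ug)
  qip <- qip_avoided_reduction(params$economic$dialysis_session_cost,
                               pr$sessions_per_week * 52,
                               pr$qip_reduction_fraction)
  cost <- implementation_cost_per_patient_year(scenario, pr)
  net <- esa + qip - cost
  structure(list(
    esa_savings = esa, qip_revenue = qip, implementation_cost = cost,
    net_per_patient = net,
    facility_profit = net * pr$facility_patient_count,
    facility_patient_count = pr$facility_patient_count,
    scenario = scenario
  ), class = "amt_nfia")
}

#' @export
print.amt_nfia <- function(x, ...) {
  cat(sprintf("<amt_nfia: %s>  ESA $%.2f + QIP $%.2f - cost $%.2f = $%.2f /patient-yr; facility (n=%d) $%s/yr\n",
              x$scenario, x$esa_savings, x$qip_revenue, x$implementation_cost,
              x$net_per_patient, x$facility_patient_count,
              format(round(x$facility_profit), big.mark = ",")))
  invisible(x)
}

#' Annual incident Medicare cases
#'
#' Sums the age-band incident counts; 65+ bands count in full, under-65 bands
#' are multiplied by the Medicare coverage share when included.
#'
#' @param params An `amt_parameters` object.
#' @param include_under65 Include under-65 bands?  Default `FALSE` (the 65+
#'   Medicare population).
#' @return Persons per year.
#' @export
incident_medicare_cases <- function(params, include_under65 = FALSE) {
  ab <- params$epidemiology$age_bands
  under65 <- ab$upper_age < 65
  n <- sum(ab$incident_count[!under65])
  if (include_under65) {
    n <- n + sum(ab$incident_count[under65]) * params$epidemiology$medicare_share_under65
  }
  n
}

#' Budget impact analysis (payer perspective)
#'
#' Annual budget impact for the incident cohort: incident cases times the
#' lifetime incremental cost per case.  Negative values are savings to the
#' payer.
#'
#' @param params An `amt_parameters` object.
#' @param lifetime_cost_difference Lifetime discounted incremental cost per
#'   patient (USD; typically `delta_cost` from [run_cea()], negative when the
#'   intervention saves money).  Computed from a fresh [run_cea()] on the 65+
#'   cohort when missing.
#' @param include_under65 Include under-65 incident cases (down-weighted by
#'   the Medicare share)?  Default `FALSE`.
#' @return An object of class `amt_bia`: `incident_cases`,
#'   `lifetime_cost_difference`, `budget_impact`.
#' @export
budget_impact <- function(params, lifetime_cost_difference = NULL,
                          include_under65 = FALSE) {
  stopifnot(inherits(params, "amt_parameters"))
  if (is.null(lifetime_cost_difference)) {
    res <- run_cea(params, cohort = default_cohort(params, include_under65 = include_under65))
    lifetime_cost_difference <- res$delta_cost
  }
  cases <- incident_medicare_cases(params, include_under65 = include_under65)
  structure(list(
    incident_cases = cases,
    lifetime_cost_difference = lifetime_cost_difference,
    budget_impact = cases * lifetime_cost_difference
  ), class = "amt_bia")
}

#' @export
print.amt_bia <- function(x, ...) {
  cat(sprintf("<amt_bia>  %s incident cases x $%s = $%s/yr (negative = payer savings)\n",
              format(round(x$incident_cases), big.mark = ","),
              format(round(x$lifetime_cost_difference), big.mark = ","),
              format(round(x$budget_impact), big.mark = ",")))
  invisible(x)
}
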