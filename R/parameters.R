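# Parameter registry: embedded base-case inputs for the anemia-management-tool
# (AMT) cost-utility model, override plumbing, validation, and the calibrators
# that turn printed summaries (CI, IQR, min/mode/max) into distribution
# parameters.

#' Default age-band table for the US Medicare in-center hemodialysis population
#'
#' Four age bands (18-44, 45-64, 65-74, 75+) with annual all-cause mortality
#' probabilities, annual Medicare maintenance costs (USD/patient-year) and
#' annual incident case counts.  Annual costs are only published for the 65+
#' bands; the under-65 bands default to the 65-74 value and are flagged so that
#' payer-perspective outputs restricted to the 65+ population can exclude them.
#'
#' @return A `data.frame` with columns `label`, `lower_age`, `upper_age`,
#'   `annual_mortality_prob`, `annual_cost`, `cost_imputed`, `incident_count`.
#' @export
default_age_bands <- function() {
  data.frame(
    label = c("18-44", "45-64", "65-74", "75+"),
    lower_age = c(18, 45, 65, 75),
    upper_age = c(44, 64, 74, Inf),
    annual_mortality_prob = c(0.0963, 0.1536, 0.2326, 0.3303),
    annual_cost = c(102206, 102206, 102206, 99307),
    cost_imputed = c(TRUE, TRUE, FALSE, FALSE),
    incident_count = c(12252, 40998, 31775, 27855),
    stringsAsFactors = FALSE
  )
}

# Registry of flat override keys -> (section, field).  These are the scalar
# inputs a configuration file may set; age bands are overridden
# programmatically via the `age_bands` argument of load_parameters().
.param_registry <- function() {
  reg <- list(
    hb_sd_reduction          = c("clinical", "numeric"),
    hb_in_range_increase     = c("clinical", "numeric"),
    hr_mortality_per_sd      = c("clinical", "numeric"),
    or_hosp                  = c("clinical", "numeric"),
    baseline_hosp_rate       = c("clinical", "numeric"),
    rr_hosp                  = c("clinical", "numeric"),
    utility_hd               = c("economic", "numeric"),
    hospitalization_cost     = c("economic", "numeric"),
    dialysis_session_cost    = c("economic", "numeric"),
    discount_rate            = c("economic", "numeric"),
    wtp_threshold            = c("economic", "numeric"),
    esa_price_per_ug         = c("provider", "numeric"),
    patient_weight_kg        = c("provider", "numeric"),
    esa_dose_reduction       = c("provider", "numeric"),
    amt_fee_per_treatment    = c("provider", "numeric"),
    consumable_cost_per_session = c("provider", "numeric"),
    device_cost_per_session  = c("provider", "numeric"),
    combined_cost_per_patient_year = c("provider", "numeric"),
    use_aggregate_cost       = c("provider", "logical"),
    qip_reduction_fraction   = c("provider", "numeric"),
    sessions_per_week        = c("provider", "numeric"),
    facility_patient_count   = c("provider", "numeric"),
    medicare_share_under65   = c("epidemiology", "numeric"),
    utility_premium_enabled  = c("scenario", "logical"),
    utility_premium          = c("scenario", "numeric")
  )
  reg
}

.default_parameters <- function() {
  p <- list(
    clinical = list(
      hb_sd_reduction = 0.2,               # g/dL, base-case reduction with AMT
      hb_sd_reduction_ci = c(0.04, 0.3),
      hb_in_range_increase = 0.10,         # +10 pp of Hb values in 10-11 g/dL
      hb_in_range_increase_ci = c(0.03, 0.16),
      hr_mortality_per_sd = 1.09,          # HR per 1 g/dL increase in Hb SD
      hr_mortality_per_sd_ci = c(1.01, 1.18),
      or_hosp = 0.53,                      # low- vs high-variability hosp. OR
      or_hosp_ci = c(0.45, 0.62),
      baseline_hosp_rate = 1.49,           # events per patient-year
      rr_hosp = 0.91,                      # printed (rounded) chain output
      rr_hosp_ci = c(0.88, 0.93)
    ),
    economic = list(
      utility_hd = 0.69,
      utility_hd_ci = c(0.59, 0.80),
      hospitalization_cost = 17226,        # USD per admission
      hospitalization_cost_range = c(16160, 17226),
      dialysis_session_cost = 265.57,      # USD, Medicare bundled payment
      discount_rate = 0.03,
      discount_rate_range = c(0.02, 0.09),
      wtp_threshold = NA_real_             # NA: proxy from the SOC arm
    ),
    provider = list(
      esa_price_per_ug = 1.3,
      esa_price_per_ug_range = c(1.3, 1.5),
      patient_weight_kg = 81.4,            # median adult HD patient weight
      patient_weight_iqr = c(68.1, 98),
      esa_dose_reduction = 0.4,            # ug/kg per 30 days
      esa_dose_reduction_ci = c(-0.1, 0.8),
      amt_fee_per_treatment = 0.29,
      amt_fee_per_treatment_range = c(0.29, 0.41),
      consumable_cost_per_session = 1.35,
      consumable_cost_per_session_range = c(1.35, 2.00),
      device_cost_per_session = 0.49,
      combined_cost_per_patient_year = 347,
      use_aggregate_cost = TRUE,
      qip_reduction_fraction = 0.0012,
      sessions_per_week = 3,
      facility_patient_count = 70
    ),
    epidemiology = list(
      age_bands = default_age_bands(),
      medicare_share_under65 = 0.55,
      medicare_share_under65_range = c(0.50, 0.60)
    ),
    scenario = list(
      utility_premium_enabled = FALSE,
      utility_premium = 0.005              # delta-u per in-range proportion
    )
  )
  class(p) <- "amt_parameters"
  p
}

.stop_config <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

#' Validate a parameter set
#'
#' Checks every type invariant (probabilities in \[0, 1\], positive ratios,
#' non-negative costs, age bands partitioning ages 18+).  Called by
#' [load_parameters()]; exported so modified sets can be re-checked.
#'
#' @param p An object of class `amt_parameters`.
#' @return `p`, invisibly, if valid; otherwise an error naming the offending
#'   field and bound.
#' @export
validate_parameters <- function(p) {
  stopifnot(inherits(p, "amt_parameters"))
  chk <- function(ok, field, bound) {
    if (!isTRUE(ok)) .stop_config("validation error: '%s' violates bound %s", field, bound)
  }
  cl <- p$clinical; ec <- p$economic; pr <- p$provider; ep <- p$epidemiology
  chk(cl$hb_sd_reduction >= 0, "hb_sd_reduction", ">= 0")
  chk(cl$hr_mortality_per_sd > 0, "hr_mortality_per_sd", "> 0")
  chk(cl$or_hosp > 0, "or_hosp", "> 0")
  chk(cl$baseline_hosp_rate >= 0, "baseline_hosp_rate", ">= 0")
  chk(cl$rr_hosp > 0, "rr_hosp", "> 0")
  chk(cl$hb_in_range_increase >= 0 && cl$hb_in_range_increase <= 1,
      "hb_in_range_increase", "[0, 1]")
  chk(ec$utility_hd >= 0 && ec$utility_hd <= 1, "utility_hd", "[0, 1]")
  chk(ec$hospitalization_cost >= 0, "hospitalization_cost", ">= 0")
  chk(ec$dialysis_session_cost >= 0, "dialysis_session_cost", ">= 0")
  chk(ec$discount_rate >= 0 && ec$discount_rate < 1, "discount_rate", "[0, 1)")
  chk(is.na(ec$wtp_threshold) || ec$wtp_threshold >= 0, "wtp_threshold", ">= 0")
  chk(pr$esa_price_per_ug >= 0, "esa_price_per_ug", ">= 0")
  chk(pr$patient_weight_kg > 0, "patient_weight_kg", "> 0")
  chk(pr$amt_fee_per_treatment >= 0, "amt_fee_per_treatment", ">= 0")
  chk(pr$consumable_cost_per_session >= 0, "consumable_cost_per_session", ">= 0")
  chk(pr$device_cost_per_session >= 0, "device_cost_per_session", ">= 0")
  chk(pr$combined_cost_per_patient_year >= 0, "combined_cost_per_patient_year", ">= 0")
  chk(pr$qip_reduction_fraction >= 0, "qip_reduction_fraction", ">= 0")
  chk(pr$sessions_per_week > 0 && pr$sessions_per_week == round(pr$sessions_per_week),
      "sessions_per_week", "positive integer")
  chk(pr$facility_patient_count >= 0, "facility_patient_count", ">= 0")
  chk(ep$medicare_share_under65 >= 0 && ep$medicare_share_under65 <= 1,
      "medicare_share_under65", "[0, 1]")
  ab <- ep$age_bands
  chk(is.data.frame(ab) && nrow(ab) >= 1, "age_bands", "non-empty data.frame")
  chk(all(ab$annual_mortality_prob >= 0 & ab$annual_mortality_prob <= 1),
      "age_bands$annual_mortality_prob", "[0, 1]")
  chk(all(ab$annual_cost >= 0), "age_bands$annual_cost", ">= 0")
  chk(all(ab$incident_count >= 0), "age_bands$incident_count", ">= 0")
  o <- order(ab$lower_age)
  ab <- ab[o, ]
  # bands must tile [lower_age[1], Inf) without gaps or overlap
  if (nrow(ab) > 1) {
    chk(all(ab$lower_age[-1] == ab$upper_age[-nrow(ab)] + 1),
        "age_bands", "contiguous non-overlapping bands")
  }
  chk(is.infinite(ab$upper_age[nrow(ab)]), "age_bands", "open-ended last band")
  chk(p$scenario$utility_premium >= 0, "utility_premium", ">= 0")
  invisible(p)
}

#' Load the model parameter set
#'
#' Returns the embedded base-case inputs, optionally overlaid with overrides
#' from a flat key-value configuration (a JSON object or `key = value` text
#' file, or a named list).  Unknown keys and invariant violations raise errors
#' naming the offending key or field.
#'
#' @param config Path to a configuration file (JSON object or `key = value`
#'   lines), or a named list of overrides, or `NULL` for pure defaults.
#' @param overrides Named list of overrides applied after `config`.
#' @param age_bands Optional replacement age-band `data.frame` with the columns
#'   of [default_age_bands()] (`cost_imputed` may be omitted).
#' @return An object of class `amt_parameters`.
#' @examples
#' p <- load_parameters()
#' p$economic$utility_hd           # 0.69
#' p2 <- load_parameters(overrides = list(discount_rate = 0.02))
#' @export
load_parameters <- function(config = NULL, overrides = list(), age_bands = NULL) {
  p <- .default_parameters()
  ov <- list()
  if (!is.null(config)) {
    if (is.character(config) && length(config) == 1L) {
      ov <- read_config(config)
    } else if (is.list(config)) {
      ov <- config
    } else {
      .stop_config("configuration error: 'config' must be a file path or named list")
    }
  }
  ov <- utils::modifyList(ov, overrides)
  reg <- .param_registry()
  for (key in names(ov)) {
    if (!key %in% names(reg)) {
      .stop_config("configuration error: unknown key '%s'", key)
    }
    section <- reg[[key]][1]
    mode <- reg[[key]][2]
    val <- ov[[key]]
    if (mode == "numeric") {
      val <- suppressWarnings(as.numeric(val))
      if (length(val) != 1L || is.nan(val)) {
        .stop_config("configuration error: key '%s' must be a single number", key)
      }
    } else {
      val <- as.logical(val)
      if (length(val) != 1L || is.na(val)) {
        .stop_config("configuration error: key '%s' must be TRUE/FALSE", key)
      }
    }
    p[[section]][[key]] <- val
  }
  if (!is.null(age_bands)) {
    if (is.null(age_bands$cost_imputed)) age_bands$cost_imputed <- FALSE
    p$epidemiology$age_bands <- age_bands
  }
  validate_parameters(p)
  p
}

#' Read a flat key-value configuration file
#'
#' Accepts either a JSON object of scalars or plain text `key = value` lines
#' (`#` comments and blank lines ignored).
#'
#' @param path File path.
#' @return A named list of raw override values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) .stop_config("configuration error: no such file '%s'", path)
  txt <- readLines(path, warn = FALSE)
  joined <- paste(txt, collapse = "\n")
  if (grepl("^\\s*\\{", joined)) {
    ov <- jsonlite::fromJSON(joined, simplifyVector = TRUE)
    if (!is.list(ov)) .stop_config("configuration error: JSON config must be an object")
    return(ov)
  }
  txt <- txt[!grepl("^\\s*(#|$)", txt)]
  ov <- list()
  for (line in txt) {
    m <- regmatches(line, regexec("^\\s*([A-Za-z0-9_.]+)\\s*[=:]\\s*(.*?)\\s*$", line))[[1]]
    if (length(m) != 3L) .stop_config("configuration error: cannot parse line '%s'", line)
    ov[[m[2]]] <- m[3]
  }
  ov
}

#' Serialize a parameter set to JSON
#'
#' Full-precision round-trip serialization: [parameters_from_json()] on the
#' output reproduces an identical parameter set.
#'
#' @param p An `amt_parameters` object.
#' @return A JSON string.
#' @export
parameters_to_json <- function(p) {
  stopifnot(inherits(p, "amt_parameters"))
  u <- unclass(p)
  # Inf in upper_age is not valid JSON; encode as the string "Inf"
  u$epidemiology$age_bands$upper_age <-
    ifelse(is.infinite(u$epidemiology$age_bands$upper_age), "Inf",
           as.character(u$epidemiology$age_bands$upper_age))
  jsonlite::toJSON(u, digits = NA, auto_unbox = TRUE, na = "null")
}

#' @rdname parameters_to_json
#' @param json A JSON string produced by [parameters_to_json()].
#' @export
parameters_from_json <- function(json) {
  u <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  u$epidemiology$age_bands$upper_age <-
    as.numeric(ifelse(u$epidemiology$age_bands$upper_age == "Inf", Inf,
                      u$epidemiology$age_bands$upper_age))
  if (is.null(u$economic$wtp_threshold)) u$economic$wtp_threshold <- NA_real_
  class(u) <- "amt_parameters"
  validate_parameters(u)
  u
}

#' @export
print.amt_parameters <- function(x, ...) {
  cat("<amt_parameters>\n")
  cat(sprintf("  clinical : Hb SD reduction %.2f g/dL, mortality HR/SD %.2f, OR(hosp) %.2f, baseline rate %.2f/yr\n",
              x$clinical$hb_sd_reduction, x$clinical$hr_mortality_per_sd,
              x$clinical$or_hosp, x$clinical$baseline_hosp_rate))
  cat(sprintf("  economic : utility %.2f, hosp cost $%s, discount %.0f%%\n",
              x$economic$utility_hd, format(x$economic$hospitalization_cost, big.mark = ","),
              100 * x$economic$discount_rate))
  cat(sprintf("  provider : ESA $%.2f/ug, weight %.1f kg, dose reduction %.2f ug/kg/30d\n",
              x$provider$esa_price_per_ug, x$provider$patient_weight_kg,
              x$provider$esa_dose_reduction))
  cat(sprintf("  epi      : %d age bands, Medicare share <65 = %.2f\n",
              nrow(x$epidemiology$age_bands), x$epidemiology$medicare_share_under65))
  cat(sprintf("  scenario : utility premium %s (delta-u = %.3f)\n",
              if (x$scenario$utility_premium_enabled) "ON" else "off",
              x$scenario$utility_premium))
  invisible(x)
}

# ---- distribution calibrators -----------------------------------------------

#' Beta-PERT shape parameters from (min, mode, max)
#'
#' Classic PERT parameterization: `alpha = 1 + 4 (mode - min) / (max - min)`,
#' `beta = 1 + 4 (max - mode) / (max - min)`.  The support (0.04, 0.30) with
#' mode 0.2 yields the base-case shapes (3.462, 2.538) used for the hemoglobin
#' SD reduction.
#'
#' @param min,mode,max Support minimum, most likely value, support maximum.
#' @return Named numeric vector `c(alpha, beta)`.
#' @export
pert_shape_params <- function(min, mode, max) {
  if (!(min < max)) stop("pert_shape_params: require min < max", call. = FALSE)
  if (mode < min || mode > max) {
    stop("pert_shape_params: require min <= mode <= max", call. = FALSE)
  }
  c(alpha = 1 + 4 * (mode - min) / (max - min),
    beta  = 1 + 4 * (max - mode) / (max - min))
}

#' Lognormal parameters from a ratio estimate and its 95 percent CI
#'
#' For a ratio (HR, OR, RR) reported as point (lo-hi), the log-scale mean is
#' `ln(point)` and the log-scale SD is `(ln(hi) - ln(lo)) / (2 * 1.96)`.
#'
#' @param point Point estimate (> 0).
#' @param lo,hi 95 percent CI bounds (0 < lo <= point <= hi).
#' @return Named numeric vector `c(ln_mu, ln_sigma)`.
#' @export
lognormal_params_from_ci <- function(point, lo, hi) {
  if (any(c(point, lo, hi) <= 0)) {
    stop("lognormal_params_from_ci: inputs must be positive", call. = FALSE)
  }
  if (!(lo <= point && point <= hi)) {
    stop("lognormal_params_from_ci: require lo <= point <= hi", call. = FALSE)
  }
  c(ln_mu = log(point), ln_sigma = (log(hi) - log(lo)) / (2 * 1.96))
}

#' Lognormal parameters from a median and interquartile range
#'
#' `ln_mu = ln(median)`; `ln_sigma = (ln(q3) - ln(q1)) / (2 * 0.6745)` since
#' the quartiles of a standard normal sit at +/- 0.6745 SD.  Used for patient
#' body weight.
#'
#' @param median,q1,q3 Median and quartiles (all > 0, q1 <= median <= q3).
#' @return Named numeric vector `c(ln_mu, ln_sigma)`.
#' @export
lognormal_params_from_quartiles <- function(median, q1, q3) {
  if (any(c(median, q1, q3) <= 0)) {
    stop("lognormal_params_from_quartiles: inputs must be positive", call. = FALSE)
  }
  if (!(q1 <= median && median <= q3)) {
    stop("lognormal_params_from_quartiles: require q1 <= median <= q3", call. = FALSE)
  }
  c(ln_mu = log(median), ln_sigma = (log(q3) - log(q1)) / (2 * stats::qnorm(0.75)))
}

#' Normal SD from a 95 percent CI
#'
#' `sigma = (hi - lo) / (2 * 1.96)`.  Used for the ESA dose reduction, whose
#' CI crosses zero.
#'
#' @param lo,hi CI bounds (lo <= hi).
#' @return Numeric scalar sigma.
#' @export
normal_sigma_from_ci <- function(lo, hi) {
  if (lo > hi) stop("normal_sigma_from_ci: require lo <= hi", call. = FALSE)
  (hi - lo) / (2 * 1.96)
}
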