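# Two-state (alive/dead) Markov cohort engine: age-band mortality and annual
# maintenance costs, hospitalization events accrued among the alive,
# life-table half-cycle correction, mid-cycle discounting, and a stopping rule
# at < 0.1% of the cohort alive.

#' Construct a cohort specification
#'
#' A cohort is a mixture of sub-cohorts, each a (starting age, weight) pair;
#' weights must sum to 1.
#'
#' @param starting_age Numeric vector of starting ages (years).
#' @param weight Numeric vector of non-negative mixture weights summing to 1.
#' @return An object of class `amt_cohort` (a data.frame).
#' @export
cohort_spec <- function(starting_age, weight) {
  stopifnot(length(starting_age) == length(weight))
  if (any(weight < 0)) stop("cohort_spec: weights must be non-negative", call. = FALSE)
  if (abs(sum(weight) - 1) > 1e-12) {
    stop("cohort_spec: weights must sum to 1", call. = FALSE)
  }
  out <- data.frame(starting_age = starting_age, weight = weight)
  class(out) <- c("amt_cohort", "data.frame")
  out
}

#' Default incident Medicare cohort
#'
#' Builds the cohort mixture from the age-band incident counts, down-weighting
#' the under-65 bands by the Medicare coverage share, and starting each
#' sub-cohort at its band midpoint (the open-ended 75+ band starts at 80).
#'
#' @param params An `amt_parameters` object.
#' @param include_under65 Include the under-65 bands (down-weighted by
#'   `medicare_share_under65`)?  Default `TRUE`.
#' @return An `amt_cohort`.
#' @export
default_cohort <- function(params, include_under65 = TRUE) {
  ab <- params$epidemiology$age_bands
  share <- params$epidemiology$medicare_share_under65
  mid <- ifelse(is.infinite(ab$upper_age), ab$lower_age + 5,
                (ab$lower_age + ab$upper_age) / 2)
  under65 <- ab$upper_age < 65
  w <- ab$incident_count * ifelse(under65, share, 1)
  if (!include_under65) w[under65] <- 0
  keep <- w > 0
  cohort_spec(mid[keep], w[keep] / sum(w[keep]))
}

#' Configuration of one model arm
#'
#' @param label Arm label, e.g. `"AMT"` or `"SOC"`.
#' @param mortality_hr Hazard ratio applied to the age-band mortality
#'   probabilities (1 for the standard-of-care arm).
#' @param hosp_rate Annual hospitalization rate among the alive
#'   (events/patient-year).
#' @param extra_utility_per_year Additional utility accrued per life-year
#'   (scenario in-range premium; 0 in the base case).
#' @return An object of class `amt_arm`.
#' @export
arm_config <- function(label, mortality_hr = 1, hosp_rate = 0,
                       extra_utility_per_year = 0) {
  if (mortality_hr <= 0) stop("arm_config: mortality_hr must be positive", call. = FALSE)
  if (hosp_rate < 0) stop("arm_config: hosp_rate must be non-negative", call. = FALSE)
  structure(list(label = label, mortality_hr = mortality_hr,
                 hosp_rate = hosp_rate,
                 extra_utility_per_year = extra_utility_per_year),
            class = "amt_arm")
}

#' Mid-cycle discount factor
#'
#' With annual cycles and transitions assumed to occur on average halfway
#' through each cycle, cycle `t` (1-based) is discounted by
#' `(1 + rate)^-(t - 0.5)`.
#'
#' @param cycle_index 1-based cycle (year) index.
#' @param rate Annual discount rate (>= 0).
#' @return Discount factor(s).
#' @export
mid_cycle_discount <- function(cycle_index, rate) {
  if (any(cycle_index < 1)) {
    stop("mid_cycle_discount: cycle_index must be >= 1", call. = FALSE)
  }
  if (rate < 0) stop("mid_cycle_discount: rate must be non-negative", call. = FALSE)
  (1 + rate)^(-(cycle_index - 0.5))
}

#' Apply a hazard ratio to an annual mortality probability
#'
#' Probability -> rate -> scale by HR -> probability:
#' `1 - (1 - p)^hr`.  `p = 1` maps to 1 for any HR.
#'
#' @param prob Annual probability in \[0, 1\].
#' @param hr Hazard ratio (> 0).
#' @return Adjusted annual probability.
#' @export
adjust_mortality <- function(prob, hr) {
  if (any(prob < 0 | prob > 1)) {
    stop("adjust_mortality: prob must lie in [0, 1]", call. = FALSE)
  }
  if (any(hr <= 0)) stop("adjust_mortality: hr must be positive", call. = FALSE)
  1 - (1 - prob)^hr
}

# Row index of the band containing each (integer) age; errors if any age has
# no band.  The last (open-ended) band absorbs all older ages.
.band_index <- function(age_bands, age) {
  ia <- floor(age)
  idx <- rep(NA_integer_, length(ia))
  for (b in seq_len(nrow(age_bands))) {
    hit <- ia >= age_bands$lower_age[b] & ia <= age_bands$upper_age[b]
    idx[hit] <- b
  }
  if (anyNA(idx)) {
    stop(sprintf("configuration error: no age band covers age %s",
                 paste(unique(ia[is.na(idx)]), collapse = ", ")), call. = FALSE)
  }
  idx
}

#' Run the Markov cohort simulation for one arm
#'
#' Each sub-cohort ages one year per cycle and faces its current band's annual
#' mortality probability (hazard-ratio adjusted for the intervention arm).
#' Per-cycle life-years use the life-table half-cycle mean
#' `(alive_start + alive_end) / 2`; QALYs multiply life-years by
#' `utility_hd + extra_utility_per_year`; maintenance costs use the band's
#' annual cost and hospitalization costs accrue as
#' `life_years * hosp_rate * hospitalization_cost`; everything is discounted
#' mid-cycle.  Simulation stops at the first cycle after which the alive
#' fraction falls below 0.1%.
#'
#' @param params An `amt_parameters` object.
#' @param arm An `amt_arm`.
#' @param cohort An `amt_cohort`; defaults to [default_cohort()].
#' @return A data.frame of class `amt_trace`, one row per cycle, with columns
#'   `cycle`, `mean_age` (weighted over survivors at cycle start),
#'   `alive_start`, `alive_end`, `life_years`, `disc_factor`,
#'   `disc_life_years`, `qalys`, `disc_qalys`, `maintenance_cost`,
#'   `hospitalization_cost`, `cost`, `disc_cost`.
#' @export
run_cohort <- function(params, arm, cohort = default_cohort(params)) {
  stopifnot(inherits(params, "amt_parameters"), inherits(arm, "amt_arm"))
  ab <- params$epidemiology$age_bands
  ec <- params$economic
  utility <- ec$utility_hd + arm$extra_utility_per_year
  hosp_cost_rate <- arm$hosp_rate * ec$hospitalization_cost

  alive <- cohort$weight
  ages0 <- cohort$starting_age
  rows <- vector("list", 256L)
  t <- 0L
  repeat {
    t <- t + 1L
    age_t <- ages0 + (t - 1L)           # age during cycle t
    bi <- .band_index(ab, age_t)
    q <- adjust_mortality(ab$annual_mortality_prob[bi], arm$mortality_hr)
    alive_end <- alive * (1 - q)
    ly_sub <- (alive + alive_end) / 2    # half-cycle person-years
    ly <- sum(ly_sub)
    maint <- sum(ly_sub * ab$annual_cost[bi])
    hosp <- ly * hosp_cost_rate
    df <- mid_cycle_discount(t, ec$discount_rate)
    rows[[t]] <- c(
      cycle = t,
      mean_age = sum(age_t * alive) / sum(alive),
      alive_start = sum(alive), alive_end = sum(alive_end),
      life_years = ly, disc_factor = df, disc_life_years = ly * df,
      qalys = ly * utility, disc_qalys = ly * utility * df,
      maintenance_cost = maint, hospitalization_cost = hosp,
      cost = maint + hosp, disc_cost = (maint + hosp) * df
    )
    alive <- alive_end
    if (sum(alive) < 0.001) break
    if (t >= 1000L) stop("run_cohort: cohort failed to die out within 1000 cycles",
                         call. = FALSE)
  }
  tr <- as.data.frame(do.call(rbind, rows[seq_len(t)]))
  attr(tr, "arm") <- arm$label
  class(tr) <- c("amt_trace", "data.frame")
  tr
}

#' Lifetime outcomes of a cohort trace
#'
#' Sums the discounted columns of a trace.
#'
#' @param trace An `amt_trace` from [run_cohort()].
#' @return An object of class `amt_outcomes`: `cost`, `life_years`, `qalys`
#'   (all discounted), plus undiscounted `life_years_undisc`, `qalys_undisc`,
#'   `cost_undisc` and the arm label.
#' @export
lifetime_outcomes <- function(trace) {
  stopifnot(inherits(trace, "amt_trace"), nrow(trace) > 0)
  structure(list(
    arm = attr(trace, "arm"),
    cost = sum(trace$disc_cost),
    life_years = sum(trace$disc_life_years),
    qalys = sum(trace$disc_qalys),
    cost_undisc = sum(trace$cost),
    life_years_undisc = sum(trace$life_years),
    qalys_undisc = sum(trace$qalys),
    cycles = nrow(trace)
  ), class = "amt_outcomes")
}

#' @export
print.amt_outcomes <- function(x, ...) {
  cat(sprintf("<amt_outcomes: %s>  cost $%s | %.3f LY | %.3f QALYs (discounted, %d cycles)\n",
              x$arm %||% "?", format(round(x$cost), big.mark = ","),
              x$life_years, x$qalys, x$cycles))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the two model arms from derived effects
#'
#' Standard of care: HR 1, baseline hospitalization rate, no premium.
#' Intervention: derived mortality HR, baseline rate minus the derived
#' reduction (floored at 0), and the in-range utility premium when the
#' scenario flag is on.
#'
#' @param params An `amt_parameters` object.
#' @param effects An `amt_effects` from [derive_effects()]; derived from
#'   `params` if missing.
#' @return List with elements `amt` and `soc`, both `amt_arm`.
#' @export
build_arms <- function(params, effects = derive_effects(params)) {
  premium <- if (isTRUE(params$scenario$utility_premium_enabled)) {
    effects$in_range_qaly_gain_per_year
  } else 0
  list(
    amt = arm_config("AMT", mortality_hr = effects$hr_mortality_amt,
                     hosp_rate = effects$hosp_rate_amt,
                     extra_utility_per_year = premium),
    soc = arm_config("SOC", mortality_hr = 1,
                     hosp_rate = params$clinical$baseline_hosp_rate)
  )
}
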