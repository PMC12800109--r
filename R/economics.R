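# Cost-utility arithmetic: ICERs, net monetary benefit (NMB = lambda*dE - dC),
# its annualization over discounted life expectancy, and the willingness-to-pay
# proxy from comparing dialysis care with no kidney replacement therapy.

#' Incremental cost-effectiveness ratios
#'
#' Computes incremental cost and effect between two arm outcomes and the ICER
#' per QALY and per life-year.  When the treatment saves money and gains
#' effect (or loses both), a dominance flag replaces a meaningless ratio.
#'
#' @param treatment,comparator `amt_outcomes` objects from the same parameter
#'   set.
#' @return List with `delta_cost`, `delta_qalys`, `delta_ly`, `icer_per_qaly`,
#'   `icer_per_ly` (NA when flagged), and `dominance` (one of `"dominant"`,
#'   `"dominated"`, `"indeterminate"`, `"none"`).
#' @export
icer <- function(treatment, comparator) {
  stopifnot(inherits(treatment, "amt_outcomes"), inherits(comparator, "amt_outcomes"))
  dc <- treatment$cost - comparator$cost
  dq <- treatment$qalys - comparator$qalys
  dl <- treatment$life_years - comparator$life_years
  ratio <- function(dC, dE) {
    if (dE > 0 && dC >= 0) dC / dE else NA_real_
  }
  dominance <- if (dc == 0 && dq == 0) {
    "indeterminate"
  } else if (dq == 0) {
    "indeterminate"
  } else if (dc <= 0 && dq >= 0) {
    "dominant"
  } else if (dc >= 0 && dq <= 0) {
    "dominated"
  } else "none"
  list(delta_cost = dc, delta_qalys = dq, delta_ly = dl,
       icer_per_qaly = ratio(dc, dq), icer_per_ly = ratio(dc, dl),
       dominance = dominance)
}

#' Net monetary benefit
#'
#' `NMB = lambda * delta_effect - delta_cost`.
#'
#' @param wtp Willingness-to-pay threshold lambda, USD per QALY (>= 0).
#' @param delta_effect Incremental effect (QALYs).
#' @param delta_cost Incremental cost (USD).
#' @return NMB in USD.
#' @export
nmb <- function(wtp, delta_effect, delta_cost) {
  if (any(wtp < 0)) stop("nmb: wtp must be non-negative", call. = FALSE)
  wtp * delta_effect - delta_cost
}

#' Willingness-to-pay proxy from the standard-of-care arm
#'
#' The threshold is proxied by the cost-utility ratio of dialysis versus no
#' kidney replacement therapy, treating the latter as zero cost and zero
#' benefit: `lambda = cost_SOC / QALYs_SOC`.
#'
#' @param soc An `amt_outcomes` for the standard-of-care arm.
#' @return USD per QALY.
#' @export
wtp_proxy <- function(soc) {
  stopifnot(inherits(soc, "amt_outcomes"))
  if (soc$qalys <= 0) stop("wtp_proxy: SOC QALYs must be positive", call. = FALSE)
  soc$cost / soc$qalys
}

#' Annualized net monetary benefit
#'
#' Lifetime NMB divided by the (discounted) remaining life expectancy on the
#' intervention arm: the maximum annual price at which the intervention stays
#' cost-effective.
#'
#' @param nmb_lifetime Lifetime NMB, USD.
#' @param life_expectancy_amt Discounted life expectancy with the
#'   intervention, years (> 0).
#' @return USD per year.
#' @export
annualize_nmb <- function(nmb_lifetime, life_expectancy_amt) {
  if (life_expectancy_amt <= 0) {
    stop("annualize_nmb: life expectancy must be positive", call. = FALSE)
  }
  nmb_lifetime / life_expectancy_amt
}

#' Run the full cost-effectiveness analysis
#'
#' Derives effects, simulates both arms over the cohort, and assembles the
#' cost-utility result: incremental costs/effects, ICERs, the WTP threshold
#' (configured or proxied from the SOC arm), lifetime and annualized NMB.
#'
#' @param params An `amt_parameters` object.
#' @param cohort An `amt_cohort`; defaults to [default_cohort()].
#' @param rr_override Optional RR passed through to [derive_effects()].
#' @return An object of class `amt_ce_result`: fields `effects`, `amt`, `soc`
#'   (outcomes), `traces`, `delta_cost`, `delta_qalys`, `delta_ly`,
#'   `icer_per_qaly`, `icer_per_ly`, `dominance`, `wtp`, `wtp_source`,
#'   `nmb_lifetime`, `nmb_annual`.
#' @examples
#' res <- run_cea(load_parameters())
#' res$dominance       # "dominant": cheaper and more effective
#' @export
run_cea <- function(params, cohort = default_cohort(params), rr_override = NULL) {
  eff <- derive_effects(params, rr_override = rr_override)
  arms <- build_arms(params, eff)
  tr_amt <- run_cohort(params, arms$amt, cohort)
  tr_soc <- run_cohort(params, arms$soc, cohort)
  out_amt <- lifetime_outcomes(tr_amt)
  out_soc <- lifetime_outcomes(tr_soc)
  ic <- icer(out_amt, out_soc)
  wtp_cfg <- params$economic$wtp_threshold
  if (is.na(wtp_cfg)) {
    wtp <- wtp_proxy(out_soc); wtp_source <- "proxy_hd_vs_no_krt"
  } else {
    wtp <- wtp_cfg; wtp_source <- "configured"
  }
  nmb_life <- nmb(wtp, ic$delta_qalys, ic$delta_cost)
  res <- c(list(effects = eff, amt = out_amt, soc = out_soc,
                traces = list(amt = tr_amt, soc = tr_soc)),
           ic,
           list(wtp = wtp, wtp_source = wtp_source,
                nmb_lifetime = nmb_life,
                nmb_annual = annualize_nmb(nmb_life, out_amt$life_years)))
  class(res) <- "amt_ce_result"
  res
}

#' @export
print.amt_ce_result <- function(x, ...) {
  f <- function(v) format(round(v), big.mark = ",")
  cat("<amt_ce_result>\n")
  cat(sprintf("  AMT : cost $%s | %.3f LY | %.3f QALYs\n", f(x$amt$cost),
              x$amt$life_years, x$amt$qalys))
  cat(sprintf("  SOC : cost $%s | %.3f LY | %.3f QALYs\n", f(x$soc$cost),
              x$soc$life_years, x$soc$qalys))
  cat(sprintf("  dCost $%s | dQALY %.4f | dominance: %s\n", f(x$delta_cost),
              x$delta_qalys, x$dominance))
  cat(sprintf("  WTP (%s) $%s/QALY | NMB $%s lifetime, $%s per year\n",
              x$wtp_source, f(x$wtp), f(x$nmb_lifetime), f(x$nmb_annual)))
  invisible(x)
}

#' Flatten a CE result into a named list for export
#'
#' @param res An `amt_ce_result`.
#' @return Named list of scalars suitable for JSON export.
#' @export
ce_summary <- function(res) {
  stopifnot(inherits(res, "amt_ce_result"))
  list(
    amt_cost = res$amt$cost, amt_life_years = res$amt$life_years,
    amt_qalys = res$amt$qalys,
    soc_cost = res$soc$cost, soc_life_years = res$soc$life_years,
    soc_qalys = res$soc$qalys,
    delta_cost = res$delta_cost, delta_qalys = res$delta_qalys,
    delta_ly = res$delta_ly,
    icer_per_qaly = res$icer_per_qaly, icer_per_ly = res$icer_per_ly,
    dominance = res$dominance,
    wtp = res$wtp, wtp_source = res$wtp_source,
    nmb_lifetime = res$nmb_lifetime, nmb_annual = res$nmb_annual,
    hr_mortality_amt = res$effects$hr_mortality_amt,
    hosp_rate_reduction = res$effects$hosp_rate_reduction
  )
}
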