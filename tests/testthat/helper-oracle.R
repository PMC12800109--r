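# Shared fixtures and independent oracles, built in code at test time.

# Parameter set whose age bands collapse to a single open-ended band with
# constant mortality q and constant annual cost: the closed-form regime.
constant_mortality_params <- function(q, annual_cost = 0, discount_rate = 0,
                                      utility = 1, hosp_rate_base = 0) {
  bands <- data.frame(
    label = "18+", lower_age = 18, upper_age = Inf,
    annual_mortality_prob = q, annual_cost = annual_cost,
    incident_count = 1
  )
  load_parameters(
    overrides = list(discount_rate = discount_rate, utility_hd = utility,
                     baseline_hosp_rate = hosp_rate_base),
    age_bands = bands
  )
}

# Independent life-table annuity oracle: survival S_t = (1-q)^t, per-cycle
# person-years (S_{t-1}+S_t)/2, mid-cycle discounting, truncated at the first
# cycle with S_t < 0.001.  Written as direct sums, not via the engine.
annuity_oracle <- function(q, rate = 0, cost_per_ly = 0, utility = 1) {
  Tmax <- 0L
  repeat {
    Tmax <- Tmax + 1L
    if ((1 - q)^Tmax < 0.001) break
  }
  t <- seq_len(Tmax)
  S0 <- (1 - q)^(t - 1)
  S1 <- (1 - q)^t
  ly <- (S0 + S1) / 2
  df <- (1 + rate)^(-(t - 0.5))
  list(cycles = Tmax,
       life_years = sum(ly * df),
       qalys = sum(ly * df) * utility,
       cost = sum(ly * df) * cost_per_ly,
       life_years_undisc = sum(ly))
}
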