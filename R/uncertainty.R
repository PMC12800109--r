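# Uncertainty engine: distribution specifications for every uncertain input,
# the seeded Monte Carlo probabilistic sensitivity analysis (PSA) that draws
# whole parameter sets, and the one-way deterministic sensitivity analysis
# (tornado) over the published low/high ranges.

#' Distribution specification for one uncertain input
#'
#' @param family One of `"fixed"`, `"beta"`, `"gamma"`, `"lognormal"`,
#'   `"uniform"`, `"beta_pert"`, `"normal"`.
#' @param ... Family-specific named parameters:
#'   * fixed: `value`
#'   * beta: `alpha`, `beta`
#'   * gamma: `shape`, `scale`
#'   * lognormal: `ln_mu`, `ln_sigma`
#'   * uniform: `min`, `max`
#'   * beta_pert: `min`, `max`, and either `alpha`+`beta` or `mode`
#'   * normal: `mean`, `sd`
#' @param support Optional length-2 numeric: samples are clamped-checked
#'   against this interval (a violation is an error, not a silent clamp).
#' @return An object of class `amt_dist`.
#' @export
dist_spec <- function(family, ..., support = NULL) {
  family <- match.arg(family, c("fixed", "beta", "gamma", "lognormal",
                                "uniform", "beta_pert", "normal"))
  params <- list(...)
  need <- function(...) {
    miss <- setdiff(c(...), names(params))
    if (length(miss)) {
      stop(sprintf("configuration error: %s distribution needs parameter(s) %s",
                   family, paste(miss, collapse = ", ")), call. = FALSE)
    }
  }
  pos <- function(nm) {
    if (params[[nm]] <= 0) {
      stop(sprintf("configuration error: %s parameter '%s' must be > 0", family, nm),
           call. = FALSE)
    }
  }
  switch(family,
    fixed = need("value"),
    beta = { need("alpha", "beta"); pos("alpha"); pos("beta") },
    gamma = { need("shape", "scale"); pos("shape"); pos("scale") },
    lognormal = { need("ln_mu", "ln_sigma")
      if (params$ln_sigma < 0) stop("configuration error: ln_sigma must be >= 0", call. = FALSE) },
    uniform = { need("min", "max")
      if (params$min > params$max) stop("configuration error: uniform min > max", call. = FALSE) },
    beta_pert = {
      need("min", "max")
      if (params$min >= params$max) stop("configuration error: beta_pert min >= max", call. = FALSE)
      if (is.null(params$alpha) || is.null(params$beta)) {
        need("mode")
        sh <- pert_shape_params(params$min, params$mode, params$max)
        params$alpha <- sh[["alpha"]]; params$beta <- sh[["beta"]]
      }
    },
    normal = { need("mean", "sd")
      if (params$sd < 0) stop("configuration error: sd must be >= 0", call. = FALSE) }
  )
  structure(list(family = family, params = params, support = support),
            class = "amt_dist")
}

#' Draw from a distribution specification
#'
#' Uses R's current RNG stream; callers seed it (see [run_psa()]).
#'
#' @param spec An `amt_dist`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n = 1) {
  stopifnot(inherits(spec, "amt_dist"))
  p <- spec$params
  x <- switch(spec$family,
    fixed = rep(p$value, n),
    beta = stats::rbeta(n, p$alpha, p$beta),
    gamma = stats::rgamma(n, shape = p$shape, scale = p$scale),
    lognormal = stats::rlnorm(n, meanlog = p$ln_mu, sdlog = p$ln_sigma),
    uniform = stats::runif(n, p$min, p$max),
    beta_pert = p$min + (p$max - p$min) * stats::rbeta(n, p$alpha, p$beta),
    normal = stats::rnorm(n, p$mean, p$sd)
  )
  if (!is.null(spec$support)) {
    if (any(x < spec$support[1] - 1e-12 | x > spec$support[2] + 1e-12)) {
      stop("sample_dist: draw outside declared support", call. = FALSE)
    }
  }
  x
}

#' Expected value of a distribution specification
#'
#' Closed-form mean per family; used for calibration checks against sampled
#' moments.
#'
#' @param spec An `amt_dist`.
#' @return Numeric scalar.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "amt_dist"))
  p <- spec$params
  switch(spec$family,
    fixed = p$value,
    beta = p$alpha / (p$alpha + p$beta),
    gamma = p$shape * p$scale,
    lognormal = exp(p$ln_mu + p$ln_sigma^2 / 2),
    uniform = (p$min + p$max) / 2,
    beta_pert = p$min + (p$max - p$min) * p$alpha / (p$alpha + p$beta),
    normal = p$mean
  )
}

#' Default PSA distribution set
#'
#' One `amt_dist` per uncertain input, parameterized exactly as published:
#' Beta-PERT(3.462, 2.538) on (0.04, 0.30) for the Hb SD reduction;
#' lognormals for the mortality HR (ln-mu 0.086, ln-sigma 0.040) and the
#' hospitalization RR (ln-mu -0.092, ln-sigma 0.014); Beta(50.737, 22.795)
#' for the HD utility; Gamma(k = 1002, theta = 18.23) for the hospitalization
#' cost; Uniform(0.50, 0.60) for the under-65 Medicare share; and the
#' calibrated lognormal (weight, from median/IQR) and normal (ESA dose
#' reduction, from its 95% CI) for the provider inputs.
#'
#' @param params An `amt_parameters` object supplying the summaries the
#'   calibrated distributions are derived from.
#' @return Named list of `amt_dist` objects; names are flat parameter keys.
#' @export
default_psa_specs <- function(params = load_parameters()) {
  cl <- params$clinical; ec <- params$economic; pr <- params$provider
  ep <- params$epidemiology
  w <- lognormal_params_from_quartiles(pr$patient_weight_kg,
                                       pr$patient_weight_iqr[1],
                                       pr$patient_weight_iqr[2])
  esa_sd <- normal_sigma_from_ci(pr$esa_dose_reduction_ci[1],
                                 pr$esa_dose_reduction_ci[2])
  list(
    hb_sd_reduction = dist_spec("beta_pert",
      min = cl$hb_sd_reduction_ci[1], max = cl$hb_sd_reduction_ci[2],
      alpha = 3.462, beta = 2.538,
      support = cl$hb_sd_reduction_ci),
    hr_mortality_per_sd = dist_spec("lognormal", ln_mu = 0.086, ln_sigma = 0.040),
    rr_hosp = dist_spec("lognormal", ln_mu = -0.092, ln_sigma = 0.014),
    utility_hd = dist_spec("beta", alpha = 50.737, beta = 22.795),
    hospitalization_cost = dist_spec("gamma", shape = 1002, scale = 18.23),
    medicare_share_under65 = dist_spec("uniform",
      min = ep$medicare_share_under65_range[1],
      max = ep$medicare_share_under65_range[2]),
    patient_weight_kg = dist_spec("lognormal",
      ln_mu = w[["ln_mu"]], ln_sigma = w[["ln_sigma"]]),
    esa_dose_reduction = dist_spec("normal",
      mean = pr$esa_dose_reduction, sd = esa_sd)
  )
}

#' Sample one or more full parameter sets
#'
#' Draws every spec independently and overlays the draws onto the base
#' parameter set.  All other inputs stay at base-case values.
#'
#' @param params Base `amt_parameters`.
#' @param specs Named list of `amt_dist` (names must be registry keys);
#'   defaults to [default_psa_specs()].
#' @param n Number of parameter sets.
#' @return A list of `n` lists, each with `params` (the sampled
#'   `amt_parameters`) and `draws` (the named numeric vector of raw draws).
#' @export
sample_parameter_set <- function(params = load_parameters(),
                                 specs = default_psa_specs(params), n = 1) {
  reg <- .param_registry()
  bad <- setdiff(names(specs), names(reg))
  if (length(bad)) {
    stop(sprintf("configuration error: unknown sampled parameter(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  draws <- vapply(specs, sample_dist, numeric(n), n = n)
  if (n == 1) draws <- matrix(draws, nrow = 1, dimnames = list(NULL, names(specs)))
  lapply(seq_len(n), function(i) {
    ov <- as.list(draws[i, ])
    p <- params
    for (key in names(ov)) {
      section <- reg[[key]][1]
      p[[section]][[key]] <- ov[[key]]
    }
    validate_parameters(p)
    list(params = p, draws = draws[i, ])
  })
}

# Evaluate lifetime NMB for a parameter set at a fixed threshold.  rr_key
# marks parameters that enter as a direct RR override rather than through the
# Chinn chain.
.nmb_for <- function(params, lambda, rr_override = NULL) {
  res <- run_cea(params, rr_override = rr_override)
  nmb(lambda, res$delta_qalys, res$delta_cost)
}

#' Default one-way sensitivity ranges
#'
#' The published low/high range for every input that has one.
#'
#' @param params An `amt_parameters` object.
#' @return Named list of length-2 numeric vectors.
#' @export
default_dsa_ranges <- function(params = load_parameters()) {
  list(
    hb_sd_reduction = params$clinical$hb_sd_reduction_ci,
    hr_mortality_per_sd = params$clinical$hr_mortality_per_sd_ci,
    rr_hosp = params$clinical$rr_hosp_ci,
    utility_hd = params$economic$utility_hd_ci,
    hospitalization_cost = params$economic$hospitalization_cost_range,
    discount_rate = params$economic$discount_rate_range,
    medicare_share_under65 = params$epidemiology$medicare_share_under65_range
  )
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Recomputes lifetime NMB with each parameter set to its low and then high
#' value, all others held at base case, at a threshold fixed at its base-case
#' value.  `rr_hosp` is applied as a direct RR override (it is itself the
#' output of the effect chain); every other parameter re-runs the full
#' pipeline.
#'
#' @param params Base `amt_parameters`.
#' @param ranges Named list of `c(low, high)`; defaults to
#'   [default_dsa_ranges()].
#' @return A data.frame of class `amt_tornado`, one row per parameter, with
#'   columns `parameter`, `low`, `high`, `nmb_at_low`, `nmb_at_high`,
#'   `spread`, sorted by decreasing spread; base-case NMB and threshold in
#'   attributes `nmb_base` and `wtp`.
#' @export
one_way_dsa <- function(params, ranges = default_dsa_ranges(params)) {
  stopifnot(inherits(params, "amt_parameters"))
  base <- run_cea(params)
  lambda <- base$wtp
  reg <- .param_registry()
  rows <- lapply(names(ranges), function(key) {
    rg <- ranges[[key]]
    if (length(rg) != 2L || rg[1] > rg[2]) {
      stop(sprintf("input error: range for '%s' must be c(low, high)", key),
           call. = FALSE)
    }
    val_at <- function(v) {
      if (key == "rr_hosp") {
        .nmb_for(params, lambda, rr_override = v)
      } else {
        if (!key %in% names(reg)) {
          stop(sprintf("input error: unknown parameter '%s'", key), call. = FALSE)
        }
        p <- params
        p[[reg[[key]][1]]][[key]] <- v
        validate_parameters(p)
        .nmb_for(p, lambda)
      }
    }
    lo <- val_at(rg[1]); hi <- val_at(rg[2])
    data.frame(parameter = key, low = rg[1], high = rg[2],
               nmb_at_low = lo, nmb_at_high = hi, spread = abs(hi - lo),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$spread), ]
  rownames(out) <- NULL
  attr(out, "nmb_base") <- nmb(lambda, base$delta_qalys, base$delta_cost)
  attr(out, "wtp") <- lambda
  class(out) <- c("amt_tornado", "data.frame")
  out
}

# Run fn with a locally seeded RNG, restoring the caller's stream.
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Probabilistic sensitivity analysis
#'
#' Seeded Monte Carlo: `n` independent parameter-set draws from `specs`, a
#' full pipeline evaluation (effects -> Markov -> economics) per draw, and a
#' summary of the NMB distribution at a threshold fixed at its base-case
#' value.  The sampled hospitalization RR enters as a direct override of the
#' effect chain, matching its published distribution.
#'
#' @param params Base `amt_parameters`.
#' @param specs Named list of `amt_dist`; defaults to [default_psa_specs()].
#' @param n Number of iterations (default 1000).
#' @param seed RNG seed (default 20260103); recorded in the output.
#' @return An object of class `amt_psa`: `summary` (list with `n`, `seed`,
#'   `wtp`, `mean_nmb`, `ci_lower`, `ci_upper` (2.5/97.5 percentiles),
#'   `prop_nmb_nonneg`) and `draws` (data.frame with the sampled values and
#'   per-draw `delta_cost`, `delta_qalys`, `nmb`).
#' @export
run_psa <- function(params = load_parameters(),
                    specs = default_psa_specs(params),
                    n = 1000, seed = 20260103) {
  stopifnot(n >= 1)
  base <- run_cea(params)
  lambda <- base$wtp
  sampled <- .with_seed(seed, function() sample_parameter_set(params, specs, n = n))
  rows <- lapply(sampled, function(s) {
    rr <- if ("rr_hosp" %in% names(s$draws)) s$draws[["rr_hosp"]] else NULL
    res <- run_cea(s$params, rr_override = rr)
    c(s$draws, delta_cost = res$delta_cost, delta_qalys = res$delta_qalys,
      nmb = nmb(lambda, res$delta_qalys, res$delta_cost))
  })
  draws <- as.data.frame(do.call(rbind, rows))
  qs <- stats::quantile(draws$nmb, c(0.025, 0.975), names = FALSE, type = 7)
  out <- list(
    summary = list(n = n, seed = seed, wtp = lambda,
                   mean_nmb = mean(draws$nmb),
                   ci_lower = qs[1], ci_upper = qs[2],
                   prop_nmb_nonneg = mean(draws$nmb >= 0)),
    draws = draws
  )
  class(out) <- "amt_psa"
  out
}

#' @export
print.amt_psa <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<amt_psa>  n = %d (seed %d), WTP $%s/QALY\n", s$n, s$seed,
              format(round(s$wtp), big.mark = ",")))
  cat(sprintf("  mean NMB $%s; 95%% interval $%s to $%s; P(NMB >= 0) = %.3f\n",
              format(round(s$mean_nmb), big.mark = ","),
              format(round(s$ci_lower), big.mark = ","),
              format(round(s$ci_upper), big.mark = ","), s$prop_nmb_nonneg))
  invisible(x)
}
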