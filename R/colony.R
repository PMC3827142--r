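# Synthetic colony observations: yearly chick wing length driven by a
# covariate through a linear model with AR(2) errors, plus diet fractions
# coupled to an inflow index and a trending population size. This is the
# statistical twin of the real colony series the linkage stage assumes.

#' Parameters of the synthetic colony generator
#'
#' Wing length follows `intercept + trend*t + beta*covariate[t] + e[t]`
#' with `e` a stationary AR(2) process (`phi1`, `phi2`, innovation SD).
#'
#' @param n_years number of years
#' @param intercept mean wing length, mm
#' @param trend linear trend, mm per year
#' @param beta effect of the (standardised) covariate, mm per unit
#' @param phi1,phi2 AR coefficients; the AR polynomial must be stationary
#' @param innovation_sd innovation standard deviation, mm
#' @param diet_base baseline diet fractions (herring, capelin, sandeel,
#'   other), summing to <= 1
#' @param diet_gamma inflow sensitivity of log diet weights; positive for
#'   herring, negative for capelin by default (warm, high-inflow years
#'   bring herring into the diet and push capelin away)
#' @param diet_conc Dirichlet concentration (larger = less noisy diet)
#' @param mass_per_mm body mass per mm wing length, g/mm
#' @param mass_sd residual SD of body mass, g
#' @param pop_start,pop_growth population size intercept and per-year
#'   increment (breeding pairs)
#' @param seed RNG seed
#' @return a `colony_sim_params` list
#' @export
colony_sim_params <- function(n_years = 16L, intercept = 60, trend = 0.3,
                              beta = 3, phi1 = 0.3, phi2 = -0.2,
                              innovation_sd = 1.5,
                              diet_base = c(herring = 0.25, capelin = 0.35,
                                            sandeel = 0.10, other = 0.30),
                              diet_gamma = c(herring = 0.6, capelin = -0.6,
                                             sandeel = 0, other = 0),
                              diet_conc = 60,
                              mass_per_mm = 3.5, mass_sd = 5,
                              pop_start = 8000, pop_growth = 150,
                              seed = 1L) {
  roots <- polyroot(c(1, -phi1, -phi2))
  if (any(Mod(roots) <= 1)) {
    stop("AR(2) parameters are non-stationary (root inside the unit circle)")
  }
  structure(list(n_years = as.integer(n_years), intercept = intercept,
                 trend = trend, beta = beta, phi1 = phi1, phi2 = phi2,
                 innovation_sd = innovation_sd, diet_base = diet_base,
                 diet_gamma = diet_gamma, diet_conc = diet_conc,
                 mass_per_mm = mass_per_mm, mass_sd = mass_sd,
                 pop_start = pop_start, pop_growth = pop_growth,
                 seed = as.integer(seed)),
            class = "colony_sim_params")
}

# stationary AR(2) simulation with burn-in (all-zero when sd = 0)
sim_ar2 <- function(n, phi1, phi2, sd, burn = 200L) {
  if (sd == 0) return(numeric(n))
  ntot <- n + burn
  e <- stats::rnorm(ntot, 0, sd)
  x <- numeric(ntot)
  for (t in seq_len(ntot)) {
    x[t] <- e[t] +
      (if (t > 1) phi1 * x[t - 1] else 0) +
      (if (t > 2) phi2 * x[t - 2] else 0)
  }
  x[(burn + 1):ntot]
}

#' Generate a synthetic colony observation series
#'
#' @param params a [colony_sim_params()]
#' @param covariate yearly covariate driving wing length (length
#'   `n_years`); e.g. southern larval density
#' @param inflow optional yearly inflow index steering diet fractions
#'   (defaults to the covariate)
#' @param start_year first calendar year
#' @return data.frame: year, wing_length, body_mass, diet_herring,
#'   diet_capelin, diet_sandeel, diet_other, population_size
#' @export
generate_colony_series <- function(params, covariate,
                                   inflow = covariate,
                                   start_year = 1996L) {
  stopifnot(inherits(params, "colony_sim_params"))
  n <- params$n_years
  if (length(covariate) != n) {
    stop("covariate length must equal n_years")
  }
  set.seed(params$seed)
  tt <- seq_len(n)
  e <- sim_ar2(n, params$phi1, params$phi2, params$innovation_sd)
  wing <- params$intercept + params$trend * tt + params$beta * covariate + e
  mass <- params$mass_per_mm * wing + stats::rnorm(n, 0, params$mass_sd)

  zin <- if (n > 1 && isTRUE(stats::sd(inflow) > 0)) {
    as.numeric(scale(inflow))
  } else {
    rep(0, n)
  }
  diet <- matrix(NA_real_, n, length(params$diet_base))
  colnames(diet) <- names(params$diet_base)
  for (t in tt) {
    w <- params$diet_base * exp(params$diet_gamma * zin[t])
    w <- w / sum(w)
    g <- stats::rgamma(length(w), shape = params$diet_conc * w, rate = 1)
    diet[t, ] <- g / sum(g)
  }
  pop <- params$pop_start + params$pop_growth * tt +
    round(stats::rnorm(n, 0, params$pop_growth / 4))
  out <- data.frame(year = start_year + tt - 1L, wing_length = wing,
                    body_mass = mass)
  for (nm in colnames(diet)) out[[paste0("diet_", nm)]] <- diet[, nm]
  out$population_size <- pop
  out
}
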