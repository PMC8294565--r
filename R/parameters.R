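#' Dimensional model parameters
#'
#' Bundles the biological and physical constants of the gall wasp /
#' parasitoid system.  Defaults are the Portugal parameter set used
#' throughout the package: fecundities from orchard observations
#' (`N_d = 150`, `N_t = 71`), a 40-day egg-deposition season with a 4-day
#' adult lifespan for the gall wasp, parasitoid overwintering survival
#' `gamma = 0.47` (sexual reproduction caps it below 0.5), bud capacity
#' `M = 5` eggs per bud at `beta_max = 2e6` buds/ha, and diffusivities
#' `D_d = 0.889`, `D_t = 0.016` km^2/day.
#'
#' The gall wasp overwintering survival `eta` is the most uncertain
#' parameter and must be chosen by the user; 0.65, 0.75 and 0.85 are the
#' values explored in the reference simulations, but any value in (0, 1]
#' is accepted.
#'
#' @param eta gall wasp overwintering survival rate, in (0, 1]: fraction of
#'   eggs laid one season that emerge as adults the next.
#' @param N_d maximum eggs laid per gall wasp female (count).
#' @param N_t maximum eggs laid per parasitoid female (count).
#' @param T_d gall wasp egg-deposition season length (days).
#' @param T_t parasitoid adult lifespan / season length (days).  When `NULL`
#'   (default) the two species' seasons are assumed equal, which simplifies
#'   the nondimensional season-length ratio to `tau = 1/eta`.
#' @param a gall wasp adult lifespan (days), must be `< T_d`.
#' @param gamma parasitoid overwintering survival rate, in (0, 0.5).
#' @param M maximum eggs per chestnut bud (count).
#' @param beta_max bud density (buds per hectare).
#' @param D_d gall wasp diffusion coefficient (km^2/day).
#' @param D_t parasitoid diffusion coefficient (km^2/day).
#'
#' @return An object of class `dimensional_parameters` (a named list).
#' @seealso [nondimensionalize()], [egg_capacity_and_threshold()]
#' @examples
#' dp <- dimensional_parameters(eta = 0.65)
#' nondimensionalize(dp)
#' @export
dimensional_parameters <- function(eta, N_d = 150, N_t = 71, T_d = 40,
                                   T_t = NULL, a = 4, gamma = 0.47,
                                   M = 5, beta_max = 2e6,
                                   D_d = 0.889, D_t = 0.016) {
  stop_if <- function(bad, msg) if (isTRUE(bad)) stop(msg, call. = FALSE)
  num1 <- function(x, nm) {
    stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
            sprintf("invalid parameter: %s must be a finite number", nm))
  }
  for (nm in c("eta", "N_d", "N_t", "T_d", "a", "gamma", "M", "beta_max",
               "D_d", "D_t"))
    num1(get(nm), nm)
  if (!is.null(T_t)) num1(T_t, "T_t")

  stop_if(eta <= 0 || eta > 1,
          "invalid parameter: eta must satisfy 0 < eta <= 1")
  stop_if(gamma <= 0 || gamma >= 0.5,
          "invalid parameter: gamma must satisfy 0 < gamma < 0.5 (sexual reproduction bound)")
  stop_if(a >= T_d, "invalid parameter: adult lifespan a must be < season length T_d")
  for (nm in c("N_d", "N_t", "T_d", "a", "M", "beta_max", "D_d", "D_t"))
    stop_if(get(nm) <= 0, sprintf("invalid parameter: %s must be > 0", nm))
  if (!is.null(T_t)) stop_if(T_t <= 0, "invalid parameter: T_t must be > 0")

  structure(list(eta = eta, N_d = N_d, N_t = N_t, T_d = T_d, T_t = T_t,
                 a = a, gamma = gamma, M = M, beta_max = beta_max,
                 D_d = D_d, D_t = D_t),
            class = "dimensional_parameters")
}

#' @export
print.dimensional_parameters <- function(x, ...) {
  cat("Dimensional host-parasitoid parameters\n")
  cat(sprintf("  gall wasp:  N_d = %g eggs, T_d = %g d, a = %g d, eta = %g, D_d = %g km^2/d\n",
              x$N_d, x$T_d, x$a, x$eta, x$D_d))
  cat(sprintf("  parasitoid: N_t = %g eggs, %s gamma = %g, D_t = %g km^2/d\n",
              x$N_t,
              if (is.null(x$T_t)) "T_t = T_d (equal seasons),"
              else sprintf("T_t = %g d,", x$T_t),
              x$gamma, x$D_t))
  cat(sprintf("  habitat:    M = %g eggs/bud, beta_max = %g buds/ha\n",
              x$M, x$beta_max))
  invisible(x)
}

#' Derive the nondimensional model constants
#'
#' Converts dimensional constants to the dimensionless groups that govern
#' the season map: `mu = T_d/a` (season length over adult lifespan),
#' `E_d = eta * N_d` and `E_t = gamma * N_t` (effective fecundities),
#' `tau = T_t/(eta * T_d)` (parasitoid season in units of the wasp season,
#' simplified to `1/eta` when the seasons are equal), and the diffusivity
#' ratio `delta = D_t/D_d`.  The nondimensional unit of length is
#' `sqrt(D_d * T_d)` km; the parasitoid phase spans `eta * tau`
#' nondimensional time units (exactly 1 under the equal-season
#' simplification) and the wasp phase spans 1.
#'
#' @param dim a [dimensional_parameters()] object.
#' @return An object of class `nondim_parameters`.
#' @examples
#' nondimensionalize(dimensional_parameters(eta = 0.85))
#' @export
nondimensionalize <- function(dim) {
  if (!inherits(dim, "dimensional_parameters"))
    stop("nondimensionalize() expects a 'dimensional_parameters' object",
         call. = FALSE)
  tau <- if (is.null(dim$T_t)) 1 / dim$eta else dim$T_t / (dim$eta * dim$T_d)
  nondim_parameters(mu = dim$T_d / dim$a,
                    tau = tau,
                    E_d = dim$eta * dim$N_d,
                    E_t = dim$gamma * dim$N_t,
                    delta = dim$D_t / dim$D_d,
                    eta = dim$eta,
                    length_unit_km = sqrt(dim$D_d * dim$T_d))
}

#' Construct nondimensional parameters directly
#'
#' Low-level constructor used by [nondimensionalize()]; also handy for
#' analytic limit cases (e.g. `E_d = 0`) in tests and examples.
#'
#' @param mu ratio of the wasp season length to adult lifespan.
#' @param tau parasitoid season length in units of the wasp season, divided
#'   by `eta`.
#' @param E_d,E_t effective fecundities (`eta*N_d`, `gamma*N_t`); `E_d >= 0`,
#'   `E_t >= 0`.
#' @param delta parasitoid/wasp diffusivity ratio.
#' @param eta gall wasp overwintering survival (sets the parasitoid phase
#'   length `eta*tau`).
#' @param length_unit_km physical size of one nondimensional length unit.
#' @return An object of class `nondim_parameters`.
#' @export
nondim_parameters <- function(mu, tau, E_d, E_t, delta = NA_real_, eta = 1,
                              length_unit_km = NA_real_) {
  for (nm in c("mu", "tau", "eta"))
    if (!is.numeric(get(nm)) || length(get(nm)) != 1L || get(nm) <= 0)
      stop(sprintf("invalid parameter: %s must be a positive number", nm),
           call. = FALSE)
  if (E_d < 0 || E_t < 0)
    stop("invalid parameter: E_d and E_t must be >= 0", call. = FALSE)
  if (!is.na(delta) && delta <= 0)
    stop("invalid parameter: delta must be > 0", call. = FALSE)
  structure(list(mu = mu, tau = tau, E_d = E_d, E_t = E_t, delta = delta,
                 eta = eta,
                 parasitoid_phase_length = eta * tau,
                 wasp_phase_length = 1,
                 length_unit_km = length_unit_km),
            class = "nondim_parameters")
}

#' @export
print.nondim_parameters <- function(x, ...) {
  cat("Nondimensional host-parasitoid parameters\n")
  cat(sprintf("  mu = %g, tau = %g, E_d = %g, E_t = %g, delta = %s\n",
              x$mu, x$tau, x$E_d, x$E_t,
              if (is.na(x$delta)) "NA" else format(x$delta)))
  cat(sprintf("  phase lengths: parasitoid %g, wasp %g; length unit %s km\n",
              x$parasitoid_phase_length, x$wasp_phase_length,
              if (is.na(x$length_unit_km)) "NA" else format(x$length_unit_km)))
  invisible(x)
}

#' Habitat egg capacity and extinction threshold
#'
#' The habitat's maximum egg density is `V_max = M * beta_max` eggs/ha.
#' One insect per hectare then corresponds to the nondimensional density
#' `1/V_max`; densities below it are interpreted as local extinction.  For a
#' monitored woodland of `area_ha` hectares the threshold scales down to
#' `1/(V_max * area_ha)`.
#'
#' @param M maximum eggs per bud (count, > 0).
#' @param beta_max bud density (buds per hectare, > 0).
#' @param area_ha monitored area in hectares (> 0), default 1.
#' @return An object of class `threshold_spec` with fields `V_max`,
#'   `survival_threshold`, `area_ha` and `effective_threshold`.
#' @examples
#' egg_capacity_and_threshold(M = 5, beta_max = 2e6)  # V_max = 1e7, thr 1e-7
#' @export
egg_capacity_and_threshold <- function(M, beta_max, area_ha = 1) {
  for (nm in c("M", "beta_max", "area_ha")) {
    x <- get(nm)
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("invalid parameter: %s must be a positive number", nm),
           call. = FALSE)
  }
  V_max <- M * beta_max
  structure(list(V_max = V_max,
                 survival_threshold = 1 / V_max,
                 area_ha = area_ha,
                 effective_threshold = 1 / (V_max * area_ha)),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("Egg capacity V_max = %g eggs/ha; survival threshold %g",
              x$V_max, x$survival_threshold))
  cat(sprintf(" (effective %g over %g ha)\n", x$effective_threshold, x$area_ha))
  invisible(x)
}
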