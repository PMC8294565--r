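# Within-season dynamics of the homogeneous model.
#
# Each year n is integrated in two sequential phases in nondimensional time:
#   1. parasitoid flight on [0, eta*tau]:
#        p' = -(1/tau) (v_prev - q) p
#        q' =  (E_t/tau) (v_prev - q) p,   p(0) = q_{n-1}(end), q(0) = 0
#      where v_prev = v_{n-1}(1) is last season's gall wasp egg density.
#   2. gall wasp flight on [0, 1] with constant emergence
#      c = max(0, v_prev - q_n(end)) (parasitized larvae never emerge):
#        u' = -mu (2 - v) u + c
#        v' =  E_d mu (1 - v) u,          u(0) = v(0) = 0.
#
# The parasitoid phase carries the complementary variable r = v_prev - q
# (the unparasitized remainder) as an extra state alongside p and q.  When
# parasitism is nearly complete q saturates at v_prev to within roundoff
# and the emergence flux could not be recovered by subtraction; when
# parasitoids are scarce it is q that sits dozens of decades below v_prev.
# Integrating both lets each tail be tracked in relative error, which is
# what keeps the multi-decade post-crash densities (down to ~1e-50)
# meaningful.

.rhs_parasitoid_h <- function(t, y, pr) {
  w <- y[[3L]] * y[[1L]] / pr$tau  # r * p / tau
  list(c(-w, pr$E_t * w, -pr$E_t * w))
}

.rhs_wasp_h <- function(t, y, pr) {
  list(c(-pr$mu * (2 - y[[2L]]) * y[[1L]] + pr$c,
         pr$E_d * pr$mu * (1 - y[[2L]]) * y[[1L]]))
}

.integrate_phase <- function(y0, t_end, rhs, pr, rtol, atol, trajectory) {
  times <- if (trajectory) seq(0, t_end, length.out = 201L) else c(0, t_end)
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = pr,
                      method = "lsoda", rtol = rtol, atol = atol,
                      maxsteps = 20000)
  if (attr(out, "istate")[1L] < 0)
    stop("ODE solver failed (step-size underflow?) during a season phase",
         call. = FALSE)
  out
}

#' Integrate the parasitoid phase of one season
#'
#' Solves the egg-laying dynamics of adult parasitoid females over the
#' spring flight window `[0, eta*tau]` (nondimensional time).  The density
#' of host larvae available for oviposition is `v_prev - q`, so `q`
#' saturates at `v_prev` and the identity `q + E_t * p = const` holds
#' exactly along trajectories.
#'
#' @param p0 initial adult female density `p_n(0) = q_{n-1}(end)` (>= 0).
#' @param v_prev previous season's end-of-season gall wasp egg density
#'   (>= 0).
#' @param params a [nondim_parameters()] object.
#' @param rtol,atol relative/absolute solver tolerances.  The default
#'   absolute tolerance is extremely small because the post-crash densities
#'   of interest reach `1e-50`; the phase dynamics are linear in amplitude,
#'   so this costs little.
#' @param trajectory if `TRUE`, also return the dense `(t, p, q)` trajectory.
#' @return A list with `p_end`, `q_end`, `emergence` (the unparasitized
#'   remainder `v_prev - q_end`, carried at full relative precision) and
#'   (optionally) `trajectory`, a data frame with columns `t`, `p`, `q`.
#' @export
parasitoid_phase <- function(p0, v_prev, params, rtol = 1e-8, atol = 1e-60,
                             trajectory = FALSE) {
  if (p0 < 0 || v_prev < 0)
    stop("p0 and v_prev must be nonnegative", call. = FALSE)
  pr <- list(tau = params$tau, E_t = params$E_t)
  out <- .integrate_phase(c(p = p0, q = 0, r = v_prev),
                          params$parasitoid_phase_length,
                          .rhs_parasitoid_h, pr, rtol, atol, trajectory)
  n <- nrow(out)
  res <- list(p_end = max(0, out[n, "p"]),
              q_end = min(max(0, out[n, "q"]), v_prev),
              emergence = min(max(0, out[n, "r"]), v_prev))
  if (trajectory)
    res$trajectory <- data.frame(t = out[, "time"], p = out[, "p"],
                                 q = out[, "q"])
  res
}

#' Integrate the gall wasp phase of one season
#'
#' Solves the summer flight of adult gall wasps with a constant emergence
#' flux `max(0, v_prev - q_end)` — last year's eggs minus those parasitized.
#' Adults leave the egg-carrying pool both by death (rate `mu`) and by
#' exhausting their egg load, which near-empty habitats makes the loss rate
#' `mu * (2 - v)`; eggs accumulate at rate `E_d * mu * (1 - v) * u` and `v`
#' therefore saturates below 1.
#'
#' @param v_prev previous season's gall wasp egg density.
#' @param q_end parasitoid egg density laid this spring (`<= v_prev` up to
#'   solver tolerance; tiny overshoot is clipped).
#' @param params a [nondim_parameters()] object.
#' @param emergence optional precomputed emergence flux; when the caller
#'   has the unparasitized remainder from [parasitoid_phase()] it should be
#'   passed here, since recomputing `v_prev - q_end` by subtraction loses
#'   the flux to roundoff once parasitism is nearly complete.
#' @inheritParams parasitoid_phase
#' @return A list with `u_end`, `v_end` and optionally `trajectory`
#'   (columns `t`, `u`, `v`).
#' @export
wasp_phase <- function(v_prev, q_end, params, rtol = 1e-8, atol = 1e-60,
                       trajectory = FALSE, emergence = NULL) {
  if (v_prev < 0 || q_end < 0)
    stop("v_prev and q_end must be nonnegative", call. = FALSE)
  if (q_end > v_prev * (1 + 1e-6) + 1e-12)
    stop("q_end exceeds v_prev: more eggs parasitized than laid", call. = FALSE)
  pr <- list(mu = params$mu, E_d = params$E_d,
             c = if (is.null(emergence)) max(0, v_prev - q_end)
                 else max(0, emergence))
  out <- .integrate_phase(c(u = 0, v = 0), params$wasp_phase_length,
                          .rhs_wasp_h, pr, rtol, atol, trajectory)
  n <- nrow(out)
  res <- list(u_end = max(0, out[n, "u"]),
              v_end = min(max(0, out[n, "v"]), 1))
  if (trajectory)
    res$trajectory <- data.frame(t = out[, "time"], u = out[, "u"],
                                 v = out[, "v"])
  res
}

#' Run the homogeneous season map over multiple years
#'
#' Iterates the two-phase season integration: year `n` starts the
#' parasitoid phase from `p_n(0) = q_{n-1}(end)` against last season's egg
#' field `v_{n-1}(1)`, then runs the gall wasp phase with emergence
#' `v_{n-1}(1) - q_n(end)`.  End-of-season densities are recorded per year.
#'
#' @param v0 gall wasp egg density at the end of "year 0" (default 1: fully
#'   infested habitat).
#' @param q0 parasitoid egg density seeding year 1 (default `1e-9`,
#'   a release of a few individuals per km^2).
#' @param params a [nondim_parameters()] object.
#' @param n_years number of seasons to simulate (>= 1).
#' @param threshold optional [egg_capacity_and_threshold()] object used for
#'   extinction clamping.
#' @param clamp if `TRUE` (and `threshold` given), densities below the
#'   effective threshold are set to zero at season end and flagged.
#'   Default `FALSE`: reference runs report unclamped densities and leave
#'   threshold crossings to the diagnostics.
#' @param rtol,atol solver tolerances, see [parasitoid_phase()].
#' @return A `season_series` data frame with columns `year`, `v_end`,
#'   `q_end`, `p_end`, `u_end`, `clamped`, and the parameters attached as
#'   attribute `params`.
#' @examples
#' np <- nondimensionalize(dimensional_parameters(eta = 0.85))
#' ss <- run_multi_year(params = np, n_years = 30)
#' head(ss, 3)
#' @export
run_multi_year <- function(v0 = 1, q0 = 1e-9, params, n_years,
                           threshold = NULL, clamp = FALSE,
                           rtol = 1e-8, atol = 1e-60) {
  if (n_years < 1) stop("n_years must be >= 1", call. = FALSE)
  if (clamp && is.null(threshold))
    stop("clamping requires a threshold spec", call. = FALSE)
  v_prev <- v0
  q_prev <- q0
  res <- matrix(NA_real_, nrow = n_years, ncol = 4L,
                dimnames = list(NULL, c("v_end", "q_end", "p_end", "u_end")))
  clamped <- logical(n_years)
  for (n in seq_len(n_years)) {
    ph <- tryCatch({
      pa <- parasitoid_phase(q_prev, v_prev, params, rtol, atol)
      wa <- wasp_phase(v_prev, pa$q_end, params, rtol, atol,
                       emergence = pa$emergence)
      c(pa, wa)
    }, error = function(e) {
      stop(sprintf("season %d: %s", n, conditionMessage(e)), call. = FALSE)
    })
    v_n <- ph$v_end
    q_n <- ph$q_end
    if (clamp) {
      thr <- threshold$effective_threshold
      if (v_n < thr || q_n < thr) {
        clamped[n] <- TRUE
        if (v_n < thr) v_n <- 0
        if (q_n < thr) q_n <- 0
      }
    }
    res[n, ] <- c(v_n, q_n, ph$p_end, ph$u_end)
    v_prev <- v_n
    q_prev <- q_n
  }
  out <- data.frame(year = seq_len(n_years), res, clamped = clamped)
  attr(out, "params") <- params
  class(out) <- c("season_series", "data.frame")
  out
}
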