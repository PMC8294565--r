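# Spatially extended model: method-of-lines semi-discretization of the
# reaction-diffusion season model on a regular cell-centered grid with
# zero-flux (Neumann) boundaries.  Only the adult stages disperse: the
# parasitoid equation carries delta * Laplacian(p), the gall wasp equation
# Laplacian(u); the egg fields q and v are immobile.

#' Construct a regular simulation grid
#'
#' Cell-centered rectangular grid in nondimensional length units (one unit
#' is `sqrt(D_d * T_d)` km, about 6 km with the default Portugal
#' parameters).  Node `(i, j)` sits at `((i - 1/2) h, (j - 1/2) h)`.
#'
#' @param Lx,Ly domain side lengths (nondimensional units).
#' @param h grid spacing; must be `<= 0.1` so the front structure of the
#'   parasitoid wave stays resolved.
#' @return An object of class `spatial_grid` with fields `Lx`, `Ly`, `h`,
#'   `nx`, `ny`, `x`, `y`.
#' @examples
#' spatial_grid(4, 4, h = 0.1)
#' @export
spatial_grid <- function(Lx = 4, Ly = 4, h = 0.05) {
  if (Lx <= 0 || Ly <= 0) stop("domain sides must be positive", call. = FALSE)
  if (h <= 0 || h > 0.1)
    stop("grid spacing h must be in (0, 0.1]", call. = FALSE)
  nx <- max(2L, as.integer(round(Lx / h)))
  ny <- max(2L, as.integer(round(Ly / h)))
  if (abs(nx * h - Lx) > h + 1e-9 || abs(ny * h - Ly) > h + 1e-9)
    stop("h must divide the domain sides to within one cell", call. = FALSE)
  structure(list(Lx = Lx, Ly = Ly, h = h, nx = nx, ny = ny,
                 x = (seq_len(nx) - 0.5) * h,
                 y = (seq_len(ny) - 0.5) * h),
            class = "spatial_grid")
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf("Cell-centered grid %g x %g (nondim units), h = %g (%d x %d cells)\n",
              x$Lx, x$Ly, x$h, x$nx, x$ny))
  invisible(x)
}

#' Five-point discrete Laplacian with zero-flux boundaries
#'
#' Second-order 5-point stencil; missing neighbours at the boundary are
#' supplied by ghost-cell reflection, which enforces zero normal flux and
#' makes the operator conservative (its sum over the domain vanishes for
#' any field).
#'
#' @param field numeric matrix of shape `nx` by `ny`.
#' @param grid a [spatial_grid()].
#' @return Matrix of the same shape.
#' @export
discrete_laplacian <- function(field, grid) {
  if (!is.matrix(field) || nrow(field) != grid$nx || ncol(field) != grid$ny)
    stop(sprintf("field shape (%s) does not match grid (%d x %d)",
                 paste(dim(field), collapse = " x "), grid$nx, grid$ny),
         call. = FALSE)
  .Call(C_laplacian, field, as.numeric(grid$h))
}

.stage_spatial <- function(grid, params) {
  .Call(C_set_spatial_params, as.integer(grid$nx), as.integer(grid$ny),
        as.numeric(grid$h), as.numeric(params$delta), as.numeric(params$tau),
        as.numeric(params$E_t), as.numeric(params$E_d), as.numeric(params$mu))
  invisible(NULL)
}

.ode2d <- function(y0, t_end, func, grid, rtol, atol) {
  neq <- length(y0)
  out <- deSolve::ode.2D(y = y0, times = c(0, t_end), func = func,
                         parms = NULL, dllname = "torysim",
                         nspec = 2L, dimens = c(grid$nx, grid$ny),
                         method = "lsodes", rtol = rtol, atol = atol,
                         maxsteps = 50000, lrw = 130 * neq + 1000)
  if (attr(out, "istate")[1L] < 0)
    stop("spatial ODE solver failed", call. = FALSE)
  out[nrow(out), -1L]
}

#' Integrate the parasitoid phase on the grid
#'
#' Solves `p_t = delta * Lap(p) - (1/tau)(v_prev - q) p`,
#' `q_t = (E_t/tau)(v_prev - q) p` over the parasitoid flight window with
#' zero-flux boundaries.
#'
#' @param p0 initial adult parasitoid field (matrix `nx` by `ny`).
#' @param v_prev previous season's gall wasp egg field (same shape).
#' @param params a [nondim_parameters()] with a valid `delta`.
#' @param grid a [spatial_grid()].
#' @param q0 initial parasitoid egg field (defaults to zero, the
#'   start-of-season condition).
#' @param rtol,atol solver tolerances.  Spatial minima of interest are
#'   around `1e-6`, so the absolute tolerance is far looser than in the
#'   homogeneous engine.
#' @return List of matrices `p` and `q` at the end of the phase.
#' @export
spatial_parasitoid_phase <- function(p0, v_prev, params, grid, q0 = NULL,
                                     rtol = 1e-6, atol = 1e-12) {
  for (f in list(p0, v_prev))
    if (!is.matrix(f) || any(dim(f) != c(grid$nx, grid$ny)))
      stop("field shape does not match grid", call. = FALSE)
  if (is.null(q0)) q0 <- matrix(0, grid$nx, grid$ny)
  .stage_spatial(grid, params)
  .Call(C_set_vprev, as.numeric(v_prev))
  yT <- .ode2d(c(p0, q0), params$parasitoid_phase_length,
               "rhs_parasitoid_2d", grid, rtol, atol)
  n <- grid$nx * grid$ny
  p <- matrix(yT[seq_len(n)], grid$nx, grid$ny)
  q <- matrix(yT[n + seq_len(n)], grid$nx, grid$ny)
  list(p = pmax(p, 0), q = pmin(pmax(q, 0), pmax(v_prev, 0)))
}

#' Integrate the gall wasp phase on the grid
#'
#' Solves `u_t = Lap(u) - mu (2 - v) u + c(x, y)`,
#' `v_t = E_d mu (1 - v) u` over the summer flight window, where
#' `c = max(0, v_prev - q)` is the emergence field left after parasitism.
#'
#' @param emergence emergence flux field (matrix, >= 0).
#' @param params,grid,rtol,atol as in [spatial_parasitoid_phase()].
#' @param u0,v0 initial fields (default zero, the start-of-season
#'   condition; overridable for numerical experiments).
#' @return List of matrices `u` and `v` at the end of the phase.
#' @export
spatial_wasp_phase <- function(emergence, params, grid, u0 = NULL, v0 = NULL,
                               rtol = 1e-6, atol = 1e-12) {
  if (!is.matrix(emergence) || any(dim(emergence) != c(grid$nx, grid$ny)))
    stop("field shape does not match grid", call. = FALSE)
  if (is.null(u0)) u0 <- matrix(0, grid$nx, grid$ny)
  if (is.null(v0)) v0 <- matrix(0, grid$nx, grid$ny)
  .stage_spatial(grid, params)
  .Call(C_set_emergence, as.numeric(emergence))
  yT <- .ode2d(c(u0, v0), params$wasp_phase_length, "rhs_wasp_2d",
               grid, rtol, atol)
  n <- grid$nx * grid$ny
  u <- matrix(yT[seq_len(n)], grid$nx, grid$ny)
  v <- matrix(yT[n + seq_len(n)], grid$nx, grid$ny)
  list(u = pmax(u, 0), v = pmin(pmax(v, 0), 1))
}

.nearest_node <- function(grid, pt) {
  if (pt[1] < 0 || pt[1] > grid$Lx || pt[2] < 0 || pt[2] > grid$Ly)
    stop(sprintf("point (%g, %g) lies outside the domain", pt[1], pt[2]),
         call. = FALSE)
  c(which.min(abs(grid$x - pt[1])), which.min(abs(grid$y - pt[2])))
}

.apply_releases <- function(p, grid, schedule, year) {
  if (is.null(schedule)) return(p)
  for (ev in schedule$events) {
    if (ev$year != year) next
    for (r in seq_len(nrow(ev$stations))) {
      st <- as.numeric(ev$stations[r, ])
      if (identical(ev$footprint, "cell")) {
        ij <- .nearest_node(grid, st)
        p[ij[1], ij[2]] <- min(1, p[ij[1], ij[2]] + ev$amplitude)
      } else {
        # disc footprint of fixed physical radius: grid-independent mass
        .nearest_node(grid, st)  # validates the station location
        d2 <- outer((grid$x - st[1])^2, (grid$y - st[2])^2, `+`)
        sel <- d2 <= ev$footprint^2
        if (!any(sel)) sel[.nearest_node(grid, st)[1],
                           .nearest_node(grid, st)[2]] <- TRUE
        p[sel] <- pmin(1, p[sel] + ev$amplitude)
      }
    }
  }
  p
}

#' Run the spatial season map over multiple years
#'
#' Per season: scheduled parasitoid releases are added to the adult field
#' `p` (amplitude on the nearest grid cell, clipped at 1), the parasitoid
#' phase is integrated, the emergence field `max(0, v_prev - q)` is formed,
#' and the gall wasp phase is integrated.  End-of-season fields seed the
#' next year exactly as in the homogeneous map.
#'
#' @param grid a [spatial_grid()].
#' @param init initial state from [uniform_infestation_init()] (or any list
#'   with matrices `v` and `q`).
#' @param schedule a [make_release_schedule()] object, or `NULL` for no
#'   releases.
#' @param params a [nondim_parameters()] with a valid `delta`.
#' @param n_years number of seasons (>= 1).
#' @param probes list of `(x, y)` coordinates whose nearest-node yearly
#'   series are extracted.
#' @param store_fields if `TRUE` (default) keep every end-of-season field;
#'   set `FALSE` to save memory on long runs.
#' @param rtol,atol solver tolerances.
#' @param verbose print per-season progress to stderr.
#' @return An object of class `spatial_series`: a list with `fields` (4
#'   arrays `p`, `q`, `u`, `v` of dim `nx, ny, n_years`, when stored),
#'   `probes` (one `season_series` data frame per probe), `grid`, `params`,
#'   `schedule`.
#' @examples
#' \donttest{
#' np <- nondimensionalize(dimensional_parameters(eta = 0.65))
#' g <- spatial_grid(1, 1, h = 0.1)
#' init <- uniform_infestation_init(g, q0 = 1e-9)
#' run_spatial_multi_year(g, init, NULL, np, n_years = 2,
#'                        probes = list(c(0.5, 0.5)))
#' }
#' @export
run_spatial_multi_year <- function(grid, init, schedule, params, n_years,
                                   probes = list(c(1, 1)),
                                   store_fields = TRUE,
                                   rtol = 1e-6, atol = 1e-12,
                                   verbose = FALSE) {
  if (n_years < 1) stop("n_years must be >= 1", call. = FALSE)
  if (is.na(params$delta))
    stop("spatial runs need a diffusivity ratio delta", call. = FALSE)
  v_prev <- init$v
  q_prev <- init$q
  for (f in list(v_prev, q_prev))
    if (!is.matrix(f) || any(dim(f) != c(grid$nx, grid$ny)))
      stop("initial field shape does not match grid", call. = FALSE)
  if (!is.null(schedule)) {
    for (ev in schedule$events)
      apply(ev$stations, 1L, function(s) .nearest_node(grid, as.numeric(s)))
  }
  pij <- lapply(probes, function(pt) .nearest_node(grid, as.numeric(pt)))

  dims <- c(grid$nx, grid$ny, n_years)
  fields <- if (store_fields)
    list(p = array(NA_real_, dims), q = array(NA_real_, dims),
         u = array(NA_real_, dims), v = array(NA_real_, dims))
  probe_mat <- lapply(probes, function(...)
    matrix(NA_real_, n_years, 4L,
           dimnames = list(NULL, c("v_end", "q_end", "p_end", "u_end"))))

  for (n in seq_len(n_years)) {
    p0 <- .apply_releases(q_prev, grid, schedule, n)
    st <- tryCatch({
      pa <- spatial_parasitoid_phase(p0, v_prev, params, grid,
                                     rtol = rtol, atol = atol)
      emer <- pmax(v_prev - pa$q, 0)
      wa <- spatial_wasp_phase(emer, params, grid, rtol = rtol, atol = atol)
      c(pa, wa)
    }, error = function(e) {
      stop(sprintf("season %d: %s", n, conditionMessage(e)), call. = FALSE)
    })
    if (store_fields) {
      fields$p[, , n] <- st$p; fields$q[, , n] <- st$q
      fields$u[, , n] <- st$u; fields$v[, , n] <- st$v
    }
    for (k in seq_along(pij)) {
      ij <- pij[[k]]
      probe_mat[[k]][n, ] <- c(st$v[ij[1], ij[2]], st$q[ij[1], ij[2]],
                               st$p[ij[1], ij[2]], st$u[ij[1], ij[2]])
    }
    if (verbose)
      message(sprintf("season %3d: max v = %.3g, max q = %.3g",
                      n, max(st$v), max(st$q)))
    v_prev <- st$v
    q_prev <- st$q
  }

  probe_series <- lapply(seq_along(probes), function(k) {
    out <- data.frame(year = seq_len(n_years), probe_mat[[k]],
                      clamped = FALSE)
    attr(out, "params") <- params
    attr(out, "probe") <- probes[[k]]
    class(out) <- c("season_series", "data.frame")
    out
  })
  structure(list(fields = fields, probes = probe_series, grid = grid,
                 params = params, schedule = schedule),
            class = "spatial_series")
}

#' @export
print.spatial_series <- function(x, ...) {
  ny <- if (!is.null(x$fields)) dim(x$fields$v)[3] else nrow(x$probes[[1]])
  cat(sprintf("Spatial season series: %d seasons on a %d x %d grid, %d probe(s)\n",
              ny, x$grid$nx, x$grid$ny, length(x$probes)))
  invisible(x)
}
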