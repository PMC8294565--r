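# Release scenarios: initial conditions and release schedules for the
# simulation experiments (uniform infestation, corner release, regular
# station grids, timed re-releases, periodic releases).

#' Regular lattice of release stations
#'
#' Places release stations at the `(k + 1)^2` vertices of a regular lattice
#' spanning the square `[0, L]^2`, so neighbouring stations are `L/k`
#' apart.  `k = 1` puts one station at each corner of the domain.
#'
#' @param k pattern order (>= 1); the station spacing is `L/k`.
#' @param L domain side length (nondimensional units).
#' @return Data frame with columns `x`, `y`, one row per station.
#' @examples
#' grid_release_layout(1, 4)  # the 4 corners
#' nrow(grid_release_layout(4, 4))  # 25 stations at unit spacing
#' @export
grid_release_layout <- function(k, L) {
  if (!is.numeric(k) || length(k) != 1L || k < 1 || k != round(k))
    stop("k must be an integer >= 1", call. = FALSE)
  if (L <= 0) stop("L must be > 0", call. = FALSE)
  v <- seq(0, L, length.out = k + 1)
  out <- expand.grid(x = v, y = v, KEEP.OUT.ATTRS = FALSE)
  attr(out, "spacing") <- L / k
  out
}

#' Build a parasitoid release schedule
#'
#' Three release strategies are supported: a single initial release
#' (`"initial-only"`, at the start of season 1), an initial release plus a
#' second one in season `n_r` (`"timed"`), and releases repeated every
#' `k_r` seasons up to the run horizon (`"periodic"`).  Every event
#' releases at all stations of `stations` with the same amplitude.
#'
#' @param mode one of `"initial-only"`, `"timed"`, `"periodic"`.
#' @param stations data frame of station coordinates (columns `x`, `y`),
#'   e.g. from [grid_release_layout()], or a single `c(x, y)` point.
#' @param n_r season of the second release (timed mode; must be > 1).
#' @param k_r release period in seasons (periodic mode; >= 1).
#' @param horizon run length in seasons (needed for periodic mode).
#' @param amplitude adult density set down at each station (default 1, the
#'   local carrying scale; the field is clipped at 1 on overlap).
#' @param footprint release footprint: `"cell"` (default) marks the single
#'   nearest grid cell per station, or a numeric radius (nondimensional
#'   units) marking every cell whose centre lies within that distance —
#'   useful when the released amount must be independent of grid
#'   resolution, e.g. in grid-convergence studies.
#' @return An object of class `release_schedule`: a list with an `events`
#'   list, each event holding `year`, `stations`, `amplitude`, `footprint`.
#' @examples
#' sched <- make_release_schedule("timed", grid_release_layout(4, 4), n_r = 8)
#' vapply(sched$events, `[[`, 1, "year")  # 1 8
#' @export
make_release_schedule <- function(mode = c("initial-only", "timed", "periodic"),
                                  stations, n_r = NULL, k_r = NULL,
                                  horizon = NULL, amplitude = 1,
                                  footprint = "cell") {
  mode <- match.arg(mode)
  if (is.numeric(stations) && is.null(dim(stations)))
    stations <- data.frame(x = stations[1], y = stations[2])
  stations <- as.data.frame(stations)[c("x", "y")]
  if (nrow(stations) < 1) stop("at least one station required", call. = FALSE)
  if (any(stations < 0)) stop("stations must have nonnegative coordinates",
                              call. = FALSE)
  if (amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  if (!identical(footprint, "cell") &&
      (!is.numeric(footprint) || footprint <= 0))
    stop("footprint must be \"cell\" or a positive radius", call. = FALSE)

  years <- switch(mode,
    "initial-only" = 1L,
    "timed" = {
      if (is.null(n_r) || n_r <= 1 || n_r != round(n_r))
        stop("timed mode needs an integer n_r > 1", call. = FALSE)
      c(1L, as.integer(n_r))
    },
    "periodic" = {
      if (is.null(k_r) || k_r < 1 || k_r != round(k_r))
        stop("periodic mode needs an integer k_r >= 1", call. = FALSE)
      if (is.null(horizon) || horizon < 1)
        stop("periodic mode needs a horizon", call. = FALSE)
      seq.int(1L, as.integer(horizon), by = as.integer(k_r))
    })

  events <- lapply(years, function(y)
    list(year = as.integer(y), stations = stations,
         amplitude = amplitude, footprint = footprint))
  structure(list(mode = mode, events = events), class = "release_schedule")
}

#' @export
print.release_schedule <- function(x, ...) {
  yrs <- vapply(x$events, `[[`, integer(1), "year")
  cat(sprintf("Release schedule (%s): %d event(s) in season(s) %s, %d station(s) each\n",
              x$mode, length(x$events), paste(yrs, collapse = ", "),
              nrow(x$events[[1]]$stations)))
  invisible(x)
}

#' Fully infested initial conditions
#'
#' The reference starting point of all experiments: the habitat is at the
#' gall wasp's carrying scale (`v = 1`) everywhere.  For homogeneous runs
#' the parasitoid is seeded directly with egg density `q0` (default
#' `1e-9`, a few individuals per km^2).  For spatial runs the parasitoid
#' field defaults to zero — releases come from the schedule — but a
#' uniform `q0` can be supplied, e.g. to compare against the homogeneous
#' model.
#'
#' @param grid a [spatial_grid()] for spatial initial conditions, or `NULL`
#'   for the homogeneous model.
#' @param q0 parasitoid egg density seed (>= 0).  Defaults to `1e-9` for
#'   homogeneous runs and to 0 (await releases) for spatial runs.
#' @return For homogeneous use, a list `(v0 = 1, q0)`; for spatial use, a
#'   list of matrices `v` (all 1) and `q` (all `q0`).
#' @export
uniform_infestation_init <- function(grid = NULL, q0 = NULL) {
  if (is.null(q0)) q0 <- if (is.null(grid)) 1e-9 else 0
  if (q0 < 0) stop("q0 must be >= 0", call. = FALSE)
  if (is.null(grid))
    return(list(v0 = 1, q0 = q0))
  list(v = matrix(1, grid$nx, grid$ny),
       q = matrix(q0, grid$nx, grid$ny))
}
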