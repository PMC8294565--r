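# Run diagnostics: suppression timing, density extrema, implantation runs,
# invasion-front radii and cycle periods.  All pure functions of series or
# fields; nothing here touches the solvers.

#' Time from parasitoid establishment to pest suppression
#'
#' Finds the first season whose end-of-season parasitoid egg density
#' exceeds `trigger` (establishment; default 0.1) and the first season
#' whose gall wasp egg density falls below `threshold` (local extinction;
#' default `1e-7`, one insect per hectare), both with strict inequalities,
#' and reports the gap in seasons.
#'
#' @param series a `season_series` data frame (see [run_multi_year()]).
#' @param trigger parasitoid establishment level (on `q_end`).
#' @param threshold extinction threshold (on `v_end`); a number or a
#'   [egg_capacity_and_threshold()] object.
#' @return An object of class `suppression_report`: list with
#'   `year_q_exceeds`, `year_v_below`, `gap_seasons`, `min_v`, `year_min_v`,
#'   `min_q`, `year_min_q` and logical `defined` flags.  Events that never
#'   occur are reported as `NA` with `defined = FALSE`.
#' @examples
#' np <- nondimensionalize(dimensional_parameters(eta = 0.85))
#' time_to_suppression(run_multi_year(params = np, n_years = 20))
#' @export
time_to_suppression <- function(series, trigger = 0.1, threshold = 1e-7) {
  if (nrow(series) == 0) stop("series is empty", call. = FALSE)
  if (inherits(threshold, "threshold_spec"))
    threshold <- threshold$effective_threshold
  iq <- which(series$q_end > trigger)
  iv <- which(series$v_end < threshold)
  year_q <- if (length(iq)) series$year[iq[1]] else NA_integer_
  year_v <- if (length(iv)) series$year[iv[1]] else NA_integer_
  gap <- if (!is.na(year_q) && !is.na(year_v)) year_v - year_q else NA_integer_
  structure(list(
    year_q_exceeds = year_q,
    year_v_below = year_v,
    gap_seasons = gap,
    min_v = min(series$v_end), year_min_v = series$year[which.min(series$v_end)],
    min_q = min(series$q_end), year_min_q = series$year[which.min(series$q_end)],
    defined = c(q_exceeds = !is.na(year_q), v_below = !is.na(year_v),
                gap = !is.na(gap)),
    trigger = trigger, threshold = threshold),
    class = "suppression_report")
}

#' @export
print.suppression_report <- function(x, ...) {
  cat("Suppression report\n")
  cat(sprintf("  parasitoid q > %g first in season: %s\n", x$trigger,
              if (is.na(x$year_q_exceeds)) "never" else x$year_q_exceeds))
  cat(sprintf("  gall wasp  v < %g first in season: %s\n", x$threshold,
              if (is.na(x$year_v_below)) "never" else x$year_v_below))
  cat(sprintf("  gap: %s season(s)\n",
              if (is.na(x$gap_seasons)) "undefined" else x$gap_seasons))
  cat(sprintf("  min v = %.3g (season %d); min q = %.3g (season %d)\n",
              x$min_v, x$year_min_v, x$min_q, x$year_min_q))
  invisible(x)
}

#' Density minima over a window of seasons
#'
#' @param series a `season_series` data frame.
#' @param window year range `c(first, last)`; default the whole series.
#' @return List with `min_v`, `year_min_v`, `min_q`, `year_min_q`.
#' @export
series_extrema <- function(series, window = NULL) {
  if (is.null(window)) window <- range(series$year)
  sel <- series$year >= window[1] & series$year <= window[2]
  if (!any(sel)) stop("window contains no seasons", call. = FALSE)
  s <- series[sel, ]
  list(min_v = min(s$v_end), year_min_v = s$year[which.min(s$v_end)],
       min_q = min(s$q_end), year_min_q = s$year[which.min(s$q_end)])
}

#' Longest pest implantation run after first suppression
#'
#' An "implantation" season has the gall wasp near its carrying scale
#' (`v_end > level`, default 0.9).  After the pest has been suppressed once
#' (`v_end < level`), this reports the longest run of consecutive
#' implantation seasons — the longest stretch during which the pest has
#' re-established despite the control programme.
#'
#' @param series a `season_series` data frame.
#' @param level implantation level in (0, 1); default 0.9.
#' @return List with `longest_run` (seasons), `suppressed` (`FALSE` when
#'   the pest never dropped below `level`; the run then covers the full
#'   series).
#' @export
implantation_runs <- function(series, level = 0.9) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  high <- series$v_end > level
  first_low <- which(!high)[1]
  if (is.na(first_low)) {
    return(list(longest_run = nrow(series), suppressed = FALSE))
  }
  after <- high[seq(first_low, length(high))]
  r <- rle(after)
  runs <- r$lengths[r$values]
  list(longest_run = if (length(runs)) max(runs) else 0L, suppressed = TRUE)
}

#' Invasion-front radius around a release point, per year
#'
#' Quantifies the radially expanding suppression wave: for each year the
#' gall wasp egg field is sampled along radial transects from the release
#' point, and the front radius is the distance at which `v` first rises
#' through `iso` (default 0.5) moving outward from the suppressed core.
#' The per-year radius is the median over transects with a crossing;
#' `NA` when the release point is not suppressed or no transect crosses.
#'
#' @param v_fields array of gall wasp egg fields, dim `(nx, ny, n_years)`.
#' @param grid the [spatial_grid()] the fields live on.
#' @param release release point `c(x, y)` (must lie inside the domain).
#' @param iso density level defining the front.
#' @param n_angles number of radial transects spread over the full circle
#'   (transects leaving the domain are dropped).
#' @return Numeric vector of radii, one per year (`NA` when undefined).
#' @export
front_radius_series <- function(v_fields, grid, release = c(0, 0),
                                iso = 0.5, n_angles = 72L) {
  .nearest_node(grid, release)  # validates location
  angles <- seq(0, 2 * pi, length.out = n_angles + 1L)[-(n_angles + 1L)]
  rmax <- sqrt(grid$Lx^2 + grid$Ly^2)
  rs <- seq(0, rmax, by = grid$h / 2)
  vapply(seq_len(dim(v_fields)[3]), function(n) {
    f <- v_fields[, , n]
    cross <- vapply(angles, function(a) {
      xs <- release[1] + rs * cos(a)
      ys <- release[2] + rs * sin(a)
      ok <- xs >= 0 & xs <= grid$Lx & ys >= 0 & ys <= grid$Ly
      if (sum(ok) < 2) return(NA_real_)
      ix <- pmin(pmax(as.integer(ceiling(xs[ok] / grid$h)), 1L), grid$nx)
      iy <- pmin(pmax(as.integer(ceiling(ys[ok] / grid$h)), 1L), grid$ny)
      vv <- f[cbind(ix, iy)]
      if (vv[1] >= iso) return(NA_real_)  # core not suppressed
      hit <- which(vv >= iso)[1]
      if (is.na(hit)) NA_real_ else rs[ok][hit]
    }, numeric(1))
    if (all(is.na(cross))) NA_real_ else stats::median(cross, na.rm = TRUE)
  }, numeric(1))
}

#' Peak-to-peak cycle intervals of the pest density
#'
#' Detects local maxima of `log10(v_end)` above a floor (default
#' `v > 1e-2`) and returns the intervals, in years, between successive
#' peaks.  Saturated multi-year plateaus (consecutive seasons at the
#' carrying scale) are collapsed to a single peak.
#'
#' @param series a `season_series` data frame (length >= 3).
#' @param floor_v minimum height for a peak to count.
#' @return Integer vector of intervals (empty when fewer than 2 peaks).
#' @export
cycle_periods <- function(series, floor_v = 1e-2) {
  if (nrow(series) < 3) stop("series must have at least 3 seasons",
                             call. = FALSE)
  v <- series$v_end
  n <- length(v)
  # collapse plateaus: keep indices where value differs from predecessor
  peaks <- integer(0)
  i <- 2L
  while (i < n) {
    if (v[i] > floor_v && v[i] > v[i - 1]) {
      j <- i
      while (j < n && v[j + 1] == v[i]) j <- j + 1L  # plateau
      if (j == n || v[j + 1] < v[i]) peaks <- c(peaks, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(peaks) < 2) return(integer(0))
  diff(series$year[peaks])
}
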