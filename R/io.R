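# Configuration loading/validation and deterministic output writing.
# Configs are YAML; series go to CSV (fixed column order, full-precision
# scientific notation so byte-identical reruns are possible even at 1e-50);
# gridded fields go to a self-describing long-format CSV plus a JSON
# sidecar carrying dimensions, parameters and solver settings.

.config_defaults <- list(
  kind = "homogeneous",
  years = 300L,
  q0 = 1e-9,
  clamp = FALSE,
  area_ha = 1,
  dimensional = list(N_d = 150, N_t = 71, T_d = 40, T_t = NULL, a = 4,
                     gamma = 0.47, M = 5, beta_max = 2e6,
                     D_d = 0.889, D_t = 0.016),
  solver = list(rtol = NULL, atol = NULL),  # NULL = engine defaults
  grid = list(Lx = 4, Ly = 4, h = 0.05),
  probes = list(c(1, 1)),
  release = NULL,
  output_dir = NULL
)

.merge_section <- function(user, defaults, section) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key%s in '%s': %s",
                 if (length(unknown) > 1) "s" else "", section,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  utils::modifyList(defaults, user)
}

#' Load and validate a YAML run configuration
#'
#' Reads a run configuration, rejects unknown keys, fills documented
#' defaults, and validates the parameters via [dimensional_parameters()].
#' The only mandatory key is `eta`; `kind` selects the homogeneous or
#' spatial engine.
#'
#' @param path path to a YAML file, or a named list already parsed.
#' @return An object of class `run_config`.
#' @seealso [execute_run()], [write_outputs()], [preset_config()]
#' @export
load_config <- function(path) {
  raw <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  top_known <- c("eta", names(.config_defaults))
  unknown <- setdiff(names(raw), top_known)
  if (length(unknown))
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (is.null(raw$eta))
    stop("config must set eta (gall wasp overwintering survival)",
         call. = FALSE)

  cfg <- .config_defaults
  for (k in c("kind", "years", "q0", "clamp", "area_ha", "output_dir"))
    if (!is.null(raw[[k]])) cfg[[k]] <- raw[[k]]
  cfg$eta <- raw$eta
  cfg$dimensional <- .merge_section(raw$dimensional, cfg$dimensional,
                                    "dimensional")
  cfg$solver <- .merge_section(raw$solver, cfg$solver, "solver")
  cfg$grid <- .merge_section(raw$grid, cfg$grid, "grid")
  if (!is.null(raw$probes)) cfg$probes <- raw$probes
  if (!is.null(raw$release)) {
    rel_defaults <- list(mode = "initial-only", layout_k = NULL,
                         stations = NULL, n_r = NULL, k_r = NULL,
                         amplitude = 1)
    cfg$release <- .merge_section(raw$release, rel_defaults, "release")
  }
  # normalise optional slots: absent and NULL are the same thing, so drop
  # NULL entries (keeps write/load round-trips exact)
  drop_null <- function(l) l[!vapply(l, is.null, logical(1))]
  cfg$dimensional <- drop_null(cfg$dimensional)
  cfg$solver <- drop_null(cfg$solver)
  if (!is.null(cfg$release)) cfg$release <- drop_null(cfg$release)

  if (!cfg$kind %in% c("homogeneous", "spatial"))
    stop("kind must be 'homogeneous' or 'spatial'", call. = FALSE)
  if (!is.numeric(cfg$years) || cfg$years < 1)
    stop("years must be a positive integer", call. = FALSE)

  # validates invariants (gamma bound, positivity, a < T_d, ...)
  d <- cfg$dimensional
  dp <- dimensional_parameters(eta = cfg$eta, N_d = d$N_d, N_t = d$N_t,
                               T_d = d$T_d, T_t = d$T_t, a = d$a,
                               gamma = d$gamma, M = d$M,
                               beta_max = d$beta_max, D_d = d$D_d,
                               D_t = d$D_t)
  cfg$params <- nondimensionalize(dp)
  cfg$threshold <- egg_capacity_and_threshold(d$M, d$beta_max, cfg$area_ha)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("Run config: %s model, %d season(s), eta = %g\n",
              x$kind, as.integer(x$years), x$eta))
  invisible(x)
}

.config_as_plain_list <- function(cfg) {
  keep <- c("kind", "years", "eta", "q0", "clamp", "area_ha", "dimensional",
            "solver", "grid", "probes", "release", "output_dir")
  out <- unclass(cfg)[keep]
  out[!vapply(out, is.null, logical(1))]
}

#' Write the effective configuration back to YAML
#'
#' The echoed file is itself a valid standalone config: loading it
#' reproduces the run settings exactly.
#'
#' @param cfg a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_effective_config <- function(cfg, path) {
  yaml::write_yaml(.config_as_plain_list(cfg), path, precision = 17L)
  invisible(path)
}

.release_from_config <- function(cfg) {
  rel <- cfg$release
  if (is.null(rel)) return(NULL)
  stations <- if (!is.null(rel$layout_k))
    grid_release_layout(rel$layout_k, cfg$grid$Lx)
  else if (!is.null(rel$stations))
    as.data.frame(do.call(rbind, lapply(rel$stations, function(s)
      c(x = s[[1]], y = s[[2]]))))
  else
    stop("release needs either layout_k or stations", call. = FALSE)
  make_release_schedule(rel$mode, stations, n_r = rel$n_r, k_r = rel$k_r,
                        horizon = cfg$years, amplitude = rel$amplitude)
}

#' Execute a validated run configuration
#'
#' Dispatches to [run_multi_year()] or [run_spatial_multi_year()] according
#' to `kind`, constructing the grid, initial conditions and release
#' schedule from the config.
#'
#' @param cfg a `run_config` from [load_config()].
#' @param store_fields keep end-of-season fields for spatial runs.
#' @param verbose print per-season progress (spatial runs).
#' @return A `season_series` or `spatial_series`.
#' @export
execute_run <- function(cfg, store_fields = TRUE, verbose = FALSE) {
  if (!inherits(cfg, "run_config")) cfg <- load_config(cfg)
  sv <- cfg$solver
  if (cfg$kind == "homogeneous") {
    init <- uniform_infestation_init(q0 = cfg$q0)
    run_multi_year(v0 = init$v0, q0 = init$q0, params = cfg$params,
                   n_years = cfg$years, threshold = cfg$threshold,
                   clamp = isTRUE(cfg$clamp),
                   rtol = if (is.null(sv$rtol)) 1e-8 else sv$rtol,
                   atol = if (is.null(sv$atol)) 1e-60 else sv$atol)
  } else {
    grid <- spatial_grid(cfg$grid$Lx, cfg$grid$Ly, cfg$grid$h)
    init <- uniform_infestation_init(grid, q0 = cfg$q0)
    run_spatial_multi_year(grid, init, .release_from_config(cfg),
                           cfg$params, n_years = cfg$years,
                           probes = cfg$probes,
                           store_fields = store_fields,
                           rtol = if (is.null(sv$rtol)) 1e-6 else sv$rtol,
                           atol = if (is.null(sv$atol)) 1e-12 else sv$atol,
                           verbose = verbose)
  }
}

.fmt <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

.write_series_csv <- function(series, path) {
  df <- data.frame(year = series$year,
                   v_end = .fmt(series$v_end), q_end = .fmt(series$q_end),
                   p_end = .fmt(series$p_end), u_end = .fmt(series$u_end),
                   clamped = series$clamped)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.sidecar <- function(x, extra = list()) {
  pr <- if (inherits(x, "spatial_series")) x$params else attr(x, "params")
  c(list(package = "torysim",
         version = as.character(utils::packageVersion("torysim")),
         params = pr[c("mu", "tau", "E_d", "E_t", "delta", "eta",
                       "parasitoid_phase_length", "wasp_phase_length")]),
    extra)
}

#' Write run outputs to disk
#'
#' Homogeneous (`season_series`) runs produce `<name>-series.csv` and a
#' JSON metadata sidecar.  Spatial (`spatial_series`) runs additionally
#' produce one probe CSV per probe (identical schema to the series CSV)
#' and, when fields were stored, `<name>-fields.csv` in long format
#' (`year, x, y, p, q, u, v`) with the grid dimensions recorded in the
#' sidecar.  Numeric output uses 17-significant-digit scientific notation,
#' so identical runs give byte-identical files.
#'
#' @param x a `season_series` or `spatial_series`.
#' @param dir output directory (created if needed).
#' @param name basename for the output files.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(x, dir, name = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  path <- function(suffix) file.path(dir, paste0(name, suffix))
  if (inherits(x, "spatial_series")) {
    for (k in seq_along(x$probes)) {
      f <- path(sprintf("-probe%d.csv", k))
      .write_series_csv(x$probes[[k]], f)
      files <- c(files, f)
    }
    if (!is.null(x$fields)) {
      ny <- dim(x$fields$v)[3]
      idx <- expand.grid(ix = seq_len(x$grid$nx), iy = seq_len(x$grid$ny),
                         year = seq_len(ny))
      df <- data.frame(year = idx$year,
                       x = .fmt(x$grid$x[idx$ix]), y = .fmt(x$grid$y[idx$iy]),
                       p = .fmt(as.vector(x$fields$p)),
                       q = .fmt(as.vector(x$fields$q)),
                       u = .fmt(as.vector(x$fields$u)),
                       v = .fmt(as.vector(x$fields$v)))
      f <- path("-fields.csv")
      utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
      files <- c(files, f)
    }
    meta <- .sidecar(x, list(
      grid = x$grid[c("Lx", "Ly", "h", "nx", "ny")],
      dims = list(year = if (!is.null(x$fields)) dim(x$fields$v)[3]
                  else nrow(x$probes[[1]]),
                  y = x$grid$ny, x = x$grid$nx),
      variables = c("p", "q", "u", "v"),
      probes = lapply(x$probes, function(s) attr(s, "probe")),
      schedule = if (!is.null(x$schedule))
        lapply(x$schedule$events, function(ev)
          list(year = ev$year, amplitude = ev$amplitude,
               footprint = ev$footprint,
               stations = unname(as.matrix(ev$stations))))))
  } else {
    f <- path("-series.csv")
    .write_series_csv(x, f)
    files <- c(files, f)
    meta <- .sidecar(x)
  }
  fm <- path("-meta.json")
  jsonlite::write_json(meta, fm, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  files <- c(files, fm)
  invisible(files)
}

#' Read a series CSV back into a `season_series`
#'
#' @param path CSV written by [write_outputs()].
#' @return A `season_series` data frame.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path)
  class(df) <- c("season_series", "data.frame")
  df
}

#' Named preset configurations
#'
#' Ready-made configs for the package's reference experiments:
#' `homog-eta065`, `homog-eta075`, `homog-eta085` (300-year homogeneous
#' runs); `corner-release` (single release at the lower-left corner of the
#' 4 x 4 domain); `grid-k1` ... `grid-k4` (simultaneous releases on regular
#' station lattices with spacings 4, 2, 4/3, 1); `rerelease-nr6` ...
#' `rerelease-nr9` (second release in season n_r); `periodic-kr1` ...
#' `periodic-kr4` (releases every k_r seasons).
#'
#' @param name preset name; see [list_presets()].
#' @return A `run_config`.
#' @export
preset_config <- function(name) {
  f <- system.file("extdata", "presets", paste0(name, ".yaml"),
                   package = "torysim")
  if (f == "")
    stop(sprintf("unknown preset '%s'; see list_presets()", name),
         call. = FALSE)
  load_config(f)
}

#' @rdname preset_config
#' @export
list_presets <- function() {
  sort(sub("\\.yaml$", "",
           list.files(system.file("extdata", "presets", package = "torysim"),
                      pattern = "\\.yaml$")))
}
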