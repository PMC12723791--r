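#' Default run parameters
#'
#' The standard protocol values: dt = 0.2 for many-body simulation, 0.02 for
#' the DMFT grid, 0.25 for flow maps; horizon T = 2000; gain g = 1.5;
#' modulator time-constant tau_z = 1; N = 1000.
#' @keywords internal
default_config <- function() {
  list(experiment = "simulate",
       N = 1000L, P = NULL, alpha = NULL, gamma = 0, g = 1.5, tau_z = 1,
       m0 = 0.55, dt = 0.2, T = 2000, M = 5000L, tol = 1e-3,
       reps = 100L, record_every = 10L, convergence_tol = 0,
       seed = 1L, out = NULL, paper_scale = FALSE)
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration (or starts from the defaults), overlays any
#' `...` overrides, validates types and ranges, and resolves the pattern
#' count: when `alpha` is given together with `N`, `P = round(alpha * N)`
#' and `alpha` is recomputed exactly as P/N. The string `"inf"` (any case)
#' for `gamma` maps to the binary-gate sentinel `Inf`.
#'
#' @param path optional path to a JSON file.
#' @param ... named overrides of individual fields.
#' @return object of class `run_config` (a validated named list).
#' @export
#' @examples
#' cfg <- load_config(gamma = "inf", alpha = 0.4, N = 500)
#' cfg$P
load_config <- function(path = NULL, ...) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    cfg[names(user)] <- user
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  bad <- setdiff(names(cfg), names(default_config()))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (is.character(cfg$gamma)) {
    if (tolower(cfg$gamma) %in% c("inf", "+inf", "infinity")) cfg$gamma <- Inf
    else cfg$gamma <- as.numeric(cfg$gamma)
  }
  if (!cfg$experiment %in% c("simulate", "phase", "dmft", "flow"))
    stop("experiment must be one of simulate, phase, dmft, flow")
  if (is.na(cfg$gamma) || cfg$gamma < 0) stop("invalid gamma")
  if (cfg$dt <= 0 || cfg$T <= 0 || cfg$tau_z <= 0 || cfg$g <= 0)
    stop("dt, T, tau_z and g must be positive")
  if (!is.null(cfg$alpha) && !is.null(cfg$N)) {
    cfg$P <- as.integer(round(cfg$alpha * cfg$N))
    cfg$alpha <- cfg$P / cfg$N
  }
  structure(cfg, class = "run_config")
}

#' Deterministic small test instances
#'
#' Named tiny instances used across examples and the test suite, generated
#' in code (never stored): an ungated retrieval run at N = 50, a gated
#' overload run at N = 50, an orthogonal pattern pair at N = 100, and a
#' small linear-kernel toy grid for the Volterra propagator.
#'
#' @param name one of `"ungated_retrieval"`, `"gated_overload"`,
#'   `"orthogonal_pair"`, `"linear_kernel_toy"`.
#' @param seed integer seed; the same seed always yields identical objects.
#' @return a list whose contents depend on the fixture.
#' @export
make_fixture <- function(name = c("ungated_retrieval", "gated_overload",
                                  "orthogonal_pair", "linear_kernel_toy"),
                         seed = 1L) {
  name <- match.arg(name)
  switch(name,
    ungated_retrieval = {
      spec <- network_spec(N = 50, P = 2, gamma = 0, seed = seed)
      init <- construct_cued_state(as_pattern_matrix(spec$patterns)[1, ],
                                   0.6, seed = seed + 1L)
      list(spec = spec, init = init, cfg = sim_config(dt = 0.2, T = 50))
    },
    gated_overload = {
      spec <- network_spec(N = 50, P = 20, gamma = Inf, seed = seed)
      init <- construct_cued_state(as_pattern_matrix(spec$patterns)[1, ],
                                   0.55, seed = seed + 1L)
      list(spec = spec, init = init, cfg = sim_config(dt = 0.2, T = 100))
    },
    orthogonal_pair = make_orthogonal_pair(100, seed = seed),
    linear_kernel_toy = {
      L <- 40L; dt <- 0.1
      list(L = L, dt = dt, lambda = 0.7,
           R = diag(-0.7 / dt, L))
    })
}

#' Save experiment results with a reproducibility manifest
#'
#' Writes tabular results to CSV, array results (matrices) to
#' whitespace-free CSV matrices, and a JSON manifest carrying the
#' configuration, its hash, the seed and the package version, so a run can
#' be identified and reproduced exactly.
#'
#' @param record named list; data.frames go to `<name>.csv`, matrices to
#'   `<name>.csv` (dense), scalars/vectors into the manifest.
#' @param path output directory (created if missing).
#' @param config optional `run_config` to embed in the manifest.
#' @return (invisibly) the manifest as a list.
#' @export
save_results <- function(record, path, config = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  scalars <- list()
  for (nm in names(record)) {
    obj <- record[[nm]]
    if (is.data.frame(obj) || is.matrix(obj)) {
      f <- file.path(path, paste0(nm, ".csv"))
      utils::write.csv(as.data.frame(obj), f, row.names = FALSE)
      files <- c(files, basename(f))
    } else {
      scalars[[nm]] <- obj
    }
  }
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, null = "null")
  tf <- tempfile()
  writeLines(cfg_json, tf)
  manifest <- list(
    files = files, scalars = scalars,
    config = if (is.null(config)) NULL else unclass(config),
    config_hash = unname(tools::md5sum(tf)),
    package_version = as.character(utils::packageVersion("gatednet")),
    timestamp = format(Sys.time(), tz = "UTC"))
  unlink(tf)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(manifest)
}
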