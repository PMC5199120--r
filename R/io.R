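# Configuration files, provenance, and the end-to-end pipeline runner.

run_config_keys <- c("variant", "params", "abundances", "l_grid", "solver",
                     "sampler", "robustness", "seed", "out_dir")

#' Default run configuration
#'
#' A fully serializable description of a pipeline run: model variant,
#' parameter overrides, abundances, ligand grid, solver settings, sampler
#' spec and robustness-classification settings. A run is reproducible from
#' its saved configuration and seed.
#'
#' @param n sample size for the scan stage (stored as `sampler$n_points`;
#'   plain `n` is avoided as a YAML key because YAML 1.1 reads it as a
#'   boolean).
#' @param seed RNG seed.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(n = 1000, seed = 1L) {
  structure(list(
    variant = "simplified",
    params = list(),                      # overrides on the reference values
    abundances = list(R_tot = 1400, G_tot = 860, V_cyt = 36.4),
    l_grid = list(lo = 1e-3, hi = 1e5, points = 25),
    solver = list(tol = 1e-9, maxit = 400, method = "hybrid"),
    sampler = list(n_points = n, span = 8,
                   sampled = kinetic_parameter_names()),
    robustness = list(multipliers = c(0.1, 1, 10), amplitude_tol = 1.5,
                      ec50_tol = 3, amplitude_floor = 0.05,
                      dora_band = c(1 / 3, 3), grid_points = 20,
                      grid_decades = 4),
    seed = as.integer(seed),
    out_dir = NULL
  ), class = "run_config")
}

#' Load / save a run configuration
#'
#' YAML round trip with strict key checking: unknown keys and invalid values
#' (e.g. non-positive rates) are rejected.
#'
#' @param path file path (YAML).
#' @return `load_config`: a `run_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), run_config_keys)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  cfg <- default_run_config()
  # single-bracket assignment keeps explicit-NULL values (e.g. out_dir)
  for (nm in names(raw)) cfg[nm] <- raw[nm]
  validate_run_config(cfg)
  cfg
}

#' @rdname load_config
#' @param cfg a `run_config`.
#' @export
save_config <- function(cfg, path) {
  validate_run_config(cfg)
  yaml::write_yaml(unclass(cfg), path, precision = 15)
  invisible(path)
}

validate_run_config <- function(cfg) {
  if (!cfg$variant %in% c("simplified", "extended", "two_pool")) {
    stop("invalid variant: ", cfg$variant)
  }
  as_carousel_params(cfg$params)              # rejects unknown/invalid rates
  with(cfg$abundances, carousel_abundances(R_tot, G_tot, V_cyt))
  if (cfg$solver$tol <= 0) stop("solver tol must be positive")
  if (cfg$sampler$n_points < 1) stop("sampler n_points must be >= 1")
  do.call(robustness_config,
          c(cfg$robustness,
            list(abundances = do.call(carousel_abundances, cfg$abundances),
                 tol = cfg$solver$tol)))
  invisible(TRUE)
}

config_params <- function(cfg) as_carousel_params(cfg$params)

config_robustness <- function(cfg) {
  do.call(robustness_config,
          c(cfg$robustness,
            list(abundances = do.call(carousel_abundances, cfg$abundances),
                 tol = cfg$solver$tol)))
}

#' Run the full scan pipeline and write its artifacts
#'
#' Samples the parameter space, classifies every point, mines restrictions
#' on the robust-response subset, and writes plain-text artifacts to
#' `out_dir`: `config.yaml`, `manifest.json` (sample provenance + config
#' hash), `draws.csv`, `labels.csv`, `fractions.json`,
#' `restrictions.json`, and per-pair histogram tables under `histograms/`.
#'
#' @param cfg a `run_config`.
#' @param out_dir output directory (created if missing); defaults to
#'   `cfg$out_dir`.
#' @param progress passed to [run_scan()].
#' @return The `scan_result`, invisibly.
#' @export
run_pipeline <- function(cfg = default_run_config(), out_dir = cfg$out_dir,
                         progress = 0) {
  if (is.null(out_dir)) stop("an output directory is required")
  validate_run_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "histograms"), showWarnings = FALSE)

  cfg_path <- file.path(out_dir, "config.yaml")
  save_config(cfg, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))

  spec <- lhs_spec(n = cfg$sampler$n_points, span = cfg$sampler$span,
                   sampled = unlist(cfg$sampler$sampled),
                   center = config_params(cfg), seed = cfg$seed)
  draws <- lhs_sample(spec)
  utils::write.csv(draws, file.path(out_dir, "draws.csv"),
                   row.names = FALSE)

  manifest <- sample_manifest(spec, draws)
  manifest$config_md5 <- cfg_hash
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  scan <- run_scan(draws, config_robustness(cfg), progress = progress)
  utils::write.csv(cbind(point = seq_len(scan$n), scan$labels),
                   file.path(out_dir, "labels.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(fractions_percent = as.list(scan$fractions),
         n = scan$n, n_failed = scan$n_failed,
         seed = cfg$seed, config_md5 = cfg_hash),
    file.path(out_dir, "fractions.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  robust <- draws[scan$labels$robust_response, , drop = FALSE]
  restr <- if (nrow(robust) >= 50) {
    mine_restrictions(robust, sampled = unlist(cfg$sampler$sampled))
  } else {
    data.frame(x = character(), y = character(), fraction = numeric(),
               necessary = logical())
  }
  jsonlite::write_json(
    list(restrictions = restr, n_robust = nrow(robust),
         seed = cfg$seed, config_md5 = cfg_hash),
    file.path(out_dir, "restrictions.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (nrow(robust) >= 2) {
    hm <- histogram_matrix(robust, sampled = unlist(cfg$sampler$sampled))
    for (xnm in hm$sampled) for (ynm in hm$sampled) {
      f <- file.path(out_dir, "histograms",
                     paste0(xnm, "__", ynm, ".csv"))
      tab <- hm$panels[[xnm]][[ynm]]
      df <- if (xnm == ynm) as.data.frame(tab) else as.data.frame.matrix(tab)
      utils::write.csv(df, f, row.names = (xnm != ynm))
    }
  }
  invisible(scan)
}
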