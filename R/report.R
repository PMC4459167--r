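# Report assembly: one schema-validated configuration drives any
# combination of analysis stages and writes a deterministic bundle (JSON
# summary + CSV tables). The numbered driver scripts under analysis/ are
# thin wrappers over this and the individual stage functions.

.run_config_keys <- c("input", "topology", "stages", "selections",
                      "hbond_params", "rdf", "profile", "adhesion",
                      "modulus", "tg_curve", "seed", "output_dir")

validate_run_config <- function(config) {
  unknown <- setdiff(names(config), .run_config_keys)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  if (is.null(config$output_dir)) stop("config requires output_dir")
  stages <- config$stages %||% character(0)
  bad <- setdiff(stages, c("hbond", "rdf", "profile", "adhesion", "modulus", "tg"))
  if (length(bad)) stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  needs_input <- length(intersect(stages,
                                  c("hbond", "rdf", "profile", "adhesion", "modulus")))
  if (needs_input && is.null(config$input))
    stop("config requires an input structure for the requested stages")
  if (needs_input && is.null(config$topology))
    stop("config requires a topology sidecar for the requested stages")
  invisible(config)
}

#' Run a configured analysis and write a report bundle
#'
#' Validates the configuration (unknown keys are rejected before any
#' computation), runs the requested stages through the same library
#' functions a direct caller would use, and writes `summary.json` plus
#' per-stage CSV tables to the output directory. Identical inputs produce
#' byte-identical bundles (no timestamps).
#'
#' @param config named list (or YAML file path) with keys: `input` (XYZ
#'   path), `topology` (sidecar path), `stages` (subset of "hbond",
#'   "rdf", "profile", "adhesion", "modulus", "tg"), per-stage parameter
#'   blocks, `seed`, `output_dir`.
#' @return (invisibly) the summary list that was written.
#' @export
run_report <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_run_config(config)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  stages <- config$stages %||% character(0)
  summary <- list(package_version = as.character(utils::packageVersion("fibrilkit")),
                  seed = config$seed,
                  config_hash = config_hash(config))
  traj <- NULL
  if (!is.null(config$input))
    traj <- read_xyz(config$input, config$topology)
  cfg <- if (!is.null(traj)) traj$frames[[1L]] else NULL
  sel_of <- function(name) {
    spec <- (config$selections %||% list())[[name]]
    if (is.null(spec)) stop(sprintf("stage needs selection '%s'", name))
    if (!is.null(spec$element)) select_atoms(cfg, element = spec$element)
    else if (!is.null(spec$group)) select_atoms(cfg, group = spec$group)
    else select_atoms(cfg, pattern = spec$pattern)
  }
  out_csv <- function(df, name) {
    utils::write.csv(df, file.path(config$output_dir, name), row.names = FALSE)
  }
  if ("hbond" %in% stages) {
    p <- do.call(hbond_params, config$hbond_params %||% list())
    hb <- detect_hbonds(cfg, p)
    out_csv(as.data.frame(hb), "hbonds.csv")
    dens <- hbond_energy_density(cfg, hb)
    coop <- cooperativity_chains(hb)
    st <- if (nrow(hb)) hbond_geometry_stats(hb) else NULL
    summary$hbond <- list(count = nrow(hb),
                          mean_r_HA = st$mean_r_HA, mean_theta = st$mean_theta,
                          energy_density_J_m3 = dens$density_J_m3,
                          cooperativity_fraction = coop$participation_fraction)
  }
  if ("rdf" %in% stages) {
    pars <- config$rdf %||% list()
    r <- rdf(traj, sel_of("rdf_a"), sel_of("rdf_b"),
             dr = pars$dr %||% 0.05, r_max = pars$r_max)
    out_csv(as.data.frame(r), "rdf.csv")
    pk <- find_rdf_peaks(r, pars$min_prominence %||% 0.1)
    summary$rdf <- list(n_bins = nrow(r), peaks = pk)
  }
  if ("profile" %in% stages) {
    pars <- config$profile %||% list()
    pr <- density_profile(cfg, sel_of("profile"), axis = pars$axis %||% "z",
                          bin_width = pars$bin_width %||% 0.2)
    out_csv(as.data.frame(pr), "profile.csv")
    summary$profile <- list(mode = attr(pr, "mode"))
  }
  if ("adhesion" %in% stages) {
    pars <- config$adhesion %||% list()
    adh <- adhesion_energy(cfg, sel_of("matrix"), sel_of("substrate"),
                           interface_area = pars$area)
    summary$adhesion <- list(vdw = adh$vdw, elec = adh$elec, total = adh$total,
                             per_area_mJ_m2 = as.list(adh$per_area))
  }
  if ("modulus" %in% stages) {
    pars <- config$modulus %||% list()
    ym <- youngs_modulus(traj, axis = pars$axis %||% "z")
    out_csv(ym$series, "stress_strain.csv")
    summary$modulus <- list(E_GPa = ym$E, intercept_GPa = ym$fit_intercept,
                            r_squared = ym$r_squared,
                            n_rejected = ym$n_rejected)
  }
  if ("tg" %in% stages) {
    tc <- config$tg_curve
    if (is.null(tc)) stop("tg stage requires tg_curve (CSV path)")
    df <- utils::read.csv(tc)
    fit <- fit_glass_transition(vtcurve(df[[1L]], df[[2L]]))
    summary$tg <- fit[c("tg", "slope_glass", "slope_melt", "no_transition")]
  }
  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(summary)
}

config_hash <- function(config) {
  # stable content hash of the scientific configuration (output location
  # excluded), without digest dependencies: canonical JSON folded into a
  # hex accumulator
  config <- config[setdiff(names(config), "output_dir")]
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        digits = NA, null = "null")
  bytes <- as.integer(charToRaw(as.character(s)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}
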