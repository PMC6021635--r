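#' Default run configuration
#'
#' The full configuration for a feedback-control simulation run, as a
#' nested list with explicit units in the key names. Non-published
#' defaults (V1/Q/V2, residual-error magnitudes, the 70-kg fallback
#' weight) carry provenance notes in the shipped YAML.
#'
#' @return Nested list with blocks \code{population}, \code{regimen},
#'   \code{window}, \code{simulation} and \code{strategies}.
#' @export
default_run_config <- function() {
  list(
    population = list(
      cl_L_h_kg = 0.0276, v1_L_kg = 0.25, q_L_h_kg = 0.06, v2_L_kg = 0.25,
      bsv_cv = list(cl = 0.324, v1 = 0.30, q = 0.30, v2 = 0.30),
      residual = list(proportional_cv = 0.20, additive_sd_mg_L = 0.05)
    ),
    regimen = list(
      loading_mg_kg = 2.5, loading_duration_h = 2,
      maintenance_mg_kg = 1.5, maintenance_duration_h = 1,
      interval_h = 12
    ),
    window = list(lower_mg_h_L = 50, mid_mg_h_L = 75, upper_mg_h_L = 100),
    simulation = list(n_subjects = 5000, seed = 42, default_weight_kg = 70),
    strategies = lapply(table3_strategies(),
                        function(s) list(label = s$label,
                                         times_h = as.numeric(s$times)))
  )
}

.cfg_keys <- function() {
  list(top = c("population", "regimen", "window", "simulation", "strategies"),
       population = c("cl_L_h_kg", "v1_L_kg", "q_L_h_kg", "v2_L_kg",
                      "bsv_cv", "residual"),
       bsv_cv = c("cl", "v1", "q", "v2"),
       residual = c("proportional_cv", "additive_sd_mg_L"),
       regimen = c("loading_mg_kg", "loading_duration_h", "maintenance_mg_kg",
                   "maintenance_duration_h", "interval_h"),
       window = c("lower_mg_h_L", "mid_mg_h_L", "upper_mg_h_L"),
       simulation = c("n_subjects", "seed", "default_weight_kg"))
}

.check_known <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop(sprintf("unknown config key%s in %s: %s",
                 if (length(extra) > 1) "s" else "", where,
                 paste(extra, collapse = ", ")), call. = FALSE)
}

#' Validate a run configuration
#'
#' Checks structure, key names and every module-level invariant
#' (positive typical values, non-negative variabilities, ordered window,
#' valid regimen, day-1 sampling times). Errors name the offending key.
#'
#' @param cfg Nested configuration list.
#' @return \code{cfg}, invisibly, after validation.
#' @export
validate_run_config <- function(cfg) {
  keys <- .cfg_keys()
  .check_known(cfg, keys$top, "config")
  for (b in keys$top)
    if (is.null(cfg[[b]])) stop("missing config block: ", b, call. = FALSE)
  p <- cfg$population
  .check_known(p, keys$population, "population")
  .check_known(p$bsv_cv, keys$bsv_cv, "population$bsv_cv")
  .check_known(p$residual, keys$residual, "population$residual")
  for (k in c("cl_L_h_kg", "v1_L_kg", "q_L_h_kg", "v2_L_kg"))
    if (!is.numeric(p[[k]]) || p[[k]] <= 0)
      stop("population$", k, " must be strictly positive", call. = FALSE)
  if (any(unlist(p$bsv_cv) < 0))
    stop("population$bsv_cv values must be non-negative", call. = FALSE)
  if (p$residual$proportional_cv < 0 || p$residual$additive_sd_mg_L < 0)
    stop("population$residual components must be non-negative", call. = FALSE)
  r <- cfg$regimen
  .check_known(r, keys$regimen, "regimen")
  if (r$loading_mg_kg < 0 || r$maintenance_mg_kg < 0)
    stop("regimen doses must be non-negative", call. = FALSE)
  if (r$loading_duration_h <= 0 || r$maintenance_duration_h <= 0)
    stop("regimen infusion durations must be positive", call. = FALSE)
  if (r$interval_h <= 0 || 24 %% r$interval_h != 0)
    stop("regimen$interval_h must be a positive divisor of 24", call. = FALSE)
  w <- cfg$window
  .check_known(w, keys$window, "window")
  if (!(0 < w$lower_mg_h_L && w$lower_mg_h_L < w$mid_mg_h_L &&
        w$mid_mg_h_L < w$upper_mg_h_L))
    stop("window must satisfy 0 < lower < mid < upper", call. = FALSE)
  s <- cfg$simulation
  .check_known(s, keys$simulation, "simulation")
  if (s$n_subjects < 1) stop("simulation$n_subjects must be >= 1", call. = FALSE)
  if (s$default_weight_kg <= 0)
    stop("simulation$default_weight_kg must be positive", call. = FALSE)
  for (st in cfg$strategies) {
    .check_known(st, c("label", "times_h"), "strategies[[...]]")
    sampling_strategy(st$times_h)  # validates ordering and the day-1 constraint
  }
  invisible(cfg)
}

#' Read / write a run configuration as YAML
#'
#' @param path File path.
#' @return \code{load_run_config} returns the validated configuration
#'   list; \code{write_run_config} returns \code{path} invisibly. A
#'   load -> dump -> load round trip is the identity.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  # YAML reads empty/heterogeneous sequences as lists; normalize schedules
  if (!is.null(cfg$strategies))
    cfg$strategies <- lapply(cfg$strategies, function(st) {
      st$times_h <- as.numeric(unlist(st$times_h))
      st
    })
  validate_run_config(cfg)
  cfg
}

#' @param cfg Configuration list (validated before writing).
#' @rdname load_run_config
#' @export
write_run_config <- function(cfg, path) {
  validate_run_config(cfg)
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

#' Build module objects from a configuration
#'
#' @param cfg Validated configuration list.
#' @return \code{cfg_pop_model}: a \code{\link{pop_model}};
#'   \code{cfg_window}: a \code{\link{target_window}};
#'   \code{cfg_regimen}: the traditional \code{\link{infusion_regimen}}
#'   for a given weight.
#' @export
cfg_pop_model <- function(cfg) {
  p <- cfg$population
  pop_model(cl = p$cl_L_h_kg, v1 = p$v1_L_kg, q = p$q_L_h_kg, v2 = p$v2_L_kg,
            bsv = unlist(p$bsv_cv)[c("cl", "v1", "q", "v2")],
            prop_cv = p$residual$proportional_cv,
            add_sd = p$residual$additive_sd_mg_L)
}

#' @rdname cfg_pop_model
#' @export
cfg_window <- function(cfg) {
  w <- cfg$window
  target_window(w$lower_mg_h_L, w$upper_mg_h_L, w$mid_mg_h_L)
}

#' @param weight Body weight, kg.
#' @param n_days Days of dosing to lay out.
#' @rdname cfg_pop_model
#' @export
cfg_regimen <- function(cfg, weight = 1, n_days = 2) {
  r <- cfg$regimen
  traditional_regimen(weight = weight, n_days = n_days,
                      loading_mg_kg = r$loading_mg_kg,
                      loading_dur_h = r$loading_duration_h,
                      maintenance_mg_kg = r$maintenance_mg_kg,
                      maintenance_dur_h = r$maintenance_duration_h,
                      interval_h = r$interval_h)
}

#' Write the packaged fixtures to a directory
#'
#' Writes (1) the nephrotoxicity study table, (2) the eleven benchmark
#' sampling strategies, and (3) a small simulated concentration dataset
#' (fixed seed) for estimator demonstrations. Regeneration with the
#' same seed is byte-identical.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the demo concentration records.
#' @param n_demo_subjects Number of demo subjects.
#' @return Character vector of the files written, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 42, n_demo_subjects = 5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  studies_path <- file.path(out_dir, "polymyxin_nephrotox_studies.csv")
  utils::write.csv(nephrotox_studies(), studies_path, row.names = FALSE,
                   quote = FALSE, na = "")
  strat_path <- file.path(out_dir, "sampling_strategies.csv")
  strategies <- table3_strategies()
  utils::write.csv(
    data.frame(strategy = seq_along(strategies),
               n_samples = vapply(strategies, function(s) length(s$times), 0L),
               times_h = vapply(strategies, function(s)
                 paste(as.numeric(s$times), collapse = ";"), "")),
    strat_path, row.names = FALSE, quote = FALSE)
  demo_path <- file.path(out_dir, "demo_concentrations.csv")
  model <- pop_model()
  subjects <- sample_subjects(model, n_demo_subjects, weight = 70, seed = seed)
  recs <- do.call(rbind, lapply(seq_len(n_demo_subjects), function(i) {
    reg <- traditional_regimen(weight = 70)
    obs <- simulate_observations(subjects[i, ], reg, c(2, 4, 12, 24),
                                 model = model, seed = seed + i)
    data.frame(subject_id = subjects$id[i], time_h = obs$time,
               conc_mg_L = round(obs$conc, 4), weight_kg = 70)
  }))
  utils::write.csv(recs, demo_path, row.names = FALSE, quote = FALSE)
  invisible(c(studies_path, strat_path, demo_path))
}
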