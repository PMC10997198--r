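# Run configuration and end-to-end pipeline commands:
# extract -> couple -> rate -> simulate -> report. A single YAML file drives
# everything; every defaulted field is echoed into the run manifest so no
# hidden defaults enter a result.

.default_run_config <- function() {
  list(
    input = list(type = "toy", structure_path = NULL),
    toy = list(n_rods = 6, pigments_per_rod = 6, core_cylinders = 3,
               pigments_per_cylinder = 8, nn_distance = 25, n_can = 4,
               can_distance = 12, tdm_jitter_sd = 0.1, seed = 1),
    extraction = NULL,    # NULL -> default_extraction_config()
    scheme = NULL,        # NULL -> default_site_scheme()
    coupling = list(can_pcb_method = "SAMPLED", screening_factor = 1,
                    coupling_means = c(54, 27)),
    lineshapes = NULL,    # NULL -> default_lineshape_library()
    can_sampler = list(e_s1_mean = 2.00, e_s1_sd = 0.07,
                       coupling_means = c(54, 27),
                       coupling_sds = c(21.6, 10.8),
                       e00_shift_cm1 = 1400),
    simulation = list(n_runs = 100, master_seed = 1, temperature = 300,
                      time_max_ps = 2000, time_step_ps = 10),
    output_dir = "pbsquench_out"
  )
}

# deep-merge user values over defaults, complaining about unknown keys
.merge_config <- function(defaults, user, path = "") {
  if (is.null(user)) return(defaults)
  if (!is.list(defaults) || !is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0 && path %in% c("", "input", "toy", "coupling",
                                         "can_sampler", "simulation"))
    stop("unknown configuration key(s) under '", path, "': ",
         paste(unknown, collapse = ", "))
  out <- defaults
  for (nm in names(user))
    out[[nm]] <- .merge_config(defaults[[nm]], user[[nm]],
                               paste0(path, if (nzchar(path)) "." else "",
                                      nm))
  out
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration, merges it over the documented defaults
#' (unknown keys are a validation error), and performs schema checks before
#' any computation. The returned object contains every field, defaulted or
#' not, and is what gets hashed into the run manifest.
#'
#' @param path Path to a YAML file, or `NULL` for the pure defaults.
#' @return Validated configuration list of class `run_config`.
#' @export
load_run_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  }
  cfg <- .merge_config(.default_run_config(), user)
  errs <- character()
  if (!cfg$input$type %in% c("toy", "structure"))
    errs <- c(errs, "input.type must be 'toy' or 'structure'")
  if (cfg$input$type == "structure" && is.null(cfg$input$structure_path))
    errs <- c(errs, "input.type 'structure' requires input.structure_path")
  if (cfg$simulation$n_runs < 1) errs <- c(errs, "simulation.n_runs must be >= 1")
  if (cfg$simulation$temperature <= 0)
    errs <- c(errs, "simulation.temperature must be > 0")
  if (cfg$simulation$time_max_ps <= 0 || cfg$simulation$time_step_ps <= 0)
    errs <- c(errs, "simulation time grid must be positive")
  if (length(cfg$coupling$coupling_means) != 2 ||
      any(cfg$coupling$coupling_means <= 0))
    errs <- c(errs, "coupling.coupling_means must be two positive numbers")
  if (cfg$coupling$screening_factor <= 0)
    errs <- c(errs, "coupling.screening_factor must be > 0")
  if (length(errs) > 0)
    stop("invalid run configuration:\n  - ", paste(errs, collapse = "\n  - "))
  structure(cfg, class = c("run_config", "list"))
}

# realize config sections into package objects
.config_network <- function(cfg) {
  scheme <- if (is.null(cfg$scheme)) default_site_scheme() else {
    s <- default_site_scheme()
    for (nm in names(cfg$scheme)) s[[nm]] <- utils::modifyList(
      s[[nm]], cfg$scheme[[nm]])
    s
  }
  if (cfg$input$type == "toy") {
    tc <- cfg$toy
    make_toy_pbs(toy_pbs_config(
      n_rods = tc$n_rods, pigments_per_rod = tc$pigments_per_rod,
      core_cylinders = tc$core_cylinders,
      pigments_per_cylinder = tc$pigments_per_cylinder,
      nn_distance = tc$nn_distance, n_can = tc$n_can,
      can_distance = tc$can_distance, tdm_jitter_sd = tc$tdm_jitter_sd,
      seed = tc$seed),
      scheme = scheme,
      coupling_means = cfg$coupling$coupling_means,
      screening_factor = cfg$coupling$screening_factor)
  } else {
    ex <- if (is.null(cfg$extraction)) default_extraction_config()
          else cfg$extraction
    pg <- read_structure(cfg$input$structure_path, ex)
    pg <- assign_site_properties(pg, scheme)
    pigment_network(pg, matrix(0, nrow(pg), nrow(pg)),
                    metadata = list(source = cfg$input$structure_path))
  }
}

.config_lineshapes <- function(cfg) {
  lib <- default_lineshape_library()
  for (nm in names(cfg$lineshapes)) {
    ls <- cfg$lineshapes[[nm]]
    lib[[nm]] <- data.frame(offset = ls$offset, weight = ls$weight,
                            sigma = ls$sigma)
  }
  lib
}

.config_sampler <- function(cfg) {
  cs <- cfg$can_sampler
  can_parameter_spec(e_s1_mean = cs$e_s1_mean, e_s1_sd = cs$e_s1_sd,
                     coupling_means = cs$coupling_means,
                     coupling_sds = cs$coupling_sds,
                     e00_shift_cm1 = cs$e00_shift_cm1)
}

#' Run the full simulation pipeline
#'
#' Builds the network from the configured input, assembles couplings and the
#' mean-parameter rate matrix, runs the stochastic ensemble, and writes:
#' pigment table CSV, coupling matrix CSV, rate-matrix CSV, decay-time CSV,
#' survival-curve CSV, and a JSON manifest with the full echoed
#' configuration, its hash, and the summary (mean lifetime +/- SE, quench
#' fraction).
#'
#' @param config A `run_config` or path to a YAML file.
#' @param out_dir Output directory (created if needed); overrides the
#'   configured one.
#' @return Invisibly, a list with the `network`, `rates`, `ensemble`,
#'   `summary`, and output `files`.
#' @export
cmd_simulate <- function(config = NULL, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else
    load_run_config(config)
  if (is.null(out_dir)) out_dir <- cfg$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  net <- .config_network(cfg)
  lib <- .config_lineshapes(cfg)
  rates <- build_rate_matrix(net, lib, cfg$simulation$temperature)
  ens <- run_ensemble(net, .config_sampler(cfg),
                      n_runs = cfg$simulation$n_runs,
                      master_seed = cfg$simulation$master_seed,
                      lineshape_library = lib,
                      temperature = cfg$simulation$temperature)
  tgrid <- seq(0, cfg$simulation$time_max_ps,
               by = cfg$simulation$time_step_ps)
  surv <- survival_curve(ens, tgrid)
  lt <- mean_lifetime(ens)
  summary <- list(mean_lifetime_ps = lt$mean_ps, se_ps = lt$se_ps,
                  tau_exp_fit_ps = lt$tau_exp_fit_ps,
                  quench_fraction = quench_fraction(ens),
                  n_runs = lt$n)

  files <- list(
    pigments = file.path(out_dir, "pigments.csv"),
    couplings = file.path(out_dir, "couplings.csv"),
    rates = file.path(out_dir, "rate_matrix.csv"),
    decay_times = file.path(out_dir, "decay_times.csv"),
    survival = file.path(out_dir, "survival.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  write_pigment_csv(net$pigments, files$pigments)
  write_coupling_csv(net, files$couplings)
  write_rate_matrix(rates, files$rates)
  utils::write.csv(ens$runs, files$decay_times, row.names = FALSE)
  utils::write.csv(cbind(surv, config_hash = ens$config_hash),
                   files$survival, row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(cfg), config_hash = ens$config_hash,
         package_version = as.character(utils::packageVersion("pbsquench")),
         summary = summary),
    files$manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  invisible(list(network = net, rates = rates, ensemble = ens,
                 summary = summary, files = files))
}

#' Compute and export the coupling matrix only
#'
#' @param config A `run_config` or path to a YAML file.
#' @param path Output CSV path (defaults to `couplings.csv` under the
#'   configured output directory).
#' @return Invisibly, the `pigment_network`.
#' @export
cmd_couplings <- function(config = NULL, path = NULL) {
  cfg <- if (inherits(config, "run_config")) config else
    load_run_config(config)
  net <- .config_network(cfg)
  if (is.null(path)) {
    dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(cfg$output_dir, "couplings.csv")
  }
  write_coupling_csv(net, path)
  invisible(net)
}

#' Run the reduced internal validation suite
#'
#' Re-checks, at reduced size, the physical invariants the test suite
#' enforces: the Forster rate prefactor, the TrEsp to point-dipole limit,
#' Boltzmann equilibrium of the master equation on a closed network, and
#' agreement of the Gillespie engine with the master-equation survival.
#' Failures are report content, not errors.
#'
#' @param seed Seed for the stochastic checks (recorded in the report).
#' @param n_gillespie Trajectories for the engine check.
#' @return Data.frame `check`, `pass`, `value`, `target`, `seed`.
#' @export
cmd_validate <- function(seed = 42, n_gillespie = 2000) {
  rows <- list()
  add <- function(check, value, target, tol)
    rows[[length(rows) + 1]] <<- data.frame(
      check = check, pass = abs(value - target) <= tol, value = value,
      target = target, seed = seed)

  add("forster_rate_prefactor", forster_rate(1, 1), 1.18, 0)

  mu <- 0.1 * .const$eA_debye
  a <- transition_charges("a", rbind(c(0, 0, 0.5), c(0, 0, -0.5)),
                          c(0.1, -0.1))
  b <- transition_charges("b", rbind(c(50, 0, 0.5), c(50, 0, -0.5)),
                          c(0.1, -0.1))
  pda <- .const$c_pda * mu^2 / 50^3  # parallel, kappa = 1
  add("tresp_pda_limit_reldiff", tresp_coupling(a, b) / pda, 1, 0.01)

  E <- c(15152, 14900, 15400, 14706)
  set.seed(seed)
  pg <- pigment_table(paste0("p", 1:4), rep("APCA_PCB", 4),
                      matrix(stats::rnorm(12, sd = 30), 4),
                      matrix(stats::rnorm(12), 4),
                      tdm_D = 13, E_cm1 = E, kdecay_ps1 = 0,
                      lineshape = "pcb")
  V <- matrix(20, 4, 4); diag(V) <- 0
  net <- pigment_network(pg, V)
  rates <- build_rate_matrix(net, temperature = 300)
  pop <- master_equation_solve(rates, c(1, 0, 0, 0), c(2000, 4000))
  w <- exp(-E / (.const$kB_cm1 * 300)); w <- w / sum(w)
  add("boltzmann_equilibrium_maxrelerr",
      max(abs(pop[2, ] - w) / w), 0, 1e-6)

  pg2 <- pg
  pg2$kdecay_ps1 <- c(0.02, 0.01, 0.015, 0.01)
  rates2 <- build_rate_matrix(pigment_network(pg2, V), temperature = 300)
  set.seed(seed + 1)
  ens <- .gillespie_ensemble_cpp(rates2$transfer, unname(rates2$decay),
                                 rep(1L, n_gillespie))
  tchk <- stats::quantile(ens$decay_time, c(0.25, 0.5, 0.75))
  pop2 <- master_equation_solve(rates2, c(1, 0, 0, 0), unname(tchk))
  s_me <- rowSums(pop2)
  s_mc <- vapply(tchk, function(t) mean(ens$decay_time > t), 0)
  sigma <- sqrt(s_me * (1 - s_me) / n_gillespie)
  add("gillespie_vs_master_equation_maxz",
      max(abs(s_mc - s_me) / sigma), 0, 3)

  do.call(rbind, rows)
}
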