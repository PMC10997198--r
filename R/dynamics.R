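# Stochastic exciton dynamics: Gillespie trajectories on a rate matrix,
# ensembles with per-run resampled carotenoid parameters, survival and
# lifetime estimators, and a deterministic master-equation solver used as
# the reference for the stochastic engine.

#' Run one Gillespie trajectory
#'
#' Simulates a single excitation as a continuous-time Markov jump process on
#' the rate matrix: from pigment i with total exit rate Lambda = decay_i +
#' sum_j transfer_ij, the waiting time is Exponential(Lambda) and the channel
#' is chosen with probability proportional to its rate. The trajectory ends
#' at a decay event. Fully reproducible from `seed`.
#'
#' @param rates A [rate_matrix()].
#' @param start_index 1-based index of the initially excited pigment.
#' @param seed Integer RNG seed (`NULL` uses the current RNG stream).
#' @param record_hops Keep the full hop sequence (time, pigment index).
#' @return Object of class `trajectory`: `hops` (data.frame `time`,
#'   `pigment`), `decay_time` (ps), `terminal_index`, `terminal_id`,
#'   `n_hops`, `rng_seed`.
#' @export
gillespie_run <- function(rates, start_index, seed = NULL,
                          record_hops = TRUE) {
  stopifnot(inherits(rates, "rate_matrix"))
  n <- length(rates$labels)
  if (start_index < 1 || start_index > n) stop("start_index out of range")
  if (!is.null(seed)) set.seed(seed)
  res <- .gillespie_cpp(rates$transfer, unname(rates$decay),
                        as.integer(start_index), record_hops)
  structure(list(
    hops = data.frame(time = res$hop_times, pigment = res$hop_states),
    decay_time = res$decay_time,
    terminal_index = res$terminal,
    terminal_id = rates$labels[res$terminal],
    n_hops = res$n_hops,
    start_index = start_index,
    rng_seed = if (is.null(seed)) NA_integer_ else seed),
    class = "trajectory")
}

# Per-run seeds derived from the master seed: a fixed-seed draw of n distinct
# integers, so run r is individually replayable from ensemble$runs$seed[r].
.derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(2147483646L, n)
}

.hash_config <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Simulate an ensemble of exciton-decay trajectories
#'
#' For each run: carotenoid parameters (S1 energy and the two whitelisted
#' couplings) are drawn independently for every CAN pigment from
#' `can_spec`, the rate matrix is rebuilt with those values, a rod bilin is
#' picked uniformly at random as the start, and one Gillespie trajectory is
#' run. Per-run seeds are derived from `master_seed`, so the whole ensemble
#' is a pure function of its inputs.
#'
#' Networks with CAN pigments must carry `metadata$can_pairs` (columns
#' `can_id`, `pcb_id`, `rank` 1/2) naming each carotenoid's two coupling
#' partners; [make_toy_pbs()] records this automatically.
#'
#' @param network A `pigment_network` with assigned site properties.
#' @param can_spec A [can_parameter_spec()]; ignored when the network has no
#'   CAN pigment.
#' @param n_runs Number of trajectories (>= 1).
#' @param master_seed Integer master seed.
#' @param lineshape_library,temperature Passed to [build_rate_matrix()].
#' @param record_hops Keep full hop sequences (memory-heavy; default off).
#' @return Object of class `decay_ensemble`: `runs` (one row per trajectory:
#'   seed, start, decay time ps, terminal pigment and class, hop count),
#'   `sampled` (per run and per CAN: drawn vertical energy eV, 0-0 energy
#'   cm^-1, couplings cm^-1), `config_hash`, and optionally `trajectories`.
#' @export
run_ensemble <- function(network, can_spec = can_parameter_spec(),
                         n_runs = 100, master_seed = 1,
                         lineshape_library = default_lineshape_library(),
                         temperature = 300, record_hops = FALSE) {
  stopifnot(inherits(network, "pigment_network"), n_runs >= 1)
  pg <- network$pigments
  validate_pigments(pg, require_properties = TRUE)
  rod_idx <- which(pg$class == "ROD_PCB")
  if (length(rod_idx) == 0)
    stop("network has no ROD_PCB pigment to start the excitation from")
  can_idx <- which(pg$class == "CAN")
  has_can <- length(can_idx) > 0
  if (has_can) {
    cp <- network$metadata$can_pairs
    if (is.null(cp) || !all(c("can_id", "pcb_id", "rank") %in% names(cp)))
      stop("network metadata lacks can_pairs (can_id, pcb_id, rank)")
  }

  base <- build_rate_matrix(network, lineshape_library, temperature)
  seeds <- .derive_seeds(master_seed, n_runs)

  runs <- data.frame(run = seq_len(n_runs), seed = seeds,
                     start_index = NA_integer_, start_id = NA_character_,
                     decay_time_ps = NA_real_, terminal_index = NA_integer_,
                     terminal_id = NA_character_,
                     terminal_class = NA_character_, n_hops = NA_integer_)
  sampled_list <- vector("list", n_runs)
  traj_list <- if (record_hops) vector("list", n_runs) else NULL

  for (r in seq_len(n_runs)) {
    set.seed(seeds[r])
    rates <- base
    if (has_can) {
      draws <- sample_can_parameters(can_spec, length(can_idx))
      if (any(draws$e_s1_eV <= 0))
        stop("sampler returned a non-positive S1 energy (run ", r, ")")
      net_r <- network
      e00 <- ev_to_cm1(draws$e_s1_eV) - can_spec$e00_shift_cm1
      if (any(e00 <= 0))
        stop("sampler draw gives non-positive 0-0 energy (run ", r, ")")
      net_r$pigments$E_cm1[can_idx] <- e00
      cp <- network$metadata$can_pairs
      for (k in seq_along(can_idx)) {
        cid <- pg$id[can_idx[k]]
        for (rank in 1:2) {
          pid <- cp$pcb_id[cp$can_id == cid & cp$rank == rank]
          if (length(pid) != 1) next
          v <- if (rank == 1) draws$v1_cm1[k] else draws$v2_cm1[k]
          j <- match(pid, pg$id)
          net_r$couplings[can_idx[k], j] <- v
          net_r$couplings[j, can_idx[k]] <- v
        }
      }
      rates <- build_rate_matrix(net_r, lineshape_library, temperature,
                                 base = base, changed = can_idx)
      sampled_list[[r]] <- data.frame(run = r, can_id = pg$id[can_idx],
                                      e_s1_eV = draws$e_s1_eV,
                                      e00_cm1 = e00,
                                      v1_cm1 = draws$v1_cm1,
                                      v2_cm1 = draws$v2_cm1)
    }
    start <- rod_idx[sample.int(length(rod_idx), 1)]
    tr <- gillespie_run(rates, start, seed = NULL,
                        record_hops = record_hops)
    runs$start_index[r] <- start
    runs$start_id[r] <- pg$id[start]
    runs$decay_time_ps[r] <- tr$decay_time
    runs$terminal_index[r] <- tr$terminal_index
    runs$terminal_id[r] <- tr$terminal_id
    runs$terminal_class[r] <- pg$class[tr$terminal_index]
    runs$n_hops[r] <- tr$n_hops
    if (record_hops) traj_list[[r]] <- tr
  }

  structure(list(
    runs = runs,
    sampled = if (has_can) do.call(rbind, sampled_list) else NULL,
    trajectories = traj_list,
    config_hash = .hash_config(list(pigments = pg,
                                    couplings = network$couplings,
                                    can_spec = can_spec,
                                    n_runs = n_runs,
                                    master_seed = master_seed,
                                    temperature = temperature))),
    class = "decay_ensemble")
}

#' @export
print.decay_ensemble <- function(x, ...) {
  lt <- mean_lifetime(x)
  cat("<decay_ensemble> ", nrow(x$runs), " trajectories; mean lifetime ",
      signif(lt$mean_ps, 4), " +/- ", signif(lt$se_ps, 2), " ps; ",
      "quench fraction ", signif(quench_fraction(x), 3), "\n", sep = "")
  invisible(x)
}

#' Empirical survival curve of an ensemble
#'
#' P(t) is the fraction of trajectories still excited at time t, with a
#' normal-approximation binomial confidence band.
#'
#' @param ensemble A `decay_ensemble`.
#' @param time_grid Increasing vector of times, ps (non-empty).
#' @param conf Confidence level for the band.
#' @return Data.frame `t`, `P`, `ci_lo`, `ci_hi`.
#' @export
survival_curve <- function(ensemble, time_grid, conf = 0.95) {
  stopifnot(inherits(ensemble, "decay_ensemble"))
  if (length(time_grid) == 0) stop("time grid is empty")
  dt <- ensemble$runs$decay_time_ps
  n <- length(dt)
  p <- vapply(time_grid, function(t) mean(dt > t), 0)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(p * (1 - p) / n)
  data.frame(t = time_grid, P = p,
             ci_lo = pmax(0, p - z * se), ci_hi = pmin(1, p + z * se))
}

#' Mean excited-state lifetime of an ensemble
#'
#' Arithmetic mean of the decay times (equal to the area under the empirical
#' survival curve), with its standard error; a single-exponential fit of the
#' survival curve is reported alongside for comparison with fitted lifetime
#' components.
#'
#' @param ensemble A `decay_ensemble`.
#' @return List `mean_ps`, `se_ps`, `n`, `tau_exp_fit_ps`.
#' @export
mean_lifetime <- function(ensemble) {
  stopifnot(inherits(ensemble, "decay_ensemble"))
  dt <- ensemble$runs$decay_time_ps
  if (length(dt) == 0) stop("empty ensemble")
  m <- mean(dt)
  tau_fit <- tryCatch({
    tg <- stats::quantile(dt, probs = seq(0.05, 0.95, by = 0.05))
    sc <- survival_curve(ensemble, unname(tg))
    keep <- sc$P > 0
    # log-linear least squares on the empirical survival
    -1 / unname(stats::coef(stats::lm(log(sc$P[keep]) ~ sc$t[keep]))[2])
  }, error = function(e) NA_real_)
  list(mean_ps = m, se_ps = stats::sd(dt) / sqrt(length(dt)),
       n = length(dt), tau_exp_fit_ps = tau_fit)
}

#' Fraction of excitations terminating on a carotenoid
#'
#' Diagnostic for quenching efficiency: the fraction of trajectories whose
#' decay event happened on a CAN pigment (heat dissipation) rather than a
#' bilin (fluorescence/intrinsic loss).
#'
#' @param ensemble A `decay_ensemble`.
#' @return Fraction in [0, 1].
#' @export
quench_fraction <- function(ensemble) {
  stopifnot(inherits(ensemble, "decay_ensemble"))
  mean(ensemble$runs$terminal_class == "CAN")
}

#' Solve the master equation of a rate matrix
#'
#' Integrates dp/dt = K p with K assembled from the rate matrix
#' (off-diagonal K[j, i] = transfer i -> j; diagonal = minus total exit
#' rate), via deSolve's lsoda with tight tolerances. Population plus
#' cumulative decayed mass is conserved to 1e-8.
#'
#' @param rates A [rate_matrix()].
#' @param p0 Initial probability vector (non-negative, sums to 1).
#' @param times Increasing time grid, ps (0 is prepended if absent).
#' @param rtol,atol Integrator tolerances.
#' @return Matrix `length(times)` x n of populations, with attributes
#'   `times` and `decayed` (cumulative decayed mass per time point).
#' @export
master_equation_solve <- function(rates, p0, times,
                                  rtol = 1e-10, atol = 1e-12) {
  stopifnot(inherits(rates, "rate_matrix"))
  n <- length(rates$labels)
  if (length(p0) != n)
    stop("p0 length (", length(p0), ") does not match pigment count (", n,
         ")")
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-8)
    stop("p0 must be non-negative and sum to 1")
  K <- t(rates$transfer)
  diag(K) <- -(unname(rates$decay) + rowSums(rates$transfer))
  prepend <- times[1] > 0
  tt <- if (prepend) c(0, times) else times
  sol <- deSolve::ode(y = p0, times = tt,
                      func = function(t, y, parms) list(parms %*% y),
                      parms = K, method = "lsoda", rtol = rtol, atol = atol)
  pop <- unname(sol[, -1, drop = FALSE])
  if (prepend) pop <- pop[-1, , drop = FALSE]
  pop[pop < 0 & pop > -atol * 10] <- 0
  colnames(pop) <- rates$labels
  attr(pop, "times") <- times
  attr(pop, "decayed") <- 1 - rowSums(pop)
  pop
}

#' Flux splitting of the master equation
#'
#' Probability that the excitation decays through each pigment's intrinsic
#' channel: decay_i * integral of p_i(t) dt, computed exactly as
#' decay_i * (-K^-1 p0)_i. Used as the deterministic reference for
#' [quench_fraction()].
#'
#' @param rates A [rate_matrix()] with at least one positive decay rate.
#' @param p0 Initial probability vector.
#' @return Named vector of terminal-channel probabilities (sums to 1).
#' @export
terminal_channel_probabilities <- function(rates, p0) {
  stopifnot(inherits(rates, "rate_matrix"))
  K <- t(rates$transfer)
  diag(K) <- -(unname(rates$decay) + rowSums(rates$transfer))
  occ <- solve(-K, p0)  # integrated occupation time per pigment, ps
  stats::setNames(unname(rates$decay) * occ, rates$labels)
}

#' Mean lifetime from the master equation
#'
#' Exact mean decay time sum_i decay_i * t-weighted flux, computed as
#' 1' (-K)^-2 ... equivalently the integral of the survival function:
#' sum((-K)^-1 p0 summed over pigments).
#'
#' @param rates A [rate_matrix()].
#' @param p0 Initial probability vector.
#' @return Mean lifetime, ps.
#' @export
master_equation_mean_lifetime <- function(rates, p0) {
  stopifnot(inherits(rates, "rate_matrix"))
  K <- t(rates$transfer)
  diag(K) <- -(unname(rates$decay) + rowSums(rates$transfer))
  sum(solve(-K, p0))
}
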