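# Shared fixture builders. Everything is generated in code; no data files.

# Random fully-assigned pigment table of n bilins in a blob of the given
# spatial scale (Angstrom).
random_pigments <- function(n, seed, scale = 30,
                            E_range = c(14500, 16200),
                            decay_range = c(0.005, 0.02)) {
  set.seed(seed)
  pigment_table(
    id = sprintf("p%02d", seq_len(n)),
    class = rep("APCA_PCB", n),
    position = matrix(rnorm(3 * n, sd = scale), n),
    tdm_direction = matrix(rnorm(3 * n), n),
    tdm_D = 13,
    E_cm1 = runif(n, E_range[1], E_range[2]),
    kdecay_ps1 = runif(n, decay_range[1], decay_range[2]),
    lineshape = "pcb"
  )
}

# Random symmetric coupling matrix with zero diagonal, all pairs coupled.
random_couplings <- function(n, seed, vmax = 30) {
  set.seed(seed)
  V <- matrix(0, n, n)
  V[upper.tri(V)] <- runif(n * (n - 1) / 2, 2, vmax)
  V + t(V)
}

# Random decaying network plus its rate matrix.
random_rate_network <- function(n, seed, decay_range = c(0.005, 0.02)) {
  pg <- random_pigments(n, seed, decay_range = decay_range)
  net <- pigment_network(pg, random_couplings(n, seed + 1))
  list(network = net, rates = build_rate_matrix(net, temperature = 300))
}

# A discretized dipole: +/- q charges `extent` apart, centred at `center`,
# oriented along unit vector `axis`.
discretized_dipole <- function(id, center, axis, q = 0.1, extent = 1) {
  axis <- axis / sqrt(sum(axis^2))
  transition_charges(
    id,
    rbind(center + axis * extent / 2, center - axis * extent / 2),
    c(q, -q)
  )
}

# Minimal decay ensemble wrapping given decay times (for estimator tests).
ensemble_from_times <- function(times, terminal_class = "ROD_PCB") {
  structure(list(
    runs = data.frame(run = seq_along(times), seed = NA_integer_,
                      start_index = 1L, start_id = "p1",
                      decay_time_ps = times, terminal_index = 1L,
                      terminal_id = "p1",
                      terminal_class = rep_len(terminal_class,
                                               length(times)),
                      n_hops = 0L),
    sampled = NULL, trajectories = NULL, config_hash = "test"),
    class = "decay_ensemble")
}

# Small quenched network: 1 rod bilin, 2 core ApcA, 1 carotenoid wired to
# both ApcA, with can_pairs metadata so run_ensemble can resample it.
tiny_quenched_network <- function(v1 = 54, v2 = 27) {
  cfg <- toy_pbs_config(n_rods = 1, pigments_per_rod = 2,
                        core_cylinders = 1, pigments_per_cylinder = 4,
                        n_can = 1, seed = 3)
  make_toy_pbs(cfg, coupling_means = c(v1, v2))
}

kB300 <- function() physical_constants()$kB_cm1 * 300
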