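# Gillespie engine, ensembles, estimators, and the master-equation oracle.

test_that("gillespie_run: exponential waiting statistics, confinement, determinism", {
  # single pigment, decay 1 ps^-1: mean over 1e4 runs = 1.00 +/- 3 SE
  r1 <- rate_matrix(matrix(0, 1, 1), 1)
  set.seed(7)
  dts <- pbsquench:::.gillespie_ensemble_cpp(r1$transfer, unname(r1$decay),
                                             rep(1L, 10000))$decay_time
  expect_lt(abs(mean(dts) - 1), 3 * sd(dts) / sqrt(10000))

  # two pigments, zero coupling: the second is never visited
  r2 <- rate_matrix(matrix(0, 2, 2), c(0.5, 0.5))
  tr <- gillespie_run(r2, 1, seed = 11)
  expect_equal(nrow(tr$hops), 0)
  expect_equal(tr$terminal_index, 1)

  # identical seed and inputs give a bit-identical trajectory
  rr <- random_rate_network(5, seed = 13)$rates
  t1 <- gillespie_run(rr, 2, seed = 99)
  t2 <- gillespie_run(rr, 2, seed = 99)
  expect_identical(t1, t2)
  # hop times strictly increase and the decay time bounds them
  expect_true(all(diff(c(0, t1$hops$time)) > 0))
  expect_gte(t1$decay_time, max(c(0, t1$hops$time)))
  expect_equal(t1$terminal_index,
               if (nrow(t1$hops) > 0) t1$hops$pigment[nrow(t1$hops)] else 2)

  # an absorbing state with no exit channel is an explicit error
  r0 <- rate_matrix(matrix(0, 1, 1), 0)
  expect_error(gillespie_run(r0, 1, seed = 1), "non-terminating")
})

test_that("master_equation_solve reproduces analytic solutions and conserves probability", {
  # scalar decay: p(t) = exp(-k t)
  r1 <- rate_matrix(matrix(0, 1, 1), 0.2)
  tt <- c(1, 5, 10)
  pop <- master_equation_solve(r1, 1, tt)
  expect_equal(unname(pop[, 1]), exp(-0.2 * tt), tolerance = 1e-8)
  # closed symmetric two-state exchange: populations -> 1/2, 1/2
  r2 <- rate_matrix(matrix(c(0, 0.3, 0.3, 0), 2), c(0, 0))
  pop2 <- master_equation_solve(r2, c(1, 0), c(0.5, 50))
  expect_equal(unname(pop2[2, ]), c(0.5, 0.5), tolerance = 1e-8)
  # analytic relaxation at the intermediate time
  expect_equal(unname(pop2[1, 1]), 0.5 * (1 + exp(-2 * 0.3 * 0.5)),
               tolerance = 1e-8)
  expect_equal(rowSums(pop2), c(1, 1), tolerance = 1e-8)
  # against an independent matrix-exponential oracle on a decaying network
  rr <- random_rate_network(6, seed = 17)$rates
  K <- t(rr$transfer); diag(K) <- -(unname(rr$decay) + rowSums(rr$transfer))
  p0 <- c(1, rep(0, 5))
  tt <- c(2, 20, 100)
  pop3 <- master_equation_solve(rr, p0, tt)
  for (i in seq_along(tt)) {
    oracle <- as.numeric(Matrix::expm(K * tt[i]) %*% p0)
    expect_equal(unname(pop3[i, ]), oracle, tolerance = 1e-7)
  }
  expect_true(all(attr(pop3, "decayed") >= 0))
  expect_error(master_equation_solve(rr, c(1, 0), tt), "length")
  expect_error(master_equation_solve(rr, c(2, rep(0, 5)), tt), "sum to 1")
})

test_that("Gillespie survival matches master-equation survival on random networks", {
  # the core engine property: ensemble survival within 3 sigma binomial
  # error of the deterministic solution at 10 checkpoints
  n_runs <- 10000
  rr <- random_rate_network(6, seed = 19)$rates
  set.seed(23)
  ens <- pbsquench:::.gillespie_ensemble_cpp(rr$transfer, unname(rr$decay),
                                             rep(1L, n_runs))
  pop <- master_equation_solve(rr, c(1, rep(0, 5)),
                               tq <- unname(quantile(ens$decay_time,
                                                     seq(0.05, 0.95,
                                                         length.out = 10))))
  s_me <- rowSums(pop)
  s_mc <- vapply(tq, function(t) mean(ens$decay_time > t), 0)
  sigma <- sqrt(s_me * (1 - s_me) / n_runs)
  expect_true(all(abs(s_mc - s_me) <= 3 * sigma))
})

test_that("survival_curve has the contracted step, exponential and monotone behaviour", {
  e5 <- ensemble_from_times(rep(5, 40))
  sc <- survival_curve(e5, c(0, 2, 4.999, 5, 6))
  expect_equal(sc$P, c(1, 1, 1, 0, 0))
  set.seed(29)
  k <- 0.05
  ee <- ensemble_from_times(rexp(4000, k))
  sce <- survival_curve(ee, c(5, 10, 20, 40, 80))
  expect_true(all(sce$ci_lo <= exp(-k * sce$t) & exp(-k * sce$t) <= sce$ci_hi))
  # non-increasing for arbitrary ensembles
  er <- ensemble_from_times(runif(200, 0, 100))
  scr <- survival_curve(er, seq(0, 120, 5))
  expect_true(all(diff(scr$P) <= 0))
  expect_equal(scr$P[1], 1)
  expect_error(survival_curve(er, numeric(0)), "empty")
})

test_that("mean_lifetime is the arithmetic mean with a sane exponential fit", {
  lt <- mean_lifetime(ensemble_from_times(c(1, 2, 3)))
  expect_equal(lt$mean_ps, 2)
  expect_equal(lt$se_ps, sd(c(1, 2, 3)) / sqrt(3))
  set.seed(31)
  ee <- ensemble_from_times(rexp(10000, 0.01))
  lte <- mean_lifetime(ee)
  expect_lt(abs(lte$mean_ps - 100), 3 * lte$se_ps)
  expect_equal(lte$tau_exp_fit_ps, 100, tolerance = 0.1)
  expect_gte(mean_lifetime(ensemble_from_times(runif(50)))$mean_ps, 0)
})

test_that("quench_fraction matches the master-equation flux splitting", {
  # deterministic CAN parameters (sd = 0) so every run shares one rate matrix
  net <- tiny_quenched_network()
  spec0 <- can_parameter_spec(e_s1_sd = 0, coupling_sds = c(0, 0))
  ens <- run_ensemble(net, spec0, n_runs = 3000, master_seed = 37)
  qf <- quench_fraction(ens)
  rates <- build_rate_matrix(net)
  can_idx <- which(net$pigments$class == "CAN")
  rod_idx <- which(net$pigments$class == "ROD_PCB")
  # oracle: decay_i * integrated occupation, averaged over uniform rod starts
  fl <- rowMeans(vapply(rod_idx, function(s) {
    p0 <- numeric(nrow(net$pigments)); p0[s] <- 1
    terminal_channel_probabilities(rates, p0)
  }, numeric(nrow(net$pigments))))
  q_oracle <- sum(fl[can_idx])
  expect_lt(abs(qf - q_oracle), 3 * sqrt(q_oracle * (1 - q_oracle) / 3000))
  # no carotenoid -> no quenching channel
  netu <- make_toy_pbs(toy_pbs_config(n_rods = 1, pigments_per_rod = 2,
                                      core_cylinders = 1,
                                      pigments_per_cylinder = 4, n_can = 0,
                                      seed = 3))
  ensu <- run_ensemble(netu, n_runs = 50, master_seed = 37)
  expect_equal(quench_fraction(ensu), 0)
})

test_that("run_ensemble is reproducible, records draws, and matches the oracle without quenchers", {
  net <- tiny_quenched_network()
  e1 <- run_ensemble(net, n_runs = 40, master_seed = 41)
  e2 <- run_ensemble(net, n_runs = 40, master_seed = 41)
  expect_identical(e1$runs, e2$runs)
  expect_identical(e1$sampled, e2$sampled)
  expect_identical(e1$config_hash, e2$config_hash)
  expect_false(identical(
    e1$runs, run_ensemble(net, n_runs = 40, master_seed = 42)$runs))
  # one draw per carotenoid per run, positive and recorded
  expect_equal(nrow(e1$sampled), 40 * sum(net$pigments$class == "CAN"))
  expect_true(all(e1$sampled$e00_cm1 > 0))
  expect_true(all(e1$runs$start_id %in%
                    net$pigments$id[net$pigments$class == "ROD_PCB"]))

  # with no carotenoid, the ensemble mean equals the master-equation mean
  netu <- make_toy_pbs(toy_pbs_config(n_rods = 1, pigments_per_rod = 2,
                                      core_cylinders = 1,
                                      pigments_per_cylinder = 4, n_can = 0,
                                      seed = 3))
  ensu <- run_ensemble(netu, n_runs = 2500, master_seed = 43)
  rates_u <- build_rate_matrix(netu)
  rod_idx <- which(netu$pigments$class == "ROD_PCB")
  mlt <- mean(vapply(rod_idx, function(s) {
    p0 <- numeric(nrow(netu$pigments)); p0[s] <- 1
    master_equation_mean_lifetime(rates_u, p0)
  }, 0))
  lt <- mean_lifetime(ensu)
  expect_lt(abs(lt$mean_ps - mlt), 3 * lt$se_ps)

  # a network without rod pigments cannot be started
  core_only <- make_toy_pbs(toy_pbs_config(n_rods = 0, pigments_per_rod = 0,
                                           core_cylinders = 1,
                                           pigments_per_cylinder = 4,
                                           n_can = 0, seed = 3))
  expect_error(run_ensemble(core_only, n_runs = 2, master_seed = 1),
               "ROD_PCB")
})

test_that("strengthening a quencher coupling never lengthens the lifetime", {
  # deterministic check across a coupling grid via the master equation
  vgrid <- c(10, 27, 54, 90, 150)
  lts <- vapply(vgrid, function(v) {
    net <- tiny_quenched_network(v1 = v, v2 = v / 2)
    rates <- build_rate_matrix(net)
    p0 <- as.numeric(net$pigments$id == "R1_01")
    master_equation_mean_lifetime(rates, p0)
  }, 0)
  expect_true(all(diff(lts) < 0))
})
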