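# TrEsp and point-dipole couplings, matrix assembly, dipole fold change.

test_that("TrEsp Coulomb constant matches the CODATA-derived value", {
  # +1e and +1e separated by 1 Angstrom: V = K itself
  a <- transition_charges("a", rbind(c(0, 0, 0)), 1, sum_tolerance = Inf)
  b <- transition_charges("b", rbind(c(1, 0, 0)), 1, sum_tolerance = Inf)
  v <- tresp_coupling(a, b)
  expect_equal(v, physical_constants()$k_tresp)
  # independently: e^2/(4 pi eps0 Angstrom) = 14.3996 eV * 8065.544 cm^-1/eV
  expect_equal(v, 14.3996454 * 8065.544, tolerance = 1e-6)
})

test_that("tresp_coupling is symmetric, linear in charges, and rejects coincident atoms", {
  set.seed(21)
  for (rep in 1:5) {
    qa <- rnorm(6); qa <- qa - mean(qa)
    qb <- rnorm(5); qb <- qb - mean(qb)
    a <- transition_charges("a", matrix(rnorm(18), 6), qa)
    b <- transition_charges("b", matrix(rnorm(15), 5) + 20, qb)
    expect_equal(tresp_coupling(a, b), tresp_coupling(b, a))
    a2 <- transition_charges("a", a$positions, 2 * qa)
    expect_equal(tresp_coupling(a2, b), 2 * tresp_coupling(a, b))
  }
  a <- transition_charges("a", rbind(c(0, 0, 0), c(1, 0, 0)), c(0.1, -0.1))
  b <- transition_charges("b", rbind(c(1, 0, 0), c(2, 0, 0)), c(0.1, -0.1))
  expect_error(tresp_coupling(a, b), "coincident")
})

test_that("point-dipole coupling reproduces the analytic kappa geometries", {
  mk <- function(pos, u) pigment_table("p", "APCA_PCB", rbind(pos), rbind(u),
                                       tdm_D = 7, E_cm1 = 15152,
                                       kdecay_ps1 = 0, lineshape = "pcb")
  C <- physical_constants()$c_pda
  # parallel dipoles perpendicular to R: kappa = 1
  a <- mk(c(0, 0, 0), c(0, 0, 1)); b <- mk(c(15, 0, 0), c(0, 0, 1))
  v_perp <- point_dipole_coupling(a, b)
  expect_equal(v_perp, C * 49 / 15^3)
  expect_equal(v_perp, 73.2, tolerance = 0.01)  # quoted with C ~ 5040
  # head-to-tail collinear: kappa = -2 -> twice the magnitude, opposite sign
  b2 <- mk(c(15, 0, 0), c(1, 0, 0)); a2 <- mk(c(0, 0, 0), c(1, 0, 0))
  expect_equal(point_dipole_coupling(a2, b2), -2 * v_perp)
  # kappa bound for random unit vectors
  set.seed(31)
  for (rep in 1:50) {
    u1 <- rnorm(3); u1 <- u1 / sqrt(sum(u1^2))
    u2 <- rnorm(3); u2 <- u2 / sqrt(sum(u2^2))
    rh <- rnorm(3); rh <- rh / sqrt(sum(rh^2))
    k <- orientation_factor(u1, u2, rh)
    expect_gte(k, -2); expect_lte(k, 2)
  }
  expect_error(point_dipole_coupling(a, a), "coincident")
})

test_that("TrEsp converges to the point-dipole limit as separation grows", {
  # two discretized 0.1 e dipoles of 1 Angstrom extent, parallel,
  # perpendicular to the separation axis
  mu_D <- tcs_dipole_debye(discretized_dipole("u", c(0, 0, 0), c(0, 0, 1)))
  C <- physical_constants()$c_pda
  reldiff <- vapply(c(10, 25, 50, 100), function(R) {
    a <- discretized_dipole("a", c(0, 0, 0), c(0, 0, 1))
    b <- discretized_dipole("b", c(R, 0, 0), c(0, 0, 1))
    v_pda <- C * mu_D^2 / R^3  # kappa = 1
    abs(tresp_coupling(a, b) - v_pda) / v_pda
  }, 0)
  # monotone decay with distance; < 1% beyond 25x the intra-dipole extent
  expect_true(all(diff(reldiff) < 0))
  expect_lt(reldiff[2], 0.01)
  expect_lt(reldiff[3], 0.01)
})

test_that("build_coupling_matrix: PDA block, whitelisted sampled entries, zeros elsewhere", {
  net <- tiny_quenched_network(v1 = 54, v2 = 27)
  V <- net$couplings
  expect_equal(V, t(V))
  expect_equal(unname(diag(V)), rep(0, nrow(V)))
  cp <- net$metadata$can_pairs
  expect_equal(V["CAN_1", cp$pcb_id[cp$rank == 1]], 54)
  expect_equal(V["CAN_1", cp$pcb_id[cp$rank == 2]], 27)
  # every non-whitelisted carotenoid entry is exactly zero
  can_row <- V["CAN_1", ]
  expect_equal(sum(can_row != 0), 2)
  # bilin-bilin entries agree with the pairwise PDA operator
  pg <- net$pigments
  i <- match("R1_01", pg$id); j <- match("R1_02", pg$id)
  expect_equal(V[i, j], point_dipole_coupling(pg[i, ], pg[j, ]))
  # missing sampled value for a whitelisted pair is a named error
  rules <- coupling_rules("SAMPLED",
                          can_pcb_whitelist = data.frame(
                            can_id = "CAN_1", pcb_id = cp$pcb_id[1]))
  expect_error(build_coupling_matrix(net, rules, sampled = NULL), "CAN_1")
  # single pigment -> 1x1 zero matrix
  one <- pigment_network(random_pigments(1, seed = 2), matrix(0, 1, 1))
  out <- build_coupling_matrix(one, coupling_rules("SAMPLED"))
  expect_equal(unname(out$couplings), matrix(0, 1, 1))
})

test_that("tdm_fold_change is the antisymmetric log ratio", {
  expect_equal(tdm_fold_change(7, 7), 0)
  expect_equal(tdm_fold_change(7 / 3, 7), log10(1 / 3))  # threefold drop
  expect_equal(tdm_fold_change(7 / 3, 7), -0.477, tolerance = 1e-3)
  set.seed(41)
  a <- runif(10, 0.1, 20); b <- runif(10, 0.1, 20)
  expect_equal(tdm_fold_change(a, b), -tdm_fold_change(b, a))
  expect_equal(tdm_fold_change(a, b, base = exp(1)), log(a / b))
  expect_error(tdm_fold_change(-1, 7), "positive")
})

test_that("transition-charge sets validate neutrality and declared dipoles; tables round-trip", {
  expect_error(transition_charges("x", matrix(0, 2, 3), 1), "equal lengths")
  expect_error(transition_charges("x", rbind(c(0, 0, 0), c(1, 0, 0)),
                                  c(0.5, -0.4)), "neutral")
  # +/- 0.1 e at 1 Angstrom: dipole = 0.1 e*A ~ 0.48032 D
  tcs <- transition_charges("x", rbind(c(0, 0, 0), c(1, 0, 0)),
                            c(0.1, -0.1), declared_tdm_D = 0.48032)
  expect_equal(tcs_dipole_debye(tcs), 0.480321, tolerance = 1e-5)
  expect_error(transition_charges("x", rbind(c(0, 0, 0), c(1, 0, 0)),
                                  c(0.1, -0.1), declared_tdm_D = 7),
               "deviates")
  f <- withr::local_tempfile(fileext = ".txt")
  write_charge_table(tcs, f)
  back <- read_charge_table(f)
  expect_equal(back$charges, tcs$charges)
  expect_equal(back$positions, tcs$positions, ignore_attr = TRUE)
})

test_that("coupling matrix CSV round-trips symmetrically", {
  net <- tiny_quenched_network()
  f <- withr::local_tempfile(fileext = ".csv")
  write_coupling_csv(net, f)
  back <- read_coupling_csv(f)
  expect_equal(back, net$couplings, tolerance = 1e-12)
  expect_equal(back, t(back), tolerance = 1e-12)
})
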