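test_that("derivatives match the equation structure at the injection state", {
  p <- headline_params()
  d <- six_comp_rhs(c(100, 0, 0, 0, 0, 0), p)
  expect_equal(d[["xb"]],
               -(p$K_el + p$K_bp + p$K_bt + p$k_b * p$K_bm) * 100)
  expect_equal(d[["xp"]], p$K_bp * 100)
  expect_equal(d[["xt"]], p$K_bt * 100)
  expect_equal(d[["mb"]], p$k_b * p$K_bm * 100)
  expect_identical(d[["mp"]], 0)
  expect_identical(d[["mt"]], 0)
  expect_error(six_comp_rhs(c(-1, 0, 0, 0, 0, 0), p), "invalid state")
})

test_that("elimination is the only sink: derivative sum equals -K_el * xb", {
  set.seed(13)
  for (i in 1:100) {
    p <- random_six_params()
    s <- runif(6, 0, 50)
    d <- six_comp_rhs(s, p)
    expect_lt(abs(sum(d) + p$K_el * s[1]), 1e-10 * max(sum(abs(d)), 1))
  }
  pz <- six_compartment_params(0, 0, 0)
  expect_equal(unname(six_comp_rhs(c(10, 1, 1, 1, 1, 1), pz)), rep(0, 6))
})

test_that("parameter assembly applies the tumor-exchange scaling and phenotype map", {
  p <- headline_params()
  expect_equal(signif(p$K_bt, 2), 0.0088)
  expect_equal(signif(p$K_tb, 2), 0.0011)
  expect_lte(p$K_bt, p$K_bp)
  expect_lte(p$K_tb, p$K_pb)
  # macrophage rates: M0 in blood, M1 in peripheral and tumor
  expect_equal(p$K_bm, 0.00092)
  expect_equal(p$K_mb, 0.11562)
  expect_equal(p$K_pm, 0.00101)
  expect_equal(p$K_mp, 0)
  expect_equal(p$K_tm, 0.00101)
  expect_equal(p$K_mt, 0)
  expect_equal(p$k_b, 40)

  expect_error(assemble_params(table1_params(100), load_bundled_rate_tables(),
                               "BNF-Unknown"), "missing parameter")
})

test_that("simulated trajectory conserves mass and starts from the injection state", {
  traj <- simulate_six_compartment(headline_params())
  expect_identical(traj$time_h[1], 0)
  expect_equal(traj$xb[1], 100)
  expect_equal(unname(unlist(traj[1, c("xp", "xt", "mb", "mp", "mt",
                                       "eliminated")])), rep(0, 6))
  total <- rowSums(traj[, c("xb", "xp", "xt", "mb", "mp", "mt", "eliminated")])
  expect_lt(max(abs(total - 100)), 1e-6)
  expect_true(all(as.matrix(traj[, -1]) > -1e-9))
})

test_that("the headline simulation reproduces the known retention levels", {
  traj <- simulate_six_compartment(headline_params())
  n <- nrow(traj)
  expect_equal(traj$xt[n] + traj$mt[n], 1, tolerance = 0.3)
  expect_equal(traj$xp[n] + traj$mp[n], 40, tolerance = 0.3)
})

test_that("ODE solution matches the matrix-exponential closed form", {
  skip_if_not_installed("Matrix")
  p <- headline_params()
  traj <- simulate_six_compartment(p, times = c(0, 1, 12, 48))
  for (i in 2:4) {
    ref <- expm_state(p, traj$time_h[i])
    got <- unname(unlist(traj[i, c("xb", "xp", "xt", "mb", "mp", "mt")]))
    expect_lt(max(abs(got - ref)) / p$X0, 1e-8)
  }
})

test_that("reduction chain: six to three to two compartments", {
  tc <- table1_params(100)
  # k = 0: macrophage pools decouple; three-compartment model
  p3 <- assemble_params(tc, load_bundled_rate_tables(), "BNF-Plain",
                        k_factors = c(0, 0, 0))
  traj3 <- simulate_six_compartment(p3)
  expect_lt(max(abs(traj3$mb) + abs(traj3$mp) + abs(traj3$mt)), 1e-10)

  # additionally no tumor exchange: exact two-compartment reduction
  p2 <- six_compartment_params(K_el = tc$K_el, K_bp = tc$K_bp, K_pb = tc$K_pb,
                               k_b = 0, k_p = 0, k_t = 0)
  traj2 <- simulate_six_compartment(p2)
  expect_lt(max(rel_err(traj2$xb, xb_analytic(tc, traj2$time_h), floor = 1e-3)),
            1e-6)
  expect_lt(max(rel_err(traj2$xp, xp_analytic(tc, traj2$time_h), floor = 1e-3)),
            1e-6)
  expect_lt(max(abs(traj2$xt)), 1e-10)
})

test_that("trajectories scale linearly in the injected dose", {
  p1 <- headline_params()
  p5 <- p1
  p5$X0 <- 500
  t1 <- simulate_six_compartment(p1, n_points = 49)
  t5 <- simulate_six_compartment(p5, n_points = 49)
  cols <- c("xb", "xp", "xt", "mb", "mp", "mt", "eliminated")
  expect_lt(max(abs(as.matrix(t5[, cols]) - 5 * as.matrix(t1[, cols]))) / 500,
            1e-10)
})

test_that("states stay nonnegative and absorbing macrophage pools grow monotonically", {
  set.seed(17)
  for (i in 1:10) {
    p <- random_six_params()
    traj <- simulate_six_compartment(p, n_points = 97)
    expect_gt(min(as.matrix(traj[, -1])), -1e-8)
  }
  p <- headline_params()  # K_mt = K_mp = 0: tumor/peripheral pools absorb
  traj <- simulate_six_compartment(p)
  expect_gte(min(diff(traj$mt)), -1e-10)
  expect_gte(min(diff(traj$mp)), -1e-10)
})

test_that("retention decomposition splits passive and active exactly", {
  traj <- simulate_six_compartment(headline_params())
  dec <- retention_decomposition(traj)
  expect_lt(max(abs(dec$passive + dec$active - dec$total)), 1e-12)
  tum <- dec[dec$compartment == "tumor", ]
  expect_lt(max(abs(tum$total - (traj$xt + traj$mt))), 1e-12)
  # macrophage-internalized content eventually dominates retention: the
  # peripheral crossing falls near 13 h, the tumor crossing near 26 h, and
  # both stay dominated by the active pool thereafter
  per <- dec[dec$compartment == "peripheral", ]
  cross_p <- min(per$time_h[per$active > per$passive])
  cross_t <- min(tum$time_h[tum$active > tum$passive])
  expect_lt(cross_p, 15)
  expect_lt(cross_t, 30)
  expect_true(all(tum$active[tum$time_h >= cross_t] >
                    tum$passive[tum$time_h >= cross_t]))
  expect_true(all(per$active[per$time_h >= cross_p] >
                    per$passive[per$time_h >= cross_p]))

  # no multiplication factors: no active retention anywhere
  p0 <- assemble_params(table1_params(100), load_bundled_rate_tables(),
                        "BNF-Plain", k_factors = c(0, 0, 0))
  dec0 <- retention_decomposition(simulate_six_compartment(p0))
  expect_identical(max(abs(dec0$active)), 0)
})

test_that("delivery metrics locate endpoints and peaks", {
  traj <- simulate_six_compartment(headline_params())
  m <- delivery_metrics(traj)
  n <- nrow(traj)
  expect_equal(m$tumor_total_end, traj$xt[n] + traj$mt[n])
  expect_equal(m$peripheral_total_end, traj$xp[n] + traj$mp[n])
  expect_gte(m$tumor_peak, m$tumor_total_end)
  # tumor content is monotone here (absorbing macrophage pool dominates),
  # so the peak sits at the horizon
  expect_equal(m$tumor_peak_time_h, traj$time_h[n], tolerance = 1e-6)

  # no routes into the tumor: all tumor metrics vanish
  pz <- six_compartment_params(K_el = 0.471, K_bp = 17.613, K_pb = 2.241)
  mz <- delivery_metrics(simulate_six_compartment(pz, n_points = 25))
  expect_identical(mz$tumor_total_end, 0)
  expect_identical(mz$tumor_peak, 0)
})

test_that("parameter sweeps leave the base unchanged and respond in the expected direction", {
  base <- headline_params()
  one <- sweep_parameter(base, "K_pb", 1, n_points = 49)
  ref <- simulate_six_compartment(base, n_points = 49)
  expect_equal(as.data.frame(one[[1]]), as.data.frame(ref))

  fam <- sweep_parameter(base, "K_pb", c(1, 2, 4, 8), n_points = 49)
  expect_identical(base$K_pb, headline_params()$K_pb)
  tum48 <- vapply(fam, function(tr) {
    n <- nrow(tr); tr$xt[n] + tr$mt[n]
  }, numeric(1))
  expect_true(all(diff(tum48) >= 0))

  fam2 <- sweep_parameter(base, "K_pm", c(1, 0.5, 0.25, 0.1), n_points = 49)
  per48 <- vapply(fam2, function(tr) {
    n <- nrow(tr); tr$xp[n] + tr$mp[n]
  }, numeric(1))
  expect_true(all(diff(per48) <= 0))

  expect_error(sweep_parameter(base, "K_zz", 1), "unknown parameter")
  expect_error(sweep_parameter(base, "K_pb", c(1, 0)), "positive")
})

test_that("the passive-only scenario behaves as the model family limit", {
  tc <- table1_params(100)
  # y = 0: tumor never receives mass
  t0 <- passive_only_scenario(tc, y = 0, n_points = 49)
  expect_identical(max(abs(t0$xt) + abs(t0$mt)), 0)

  # y = 0.0005, k = 0 equals the three-compartment reduction
  tp <- passive_only_scenario(tc, y = 0.0005, n_points = 49)
  p3 <- six_compartment_params(K_el = tc$K_el, K_bp = tc$K_bp, K_pb = tc$K_pb,
                               K_bt = 0.0005 * tc$K_bp,
                               K_tb = 0.0005 * tc$K_pb,
                               k_b = 0, k_p = 0, k_t = 0)
  t3 <- simulate_six_compartment(p3, n_points = 49)
  expect_equal(as.data.frame(tp), as.data.frame(t3), tolerance = 1e-12)

  # strong passive tumor exchange trades peripheral uptake for clearance
  tpass <- passive_only_scenario(tc, y = 0.44)
  tact <- simulate_six_compartment(headline_params())
  n <- nrow(tpass)
  expect_lt(tpass$xp[n] + tpass$mp[n], tact$xp[n] + tact$mp[n])
})
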