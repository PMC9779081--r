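test_that("internalization solution satisfies boundary, limiting and steady-state cases", {
  p <- uptake_params(0.00092, 0.11562)
  expect_identical(xin_analytic(p, 0), 0)
  expect_identical(xout_analytic(p, 0), p$X0)

  # zero efflux: saturating exponential toward the full dose
  p0 <- uptake_params(0.00101, 0)
  tt <- c(0, 3, 6, 12, 24)
  expect_equal(xin_analytic(p0, tt), 1 - exp(-0.00101 * tt), tolerance = 1e-12)

  # steady states are the nonzero equilibrium split of the initial amount
  expect_equal(xin_analytic(p, 1e7), p$K_in * p$X0 / (p$K_in + p$K_out),
               tolerance = 1e-9)
  expect_equal(xout_analytic(p, 1e7), p$K_out * p$X0 / (p$K_in + p$K_out),
               tolerance = 1e-9)
  expect_error(uptake_params(0, 0), "ill-posed")
})

test_that("intracellular and extracellular amounts conserve the initial dose", {
  set.seed(3)
  for (i in 1:100) {
    p <- uptake_params(runif(1, 1e-4, 0.01), runif(1, 0, 0.3),
                       X0 = runif(1, 0.1, 10))
    t <- runif(1, 0, 48)
    expect_lt(abs(xin_analytic(p, t) + xout_analytic(p, t) - p$X0), 1e-12)
  }
})

test_that("internalization is monotone nondecreasing and concave", {
  set.seed(5)
  tt <- seq(0, 48, length.out = 400)
  for (i in 1:20) {
    p <- uptake_params(runif(1, 1e-4, 0.05), runif(1, 0, 0.3))
    v <- xin_analytic(p, tt)
    d1 <- diff(v)
    expect_gte(min(d1), -1e-14)
    expect_lte(max(diff(d1)), 1e-14)
  }
})

test_that("uptake fit recovers truth and flags boundary hits", {
  tt <- c(3, 6, 12, 24)
  p <- uptake_params(0.00092, 0.11562)
  fit <- fit_uptake(data.frame(time_h = tt, value = xin_analytic(p, tt)))
  expect_true(fit$converged)
  expect_lt(rel_err(fit$estimates[["K_in"]], 0.00092), 1e-4)
  expect_lt(rel_err(fit$estimates[["K_out"]], 0.11562), 1e-4)
  expect_false(any(fit$boundary_flags))

  # zero-efflux truth: estimate pinned at the zero bound and flagged
  p0 <- uptake_params(0.00101, 0)
  fit0 <- fit_uptake(data.frame(time_h = tt, value = xin_analytic(p0, tt)))
  expect_lt(fit0$estimates[["K_out"]], 1e-6)
  expect_true(fit0$boundary_flags[["K_out"]])
  expect_lt(rel_err(fit0$estimates[["K_in"]], 0.00101), 1e-4)

  # noisy zero-efflux data: boundary estimate carries a nonzero profile SE
  set.seed(21)
  d <- data.frame(time_h = rep(tt, times = c(3, 2, 1, 3)))
  d$value <- pmax(xin_analytic(p0, d$time_h) * (1 + rnorm(nrow(d), 0, 0.1)), 0)
  fitn <- fit_uptake(d, weighting = "uniform")
  if (fitn$boundary_flags[["K_out"]])
    expect_gt(fitn$standard_errors[["K_out"]], 0)

  expect_error(fit_uptake(data.frame(time_h = c(3, 6), value = c(1, 2))),
               "insufficient")
  expect_error(fit_uptake(data.frame(time_h = tt, value = rep(0, 4))),
               "insufficient")
})

test_that("uptake fit is invariant under common rescaling of amounts", {
  tt <- c(3, 6, 12, 24)
  p <- uptake_params(0.0015, 0.08)
  y <- xin_analytic(p, tt)
  f1 <- fit_uptake(data.frame(time_h = tt, value = y), X0 = 1)
  f2 <- fit_uptake(data.frame(time_h = tt, value = y * 0.25), X0 = 0.25)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-6)
})

test_that("dose averaging is the arithmetic mean with quadrature uncertainty", {
  avg <- average_rates_over_doses(
    data.frame(K_in = c(0.00146, 0.00070, 0.00061),
               K_out = c(0.13862, 0.11676, 0.09149),
               K_in_se = c(0.00150, 0.00012, 0.00022),
               K_out_se = c(0.20191, 0.03122, 0.05568)))
  expect_lt(abs(avg$K_in - 0.00092), 5e-6)
  expect_lt(abs(avg$K_out - 0.11562), 5e-6)
  expect_lt(abs(avg$K_in_se - 0.00051), 5e-6)

  avg2 <- average_rates_over_doses(
    data.frame(K_in = c(0.00267, 0.00232, 0.00215),
               K_out = c(0, 0, 0)))
  expect_lt(abs(avg2$K_in - 0.00238), 5e-6)

  same <- average_rates_over_doses(data.frame(K_in = rep(0.002, 3),
                                              K_out = rep(0.1, 3)))
  expect_identical(same$K_in, 0.002)
  expect_error(average_rates_over_doses(data.frame(K_in = 1, K_out = 1)),
               "three")
})

test_that("bundled rate tables are complete and self-consistent", {
  rt <- load_bundled_rate_tables()
  expect_equal(nrow(rt), 36)  # 3 configs x 3 phenotypes x (3 doses + average)
  expect_setequal(unique(rt$config), c("BNF-Plain", "BNF-Her", "BNF-IgG"))
  expect_setequal(unique(rt$phenotype), c("M0", "M1", "M2"))

  expect_equal(rate_entry(rt, "BNF-IgG", "M0")$K_out, 0.13006)
  expect_equal(rate_entry(rt, "BNF-Plain", "M1")$K_out, 0)
  expect_equal(rate_entry(rt, "BNF-Plain", "M1")$K_out_se, 0.01380)

  for (cfg in unique(rt$config)) {
    for (ph in unique(rt$phenotype)) {
      per <- rt[rt$config == cfg & rt$phenotype == ph & rt$dose != "average", ]
      avg <- rate_entry(rt, cfg, ph)
      expect_lt(abs(mean(per$K_in) - avg$K_in), 5e-6)
      expect_lt(abs(mean(per$K_out) - avg$K_out), 5e-6)
      expect_lt(abs(sqrt(sum(per$K_in_se^2)) / 3 - avg$K_in_se), 1e-5)
      expect_lt(abs(sqrt(sum(per$K_out_se^2)) / 3 - avg$K_out_se), 1e-5)
    }
  }
  expect_error(rate_entry(rt, "BNF-Plain", "M9"), "missing parameter")
})

test_that("a corrupted fixture file is rejected by its checksum", {
  tmp <- tempfile(fileext = ".csv")
  src <- system.file("extdata", "bnf_uptake_rates.csv", package = "nanoretain")
  txt <- readLines(src)
  txt[2] <- sub("0.00146", "0.00147", txt[2], fixed = TRUE)
  writeLines(txt, tmp)
  expect_error(nanoretain:::.read_fixture("bnf_uptake_rates.csv", path = tmp),
               "corrupted fixture")
})

test_that("refitting noise-free data from every averaged entry is a fixed point", {
  rt <- load_bundled_rate_tables()
  avg <- rt[rt$dose == "average", ]
  tt <- c(3, 6, 12, 24)
  for (i in seq_len(nrow(avg))) {
    truth <- uptake_params(avg$K_in[i], avg$K_out[i])
    fit <- fit_uptake(data.frame(time_h = tt, value = xin_analytic(truth, tt)))
    expect_lt(rel_err(fit$estimates[["K_in"]], avg$K_in[i]), 1e-3)
    if (avg$K_out[i] == 0) {
      expect_lt(fit$estimates[["K_out"]], 1e-6)
    } else {
      expect_lt(rel_err(fit$estimates[["K_out"]], avg$K_out[i]), 1e-3)
    }
  }
})
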