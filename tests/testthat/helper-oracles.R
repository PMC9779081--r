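# Independent oracles and shared fixtures for the test suite.
# Oracles are written against the model equations directly, not against the
# package's solution paths.

# numeric integration of the plain two-compartment system (independent check
# of the closed-form biexponential solutions)
ode_two_compartment <- function(K_el, K_bp, K_pb, times, X0 = 100) {
  rhs <- function(t, y, p) {
    list(c(-(K_el + K_bp) * y[1] + K_pb * y[2],
           K_bp * y[1] - K_pb * y[2]))
  }
  sol <- deSolve::lsoda(c(xb = X0, xp = 0), times, rhs, parms = NULL,
                        rtol = 1e-12, atol = 1e-14)
  as.data.frame(sol)
}

# 6x6 rate matrix of the linear retention system, built from the equation
# structure (uptake and efflux both scaled by the compartment's k factor)
six_comp_matrix <- function(p) {
  rbind(
    c(-(p$K_el + p$K_bp + p$K_bt + p$k_b * p$K_bm),
      p$K_pb, p$K_tb, p$k_b * p$K_mb, 0, 0),
    c(p$K_bp, -(p$K_pb + p$k_p * p$K_pm), 0, 0, p$k_p * p$K_mp, 0),
    c(p$K_bt, 0, -(p$K_tb + p$k_t * p$K_tm), 0, 0, p$k_t * p$K_mt),
    c(p$k_b * p$K_bm, 0, 0, -p$k_b * p$K_mb, 0, 0),
    c(0, p$k_p * p$K_pm, 0, 0, -p$k_p * p$K_mp, 0),
    c(0, 0, p$k_t * p$K_tm, 0, 0, -p$k_t * p$K_mt)
  )
}

# closed-form state at time t via the matrix exponential (Matrix package)
expm_state <- function(p, t) {
  A <- six_comp_matrix(p)
  as.numeric(Matrix::expm(A * t) %*% c(p$X0, 0, 0, 0, 0, 0))
}

# bundled blood disposition parameters by diameter
table1_params <- function(diameter) {
  row <- load_blood_pk_rates()
  row <- row[row$diameter_nm == diameter, ]
  two_compartment_params(row$lambda_b, row$lambda_p, row$K_pb)
}

# the headline assembled parameter set: 100-nm disposition, BNF-Plain
# macrophage rates (M0 in blood, M1 in peripheral and tumor), y = 0.05%,
# multiplication factors 40
headline_params <- function() {
  assemble_params(table1_params(100), load_bundled_rate_tables(), "BNF-Plain")
}

# random admissible six-compartment parameter draw (rates on scales spanning
# the fitted values)
random_six_params <- function() {
  lp <- stats::runif(1, 0.01, 0.2)
  lb <- stats::runif(1, 1, 25)
  kpb <- stats::runif(1, lp, lb)
  dep <- derive_dependent_rates(lb, lp, kpb)
  six_compartment_params(
    K_el = dep[["K_el"]], K_bp = dep[["K_bp"]], K_pb = kpb,
    K_bt = stats::runif(1, 0, 0.05), K_tb = stats::runif(1, 0, 0.05),
    K_bm = stats::runif(1, 0, 0.01), K_mb = stats::runif(1, 0, 0.2),
    K_pm = stats::runif(1, 0, 0.01), K_mp = stats::runif(1, 0, 0.2),
    K_tm = stats::runif(1, 0, 0.01), K_mt = stats::runif(1, 0, 0.2),
    k_b = stats::runif(1, 0, 50), k_p = stats::runif(1, 0, 50),
    k_t = stats::runif(1, 0, 50)
  )
}

rel_err <- function(x, ref, floor = 1e-12) {
  abs(x - ref) / pmax(abs(ref), floor)
}
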