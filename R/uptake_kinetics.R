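#' In vitro macrophage uptake parameters
#'
#' Two-state internalization/efflux kinetics for nanoparticles incubated with
#' macrophages: extracellular particles enter the intracellular pool at rate
#' `K_in` and leave it at rate `K_out` (both first order, per hour).
#' Intracellular biodegradation is neglected over the assay timeframe, so the
#' steady states are nonzero: `xin -> K_in X0 / (K_in + K_out)` and
#' `xout -> K_out X0 / (K_in + K_out)`.
#'
#' @param K_in Internalization rate, per hour, `>= 0`.
#' @param K_out Efflux (exocytosis) rate, per hour, `>= 0`.
#' @param X0 Initial extracellular amount (normalized fraction, or mg Fe).
#' @return An object of class `uptake_params`.
#' @export
uptake_params <- function(K_in, K_out, X0 = 1) {
  stopifnot(is.finite(K_in), is.finite(K_out), is.finite(X0),
            K_in >= 0, K_out >= 0, X0 > 0)
  if (K_in + K_out <= 0)
    stop("ill-posed parameters: K_in + K_out must be positive", call. = FALSE)
  structure(list(K_in = K_in, K_out = K_out, X0 = X0), class = "uptake_params")
}

#' Analytic internalized amount
#'
#' \deqn{x_{in}(t) = \frac{K_{in} X_0}{K_{in}+K_{out}}
#'   \left(1 - e^{-(K_{in}+K_{out}) t}\right)}
#'
#' @param params An [uptake_params()] object.
#' @param t Time(s), hours, `>= 0`. Vectorized.
#' @return Internalized amount in the units of `X0`.
#' @export
xin_analytic <- function(params, t) {
  stopifnot(inherits(params, "uptake_params"))
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  ks <- params$K_in + params$K_out
  params$K_in * params$X0 / ks * (1 - exp(-ks * t))
}

#' Analytic extracellular amount
#'
#' \deqn{x_{out}(t) = \frac{X_0}{K_{in}+K_{out}}
#'   \left(K_{out} + K_{in} e^{-(K_{in}+K_{out}) t}\right)}
#' Conservation `xin(t) + xout(t) = X0` holds for all `t`.
#'
#' @inheritParams xin_analytic
#' @return Extracellular amount in the units of `X0`.
#' @export
xout_analytic <- function(params, t) {
  stopifnot(inherits(params, "uptake_params"))
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  ks <- params$K_in + params$K_out
  params$X0 / ks * (params$K_out + params$K_in * exp(-ks * t))
}

# One-sided profile standard error for a parameter pinned at its lower bound:
# the displacement d at which the profiled weighted RSS (other parameter
# re-optimized) exceeds the optimum by the residual variance sigma^2.
.profile_se_boundary <- function(resid_fn, par, index, n_obs, upper = 1) {
  p <- length(par)
  dof <- max(n_obs - p, 1)
  rss0 <- sum(resid_fn(par)^2)
  sigma2 <- rss0 / dof
  if (sigma2 <= 0) return(0)
  prof <- function(d) {
    fixed <- par
    fixed[index] <- d
    free <- setdiff(seq_len(p), index)
    f <- function(th) {
      full <- fixed
      full[free] <- th
      resid_fn(full)
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par[free], fn = f,
                         lower = rep(0, length(free)),
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) sum(f(par[free])^2) else fit$deviance
  }
  g <- function(d) prof(d) - rss0 - sigma2
  hi <- upper
  for (i in 1:20) {
    if (g(hi) > 0) break
    hi <- hi * 2
  }
  if (g(hi) <= 0) return(NA_real_)
  stats::uniroot(g, c(par[index], hi), tol = 1e-8)$root - par[index]
}

#' Fit the two-state uptake model to an internalization time course
#'
#' Weighted least-squares fit of the analytic internalized amount to a single
#' uptake series (one nanoparticle configuration, phenotype and dose). The
#' series is normalized to its initial dose (`X0 = 1`) since the kinetics are
#' homogeneous in amount, making the rate estimates unit-free. Estimates are
#' box-constrained to be nonnegative; an estimate pinned at zero is reported
#' with a profile-based standard error and flagged as a boundary hit, matching
#' the convention of reporting zero efflux with a nonzero uncertainty.
#'
#' @param series Data frame with columns `time_h` and `value` (internalized
#'   amount, normalized to the initial dose) and optionally `replicate`.
#'   At least 3 distinct times are required. By default all replicate values
#'   are fitted; set `use_means = TRUE` to fit per-time means.
#' @param weighting `"auto"`/`"inverse_variance"` (weights `1/var` from
#'   replicate spread, where at least two replicates exist) or `"uniform"`.
#' @param use_means Fit per-time mean values instead of all replicates.
#' @param X0 Initial extracellular amount after normalization (default 1).
#' @return A `pk_fit` object with estimates over `K_in` and `K_out`.
#' @examples
#' p <- uptake_params(0.00092, 0.11562)
#' tt <- c(3, 6, 12, 24)
#' fit <- fit_uptake(data.frame(time_h = tt, value = xin_analytic(p, tt)))
#' fit$estimates
#' @export
fit_uptake <- function(series,
                       weighting = c("auto", "inverse_variance", "uniform"),
                       use_means = FALSE, X0 = 1) {
  weighting <- match.arg(weighting)
  need <- c("time_h", "value")
  miss <- setdiff(need, names(series))
  if (length(miss))
    stop("series is missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  series <- series[is.finite(series$time_h) & is.finite(series$value), ]
  if (length(unique(series$time_h)) < 3L)
    stop("insufficient data: need at least 3 distinct time points", call. = FALSE)
  if (all(series$value == 0))
    stop("insufficient data: all values are zero", call. = FALSE)

  if (use_means) {
    agg <- stats::aggregate(value ~ time_h, data = series, FUN = mean)
    tt <- agg$time_h
    yy <- agg$value
    vv <- rep(NA_real_, length(tt))
  } else {
    tt <- series$time_h
    yy <- series$value
    # replicate variance per time, used for inverse-variance weights
    vtab <- stats::aggregate(value ~ time_h, data = series,
                             FUN = function(v) if (length(v) > 1) stats::var(v) else NA_real_)
    vv <- vtab$value[match(tt, vtab$time_h)]
  }
  scheme <- if (weighting == "auto") {
    if (any(is.finite(vv) & vv > 0)) "inverse_variance" else "uniform"
  } else weighting
  if (scheme == "inverse_variance") {
    vpos <- vv[is.finite(vv) & vv > 0]
    if (!length(vpos))
      stop("inverse-variance weighting requires replicate spread", call. = FALSE)
    fill <- stats::median(vpos)
    w <- 1 / ifelse(is.finite(vv) & vv > 0, vv, fill)
  } else {
    w <- rep(1, length(tt))
  }
  sw <- sqrt(w)

  model <- function(par, t) {
    ks <- par[1] + par[2]
    if (ks <= 0) return(rep(0, length(t)))
    par[1] * X0 / ks * (1 - exp(-ks * t))
  }
  resid_fn <- function(par) sw * (model(par, tt) - yy)

  starts <- expand.grid(K_in = c(1e-4, 1e-3, 1e-2, 0.1),
                        K_out = c(1e-4, 0.01, 0.1, 0.5))
  fit <- .multistart_lm(resid_fn, starts, lower = c(0, 0))
  if (is.null(fit)) stop("uptake fit failed from every start", call. = FALSE)

  par <- fit$par
  names(par) <- c("K_in", "K_out")
  flags <- par < .boundary_tol
  cov <- .lm_covariance(resid_fn, par, length(yy))
  ses <- sqrt(pmax(diag(cov), 0))
  names(ses) <- names(par)
  for (j in which(flags)) {
    pse <- .profile_se_boundary(resid_fn, par, j, length(yy),
                                upper = max(par) + 0.05)
    if (is.finite(pse)) ses[j] <- pse
  }
  structure(
    list(estimates = par,
         standard_errors = ses,
         boundary_flags = flags,
         residual_sum = fit$deviance,
         converged = fit$info %in% 1:4,
         weighting = scheme,
         n_obs = length(yy)),
    class = "pk_fit"
  )
}

#' Average uptake rates over the three assay doses
#'
#' The per-dose rate estimates for one (nanoparticle configuration, phenotype)
#' pair are combined by arithmetic mean; uncertainties propagate in quadrature,
#' `sqrt(se1^2 + se2^2 + se3^2) / 3`, treating the per-dose fits as
#' independent.
#'
#' @param per_dose Data frame with exactly three rows and columns `K_in`,
#'   `K_out` and optionally `K_in_se`, `K_out_se`.
#' @return Named list with `K_in`, `K_out` and, when input uncertainties are
#'   present, `K_in_se`, `K_out_se`.
#' @examples
#' average_rates_over_doses(
#'   data.frame(K_in = c(0.00146, 0.00070, 0.00061),
#'              K_out = c(0.13862, 0.11676, 0.09149)))
#' @export
average_rates_over_doses <- function(per_dose) {
  if (!all(c("K_in", "K_out") %in% names(per_dose)))
    stop("per_dose must contain columns K_in and K_out", call. = FALSE)
  if (nrow(per_dose) != 3L)
    stop("expected exactly three per-dose entries", call. = FALSE)
  out <- list(K_in = mean(per_dose$K_in), K_out = mean(per_dose$K_out))
  for (col in c("K_in_se", "K_out_se")) {
    if (col %in% names(per_dose))
      out[[col]] <- sqrt(sum(per_dose[[col]]^2)) / nrow(per_dose)
  }
  out
}

.fixture_md5 <- c(
  bnf_uptake_rates.csv = "0bf54a5ab4fc4835ac850111fd304e7b",
  blood_pk_rates.csv = "8c20f5c10af9d38992206ca302ad75b6",
  np_characteristics.csv = "efab9aa47ae0d5e607891c1cd5c7f684"
)

.read_fixture <- function(name, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", name, package = "nanoretain", mustWork = TRUE)
  sum <- unname(tools::md5sum(path))
  if (!identical(sum, unname(.fixture_md5[[name]])))
    stop("corrupted fixture: checksum mismatch for ", name, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Bundled macrophage uptake rate tables
#'
#' Internalization (`K_in`) and efflux (`K_out`) rates, per hour, fitted to
#' ferene-s uptake time courses of RAW264.7 macrophages for three nanoparticle
#' configurations (BNF-Plain, BNF-Her, BNF-IgG), three polarization states
#' (M0, M1, M2) and three initial iron doses (0.125, 0.250, 0.500 mg Fe/mL),
#' plus the dose-averaged entry per configuration/phenotype. The fixture is
#' checksum-verified on load.
#'
#' @return Data frame with columns `config`, `phenotype`, `dose` (one of
#'   `"0.125"`, `"0.250"`, `"0.500"`, `"average"`), `K_in`, `K_in_se`,
#'   `K_out`, `K_out_se`.
#' @export
load_bundled_rate_tables <- function() {
  df <- .read_fixture("bnf_uptake_rates.csv")
  df$dose <- as.character(df$dose)
  df
}

#' Look up one entry of a rate table
#'
#' @param rates A rate table as returned by [load_bundled_rate_tables()].
#' @param config Nanoparticle configuration label.
#' @param phenotype Macrophage polarization label (`"M0"`, `"M1"`, `"M2"`).
#' @param dose Dose label; `"average"` (default) selects the dose-averaged row.
#' @return One-row data frame.
#' @export
rate_entry <- function(rates, config, phenotype, dose = "average") {
  row <- rates[rates$config == config & rates$phenotype == phenotype &
                 rates$dose == dose, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("missing parameter: no unique rate entry for (", config, ", ",
         phenotype, ", ", dose, ")", call. = FALSE)
  row
}

#' Bundled blood disposition rate table
#'
#' Fitted biexponential rate constants (`lambda_b`, `lambda_p`, `K_pb`) and
#' the derived `K_el`, `K_bp` (per hour, with uncertainties) for nanoparticles
#' of 20, 30 and 100 nm core diameter. Checksum-verified on load.
#'
#' @return Data frame keyed by `diameter_nm`.
#' @export
load_blood_pk_rates <- function() {
  .read_fixture("blood_pk_rates.csv")
}

#' Bundled nanoparticle physical characteristics
#'
#' Hydrodynamic diameter, polydispersity, zeta potential and conjugated
#' protein load of the three nanoparticle configurations. Metadata only: none
#' of these values parameterize the kinetic models.
#'
#' @return Data frame keyed by `nanoparticle`.
#' @export
load_np_characteristics <- function() {
  .read_fixture("np_characteristics.csv")
}
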