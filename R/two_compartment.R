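#' Two-compartment blood disposition parameters
#'
#' Constructs the parameter set of the classical two-compartment (central +
#' peripheral) pharmacokinetic model for intravenously injected nanoparticles.
#' Blood concentration follows a biexponential decay with a fast (distributive)
#' rate constant `lambda_b` and a slow (post-distributive) rate constant
#' `lambda_p`. The micro rate constants are the peripheral-to-blood return rate
#' `K_pb`, the elimination rate `K_el` and the blood-to-peripheral rate `K_bp`.
#' They are tied to the eigenvalues by
#' \deqn{\lambda_b + \lambda_p = K_{el} + K_{bp} + K_{pb}, \qquad
#'       \lambda_b \lambda_p = K_{el} K_{pb}.}
#' If `K_el` and `K_bp` are omitted they are derived from these identities via
#' [derive_dependent_rates()].
#'
#' @param lambda_b Fast (distributive-phase) rate constant, per hour. Must
#'   exceed `lambda_p`.
#' @param lambda_p Slow (post-distributive-phase) rate constant, per hour,
#'   `>= 0`.
#' @param K_pb Peripheral-to-blood return rate, per hour. Must lie in
#'   `[lambda_p, lambda_b]` for the blood solution to stay nonnegative.
#' @param K_el,K_bp Elimination and blood-to-peripheral rates, per hour.
#'   Derived from the eigenvalue identities when `NULL`.
#' @param X0 Injected dose, in percent of injected dose (default 100).
#' @return An object of class `two_compartment_params`: a named list with
#'   fields `lambda_b`, `lambda_p`, `K_pb`, `K_el`, `K_bp`, `X0`.
#' @seealso [xb_analytic()], [xp_analytic()], [fit_blood_pk()]
#' @examples
#' p <- two_compartment_params(lambda_b = 20.273, lambda_p = 0.052, K_pb = 2.241)
#' p$K_el   # ~0.470 per hour
#' xb_analytic(p, c(0, 1, 24, 48))
#' @export
two_compartment_params <- function(lambda_b, lambda_p, K_pb,
                                   K_el = NULL, K_bp = NULL, X0 = 100) {
  stopifnot(is.numeric(lambda_b), is.numeric(lambda_p), is.numeric(K_pb),
            length(lambda_b) == 1L, length(lambda_p) == 1L, length(K_pb) == 1L,
            is.finite(lambda_b), is.finite(lambda_p), is.finite(K_pb),
            is.numeric(X0), length(X0) == 1L, X0 > 0)
  if (lambda_p < 0 || K_pb < 0)
    stop("rate constants must be nonnegative", call. = FALSE)
  if (lambda_b <= lambda_p)
    stop("degenerate or misordered eigenvalues: lambda_b must exceed lambda_p ",
         "(the repeated-eigenvalue case is not supported)", call. = FALSE)
  if (is.null(K_el) || is.null(K_bp)) {
    dep <- derive_dependent_rates(lambda_b, lambda_p, K_pb)
    K_el <- dep[["K_el"]]
    K_bp <- dep[["K_bp"]]
  } else {
    .check_eigen_identities(lambda_b, lambda_p, K_pb, K_el, K_bp)
  }
  if (K_pb < lambda_p || K_pb > lambda_b)
    stop("inconsistent eigenstructure: K_pb must lie between lambda_p and ",
         "lambda_b", call. = FALSE)
  structure(
    list(lambda_b = lambda_b, lambda_p = lambda_p, K_pb = K_pb,
         K_el = K_el, K_bp = K_bp, X0 = X0),
    class = "two_compartment_params"
  )
}

.check_eigen_identities <- function(lambda_b, lambda_p, K_pb, K_el, K_bp,
                                    rtol = 1e-6) {
  s <- K_el + K_bp + K_pb
  p <- K_el * K_pb
  ok_sum <- abs(lambda_b + lambda_p - s) <= rtol * max(abs(s), 1e-12)
  ok_prod <- abs(lambda_b * lambda_p - p) <= rtol * max(abs(p), abs(lambda_b * lambda_p), 1e-12)
  if (!ok_sum || !ok_prod)
    stop("eigenvalues and rate constants violate the two-compartment ",
         "identities (sum and product rules)", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.two_compartment_params <- function(x, ...) {
  cat("Two-compartment PK parameters (per hour):\n")
  cat(sprintf("  lambda_b = %.4g  lambda_p = %.4g\n", x$lambda_b, x$lambda_p))
  cat(sprintf("  K_pb = %.4g  K_el = %.4g  K_bp = %.4g  X0 = %g %%ID\n",
              x$K_pb, x$K_el, x$K_bp, x$X0))
  invisible(x)
}

#' Derive elimination and distribution rates from the eigen-parameters
#'
#' Given the biexponential rate constants `lambda_b > lambda_p` and the return
#' rate `K_pb` estimated from a blood concentration fit, computes the
#' elimination rate `K_el = lambda_b * lambda_p / K_pb` (product rule) and the
#' blood-to-peripheral rate `K_bp = lambda_b + lambda_p - K_el - K_pb`
#' (sum rule).
#'
#' @inheritParams two_compartment_params
#' @return Named numeric vector with elements `K_el` and `K_bp`, per hour.
#' @examples
#' derive_dependent_rates(20.273, 0.052, 2.241)  # K_el ~0.470, K_bp ~17.614
#' @export
derive_dependent_rates <- function(lambda_b, lambda_p, K_pb) {
  stopifnot(is.finite(lambda_b), is.finite(lambda_p), is.finite(K_pb))
  if (lambda_b <= lambda_p || lambda_p < 0)
    stop("require lambda_b > lambda_p >= 0", call. = FALSE)
  if (K_pb <= 0)
    stop("K_pb must be positive", call. = FALSE)
  if (K_pb < lambda_p || K_pb > lambda_b)
    stop("inconsistent eigenstructure: K_pb must lie in [lambda_p, lambda_b]; ",
         "values outside give a negative K_bp or a negative blood solution",
         call. = FALSE)
  K_el <- lambda_b * lambda_p / K_pb
  K_bp <- lambda_b + lambda_p - K_el - K_pb
  c(K_el = K_el, K_bp = K_bp)
}

#' Eigenvalues of the two-compartment rate matrix
#'
#' Inverse of [derive_dependent_rates()]: from the micro rate constants,
#' returns the two eigenvalue magnitudes of the disposition matrix, i.e. the
#' roots of \eqn{\lambda^2 - (K_{el}+K_{bp}+K_{pb})\lambda + K_{el}K_{pb} = 0},
#' sorted descending.
#'
#' @inheritParams two_compartment_params
#' @return Named numeric vector `c(lambda_b = ..., lambda_p = ...)`, per hour.
#' @examples
#' eigenvalues_from_rates(0.471, 17.613, 2.241)
#' @export
eigenvalues_from_rates <- function(K_el, K_bp, K_pb) {
  stopifnot(is.finite(K_el), is.finite(K_bp), is.finite(K_pb),
            K_el >= 0, K_bp >= 0, K_pb >= 0)
  s <- K_el + K_bp + K_pb
  p <- K_el * K_pb
  disc <- s^2 - 4 * p   # always >= 0 for nonnegative rates
  root <- sqrt(max(disc, 0))
  # stable quadratic roots: compute the large one first, the small by product
  lb <- (s + root) / 2
  lp <- if (lb > 0) p / lb else 0
  c(lambda_b = lb, lambda_p = lp)
}

.assert_biexp <- function(params, t) {
  stopifnot(inherits(params, "two_compartment_params"))
  if (any(t < 0)) stop("t must be nonnegative", call. = FALSE)
  if (params$lambda_b <= params$lambda_p)
    stop("degenerate eigenvalues are not supported", call. = FALSE)
  invisible(TRUE)
}

#' Analytic blood amount under the two-compartment model
#'
#' Closed-form solution for the noninternalized amount in blood,
#' \deqn{x_b(t) = \frac{X_0}{\lambda_b-\lambda_p}
#'   \left[(\lambda_b - K_{pb}) e^{-\lambda_b t}
#'       - (\lambda_p - K_{pb}) e^{-\lambda_p t}\right].}
#'
#' @param params A [two_compartment_params()] object.
#' @param t Time(s) after injection, hours, `>= 0`. Vectorized.
#' @return Amount in blood, percent of injected dose.
#' @export
xb_analytic <- function(params, t) {
  .assert_biexp(params, t)
  lb <- params$lambda_b; lp <- params$lambda_p; kpb <- params$K_pb
  params$X0 / (lb - lp) *
    ((lb - kpb) * exp(-lb * t) - (lp - kpb) * exp(-lp * t))
}

#' Analytic peripheral amount under the two-compartment model
#'
#' Closed-form solution for the noninternalized peripheral amount,
#' \deqn{x_p(t) = \frac{K_{bp} X_0}{\lambda_p-\lambda_b}
#'   \left(e^{-\lambda_b t} - e^{-\lambda_p t}\right).}
#'
#' @inheritParams xb_analytic
#' @return Amount in peripheral tissues, percent of injected dose.
#' @export
xp_analytic <- function(params, t) {
  .assert_biexp(params, t)
  lb <- params$lambda_b; lp <- params$lambda_p
  params$K_bp * params$X0 / (lp - lb) * (exp(-lb * t) - exp(-lp * t))
}

#' Blood concentration-time series container
#'
#' @param times Sampling times, hours, strictly increasing, `>= 0`.
#' @param values Mean amounts, percent of injected dose, `>= 0`.
#' @param sds Optional per-point standard deviations, `> 0` where given.
#' @param n_replicates Optional per-point replicate counts, integer `>= 1`.
#' @return A `concentration_curve`: data frame with columns `time_h`,
#'   `value_pct_id` and optionally `sd_pct_id`, `n`.
#' @export
concentration_curve <- function(times, values, sds = NULL, n_replicates = NULL) {
  stopifnot(is.numeric(times), is.numeric(values))
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(values)))
    stop("times and values must be finite", call. = FALSE)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  if (any(values < 0)) stop("values must be >= 0", call. = FALSE)
  df <- data.frame(time_h = times, value_pct_id = values)
  if (!is.null(sds)) {
    stopifnot(length(sds) == length(times))
    if (any(sds[!is.na(sds)] <= 0)) stop("sds must be > 0 where given", call. = FALSE)
    df$sd_pct_id <- sds
  }
  if (!is.null(n_replicates)) {
    stopifnot(length(n_replicates) == length(times))
    if (any(n_replicates[!is.na(n_replicates)] < 1))
      stop("n_replicates must be >= 1", call. = FALSE)
    df$n <- as.integer(n_replicates)
  }
  class(df) <- c("concentration_curve", "data.frame")
  df
}

# Resolve a weighting scheme label into per-point weights.
.resolve_weights <- function(curve, weighting) {
  weighting <- match.arg(weighting, c("auto", "inverse_variance", "uniform"))
  has_sd <- !is.null(curve$sd_pct_id) && all(is.finite(curve$sd_pct_id))
  scheme <- if (weighting == "auto") {
    if (has_sd) "inverse_variance" else "uniform"
  } else weighting
  if (scheme == "inverse_variance") {
    if (!has_sd)
      stop("inverse-variance weighting requires per-point sds", call. = FALSE)
    n <- if (!is.null(curve$n)) curve$n else rep(1L, nrow(curve))
    w <- n / curve$sd_pct_id^2
  } else {
    w <- rep(1, nrow(curve))
  }
  list(weights = w, scheme = scheme)
}

# Weighted Levenberg-Marquardt with a fixed multi-start grid; returns the
# best nls.lm fit plus the start that produced it. Ties go to the start with
# the smaller first parameter (a labeling convention, not a model choice).
.multistart_lm <- function(residual_fn, starts, lower, upper = NULL) {
  if (is.null(upper)) upper <- rep(Inf, length(lower))
  best <- NULL
  best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    st <- as.numeric(starts[i, ])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = residual_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- fit$deviance
    take <- rss < best_rss * (1 - 1e-10) ||
      (abs(rss - best_rss) <= 1e-10 * max(best_rss, 1) &&
         !is.null(best) && fit$par[1] < best$par[1])
    if (is.null(best) || take) {
      best <- fit
      best_rss <- rss
    }
  }
  best
}

# Asymptotic covariance of the parameters from the weighted-residual jacobian
# at the optimum: sigma^2 (J'J)^{-1}, with a pseudo-inverse fallback when the
# fit sits on a boundary and the jacobian loses rank.
.lm_covariance <- function(residual_fn, par, n_obs) {
  p <- length(par)
  dof <- max(n_obs - p, 1)
  r0 <- residual_fn(par)
  sigma2 <- sum(r0^2) / dof
  J <- matrix(0, length(r0), p)
  h <- pmax(abs(par), 1e-4) * 1e-6
  for (j in seq_len(p)) {
    up <- par; up[j] <- par[j] + h[j]
    dn <- par; dn[j] <- max(par[j] - h[j], 0)
    J[, j] <- (residual_fn(up) - residual_fn(dn)) / (up[j] - dn[j])
  }
  JtJ <- crossprod(J)
  cov <- tryCatch(solve(JtJ), error = function(e) {
    s <- svd(JtJ)
    keep <- s$d > max(s$d) * 1e-10
    s$v[, keep, drop = FALSE] %*%
      diag(1 / s$d[keep], sum(keep)) %*% t(s$u[, keep, drop = FALSE])
  })
  sigma2 * cov
}

.boundary_tol <- 1e-6

#' Fit the biexponential blood model to a concentration curve
#'
#' Weighted least-squares fit of the analytic blood solution to a
#' concentration-time curve normalized to an injected dose of 100 percent. The
#' free parameters are `(lambda_b, lambda_p, K_pb)`; `K_el` and `K_bp` are
#' derived from the eigenvalue identities and reported with delta-method
#' standard errors. Optimization uses Levenberg-Marquardt with nonnegativity
#' box constraints, started from a fixed grid
#' (`lambda_b` in 1, 5, 20, 50; `lambda_p` in 0.01, 0.05, 0.2; `K_pb` the
#' geometric mean of the pair), so the fit is deterministic. Eigenvalue
#' ordering `lambda_b > lambda_p` is imposed by sorting after the fit.
#'
#' @param curve A [concentration_curve()] with at least 4 distinct times.
#' @param weighting `"auto"` (inverse-variance `n/sd^2` when per-point sds are
#'   present, uniform otherwise), `"inverse_variance"`, or `"uniform"`.
#' @return A `pk_fit` object: list with `estimates` (named vector over
#'   `lambda_b`, `lambda_p`, `K_pb`, `K_el`, `K_bp`), `standard_errors`,
#'   `boundary_flags`, `residual_sum` (weighted RSS), `converged`, `weighting`,
#'   `n_obs`.
#' @examples
#' p <- two_compartment_params(9.304, 0.038, 2.325)
#' tt <- exp(seq(log(0.01), log(48), length.out = 12))
#' fit <- fit_blood_pk(concentration_curve(tt, xb_analytic(p, tt)))
#' fit$estimates
#' @export
fit_blood_pk <- function(curve, weighting = c("auto", "inverse_variance", "uniform")) {
  if (!inherits(curve, "concentration_curve"))
    curve <- concentration_curve(curve$time_h, curve$value_pct_id,
                                 curve$sd_pct_id, curve$n)
  if (length(unique(curve$time_h)) < 4L)
    stop("insufficient data: need at least 4 distinct time points", call. = FALSE)
  if (any(!is.finite(curve$value_pct_id)))
    stop("insufficient data: non-finite values", call. = FALSE)
  w <- .resolve_weights(curve, match.arg(weighting))
  sw <- sqrt(w$weights)
  tt <- curve$time_h
  yy <- curve$value_pct_id
  X0 <- 100

  model <- function(par, t) {
    lb <- max(par[1], par[2]); lp <- min(par[1], par[2]); kpb <- par[3]
    if (lb - lp < 1e-12) lb <- lp + 1e-12
    X0 / (lb - lp) * ((lb - kpb) * exp(-lb * t) - (lp - kpb) * exp(-lp * t))
  }
  resid_fn <- function(par) sw * (model(par, tt) - yy)

  lb_grid <- c(1, 5, 20, 50)
  lp_grid <- c(0.01, 0.05, 0.2)
  starts <- expand.grid(lambda_b = lb_grid, lambda_p = lp_grid)
  starts$K_pb <- sqrt(starts$lambda_b * starts$lambda_p)
  starts <- starts[order(starts$lambda_b, starts$lambda_p), ]

  fit <- .multistart_lm(resid_fn, starts, lower = c(0, 0, 0))
  if (is.null(fit))
    stop("blood PK fit failed from every start", call. = FALSE)

  par <- fit$par
  # ordering convention: lambda_b is the faster eigenvalue
  if (par[1] < par[2]) par[c(1, 2)] <- par[c(2, 1)]
  names(par) <- c("lambda_b", "lambda_p", "K_pb")

  cov <- .lm_covariance(resid_fn, par, length(yy))
  se3 <- sqrt(pmax(diag(cov), 0))

  lb <- par[1]; lp <- par[2]; kpb <- par[3]
  # clamp K_pb into the admissible eigen-band before deriving rates
  kpb_c <- min(max(kpb, lp), lb)
  K_el <- if (kpb_c > 0) lb * lp / kpb_c else 0
  K_bp <- max(lb + lp - K_el - kpb_c, 0)
  # delta method for (K_el, K_bp) = g(lambda_b, lambda_p, K_pb)
  g <- rbind(
    K_el = c(lp / max(kpb_c, 1e-12), lb / max(kpb_c, 1e-12),
             -lb * lp / max(kpb_c, 1e-12)^2),
    K_bp = c(1 - lp / max(kpb_c, 1e-12), 1 - lb / max(kpb_c, 1e-12),
             -1 + lb * lp / max(kpb_c, 1e-12)^2)
  )
  se_dep <- sqrt(pmax(diag(g %*% cov %*% t(g)), 0))

  estimates <- c(par[1], par[2], K_pb = unname(kpb), K_el = unname(K_el),
                 K_bp = unname(K_bp))
  ses <- c(se3, se_dep)
  names(ses) <- names(estimates)
  flags <- estimates < .boundary_tol
  structure(
    list(estimates = estimates,
         standard_errors = ses,
         boundary_flags = flags,
         residual_sum = fit$deviance,
         converged = fit$info %in% 1:4,
         weighting = w$scheme,
         n_obs = length(yy)),
    class = "pk_fit"
  )
}

#' @export
print.pk_fit <- function(x, ...) {
  cat("Weighted least-squares PK fit (", x$weighting, " weights, n = ",
      x$n_obs, ")\n", sep = "")
  tab <- data.frame(estimate = x$estimates, se = x$standard_errors,
                    boundary = x$boundary_flags)
  print(tab, digits = 5)
  cat(sprintf("weighted RSS = %.6g; converged: %s\n",
              x$residual_sum, x$converged))
  invisible(x)
}
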