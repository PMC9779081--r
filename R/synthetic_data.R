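#' Measurement noise model for synthetic assays
#'
#' Observations are generated as
#' `value = truth * (1 + eps_prop) + eps_add`, with independent Gaussian
#' `eps_prop ~ N(0, proportional_cv^2)` and `eps_add ~ N(0, additive_sd^2)`,
#' truncated at zero (concentrations cannot be negative). The defaults
#' (10 percent proportional CV, no additive term) match the magnitude of
#' replicate scatter typical of the ferene-s uptake assay without inventing
#' extra structure.
#'
#' @param proportional_cv Coefficient of variation of the proportional
#'   component, dimensionless, `>= 0`.
#' @param additive_sd Standard deviation of the additive component, in the
#'   units of the generated values, `>= 0`.
#' @param seed Integer seed; identical seeds reproduce identical datasets.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(proportional_cv = 0.1, additive_sd = 0, seed = 1L) {
  stopifnot(is.numeric(proportional_cv), proportional_cv >= 0,
            is.numeric(additive_sd), additive_sd >= 0,
            is.numeric(seed), length(seed) == 1L, is.finite(seed))
  structure(list(proportional_cv = proportional_cv,
                 additive_sd = additive_sd,
                 seed = as.integer(seed)),
            class = "noise_model")
}

# apply the noise law to a vector of true values; counts truncations
.apply_noise <- function(truth, noise) {
  n <- length(truth)
  v <- truth * (1 + stats::rnorm(n, 0, noise$proportional_cv)) +
    stats::rnorm(n, 0, noise$additive_sd)
  trunc_n <- sum(v < 0)
  v[v < 0] <- 0
  list(values = v, truncated = trunc_n)
}

# run expr with the RNG seeded from the noise model, restoring global state
.with_noise_seed <- function(noise, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv())
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(noise$seed)
  force(expr)
}

#' Dose/timepoint/replicate layout of an uptake assay
#'
#' The default layout mirrors the ferene-s uptake experiment: three initial
#' iron doses, sampling at 3, 6, 12 and 24 hours with 3, 2, 1 and 3 replicate
#' measurements respectively.
#'
#' @param doses Initial doses, mg Fe per mL.
#' @param times Sampling times, hours.
#' @param replicates Per-time replicate counts (same length as `times`).
#' @return Object of class `assay_design`.
#' @export
assay_design <- function(doses = c(0.125, 0.25, 0.5),
                         times = c(3, 6, 12, 24),
                         replicates = c(3L, 2L, 1L, 3L)) {
  stopifnot(is.numeric(doses), all(doses > 0),
            is.numeric(times), all(times >= 0),
            length(times) == length(replicates), all(replicates >= 1))
  structure(list(doses = doses, times = times,
                 replicates = as.integer(replicates)),
            class = "assay_design")
}

#' Generate a synthetic blood concentration curve
#'
#' Replicate observations are drawn around the analytic biexponential blood
#' solution under the given noise model; the returned curve carries per-point
#' means, standard deviations and replicate counts, with the raw replicate
#' draws attached as attribute `"replicates"` and the number of zero-truncated
#' draws as attribute `"truncated"`.
#'
#' @param params A [two_compartment_params()] object.
#' @param times Sampling times, hours, strictly increasing.
#' @param noise A [noise_model()].
#' @param n_replicates Replicates per time point.
#' @return A [concentration_curve()].
#' @export
gen_blood_pk <- function(params, times, noise = noise_model(),
                         n_replicates = 3L) {
  stopifnot(inherits(params, "two_compartment_params"),
            inherits(noise, "noise_model"),
            length(times) >= 1, all(times >= 0), n_replicates >= 1)
  truth <- xb_analytic(params, times)
  .with_noise_seed(noise, {
    reps <- .apply_noise(rep(truth, each = n_replicates), noise)
    mat <- matrix(reps$values, nrow = n_replicates)
    means <- colMeans(mat)
    sds <- if (n_replicates > 1) apply(mat, 2, stats::sd) else rep(NA_real_, length(times))
    curve <- concentration_curve(
      times, means,
      sds = if (n_replicates > 1) pmax(sds, 1e-12) else NULL,
      n_replicates = rep(n_replicates, length(times))
    )
    attr(curve, "replicates") <- data.frame(
      time_h = rep(times, each = n_replicates),
      replicate = rep(seq_len(n_replicates), length(times)),
      value_pct_id = reps$values
    )
    attr(curve, "truncated") <- reps$truncated
    curve
  })
}

#' Generate a synthetic uptake assay table
#'
#' Values follow the analytic internalized-amount solution with the supplied
#' `(K_in, K_out)`, normalized to `X0 = 1` per dose, under the assay design
#' and noise model. With zero noise the generated values equal the analytic
#' model exactly.
#'
#' @param entry List or one-row data frame with `K_in` and `K_out` (e.g. a
#'   [rate_entry()] row), plus optionally `config` and `phenotype` labels.
#' @param design An [assay_design()].
#' @param noise A [noise_model()].
#' @return Data frame with columns `config`, `phenotype`, `dose_mg_per_ml`,
#'   `time_h`, `value`, `replicate`; truncation count attached as attribute
#'   `"truncated"`.
#' @export
gen_uptake_assay <- function(entry, design = assay_design(),
                             noise = noise_model()) {
  stopifnot(inherits(design, "assay_design"), inherits(noise, "noise_model"))
  up <- uptake_params(entry$K_in, entry$K_out, X0 = 1)
  cfg <- if (!is.null(entry$config)) entry$config else "synthetic"
  phe <- if (!is.null(entry$phenotype)) entry$phenotype else "synthetic"
  grid <- do.call(rbind, lapply(design$doses, function(d) {
    do.call(rbind, Map(function(tm, nr) {
      data.frame(config = cfg, phenotype = phe, dose_mg_per_ml = d,
                 time_h = tm, replicate = seq_len(nr))
    }, design$times, design$replicates))
  }))
  truth <- xin_analytic(up, grid$time_h)
  .with_noise_seed(noise, {
    noisy <- .apply_noise(truth, noise)
    grid$value <- noisy$values
    grid <- grid[, c("config", "phenotype", "dose_mg_per_ml",
                     "time_h", "value", "replicate")]
    attr(grid, "truncated") <- noisy$truncated
    grid
  })
}

#' Biodistribution snapshot from a trajectory endpoint
#'
#' Converts the trajectory's per-compartment totals at the final time into a
#' table of percent injected dose and percent injected dose per gram, given
#' the tumor mass (from volume x density) and named organ masses for the
#' other compartments. Inverse of the percent-per-gram conversion in
#' [convert_id_per_g_to_id()].
#'
#' @param traj A `pk_trajectory`.
#' @param tumor_mass_g Tumor mass, grams, `> 0`.
#' @param organ_masses_g Named numeric vector of masses (grams) for `blood`
#'   and `peripheral`.
#' @return Data frame with columns `compartment`, `mass_g`, `pct_id`,
#'   `pct_id_per_g`.
#' @export
gen_bd_snapshot <- function(traj, tumor_mass_g = 0.225,
                            organ_masses_g = c(blood = 2, peripheral = 20)) {
  stopifnot(inherits(traj, "pk_trajectory"), tumor_mass_g > 0,
            all(organ_masses_g > 0),
            all(c("blood", "peripheral") %in% names(organ_masses_g)))
  n <- nrow(traj)
  tot <- c(blood = traj$xb[n] + traj$mb[n],
           peripheral = traj$xp[n] + traj$mp[n],
           tumor = traj$xt[n] + traj$mt[n])
  mass <- c(organ_masses_g[c("blood", "peripheral")], tumor = tumor_mass_g)
  data.frame(compartment = names(tot), mass_g = unname(mass),
             pct_id = unname(tot), pct_id_per_g = unname(tot / mass))
}
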