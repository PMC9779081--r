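#' Convert percent injected dose per gram to percent injected dose
#'
#' Biodistribution tables are often reported per gram of tissue. For a tumor
#' of known volume and density the conversion is
#' `pct_id = value * (volume_mm3 / 1000) * density` (the bracket is the tissue
#' mass in grams). The conventional reference tumor is 225 mm3 at a density of
#' 1 g/cm3.
#'
#' @param value Amount, percent of injected dose per gram.
#' @param tumor_volume_mm3 Tissue volume, mm3, `> 0`.
#' @param density_g_per_cm3 Tissue density, g/cm3, `> 0`.
#' @return Amount in percent of injected dose.
#' @examples
#' convert_id_per_g_to_id(4.4444, 225, 1)  # ~1 %ID
#' @export
convert_id_per_g_to_id <- function(value, tumor_volume_mm3 = 225,
                                   density_g_per_cm3 = 1) {
  if (!is.numeric(tumor_volume_mm3) || any(tumor_volume_mm3 <= 0))
    stop("invalid argument: tumor_volume_mm3 must be > 0", call. = FALSE)
  if (!is.numeric(density_g_per_cm3) || any(density_g_per_cm3 <= 0))
    stop("invalid argument: density_g_per_cm3 must be > 0", call. = FALSE)
  value * (tumor_volume_mm3 / 1000) * density_g_per_cm3
}

#' @rdname convert_id_per_g_to_id
#' @param mass_g Tissue mass in grams, `> 0`.
#' @export
convert_id_to_id_per_g <- function(value, mass_g) {
  if (!is.numeric(mass_g) || any(mass_g <= 0))
    stop("invalid argument: mass_g must be > 0", call. = FALSE)
  value / mass_g
}

# write a data frame as CSV with floats at 17 significant digits (lossless
# binary round trip through text)
.write_csv17 <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      s <- sprintf("%.17g", out[[j]])
      s[is.na(out[[j]])] <- "NA"
      out[[j]] <- s
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

.require_columns <- function(df, cols, what, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("schema error in ", what, " file '", path,
         "': missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Read and write blood concentration curves
#'
#' CSV schema: required columns `time_h`, `value_pct_id`; optional
#' `sd_pct_id`, `n`.
#'
#' @param path File path.
#' @return `read_curve` returns a [concentration_curve()]; `write_curve`
#'   returns `path` invisibly.
#' @export
read_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("time_h", "value_pct_id"), "concentration curve", path)
  concentration_curve(df$time_h, df$value_pct_id,
                      sds = df$sd_pct_id, n_replicates = df$n)
}

#' @rdname read_curve
#' @param curve A [concentration_curve()].
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "concentration_curve"))
  .write_csv17(as.data.frame(curve), path)
}

#' Read and write uptake assay tables
#'
#' CSV schema: columns `config`, `phenotype`, `dose_mg_per_ml`, `time_h`,
#' `value`, `replicate`.
#'
#' @param path File path.
#' @return `read_assay` returns a data frame; `write_assay` returns `path`
#'   invisibly.
#' @export
read_assay <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("config", "phenotype", "dose_mg_per_ml", "time_h",
                         "value", "replicate"), "uptake assay", path)
  if (any(df$value < 0))
    stop("schema error in uptake assay file '", path,
         "': negative values in column value", call. = FALSE)
  df
}

#' @rdname read_assay
#' @param assay Uptake assay data frame.
#' @export
write_assay <- function(assay, path) {
  .require_columns(assay, c("config", "phenotype", "dose_mg_per_ml", "time_h",
                            "value", "replicate"), "uptake assay", "<memory>")
  .write_csv17(as.data.frame(assay), path)
}

#' Read and write simulated trajectories
#'
#' CSV schema: `time_h`, the six state columns `xb`, `xp`, `xt`, `mb`, `mp`,
#' `mt`, `eliminated`, plus derived totals `blood_total`, `peripheral_total`,
#' `tumor_total` (all percent of injected dose).
#'
#' @param path File path.
#' @return `read_trajectory` returns a `pk_trajectory`; `write_trajectory`
#'   returns `path` invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "pk_trajectory"))
  df <- as.data.frame(traj)
  df$blood_total <- df$xb + df$mb
  df$peripheral_total <- df$xp + df$mp
  df$tumor_total <- df$xt + df$mt
  .write_csv17(df, path)
}

#' @rdname write_trajectory
#' @param traj A `pk_trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .require_columns(df, c("time_h", "xb", "xp", "xt", "mb", "mp", "mt",
                         "eliminated"), "trajectory", path)
  df$blood_total <- NULL
  df$peripheral_total <- NULL
  df$tumor_total <- NULL
  structure(df, class = c("pk_trajectory", "data.frame"))
}

.scenario_allowed <- list(
  top = c("two_compartment", "phenotype_map", "scaling", "k_factors",
          "np_config", "t_end_h", "n_points"),
  two_compartment = c("lambda_b", "lambda_p", "K_pb", "K_el", "K_bp", "X0"),
  phenotype_map = c("blood", "peripheral", "tumor"),
  scaling = "y",
  k_factors = c("kb", "kp", "kt")
)

#' Read a simulation scenario configuration
#'
#' Scenarios are YAML or JSON (chosen by file extension) with nested keys
#' `two_compartment` (`lambda_b`, `lambda_p`, `K_pb`, optional `K_el`,
#' `K_bp`, `X0`), `phenotype_map` (`blood`, `peripheral`, `tumor`),
#' `scaling` (`y`), `k_factors` (`kb`, `kp`, `kt`), `np_config`, `t_end_h`,
#' `n_points`. Unknown keys are rejected with the list of allowed keys.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return Named list of class `pk_scenario` with defaults filled in.
#' @export
read_scenario <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    stop("scenario file must be .yaml, .yml or .json", call. = FALSE)
  }
  .check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad))
      stop("unknown key(s) in scenario ", where, ": ",
           paste(bad, collapse = ", "), "; allowed keys: ",
           paste(allowed, collapse = ", "), call. = FALSE)
  }
  .check_keys(raw, .scenario_allowed$top, "top level")
  for (blk in intersect(names(raw), names(.scenario_allowed)[-1]))
    .check_keys(raw[[blk]], .scenario_allowed[[blk]], paste0("block '", blk, "'"))
  if (is.null(raw$two_compartment))
    stop("scenario must contain a two_compartment block", call. = FALSE)
  scn <- list(
    two_compartment = raw$two_compartment,
    phenotype_map = utils::modifyList(
      list(blood = "M0", peripheral = "M1", tumor = "M1"),
      raw$phenotype_map %||% list()),
    y = (raw$scaling %||% list(y = 0.0005))$y %||% 0.0005,
    k_factors = unlist(utils::modifyList(
      list(kb = 40, kp = 40, kt = 40), raw$k_factors %||% list())),
    np_config = raw$np_config %||% "BNF-Plain",
    t_end_h = raw$t_end_h %||% 48,
    n_points = raw$n_points %||% 481L
  )
  class(scn) <- "pk_scenario"
  scn
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build six-compartment parameters from a scenario
#'
#' @param scenario A `pk_scenario` from [read_scenario()].
#' @param rates Rate table; defaults to the bundled tables.
#' @return A [six_compartment_params()] object.
#' @export
scenario_params <- function(scenario, rates = load_bundled_rate_tables()) {
  stopifnot(inherits(scenario, "pk_scenario"))
  tcp <- scenario$two_compartment
  tc <- two_compartment_params(tcp$lambda_b, tcp$lambda_p, tcp$K_pb,
                               K_el = tcp$K_el, K_bp = tcp$K_bp,
                               X0 = tcp$X0 %||% 100)
  pm <- phenotype_map(scenario$phenotype_map$blood,
                      scenario$phenotype_map$peripheral,
                      scenario$phenotype_map$tumor)
  assemble_params(tc, rates, config = scenario$np_config, pheno_map = pm,
                  y = scenario$y,
                  k_factors = unname(scenario$k_factors[c("kb", "kp", "kt")]))
}

#' Write a run manifest
#'
#' Records inputs, parameters, package version and seed next to the outputs of
#' a run, for provenance.
#'
#' @param dir Output directory.
#' @param subcommand Label of the operation performed.
#' @param inputs Named list of input paths/values.
#' @param seed Integer seed or `NA`.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, subcommand, inputs = list(), seed = NA) {
  manifest <- list(
    tool = "nanoretain",
    version = as.character(utils::packageVersion("nanoretain")),
    subcommand = subcommand,
    inputs = inputs,
    seed = seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
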