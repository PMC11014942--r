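#' Mass-independent oxygen isotope anomaly (Delta-17O)
#'
#' Computes the linear-form anomaly
#' \deqn{\Delta^{17}O = \delta^{17}O - \lambda \cdot \delta^{18}O}
#' i.e. the deviation of delta-17O from the mass-dependent fractionation line.
#' Biologically produced nitrate sits on this line (anomaly ~0), while
#' atmospheric nitrate formed via ozone chemistry carries a strongly positive
#' anomaly, which is what makes Delta-17O a conservative source tracer.
#'
#' @param d17O delta-17O, per mil vs VSMOW.
#' @param d18O delta-18O, per mil vs VSMOW.
#' @param lambda_mdf Mass-dependent slope (dimensionless, in (0, 1));
#'   default 0.52, the community-standard value for the linear definition.
#' @return Delta-17O, per mil. Vectorised over `d17O`/`d18O`.
#' @examples
#' delta17O_anomaly(d17O = 18, d18O = 20)   # 7.6
#' delta17O_anomaly(0.52 * 10, 10)          # 0: on the mass-dependent line
#' @export
delta17O_anomaly <- function(d17O, d18O, lambda_mdf = 0.52) {
  ns_stopifnot_finite(d17O, "d17O")
  ns_stopifnot_finite(d18O, "d18O")
  if (!is.numeric(lambda_mdf) || length(lambda_mdf) != 1L ||
      !is.finite(lambda_mdf) || lambda_mdf <= 0 || lambda_mdf >= 1) {
    ns_abort("`lambda_mdf` must be a single number in (0, 1).",
             class = "nitrosource_error_config")
  }
  d17O - lambda_mdf * d18O
}

#' delta-18O of biologically produced nitrate from its oxygen sources
#'
#' During nitrification, the three oxygen atoms of the nitrate product are
#' expected to derive one from dissolved atmospheric O2 and two from ambient
#' water, so the product delta-18O is the abundance-weighted mean
#' `w_water * d18O_water + (1 - w_water) * d18O_O2` with `w_water = 2/3`.
#'
#' Note that with published inputs (water -12.7 per mil, O2 23.9 per mil) this
#' arithmetic gives -0.5 per mil, whereas the shipped biological endmember
#' constant is 0.6 per mil (the field value, which may fold in fractionation
#' effects the simple mixing rule omits). Both values are exposed; see
#' [default_endmembers()].
#'
#' @param d18O_water delta-18O of ambient water, per mil vs VSMOW.
#' @param d18O_O2 delta-18O of dissolved O2, per mil vs VSMOW (atmospheric O2
#'   is 23.9 per mil).
#' @param w_water Fraction of product oxygen from water, in `[0, 1]`;
#'   default `2/3`.
#' @return Product delta-18O, per mil.
#' @examples
#' biological_endmember_d18O(-12.7, 23.9)  # -0.5
#' @export
biological_endmember_d18O <- function(d18O_water, d18O_O2, w_water = 2 / 3) {
  ns_stopifnot_finite(d18O_water, "d18O_water")
  ns_stopifnot_finite(d18O_O2, "d18O_O2")
  if (!is.numeric(w_water) || length(w_water) != 1L || !is.finite(w_water) ||
      w_water < 0 || w_water > 1) {
    ns_abort("`w_water` must be a single fraction in [0, 1].",
             class = "nitrosource_error_config")
  }
  w_water * d18O_water + (1 - w_water) * d18O_O2
}

#' Two-endmember isotope mass balance
#'
#' Apportions an observed isotope value between an atmospheric and a
#' biological source pool:
#' \deqn{f_{atm} = (obs - em_{bio}) / (em_{atm} - em_{bio}), \quad
#'       f_{bio} = 1 - f_{atm}.}
#' Observations outside the endmember interval (possible under measurement
#' noise) are clipped to `[0, 1]` when `clip = TRUE` and flagged; with
#' `clip = FALSE` they are returned as-is with an out-of-hull flag.
#'
#' @param obs Observed value(s), per mil (same tracer as the endmembers).
#' @param em_bio,em_atm Biological and atmospheric endmember values, per mil.
#' @param tracer `"d18O"` or `"D17O"`; recorded on the result.
#' @param clip Clip fractions to `[0, 1]`? Default `TRUE`.
#' @return A tibble with one row per observation: `f_atm`, `f_bio`, `tracer`,
#'   `point_obs`, `ci_low`, `ci_high`, `n_draws`, `seed`, `clipped`,
#'   `out_of_hull`. `f_atm + f_bio == 1` exactly.
#' @examples
#' two_endmember_fraction(4.6, em_bio = 0.6, em_atm = 92)   # f_bio ~ 0.956
#' two_endmember_fraction(1.3, em_bio = 0, em_atm = 32, tracer = "D17O")
#' @export
two_endmember_fraction <- function(obs, em_bio, em_atm,
                                   tracer = c("d18O", "D17O"), clip = TRUE) {
  tracer <- match.arg(tracer)
  ns_stopifnot_finite(obs, "obs")
  ns_stopifnot_finite(em_bio, "em_bio")
  ns_stopifnot_finite(em_atm, "em_atm")
  if (isTRUE(all.equal(em_atm, em_bio, tolerance = 0))) {
    ns_abort("Endmembers are identical; the mixing model is degenerate.",
             class = "nitrosource_error_degenerate_endmember")
  }
  f_atm <- (obs - em_bio) / (em_atm - em_bio)
  out_of_hull <- f_atm < 0 | f_atm > 1
  clipped <- rep(FALSE, length(f_atm))
  if (clip) {
    clipped <- out_of_hull
    f_atm <- pmin(pmax(f_atm, 0), 1)
  } else if (any(out_of_hull)) {
    rlang::warn(
      "Observation(s) outside the endmember interval; fractions exceed [0, 1].",
      class = "nitrosource_warning_out_of_hull"
    )
  }
  tibble::tibble(
    f_atm = f_atm, f_bio = 1 - f_atm, tracer = tracer, point_obs = obs,
    ci_low = NA_real_, ci_high = NA_real_, n_draws = NA_integer_,
    seed = NA_integer_, clipped = clipped, out_of_hull = out_of_hull
  )
}

#' Aggregate isotope observations before or instead of mixing
#'
#' `"mean_first"` (the default) returns the arithmetic mean of the values, to
#' be apportioned once; `"per_sample"` returns the values unchanged, for
#' per-sample mixing followed by averaging of the fractions.
#'
#' @param values Numeric vector of per-sample isotope values, per mil.
#' @param mode `"mean_first"` or `"per_sample"`.
#' @return A single mean (mean_first) or the input vector (per_sample).
#' @export
aggregate_observations <- function(values, mode = c("mean_first", "per_sample")) {
  mode <- match.arg(mode)
  values <- values[!is.na(values)]
  if (length(values) == 0L) {
    ns_abort("No observations available to aggregate.",
             class = "nitrosource_error_no_data")
  }
  ns_stopifnot_finite(values, "values")
  if (mode == "mean_first") mean(values) else values
}

#' Monte-Carlo uncertainty propagation for the two-endmember balance
#'
#' Draws the observation and both endmember values from independent Gaussians
#' at their stated 1-sigma uncertainties, computes the biological fraction per
#' draw (clipped to `[0, 1]`), and returns the closed-form point estimate on
#' the means together with the Monte-Carlo median and the 2.5-97.5 percentile
#' interval. Identical seed and inputs give identical output; the caller's RNG
#' state is untouched.
#'
#' @param obs Observed value (typically a group mean), per mil.
#' @param sigma_obs 1-sigma uncertainty on `obs`, per mil (>= 0).
#' @param em_bio,em_atm [endmember()] objects.
#' @param tracer `"d18O"` or `"D17O"`: selects which endmember field is used.
#' @param n_draws Number of Monte-Carlo draws (>= 1); default 10000.
#' @param seed Integer seed (required; no hidden global RNG state).
#' @return One-row tibble: `f_atm`, `f_bio`, `tracer`, `point_obs`,
#'   `f_atm_median`, `f_bio_median`, `ci_low`, `ci_high` (percentile interval
#'   for `f_atm`), `n_draws`, `seed`, `clipped`, `out_of_hull`.
#' @examples
#' em <- default_endmembers()
#' monte_carlo_fraction(4.6, 0.3, em$biological, em$atmospheric,
#'                      n_draws = 1000, seed = 1)
#' @export
monte_carlo_fraction <- function(obs, sigma_obs, em_bio, em_atm,
                                 tracer = c("d18O", "D17O"),
                                 n_draws = 10000L, seed) {
  tracer <- match.arg(tracer)
  if (missing(seed) || is.null(seed)) {
    ns_abort("An explicit `seed` is required for Monte-Carlo propagation.",
             class = "nitrosource_error_config")
  }
  if (!inherits(em_bio, "endmember") || !inherits(em_atm, "endmember")) {
    ns_abort("`em_bio` and `em_atm` must be endmember objects.",
             class = "nitrosource_error_config")
  }
  if (!is.numeric(n_draws) || n_draws < 1) {
    ns_abort("`n_draws` must be >= 1.", class = "nitrosource_error_config")
  }
  ns_stopifnot_finite(obs, "obs")
  ns_check_sigma(sigma_obs, "sigma_obs")

  val <- function(e) if (tracer == "d18O") e$d18O else e$D17O
  sig <- function(e) if (tracer == "d18O") e$sigma_d18O else e$sigma_D17O

  point <- two_endmember_fraction(obs, val(em_bio), val(em_atm),
                                  tracer = tracer, clip = TRUE)

  draws <- withr::with_seed(as.integer(seed), {
    o <- stats::rnorm(n_draws, obs, sigma_obs)
    b <- stats::rnorm(n_draws, val(em_bio), sig(em_bio))
    a <- stats::rnorm(n_draws, val(em_atm), sig(em_atm))
    pmin(pmax((o - b) / (a - b), 0), 1)
  })
  qs <- stats::quantile(draws, c(0.025, 0.5, 0.975), names = FALSE, type = 7)

  tibble::tibble(
    f_atm = point$f_atm, f_bio = point$f_bio, tracer = tracer,
    point_obs = obs,
    f_atm_median = qs[2], f_bio_median = 1 - qs[2],
    ci_low = qs[1], ci_high = qs[3],
    n_draws = as.integer(n_draws), seed = as.integer(seed),
    clipped = point$clipped, out_of_hull = point$out_of_hull
  )
}

# Default 1-sigma instrument precisions (per mil), pooled standard deviations
# of the denitrifier method.
default_precisions <- function() {
  c(d18O = 0.3, D17O = 0.8, d15N = 0.6)
}

#' Validate an isotope measurement table
#'
#' Checks the schema of a table of per-sample nitrate (or water) isotope
#' measurements and fills in default instrument precisions (0.3 / 0.8 / 0.6
#' per mil 1-sigma for delta-18O / Delta-17O / delta-15N) where sigma columns
#' are missing or empty.
#'
#' @param df Data frame with columns `sample_id`, `sample_type`, `d18O` and
#'   optionally `d17O`, `D17O`, `d15N`, `sigma_d18O`, `sigma_D17O`,
#'   `sigma_d15N`.
#' @return A validated tibble with all optional columns present.
#' @export
validate_isotope_table <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("sample_id", "sample_type")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    ns_abort(sprintf("Isotope table is missing column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             class = "nitrosource_error_schema")
  }
  bad <- setdiff(unique(df$sample_type), sample_types())
  if (length(bad) > 0L) {
    ns_abort(sprintf("Unknown sample_type value(s): %s (expected %s)",
                     paste(bad, collapse = ", "),
                     paste(sample_types(), collapse = ", ")),
             class = "nitrosource_error_schema")
  }
  prec <- default_precisions()
  opt_num <- c("d18O", "d17O", "D17O", "d15N",
               "sigma_d18O", "sigma_D17O", "sigma_d15N")
  for (col in opt_num) {
    if (!col %in% names(df)) df[[col]] <- NA_real_
    if (is.logical(df[[col]]) && all(is.na(df[[col]]))) {
      df[[col]] <- as.numeric(df[[col]])   # empty CSV column parses as logical
    }
    if (!is.numeric(df[[col]])) {
      ns_abort(sprintf("Column `%s` must be numeric.", col),
               class = "nitrosource_error_schema")
    }
  }
  df$sigma_d18O[is.na(df$sigma_d18O)] <- prec[["d18O"]]
  df$sigma_D17O[is.na(df$sigma_D17O)] <- prec[["D17O"]]
  df$sigma_d15N[is.na(df$sigma_d15N)] <- prec[["d15N"]]
  for (col in c("sigma_d18O", "sigma_D17O", "sigma_d15N")) {
    ns_check_sigma(df[[col]], col)
  }
  for (col in c("d18O", "d17O", "D17O", "d15N")) {
    vals <- df[[col]]
    if (any(!is.na(vals) & !is.finite(vals))) {
      ns_abort(sprintf("Column `%s` contains non-finite values.", col),
               class = "nitrosource_error_invalid_measurement")
    }
  }
  df
}

#' Apportion a full isotope dataset by sample type and tracer
#'
#' Groups measurements by `sample_type` and runs the two-endmember balance per
#' available tracer: delta-18O always, and Delta-17O whenever measured
#' (a `D17O` column takes precedence; otherwise Delta-17O is derived from
#' `d17O` and `d18O` via [delta17O_anomaly()]). Tracers are reported side by
#' side, never averaged across.
#'
#' With `mode = "mean_first"` (the default) the group mean is apportioned
#' once; its Monte-Carlo uncertainty uses the standard error of the mean
#' (mean per-sample sigma / sqrt(n)). With `mode = "per_sample"` each sample
#' is apportioned and the fractions averaged (no Monte-Carlo interval).
#'
#' @param measurements Isotope table (see [validate_isotope_table()]).
#' @param endmembers Named list with `atmospheric` and `biological`
#'   [endmember()] objects; default [default_endmembers()].
#' @param mode Aggregation mode, `"mean_first"` or `"per_sample"`.
#' @param n_draws Monte-Carlo draws per group (0 disables Monte-Carlo).
#' @param seed Integer seed; required when `n_draws > 0`.
#' @param clip Clip fractions to `[0, 1]`?
#' @param lambda_mdf Mass-dependent slope used when Delta-17O must be derived
#'   from `d17O`; see [delta17O_anomaly()].
#' @return Tibble of mixing results, one row per sample type per tracer, with
#'   columns `sample_type`, `n_samples` plus the [two_endmember_fraction()] /
#'   [monte_carlo_fraction()] columns. Empty input gives an empty tibble.
#' @export
apportion_dataset <- function(measurements,
                              endmembers = default_endmembers(),
                              mode = c("mean_first", "per_sample"),
                              n_draws = 10000L, seed = NULL, clip = TRUE,
                              lambda_mdf = 0.52) {
  mode <- match.arg(mode)
  df <- validate_isotope_table(measurements)
  if (is.null(endmembers$atmospheric) || is.null(endmembers$biological)) {
    ns_abort("`endmembers` must contain `atmospheric` and `biological`.",
             class = "nitrosource_error_config")
  }
  if (n_draws > 0 && is.null(seed)) {
    ns_abort("An explicit `seed` is required when `n_draws` > 0.",
             class = "nitrosource_error_config")
  }
  if (nrow(df) == 0L) return(empty_mixing_table())

  # Delta-17O: measured column wins; else derive from d17O/d18O
  df$D17O_eff <- ifelse(!is.na(df$D17O), df$D17O,
                        ifelse(!is.na(df$d17O) & !is.na(df$d18O),
                               df$d17O - lambda_mdf * df$d18O, NA_real_))

  em_atm <- endmembers$atmospheric
  em_bio <- endmembers$biological

  groups <- split(df, df$sample_type)
  out <- purrr::imap(groups, function(g, type) {
    rows <- list()
    gi <- 0L
    for (tr in c("d18O", "D17O")) {
      vals <- if (tr == "d18O") g$d18O else g$D17O_eff
      sigs <- if (tr == "d18O") g$sigma_d18O else g$sigma_D17O
      keep <- !is.na(vals)
      if (!any(keep)) next
      vals <- vals[keep]; sigs <- sigs[keep]
      gi <- gi + 1L
      grp_seed <- if (!is.null(seed)) {
        child_seed(seed, match(type, sample_types()) * 10L + gi)
      } else NULL
      row <- apportion_group(vals, sigs, em_bio, em_atm, tr, mode,
                             n_draws, grp_seed, clip)
      row$sample_type <- type
      row$n_samples <- length(vals)
      rows[[tr]] <- row
    }
    dplyr::bind_rows(rows)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) return(empty_mixing_table())
  dplyr::relocate(res, "sample_type", "tracer", "n_samples")
}

apportion_group <- function(vals, sigs, em_bio, em_atm, tracer, mode,
                            n_draws, seed, clip) {
  val <- function(e) if (tracer == "d18O") e$d18O else e$D17O
  if (mode == "per_sample") {
    per <- two_endmember_fraction(vals, val(em_bio), val(em_atm),
                                  tracer = tracer, clip = clip)
    return(tibble::tibble(
      f_atm = mean(per$f_atm), f_bio = mean(per$f_bio), tracer = tracer,
      point_obs = mean(vals),
      f_atm_median = NA_real_, f_bio_median = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_,
      n_draws = NA_integer_, seed = NA_integer_,
      clipped = any(per$clipped), out_of_hull = any(per$out_of_hull)
    ))
  }
  obs <- mean(vals)
  if (n_draws > 0) {
    sem <- mean(sigs) / sqrt(length(vals))
    monte_carlo_fraction(obs, sem, em_bio, em_atm, tracer = tracer,
                         n_draws = n_draws, seed = seed)
  } else {
    pt <- two_endmember_fraction(obs, val(em_bio), val(em_atm),
                                 tracer = tracer, clip = clip)
    tibble::tibble(
      f_atm = pt$f_atm, f_bio = pt$f_bio, tracer = tracer, point_obs = obs,
      f_atm_median = NA_real_, f_bio_median = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_,
      n_draws = NA_integer_, seed = NA_integer_,
      clipped = pt$clipped, out_of_hull = pt$out_of_hull
    )
  }
}

empty_mixing_table <- function() {
  tibble::tibble(
    sample_type = character(), tracer = character(), n_samples = integer(),
    f_atm = double(), f_bio = double(), point_obs = double(),
    f_atm_median = double(), f_bio_median = double(),
    ci_low = double(), ci_high = double(),
    n_draws = integer(), seed = integer(),
    clipped = logical(), out_of_hull = logical()
  )
}
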