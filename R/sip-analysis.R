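#' Construct a DNA-SIP density-fraction profile
#'
#' A profile is the abundance of a target gene (qPCR copies or relative
#' abundance) across the buoyant-density fractions of one CsCl gradient.
#' Organisms assimilating a 13C substrate build denser DNA, so the 13C
#' treatment's profile sits at higher density than the unlabelled 12C
#' control; the shift between the two is the labelling signal.
#'
#' @param density Buoyant densities, g/mL, strictly increasing.
#' @param abundance Non-negative abundances, one per fraction.
#' @param treatment `"13C"` or `"12C"`.
#' @param temperature_C Incubation temperature, degrees Celsius.
#' @param target_gene Gene the abundances quantify (e.g. `"amoA"`).
#' @param replicate Replicate microcosm id (integer; default 1).
#' @return A tibble of class `"sip_profile"` with columns `treatment`,
#'   `temperature_C`, `target_gene`, `replicate`, `density_g_per_mL`,
#'   `abundance`.
#' @export
sip_profile <- function(density, abundance, treatment = c("13C", "12C"),
                        temperature_C, target_gene, replicate = 1L) {
  treatment <- match.arg(treatment)
  ns_stopifnot_finite(density, "density")
  if (length(density) != length(abundance)) {
    ns_abort("`density` and `abundance` must have equal length.",
             class = "nitrosource_error_schema")
  }
  if (is.unsorted(density, strictly = TRUE)) {
    ns_abort("Densities must be strictly increasing.",
             class = "nitrosource_error_schema")
  }
  if (any(!is.finite(abundance)) || any(abundance < 0)) {
    ns_abort("Abundances must be finite and >= 0.",
             class = "nitrosource_error_schema")
  }
  out <- tibble::tibble(
    treatment = treatment, temperature_C = temperature_C,
    target_gene = target_gene, replicate = as.integer(replicate),
    density_g_per_mL = density, abundance = abundance
  )
  class(out) <- c("sip_profile", class(out))
  out
}

as_sip_profile <- function(df) {
  req <- c("treatment", "temperature_C", "target_gene", "replicate",
           "density_g_per_mL", "abundance")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    ns_abort(sprintf("SIP profile is missing column(s): %s",
                     paste(missing_cols, collapse = ", ")),
             class = "nitrosource_error_schema")
  }
  out <- tibble::as_tibble(df)
  if (!inherits(out, "sip_profile")) {
    class(out) <- c("sip_profile", class(out))
  }
  out
}

#' Normalise a SIP profile to unit total abundance
#'
#' Scales abundances to sum to 1 (per replicate, when the profile contains
#' several); densities are untouched. Idempotent.
#'
#' @param p A [sip_profile()].
#' @return The normalised profile.
#' @export
normalize_profile <- function(p) {
  p <- as_sip_profile(p)
  p <- dplyr::group_by(p, .data$treatment, .data$replicate)
  tot <- dplyr::summarise(p, s = sum(.data$abundance), .groups = "drop")
  if (any(tot$s <= 0)) {
    ns_abort("Profile has zero total abundance; cannot normalise.",
             class = "nitrosource_error_empty_profile")
  }
  out <- dplyr::ungroup(dplyr::mutate(p, abundance = .data$abundance / sum(.data$abundance)))
  as_sip_profile(out)
}

#' Average replicate gradients of one treatment
#'
#' Replicate microcosm profiles are first normalised (so gradients with
#' different absolute yields weigh equally) and then averaged per density
#' fraction. Replicates must share the density grid.
#'
#' @param p A [sip_profile()] possibly holding several replicates.
#' @return A single-replicate normalised profile.
#' @export
average_replicates <- function(p) {
  p <- normalize_profile(p)
  grids <- split(p$density_g_per_mL, p$replicate)
  if (length(unique(lapply(grids, unname))) > 1L) {
    ns_abort("Replicates must share the same density grid to be averaged.",
             class = "nitrosource_error_schema")
  }
  out <- dplyr::summarise(
    dplyr::group_by(p, .data$treatment, .data$temperature_C,
                    .data$target_gene, .data$density_g_per_mL),
    abundance = mean(.data$abundance), .groups = "drop"
  )
  out$replicate <- 1L
  out <- dplyr::arrange(out, .data$density_g_per_mL)
  as_sip_profile(out)
}

#' Abundance-weighted mean buoyant density of a profile
#'
#' The first moment of the (normalised) abundance distribution over density:
#' `sum(density * weight)`. Robust to fraction granularity, which is why the
#' 13C-minus-12C difference in weighted mean density (delta-WMD) is used as
#' the primary labelling statistic.
#'
#' @param p A [sip_profile()] with at least 3 fractions (per replicate,
#'   averaged first if several).
#' @return Weighted mean density, g/mL.
#' @examples
#' p <- sip_profile(c(1.70, 1.72, 1.74), c(1, 1, 1), "12C", 4, "amoA")
#' weighted_mean_density(p)  # 1.72
#' @export
weighted_mean_density <- function(p) {
  p <- as_sip_profile(p)
  if (length(unique(p$replicate)) > 1L) p <- average_replicates(p)
  if (nrow(p) < 3L) {
    ns_abort("At least 3 density fractions are required.",
             class = "nitrosource_error_insufficient_fractions")
  }
  p <- normalize_profile(p)
  sum(p$density_g_per_mL * p$abundance)
}

# Modal fraction density; ties resolve to the lightest fraction.
peak_density <- function(p) {
  p$density_g_per_mL[which.max(p$abundance)]
}

#' Quantify the 13C-versus-12C buoyant-density shift
#'
#' The labelling statistic: the difference in abundance-weighted mean density
#' between the 13C-treatment and 12C-control profiles of the same target gene
#' and incubation temperature, with the modal-fraction (peak) shift as a
#' secondary readout. The pair is called labelled when delta-WMD exceeds the
#' threshold.
#'
#' @param p13,p12 [sip_profile()]s for the 13C and 12C treatments; replicates
#'   are averaged after normalisation.
#' @param threshold Labelling threshold on delta-WMD, g/mL (default 0.005).
#' @return One-row tibble: `target_gene`, `temperature_C`, `wmd_13C`,
#'   `wmd_12C`, `delta_wmd`, `peak_13C`, `peak_12C`, `delta_peak`,
#'   `threshold`, `labeled`.
#' @export
compute_shift <- function(p13, p12, threshold = 0.005) {
  p13 <- as_sip_profile(p13)
  p12 <- as_sip_profile(p12)
  g13 <- unique(p13$target_gene); g12 <- unique(p12$target_gene)
  t13 <- unique(p13$temperature_C); t12 <- unique(p12$temperature_C)
  if (length(g13) != 1L || length(g12) != 1L || g13 != g12 ||
      length(t13) != 1L || length(t12) != 1L || t13 != t12) {
    ns_abort("Profiles must share one target gene and one temperature.",
             class = "nitrosource_error_pairing")
  }
  a13 <- average_replicates(p13)
  a12 <- average_replicates(p12)
  wmd13 <- weighted_mean_density(a13)
  wmd12 <- weighted_mean_density(a12)
  delta <- wmd13 - wmd12
  tibble::tibble(
    target_gene = g13, temperature_C = t13,
    wmd_13C = wmd13, wmd_12C = wmd12, delta_wmd = delta,
    peak_13C = peak_density(a13), peak_12C = peak_density(a12),
    delta_peak = peak_density(a13) - peak_density(a12),
    threshold = threshold, labeled = delta > threshold
  )
}

#' Read a long-format SIP fraction table
#'
#' Expects comma-separated columns `treatment`, `temperature_C`,
#' `target_gene`, `replicate`, `density_g_per_mL`, `abundance`.
#'
#' @param path CSV path.
#' @return Tibble of class `"sip_profile"` (all treatments together; split by
#'   `treatment` before calling [compute_shift()], or use [run_sip()]).
#' @export
read_sip_csv <- function(path) {
  df <- read_checked_csv(path, c("treatment", "temperature_C", "target_gene",
                                 "replicate", "density_g_per_mL", "abundance"))
  if (!all(df$treatment %in% c("13C", "12C"))) {
    ns_abort("`treatment` must be '13C' or '12C'.",
             class = "nitrosource_error_schema")
  }
  as_sip_profile(df)
}
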