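#' Specify a synthetic study with known ground truth
#'
#' Bundles every knob of the synthetic-data generators: sample counts and
#' true atmospheric fractions per sample type for the isotope tables,
#' measurement noise at the instrument precisions, process presence and
#' abundance range for the annotation tables, and the density-gradient layout
#' and true shift for the SIP profiles. A single mandatory seed drives all
#' generators via deterministic child streams, so each generator reproduces
#' in isolation and jointly.
#'
#' Defaults emulate the Antarctic lake-catchment study conditions: six
#' samples per type; true atmospheric fraction 0.05 in sediment and 0.04 in
#' soil (biological fractions 95% / 96%); Gaussian noise at 0.3 / 0.8 / 0.6
#' per mil 1-sigma for delta-18O / Delta-17O / delta-15N; qPCR abundances
#' log-uniform over 1e2-1e4 copies per ng DNA with anammox absent, mimicking
#' habitats where the hzo/hzs markers go undetected; SIP gradients of 14
#' fractions
#' over 1.69-1.77 g/mL with an unlabelled peak at 1.715 g/mL (sd 0.015), a
#' true 13C shift of 0.015 g/mL, 20% multiplicative noise and 3 replicate
#' microcosms.
#'
#' @param seed Integer seed (mandatory; no implicit randomness).
#' @param n_samples Named integer vector, samples per sample type.
#' @param true_f_atm Named vector of true atmospheric fractions in `[0, 1]`.
#' @param endmembers Endmember pair as in [default_endmembers()].
#' @param sigma Named vector of 1-sigma noise levels, per mil:
#'   `d18O`, `D17O`, `d15N`, `water_d18O`.
#' @param process_presence Named logical vector over the [ncycle_panel()]
#'   processes; `TRUE` = process present in the simulated habitat.
#' @param abundance_range Length-2 range for log-uniform gene abundances,
#'   copies per ng DNA.
#' @param n_annotation_samples Rows of the simulated annotation table.
#' @param sip List: `true_shift` (g/mL), `n_fractions`, `density_range`
#'   (length 2, g/mL), `peak_density`, `peak_sd` (g/mL), `noise_sd`
#'   (sd of multiplicative log-normal noise), `replicates`,
#'   `temperature_C`, `target_gene`.
#' @return Object of class `"sim_spec"`.
#' @export
sim_spec <- function(seed,
                     n_samples = c(sediment = 6L, soil = 6L),
                     true_f_atm = c(sediment = 0.05, soil = 0.04),
                     endmembers = default_endmembers(),
                     sigma = c(d18O = 0.3, D17O = 0.8, d15N = 0.6,
                               water_d18O = 1.5),
                     process_presence = NULL,
                     abundance_range = c(1e2, 1e4),
                     n_annotation_samples = 8L,
                     sip = list()) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    ns_abort("`seed` is mandatory in a sim_spec.",
             class = "nitrosource_error_config")
  }
  if (any(true_f_atm < 0 | true_f_atm > 1)) {
    ns_abort("`true_f_atm` values must lie in [0, 1].",
             class = "nitrosource_error_config")
  }
  if (!setequal(names(n_samples), names(true_f_atm))) {
    ns_abort("`n_samples` and `true_f_atm` must cover the same sample types.",
             class = "nitrosource_error_config")
  }
  bad_type <- setdiff(names(n_samples), sample_types())
  if (length(bad_type) > 0L) {
    ns_abort(sprintf("Unknown sample type(s): %s",
                     paste(bad_type, collapse = ", ")),
             class = "nitrosource_error_config")
  }
  ns_check_sigma(unname(sigma), "sigma")
  if (is.null(process_presence)) {
    procs <- names(ncycle_panel()$processes)
    process_presence <- stats::setNames(procs != "anammox", procs)
  }
  sip_defaults <- list(
    true_shift = 0.015, n_fractions = 14L, density_range = c(1.69, 1.77),
    peak_density = 1.715, peak_sd = 0.015, noise_sd = 0.2, replicates = 3L,
    temperature_C = 4, target_gene = "amoA"
  )
  sip <- utils::modifyList(sip_defaults, sip)
  if (sip$n_fractions < 3L) {
    ns_abort("`sip$n_fractions` must be >= 3.",
             class = "nitrosource_error_config")
  }
  ns_check_sigma(sip$noise_sd, "sip$noise_sd")
  structure(
    list(seed = as.integer(seed), n_samples = n_samples,
         true_f_atm = true_f_atm, endmembers = endmembers, sigma = sigma,
         process_presence = process_presence,
         abundance_range = abundance_range,
         n_annotation_samples = as.integer(n_annotation_samples),
         sip = sip),
    class = "sim_spec"
  )
}

check_sim_spec <- function(spec) {
  if (!inherits(spec, "sim_spec")) {
    ns_abort("Expected a sim_spec object.", class = "nitrosource_error_config")
  }
  invisible(spec)
}

#' Generate a synthetic nitrate isotope table
#'
#' For each sample, the true tracer values are the exact two-endmember mix
#' `f_atm * em_atm + (1 - f_atm) * em_bio` for delta-18O and Delta-17O;
#' observed values add independent Gaussian noise at the spec's sigmas.
#' Ground truth is returned separately and is never placed in the
#' measurement table, so downstream code cannot read it by accident.
#'
#' @param spec A [sim_spec()].
#' @return List with `measurements` (a valid isotope table) and `truth`
#'   (per-sample true fractions and true tracer values).
#' @export
gen_isotope_dataset <- function(spec) {
  check_sim_spec(spec)
  em_atm <- spec$endmembers$atmospheric
  em_bio <- spec$endmembers$biological
  types <- names(spec$n_samples)
  rows <- withr::with_seed(child_seed(spec$seed, 1L), {
    purrr::map(types, function(type) {
      n <- spec$n_samples[[type]]
      if (n == 0L) return(NULL)
      f <- spec$true_f_atm[[type]]
      true_d18O <- f * em_atm$d18O + (1 - f) * em_bio$d18O
      true_D17O <- f * em_atm$D17O + (1 - f) * em_bio$D17O
      tibble::tibble(
        sample_id = sprintf("%s_%02d", type, seq_len(n)),
        sample_type = type,
        d18O = true_d18O + stats::rnorm(n, 0, spec$sigma[["d18O"]]),
        d17O = NA_real_,
        D17O = true_D17O + stats::rnorm(n, 0, spec$sigma[["D17O"]]),
        d15N = NA_real_,
        sigma_d18O = spec$sigma[["d18O"]],
        sigma_D17O = spec$sigma[["D17O"]],
        sigma_d15N = spec$sigma[["d15N"]],
        true_f_atm = f, true_d18O = true_d18O, true_D17O = true_D17O
      )
    })
  })
  all <- dplyr::bind_rows(rows)
  truth <- dplyr::select(all, "sample_id", "sample_type",
                         "true_f_atm", "true_d18O", "true_D17O")
  measurements <- dplyr::select(all, -"true_f_atm", -"true_d18O", -"true_D17O")
  list(measurements = measurements, truth = truth)
}

#' Generate a synthetic marker-gene annotation table
#'
#' Genes of present processes receive independent log-uniform abundances over
#' the spec's range (default 1e2-1e4 copies per ng DNA, the magnitude range
#' of environmental qPCR inventories); genes of absent processes are exactly
#' zero. The default presence map has anammox absent, mimicking habitats
#' where hzo/hzs are undetected.
#'
#' @param spec A [sim_spec()].
#' @param map Panel defining processes and genes; default [ncycle_panel()].
#' @return List with `table` (annotation table) and `truth` (named logical
#'   presence vector, the generator's ground truth).
#' @export
gen_annotation_table <- function(spec, map = ncycle_panel()) {
  check_sim_spec(spec)
  procs <- names(map$processes)
  presence <- spec$process_presence
  missing_p <- setdiff(procs, names(presence))
  if (length(missing_p) > 0L) {
    presence[missing_p] <- TRUE
  }
  n <- spec$n_annotation_samples
  lo <- log10(spec$abundance_range[1])
  hi <- log10(spec$abundance_range[2])
  genes <- unique(unlist(map$processes, use.names = FALSE))
  # a gene is "on" when any of its processes is present
  gene_on <- vapply(genes, function(g) {
    any(vapply(procs, function(p) g %in% map$processes[[p]] && presence[[p]],
               logical(1)))
  }, logical(1))
  tab <- withr::with_seed(child_seed(spec$seed, 2L), {
    cols <- lapply(genes, function(g) {
      if (gene_on[[g]]) 10^stats::runif(n, lo, hi) else rep(0, n)
    })
    names(cols) <- genes
    tibble::as_tibble(c(list(sample_id = sprintf("ann_%02d", seq_len(n))),
                        cols))
  })
  list(table = tab, truth = presence[procs])
}

#' Generate paired 13C/12C SIP profiles with a known shift
#'
#' The unlabelled (12C) gradient is a Gaussian abundance curve over the
#' density grid; the 13C gradient is the identical curve translated upward in
#' density by `true_shift` (its fraction densities are shifted, so the
#' translation is exact). Each replicate gets independent multiplicative
#' log-normal noise per fraction.
#'
#' @param spec A [sim_spec()].
#' @return List with `profiles` (long tibble of both treatments, class
#'   `"sip_profile"`) and `truth` (list with `true_shift`).
#' @export
gen_sip_profiles <- function(spec) {
  check_sim_spec(spec)
  s <- spec$sip
  grid <- seq(s$density_range[1], s$density_range[2],
              length.out = s$n_fractions)
  base <- stats::dnorm(grid, mean = s$peak_density, sd = s$peak_sd)
  profiles <- withr::with_seed(child_seed(spec$seed, 3L), {
    purrr::map(seq_len(s$replicates), function(r) {
      noise12 <- exp(stats::rnorm(s$n_fractions, 0, s$noise_sd))
      noise13 <- exp(stats::rnorm(s$n_fractions, 0, s$noise_sd))
      dplyr::bind_rows(
        sip_profile(grid, base * noise12, "12C", s$temperature_C,
                    s$target_gene, replicate = r),
        sip_profile(grid + s$true_shift, base * noise13, "13C",
                    s$temperature_C, s$target_gene, replicate = r)
      )
    })
  })
  out <- as_sip_profile(dplyr::bind_rows(profiles))
  list(profiles = out, truth = list(true_shift = s$true_shift))
}
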