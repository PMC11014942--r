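#' Define an isotopic endmember
#'
#' An endmember is a nitrate source pool with a characteristic oxygen-isotope
#' composition: its \eqn{\delta^{18}}O (vs VSMOW) and its mass-independent
#' anomaly \eqn{\Delta^{17}}O, each with a 1-sigma uncertainty. Two-endmember
#' mixing apportions an observation between such pools.
#'
#' @param name Label, e.g. `"atmospheric"` or `"biological"`.
#' @param d18O delta-18O of the pool, per mil vs VSMOW.
#' @param sigma_d18O 1-sigma uncertainty on `d18O`, per mil (>= 0).
#' @param D17O Delta-17O anomaly of the pool, per mil.
#' @param sigma_D17O 1-sigma uncertainty on `D17O`, per mil (>= 0).
#'
#' @return An object of class `"endmember"` (a named list).
#' @examples
#' endmember("atmospheric", d18O = 92, D17O = 32)
#' @export
endmember <- function(name, d18O, sigma_d18O = 0, D17O = 0, sigma_D17O = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  ns_stopifnot_finite(d18O, "d18O")
  ns_stopifnot_finite(D17O, "D17O")
  ns_check_sigma(sigma_d18O, "sigma_d18O")
  ns_check_sigma(sigma_D17O, "sigma_D17O")
  structure(
    list(name = name, d18O = d18O, sigma_d18O = sigma_d18O,
         D17O = D17O, sigma_D17O = sigma_D17O),
    class = "endmember"
  )
}

#' @export
print.endmember <- function(x, ...) {
  cat(sprintf("<endmember> %s: d18O = %g +/- %g permil, D17O = %g +/- %g permil\n",
              x$name, x$d18O, x$sigma_d18O, x$D17O, x$sigma_D17O))
  invisible(x)
}

#' Default atmospheric and biological nitrate endmembers
#'
#' The shipped constants for coastal East Antarctica: atmospheric nitrate
#' delta-18O ~92 per mil with Delta-17O ~32 per mil (annual means at a coastal
#' station), and biologically produced (nitrification-derived) nitrate with
#' delta-18O ~0.6 per mil and Delta-17O of 0 per mil. The biological delta-18O
#' constant is the published field value; the value implied by the 1:2
#' O2:water mixing arithmetic is available separately from
#' [biological_endmember_d18O()] and is not silently substituted.
#'
#' @return Named list with elements `atmospheric` and `biological`, each an
#'   [endmember()].
#' @export
default_endmembers <- function() {
  list(
    atmospheric = endmember("atmospheric", d18O = 92, sigma_d18O = 0,
                            D17O = 32, sigma_D17O = 0),
    biological  = endmember("biological", d18O = 0.6, sigma_d18O = 0,
                            D17O = 0, sigma_D17O = 0)
  )
}

#' Read an endmember pair from a YAML config file
#'
#' The file holds two top-level keys, `atmospheric` and `biological`, each
#' with `d18O`, `D17O` and optional `sigma_d18O` / `sigma_D17O` (per mil).
#' A default config with the shipped constants is installed at
#' `system.file("extdata", "endmembers.yaml", package = "nitrosource")`.
#'
#' @param path Path to a YAML file.
#' @return Named list of two [endmember()] objects.
#' @export
read_endmember_config <- function(path) {
  if (!file.exists(path)) {
    ns_abort(sprintf("Endmember config not found: %s", path),
             class = "nitrosource_error_config")
  }
  cfg <- yaml::read_yaml(path)
  for (nm in c("atmospheric", "biological")) {
    if (is.null(cfg[[nm]]) || is.null(cfg[[nm]]$d18O)) {
      ns_abort(sprintf("Endmember config must define `%s` with a `d18O` value.", nm),
               class = "nitrosource_error_config")
    }
  }
  mk <- function(nm) {
    e <- cfg[[nm]]
    endmember(nm, d18O = e$d18O,
              sigma_d18O = e$sigma_d18O %||% 0,
              D17O = e$D17O %||% 0,
              sigma_D17O = e$sigma_D17O %||% 0)
  }
  list(atmospheric = mk("atmospheric"), biological = mk("biological"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
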