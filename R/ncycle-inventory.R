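#' Build a gene-to-process panel
#'
#' A panel maps nitrogen-cycle (or other metabolic) processes to the marker
#' genes that evidence them. `processes` is a named list of character vectors;
#' `rules` optionally sets, per process, whether any one gene (`"any"`, the
#' default) or all genes (`"all"`) must be detected for the process to count
#' as present in presence screening.
#'
#' @param processes Named list: process name -> character vector of gene
#'   symbols.
#' @param rules Optional named character vector (`"any"`/`"all"`), recycled to
#'   `"any"` for unlisted processes.
#' @param aliases Optional named character vector mapping alternative
#'   (lower-case) gene spellings to canonical symbols. Matching is always
#'   case-insensitive; aliases are explicit, never fuzzy.
#' @return Object of class `"gene_process_map"`.
#' @export
gene_process_map <- function(processes, rules = NULL, aliases = NULL) {
  if (!is.list(processes) ||
      (length(processes) > 0L &&
       (is.null(names(processes)) || any(names(processes) == "")))) {
    ns_abort("`processes` must be a named list of gene vectors.",
             class = "nitrosource_error_config")
  }
  processes <- lapply(processes, as.character)
  if (any(vapply(processes, length, 1L) == 0L)) {
    ns_abort("Every process must map to at least one gene.",
             class = "nitrosource_error_config")
  }
  rule <- stats::setNames(rep("any", length(processes)), names(processes))
  if (!is.null(rules)) {
    bad <- setdiff(names(rules), names(processes))
    if (length(bad) > 0L) {
      ns_abort(sprintf("Rules refer to unknown process(es): %s",
                       paste(bad, collapse = ", ")),
               class = "nitrosource_error_config")
    }
    if (!all(rules %in% c("any", "all"))) {
      ns_abort("Rules must be 'any' or 'all'.",
               class = "nitrosource_error_config")
    }
    rule[names(rules)] <- rules
  }
  structure(
    list(processes = processes, rule = rule,
         aliases = aliases %||% character()),
    class = "gene_process_map"
  )
}

#' @export
print.gene_process_map <- function(x, ...) {
  cat(sprintf("<gene_process_map> %d processes\n", length(x$processes)))
  for (p in names(x$processes)) {
    cat(sprintf("  %s [%s]: %s\n", p, x$rule[[p]],
                paste(x$processes[[p]], collapse = ", ")))
  }
  invisible(x)
}

#' Default nitrogen-cycle marker panel
#'
#' The canonical process-to-marker map used for qPCR-style inventories of
#' nitrogen cycling potential: N2 fixation (nifH), nitrification (amoA, hao,
#' nxrB), denitrification (napA, narG, nirS, nirK, norB, nosZ), DNRA (nrfA),
#' assimilatory nitrite reduction (nasA, nirA), and anammox (hzo, hzs).
#'
#' nirS/nirK occur in nitrifiers as well as denitrifiers; the default map
#' counts them under denitrification only. Pass `dual_nir = TRUE` to also
#' credit them to a `nitrifier_NO2_reduction` process.
#'
#' @param dual_nir Also map nirS/nirK to nitrifier nitrite reduction?
#' @return A [gene_process_map()].
#' @export
ncycle_panel <- function(dual_nir = FALSE) {
  procs <- list(
    N2_fixation     = "nifH",
    nitrification   = c("amoA", "hao", "nxrB"),
    denitrification = c("napA", "narG", "nirS", "nirK", "norB", "nosZ"),
    DNRA            = "nrfA",
    ANR             = c("nasA", "nirA"),
    anammox         = c("hzo", "hzs")
  )
  if (dual_nir) {
    procs$nitrifier_NO2_reduction <- c("nirS", "nirK")
  }
  gene_process_map(procs)
}

#' Read a marker panel from a YAML file
#'
#' The file has a top-level `processes` mapping (process -> gene list) and
#' optional `rules` and `aliases` mappings. Two panels ship with the package:
#' `ncycle_panel.yaml` (the nitrogen-cycle map of [ncycle_panel()]) and
#' `energy_panel.yaml` (respiration / carbon-fixation / trace-gas markers),
#' under `system.file("extdata", package = "nitrosource")`.
#'
#' @param path Path to the YAML panel.
#' @return A [gene_process_map()].
#' @export
read_panel_yaml <- function(path) {
  if (!file.exists(path)) {
    ns_abort(sprintf("Panel file not found: %s", path),
             class = "nitrosource_error_config")
  }
  y <- yaml::read_yaml(path)
  if (is.null(y$processes)) {
    ns_abort("Panel YAML must have a top-level `processes` mapping.",
             class = "nitrosource_error_config")
  }
  gene_process_map(y$processes,
                   rules = if (!is.null(y$rules)) unlist(y$rules),
                   aliases = if (!is.null(y$aliases)) unlist(y$aliases))
}

# Resolve annotation-table column symbols against panel genes:
# case-insensitive exact match, then the panel's explicit alias table.
resolve_genes <- function(columns, map) {
  panel_genes <- unique(as.character(unlist(map$processes, use.names = FALSE)))
  lookup <- stats::setNames(panel_genes, tolower(panel_genes))
  if (length(map$aliases) > 0L) {
    lookup <- c(lookup, stats::setNames(as.character(map$aliases),
                                        tolower(names(map$aliases))))
  }
  resolved <- unname(lookup[tolower(columns)])
  tibble::tibble(column = columns, gene = resolved,
                 mapped = !is.na(resolved))
}

#' Validate an annotation table
#'
#' @param table Data frame: one `sample_id` column plus one numeric column per
#'   gene symbol (copies per ng DNA, relative abundance, or presence counts;
#'   all values >= 0).
#' @return A tibble with `sample_id` first.
#' @export
validate_annotation_table <- function(table) {
  df <- tibble::as_tibble(table)
  if (!"sample_id" %in% names(df)) {
    ns_abort("Annotation table needs a `sample_id` column.",
             class = "nitrosource_error_schema")
  }
  gene_cols <- setdiff(names(df), "sample_id")
  if (length(gene_cols) == 0L) {
    ns_abort("Annotation table has no gene columns.",
             class = "nitrosource_error_empty_inventory")
  }
  for (g in gene_cols) {
    if (!is.numeric(df[[g]]) || any(!is.finite(df[[g]])) || any(df[[g]] < 0)) {
      ns_abort(sprintf("Gene column `%s` must be finite, non-negative numeric.", g),
               class = "nitrosource_error_schema")
    }
  }
  dplyr::relocate(df, "sample_id")
}

#' Aggregate marker-gene abundances into a process-by-sample inventory
#'
#' For each process in the panel, aggregates the abundances of its genes
#' present in the table (`sum` by default: per-gene abundances jointly
#' evidence a process; `max` takes the strongest single marker). A gene
#' mapped to several processes contributes to each. Presence is defined as
#' aggregated abundance strictly above `threshold`; a process absent in every
#' sample lands on the global absence list.
#'
#' @param table Annotation table (see [validate_annotation_table()]).
#' @param map A [gene_process_map()]; default [ncycle_panel()].
#' @param agg `"sum"` or `"max"`.
#' @param threshold Detection threshold on the aggregated abundance
#'   (>= 0; default 0, i.e. any positive signal counts). For qPCR-style
#'   copies-per-ng data a threshold of 10 is a conventional
#'   low-quantity yardstick.
#' @return Object of class `"ncycle_inventory"`: list with `abundance` and
#'   `presence` (process x sample matrices), `absent_by_sample`,
#'   `absent_global`, `unmapped_genes`, `threshold`, `agg`.
#' @examples
#' tab <- tibble::tibble(sample_id = "s1", nifH = 100, hzo = 0, hzs = 0)
#' inv <- build_inventory(tab)
#' inv$absent_global
#' @export
build_inventory <- function(table, map = ncycle_panel(),
                            agg = c("sum", "max"), threshold = 0) {
  agg <- match.arg(agg)
  if (!inherits(map, "gene_process_map")) {
    ns_abort("`map` must be a gene_process_map.",
             class = "nitrosource_error_config")
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0) {
    ns_abort("`threshold` must be a single number >= 0.",
             class = "nitrosource_error_config")
  }
  df <- validate_annotation_table(table)
  gene_cols <- setdiff(names(df), "sample_id")
  res <- resolve_genes(gene_cols, map)
  if (!any(res$mapped)) {
    ns_abort("No annotation column maps to any panel gene.",
             class = "nitrosource_error_empty_inventory")
  }

  samples <- df$sample_id
  procs <- names(map$processes)
  abundance <- matrix(0, nrow = length(procs), ncol = length(samples),
                      dimnames = list(procs, samples))
  aggfun <- if (agg == "sum") {
    function(m) colSums(m)
  } else {
    function(m) apply(m, 2, max)
  }
  for (p in procs) {
    cols <- res$column[res$mapped & res$gene %in% map$processes[[p]]]
    if (length(cols) == 0L) next
    m <- t(as.matrix(df[, cols, drop = FALSE]))
    abundance[p, ] <- aggfun(m)
  }
  presence <- abundance > threshold
  absent_by_sample <- apply(presence, 2, function(col) procs[!col],
                            simplify = FALSE)
  absent_global <- procs[rowSums(presence) == 0L]

  structure(
    list(abundance = abundance, presence = presence,
         absent_by_sample = absent_by_sample, absent_global = absent_global,
         unmapped_genes = res$column[!res$mapped],
         threshold = threshold, agg = agg),
    class = "ncycle_inventory"
  )
}

#' @export
print.ncycle_inventory <- function(x, ...) {
  cat(sprintf("<ncycle_inventory> %d processes x %d samples (agg = %s, threshold = %g)\n",
              nrow(x$abundance), ncol(x$abundance), x$agg, x$threshold))
  if (length(x$absent_global) > 0L) {
    cat("  globally absent:", paste(x$absent_global, collapse = ", "), "\n")
  }
  if (length(x$unmapped_genes) > 0L) {
    cat("  unmapped columns:", paste(x$unmapped_genes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Compare two inventories process by process
#'
#' For each process, contrasts the mean aggregated abundance across samples
#' and whether the process is detected (in any sample) in each group — e.g.
#' soils versus lake sediments.
#'
#' @param inv_a,inv_b [build_inventory()] results over the same process set.
#' @return Tibble: `process`, `abundance_a`, `abundance_b`, `difference`
#'   (a - b), `present_a`, `present_b`, `concordant`.
#' @export
compare_groups <- function(inv_a, inv_b) {
  if (!inherits(inv_a, "ncycle_inventory") || !inherits(inv_b, "ncycle_inventory")) {
    ns_abort("Both arguments must be ncycle_inventory objects.",
             class = "nitrosource_error_config")
  }
  pa <- rownames(inv_a$abundance)
  pb <- rownames(inv_b$abundance)
  if (!setequal(pa, pb) || length(intersect(pa, pb)) == 0L) {
    ns_abort("Inventories have mismatched process sets.",
             class = "nitrosource_error_schema")
  }
  procs <- pa
  a_mean <- rowMeans(inv_a$abundance[procs, , drop = FALSE])
  b_mean <- rowMeans(inv_b$abundance[procs, , drop = FALSE])
  a_pres <- rowSums(inv_a$presence[procs, , drop = FALSE]) > 0L
  b_pres <- rowSums(inv_b$presence[procs, , drop = FALSE]) > 0L
  tibble::tibble(
    process = procs,
    abundance_a = unname(a_mean), abundance_b = unname(b_mean),
    difference = unname(a_mean - b_mean),
    present_a = unname(a_pres), present_b = unname(b_pres),
    concordant = unname(a_pres == b_pres)
  )
}

#' Screen rows against a marker panel
#'
#' Produces a boolean feature-by-row presence matrix in the style of
#' genome-level metabolic screens: a feature is present in a row when its
#' marker genes exceed the threshold under the panel's per-process rule
#' (`any` gene, or `all` genes).
#'
#' @param table Annotation table (rows may be samples or genomes).
#' @param panel A [gene_process_map()]; e.g. the shipped energy/carbon panel
#'   via `read_panel_yaml(system.file("extdata", "energy_panel.yaml",
#'   package = "nitrosource"))`.
#' @param threshold Per-gene detection threshold (default 0).
#' @return Logical matrix, features x rows. An empty panel gives a
#'   zero-row matrix.
#' @export
screen_markers <- function(table, panel, threshold = 0) {
  if (!inherits(panel, "gene_process_map")) {
    ns_abort("`panel` must be a gene_process_map.",
             class = "nitrosource_error_config")
  }
  df <- validate_annotation_table(table)
  gene_cols <- setdiff(names(df), "sample_id")
  res <- resolve_genes(gene_cols, panel)
  samples <- df$sample_id
  procs <- names(panel$processes)
  out <- matrix(FALSE, nrow = length(procs), ncol = length(samples),
                dimnames = list(procs, samples))
  for (p in procs) {
    cols <- res$column[res$mapped & res$gene %in% panel$processes[[p]]]
    if (length(cols) == 0L) next
    det <- as.matrix(df[, cols, drop = FALSE]) > threshold
    out[p, ] <- if (panel$rule[[p]] == "all") {
      apply(det, 1, all)
    } else {
      apply(det, 1, any)
    }
  }
  out
}
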