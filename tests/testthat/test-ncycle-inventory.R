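test_that("default panel maps each process to its canonical markers", {
  p <- ncycle_panel()
  expect_setequal(names(p$processes),
                  c("N2_fixation", "nitrification", "denitrification",
                    "DNRA", "ANR", "anammox"))
  expect_setequal(p$processes$nitrification, c("amoA", "hao", "nxrB"))
  expect_setequal(p$processes$denitrification,
                  c("napA", "narG", "nirS", "nirK", "norB", "nosZ"))
  expect_setequal(p$processes$anammox, c("hzo", "hzs"))
  dual <- ncycle_panel(dual_nir = TRUE)
  expect_setequal(dual$processes$nitrifier_NO2_reduction, c("nirS", "nirK"))
})

test_that("inventory flags anammox absent when hzo/hzs carry no signal", {
  inv <- build_inventory(make_anammox_free_table())
  expect_identical(inv$absent_global, "anammox")
  others <- setdiff(rownames(inv$presence), "anammox")
  expect_true(all(inv$presence[others, ]))
  expect_true(all(!inv$presence["anammox", ]))
})

test_that("all-zero table renders every process absent", {
  tab <- make_anammox_free_table()
  tab[, -1] <- 0
  inv <- build_inventory(tab)
  expect_setequal(inv$absent_global, names(ncycle_panel()$processes))
})

test_that("gene-to-process attribution follows the map, incl. dual nir mapping", {
  tab <- tibble::tibble(sample_id = "g1", nirK = 5)
  inv <- build_inventory(tab)
  expect_equal(unname(inv$abundance["denitrification", "g1"]), 5)
  expect_equal(unname(inv$abundance["nitrification", "g1"]), 0)

  inv2 <- build_inventory(tab, map = ncycle_panel(dual_nir = TRUE))
  expect_equal(unname(inv2$abundance["denitrification", "g1"]), 5)
  expect_equal(unname(inv2$abundance["nitrifier_NO2_reduction", "g1"]), 5)
})

test_that("aggregation is sum by default, max optionally; thresholding is strict", {
  tab <- tibble::tibble(sample_id = "s", amoA = 3, hao = 4, nxrB = 5)
  expect_equal(unname(build_inventory(tab)$abundance["nitrification", "s"]), 12)
  expect_equal(
    unname(build_inventory(tab, agg = "max")$abundance["nitrification", "s"]), 5
  )
  # presence <=> aggregated abundance strictly above threshold
  inv <- build_inventory(tab, threshold = 12)
  expect_false(inv$presence["nitrification", "s"])
})

test_that("raising the threshold never turns an absent process present", {
  spec <- sim_spec(seed = 21)
  tab <- gen_annotation_table(spec)$table
  prev <- NULL
  for (thr in c(0, 10, 1e3, 1e5)) {
    inv <- build_inventory(tab, threshold = thr)
    if (!is.null(prev)) {
      expect_true(all(inv$presence <= prev))
    }
    prev <- inv$presence
  }
})

test_that("inventory is deterministic and symbol matching is case-insensitive", {
  tab <- make_anammox_free_table()
  expect_identical(build_inventory(tab), build_inventory(tab))

  renamed <- tab
  names(renamed)[names(renamed) == "nifH"] <- "NIFH"
  inv <- build_inventory(renamed)
  expect_true(all(inv$presence["N2_fixation", ]))
  expect_length(inv$unmapped_genes, 0)
})

test_that("unmapped columns are retained as flags, not matched fuzzily", {
  tab <- tibble::tibble(sample_id = "s", nifH = 1, amoB = 7, mystery = 2)
  inv <- build_inventory(tab)
  expect_setequal(inv$unmapped_genes, c("amoB", "mystery"))
  expect_error(build_inventory(tibble::tibble(sample_id = "s", foo = 1)),
               class = "nitrosource_error_empty_inventory")
})

test_that("compare_groups: self-comparison is null, a toggled process is discordant", {
  inv <- build_inventory(make_anammox_free_table())
  self <- compare_groups(inv, inv)
  expect_true(all(self$difference == 0))
  expect_true(all(self$concordant))

  tab_b <- make_anammox_free_table()
  tab_b$nifH <- 0
  inv_b <- build_inventory(tab_b)
  cmp <- compare_groups(inv, inv_b)
  expect_identical(cmp$process[!cmp$concordant], "N2_fixation")

  small <- build_inventory(tibble::tibble(sample_id = "s", nifH = 1),
                           map = gene_process_map(list(N2_fixation = "nifH")))
  expect_error(compare_groups(inv, small),
               class = "nitrosource_error_schema")
})

test_that("marker screening honours per-process any/all rules and empty panels", {
  tab <- tibble::tibble(sample_id = c("g1", "g2"),
                        coxL = c(10, 0), rbcL = c(0, 3), cbbL = c(5, 2))
  panel <- gene_process_map(
    list(CO_oxidation = "coxL", CBB_cycle = c("rbcL", "cbbL")),
    rules = c(CBB_cycle = "all")
  )
  m <- screen_markers(tab, panel)
  expect_true(m["CO_oxidation", "g1"])
  expect_false(m["CO_oxidation", "g2"])
  expect_false(m["CBB_cycle", "g1"])   # rbcL missing, rule = all
  expect_true(m["CBB_cycle", "g2"])

  empty <- screen_markers(tab, gene_process_map(stats::setNames(list(), character())))
  expect_equal(dim(empty), c(0L, 2L))
})

test_that("shipped YAML panels load and resolve aliases", {
  np <- read_panel_yaml(system.file("extdata", "ncycle_panel.yaml",
                                    package = "nitrosource"))
  expect_setequal(names(np$processes), names(ncycle_panel()$processes))

  ep <- read_panel_yaml(system.file("extdata", "energy_panel.yaml",
                                    package = "nitrosource"))
  tab <- tibble::tibble(sample_id = "g", cbbLR = 4)
  m <- screen_markers(tab, ep)
  expect_true(m["CBB_cycle", "g"])
})
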