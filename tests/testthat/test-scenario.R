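make_scenario_grid <- function(seed = 1, n = 50) {
  synth_habitat(
    n_rows = n, n_cols = n, cell_size = 100,
    prevalence = c(a = 0.4, b = 0.35, c = 0.25),
    correlation_length = 400, seed = seed
  )
}

test_that("grow_conversion hits its target exactly and touches only source cells", {
  g <- make_scenario_grid()
  base_a <- sum(g$classes == 1)
  for (seed in c(1, 99, 12345)) {
    res <- grow_conversion(g, conversion_rule("a", "b", 0.10), rng_seed = seed)
    diff_cells <- which(res$grid$classes != g$classes)
    expect_length(diff_cells, round(0.10 * base_a))
    expect_true(all(g$classes[diff_cells] == 1)) # only source cells changed
    expect_true(all(res$grid$classes[diff_cells] == 2))
    # total cell count conserved
    expect_equal(sum(class_areas(res$grid)$cells), sum(class_areas(g)$cells))
  }
})

test_that("degenerate fractions give identity and full conversion", {
  g <- make_scenario_grid(seed = 2)
  res0 <- grow_conversion(g, conversion_rule("a", "b", 1e-9), rng_seed = 1)
  expect_identical(res0$grid$classes, g$classes)
  res1 <- grow_conversion(g, conversion_rule("a", "b", 1.0), rng_seed = 1)
  expect_equal(sum(res1$grid$classes == 1), 0)
  expect_equal(
    sum(res1$grid$classes == 2),
    sum(g$classes == 2) + sum(g$classes == 1)
  )
})

test_that("converted cells form at most n_seeds patches, at least one", {
  g <- make_scenario_grid(seed = 3)
  res <- grow_conversion(g, conversion_rule("a", "c", 0.15),
    n_seeds = 20, rng_seed = 7
  )
  changed <- res$grid$classes != g$classes
  mask_grid <- habitat_grid(
    matrix(ifelse(changed, 1L, 0L), nrow(changed)),
    g$spec, c(no = 0, yes = 1)
  )
  lab <- label_patches(mask_grid, "yes", connectivity = 8L)
  expect_gte(lab$np, 1)
  expect_lte(lab$np, 20)
})

test_that("apply_scenario computes targets from the baseline before any rule", {
  g <- make_scenario_grid(seed = 4)
  scn <- scenario("swap", dplyr::bind_rows(
    conversion_rule("a", "b", 0.10),
    conversion_rule("b", "a", 0.10) # same class both directions
  ))
  base <- class_areas(g)
  res <- apply_scenario(g, scn, rng_seed = 11)
  # rule 2's target uses baseline b area, not b inflated by rule 1
  expect_equal(
    res$summary$rules$target_cells,
    c(round(0.10 * base$cells[1]), round(0.10 * base$cells[2]))
  )
  expect_equal(res$summary$rules$converted_cells, res$summary$rules$target_cells)
})

test_that("the reduced-grazing scenario moves the published percentages", {
  land <- paper_like_landscape(seed = 5)
  g <- land$grid
  base <- class_areas(g)
  grazed0 <- base$cells[base$class == "grazed"]
  scn <- paper_like_scenarios()$reduced_grazing
  res <- apply_scenario(g, scn, rng_seed = 21)
  cl <- res$summary$classes
  # net grazed change = -10% of baseline grazed, moorland +7%, open canopy +3%
  expect_equal(cl$net_cells[cl$class == "grazed"], -round(0.07 * grazed0) - round(0.03 * grazed0))
  expect_lte(abs(cl$net_cells[cl$class == "grazed"] + 0.10 * grazed0), 1)
  expect_lte(abs(cl$net_cells[cl$class == "moorland"] - 0.07 * grazed0), 1)
  expect_lte(abs(cl$net_cells[cl$class == "open_canopy"] - 0.03 * grazed0), 1)
})

test_that("the increased grouse moor scenario draws on both published sources", {
  land <- paper_like_landscape(seed = 6)
  g <- land$grid
  base <- class_areas(g)
  grazed0 <- base$cells[base$class == "grazed"]
  open0 <- base$cells[base$class == "open_canopy"]
  res <- apply_scenario(g, paper_like_scenarios()$increased_grouse_moor, rng_seed = 3)
  cl <- res$summary$classes
  expect_lte(abs(cl$net_cells[cl$class == "moorland"] - (0.05 * grazed0 + 0.05 * open0)), 2)
  expect_lte(abs(cl$net_cells[cl$class == "grazed"] + 0.05 * grazed0), 1)
  expect_lte(abs(cl$net_cells[cl$class == "open_canopy"] + 0.05 * open0), 1)
})

test_that("infeasible conversions raise infeasible-scenario errors", {
  g <- habitat_grid(
    matrix(c(1L, 1L, 1L, 2L), 2, 2), grid_spec(2, 2, 30),
    c(a = 1, b = 2)
  )
  # a scenario whose second rule needs source cells consumed by the first
  scn <- scenario("bad", dplyr::bind_rows(
    conversion_rule("a", "b", 1.0),
    conversion_rule("a", "b", 0.5)
  ))
  expect_error(apply_scenario(g, scn, rng_seed = 1), class = "scenhab_error_infeasible")
})

test_that("null scenarios leave every class area unchanged", {
  land <- paper_like_landscape(seed = 7)
  g <- land$grid
  for (scn in paper_like_scenarios()[c("increased_grazing", "increased_open_canopy")]) {
    nul <- null_scenario(scn, g)
    expect_equal(nrow(nul$rules), 2 * nrow(scn$rules))
    res <- apply_scenario(g, nul, rng_seed = 13)
    per_rule_pairs <- nrow(scn$rules)
    expect_true(all(abs(res$summary$classes$net_cells) <= per_rule_pairs))
    # total converted area is twice the original scenario's
    orig <- apply_scenario(g, scn, rng_seed = 13)
    expect_lte(
      abs(sum(res$summary$rules$converted_cells) - 2 * sum(orig$summary$rules$converted_cells)),
      per_rule_pairs
    )
  }
  # a zero-fraction scenario's null is still an identity
  z <- scenario("zero", conversion_rule("grazed", "moorland", 0))
  nulz <- null_scenario(z, g)
  resz <- apply_scenario(g, nulz, rng_seed = 2)
  expect_identical(resz$grid$classes, g$classes)
})

test_that("ensembles are reproducible and runs differ in layout, not composition", {
  g <- make_scenario_grid(seed = 8, n = 40)
  scn <- scenario("mix", conversion_rule("a", "c", 0.12))
  e1 <- run_ensemble(g, scn, n_runs = 2, base_seed = 100)
  e2 <- run_ensemble(g, scn, n_runs = 2, base_seed = 100)
  expect_identical(e1$grid[[1]]$classes, e2$grid[[1]]$classes)
  expect_identical(e1$grid[[2]]$classes, e2$grid[[2]]$classes)
  # n_runs = 1 equals apply_scenario at that seed
  single <- apply_scenario(g, scn, rng_seed = 101)
  expect_identical(e1$grid[[1]]$classes, single$grid$classes)

  e30 <- run_ensemble(g, scn, n_runs = 30, base_seed = 7)
  nets <- vapply(e30$summary, function(s) s$classes$net_cells[1], numeric(1))
  expect_true(all(nets == nets[1])) # identical per-class net change
  layouts <- vapply(e30$grid, function(gr) paste(gr$classes, collapse = ""), character(1))
  expect_gt(length(unique(layouts)), 25) # distinct landscapes
})

test_that("extent sweep scales targets linearly and preserves rule splits", {
  land <- paper_like_landscape(seed = 9)
  g <- land$grid
  grazed0 <- class_areas(g)$cells[2]
  scn <- paper_like_scenarios()$reduced_grazing # nominal 10%, split 7:3
  sw <- extent_sweep(g, scn, levels = c(5, 10, 20), n_runs = 1, base_seed = 40)
  expect_equal(unique(sw$level), c(5, 10, 20))
  tgt <- function(lev) {
    s <- sw$summary[[which(sw$level == lev)]]
    s$rules$target_cells
  }
  # level equal to the nominal total reproduces apply_scenario's targets
  direct <- apply_scenario(g, scn, rng_seed = 1)
  expect_equal(tgt(10), direct$summary$rules$target_cells)
  # level 20 doubles: 14% moor / 6% open canopy of baseline grazed
  expect_lte(max(abs(tgt(20) - c(round(0.14 * grazed0), round(0.06 * grazed0)))), 1)
  # level 5 is half of level 10
  expect_lte(max(abs(2 * tgt(5) - tgt(10))), 2)
})

test_that("scenarios round-trip through JSON and YAML", {
  scn <- paper_like_scenarios()$increased_closed_canopy
  for (ext in c(".json", ".yaml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_scenario(scn, path)
    scn2 <- read_scenario(path)
    expect_equal(scn2$name, scn$name)
    expect_equal(scn2$rules, scn$rules)
    expect_equal(scn2$growth_prob, scn$growth_prob)
  }
})
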