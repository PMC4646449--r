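#' Land-use conversion rule
#'
#' One declarative landscape change: convert a given fraction of the baseline
#' area of a source class into a destination class.
#'
#' @param source,dest Class names (resolved against the grid legend when the
#'   rule is applied). Must differ.
#' @param fraction Fraction of the baseline source-class area to convert, in
#'   `[0, 1]`.
#' @return A one-row tibble (`source`, `dest`, `fraction`).
#' @export
conversion_rule <- function(source, dest, fraction) {
  if (identical(source, dest)) {
    rlang::abort("source and dest classes must differ", class = "scenhab_error_parameter")
  }
  if (fraction < 0 || fraction > 1) {
    rlang::abort("fraction must be in [0, 1]", class = "scenhab_error_parameter")
  }
  tibble::tibble(source = source, dest = dest, fraction = fraction)
}

#' Land-use-change scenario
#'
#' A named set of conversion rules plus the patch-growth parameters that
#' control how the change is laid out: number of random starting locations
#' per rule, the per-cell growth probability, and neighbourhood connectivity.
#'
#' @param name Scenario name.
#' @param rules A tibble of [conversion_rule()]s (bind rows to combine).
#' @param n_seeds Random starting locations per rule (default 20).
#' @param growth_prob Probability that a frontier cell converts in one sweep
#'   (default 0.25); shapes the patches, not the final area.
#' @param connectivity 4 or 8 (default 8).
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, rules, n_seeds = 20L, growth_prob = 0.25, connectivity = 8L) {
  if (nrow(rules) == 0) rlang::abort("rules must be nonempty", class = "scenhab_error_parameter")
  if (n_seeds < 1) rlang::abort("n_seeds must be >= 1", class = "scenhab_error_parameter")
  if (growth_prob <= 0 || growth_prob > 1) {
    rlang::abort("growth_prob must be in (0, 1]", class = "scenhab_error_parameter")
  }
  if (!connectivity %in% c(4L, 8L)) {
    rlang::abort("connectivity must be 4 or 8", class = "scenhab_error_parameter")
  }
  structure(
    list(
      name = name, rules = rules, n_seeds = as.integer(n_seeds),
      growth_prob = growth_prob, connectivity = as.integer(connectivity)
    ),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario> '%s': %d rule(s), %d seeds, p = %g, %d-neighbour\n",
    x$name, nrow(x$rules), x$n_seeds, x$growth_prob, x$connectivity
  ))
  for (i in seq_len(nrow(x$rules))) {
    r <- x$rules[i, ]
    cat(sprintf("  %g%% of %s -> %s\n", 100 * r$fraction, r$source, r$dest))
  }
  invisible(x)
}

# Logical matrix: cells with at least one TRUE neighbour in `m`.
neighbor_any <- function(m, connectivity = 8L) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(FALSE, nr, nc)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8L) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  for (o in offs) {
    sr <- max(1, 1 + o[1]):min(nr, nr + o[1])
    sc <- max(1, 1 + o[2]):min(nc, nc + o[2])
    out[sr, sc] <- out[sr, sc] | m[sr - o[1], sc - o[2]]
  }
  out
}

resolve_class <- function(legend, cls) {
  if (is.character(cls)) {
    if (!cls %in% names(legend)) {
      rlang::abort(sprintf("class '%s' not in legend", cls), class = "scenhab_error_mapping")
    }
    unname(legend[cls])
  } else {
    as.integer(cls)
  }
}

# Core stochastic patch growth for one rule. `target` cells of `source_code`
# (outside `frozen`) become `dest_code`, grown from `n_seeds` random starting
# cells. Seeds convert immediately; afterwards each sweep visits every
# frontier cell (source cells adjacent to converted cells) and converts it
# with probability `growth_prob`; the sweep that overshoots the target has a
# random surplus subset un-converted so the target is hit exactly. When all
# frontiers are exhausted a fresh seed is drawn; an exhausted source class is
# an infeasible scenario.
grow_cells <- function(classes, source_code, dest_code, target, n_seeds,
                       growth_prob, connectivity, frozen) {
  avail <- !is.na(classes) & classes == source_code & !frozen
  if (target > sum(avail)) {
    rlang::abort(sprintf(
      "conversion target (%d cells) exceeds available source cells (%d)",
      target, sum(avail)
    ), class = "scenhab_error_infeasible")
  }
  converted <- matrix(FALSE, nrow(classes), ncol(classes))
  if (target == 0) {
    return(converted)
  }
  pick <- function(x, k) x[sample.int(length(x), k)] # safe for length-1 x
  k <- min(n_seeds, target)
  seeds <- pick(which(avail), k)
  converted[seeds] <- TRUE
  avail[seeds] <- FALSE
  count <- k
  while (count < target) {
    frontier <- which(avail & neighbor_any(converted, connectivity))
    if (length(frontier) == 0) {
      if (!any(avail)) {
        rlang::abort("source class exhausted before reaching the conversion target",
          class = "scenhab_error_infeasible"
        )
      }
      reseed <- pick(which(avail), 1)
      converted[reseed] <- TRUE
      avail[reseed] <- FALSE
      count <- count + 1
      next
    }
    grown <- frontier[stats::runif(length(frontier)) < growth_prob]
    if (count + length(grown) > target) {
      # this sweep overshoots: un-convert a random surplus to hit the target
      grown <- grown[sample.int(length(grown), target - count)]
    }
    converted[grown] <- TRUE
    avail[grown] <- FALSE
    count <- count + length(grown)
  }
  converted
}

#' Grow one conversion rule on a landscape
#'
#' Converts exactly `round(fraction * baseline source cells)` cells of the
#' rule's source class into its destination class, as `n_seeds` stochastically
#' grown patches. Deterministic given `rng_seed`; only source-class cells
#' change.
#'
#' @param grid A [habitat_grid()].
#' @param rule A [conversion_rule()] (one-row tibble).
#' @param n_seeds,growth_prob,connectivity Growth parameters, see
#'   [scenario()].
#' @param rng_seed Integer seed.
#' @return A list with `grid` (the changed [habitat_grid()]) and `summary`
#'   (a [change_summary()]).
#' @export
grow_conversion <- function(grid, rule, n_seeds = 20L, growth_prob = 0.25,
                            connectivity = 8L, rng_seed = 1L) {
  sc <- scenario("rule", rule,
    n_seeds = n_seeds, growth_prob = growth_prob,
    connectivity = connectivity
  )
  apply_scenario(grid, sc, rng_seed)
}

#' Apply a scenario to a landscape
#'
#' Conversion targets for every rule are computed from the baseline grid
#' before any rule runs; rules then execute sequentially, and later rules may
#' not consume cells converted earlier in the same run. Total cell count is
#' conserved and each rule converts exactly its target number of cells.
#'
#' @param grid Baseline [habitat_grid()].
#' @param scn A [scenario()].
#' @param rng_seed Integer seed; the full run is reproducible from it.
#' @return A list with `grid` (changed landscape) and `summary`
#'   ([change_summary()]).
#' @export
apply_scenario <- function(grid, scn, rng_seed = 1L) {
  classes <- grid$classes
  legend <- grid$legend
  rules <- scn$rules
  src <- vapply(rules$source, function(s) resolve_class(legend, s), integer(1))
  dst <- vapply(rules$dest, function(d) resolve_class(legend, d), integer(1))
  baseline_counts <- vapply(legend, function(code) {
    sum(classes == code, na.rm = TRUE)
  }, integer(1))
  targets <- round(rules$fraction * baseline_counts[match(src, legend)])
  frozen <- matrix(FALSE, nrow(classes), ncol(classes))
  converted_per_rule <- integer(nrow(rules))
  out <- classes
  withr::with_seed(rng_seed, {
    for (i in seq_len(nrow(rules))) {
      conv <- grow_cells(
        out, src[i], dst[i], targets[i], scn$n_seeds,
        scn$growth_prob, scn$connectivity, frozen
      )
      out[conv] <- dst[i]
      frozen <- frozen | conv
      converted_per_rule[i] <- sum(conv)
    }
  })
  result <- habitat_grid(out, grid$spec, legend)
  summary <- change_summary(grid, result,
    rules = tibble::tibble(
      scenario = scn$name,
      rule = seq_len(nrow(rules)),
      source = rules$source, dest = rules$dest,
      fraction = rules$fraction,
      target_cells = as.integer(targets),
      converted_cells = converted_per_rule
    ),
    seed = rng_seed
  )
  list(grid = result, summary = summary)
}

#' Per-class and per-rule change summary
#'
#' @param baseline,result [habitat_grid()]s before and after a scenario run.
#' @param rules Per-rule conversion tibble (internal).
#' @param seed Run seed.
#' @return An object of class `change_summary` with tibbles `classes`
#'   (baseline/final/net cells and km2 per class) and `rules`, plus `seed`.
#' @export
change_summary <- function(baseline, result, rules = NULL, seed = NA_integer_) {
  b <- class_areas(baseline)
  f <- class_areas(result)
  classes <- tibble::tibble(
    class = b$class, code = b$code,
    baseline_cells = b$cells, final_cells = f$cells,
    net_cells = f$cells - b$cells,
    net_km2 = (f$cells - b$cells) * baseline$spec$cell_size^2 / 1e6
  )
  structure(list(classes = classes, rules = rules, seed = seed),
    class = "change_summary"
  )
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf("<change_summary> seed %s\n", x$seed))
  print(x$classes)
  if (!is.null(x$rules)) print(x$rules)
  invisible(x)
}

#' Matched null scenario with no net change in any class
#'
#' Extends a scenario with one reciprocal rule per original rule: if a rule
#' converts a target number of cells from class A to class B, the reciprocal
#' converts the same number of cells from B back to A (its fraction is the
#' original target divided by the baseline area of B). The result moves the
#' same amount of every habitat around the landscape while leaving every
#' class's net area unchanged, isolating configuration effects from
#' composition effects. A change and its exact reverse (e.g. increased vs
#' reduced grazing of the same magnitude) share the same null up to rule
#' composition.
#'
#' @param scn A [scenario()].
#' @param grid Baseline [habitat_grid()] providing class areas for the
#'   reciprocal fractions.
#' @return A [scenario()] named `<name>_null`.
#' @export
null_scenario <- function(scn, grid) {
  legend <- grid$legend
  counts <- vapply(legend, function(code) sum(grid$classes == code, na.rm = TRUE), integer(1))
  recip <- purrr::map_dfr(seq_len(nrow(scn$rules)), function(i) {
    r <- scn$rules[i, ]
    src_code <- resolve_class(legend, r$source)
    dst_code <- resolve_class(legend, r$dest)
    target <- round(r$fraction * counts[match(src_code, legend)])
    dest_count <- counts[match(dst_code, legend)]
    if (target > dest_count) {
      rlang::abort(sprintf(
        "null reciprocal of rule %d needs %d cells of '%s' but only %d exist",
        i, target, r$dest, dest_count
      ), class = "scenhab_error_infeasible")
    }
    frac <- if (target == 0) 0 else target / dest_count
    conversion_rule(r$dest, r$source, frac)
  })
  scenario(paste0(scn$name, "_null"), dplyr::bind_rows(scn$rules, recip),
    n_seeds = scn$n_seeds, growth_prob = scn$growth_prob,
    connectivity = scn$connectivity
  )
}

#' Run a scenario ensemble
#'
#' Generates `n_runs` independent simulated landscapes; run `i` uses seed
#' `base_seed + i`, so any single run is individually reproducible.
#'
#' @param grid Baseline [habitat_grid()].
#' @param scn A [scenario()].
#' @param n_runs Number of runs (default 30).
#' @param base_seed Integer base seed.
#' @return A tibble with columns `scenario`, `run`, `seed`, and list-columns
#'   `grid` ([habitat_grid()]s) and `summary` ([change_summary()]s).
#' @export
run_ensemble <- function(grid, scn, n_runs = 30L, base_seed = 1L) {
  if (n_runs < 1) rlang::abort("n_runs must be >= 1", class = "scenhab_error_parameter")
  runs <- purrr::map(seq_len(n_runs), function(i) apply_scenario(grid, scn, base_seed + i))
  tibble::tibble(
    scenario = scn$name,
    run = seq_len(n_runs),
    seed = base_seed + seq_len(n_runs),
    grid = purrr::map(runs, "grid"),
    summary = purrr::map(runs, "summary")
  )
}

#' Sweep the extent of a scenario's land-use change
#'
#' Rescales every rule's fraction so the scenario's total nominal conversion
#' equals each requested level (in percent of the respective source-class
#' areas), preserving the internal split between rules (a 7:3 split stays
#' 7:3 at every level), and runs an ensemble at each feasible level. Levels
#' whose scaled fractions exceed 1 are infeasible, reported with a warning
#' and skipped.
#'
#' @param grid Baseline [habitat_grid()].
#' @param scn A [scenario()].
#' @param levels Total conversion percentages to test (default 5-30%).
#' @param n_runs Runs per level.
#' @param base_seed Integer base seed; levels get independent seed blocks.
#' @return A tibble like [run_ensemble()]'s with an extra leading `level`
#'   column.
#' @export
extent_sweep <- function(grid, scn, levels = c(5, 10, 15, 20, 25, 30),
                         n_runs = 30L, base_seed = 1L) {
  if (any(levels <= 0 | levels > 100)) {
    rlang::abort("levels must be in (0, 100]", class = "scenhab_error_parameter")
  }
  nominal <- sum(scn$rules$fraction) * 100
  purrr::map_dfr(seq_along(levels), function(li) {
    lev <- levels[li]
    scale <- lev / nominal
    fr <- scn$rules$fraction * scale
    if (any(fr > 1)) {
      rlang::warn(sprintf("level %g%% infeasible (scaled fraction > 1); skipped", lev))
      return(NULL)
    }
    rules <- scn$rules
    rules$fraction <- fr
    scaled <- scenario(sprintf("%s@%g%%", scn$name, lev), rules,
      n_seeds = scn$n_seeds, growth_prob = scn$growth_prob,
      connectivity = scn$connectivity
    )
    ens <- run_ensemble(grid, scaled, n_runs = n_runs, base_seed = base_seed + 100000L * li)
    dplyr::mutate(ens, level = lev, .before = 1)
  })
}
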