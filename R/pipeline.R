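#' Minimum number of sites per indicator group
#'
#' For each indicator group — and for all species pooled (`"All species"`) —
#' finds the smallest set of cells in which every group member meets the
#' (occupancy-capped) representation goal, via [anneal()] in `min_set` mode.
#'
#' @param x An `assemblage`.
#' @param groups Group membership tibble from [build_all_groups()].
#' @param goal Representation goal in cells; default 3.
#' @param schedule [anneal_schedule()] for the minimum-set solves. The
#'   default (50k iterations, 3 restarts) is ample at synthetic scale, where
#'   instances have a few hundred cells.
#' @param seed Integer seed.
#' @return Tibble with columns `region`, `group`, `n_species`, `n_sites`.
#' @export
minimum_sites_table <- function(x, groups, goal = 3,
                                schedule = anneal_schedule(iterations = 50000,
                                                           restarts = 3),
                                seed = 1L) {
  stopifnot(inherits(x, "assemblage"))
  group_names <- unique(groups$group)
  scopes <- c(stats::setNames(
    lapply(group_names, function(g) group_members(groups, g)), group_names),
    list("All species" = species_ids(x)))
  rows <- purrr::imap(scopes, function(members, gname) {
    pa_sub <- x$pa[members, , drop = FALSE]
    tg <- capped_targets(pa_sub, goal)
    sol <- anneal(pa_sub, tg, mode = "min_set", schedule = schedule,
                  seed = mix_seed(seed, which(names(scopes) == gname)))
    tibble::tibble(region = x$region, group = gname,
                   n_species = length(members),
                   n_sites = length(sol$cells))
  })
  dplyr::bind_rows(rows)
}

#' Site budget from the least-demanding indicator group
#'
#' The evaluation budget for a region is the smallest minimum-set size over
#' the indicator groups (the pooled "All species" row is excluded), so every
#' group's best sites fit in a selection that at least one group can fully
#' satisfy — mirroring a design where the cheapest order sets the common
#' budget.
#'
#' @param sites_tbl Output of [minimum_sites_table()] for one region.
#' @return A positive integer.
#' @export
budget_from_smallest_group <- function(sites_tbl) {
  rows <- dplyr::filter(sites_tbl, .data$group != "All species")
  if (nrow(rows) == 0) stopf("sites table has no indicator-group rows")
  as.integer(min(rows$n_sites))
}

#' Percentage of target species represented by a selection
#'
#' A target species counts as represented when it is present in at least
#' `min(eval_threshold, occupancy)` selected cells; the per-species cap
#' means a species whose whole range is selected always counts, even when
#' its occupancy is below the threshold.
#'
#' @param solution A `reserve_solution`, or an integer vector of 0-based
#'   cell ids.
#' @param x An `assemblage` or 0/1 matrix.
#' @param target_species Character vector of target species ids (non-empty).
#' @param eval_threshold Cells a species must appear in to count; default 1.
#' @return A percentage in `[0, 100]`.
#' @export
representation_pct <- function(solution, x, target_species,
                               eval_threshold = 1) {
  eval_threshold <- assert_count(eval_threshold, "eval_threshold")
  if (length(target_species) == 0) stopf("target species set is empty")
  cells <- if (inherits(solution, "reserve_solution")) solution$cells
           else as.integer(solution)
  pa <- as_pa_matrix(x)
  miss <- setdiff(target_species, rownames(pa))
  if (length(miss)) stopf("unknown target species: %s", miss[1])
  pa_t <- pa[target_species, , drop = FALSE]
  rep_counts <- representation_counts(pa_t, cells)
  thr <- pmin(eval_threshold, rowSums(pa_t))
  100 * sum(rep_counts >= thr) / length(target_species)
}

#' Evaluate indicator groups in one region
#'
#' For every indicator group, plus a null model (a fresh random species set
#' each run) and an ideal model (all species), runs `n_runs` independently
#' seeded budget-constrained maximal-representation solves and scores each
#' solution by the percentage of target species represented. Target sets are
#' `"all"` (every species except the tested group's members) and each
#' indicator group (minus species shared with the tested group). Null and
#' ideal rows use unmodified target sets. Records whose target set empties
#' after removal are omitted.
#'
#' @param x An `assemblage`.
#' @param groups Group tibble from [build_all_groups()].
#' @param budget Number of cells per solution (from
#'   [budget_from_smallest_group()]); must not exceed the number of cells.
#' @param n_runs Solutions per group; default 20.
#' @param goal Representation goal used in the solver's targets; default 3.
#' @param eval_threshold Cells a species must occupy within the selection to
#'   count as represented; default 1.
#' @param null_set_size Size of each run's random species set; default the
#'   rounded mean indicator-group size in this region.
#' @param schedule [anneal_schedule()] per run; the default (10k iterations,
#'   1 restart) relies on the `n_runs` independent seeds for coverage of the
#'   solution space.
#' @param seed Integer seed; run seeds are derived sub-streams.
#' @return Long tibble: `region`, `group`, `run`, `target`,
#'   `representation_pct`.
#' @export
evaluate_region <- function(x, groups, budget, n_runs = 20, goal = 3,
                            eval_threshold = 1, null_set_size = NULL,
                            schedule = anneal_schedule(iterations = 10000,
                                                       restarts = 1),
                            seed = 1L) {
  stopifnot(inherits(x, "assemblage"))
  budget <- assert_count(budget, "budget")
  if (budget > ncol(x$pa)) {
    stopf("budget (%d) exceeds the number of cells (%d)", budget, ncol(x$pa))
  }
  group_names <- unique(groups$group)
  if (length(group_names) == 0) stopf("no indicator groups supplied")
  all_sp <- species_ids(x)
  member_list <- stats::setNames(
    lapply(group_names, function(g) group_members(groups, g)), group_names)
  null_set_size <- null_set_size %||%
    max(1L, as.integer(round(mean(lengths(member_list)))))

  units <- c(group_names, "null", "ideal")
  rows <- vector("list", length(units) * n_runs)
  k <- 0L
  for (ui in seq_along(units)) {
    unit <- units[ui]
    for (run in seq_len(n_runs)) {
      run_seed <- mix_seed(seed, ui * 10000L + run)
      scope <- switch(unit,
        null = with_seed(run_seed,
                         sample(all_sp, min(null_set_size, length(all_sp)))),
        ideal = all_sp,
        member_list[[unit]]
      )
      pa_sub <- x$pa[scope, , drop = FALSE]
      tg <- capped_targets(pa_sub, goal)
      sol <- anneal(pa_sub, tg, mode = "max_coverage", budget = budget,
                    schedule = schedule, seed = run_seed)
      indicator_members <- if (unit %in% group_names) member_list[[unit]]
                           else character(0)
      targets <- c(list(all = setdiff(all_sp, indicator_members)),
                   lapply(member_list, setdiff, y = indicator_members))
      names(targets) <- c("all", group_names)
      targets <- targets[lengths(targets) > 0]
      pct <- vapply(targets, function(ts) {
        representation_pct(sol, x, ts, eval_threshold)
      }, numeric(1))
      k <- k + 1L
      rows[[k]] <- tibble::tibble(region = x$region, group = unit, run = run,
                                  target = names(targets),
                                  representation_pct = unname(pct))
    }
  }
  dplyr::bind_rows(rows[seq_len(k)])
}

#' Evaluate a pair of regions and combine the tables
#'
#' Consistency is a two-region property: this runs [evaluate_region()] on
#' each region with its own groups and budget and concatenates the long
#' tables, preserving the region labels.
#'
#' @param a,b The two `assemblage` objects (distinct region labels).
#' @param groups_a,groups_b Group tibbles; built with [build_all_groups()]
#'   when omitted.
#' @param budget_a,budget_b Per-region budgets; when omitted they are
#'   derived from each region's [minimum_sites_table()] via
#'   [budget_from_smallest_group()].
#' @param goal,n_runs,eval_threshold,null_set_size,schedule,seed As in
#'   [evaluate_region()]; seeds are split into per-region sub-streams.
#' @return Combined evaluation tibble.
#' @export
evaluate_paired <- function(a, b, groups_a = NULL, groups_b = NULL,
                            budget_a = NULL, budget_b = NULL, goal = 3,
                            n_runs = 20, eval_threshold = 1,
                            null_set_size = NULL,
                            schedule = anneal_schedule(iterations = 10000,
                                                       restarts = 1),
                            seed = 1L) {
  if (!inherits(a, "assemblage") || !inherits(b, "assemblage")) {
    stopf("`a` and `b` must both be assemblages (two regions are required)")
  }
  if (identical(a$region, b$region)) {
    stopf("the two assemblages must carry distinct region labels")
  }
  groups_a <- groups_a %||% build_all_groups(a)
  groups_b <- groups_b %||% build_all_groups(b)
  if (is.null(budget_a)) {
    budget_a <- budget_from_smallest_group(
      minimum_sites_table(a, groups_a, goal, seed = mix_seed(seed, 11L)))
  }
  if (is.null(budget_b)) {
    budget_b <- budget_from_smallest_group(
      minimum_sites_table(b, groups_b, goal, seed = mix_seed(seed, 12L)))
  }
  out <- dplyr::bind_rows(
    evaluate_region(a, groups_a, budget_a, n_runs, goal, eval_threshold,
                    null_set_size, schedule, seed = mix_seed(seed, 21L)),
    evaluate_region(b, groups_b, budget_b, n_runs, goal, eval_threshold,
                    null_set_size, schedule, seed = mix_seed(seed, 22L))
  )
  attr(out, "budgets") <- stats::setNames(c(budget_a, budget_b),
                                          c(a$region, b$region))
  out
}

#' Run the full surrogacy analysis on a pair of synthetic regions
#'
#' End-to-end convenience wrapper: generates the paired hotspots, builds the
#' indicator groups, computes per-group minimum-set sizes and the per-region
#' budgets, runs the budget-constrained evaluation with null and ideal
#' models, and fits the ANOVA / Tukey / classification layer.
#'
#' @param config_a,config_b [assemblage_config()]s for the two regions;
#'   default [paired_hotspot_configs()] at desk scale.
#' @param seed Integer master seed.
#' @param goal,n_runs,eval_threshold,alpha Analysis knobs: representation
#'   goal (3), solutions per group (20), representation threshold (1),
#'   significance level (0.01).
#' @param schedule_sites,schedule_eval Annealing schedules for the two
#'   stages.
#' @return An object of class `surrogacy_result`: a list with `assemblages`,
#'   `groups`, `sites`, `budgets`, `evaluation`, `anova`, `tukey`,
#'   `classification`.
#' @export
run_surrogacy_analysis <- function(config_a = NULL, config_b = NULL,
                                   seed = 1L, goal = 3, n_runs = 20,
                                   eval_threshold = 1, alpha = 0.01,
                                   schedule_sites =
                                     anneal_schedule(iterations = 50000,
                                                     restarts = 3),
                                   schedule_eval =
                                     anneal_schedule(iterations = 10000,
                                                     restarts = 1)) {
  if (is.null(config_a) || is.null(config_b)) {
    cfg <- paired_hotspot_configs("desk")
    config_a <- config_a %||% cfg$a
    config_b <- config_b %||% cfg$b
  }
  hs <- generate_paired_hotspots(config_a, config_b, seed = seed)
  groups_a <- build_all_groups(hs$a)
  groups_b <- build_all_groups(hs$b)
  sites <- dplyr::bind_rows(
    minimum_sites_table(hs$a, groups_a, goal, schedule_sites,
                        seed = mix_seed(seed, 11L)),
    minimum_sites_table(hs$b, groups_b, goal, schedule_sites,
                        seed = mix_seed(seed, 12L))
  )
  budget_a <- budget_from_smallest_group(
    dplyr::filter(sites, .data$region == hs$a$region))
  budget_b <- budget_from_smallest_group(
    dplyr::filter(sites, .data$region == hs$b$region))
  evaluation <- dplyr::bind_rows(
    evaluate_region(hs$a, groups_a, budget_a, n_runs, goal, eval_threshold,
                    schedule = schedule_eval, seed = mix_seed(seed, 21L)),
    evaluate_region(hs$b, groups_b, budget_b, n_runs, goal, eval_threshold,
                    schedule = schedule_eval, seed = mix_seed(seed, 22L))
  )
  av <- two_way_anova(evaluation, target = "all")
  tk <- tukey_hsd(av, alpha = alpha)
  cl <- classify_groups(evaluation, tk, alpha = alpha)
  structure(
    list(assemblages = hs, groups = list(a = groups_a, b = groups_b),
         sites = sites,
         budgets = stats::setNames(c(budget_a, budget_b),
                                   c(hs$a$region, hs$b$region)),
         evaluation = evaluation, anova = av, tukey = tk,
         classification = cl, seed = seed),
    class = "surrogacy_result"
  )
}

#' @export
print.surrogacy_result <- function(x, ...) {
  cat(sprintf("<surrogacy_result> regions: %s\n",
              paste(names(x$budgets), collapse = ", ")))
  cat(sprintf("  budgets: %s\n",
              paste(sprintf("%s=%d", names(x$budgets), x$budgets),
                    collapse = ", ")))
  gl <- glance(x$anova)
  cat(sprintf("  overall model: F(%d, %d) = %.2f\n",
              gl$df_model, gl$df_residual, gl$statistic))
  eff <- x$classification$effectiveness
  cat(sprintf("  effective group-region combinations: %d of %d\n",
              sum(eff$effective), nrow(eff)))
  cons <- x$classification$consistency
  cat(sprintf("  consistent groups: %s\n",
              paste(cons$group[cons$consistent], collapse = ", ")))
  invisible(x)
}
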