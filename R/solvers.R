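#' Representation targets capped at occupancy
#'
#' The representation goal (default: presence in at least 3 selected cells)
#' is capped per species at its occupancy, `target_i = min(goal,
#' occupancy_i)`, so every instance stays feasible: a species occupying 2
#' cells can never be represented in 3.
#'
#' @param x An `assemblage` or 0/1 matrix.
#' @param goal Positive integer representation goal; default 3.
#' @return Tibble with columns `species_id`, `target`.
#' @export
capped_targets <- function(x, goal = 3) {
  goal <- assert_count(goal, "goal")
  occ <- occupancy(x)
  tibble::tibble(species_id = occ$species_id,
                 target = pmin(goal, occ$occupancy))
}

#' Penalised minimum-set objective
#'
#' Cost of a candidate selection for the minimum-set-coverage problem:
#' `|selection| + spf * sum_s max(0, target_s - representation_s)`. Equals
#' the selection size when the selection is feasible.
#'
#' @param cells Integer vector of selected 0-based cell ids.
#' @param x An `assemblage` or 0/1 matrix.
#' @param targets Targets tibble or named vector (see [capped_targets()]).
#' @param spf Species penalty factor; default `10 * n_cells` so any
#'   shortfall dominates any site-count saving.
#' @return A single number.
#' @export
min_cover_cost <- function(cells, x, targets, spf = NULL) {
  pa <- as_pa_matrix(x)
  tg <- as_target_vector(targets, pa)
  spf <- spf %||% (10 * ncol(pa))
  rep_counts <- representation_counts(pa, cells)
  length(cells) + spf * sum(pmax(0L, tg - rep_counts))
}

# representation count per species for a 0-based cell selection
representation_counts <- function(pa, cells) {
  if (length(cells) == 0) {
    return(stats::setNames(integer(nrow(pa)), rownames(pa)))
  }
  idx <- match(as.character(cells), colnames(pa))
  if (anyNA(idx)) stopf("unknown cell id: %s", cells[is.na(idx)][1])
  stats::setNames(as.integer(rowSums(pa[, idx, drop = FALSE])), rownames(pa))
}

# Make a selection feasible (greedy additions by largest shortfall coverage,
# ties to the lowest cell id), then drop redundant cells: repeatedly remove
# the lowest-id selected cell whose removal keeps every target met.
repair_and_prune <- function(pa, tg, selected) {
  rep_int <- as.integer(pa %*% as.numeric(selected))
  while (any(rep_int < tg)) {
    unmet <- rep_int < tg
    gains <- colSums(pa[unmet, , drop = FALSE])
    gains[selected] <- -1
    best <- which.max(gains)
    selected[best] <- TRUE
    rep_int <- rep_int + pa[, best]
  }
  repeat {
    removable <- FALSE
    for (c in which(selected)) {
      sp <- pa[, c] == 1L
      if (all(rep_int[sp] - 1L >= tg[sp])) {
        selected[c] <- FALSE
        rep_int <- rep_int - pa[, c]
        removable <- TRUE
      }
    }
    if (!removable) break
  }
  selected
}

new_solution <- function(pa, cells, objective, feasible, solver, seed,
                         mode, budget = NA_integer_) {
  cells <- sort(as.integer(cells))
  structure(
    list(cells = cells,
         representation = representation_counts(pa, cells),
         objective = objective, feasible = feasible,
         solver = solver, seed = seed, mode = mode, budget = budget),
    class = "reserve_solution"
  )
}

#' @export
print.reserve_solution <- function(x, ...) {
  cat(sprintf("<reserve_solution> %s (%s): %d cells, objective %g, %s\n",
              x$mode, x$solver, length(x$cells), x$objective,
              if (x$feasible) "feasible" else "infeasible"))
  invisible(x)
}

#' Simulated-annealing schedule
#'
#' @param iterations Iterations per restart.
#' @param t_init Initial temperature, or `"auto"` to set it to the standard
#'   deviation of the objective deltas of 100 random moves from the initial
#'   state.
#' @param cooling Geometric cooling factor in (0, 1), applied every
#'   `t_interval` iterations.
#' @param t_interval Iterations between temperature updates.
#' @param restarts Independent restarts; the best state across all restarts
#'   is returned.
#' @return An object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(iterations = 100000, t_init = "auto",
                            cooling = 0.95, t_interval = 1000, restarts = 10) {
  iterations <- assert_count(iterations, "iterations")
  t_interval <- assert_count(t_interval, "t_interval")
  restarts <- assert_count(restarts, "restarts")
  if (identical(t_init, "auto")) t_init <- -1
  if (!is.numeric(t_init) || (t_init <= 0 && t_init != -1)) {
    stopf("`t_init` must be a positive number or \"auto\"")
  }
  if (cooling <= 0 || cooling >= 1) stopf("`cooling` must be in (0, 1)")
  structure(list(iterations = iterations, t_init = t_init, cooling = cooling,
                 t_interval = t_interval, restarts = restarts),
            class = "anneal_schedule")
}

#' Greedy minimum-set heuristic
#'
#' Repeatedly adds the cell covering the largest remaining shortfall (ties
#' broken by lowest cell id) until every target is met. Always feasible when
#' targets are capped at occupancy; serves as the annealer's baseline and
#' upper bound.
#'
#' @inheritParams min_cover_cost
#' @param targets Targets tibble or named vector; cap with
#'   [capped_targets()] first.
#' @return A `reserve_solution`.
#' @export
greedy_min_cover <- function(x, targets) {
  pa <- as_pa_matrix(x)
  tg <- as_target_vector(targets, pa)
  rep_counts <- integer(nrow(pa))
  selected <- logical(ncol(pa))
  while (any(rep_counts < tg)) {
    unmet <- rep_counts < tg
    gains <- colSums(pa[unmet, , drop = FALSE])
    gains[selected] <- -1
    best <- which.max(gains) # which.max takes the first (lowest id) on ties
    if (gains[best] <= 0) stopf("targets unattainable; cap them at occupancy")
    selected[best] <- TRUE
    rep_counts <- rep_counts + pa[, best]
  }
  cells <- as.integer(colnames(pa)[selected])
  new_solution(pa, cells, objective = sum(selected), feasible = TRUE,
               solver = "greedy", seed = NA_integer_, mode = "min_set")
}

#' Solve a reserve-selection problem by simulated annealing
#'
#' `mode = "min_set"` minimises the penalised cost
#' (selection size + `spf` x total shortfall) with add/remove moves. The
#' best-ever state is then polished deterministically: a greedy repair pass
#' adds cells until every target is met and a prune pass drops redundant
#' cells, and the result is never worse than the [greedy_min_cover()]
#' baseline, so the returned solution is always feasible and irredundant.
#' `mode = "max_coverage"` maximises the number of in-scope species
#' meeting their targets over selections of exactly `budget` cells (swap
#' moves at fixed size, so solutions for different species sets stay
#' comparable without site-count bias; budgets of `n_cells` or more select
#' every cell). Worse states
#' are accepted with probability `exp(-delta / T)` under the geometric
#' cooling schedule; the best-ever state across restarts is returned.
#'
#' @inheritParams min_cover_cost
#' @param mode `"min_set"` or `"max_coverage"`.
#' @param budget Selection size for `max_coverage`.
#' @param schedule An [anneal_schedule()].
#' @param seed Integer seed; identical seed, problem and schedule reproduce
#'   the identical solution.
#' @return A `reserve_solution`; for `max_coverage` the objective is the
#'   covered-species count.
#' @export
anneal <- function(x, targets, mode = c("min_set", "max_coverage"),
                   budget = NULL, schedule = anneal_schedule(), spf = NULL,
                   seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "anneal_schedule"))
  pa <- as_pa_matrix(x)
  tg <- as_target_vector(targets, pa)
  seed <- as.integer(seed)

  if (mode == "min_set") {
    spf <- spf %||% (10 * ncol(pa))
    res <- anneal_min_set_cpp(pa, tg, spf, schedule$iterations,
                              schedule$t_init, schedule$cooling,
                              schedule$t_interval, schedule$restarts, seed)
    selected <- logical(ncol(pa))
    selected[res$cells + 1L] <- TRUE
    selected <- repair_and_prune(pa, tg, selected)
    # the greedy baseline is a guaranteed upper bound; never return worse
    greedy <- greedy_min_cover(pa, tg)
    if (sum(selected) > length(greedy$cells)) {
      cells <- greedy$cells
    } else {
      cells <- as.integer(colnames(pa)[selected])
    }
    new_solution(pa, cells, objective = length(cells), feasible = TRUE,
                 solver = "anneal", seed = seed, mode = mode)
  } else {
    if (is.null(budget)) stopf("`budget` is required for max_coverage")
    budget <- as.integer(budget)
    if (budget < 0) stopf("`budget` must be non-negative")
    if (budget == 0) {
      return(new_solution(pa, integer(0), objective = 0L,
                          feasible = all(tg == 0L), solver = "anneal",
                          seed = seed, mode = mode, budget = 0L))
    }
    res <- anneal_max_cov_cpp(pa, tg, budget, schedule$iterations,
                              schedule$t_init, schedule$cooling,
                              schedule$t_interval, schedule$restarts, seed)
    cells <- as.integer(colnames(pa)[res$cells + 1L])
    rep_counts <- representation_counts(pa, cells)
    new_solution(pa, cells, objective = as.integer(res$covered),
                 feasible = all(rep_counts >= tg), solver = "anneal",
                 seed = seed, mode = mode, budget = budget)
  }
}

#' Exhaustive reserve-selection oracle
#'
#' Enumerates every cell subset (size-ascending, lexicographic within size)
#' and returns the exact optimum: the smallest feasible selection
#' (`min_set`) or the selection of at most `budget` cells covering the most
#' species (`max_coverage`). The first optimum in enumeration order is kept,
#' i.e. smallest size then lexicographically smallest id set. Refuses
#' instances above 20 cells.
#'
#' @inheritParams anneal
#' @return A `reserve_solution` with solver `"brute_force"`.
#' @export
brute_force <- function(x, targets, mode = c("min_set", "max_coverage"),
                        budget = NULL) {
  mode <- match.arg(mode)
  pa <- as_pa_matrix(x)
  tg <- as_target_vector(targets, pa)
  n <- ncol(pa)
  if (n > 20) stopf("brute_force refuses instances with more than 20 cells (%d)", n)

  if (mode == "min_set") {
    for (k in 0:n) {
      combs <- utils::combn(n, k)
      for (j in seq_len(ncol(combs))) {
        idx <- combs[, j]
        rep_counts <- if (k == 0) integer(nrow(pa)) else
          as.integer(rowSums(pa[, idx, drop = FALSE]))
        if (all(rep_counts >= tg)) {
          cells <- as.integer(colnames(pa)[idx])
          return(new_solution(pa, cells, objective = k, feasible = TRUE,
                              solver = "brute_force", seed = NA_integer_,
                              mode = mode))
        }
      }
    }
    stopf("no feasible selection exists; cap targets at occupancy")
  } else {
    if (is.null(budget)) stopf("`budget` is required for max_coverage")
    budget <- min(as.integer(budget), n)
    best_idx <- integer(0)
    best_cov <- -1L
    for (k in 0:budget) {
      combs <- utils::combn(n, k)
      for (j in seq_len(ncol(combs))) {
        idx <- combs[, j]
        rep_counts <- if (k == 0) integer(nrow(pa)) else
          as.integer(rowSums(pa[, idx, drop = FALSE]))
        cov <- sum(rep_counts >= tg)
        if (cov > best_cov) {
          best_cov <- cov
          best_idx <- idx
        }
      }
    }
    cells <- as.integer(colnames(pa)[best_idx])
    rep_counts <- representation_counts(pa, cells)
    new_solution(pa, cells, objective = best_cov,
                 feasible = all(rep_counts >= tg), solver = "brute_force",
                 seed = NA_integer_, mode = mode, budget = budget)
  }
}
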