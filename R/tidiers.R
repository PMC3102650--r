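#' @export
tidy.reserve_solution <- function(x, ...) {
  tibble::tibble(species_id = names(x$representation),
                 representation = unname(x$representation))
}

#' @export
glance.reserve_solution <- function(x, ...) {
  tibble::tibble(mode = x$mode, solver = x$solver,
                 n_cells = length(x$cells), objective = x$objective,
                 feasible = x$feasible, budget = x$budget, seed = x$seed)
}

#' @export
tidy.surrogacy_tukey <- function(x, ...) tibble::as_tibble(unclass(x))

#' Solutions of repeated independently seeded solves as a tibble
#'
#' Runs `n_runs` annealing solves with derived seeds and returns one row per
#' run — the shape used for a group's solution ensemble.
#'
#' @inheritParams anneal
#' @param n_runs Number of independent runs.
#' @param seed Master seed; run seeds are derived sub-streams.
#' @return Tibble: `run`, `seed`, `n_cells`, `objective`, `feasible`,
#'   `cells` (semicolon-joined 0-based ids).
#' @export
solve_runs <- function(x, targets, mode = c("min_set", "max_coverage"),
                       budget = NULL, schedule = anneal_schedule(),
                       n_runs = 20, seed = 1L) {
  mode <- match.arg(mode)
  purrr::map_dfr(seq_len(n_runs), function(r) {
    rs <- mix_seed(seed, r)
    sol <- anneal(x, targets, mode = mode, budget = budget,
                  schedule = schedule, seed = rs)
    tibble::tibble(run = r, seed = rs, n_cells = length(sol$cells),
                   objective = sol$objective, feasible = sol$feasible,
                   cells = paste(sol$cells, collapse = ";"))
  })
}
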