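#' Create a rectangular planning-unit lattice
#'
#' Cells are numbered 0-based in row-major order (cell `r * n_cols + c` for
#' row `r`, column `c`). Adjacency is rook (4-neighbour): cells sharing an
#' edge are neighbours, cells touching only at a corner are not.
#'
#' @param n_rows,n_cols Positive integers, the lattice dimensions.
#' @return An object of class `pa_grid`: a list with `n_rows`, `n_cols`,
#'   `n_cells` and `neighbors`, a list whose element `i + 1` holds the
#'   0-based ids of the cells adjacent to cell `i`.
#' @examples
#' g <- make_grid(3, 4)
#' g$neighbors[[6]] # rook neighbours of cell 5
#' @export
make_grid <- function(n_rows, n_cols) {
  n_rows <- assert_count(n_rows, "n_rows")
  n_cols <- assert_count(n_cols, "n_cols")
  n_cells <- n_rows * n_cols
  ids <- seq_len(n_cells) - 1L
  row <- ids %/% n_cols
  col <- ids %% n_cols
  neighbors <- lapply(ids, function(i) {
    r <- i %/% n_cols
    c <- i %% n_cols
    out <- integer(0)
    if (r > 0L) out <- c(out, i - n_cols)
    if (r < n_rows - 1L) out <- c(out, i + n_cols)
    if (c > 0L) out <- c(out, i - 1L)
    if (c < n_cols - 1L) out <- c(out, i + 1L)
    as.integer(out)
  })
  structure(
    list(n_rows = n_rows, n_cols = n_cols, n_cells = n_cells,
         row = row, col = col, neighbors = neighbors),
    class = "pa_grid"
  )
}

#' @export
print.pa_grid <- function(x, ...) {
  cat(sprintf("<pa_grid> %d x %d lattice, %d cells, rook adjacency\n",
              x$n_rows, x$n_cols, x$n_cells))
  invisible(x)
}

#' Grow a contiguous range by spreading dye
#'
#' Starting from `seed_cell`, repeatedly adds one uniformly random frontier
#' cell (a rook neighbour of the current set not yet in it) until the range
#' reaches `target_size` cells or fills the grid. This is the standard null
#' model for a contiguous geographic range (extent-of-occurrence structure)
#' on a lattice.
#'
#' Uses the current R random number stream; call [set.seed()] (or pass a
#' `seed` to the higher-level generators) for reproducibility.
#'
#' @param grid A [make_grid()] lattice.
#' @param target_size Positive integer, the desired range size in cells;
#'   capped at the number of grid cells.
#' @param seed_cell 0-based id of the starting cell.
#' @return Sorted integer vector of 0-based cell ids; always rook-connected
#'   and always containing `seed_cell`.
#' @export
spread_dye <- function(grid, target_size, seed_cell) {
  stopifnot(inherits(grid, "pa_grid"))
  target_size <- assert_count(target_size, "target_size")
  if (length(seed_cell) != 1 || is.na(seed_cell) ||
      seed_cell < 0 || seed_cell >= grid$n_cells) {
    stopf("`seed_cell` must be a cell id in [0, %d]", grid$n_cells - 1L)
  }
  seed_cell <- as.integer(seed_cell)
  size <- min(target_size, grid$n_cells)
  in_set <- logical(grid$n_cells)
  in_set[seed_cell + 1L] <- TRUE
  frontier <- setdiff(grid$neighbors[[seed_cell + 1L]], seed_cell)
  n_in <- 1L
  while (n_in < size && length(frontier) > 0L) {
    pick <- frontier[sample.int(length(frontier), 1L)]
    in_set[pick + 1L] <- TRUE
    n_in <- n_in + 1L
    new_nb <- grid$neighbors[[pick + 1L]]
    frontier <- frontier[frontier != pick]
    frontier <- union(frontier, new_nb[!in_set[new_nb + 1L]])
  }
  which(in_set) - 1L
}
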