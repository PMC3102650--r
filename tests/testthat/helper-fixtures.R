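# Shared fixtures, all built in code.

# 6 species x 5 cells with hand-tallied occupancies 3, 1, 5, 2, 4, 2
tiny_pa <- function() {
  pa <- rbind(
    spA = c(1, 1, 1, 0, 0),
    spB = c(0, 0, 0, 1, 0),
    spC = c(1, 1, 1, 1, 1),
    spD = c(1, 0, 0, 0, 1),
    spE = c(0, 1, 1, 1, 1),
    spF = c(1, 1, 0, 0, 0)
  )
  colnames(pa) <- as.character(0:4)
  pa
}

tiny_meta <- function(ids = rownames(tiny_pa())) {
  tibble::tibble(
    species_id = ids,
    order = c("Carnivora", "Carnivora", "Rodentia", "Rodentia", "Pilosa",
              "Pilosa")[seq_along(ids)],
    threatened = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)[seq_along(ids)],
    endemic = c(FALSE, TRUE, FALSE, FALSE, TRUE, FALSE)[seq_along(ids)]
  )
}

tiny_assemblage <- function(region = "toyland") {
  assemblage(tiny_pa(), tiny_meta(), region = region)
}

# random solvable instance: every species occupies >= 1 cell
random_instance <- function(n_species, n_cells, p = 0.35) {
  pa <- matrix(rbinom(n_species * n_cells, 1, p), n_species, n_cells)
  for (i in which(rowSums(pa) == 0)) pa[i, sample.int(n_cells, 1)] <- 1
  rownames(pa) <- sprintf("s%02d", seq_len(n_species))
  colnames(pa) <- as.character(seq_len(n_cells) - 1L)
  pa
}

# independent connectivity oracle: breadth-first flood fill under rook moves
is_rook_connected <- function(cells, n_rows, n_cols) {
  if (length(cells) <= 1) return(TRUE)
  cells <- sort(cells)
  seen <- cells[1]
  frontier <- cells[1]
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (cl in frontier) {
      r <- cl %/% n_cols; c <- cl %% n_cols
      nb <- c(if (r > 0) cl - n_cols, if (r < n_rows - 1) cl + n_cols,
              if (c > 0) cl - 1, if (c < n_cols - 1) cl + 1)
      nxt <- c(nxt, setdiff(intersect(nb, cells), seen))
    }
    nxt <- unique(nxt)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(cells)
}

# small paired configs for fast end-to-end tests
fast_configs <- function(...) paired_hotspot_configs("reduced", ...)
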