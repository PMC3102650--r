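#' Write MARXAN-dialect input files
#'
#' Emits the three comma-separated tables the MARXAN decision-support tool
#' reads: `pu.dat` (planning units; all costs 1, status 0), `spec.dat`
#' (species with representation targets and the species penalty factor) and
#' `puvspr.dat` (one row per presence, amount 1, sorted by planning unit then
#' species). Costs are uniform and there is no boundary term because the
#' analyses here optimise site counts only.
#'
#' @param x An `assemblage` or 0/1 matrix.
#' @param targets A tibble as returned by [capped_targets()] (columns
#'   `species_id`, `target`), or a named integer vector.
#' @param spf Species penalty factor written to `spec.dat`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_marxan_inputs <- function(x, targets, spf = 10, dir) {
  pa <- as_pa_matrix(x)
  tg <- as_target_vector(targets, pa)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  cell_ids <- as.integer(colnames(pa))
  pu <- tibble::tibble(id = cell_ids, cost = 1, status = 0L)
  readr::write_csv(pu, file.path(dir, "pu.dat"))

  sp_num <- seq_len(nrow(pa))
  spec <- tibble::tibble(id = sp_num, target = as.integer(tg), spf = spf,
                         name = rownames(pa))
  readr::write_csv(spec, file.path(dir, "spec.dat"))

  idx <- which(pa == 1L, arr.ind = TRUE)
  puvspr <- tibble::tibble(
    species = sp_num[idx[, "row"]],
    pu = cell_ids[idx[, "col"]],
    amount = 1L
  )
  puvspr <- dplyr::arrange(puvspr, .data$pu, .data$species)
  readr::write_csv(puvspr, file.path(dir, "puvspr.dat"))
  invisible(dir)
}

#' Read back a MARXAN input triplet
#'
#' Reconstructs the incidence matrix and target vector from the files written
#' by [write_marxan_inputs()]; the round trip preserves incidence content.
#'
#' @param dir Directory containing `pu.dat`, `spec.dat`, `puvspr.dat`.
#' @return A list with `pa` (0/1 integer matrix, species x cells) and
#'   `targets` (tibble `species_id`, `target`).
#' @export
read_marxan_inputs <- function(dir) {
  rd <- function(f) readr::read_csv(file.path(dir, f), show_col_types = FALSE,
                                    progress = FALSE)
  pu <- rd("pu.dat")
  spec <- rd("spec.dat")
  puvspr <- rd("puvspr.dat")
  pa <- matrix(0L, nrow = nrow(spec), ncol = nrow(pu),
               dimnames = list(spec$name, as.character(pu$id)))
  if (nrow(puvspr)) {
    pa[cbind(match(puvspr$species, spec$id), match(puvspr$pu, pu$id))] <- 1L
  }
  list(pa = pa,
       targets = tibble::tibble(species_id = spec$name,
                                target = as.integer(spec$target)))
}

# Normalise a targets argument (tibble or named vector) against a matrix,
# returning an integer vector aligned with the matrix rows.
as_target_vector <- function(targets, pa) {
  if (is.data.frame(targets)) {
    if (!all(c("species_id", "target") %in% names(targets))) {
      stopf("targets must have columns species_id, target")
    }
    v <- stats::setNames(as.integer(targets$target), targets$species_id)
  } else {
    v <- as.integer(targets)
    names(v) <- names(targets)
  }
  if (!is.null(names(v))) {
    miss <- setdiff(rownames(pa), names(v))
    if (length(miss)) stopf("no target for species: %s", miss[1])
    v <- v[rownames(pa)]
  } else if (length(v) != nrow(pa)) {
    stopf("targets length %d does not match %d species", length(v), nrow(pa))
  }
  if (any(is.na(v) | v < 0)) stopf("targets must be non-negative integers")
  stats::setNames(as.integer(v), rownames(pa))
}
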