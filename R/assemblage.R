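#' Construct an assemblage
#'
#' An assemblage bundles a species-by-cell presence/absence matrix with
#' per-species metadata (taxonomic order, threatened and endemic flags) and a
#' region label. It is the substrate of every downstream stage: indicator
#' group construction, reserve selection and the surrogacy evaluation.
#'
#' @param pa Integer or logical matrix, species in rows (rownames are species
#'   ids), cells in columns (colnames are 0-based cell ids as character).
#' @param metadata A data frame with columns `species_id`, `order`,
#'   `threatened`, `endemic`; one row per species in `pa`, any order.
#' @param region Single string naming the region.
#' @param grid Optional [make_grid()] lattice the cells live on.
#' @return An object of class `assemblage`.
#' @export
assemblage <- function(pa, metadata, region, grid = NULL) {
  pa <- as.matrix(pa)
  storage.mode(pa) <- "integer"
  if (is.null(rownames(pa))) stopf("`pa` must have species ids as rownames")
  if (is.null(colnames(pa))) colnames(pa) <- as.character(seq_len(ncol(pa)) - 1L)
  if (!all(pa %in% c(0L, 1L))) stopf("`pa` must contain only 0/1 values")
  if (anyDuplicated(rownames(pa))) {
    stopf("duplicate species id: %s", rownames(pa)[duplicated(rownames(pa))][1])
  }
  if (anyDuplicated(colnames(pa))) {
    stopf("duplicate cell id: %s", colnames(pa)[duplicated(colnames(pa))][1])
  }
  occ <- rowSums(pa)
  if (any(occ == 0)) {
    stopf("species with zero occupancy: %s", rownames(pa)[occ == 0][1])
  }
  metadata <- tibble::as_tibble(metadata)
  need <- c("species_id", "order", "threatened", "endemic")
  if (!all(need %in% names(metadata))) {
    stopf("metadata must have columns %s", paste(need, collapse = ", "))
  }
  missing_meta <- setdiff(rownames(pa), metadata$species_id)
  if (length(missing_meta)) {
    stopf("metadata missing species id: %s", missing_meta[1])
  }
  extra_meta <- setdiff(metadata$species_id, rownames(pa))
  if (length(extra_meta)) {
    stopf("metadata has species id absent from matrix: %s", extra_meta[1])
  }
  if (any(!nzchar(metadata$order))) stopf("empty order name in metadata")
  metadata <- metadata[match(rownames(pa), metadata$species_id), ]
  metadata$threatened <- as.logical(metadata$threatened)
  metadata$endemic <- as.logical(metadata$endemic)
  structure(
    list(pa = pa, metadata = metadata, region = as.character(region),
         grid = grid),
    class = "assemblage"
  )
}

#' @export
print.assemblage <- function(x, ...) {
  cat(sprintf(
    "<assemblage> region '%s': %d species x %d cells, %d presences\n",
    x$region, nrow(x$pa), ncol(x$pa), sum(x$pa)))
  cat(sprintf("  orders: %s\n",
              paste(sort(unique(x$metadata$order)), collapse = ", ")))
  cat(sprintf("  threatened: %d, endemic: %d\n",
              sum(x$metadata$threatened), sum(x$metadata$endemic)))
  invisible(x)
}

#' @export
species_ids <- function(x) UseMethod("species_ids")

#' @export
species_ids.assemblage <- function(x) rownames(x$pa)

# Coerce an assemblage or 0/1 matrix to the internal integer matrix form.
as_pa_matrix <- function(x) {
  if (inherits(x, "assemblage")) return(x$pa)
  pa <- as.matrix(x)
  storage.mode(pa) <- "integer"
  if (is.null(rownames(pa))) rownames(pa) <- paste0("sp", seq_len(nrow(pa)))
  if (is.null(colnames(pa))) colnames(pa) <- as.character(seq_len(ncol(pa)) - 1L)
  pa
}

#' Per-species occupancy
#'
#' Counts the grid cells each species occupies; this is the quantity the
#' restricted-range rule ranks.
#'
#' @param x An `assemblage` or a species-by-cell 0/1 matrix.
#' @return A tibble with columns `species_id` and `occupancy`, in matrix row
#'   order.
#' @export
occupancy <- function(x) {
  pa <- as_pa_matrix(x)
  tibble::tibble(species_id = rownames(pa), occupancy = as.integer(rowSums(pa)))
}

#' Write an assemblage to a directory as two CSV files
#'
#' `matrix.csv` holds the incidence matrix (first column `species_id`, then
#' one 0/1 column per cell id) and `metadata.csv` the species table
#' (`species_id`, `order`, `threatened`, `endemic`, flags as 0/1).
#'
#' @param x An `assemblage`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_assemblage <- function(x, dir) {
  stopifnot(inherits(x, "assemblage"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- tibble::as_tibble(as.data.frame(x$pa, check.names = FALSE))
  mat <- dplyr::bind_cols(tibble::tibble(species_id = rownames(x$pa)), mat)
  readr::write_csv(mat, file.path(dir, "matrix.csv"))
  meta <- dplyr::mutate(
    x$metadata,
    threatened = as.integer(.data$threatened),
    endemic = as.integer(.data$endemic)
  )
  readr::write_csv(meta, file.path(dir, "metadata.csv"))
  writeLines(x$region, file.path(dir, "region.txt"))
  invisible(dir)
}

#' Read an assemblage written by [write_assemblage()]
#'
#' @param matrix_path Path to the incidence CSV, or a directory containing
#'   `matrix.csv` and `metadata.csv`.
#' @param metadata_path Path to the metadata CSV (ignored when `matrix_path`
#'   is a directory).
#' @param region Region label; defaults to the stored label (directory form)
#'   or the matrix file's directory name.
#' @return A validated `assemblage`; file order of species is preserved.
#' @export
read_assemblage <- function(matrix_path, metadata_path = NULL, region = NULL) {
  if (dir.exists(matrix_path)) {
    dir <- matrix_path
    matrix_path <- file.path(dir, "matrix.csv")
    metadata_path <- file.path(dir, "metadata.csv")
    region_file <- file.path(dir, "region.txt")
    if (is.null(region) && file.exists(region_file)) {
      region <- readLines(region_file, n = 1L)
    }
  }
  if (!file.exists(matrix_path)) stopf("matrix file not found: %s", matrix_path)
  if (is.null(metadata_path) || !file.exists(metadata_path)) {
    stopf("metadata file not found: %s", metadata_path %||% "<missing>")
  }
  if (is.null(region)) region <- basename(dirname(matrix_path))
  mat <- readr::read_csv(matrix_path, show_col_types = FALSE, progress = FALSE)
  if (names(mat)[1] != "species_id") stopf("matrix CSV must start with species_id")
  pa <- as.matrix(mat[, -1, drop = FALSE])
  rownames(pa) <- mat$species_id
  meta <- readr::read_csv(metadata_path, show_col_types = FALSE, progress = FALSE)
  assemblage(pa, meta, region = region)
}
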