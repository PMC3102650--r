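#' Restricted-range indicator group
#'
#' The species with the smallest local occupancy: ranks species by occupied
#' cell count ascending, takes the smallest `ceiling(fraction * S)` and adds
#' every species tied with the occupancy value at the cutoff.
#'
#' @param x An `assemblage` or 0/1 matrix.
#' @param fraction Proportion of species to take, in (0, 1); default 0.10.
#' @return Tibble with columns `group` (`"restricted_range"`), `species_id`,
#'   `kind`.
#' @export
restricted_range_group <- function(x, fraction = 0.10) {
  if (fraction <= 0 || fraction >= 1) stopf("`fraction` must be in (0, 1)")
  occ <- occupancy(x)
  if (nrow(occ) < 1) stopf("need at least one species")
  k <- ceiling(fraction * nrow(occ))
  cutoff <- sort(occ$occupancy)[k]
  members <- occ$species_id[occ$occupancy <= cutoff]
  tibble::tibble(group = "restricted_range", species_id = members,
                 kind = "restricted_range")
}

#' Species-poor-orders indicator group
#'
#' Pools every species whose taxonomic order has strictly fewer than
#' `threshold` species in this region.
#'
#' @param metadata Species metadata tibble (or an `assemblage`).
#' @param threshold Order-size cutoff; orders with `< threshold` species
#'   qualify. Default 17.
#' @return Tibble with columns `group` (`"species_poor_orders"`),
#'   `species_id`, `kind`.
#' @export
species_poor_orders_group <- function(metadata, threshold = 17) {
  if (inherits(metadata, "assemblage")) metadata <- metadata$metadata
  sizes <- dplyr::count(metadata, .data$order)
  poor <- sizes$order[sizes$n < threshold]
  members <- metadata$species_id[metadata$order %in% poor]
  if (length(members) == 0) {
    stopf("species-poor-orders group is empty (all orders have >= %d species)",
          threshold)
  }
  tibble::tibble(group = "species_poor_orders", species_id = members,
                 kind = "species_poor_orders")
}

#' Build all candidate indicator groups for a region
#'
#' Returns up to nine groups: one per named taxonomic order present in the
#' assemblage, the pooled species-poor orders, threatened species, endemic
#' species, and the restricted-range group. Groups that come out empty in
#' this region are omitted with a warning rather than failing, so small
#' assemblages still run end-to-end.
#'
#' @param x An `assemblage`.
#' @param fraction Restricted-range cutoff fraction (default 0.10).
#' @param poor_threshold Species-poor order-size cutoff (default 17).
#' @param named_orders Orders that get their own group.
#' @return A tibble with columns `group`, `species_id`, `kind`; one row per
#'   group membership.
#' @export
build_all_groups <- function(x, fraction = 0.10, poor_threshold = 17,
                             named_orders = c("Carnivora", "Chiroptera",
                                              "Primates", "Rodentia",
                                              "Didelphimorphia")) {
  stopifnot(inherits(x, "assemblage"))
  meta <- x$metadata
  groups <- list()

  for (ord in named_orders) {
    members <- meta$species_id[meta$order == ord]
    if (length(members)) {
      groups[[ord]] <- tibble::tibble(group = ord, species_id = members,
                                      kind = "taxonomic")
    } else {
      warning(sprintf("order '%s' absent in region '%s'; group omitted",
                      ord, x$region), call. = FALSE)
    }
  }

  poor <- tryCatch(species_poor_orders_group(meta, poor_threshold),
                   error = function(e) NULL)
  if (is.null(poor)) {
    warning(sprintf("species-poor-orders group empty in region '%s'; omitted",
                    x$region), call. = FALSE)
  } else {
    groups$species_poor_orders <- poor
  }

  for (flag in c("threatened", "endemic")) {
    members <- meta$species_id[meta[[flag]]]
    if (length(members)) {
      groups[[flag]] <- tibble::tibble(group = flag, species_id = members,
                                       kind = flag)
    } else {
      warning(sprintf("no %s species in region '%s'; group omitted",
                      flag, x$region), call. = FALSE)
    }
  }

  groups$restricted_range <- restricted_range_group(x, fraction)
  dplyr::bind_rows(groups)
}

# Member species ids of one group from a group tibble.
group_members <- function(groups, name) {
  groups$species_id[groups$group == name]
}
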