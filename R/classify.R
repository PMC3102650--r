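#' Classify indicator groups as effective and consistent
#'
#' A group is *effective* in a region when its mean target representation
#' exceeds the null model's mean in that region *and* the group-vs-null
#' Tukey contrast is significant at `alpha`. A group is *consistent* when
#' its same-group contrast between the two regions is *not* significant at
#' `alpha` (statistically indistinguishable performance).
#'
#' @param table Evaluation tibble (the same one the ANOVA was fitted to).
#' @param tukey A [tukey_hsd()] result covering the needed contrasts.
#' @param alpha Significance level; default 0.01.
#' @param target Target whose records define the cell means; default
#'   `"all"`.
#' @param null_label Label of the null-model rows; default `"null"`.
#' @param exclude Units that are not candidate indicators; default the null
#'   and ideal models.
#' @return An object of class `surrogacy_classification`: list of two
#'   tibbles, `effectiveness` (`region`, `group`, `effective`,
#'   `mean`, `null_mean`, `p.value`) and `consistency` (`group`,
#'   `consistent`, `p.value`).
#' @export
classify_groups <- function(table, tukey, alpha = 0.01, target = "all",
                            null_label = "null",
                            exclude = c("null", "ideal")) {
  stopifnot(inherits(tukey, "surrogacy_tukey"))
  df <- dplyr::filter(table, .data$target == !!target)
  cells <- dplyr::summarise(
    dplyr::group_by(df, .data$region, .data$group),
    mean = mean(.data$representation_pct), .groups = "drop")
  regions <- sort(unique(cells$region))
  groups <- setdiff(unique(cells$group), exclude)
  if (!all(null_label %in% cells$group[cells$region == regions[1]])) {
    stopf("null model cell missing from the evaluation table")
  }

  find_pair <- function(r1, g1, r2, g2) {
    hit <- (tukey$region1 == r1 & tukey$group1 == g1 &
            tukey$region2 == r2 & tukey$group2 == g2) |
           (tukey$region1 == r2 & tukey$group1 == g2 &
            tukey$region2 == r1 & tukey$group2 == g1)
    if (!any(hit)) stopf("Tukey contrast (%s,%s) vs (%s,%s) missing",
                         r1, g1, r2, g2)
    tukey[which(hit)[1], ]
  }
  cell_mean <- function(r, g) cells$mean[cells$region == r & cells$group == g]

  eff <- purrr::map_dfr(regions, function(r) {
    null_mean <- cell_mean(r, null_label)
    if (length(null_mean) == 0) stopf("null model cell missing in region %s", r)
    here <- intersect(groups, cells$group[cells$region == r])
    purrr::map_dfr(here, function(g) {
      m <- cell_mean(r, g)
      ct <- find_pair(r, g, r, null_label)
      tibble::tibble(region = r, group = g,
                     effective = m > null_mean & isTRUE(ct$significant),
                     mean = m, null_mean = null_mean, p.value = ct$p.value)
    })
  })

  both <- intersect(cells$group[cells$region == regions[1]],
                    cells$group[cells$region == regions[2]])
  cons <- purrr::map_dfr(intersect(groups, both), function(g) {
    ct <- find_pair(regions[1], g, regions[2], g)
    tibble::tibble(group = g, consistent = !isTRUE(ct$significant),
                   p.value = ct$p.value)
  })

  structure(list(effectiveness = eff, consistency = cons, alpha = alpha),
            class = "surrogacy_classification")
}

#' @export
print.surrogacy_classification <- function(x, ...) {
  cat(sprintf("<surrogacy_classification> alpha = %g\n", x$alpha))
  cat("effectiveness:\n")
  print(as.data.frame(x$effectiveness), row.names = FALSE)
  cat("consistency:\n")
  print(as.data.frame(x$consistency), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.surrogacy_classification <- function(x, ...) {
  dplyr::left_join(x$effectiveness,
                   dplyr::select(x$consistency, "group", "consistent"),
                   by = "group")
}
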