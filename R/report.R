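#' Bar chart of representation by group and region
#'
#' Mean representation percentage per region x group with standard-deviation
#' error bars over the runs; the two-region analogue of the classic
#' indicator-group performance figure.
#'
#' @param table Evaluation tibble.
#' @param target Target to plot; `"all"` (default) gives the overall-
#'   diversity figure, anything else the per-target panels.
#' @return A ggplot object.
#' @export
plot_representation <- function(table, target = "all") {
  df <- dplyr::filter(table, .data$target == !!target)
  if (nrow(df) == 0) stopf("no records for target '%s'", target)
  summ <- dplyr::summarise(
    dplyr::group_by(df, .data$region, .data$group),
    mean = mean(.data$representation_pct),
    sd = stats::sd(.data$representation_pct), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group, y = .data$mean,
                                     fill = .data$region)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::labs(x = NULL, y = "Target-species representation (%)",
                  fill = "Region",
                  title = sprintf("Representation of target '%s'", target)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Faceted bar chart of per-target representation
#'
#' One facet per target group, bars per indicator group and region.
#'
#' @param table Evaluation tibble.
#' @return A ggplot object.
#' @export
plot_target_representation <- function(table) {
  df <- dplyr::filter(table, .data$target != "all")
  if (nrow(df) == 0) stopf("no per-target records in the table")
  summ <- dplyr::summarise(
    dplyr::group_by(df, .data$region, .data$group, .data$target),
    mean = mean(.data$representation_pct),
    sd = stats::sd(.data$representation_pct), .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$group, y = .data$mean,
                                     fill = .data$region)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::facet_wrap(~target) +
    ggplot2::labs(x = NULL, y = "Representation (%)", fill = "Region") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' @export
autoplot.surrogacy_result <- function(object, ...) {
  plot_representation(object$evaluation, target = "all")
}

#' Write the full tabular and graphical report
#'
#' Emits `table1.csv` (species counts and minimum-set sizes per group and
#' region), `fig1_data.csv` / `fig2_data.csv` (means and SDs behind the bar
#' charts), `anova.csv`, `tukey.csv`, `classification.csv`, and the two bar
#' charts `fig1.pdf` / `fig2.pdf`.
#'
#' @param sites [minimum_sites_table()] output (both regions).
#' @param table Evaluation tibble.
#' @param anova [two_way_anova()] result.
#' @param tukey [tukey_hsd()] result.
#' @param classification [classify_groups()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
render_report <- function(sites, table, anova, tukey, classification, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  t1 <- tidyr::pivot_wider(sites, names_from = "region",
                           values_from = c("n_species", "n_sites"))
  readr::write_csv(t1, file.path(dir, "table1.csv"))

  fig1 <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(table, .data$target == "all"),
                    .data$region, .data$group),
    mean = mean(.data$representation_pct),
    sd = stats::sd(.data$representation_pct), .groups = "drop")
  readr::write_csv(fig1, file.path(dir, "fig1_data.csv"))

  fig2 <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(table, .data$target != "all"),
                    .data$region, .data$group, .data$target),
    mean = mean(.data$representation_pct),
    sd = stats::sd(.data$representation_pct), .groups = "drop")
  readr::write_csv(fig2, file.path(dir, "fig2_data.csv"))

  readr::write_csv(tidy(anova), file.path(dir, "anova.csv"))
  readr::write_csv(tibble::as_tibble(tukey), file.path(dir, "tukey.csv"))

  cl <- tidy(classification)
  cl_wide <- tidyr::pivot_wider(
    dplyr::select(cl, "region", "group", "effective", "consistent"),
    names_from = "region", values_from = "effective",
    names_prefix = "effective_")
  readr::write_csv(cl_wide, file.path(dir, "classification.csv"))

  ggplot2::ggsave(file.path(dir, "fig1.pdf"), plot_representation(table),
                  width = 8, height = 5)
  ggplot2::ggsave(file.path(dir, "fig2.pdf"), plot_target_representation(table),
                  width = 10, height = 8)
  invisible(dir)
}
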