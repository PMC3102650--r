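#' Two-way ANOVA of representation percentages
#'
#' Fixed-effects two-way ANOVA with interaction on the representation
#' percentages of one target, with region and group as factors. Requires a
#' balanced design (the same number of runs in every region x group cell).
#' Alongside the factorial decomposition, the overall one-way model over the
#' region x group cells is reported; with 2 regions, 11 groups and 20 runs
#' its F statistic carries (21, 418) degrees of freedom.
#'
#' @param table Evaluation tibble (columns `region`, `group`, `run`,
#'   `target`, `representation_pct`), e.g. from [evaluate_paired()].
#' @param target Which target's records to analyse; default `"all"`.
#' @return An object of class `surrogacy_anova` with the term table, overall
#'   model statistics, cell means and residual mean square. Use [tidy()] and
#'   [glance()] to extract tibbles.
#' @export
two_way_anova <- function(table, target = "all") {
  df <- dplyr::filter(table, .data$target == !!target)
  if (nrow(df) == 0) stopf("no records for target '%s'", target)
  df <- dplyr::mutate(df, region = factor(.data$region),
                      group = factor(.data$group))
  if (nlevels(df$region) < 2) stopf("need 2 regions, got %d", nlevels(df$region))
  if (nlevels(df$group) < 2) stopf("need >= 2 groups, got %d", nlevels(df$group))

  counts <- dplyr::count(df, .data$region, .data$group, .drop = FALSE)
  if (length(unique(counts$n)) != 1) {
    bad <- counts[counts$n == min(counts$n), ][1, ]
    stopf("unbalanced design: cell (%s, %s) has %d observations",
          bad$region, bad$group, bad$n)
  }
  n_per_cell <- counts$n[1]
  if (n_per_cell < 1) stopf("empty design cell")

  y <- df$representation_pct
  zero_variance <- isTRUE(all.equal(stats::var(y), 0)) || stats::var(y) == 0

  fit <- stats::aov(representation_pct ~ region * group, data = df)
  tab <- summary(fit)[[1]]
  terms <- trimws(rownames(tab))
  term_tbl <- tibble::tibble(
    term = c("region", "group", "region:group", "residuals")[
      match(terms, c("region", "group", "region:group", "Residuals"))],
    df = as.integer(tab[["Df"]]),
    sumsq = tab[["Sum Sq"]],
    meansq = tab[["Mean Sq"]],
    statistic = tab[["F value"]],
    p.value = tab[["Pr(>F)"]]
  )
  if (zero_variance) {
    term_tbl$statistic <- NA_real_
    term_tbl$p.value <- NA_real_
  }

  # overall one-way model over the region x group cells
  cell <- interaction(df$region, df$group, drop = TRUE)
  k <- nlevels(cell)
  n_tot <- length(y)
  ss_total <- sum((y - mean(y))^2)
  cell_mean_vec <- tapply(y, cell, mean)
  ss_model <- sum(tabulate(cell) * (cell_mean_vec - mean(y))^2)
  ss_resid <- ss_total - ss_model
  df_model <- k - 1L
  df_resid <- n_tot - k
  ms_resid <- ss_resid / df_resid
  f_overall <- if (zero_variance || ms_resid == 0) NA_real_ else
    (ss_model / df_model) / ms_resid
  p_overall <- if (is.na(f_overall)) NA_real_ else
    stats::pf(f_overall, df_model, df_resid, lower.tail = FALSE)

  cell_stats <- dplyr::summarise(
    dplyr::group_by(df, .data$region, .data$group),
    mean = mean(.data$representation_pct),
    sd = stats::sd(.data$representation_pct),
    n = dplyr::n(), .groups = "drop")

  structure(
    list(terms = term_tbl,
         overall = tibble::tibble(statistic = f_overall, df_model = df_model,
                                  df_residual = df_resid, p.value = p_overall,
                                  sumsq_model = ss_model,
                                  sumsq_total = ss_total),
         cells = cell_stats, ms_resid = ms_resid, df_resid = df_resid,
         n_per_cell = n_per_cell, n_cells = k, target = target,
         zero_variance = zero_variance, data = df),
    class = "surrogacy_anova"
  )
}

#' @export
print.surrogacy_anova <- function(x, ...) {
  cat(sprintf("<surrogacy_anova> target '%s': %d cells x %d runs\n",
              x$target, x$n_cells, x$n_per_cell))
  if (x$zero_variance) cat("  zero-variance response: F undefined\n")
  print(as.data.frame(x$terms), row.names = FALSE)
  ov <- x$overall
  cat(sprintf("  overall model: F(%d, %d) = %s\n", ov$df_model,
              ov$df_residual,
              ifelse(is.na(ov$statistic), "undefined",
                     sprintf("%.2f", ov$statistic))))
  invisible(x)
}

#' @export
tidy.surrogacy_anova <- function(x, ...) x$terms

#' @export
glance.surrogacy_anova <- function(x, ...) x$overall

#' Tukey HSD contrasts between region x group cells
#'
#' All pairwise comparisons of the region x group cell means:
#' `q = |mean_i - mean_j| / sqrt(ms_resid / n)` with p-values from the
#' studentized range distribution with (number of cells, residual df)
#' parameters.
#'
#' @param anova A [two_way_anova()] result.
#' @param alpha Significance level; default 0.01.
#' @return Tibble of class `surrogacy_tukey`: one row per pair with
#'   `region1`, `group1`, `region2`, `group2`, `diff`, `q`, `p.value`,
#'   `significant`.
#' @export
tukey_hsd <- function(anova, alpha = 0.01) {
  stopifnot(inherits(anova, "surrogacy_anova"))
  if (anova$n_per_cell < 2) stopf("Tukey HSD needs >= 2 observations per cell")
  cells <- anova$cells
  k <- nrow(cells)
  se <- sqrt(anova$ms_resid / anova$n_per_cell)
  pairs <- utils::combn(k, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  diff <- cells$mean[i] - cells$mean[j]
  q <- abs(diff) / se
  p <- stats::ptukey(q, nmeans = k, df = anova$df_resid, lower.tail = FALSE)
  if (anova$zero_variance) {
    q <- rep(NA_real_, length(q)); p <- rep(NA_real_, length(p))
  }
  out <- tibble::tibble(
    region1 = as.character(cells$region[i]),
    group1 = as.character(cells$group[i]),
    region2 = as.character(cells$region[j]),
    group2 = as.character(cells$group[j]),
    diff = diff, q = q, p.value = p,
    significant = !is.na(p) & p < alpha
  )
  attr(out, "alpha") <- alpha
  class(out) <- c("surrogacy_tukey", class(out))
  out
}
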