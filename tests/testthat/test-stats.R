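# balanced 2 regions x 2 groups x 5 runs fixture with hand-computed sums of
# squares: cell means 12, 22, 17, 21; grand mean 18
anova_fixture <- function() {
  tibble::tibble(
    region = rep(rep(c("R1", "R2"), each = 10), 1),
    group = rep(rep(c("G1", "G2"), each = 5), 2),
    run = rep(1:5, 4),
    target = "all",
    representation_pct = c(10, 12, 14, 11, 13, 20, 22, 24, 21, 23,
                           15, 17, 19, 16, 18, 19, 21, 23, 20, 22)
  )
}

test_that("two-way ANOVA matches the closed-form decomposition", {
  av <- two_way_anova(anova_fixture())
  td <- tidy(av)
  # frozen values from the textbook SS formulas:
  # SS_region = 5*2*((17-18)^2 + (19-18)^2) = 20
  # SS_group  = 5*2*((14.5-18)^2 + (21.5-18)^2) = 245
  # SS_cells  = 5*(36+16+1+9) = 310 -> SS_int = 310-20-245 = 45
  # SS_within = 4*(4+1+0+1+4) = 40
  expect_equal(td$sumsq, c(20, 245, 45, 40), tolerance = 1e-12)
  expect_equal(td$df, c(1L, 1L, 1L, 16L))
  expect_equal(td$statistic[1:3], c(8, 98, 18), tolerance = 1e-12)
  gl <- glance(av)
  expect_equal(gl$statistic, 41.33333333333, tolerance = 1e-8)
  expect_equal(c(gl$df_model, gl$df_residual), c(3L, 16L))
  expect_equal(av$ms_resid, 2.5, tolerance = 1e-12)
})

test_that("the SS decomposition identity holds on random balanced tables", {
  set.seed(99)
  for (rep in 1:8) {
    n_g <- sample(3:6, 1); n_r <- sample(4:8, 1)
    tbl <- tidyr::expand_grid(region = c("A", "B"),
                              group = paste0("g", seq_len(n_g)),
                              run = seq_len(n_r))
    tbl$target <- "all"
    tbl$representation_pct <- stats::runif(nrow(tbl), 0, 100)
    av <- two_way_anova(tbl)
    td <- tidy(av)
    ss_total <- sum((tbl$representation_pct -
                       mean(tbl$representation_pct))^2)
    expect_equal(sum(td$sumsq), ss_total, tolerance = 1e-9)
    expect_equal(glance(av)$sumsq_total, ss_total, tolerance = 1e-9)
  }
})

test_that("ANOVA validates balance and guards zero variance", {
  tbl <- anova_fixture()
  expect_error(two_way_anova(tbl[-1, ]), "unbalanced.*R1.*G1")
  flat <- dplyr::mutate(tbl, representation_pct = 50)
  av <- two_way_anova(flat)
  expect_true(av$zero_variance)
  expect_true(all(is.na(tidy(av)$statistic)))
  expect_true(is.na(glance(av)$statistic))
  expect_error(two_way_anova(dplyr::mutate(tbl, region = "R1")), "2 regions")
})

test_that("overall model df follow the cells-minus-one structure", {
  tbl <- tidyr::expand_grid(region = c("A", "B"),
                            group = paste0("g", 1:4), run = 1:6)
  tbl$target <- "all"
  set.seed(2); tbl$representation_pct <- stats::rnorm(nrow(tbl), 50, 5)
  gl <- glance(two_way_anova(tbl))
  expect_equal(c(gl$df_model, gl$df_residual), c(7L, 40L)) # 8 cells, 48 obs
})

test_that("tukey_hsd computes q from the studentized-range formula", {
  # fixture with known pieces: MS_resid 4, n 16, means 10 and 13 -> q = 6
  fake <- structure(
    list(cells = tibble::tibble(region = c("A", "A"), group = c("g1", "g2"),
                                mean = c(10, 13), sd = c(2, 2), n = c(16, 16)),
         ms_resid = 4, df_resid = 30, n_per_cell = 16, n_cells = 2,
         zero_variance = FALSE),
    class = "surrogacy_anova"
  )
  tk <- tukey_hsd(fake, alpha = 0.01)
  expect_equal(tk$q, 6)
  expect_equal(tk$p.value,
               stats::ptukey(6, nmeans = 2, df = 30, lower.tail = FALSE))

  same <- fake
  same$cells$mean <- c(10, 10)
  tk0 <- tukey_hsd(same, alpha = 0.01)
  expect_equal(tk0$q, 0)
  expect_false(tk0$significant)
})

test_that("tukey p-values shrink as the mean difference grows", {
  base <- structure(
    list(cells = tibble::tibble(region = "A", group = c("g1", "g2"),
                                mean = c(10, 10), sd = 1, n = 10),
         ms_resid = 9, df_resid = 40, n_per_cell = 10, n_cells = 2,
         zero_variance = FALSE),
    class = "surrogacy_anova"
  )
  ps <- vapply(c(1, 3, 6, 10), function(d) {
    b <- base; b$cells$mean <- c(10, 10 + d)
    tukey_hsd(b)$p.value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("tukey_hsd agrees with stats::TukeyHSD on one-way cells", {
  av <- two_way_anova(anova_fixture())
  tk <- tukey_hsd(av, alpha = 0.01)
  df <- anova_fixture()
  df$cell <- interaction(df$region, df$group)
  ref <- stats::TukeyHSD(stats::aov(representation_pct ~ cell, data = df))$cell
  # match our pairs against TukeyHSD's labels
  ours <- stats::setNames(tk$p.value,
                          paste0(tk$region2, ".", tk$group2, "-",
                                 tk$region1, ".", tk$group1))
  for (lab in rownames(ref)) {
    rev_lab <- paste(rev(strsplit(lab, "-")[[1]]), collapse = "-")
    p_our <- ours[lab]
    if (is.na(p_our)) p_our <- ours[rev_lab]
    expect_equal(unname(p_our), ref[lab, "p adj"], tolerance = 1e-8)
  }
})

test_that("classification applies the direction and significance rules", {
  mk_table <- function(means) {
    purrr::imap_dfr(means, function(regs, g) {
      purrr::imap_dfr(regs, function(m, r) {
        tibble::tibble(region = r, group = g, run = 1:6, target = "all",
                       representation_pct = m + c(-1, 1, 0, -0.5, 0.5, 0))
      })
    })
  }
  tbl <- mk_table(list(
    good = c(A = 80, B = 81),
    weak = c(A = 50.4, B = 70),
    null = c(A = 50, B = 50),
    ideal = c(A = 85, B = 85)
  ))
  av <- two_way_anova(tbl)
  tk <- tukey_hsd(av, alpha = 0.01)
  cl <- classify_groups(tbl, tk, alpha = 0.01)
  eff <- cl$effectiveness
  expect_true(all(eff$effective[eff$group == "good"]))
  # 'weak' in region A: mean 52 vs null 50, difference inside the Tukey band
  expect_false(eff$effective[eff$group == "weak" & eff$region == "A"])
  cons <- cl$consistency
  expect_true(cons$consistent[cons$group == "good"])
  expect_false(cons$consistent[cons$group == "weak"])

  # a group mean below the null is never effective, whatever the p-value
  tbl2 <- mk_table(list(bad = c(A = 20, B = 20), null = c(A = 50, B = 50),
                        other = c(A = 60, B = 60)))
  av2 <- two_way_anova(tbl2)
  cl2 <- classify_groups(tbl2, tukey_hsd(av2), alpha = 0.01)
  expect_false(any(cl2$effectiveness$effective[
    cl2$effectiveness$group == "bad"]))

  # classification is invariant to record order
  shuffled <- tbl[sample(nrow(tbl)), ]
  cl3 <- classify_groups(shuffled, tk, alpha = 0.01)
  expect_equal(dplyr::arrange(cl3$effectiveness, region, group),
               dplyr::arrange(cl$effectiveness, region, group))

  # missing null cell is an error
  no_null <- dplyr::filter(tbl, group != "null")
  expect_error(classify_groups(no_null, tk), "null")
})

test_that("render_report writes the full table and figure set", {
  cfgs <- fast_configs()
  hs <- generate_paired_hotspots(cfgs$a, cfgs$b, seed = 14)
  ga <- build_all_groups(hs$a); gb <- build_all_groups(hs$b)
  sched <- anneal_schedule(iterations = 3000, restarts = 1)
  sites <- dplyr::bind_rows(
    minimum_sites_table(hs$a, ga, schedule = sched, seed = 1),
    minimum_sites_table(hs$b, gb, schedule = sched, seed = 2))
  ev <- evaluate_paired(hs$a, hs$b, ga, gb, budget_a = 8, budget_b = 8,
                        n_runs = 4, schedule = sched, seed = 3)
  av <- two_way_anova(ev)
  tk <- tukey_hsd(av)
  cl <- classify_groups(ev, tk)
  dir <- withr::local_tempdir()
  render_report(sites, ev, av, tk, cl, dir)
  files <- c("table1.csv", "fig1_data.csv", "fig2_data.csv", "anova.csv",
             "tukey.csv", "classification.csv", "fig1.pdf", "fig2.pdf")
  for (f in files) expect_true(file.exists(file.path(dir, f)), label = f)

  fig1 <- readr::read_csv(file.path(dir, "fig1_data.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(fig1), (9 + 2) * 2) # (groups + null + ideal) x regions
  # SDs are the sample SD over the runs
  one <- fig1[fig1$region == "region_a" & fig1$group == "ideal", ]
  raw <- ev$representation_pct[ev$region == "region_a" & ev$group == "ideal" &
                                 ev$target == "all"]
  expect_equal(one$sd, stats::sd(raw))
  expect_equal(one$mean, mean(raw))

  cls <- readr::read_csv(file.path(dir, "classification.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(cls), 9) # one consistency flag per indicator group
  expect_true("consistent" %in% names(cls))
})
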