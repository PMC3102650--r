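forced_singleton_config <- function(endemic_fraction = 0.2,
                                    endemic_zone_fraction = 0.25) {
  assemblage_config(
    6, 6, orders = c(Carnivora = 6, Rodentia = 4),
    occupancy_meanlog = log(1e-6), occupancy_sdlog = 1e-6,
    endemic_fraction = endemic_fraction,
    endemic_zone_fraction = endemic_zone_fraction,
    region = "forced"
  )
}

test_that("degenerate occupancy parameters force one presence per species", {
  asm <- generate_hotspot(forced_singleton_config(), seed = 3)
  expect_true(all(rowSums(asm$pa) == 1))
  expect_equal(nrow(asm$pa), 10)
})

test_that("endemic species are seeded inside the clumping window", {
  cfg <- assemblage_config(
    8, 8, orders = c(Carnivora = 20),
    occupancy_meanlog = log(1e-6), occupancy_sdlog = 1e-6,
    endemic_fraction = 1, endemic_zone_fraction = 0.25, region = "z"
  )
  asm <- generate_hotspot(cfg, seed = 11)
  # window = top-left quarter: rows 0..3, cols 0..3 of an 8x8 grid
  zone <- as.integer(outer((0:3) * 8, 0:3, "+"))
  occupied <- which(colSums(asm$pa) > 0) - 1L
  expect_true(all(occupied %in% zone))
  expect_true(all(asm$metadata$endemic))
})

test_that("occupancy distribution is right-skewed at reference parameters", {
  cfg <- assemblage_config(
    20, 15, orders = c(Carnivora = 100, Rodentia = 100),
    occupancy_meanlog = log(0.05), occupancy_sdlog = 1, region = "skew"
  )
  skewed <- vapply(1:50, function(s) {
    occ <- rowSums(generate_hotspot(cfg, seed = s)$pa)
    stats::median(occ) < mean(occ)
  }, logical(1))
  expect_gte(mean(skewed), 0.95)
})

test_that("every generated range is rook-connected with occupancy in range", {
  cfg <- fast_configs()$a
  asm <- generate_hotspot(cfg, seed = 9)
  occ <- rowSums(asm$pa)
  expect_true(all(occ >= 1 & occ <= ncol(asm$pa)))
  for (i in seq_len(nrow(asm$pa))) {
    cells <- which(asm$pa[i, ] == 1L) - 1L
    expect_true(is_rook_connected(cells, cfg$n_rows, cfg$n_cols))
  }
})

test_that("endemic ranges are spatially clumped relative to random subsets", {
  cfg <- fast_configs()$a
  centroid_spread <- function(pa, idx, n_cols) {
    cent <- t(vapply(idx, function(i) {
      cells <- which(pa[i, ] == 1L) - 1L
      c(mean(cells %/% n_cols), mean(cells %% n_cols))
    }, numeric(2)))
    mean(stats::dist(cent))
  }
  clumped <- vapply(1:30, function(s) {
    asm <- generate_hotspot(cfg, seed = 1000 + s)
    endem <- which(asm$metadata$endemic)
    non <- which(!asm$metadata$endemic)
    rnd <- sample(non, length(endem))
    centroid_spread(asm$pa, endem, cfg$n_cols) <
      centroid_spread(asm$pa, rnd, cfg$n_cols)
  }, logical(1))
  expect_gte(mean(clumped), 0.9)
})

test_that("threat status is biased toward small-ranged species", {
  cfg <- paired_hotspot_configs("desk")$a
  hits <- vapply(1:3, function(s) {
    asm <- generate_hotspot(cfg, seed = 300 + s)
    occ <- rowSums(asm$pa)
    thr <- asm$metadata$threatened
    mean(log(occ[thr])) < mean(log(occ[!thr]))
  }, logical(1))
  expect_gte(sum(hits), 2)
})

test_that("generation is deterministic and pairs use distinct labels", {
  cfg <- fast_configs()
  p1 <- generate_paired_hotspots(cfg$a, cfg$b, seed = 77)
  p2 <- generate_paired_hotspots(cfg$a, cfg$b, seed = 77)
  expect_identical(p1$a$pa, p2$a$pa)
  expect_identical(p1$b$metadata, p2$b$metadata)
  expect_false(identical(p1$a$region, p1$b$region))

  p3 <- generate_paired_hotspots(cfg$a, cfg$b, seed = 78)
  expect_false(identical(p1$a$pa, p3$a$pa))
})

test_that("paired generation reports the configured cell counts", {
  orders <- c(Carnivora = 5, Rodentia = 5)
  ca <- assemblage_config(26, 26, orders, region = "big_a")
  cb <- assemblage_config(22, 21, orders, region = "big_b")
  hs <- generate_paired_hotspots(ca, cb, seed = 5)
  expect_equal(ncol(hs$a$pa), 676)
  expect_equal(ncol(hs$b$pa), 462)
})

test_that("mismatched order lists and duplicate labels are rejected", {
  ca <- assemblage_config(5, 5, c(Carnivora = 3), region = "a")
  cb <- assemblage_config(5, 5, c(Rodentia = 3), region = "b")
  expect_error(generate_paired_hotspots(ca, cb, seed = 1), "order list")
  cb2 <- assemblage_config(5, 5, c(Carnivora = 3), region = "a")
  expect_error(generate_paired_hotspots(ca, cb2, seed = 1), "distinct region")
})

test_that("configs validate their fields and round-trip through YAML", {
  expect_error(assemblage_config(5, 5, c(3, 4)), "named")
  expect_error(assemblage_config(5, 5, c(Carnivora = 3),
                                 endemic_fraction = 0), "in \\(0, 1\\]")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_rows: 6", "n_cols: 7",
    "orders:", "  Carnivora: 4", "  Rodentia: 3",
    "occupancy_meanlog: -2.3", "endemic_fraction: 0.5",
    "region: yam"), path)
  cfg <- read_assemblage_config(path)
  expect_s3_class(cfg, "assemblage_config")
  expect_equal(cfg$n_cols, 7L)
  expect_equal(unname(cfg$orders["Rodentia"]), 3L)
  expect_equal(cfg$endemic_fraction, 0.5)
})
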