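test_that("residence sites sit at the centroid of each sub-threshold run", {
  tr <- data.frame(cell_id = 1, track_id = 1, frame = 1:3,
                   x_um = c(0, 0.01, 0.02), y_um = 0)
  s <- residence_sites(tr, r0 = 0.2)
  expect_identical(nrow(s), 1L)
  expect_equal(s$x_um, 0.01)
  expect_equal(s$y_um, 0)
  # two separated runs in one track give two sites
  tr2 <- data.frame(cell_id = 1, track_id = 1, frame = 1:5,
                    x_um = c(0, 0.01, 0.5, 0.51, 0.52), y_um = 0)
  s2 <- residence_sites(tr2, r0 = 0.2)
  expect_identical(nrow(s2), 2L)
  expect_equal(s2$x_um, c(0.005, 0.51))
  # nothing below threshold: empty
  tr3 <- data.frame(cell_id = 1, track_id = 1, frame = 1:3,
                    x_um = c(0, 1, 2), y_um = 0)
  expect_identical(nrow(residence_sites(tr3, 0.2)), 0L)
})

test_that("pairwise distances are enumerated within cells and normalized", {
  two <- data.frame(cell_id = 1, x_um = c(0, 0.3), y_um = 0)
  h <- pwdd(two, bin_width = 0.05)
  expect_equal(sum(h$p), 1)
  expect_equal(sum(h$p[h$bin_mid > 0.25 & h$bin_mid < 0.35]), 1)
  # 3 collinear sites at 0, d, 2d: distances d, d, 2d
  d <- 0.2
  three <- data.frame(cell_id = 1, x_um = c(0, d, 2 * d), y_um = 0)
  expect_equal(sort(smtkinetics:::site_pair_dists(three)), c(d, d, 2 * d))
  # distances are never pooled across cells: two singleton cells have none
  split_cells <- data.frame(cell_id = c(1, 2), x_um = c(0, 0.3), y_um = 0)
  expect_error(pwdd(split_cells), "at least 2 sites")
})

test_that("the random reference is matched per cell and scales with cell size", {
  cells <- make_cells(10)
  counts <- setNames(rep(20L, 10), 1:10)
  ref <- random_reference(cells, counts, seed = 61)
  expect_equal(as.numeric(table(ref$cell_id)), rep(20, 10))
  g <- cell_geometry(3, 0.5)
  expect_true(all(in_cell(g, ref$x_um, ref$y_um)))
  expect_identical(nrow(random_reference(cells[1, ], c("1" = 0L), seed = 1)),
                   0L)
  # self-consistency across seeds: pairwise distances within a cell are
  # dependent, so the check is on the KS effect size, not its p-value
  ref2 <- random_reference(cells, counts, seed = 62)
  ks <- suppressWarnings(ks.test(smtkinetics:::site_pair_dists(ref),
                                 smtkinetics:::site_pair_dists(ref2)))
  expect_lt(unname(ks$statistic), 0.08)
  # site coordinates themselves are independent draws: KS applies directly
  expect_gt(suppressWarnings(ks.test(ref$x_um, ref2$x_um))$p.value, 0.01)
  # mean pairwise distance grows with cell length
  long_ref <- random_reference(make_cells(10, length_um = 6), counts,
                               seed = 63)
  expect_gt(mean(smtkinetics:::site_pair_dists(long_ref)),
            mean(smtkinetics:::site_pair_dists(ref)))
})

test_that("fraction within R is monotone, saturates, and is 1 for coincident sites", {
  coin <- data.frame(cell_id = 1, x_um = rep(0.1, 5), y_um = rep(0, 5))
  expect_equal(fraction_within(coin, 0.01), 1)
  sites <- random_reference(make_cells(6), setNames(rep(15L, 6), 1:6),
                            seed = 64)
  R <- c(0.05, 0.1, 0.2, 0.5, 1, 3)
  fr <- fraction_within(sites, R)
  expect_true(all(diff(fr) >= 0))
  expect_equal(fr[length(fr)], 1)
  # nearest-neighbour variant is also monotone and bounded by 1
  fn <- fraction_within(sites, R, type = "nn")
  expect_true(all(diff(fn) >= 0) && all(fn <= 1))
})

test_that("the ratio curve is flat at 1 under the uniform null", {
  cells <- make_cells(25)
  counts <- setNames(rep(25L, 25), 1:25)
  obs <- random_reference(cells, counts, seed = 65)
  ref <- random_reference(cells, counts, seed = 66)
  rc <- ratio_curve(obs, ref, c(0.1, 0.2, 0.3, 0.5))
  expect_true(all(abs(rc$ratio_mean - 1) < 0.15))
})

test_that("nanometer-scale clusters raise the ratio at small R", {
  cells <- make_cells(20)
  counts <- setNames(rep(25L, 20), 1:20)
  obs <- gen_clustered_sites(1:20, 25, n_clusters = 5, sigma = 0.03,
                             seed = 67)
  ref <- random_reference(cells, counts, seed = 68)
  rc <- ratio_curve(obs, ref, c(0.05, 0.1, 0.2, 0.5))
  expect_gt(rc$ratio_mean[rc$R == 0.1], 1)
  # enrichment grows toward smaller radii
  expect_true(all(diff(rc$ratio_mean) < 0))
})

test_that("observed and reference PWDDs share bins and the difference integrates to zero", {
  cells <- make_cells(12)
  counts <- setNames(rep(15L, 12), 1:12)
  obs <- gen_clustered_sites(1:12, 15, seed = 69)
  ref <- random_reference(cells, counts, seed = 70)
  cmp <- pwdd_compare(obs, ref, bin_width = 0.05, n_boot = 60, seed = 5)
  expect_equal(sum(cmp$observed), 1, tolerance = 1e-9)
  expect_equal(sum(cmp$reference), 1, tolerance = 1e-9)
  expect_equal(sum(cmp$difference), 0, tolerance = 1e-9)
  expect_true(all(cmp$lo95 <= cmp$hi95))
})
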