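test_that("spatial clustering separates distant oligomers", {
  tbl <- data.frame(x_nm = c(0, 10, 20, 1000, 1010),
                    y_nm = c(0, 5, -5, 0, 3))
  lab <- cluster_spatial(tbl, gap = 50)
  expect_identical(lab, c(1L, 1L, 1L, 2L, 2L))
  expect_identical(cluster_spatial(tbl[1, ], gap = 50), 1L)
  expect_identical(cluster_spatial(tbl[0, ], gap = 50), integer(0))
})

test_that("spatial clustering is exact single-linkage connectivity", {
  set.seed(14)
  for (rep in 1:5) {
    pts <- data.frame(x_nm = runif(120, 0, 400), y_nm = runif(120, 0, 400))
    got <- cluster_spatial(pts, gap = 35)
    # hclust oracle: strict < gap means cutting just below the threshold
    want <- cutree(hclust(dist(pts), "single"), h = 35 * (1 - 1e-12))
    expect_true(same_partition(got, want))
  }
})

test_that("spatial partition agrees with simulated ground truth", {
  tbl <- small_tetramer_table(n_oligo = 400)
  lab <- cluster_spatial(tbl, gap = 50)
  expect_true(same_partition(lab, tbl$oligomer_id))
})

test_that("intensity clustering implements the separation threshold", {
  # two points exactly delta_p apart merge; epsilon further apart they split
  expect_identical(cluster_intensity(c(0, 400), c(0, 0), 400), c(1L, 1L))
  expect_identical(cluster_intensity(c(0, 400.001), c(0, 0), 400), c(1L, 2L))
  expect_identical(cluster_intensity(rep(500, 6), rep(700, 6), 400),
                   rep(1L, 6))
  # four tight clouds at well-separated brightness fingerprints
  set.seed(3)
  cx <- c(15000, 2000, 6000, 1000); cy <- c(2000, 14000, 5000, 800)
  truth <- rep(1:4, each = 12)
  nx <- cx[truth] + rnorm(48, 0, 60)
  ny <- cy[truth] + rnorm(48, 0, 60)
  lab <- cluster_intensity(nx, ny, 500)
  expect_identical(max(lab), 4L)
  expect_true(same_partition(lab, truth))
})

test_that("intensity clustering matches a single-linkage dendrogram cut", {
  set.seed(25)
  for (rep in 1:8) {
    m <- sample(5:60, 1)
    nx <- runif(m, 0, 1e4); ny <- runif(m, 0, 1e4)
    got <- cluster_intensity(nx, ny, 700)
    want <- oracle_threshold_groups(nx, ny, 700)
    expect_true(same_partition(got, want))
  }
})

test_that("intensity partition is permutation invariant", {
  set.seed(31)
  nx <- runif(40, 0, 8000); ny <- runif(40, 0, 8000)
  base <- cluster_intensity(nx, ny, 600)
  perm <- sample(40)
  shuf <- cluster_intensity(nx[perm], ny[perm], 600)
  expect_true(same_partition(base, shuf[order(perm)]))
})

test_that("group statistics match brute force", {
  tbl <- small_tetramer_table(n_oligo = 5)
  one <- tbl[tbl$oligomer_id == tbl$oligomer_id[1], ]
  lab <- cluster_intensity(one$Nx_photons, one$Ny_photons, 400)
  g <- protomer_groups(one, lab)
  for (k in seq_len(nrow(g))) {
    idx <- lab == g$group[k]
    expect_equal(g$m[k], sum(idx))
    expect_equal(g$x_bar[k], mean(one$x_nm[idx]), tolerance = 1e-12)
    expect_equal(g$y_bar[k], mean(one$y_nm[idx]), tolerance = 1e-12)
    expect_equal(g$z_hat[k], sum(one$sj_nm[idx]^2) / sum(idx)^2,
                 tolerance = 1e-12)
    expect_gt(g$z_hat[k], 0)
  }
})

test_that("eligibility requires exactly n pure groups", {
  g3 <- data.frame(group = 1:3, m = 1, x_bar = 0, y_bar = 0,
                   sigma2_hat = 1, z_hat = 1)
  expect_false(check_eligibility(g3, 4)$eligible)
  g4 <- rbind(g3, data.frame(group = 4, m = 1, x_bar = 0, y_bar = 0,
                             sigma2_hat = 1, z_hat = 1))
  lab <- c(1L, 1L, 2L, 3L, 4L)
  ok <- check_eligibility(g4, 4, labels = lab,
                          molecule_id = c(7L, 7L, 8L, 9L, 10L))
  expect_true(ok$eligible)
  expect_true(ok$all_correct)
  bad <- check_eligibility(g4, 4, labels = lab,
                           molecule_id = c(7L, 8L, 8L, 9L, 10L))
  expect_false(bad$all_correct)
})

test_that("batch assignment agrees with the per-oligomer operations", {
  acq <- default_acq(1e4)
  tbl <- small_tetramer_table(n_oligo = 120)
  batch <- assign_blinks(tbl, acq, 4)
  for (oid in batch$per_oligomer$oligomer_id[1:25]) {
    one <- tbl[tbl$oligomer_id == oid, ]
    lab <- cluster_intensity(one$Nx_photons, one$Ny_photons, acq$delta_p)
    g <- protomer_groups(one, lab)
    chk <- check_eligibility(g, 4, labels = lab,
                             molecule_id = one$molecule_id)
    row <- batch$per_oligomer[batch$per_oligomer$oligomer_id == oid, ]
    expect_equal(row$n_found, chk$n_found)
    expect_equal(row$eligible, chk$eligible)
    expect_equal(row$all_correct, chk$all_correct)
    if (chk$eligible) {
      bg <- batch$groups[batch$groups$oligomer_id == oid, ]
      expect_equal(sort(bg$x_bar), sort(g$x_bar), tolerance = 1e-12)
      expect_equal(sort(bg$z_hat), sort(g$z_hat), tolerance = 1e-12)
    }
  }
})

test_that("misassignment among eligible oligomers is rare at high brightness", {
  acq <- default_acq(1e5)
  tbl <- small_tetramer_table(n_oligo = 4000, N_max = 1e5, seed = 12)
  res <- assign_blinks(tbl, acq, 4)
  elig <- res$per_oligomer$eligible
  expect_lt(mean(!res$per_oligomer$all_correct[elig]), 0.02)
})

test_that("eligibility increases with brightness", {
  fr <- vapply(c(1e4, 3e4, 1e5), function(Nmax) {
    acq <- default_acq(Nmax)
    tbl <- small_tetramer_table(n_oligo = 3000, N_max = Nmax, seed = 19)
    mean(assign_blinks(tbl, acq, 4)$per_oligomer$eligible)
  }, numeric(1))
  expect_true(all(diff(fr) > 0))
})
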