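grid20 <- mkda_grid(c(20, 20, 20), spacing = 2)
mask20 <- ellipsoid_mask(grid20)

test_that("indicator maps equal the brute-force sphere count", {
  focus <- c(1, 1, 1)   # a lattice point of the 2 mm grid
  st <- foci_study("s1", "reward_mixed", rbind(focus), 20)
  map <- indicator_map(st, grid20, array(TRUE, grid20$dim), radius = 10)
  # brute force: distance of every grid point to the focus
  ax <- lapply(1:3, function(k)
    grid20$origin[k] + (seq_len(grid20$dim[k]) - 1) * grid20$spacing)
  cnt <- 0
  for (i in seq_along(ax[[1]])) for (j in seq_along(ax[[2]]))
    for (k in seq_along(ax[[3]]))
      if ((ax[[1]][i] - focus[1])^2 + (ax[[2]][j] - focus[2])^2 +
          (ax[[3]][k] - focus[3])^2 <= 100) cnt <- cnt + 1
  expect_equal(sum(map), cnt)
})

test_that("tiny radii activate only the focus voxel", {
  st <- foci_study("s1", "reward_only", rbind(c(0, 0, 0)), 10)
  map <- indicator_map(st, grid20, array(TRUE, grid20$dim), radius = 0.5)
  expect_equal(sum(map), 1)
  v <- rewpun:::mm_to_voxel(grid20, c(0, 0, 0))
  expect_true(map[v[1], v[2], v[3]])
})

test_that("well-separated foci give a disjoint union of balls", {
  full <- array(TRUE, grid20$dim)
  one <- foci_study("a", "reward_mixed", rbind(c(-12, 0, 0)), 10)
  two <- foci_study("b", "reward_mixed", rbind(c(12, 0, 0)), 10)
  both <- foci_study("c", "reward_mixed", rbind(c(-12, 0, 0), c(12, 0, 0)), 10)
  m1 <- indicator_map(one, grid20, full, radius = 8)
  m2 <- indicator_map(two, grid20, full, radius = 8)
  mb <- indicator_map(both, grid20, full, radius = 8)
  expect_equal(sum(m1 & m2), 0)
  expect_identical(mb, m1 | m2)
})

test_that("density maps are weighted means of indicators", {
  full <- array(TRUE, grid20$dim)
  s1 <- foci_study("s1", "reward_mixed", rbind(c(0, 0, 0)), 9)
  s2 <- foci_study("s2", "reward_mixed", rbind(c(14, 14, 14)), 9)
  # one study: density equals its indicator
  d1 <- density_map(list(s1), grid20, full, radius = 6)
  expect_equal(d1$values, indicator_map(s1, grid20, full, 6) * 1)
  # weights (3, 1): a voxel active only in study 1 has density 0.75
  d <- density_map(list(s1, s2), grid20, full, radius = 6,
                   weights = c(3, 1))
  v <- rewpun:::mm_to_voxel(grid20, c(0, 0, 0))
  expect_equal(d$values[v[1], v[2], v[3]], 0.75)
  # equal weights: m of n active -> m/n
  deq <- density_map(list(s1, s2), grid20, full, radius = 6,
                     weights = c(1, 1))
  expect_equal(deq$values[v[1], v[2], v[3]], 0.5)
  expect_true(all(d$values >= 0 & d$values <= 1))
  expect_error(density_map(list(s1, s2), grid20, full, weights = c(0, 0)),
               "weight sum")
})

test_that("density is monotone non-decreasing in kernel radius", {
  set.seed(31)
  st <- simulate_foci(foci_spec(n_studies = c(reward_mixed = 5,
                                              reward_only = 3),
                                foci_per_study = 4),
                      grid20, mask20, seed = 31)
  d_small <- density_map(st, grid20, mask20, radius = 4)
  d_large <- density_map(st, grid20, mask20, radius = 8)
  expect_true(all(d_large$values - d_small$values >= -1e-12))
  expect_true(all(d_small$values[!mask20] == 0))
})

test_that("simulated corpora match the requested category sizes", {
  spec <- foci_spec(n_studies = c(reward_mixed = 16, reward_only = 9),
                    cluster_center = c(0, 0, 0), cluster_sd = 3)
  st <- simulate_foci(spec, grid20, mask20, seed = 7)
  cats <- vapply(st, `[[`, "", "category")
  expect_equal(sum(cats == "reward_mixed"), 16)
  expect_equal(sum(cats == "reward_only"), 9)
  expect_identical(simulate_foci(spec, grid20, mask20, seed = 7), st)
  # all foci inside the mask
  for (s in st) {
    v <- rewpun:::mm_to_voxel(grid20, s$foci)
    expect_true(all(mask20[v]))
  }
  expect_error(simulate_foci(foci_spec(cluster_center = c(999, 0, 0)),
                             grid20, mask20, seed = 1),
               "outside mask")
})

test_that("a zero-spread planted cluster gives density 1 at its center", {
  spec <- foci_spec(n_studies = c(reward_mixed = 8, reward_only = 0),
                    cluster_center = c(0, 0, 0), cluster_sd = 0,
                    cluster_categories = "reward_mixed")
  st <- simulate_foci(spec, grid20, mask20, seed = 8)
  d <- density_map(st, grid20, mask20, radius = 6)
  v <- rewpun:::mm_to_voxel(grid20, c(0, 0, 0))
  expect_equal(d$values[v[1], v[2], v[3]], 1)
})

test_that("permutation thresholds behave at the edges", {
  st <- simulate_foci(foci_spec(n_studies = c(reward_mixed = 6,
                                              reward_only = 0),
                                foci_per_study = 3),
                      grid20, mask20, seed = 9)
  one <- permutation_threshold(st, grid20, mask20, radius = 6, n_perm = 1,
                               seed = 10)
  expect_equal(one$critical, one$maxima)
  many <- permutation_threshold(st, grid20, mask20, radius = 6, n_perm = 49,
                                alpha = 0.05, seed = 11)
  expect_equal(many$critical, sort(many$maxima)[ceiling(0.95 * 49)])
  expect_identical(permutation_threshold(st, grid20, mask20, radius = 6,
                                         n_perm = 10, seed = 12)$maxima,
                   permutation_threshold(st, grid20, mask20, radius = 6,
                                         n_perm = 10, seed = 12)$maxima)
})

test_that("a planted cluster survives thresholding; background does not", {
  hits <- 0; bg_hits <- 0
  for (k in 1:5) {
    spec <- foci_spec(n_studies = c(reward_mixed = 10, reward_only = 0),
                      foci_per_study = 3, cluster_center = c(0, 0, 0),
                      cluster_sd = 2)
    st <- simulate_foci(spec, grid20, mask20, seed = 400 + k)
    d <- density_map(st, grid20, mask20, radius = 6)
    thr <- permutation_threshold(st, grid20, mask20, radius = 6,
                                 n_perm = 99, seed = 500 + k)
    v <- rewpun:::mm_to_voxel(grid20, c(0, 0, 0))
    if (d$values[v[1], v[2], v[3]] > thr$critical) hits <- hits + 1
    far <- rewpun:::mm_to_voxel(grid20, c(-14, -14, 0))
    if (mask20[far] && d$values[far[1], far[2], far[3]] > thr$critical)
      bg_hits <- bg_hits + 1
  }
  expect_gte(hits, 4)
  expect_lte(bg_hits, 1)
})

test_that("bootstrap with the full subset and one draw is a plain contrast", {
  spec <- foci_spec(n_studies = c(reward_mixed = 6, reward_only = 4),
                    foci_per_study = 3, cluster_center = c(0, 0, 0),
                    cluster_sd = 2)
  st <- simulate_foci(spec, grid20, mask20, seed = 13)
  cats <- vapply(st, `[[`, "", "category")
  mixed <- st[cats == "reward_mixed"]
  only <- st[cats == "reward_only"]
  bc <- bootstrap_contrast(mixed, only, grid20, mask20, radius = 6,
                           n_boot = 1, subset_size = length(mixed),
                           consistency = 1, n_perm = 29, seed = 14)
  # manual replication of the single iteration
  dens_m <- density_map(mixed, grid20, mask20, radius = 6)
  thr_m <- permutation_threshold(mixed, grid20, mask20, radius = 6,
                                 n_perm = 29, seed = 15)  # seed + b
  dens_o <- density_map(only, grid20, mask20, radius = 6)
  thr_o <- permutation_threshold(only, grid20, mask20, radius = 6,
                                 n_perm = 29, seed = 14)
  manual <- (dens_m$values > thr_m$critical) & !(dens_o$values > thr_o$critical)
  expect_identical(bc$final, manual)
  expect_error(bootstrap_contrast(mixed, only, grid20, mask20,
                                  consistency = 0, seed = 1),
               "consistency")
})

test_that("a mixed-only planted cluster lands in the final contrast map", {
  spec <- foci_spec(n_studies = c(reward_mixed = 10, reward_only = 6),
                    foci_per_study = 3, cluster_center = c(0, 0, 0),
                    cluster_sd = 2, cluster_categories = "reward_mixed")
  st <- simulate_foci(spec, grid20, mask20, seed = 16)
  cats <- vapply(st, `[[`, "", "category")
  bc <- bootstrap_contrast(st[cats == "reward_mixed"],
                           st[cats == "reward_only"],
                           grid20, mask20, radius = 6, n_boot = 10,
                           subset_size = 6, consistency = 0.5,
                           n_perm = 49, seed = 17)
  v <- rewpun:::mm_to_voxel(grid20, c(0, 0, 0))
  expect_true(bc$final[v[1], v[2], v[3]])
  expect_true(all(bc$frequency >= 0 & bc$frequency <= 1))
})

test_that("overlap percentages follow the set arithmetic", {
  a <- array(FALSE, c(4, 4, 4)); b <- a; m <- array(TRUE, c(4, 4, 4))
  a[1:10] <- TRUE
  expect_equal(overlap_fraction(a, a, m)$percent, 100)
  expect_equal(overlap_fraction(a, b, m)$percent, 0)
  b[1:4] <- TRUE
  expect_equal(overlap_fraction(a, b, m)$percent, 40)
  empty <- overlap_fraction(array(FALSE, c(4, 4, 4)), b, m)
  expect_true(empty$flagged)
  expect_equal(empty$percent, 0)
  expect_error(overlap_fraction(a, array(FALSE, c(3, 3, 3)), m),
               "grid mismatch")
})

test_that("foci tables round-trip through CSV", {
  spec <- foci_spec(n_studies = c(reward_mixed = 3, reward_only = 2))
  st <- simulate_foci(spec, grid20, mask20, seed = 19)
  path <- tempfile(fileext = ".csv")
  write_foci(st, path)
  st2 <- read_foci(path)
  expect_equal(length(st2), length(st))
  orig <- st[[order(vapply(st, `[[`, "", "study_id"))[1]]]
  back <- st2[[orig$study_id]]
  expect_equal(back$foci, orig$foci)
  expect_equal(back$n_participants, orig$n_participants)
  unlink(path)
})
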