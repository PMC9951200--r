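test_that("equirectangular projection matches great-circle distances locally", {
  ref <- c(119, 29.6)
  p <- project_coordinates(rbind(ref), reference = ref)
  expect_equal(unlist(p[1, ]), c(x = 0, y = 0))
  # one degree of longitude on the equator
  eq <- project_coordinates(cbind(c(0, 1), c(0, 0)), reference = c(0, 0))
  expect_equal(dist(eq)[1], 6371000 * pi / 180, tolerance = 1e-6)
  expect_equal(dist(eq)[1], 111194.9, tolerance = 1e-6)
  # within a 30 km extent the planar distances track the haversine oracle
  set.seed(41)
  lon <- 118.9 + runif(15, 0, 0.3); lat <- 29.5 + runif(15, 0, 0.27)
  proj <- project_coordinates(cbind(lon, lat))
  dp <- as.matrix(dist(proj))
  dh <- outer(seq_along(lon), seq_along(lon), function(i, j) {
    haversine_m(lon[i], lat[i], lon[j], lat[j])
  })
  off <- abs(dp - dh) / ifelse(dh > 0, dh, 1)
  # meridian convergence across ~0.3 degrees of latitude bounds the planar
  # error near 0.1% at this latitude
  expect_lt(max(off[dh > 0]), 0.002)
  expect_lt(median(off[dh > 0]), 0.001)
  expect_error(project_coordinates(cbind(0, 95)), "lat")
})

test_that("environmental divergence is Euclidean on standardized attributes", {
  isl <- toy_islands(2)
  isl$area_m2 <- c(5, 5); isl$elevation_m <- c(120, 120)
  isl$veg_coverage <- c(0.4, 0.4); isl$habitat_richness <- c(0, 1)
  d <- environmental_distance(isl, c("habitat_richness"))
  # raw {0,1} standardized to +-1/sqrt(2): distance sqrt(2)
  expect_equal(d[1, 2], sqrt(2))
  same <- toy_islands(3)
  same[2, c("area_m2", "elevation_m", "veg_coverage", "habitat_richness")] <-
    same[1, c("area_m2", "elevation_m", "veg_coverage", "habitat_richness")]
  expect_equal(environmental_distance(same)[1, 2], 0)
  # constant columns carry no signal and are dropped with a warning
  isl3 <- toy_islands(4)
  isl3$elevation_m <- 150
  expect_warning(d3 <- environmental_distance(isl3), "zero-variance")
  isl4 <- isl3[, setdiff(names(isl3), "elevation_m")]
  d4 <- environmental_distance(isl4, c("area_m2", "veg_coverage",
                                       "habitat_richness"))
  expect_equal(unname(d3), unname(d4))
  expect_error(environmental_distance(toy_islands(3), "nope"), "missing")
})

test_that("Mantel r is exact for identical and affine-related matrices", {
  set.seed(42)
  xy <- data.frame(x = runif(12) * 1000, y = runif(12) * 1000,
                   row.names = sprintf("i%02d", 1:12))
  A <- geographic_distance(xy)
  expect_equal(mantel_test(A, A, n_perm = 99)$r, 1)
  B <- 3 + 2 * A; diag(B) <- 0
  expect_equal(mantel_test(A, B, n_perm = 99)$r, 1)
  expect_error(mantel_test(A[1:2, 1:2], A[1:2, 1:2]), "3 islands")
})

test_that("Mantel agrees with vegan on complete matrices", {
  set.seed(43)
  m <- random_occurrence(30, 12, fill = 0.4)
  xy <- data.frame(x = runif(12) * 5000, y = runif(12) * 5000,
                   row.names = colnames(m))
  A <- pairwise_beta(m); B <- geographic_distance(xy)
  r_pkg <- mantel_test(A, B, n_perm = 99)$r
  r_veg <- vegan::mantel(as.dist(A), as.dist(B), permutations = 0)$statistic
  expect_equal(r_pkg, unname(r_veg), tolerance = 1e-12)
})

test_that("permutation p-values are bounded away from zero at the stated resolution", {
  set.seed(44)
  xy <- data.frame(x = runif(10) * 1000, y = runif(10) * 1000,
                   row.names = sprintf("i%02d", 1:10))
  A <- geographic_distance(xy)
  res <- mantel_test(A, A, n_perm = 99)
  expect_gte(res$p, 1 / 100)
  expect_lte(res$p, 1)
})

test_that("partial correlation formula and reductions are exact", {
  expect_equal(islecomm:::partial_cor(0.8, 0.5, 0.5), (0.8 - 0.25) / 0.75)
  expect_equal(islecomm:::partial_cor(0.8, 0.5, 0.5), 0.73333333, tolerance = 1e-8)
  expect_error(islecomm:::partial_cor(0.5, 1, 0.2), "degenerate")
  set.seed(45)
  m <- random_occurrence(40, 15, fill = 0.35)
  xy <- data.frame(x = runif(15) * 8000, y = runif(15) * 8000,
                   row.names = colnames(m))
  A <- pairwise_beta(m); B <- geographic_distance(xy)
  Cc <- B * 0; diag(Cc) <- 0   # constant-distance covariable
  set.seed(7)
  expect_message(pr <- partial_mantel(A, B, Cc, n_perm = 99), "zero variance")
  set.seed(7)
  sr <- mantel_test(A, B, n_perm = 99)
  expect_equal(pr$r, sr$r)
  expect_equal(pr$p, sr$p)
  expect_error(partial_mantel(A, B, A, n_perm = 9), "degenerate")
})

test_that("partial Mantel matches the regression-residual oracle and vegan", {
  set.seed(46)
  m <- random_occurrence(40, 14, fill = 0.35)
  xy <- data.frame(x = runif(14) * 8000, y = runif(14) * 8000,
                   row.names = colnames(m))
  isl <- data.frame(island_id = colnames(m),
                    area_m2 = exp(runif(14, 7, 13)),
                    elevation_m = runif(14, 110, 250),
                    veg_coverage = runif(14), habitat_richness = 1:14)
  A <- pairwise_beta(m); B <- geographic_distance(xy)
  Cc <- environmental_distance(isl)
  r_pkg <- partial_mantel(A, B, Cc, n_perm = 9)$r
  ut <- upper.tri(A)
  a <- A[ut]; b <- B[ut]; cc <- Cc[ut]
  r_oracle <- cor(resid(lm(a ~ cc)), resid(lm(b ~ cc)))
  expect_equal(r_pkg, r_oracle, tolerance = 1e-12)
  r_veg <- vegan::mantel.partial(as.dist(A), as.dist(B), as.dist(Cc),
                                 permutations = 0)$statistic
  expect_equal(r_pkg, unname(r_veg), tolerance = 1e-12)
  # symmetry in the first two arguments
  expect_equal(partial_mantel(B, A, Cc, n_perm = 9)$r, r_pkg)
})

test_that("Mantel r is invariant under a consistent relabeling of islands", {
  set.seed(47)
  m <- random_occurrence(30, 12, fill = 0.35)
  xy <- data.frame(x = runif(12) * 5000, y = runif(12) * 5000,
                   row.names = colnames(m))
  A <- pairwise_beta(m); B <- geographic_distance(xy)
  p <- sample(12)
  r1 <- mantel_test(A, B, n_perm = 19)$r
  r2 <- mantel_test(A[p, p], B[p, p], n_perm = 19)$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("Mantel permutation p is approximately uniform under independence", {
  set.seed(48)
  n <- 20; reps <- 200
  ps <- vapply(seq_len(reps), function(i) {
    A <- as.matrix(dist(runif(n))); B <- as.matrix(dist(runif(n)))
    dimnames(A) <- dimnames(B) <- list(paste0("i", 1:n), paste0("i", 1:n))
    mantel_test(A, B, n_perm = 59)$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_true(mean(ps <= 0.05) >= 0.0 && mean(ps <= 0.05) <= 0.12)
})

test_that("null-expected partial correlations are reproducible and calibrated", {
  set.seed(49)
  arch <- generate_archipelago(n_islands = 25, extent = 20000)
  m <- generate_community(arch, n_species = 60, lambda = 2000, q = 0.8)
  geo <- geographic_distance(arch$coords)
  env <- environmental_distance(arch$islands)
  set.seed(5)
  a <- null_expected_partial_mantel(m, "EE", n = 30, geo = geo, env = env)
  set.seed(5)
  b <- null_expected_partial_mantel(m, "EE", n = 30, geo = geo, env = env)
  expect_identical(a$values, b$values)
  # equiprobable nulls erase the spatial signal: expected r centred near 0
  expect_lt(abs(a$comparison$expected_mean), 0.1)
  expect_gt(a$observed, a$comparison$expected_mean)
})
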