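test_that("degenerate communities and constraints give zero inertia", {
  # identical relative composition on every island: zero chi-square inertia
  m <- matrix(1L, 4, 5, dimnames = list(paste0("s", 1:4), paste0("i", 1:5)))
  x <- matrix(rnorm(5), 5, 1, dimnames = list(colnames(m), "v"))
  fit <- cca_partial(m, x)
  expect_equal(fit$total_inertia, 0, tolerance = 1e-12)
  # constant constraint explains nothing
  set.seed(61)
  m2 <- random_occurrence(6, 8, fill = 0.4)
  const <- matrix(3, 8, 1, dimnames = list(colnames(m2), "c"))
  expect_equal(cca_partial(m2, const)$constrained_inertia, 0, tolerance = 1e-12)
  expect_equal(cca_partial(m2, const)$rank, 0L)
})

test_that("inertia accounting matches the brute-force oracle on random instances", {
  set.seed(62)
  for (k in 1:50) {
    ns <- sample(3:6, 1); ni <- sample(4:8, 1)
    m <- random_occurrence(ns, ni, fill = runif(1, 0.3, 0.6))
    # ensure every island occupied so no sites are dropped
    for (j in which(colSums(m) == 0)) m[sample(ns, 1), j] <- 1L
    x <- matrix(rnorm(ni * 2), ni, 2, dimnames = list(colnames(m), c("a", "b")))
    z <- matrix(rnorm(ni), ni, 1, dimnames = list(colnames(m), "z"))
    fit <- cca_partial(m, x, covariables = z)
    ref <- oracle_cca(m, x, z)
    expect_equal(fit$total_inertia, ref$total_inertia, tolerance = 1e-10)
    expect_equal(fit$constrained_inertia, ref$constrained_inertia,
                 tolerance = 1e-10)
    expect_equal(fit$conditioned_inertia, ref$conditioned_inertia,
                 tolerance = 1e-10)
  }
})

test_that("CCA matches the vegan reference implementation", {
  set.seed(63)
  m <- random_occurrence(12, 10, fill = 0.4)
  for (j in which(colSums(m) == 0)) m[sample(nrow(m), 1), j] <- 1L
  x <- data.frame(a = rnorm(10), b = runif(10), row.names = colnames(m))
  z <- data.frame(z = rnorm(10), row.names = colnames(m))
  fit <- cca_partial(m, x)
  ref <- vegan::cca(t(m) ~ a + b, data = x)
  expect_equal(fit$total_inertia, unname(ref$tot.chi), tolerance = 1e-10)
  expect_equal(fit$constrained_inertia, unname(ref$CCA$tot.chi),
               tolerance = 1e-10)
  expect_equal(fit$eigenvalues, unname(ref$CCA$eig), tolerance = 1e-8)
  pfit <- cca_partial(m, x, covariables = z)
  pref <- vegan::cca(t(m) ~ a + b + Condition(z$z), data = x)
  expect_equal(pfit$constrained_inertia, unname(pref$CCA$tot.chi),
               tolerance = 1e-10)
  expect_equal(pfit$conditioned_inertia, unname(pref$pCCA$tot.chi),
               tolerance = 1e-10)
})

test_that("an empty covariable set is the same model as no covariables", {
  set.seed(64)
  m <- random_occurrence(8, 9, fill = 0.4)
  x <- matrix(rnorm(18), 9, 2, dimnames = list(colnames(m), c("a", "b")))
  f1 <- cca_partial(m, x)
  f2 <- cca_partial(m, x, covariables = x[, 0, drop = FALSE])
  expect_equal(f1$constrained_inertia, f2$constrained_inertia, tolerance = 1e-12)
  expect_equal(f1$eigenvalues, f2$eigenvalues, tolerance = 1e-12)
})

test_that("constrained inertia grows monotonically with added constraints", {
  set.seed(65)
  m <- random_occurrence(10, 12, fill = 0.4)
  X <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(colnames(m), paste0("v", 1:5)))
  con <- vapply(1:5, function(k) {
    cca_partial(m, X[, 1:k, drop = FALSE])$constrained_inertia
  }, numeric(1))
  expect_true(all(diff(con) >= -1e-10))
  # collinear constraints reduce rank, not error
  X2 <- cbind(X[, 1, drop = FALSE], v1b = 2 * X[, 1])
  fit <- cca_partial(m, X2)
  expect_identical(fit$rank, 1L)
})

test_that("empty islands are dropped with a warning", {
  m <- toy_matrix()
  m <- cbind(m, i4 = 0L)
  x <- matrix(rnorm(4), 4, 1, dimnames = list(colnames(m), "v"))
  expect_warning(fit <- cca_partial(m, x), "empty island")
  expect_identical(fit$n_dropped, 1L)
  expect_identical(fit$n_sites, 3L)
})

test_that("the permutation pseudo-F test attains its bounds and controls size", {
  set.seed(66)
  # perfect dependence: a compositional staircase perfectly ordered along x
  n <- 12
  x <- sort(runif(n, -2, 2))
  m <- t(vapply(seq_len(n - 1), function(j) as.integer(seq_len(n) >= j),
                integer(n)))
  dimnames(m) <- list(paste0("s", seq_len(n - 1)), paste0("i", seq_len(n)))
  X <- matrix(x, n, 1, dimnames = list(colnames(m), "x"))
  res <- cca_permutation_test(m, X, n_perm = 99)
  expect_equal(res$p, 1 / 100)
  expect_error(cca_permutation_test(m, X, n_perm = 0), "at least 1")
  # size under the null: rejection rate near alpha over 200 replicates
  rejections <- 0L
  for (i in 1:200) {
    mm <- random_occurrence(15, 12, fill = 0.35)
    for (j in which(colSums(mm) == 0)) mm[sample(15, 1), j] <- 1L
    XX <- matrix(rnorm(12), 12, 1, dimnames = list(colnames(mm), "x"))
    if (cca_permutation_test(mm, XX, n_perm = 59)$p <= 0.05) {
      rejections <- rejections + 1L
    }
  }
  expect_gte(rejections / 200, 0.02)
  expect_lte(rejections / 200, 0.09)
})

test_that("variance partitioning fractions add up and respect confounding", {
  set.seed(67)
  # fully confounded: the two sets are the same variables
  m <- random_occurrence(12, 10, fill = 0.4)
  for (j in which(colSums(m) == 0)) m[sample(12, 1), j] <- 1L
  X <- matrix(rnorm(20), 10, 2, dimnames = list(colnames(m), c("a", "b")))
  vp_dup <- variance_partition(m, X, X, n_perm = 0)
  expect_equal(vp_dup$fraction_a, 0, tolerance = 1e-8)
  expect_equal(vp_dup$fraction_c, 0, tolerance = 1e-8)
  expect_equal(vp_dup$fraction_b, vp_dup$total_explained, tolerance = 1e-8)
  # accounting identity a + b + c = total on random instances
  for (k in 1:100) {
    ns <- sample(4:8, 1); ni <- sample(6:10, 1)
    mm <- random_occurrence(ns, ni, fill = 0.4)
    for (j in which(colSums(mm) == 0)) mm[sample(ns, 1), j] <- 1L
    s1 <- matrix(rnorm(ni * 2), ni, 2, dimnames = list(colnames(mm), c("a", "b")))
    s2 <- matrix(rnorm(ni * 2), ni, 2, dimnames = list(colnames(mm), c("c", "d")))
    vp <- variance_partition(mm, s1, s2, n_perm = 0)
    expect_equal(vp$fraction_a + vp$fraction_b + vp$fraction_c,
                 vp$total_explained, tolerance = 1e-6)
  }
})

test_that("fractions are invariant to invertible reparameterization of a set", {
  set.seed(68)
  m <- random_occurrence(10, 12, fill = 0.4)
  for (j in which(colSums(m) == 0)) m[sample(10, 1), j] <- 1L
  s1 <- matrix(rnorm(24), 12, 2, dimnames = list(colnames(m), c("a", "b")))
  s2 <- matrix(rnorm(24), 12, 2, dimnames = list(colnames(m), c("c", "d")))
  vp1 <- variance_partition(m, s1, s2, n_perm = 0)
  Tm <- matrix(c(2, 1, 0, -3), 2, 2)     # invertible recombination
  vp2 <- variance_partition(m, s1 %*% Tm, s2 * 10, n_perm = 0)
  for (f in c("fraction_a", "fraction_b", "fraction_c", "total_explained")) {
    expect_equal(vp1[[f]], vp2[[f]], tolerance = 1e-8)
  }
})

test_that("isolation partitioning reports df = (2, 7) and tracks the signal", {
  set.seed(69)
  arch <- generate_archipelago(n_islands = 40, extent = 20000)
  m <- generate_community(arch, n_species = 80, q = 0.4)
  ip <- suppressWarnings(isolation_partition(m, arch$islands, n_perm = 19))
  expect_identical(ip$df_isolation, 2L)
  expect_identical(ip$df_total, 7L)
  # constant isolation columns explain nothing independently
  isl2 <- arch$islands
  isl2$isw <- 0.5; isl2$isd_m <- 100
  ip2 <- suppressWarnings(isolation_partition(m, isl2, n_perm = 0))
  expect_equal(ip2$independent_isolation, 0, tolerance = 1e-8)
  # a community driven by ISW alone loads on the independent fraction
  isl3 <- arch$islands
  isl3$isw <- runif(40)                        # decorrelate from the rest
  mm <- t(vapply(1:80, function(s) {
    as.integer(isl3$isw > runif(1, 0.05, 0.95))
  }, integer(40)))
  dimnames(mm) <- list(paste0("s", 1:80), isl3$island_id)
  mm[1, colSums(mm) == 0] <- 1L
  ip3 <- suppressWarnings(isolation_partition(mm, isl3, n_perm = 0))
  expect_gt(ip3$independent_isolation, 0.6 * ip3$total_explained)
  expect_lt(abs(ip3$confounded), 0.4 * ip3$total_explained)
})
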