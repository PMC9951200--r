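# Independent oracles used across the suite. These deliberately take
# different numerical routes from the package internals (explicit loops,
# normal equations / pseudo-inverse instead of QR) so that agreement is a
# genuine cross-check.

# Moore-Penrose pseudo-inverse via SVD.
pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

# Brute-force (partial) CCA: explicit chi-square double centring, weighted
# least squares by normal equations, dense eigendecomposition.
oracle_cca <- function(comm, X, Z = NULL) {
  Y <- t(comm)
  X <- as.matrix(X)
  if (!is.null(Z)) Z <- as.matrix(Z)
  keep <- rowSums(Y) > 0
  Y <- Y[keep, , drop = FALSE]
  X <- X[keep, , drop = FALSE]
  if (!is.null(Z)) Z <- Z[keep, , drop = FALSE]
  Y <- Y[, colSums(Y) > 0, drop = FALSE]
  f <- sum(Y)
  P <- Y / f
  r <- rowSums(P); cw <- colSums(P)
  n <- nrow(Y); m <- ncol(Y)
  Q <- matrix(0, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    Q[i, j] <- (P[i, j] - r[i] * cw[j]) / sqrt(r[i] * cw[j])
  }
  wc <- function(M) {
    for (k in seq_len(ncol(M))) M[, k] <- M[, k] - sum(r * M[, k])
    M * sqrt(r)
  }
  Xw <- wc(X)
  conditioned <- 0
  if (!is.null(Z)) {
    Zw <- wc(Z)
    H <- Zw %*% pinv(Zw)
    fitZ <- H %*% Q
    conditioned <- sum(fitZ^2)
    Q <- Q - fitZ
    Xw <- Xw - H %*% Xw
  }
  fitted <- Xw %*% pinv(Xw) %*% Q
  ev <- eigen(crossprod(fitted), symmetric = TRUE, only.values = TRUE)$values
  list(total_inertia = sum(Q^2) + conditioned,
       constrained_inertia = sum(fitted^2),
       conditioned_inertia = conditioned,
       eigenvalues = ev[ev > 1e-12 * max(ev, 1e-300)])
}

# All binary matrices with the given row and column sums (tiny cases only).
enumerate_margin_matrices <- function(row_sums, col_sums) {
  nr <- length(row_sums); nc <- length(col_sums)
  stopifnot(nr * nc <= 16)
  out <- list()
  for (k in 0:(2^(nr * nc) - 1)) {
    bits <- as.integer(intToBits(k))[seq_len(nr * nc)]
    mm <- matrix(bits, nr, nc)
    if (all(rowSums(mm) == row_sums) && all(colSums(mm) == col_sums)) {
      out[[length(out) + 1L]] <- mm
    }
  }
  out
}

matrix_key <- function(m) paste(as.integer(m), collapse = "")

# Haversine great-circle distance in metres (oracle for the projection).
haversine_m <- function(lon1, lat1, lon2, lat2, R = 6371000) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad; dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * R * asin(sqrt(a))
}

random_occurrence <- function(n_species, n_islands, fill = 0.3) {
  m <- matrix(rbinom(n_species * n_islands, 1, fill), n_species, n_islands)
  storage.mode(m) <- "integer"
  # guarantee at least one presence
  if (sum(m) == 0) m[1, 1] <- 1L
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_species)),
                      sprintf("i%02d", seq_len(n_islands)))
  m
}

toy_taxa <- function() {
  data.frame(
    species_id = c("s1", "s2", "s3", "s4"),
    family = c("famA", "famG", "famB", "famI"),
    division = c("moss", "liverwort", "moss", "hornwort"),
    growth_form = c("acrocarpous", "not_applicable", "pleurocarpous",
                    "not_applicable"),
    stringsAsFactors = FALSE)
}

toy_matrix <- function() {
  m <- matrix(c(1, 0, 1,
                0, 1, 1,
                1, 1, 0,
                0, 0, 1), 4, 3, byrow = TRUE)
  dimnames(m) <- list(c("s1", "s2", "s3", "s4"), c("i1", "i2", "i3"))
  as_occurrence_matrix(m)
}

toy_islands <- function(n = 3) {
  data.frame(
    island_id = paste0("i", seq_len(n)),
    lon = 118.9 + seq_len(n) * 0.01, lat = 29.6 + seq_len(n) * 0.005,
    area_m2 = 10^(3 + seq_len(n) / 2), elevation_m = 110 + 10 * seq_len(n),
    perimeter_m = 500 * seq_len(n), habitat_richness = seq_len(n) + 1,
    veg_coverage = seq_len(n) / (n + 1), isw = seq_len(n) / (2 * n),
    isd_m = 100 * seq_len(n), stringsAsFactors = FALSE)
}
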