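#' Shape irregularity index of an island
#'
#' Patton's shape index `SHA = P / (2 * sqrt(A * pi))`, the ratio of the
#' island perimeter to the circumference of a circle of the same area. A
#' perfect circle gives 1; larger values indicate more convoluted outlines
#' and relatively more edge habitat. The index is dimensionless and
#' scale-invariant: `SHA(k*P, k^2*A) = SHA(P, A)`.
#'
#' @param perimeter perimeter in metres (vectorized).
#' @param area area in square metres (vectorized).
#' @return numeric vector of shape indices.
#' @export
shape_irregularity <- function(perimeter, area) {
  if (any(perimeter <= 0) || any(area <= 0)) {
    stop("perimeter and area must be positive")
  }
  perimeter / (2 * sqrt(area * pi))
}

#' Water fraction within a circle around an island (isolation index)
#'
#' Computes the proportion of water in a circular neighbourhood (default
#' diameter 500 m) centred on a point of the island, on a rasterized
#' land/water mask. Cells belong to the circle when their centres fall
#' within it.
#'
#' @param land_mask binary matrix, 1 = land, 0 = water; rows index the y
#'   grid dimension, columns x.
#' @param cell_size cell edge length in metres.
#' @param center integer `c(row, col)` of the centre cell; must be land.
#' @param diameter circle diameter in metres (default 500).
#' @return water fraction in `[0, 1]`.
#' @export
isolation_water_fraction <- function(land_mask, cell_size, center,
                                     diameter = 500) {
  m <- as.matrix(land_mask)
  if (!all(m %in% c(0, 1))) stop("land_mask must be binary")
  r <- center[1]; c <- center[2]
  if (m[r, c] != 1) stop("center must lie on a land cell")
  radius <- diameter / 2
  # cell-centre coordinates in metres
  cy <- (seq_len(nrow(m)) - 0.5) * cell_size
  cx <- (seq_len(ncol(m)) - 0.5) * cell_size
  y0 <- cy[r]; x0 <- cx[c]
  if (x0 - radius < 0 || y0 - radius < 0 ||
      x0 + radius > ncol(m) * cell_size || y0 + radius > nrow(m) * cell_size) {
    stop("circle exceeds the extent of the land mask")
  }
  dy2 <- (cy - y0)^2
  dx2 <- (cx - x0)^2
  inside <- outer(dy2, dx2, "+") <= radius^2
  n_in <- sum(inside)
  sum(m[inside] == 0) / n_in
}

#' Sampling error from expected and observed richness
#'
#' Signed percentage shortfall of the observed species count relative to
#' the asymptotic expectation: `(E - O) / E * 100`.
#'
#' @param expected expected (asymptotic) species number `E`, positive.
#' @param observed observed species number `O`.
#' @return signed percent.
#' @export
sampling_error <- function(expected, observed) {
  if (any(expected <= 0)) stop("expected richness must be positive")
  (expected - observed) / expected * 100
}

#' Fit the Clench (Michaelis-Menten) accumulation model to a curve
#'
#' Least-squares fit of `S(n) = a*n / (1 + b*n)`, whose asymptote is `a/b`.
#' Used internally by [fit_species_accumulation()]; exposed because fitting
#' a precomputed mean curve directly is occasionally useful.
#'
#' @param n specimen counts (x axis).
#' @param s accumulated species counts (y axis).
#' @return list with elements `a`, `b`, `asymptote`.
#' @export
fit_clench <- function(n, s) {
  stopifnot(length(n) == length(s), length(n) >= 3)
  df <- data.frame(n = n, s = s)
  # Michaelis-Menten parameterization S = Vm*n/(K + n); asymptote = Vm
  fit <- tryCatch(
    nls(s ~ SSmicmen(n, Vm, K), data = df),
    error = function(e) tryCatch(
      suppressWarnings(
        minpack.lm::nlsLM(s ~ Vm * n / (K + n), data = df,
                          start = list(Vm = max(s) * 1.5, K = max(n) / 4),
                          lower = c(Vm = 1e-8, K = 1e-8))),
      error = function(e2) NULL)
  )
  if (!is.null(fit)) {
    co <- coef(fit)
    return(list(a = unname(co["Vm"] / co["K"]), b = unname(1 / co["K"]),
                asymptote = unname(co["Vm"])))
  }
  # linearized (double-reciprocal) fall-back for curves the iterative
  # fitters cannot handle; an unsaturated (linear) curve has no finite
  # asymptote and reports Inf
  keep <- s > 0
  lw <- lm(I(1 / s[keep]) ~ I(1 / n[keep]))
  a <- 1 / unname(coef(lw)[2])
  b <- unname(coef(lw)[1]) * a
  list(a = a, b = b, asymptote = if (b <= 1e-12) Inf else a / b)
}

#' Specimen-based species accumulation with an asymptotic fit
#'
#' Randomizes the collection order of a specimen sequence
#' `n_randomizations` times, averages the species accumulation curves, fits
#' the Clench asymptotic model to the mean curve, and reports the expected
#' asymptotic richness `E`, the observed richness `O` and the sampling
#' error `(E - O)/E * 100`. Sampling is flagged inadequate when the error
#' exceeds `flag_threshold` percent (or when the fit undershoots the
#' observed richness, which signals a curve still in its linear regime).
#'
#' @param specimens character vector of species labels in collection order.
#' @param n_randomizations number of random reorderings (default 100).
#' @param flag_threshold percent sampling error above which the island is
#'   flagged undersampled (default 10).
#' @return object of class `accumulation_fit`: list with `asymptote`, `a`,
#'   `b`, `n_specimens`, `observed_richness`, `sampling_error`, `flag`,
#'   and the mean `curve` (data frame `n`, `s`).
#' @export
fit_species_accumulation <- function(specimens, n_randomizations = 100,
                                     flag_threshold = 10) {
  specimens <- as.character(specimens)
  n <- length(specimens)
  if (n < 10) stop("need at least 10 specimens")
  if (length(unique(specimens)) < 2) {
    stop("need at least 2 distinct species")
  }
  acc <- numeric(n)
  for (i in seq_len(n_randomizations)) {
    ord <- sample(specimens)
    acc <- acc + cumsum(!duplicated(ord))
  }
  curve <- data.frame(n = seq_len(n), s = acc / n_randomizations)
  observed <- length(unique(specimens))
  fit <- fit_clench(curve$n, curve$s)
  expected <- fit$asymptote
  se <- if (is.finite(expected)) sampling_error(expected, observed) else 100
  structure(list(
    asymptote = expected, a = fit$a, b = fit$b,
    n_specimens = n, observed_richness = observed,
    sampling_error = se,
    flag = se > flag_threshold || expected < observed,
    curve = curve
  ), class = "accumulation_fit")
}

#' @export
print.accumulation_fit <- function(x, ...) {
  cat(sprintf(
    "Species accumulation: %d specimens, observed S = %d, expected E = %.2f\n",
    x$n_specimens, x$observed_richness, x$asymptote))
  cat(sprintf("Sampling error (E-O)/E: %.2f%%%s\n", x$sampling_error,
              if (x$flag) "  [flagged: possibly undersampled]" else ""))
  invisible(x)
}
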