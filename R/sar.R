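#' Fit a species-area relationship on the log scale
#'
#' Ordinary least squares of `ln(S + 1)` on `ln(A)` (areas in square
#' metres), the linearized power-law species-area relationship. The `+1`
#' offset retains zero-richness islands. The slope `z` is invariant under a
#' change of area units (only the intercept `C` shifts), and `r` is the
#' Pearson correlation of the two transformed variables (so `r^2` is the
#' coefficient of determination of the simple regression).
#'
#' @param areas island areas in square metres (positive).
#' @param richness species counts per island (non-negative integers).
#' @return object of class `sar_fit`: list with `C` (intercept), `z`
#'   (slope), `r` (correlation; `NA` flagged degenerate when richness is
#'   constant), `n`, `transform`.
#' @export
fit_sar <- function(areas, richness) {
  stopifnot(length(areas) == length(richness))
  if (length(areas) < 3) stop("need at least 3 islands")
  if (any(areas <= 0)) stop("areas must be positive")
  if (any(richness < 0)) stop("richness must be non-negative")
  la <- log(areas)
  ls <- log(richness + 1)
  if (sd(la) == 0) stop("areas are constant; the slope is undefined")
  fit <- lm(ls ~ la)
  degenerate <- sd(ls) == 0
  structure(list(
    C = unname(coef(fit)[1]), z = unname(coef(fit)[2]),
    r = if (degenerate) NA_real_ else cor(la, ls),
    n = length(areas), degenerate = degenerate,
    transform = "ln(S+1) vs ln(area m^2)"
  ), class = "sar_fit")
}

#' @export
print.sar_fit <- function(x, ...) {
  cat(sprintf("SAR fit (%s): C = %.4f, z = %.4f, r = %s, n = %d\n",
              x$transform, x$C, x$z, format(x$r, digits = 3), x$n))
  invisible(x)
}

#' Island richness vector from an occurrence matrix
#'
#' @param matrix occurrence matrix (species x islands).
#' @return named integer vector of species counts per island.
#' @export
island_richness <- function(matrix) {
  n <- colSums(as_occurrence_matrix(matrix))
  storage.mode(n) <- "integer"
  n
}

#' Rank species-area slopes across taxa or biotas
#'
#' Collects `sar_fit` objects and/or externally published `(C, z, r)` rows
#' into one table sorted by decreasing `z`. Ties preserve the input label
#' order. Published parameter rows round-trip unchanged, so slopes fitted
#' here can be ranked against literature values for other biotas of the
#' same island system.
#'
#' @param fits named list of `sar_fit` objects (may be empty).
#' @param published optional data frame with columns `label`, `C`, `z`,
#'   `r` (and optionally `reference`).
#' @return data frame with columns `label`, `C`, `z`, `r`, `source`,
#'   sorted by `z` descending.
#' @export
compare_z <- function(fits = list(), published = NULL) {
  rows <- list()
  for (label in names(fits)) {
    f <- fits[[label]]
    rows[[length(rows) + 1L]] <- data.frame(
      label = label, C = f$C, z = f$z, r = f$r, source = "fitted",
      stringsAsFactors = FALSE)
  }
  if (!is.null(published)) {
    stopifnot(all(c("label", "C", "z", "r") %in% names(published)))
    rows[[length(rows) + 1L]] <- data.frame(
      label = published$label, C = published$C, z = published$z,
      r = published$r, source = "published", stringsAsFactors = FALSE)
  }
  if (length(rows) < 1) stop("need at least one fit or published row")
  out <- do.call(rbind, rows)
  if (nrow(out) < 2) stop("need at least 2 entries to compare")
  out[order(-out$z), , drop = FALSE]
}
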