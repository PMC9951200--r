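# Internal CCA engine -------------------------------------------------------
#
# Canonical correspondence analysis in the chi-square metric, sites = island
# columns of the occurrence matrix, species not down-weighted. The community
# is converted to the weighted chi-square residual matrix
#   Qbar = diag(1/sqrt(r)) (P - r c') diag(1/sqrt(c)),  P = Y / sum(Y),
# whose squared norm is the total inertia. Constraints are r-weighted
# centred, sqrt(r)-scaled, and Qbar is projected onto them by QR; with
# covariables both Qbar and the constraints are residualized on the
# covariable space first (partial CCA).

cca_prepare <- function(community, constraints, covariables = NULL) {
  m <- as_occurrence_matrix(community)
  Y <- t(m)                                   # sites x species
  empty_sites <- rowSums(Y) == 0
  if (any(empty_sites)) {
    warning(sprintf("dropping %d empty island(s) from the ordination: %s",
                    sum(empty_sites),
                    paste(head(rownames(Y)[empty_sites], 5), collapse = ", ")))
    Y <- Y[!empty_sites, , drop = FALSE]
  }
  X <- as_constraint_matrix(constraints, rownames(Y), !empty_sites, "constraints")
  Z <- if (!is.null(constraints_nonempty(covariables))) {
    as_constraint_matrix(covariables, rownames(Y), !empty_sites, "covariables")
  } else NULL
  Y <- Y[, colSums(Y) > 0, drop = FALSE]      # unobserved species carry no inertia
  if (nrow(Y) < 3 || ncol(Y) < 1 || sum(Y) < 1) {
    stop("community must retain at least 3 occupied islands and 1 species")
  }
  f <- sum(Y)
  P <- Y / f
  r <- rowSums(P); cw <- colSums(P)
  Qbar <- (P - outer(r, cw)) / outer(sqrt(r), sqrt(cw))
  wcenter <- function(M) sweep(M, 2, colSums(M * r), "-")
  Xw <- sqrt(r) * wcenter(X)
  Zw <- if (!is.null(Z)) sqrt(r) * wcenter(Z) else NULL
  list(Qbar = Qbar, Xw = Xw, Zw = Zw, r = r,
       n_sites = nrow(Y), n_dropped = sum(empty_sites))
}

# Align a constraint table to the retained (non-empty) sites. Rows may be
# named (matched by island id) or positional over either the full or the
# retained island set.
as_constraint_matrix <- function(x, site_ids, keep = NULL, what = "constraints") {
  if (is.data.frame(x)) {
    rn <- if ("island_id" %in% names(x)) x$island_id else rownames(x)
    x <- as.matrix(x[, setdiff(names(x), "island_id"), drop = FALSE])
    rownames(x) <- rn
  }
  x <- as.matrix(x)
  if (!is.null(rownames(x)) && all(site_ids %in% rownames(x))) {
    x <- x[site_ids, , drop = FALSE]
  } else if (!is.null(keep) && nrow(x) == length(keep)) {
    x <- x[keep, , drop = FALSE]
  } else if (nrow(x) != length(site_ids)) {
    stop(sprintf("%s rows do not match the island set", what))
  }
  storage.mode(x) <- "double"
  if (anyNA(x)) stop(sprintf("%s contain missing values", what))
  x
}

constraints_nonempty <- function(x) {
  if (is.null(x)) return(NULL)
  if ((is.matrix(x) || is.data.frame(x)) && ncol(x) == 0) return(NULL)
  x
}

# Project M onto the column space of B (QR, rank-revealing); returns fitted.
qr_project <- function(M, B, qr_B = qr(B)) {
  if (qr_B$rank == 0) return(M * 0)
  qr.fitted(qr_B, M)
}

cca_engine <- function(prep) {
  Qbar <- prep$Qbar
  total <- sum(Qbar^2)
  conditioned <- 0
  Xw <- prep$Xw
  if (!is.null(prep$Zw)) {
    qz <- qr(prep$Zw)
    fitZ <- qr_project(Qbar, prep$Zw, qz)
    conditioned <- sum(fitZ^2)
    Qbar <- Qbar - fitZ
    norm_before <- colSums(Xw^2)
    Xw <- Xw - qr_project(Xw, prep$Zw, qz)
    # a constraint column absorbed by the covariables is numerical noise
    # after residualization; keep it out of the projection basis
    keep <- colSums(Xw^2) > 1e-12 * pmax(norm_before, .Machine$double.xmin)
    Xw <- Xw[, keep, drop = FALSE]
  }
  qx <- qr(Xw)
  fitted <- qr_project(Qbar, Xw, qx)
  constrained <- sum(fitted^2)
  ev <- svd(fitted, nu = 0, nv = 0)$d^2
  ev <- ev[ev > max(ev[1], 0) * 1e-12]
  list(total_inertia = total, constrained_inertia = constrained,
       conditioned_inertia = conditioned, eigenvalues = ev,
       rank = qx$rank, residual_inertia = total - conditioned - constrained,
       Qres_reduced = Qbar, Xres = Xw, qx = qx)
}

#' Canonical correspondence analysis with optional covariables
#'
#' Constrained ordination of a binary occurrence matrix in the chi-square
#' metric (sites = islands, species = rows of the occurrence matrix, rare
#' species not down-weighted). With covariables, both the community and
#' the constraints are residualized on the covariable space first (partial
#' CCA). Islands without any species are dropped with a warning (the
#' chi-square transform is undefined for empty sites). Collinear
#' constraints reduce the reported rank rather than erroring.
#'
#' @param community occurrence matrix (species x islands).
#' @param constraints numeric matrix or data frame of constraining
#'   variables, rows matching islands (by rownames or `island_id`).
#' @param covariables optional matrix/data frame of conditioning variables.
#' @return object of class `cca_result`: `total_inertia`,
#'   `constrained_inertia`, `conditioned_inertia`, `eigenvalues`, `rank`,
#'   `df_constraints` (= rank), `n_sites`, `n_dropped`.
#' @export
cca_partial <- function(community, constraints, covariables = NULL) {
  prep <- cca_prepare(community, constraints, covariables)
  eng <- cca_engine(prep)
  structure(list(
    total_inertia = eng$total_inertia,
    constrained_inertia = eng$constrained_inertia,
    conditioned_inertia = eng$conditioned_inertia,
    eigenvalues = eng$eigenvalues, rank = eng$rank,
    df_constraints = eng$rank,
    n_sites = prep$n_sites, n_dropped = prep$n_dropped
  ), class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("CCA: total inertia %.4f, constrained %.4f (%.2f%%), conditioned %.4f, rank %d\n",
              x$total_inertia, x$constrained_inertia,
              100 * x$constrained_inertia / x$total_inertia,
              x$conditioned_inertia, x$rank))
  invisible(x)
}

#' Permutation test of a (partial) CCA
#'
#' Pseudo-F test of the constrained inertia,
#' `F = (constrained / rank) / (residual / df_resid)`, with significance by
#' permuting the rows of the community's chi-square residuals under the
#' reduced model (the covariable fit, when covariables are present, is held
#' fixed and only the reduced-model residuals are permuted across islands).
#'
#' @inheritParams cca_partial
#' @param n_perm number of permutations (must be >= 1).
#' @return list with `pseudo_F`, `p`, `n_perm`, plus the fitted
#'   `cca_result` as `fit`.
#' @export
cca_permutation_test <- function(community, constraints, covariables = NULL,
                                 n_perm = 999) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  prep <- cca_prepare(community, constraints, covariables)
  eng <- cca_engine(prep)
  n <- prep$n_sites
  pz <- if (!is.null(prep$Zw)) qr(prep$Zw)$rank else 0
  df_resid <- n - 1 - eng$rank - pz
  if (df_resid < 1) stop("no residual degrees of freedom for the pseudo-F test")
  f_of <- function(Q) {
    fitted <- qr_project(Q, eng$Xres, eng$qx)
    con <- sum(fitted^2)
    (con / eng$rank) / ((sum(Q^2) - con) / df_resid)
  }
  F_obs <- f_of(eng$Qres_reduced)
  F_perm <- vapply(seq_len(n_perm), function(i) {
    f_of(eng$Qres_reduced[sample.int(n), , drop = FALSE])
  }, numeric(1))
  fit <- structure(list(
    total_inertia = eng$total_inertia,
    constrained_inertia = eng$constrained_inertia,
    conditioned_inertia = eng$conditioned_inertia,
    eigenvalues = eng$eigenvalues, rank = eng$rank,
    df_constraints = eng$rank, n_sites = prep$n_sites,
    n_dropped = prep$n_dropped), class = "cca_result")
  list(pseudo_F = F_obs, p = (1 + sum(F_perm >= F_obs)) / (n_perm + 1),
       n_perm = n_perm, fit = fit)
}

#' Variance partitioning of species composition between two predictor sets
#'
#' Partitions the compositional inertia explained by two variable sets
#' (typically spatial eigenvectors versus environmental variables) into the
#' fraction independently explained by each set (`a`, `c`), the confounded
#' fraction (`b = total - a - c`, which may be negative), and the total
#' explained fraction, all as percentages of the total inertia. Independent
#' fractions are the constrained inertias of partial CCAs with the other
#' set as covariables, and carry permutation p-values.
#'
#' @param community occurrence matrix.
#' @param set1,set2 predictor matrices or data frames (rows = islands).
#' @param n_perm permutations for the two testable fractions (default 199;
#'   0 skips testing).
#' @return object of class `partition_result`: `fraction_a`, `fraction_b`,
#'   `fraction_c`, `total_explained` (percent of total inertia), `df_a`,
#'   `df_c`, `p_a`, `p_c`, `total_inertia`.
#' @export
variance_partition <- function(community, set1, set2, n_perm = 199) {
  s1 <- as_matrix_cols(set1); s2 <- as_matrix_cols(set2)
  if (!is.null(rownames(s1)) && !is.null(rownames(s2))) {
    ids <- intersect(rownames(s1), rownames(s2))
    union_set <- cbind(s1[ids, , drop = FALSE], s2[ids, , drop = FALSE])
  } else {
    if (nrow(s1) != nrow(s2)) stop("set1 and set2 rows do not match")
    union_set <- cbind(s1, s2)
  }
  fit_a <- cca_partial(community, set1, covariables = set2)
  fit_c <- cca_partial(community, set2, covariables = set1)
  fit_t <- cca_partial(community, union_set)
  ti <- fit_t$total_inertia
  a <- fit_a$constrained_inertia / ti * 100
  cfrac <- fit_c$constrained_inertia / ti * 100
  tot <- fit_t$constrained_inertia / ti * 100
  p_a <- p_c <- NA_real_
  if (n_perm > 0) {
    p_a <- suppressWarnings(
      cca_permutation_test(community, set1, set2, n_perm)$p)
    p_c <- suppressWarnings(
      cca_permutation_test(community, set2, set1, n_perm)$p)
  }
  structure(list(
    fraction_a = a, fraction_b = tot - a - cfrac, fraction_c = cfrac,
    total_explained = tot,
    df_a = fit_a$rank, df_c = fit_c$rank, df_total = fit_t$rank,
    p_a = p_a, p_c = p_c, total_inertia = ti
  ), class = "partition_result")
}

as_matrix_cols <- function(x) {
  if (is.data.frame(x)) {
    rn <- if ("island_id" %in% names(x)) x$island_id else rownames(x)
    x <- as.matrix(x[, setdiff(colnames(x), "island_id"), drop = FALSE])
    rownames(x) <- rn
  }
  as.matrix(x)
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("Variance partitioning (%% of total inertia %.4f):\n", x$total_inertia))
  cat(sprintf("  set1 independent (a): %6.2f%%  (df = %d, p = %s)\n",
              x$fraction_a, x$df_a, format(x$p_a)))
  cat(sprintf("  set2 independent (c): %6.2f%%  (df = %d, p = %s)\n",
              x$fraction_c, x$df_c, format(x$p_c)))
  cat(sprintf("  confounded       (b): %6.2f%%\n", x$fraction_b))
  cat(sprintf("  total explained     : %6.2f%%\n", x$total_explained))
  invisible(x)
}

#' Isolation-specific variance partitioning
#'
#' Decomposes the compositional variation attributable to island isolation
#' (water fraction ISW and shore distance ISD, `df = 2`) into the part
#' independent of the remaining environmental variables, the part
#' confounded with them (marginal isolation effect minus the independent
#' part), and the total explained by the full variable set.
#'
#' @param community occurrence matrix.
#' @param islands island attribute table containing the named columns.
#' @param isolation_vars isolation columns (default `c("isw", "isd_m")`).
#' @param other_vars remaining environmental columns (default area,
#'   elevation, shape irregularity, vegetation coverage, habitat richness;
#'   shape irregularity is derived from perimeter and area when absent).
#' @param n_perm permutations (default 199).
#' @return list with `independent_isolation` (percent, with `p`),
#'   `confounded`, `total_explained` (percent, with `p`), `df_isolation`,
#'   `df_total`.
#' @export
isolation_partition <- function(community, islands,
                                isolation_vars = c("isw", "isd_m"),
                                other_vars = c("area_m2", "elevation_m", "sha",
                                               "veg_coverage", "habitat_richness"),
                                n_perm = 199) {
  tab <- islands
  if ("sha" %in% other_vars && !"sha" %in% names(tab)) {
    tab$sha <- shape_irregularity(tab$perimeter_m, tab$area_m2)
  }
  missing <- setdiff(c(isolation_vars, other_vars), names(tab))
  if (length(missing)) stop("missing island columns: ",
                            paste(missing, collapse = ", "))
  rownames(tab) <- tab$island_id
  iso <- as.matrix(tab[, isolation_vars, drop = FALSE])
  oth <- as.matrix(tab[, other_vars, drop = FALSE])
  fit_ind <- cca_partial(community, iso, covariables = oth)
  fit_marg <- cca_partial(community, iso)
  fit_full <- cca_partial(community, cbind(iso, oth))
  ti <- fit_full$total_inertia
  independent <- fit_ind$constrained_inertia / ti * 100
  marginal <- fit_marg$constrained_inertia / ti * 100
  total <- fit_full$constrained_inertia / ti * 100
  p_ind <- p_tot <- NA_real_
  if (n_perm > 0) {
    p_ind <- suppressWarnings(
      cca_permutation_test(community, iso, oth, n_perm)$p)
    p_tot <- suppressWarnings(
      cca_permutation_test(community, cbind(iso, oth), n_perm = n_perm)$p)
  }
  list(independent_isolation = independent,
       confounded = marginal - independent,
       total_explained = total,
       df_isolation = fit_ind$rank, df_total = fit_full$rank,
       p_isolation = p_ind, p_total = p_tot,
       total_inertia = ti)
}
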