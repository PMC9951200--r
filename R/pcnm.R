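#' Truncation threshold for PCNM: longest minimum-spanning-tree edge
#'
#' The smallest distance `t` such that the graph connecting all island
#' pairs closer than `t` is connected, i.e. the longest edge of the
#' Euclidean minimum spanning tree of the coordinates. This is the
#' classical choice of truncation distance for principal coordinates of
#' neighbour matrices.
#'
#' @param coords data frame or matrix with columns `x`, `y` (metres).
#' @return threshold in metres.
#' @export
truncation_threshold <- function(coords) {
  xy <- as.matrix(coords[, c("x", "y")])
  if (nrow(xy) < 2) stop("need at least 2 points")
  d <- dist(xy)
  if (nrow(xy) == 2) return(as.numeric(d))
  max(vegan::spantree(d)$dist)
}

#' PCNM spatial eigenvector basis
#'
#' Principal coordinates of neighbour matrices: pairwise distances larger
#' than the truncation threshold are replaced by `4 * threshold`, the
#' modified distance matrix is double-centred (`-D^2/2`, Gower centring)
#' and eigen-decomposed, and the eigenvectors with positive eigenvalues
#' (larger than `1e-10` of the leading one) are retained, ordered by
#' descending eigenvalue. The retained columns form an orthogonal, centred
#' spatial basis running from broad- to fine-scale patterns.
#'
#' @param coords data frame or matrix with columns `x`, `y` in metres;
#'   rownames are taken as island ids.
#' @param threshold truncation distance in metres; default the longest
#'   minimum-spanning-tree edge ([truncation_threshold()]). A threshold
#'   below that value leaves the neighbour graph disconnected and triggers
#'   a warning.
#' @return object of class `pcnm_basis`: list with `vectors` (islands x
#'   axes, unit-norm columns named `PCNM1`, `PCNM2`, ...), `values`
#'   (eigenvalues), `threshold`.
#' @export
pcnm_basis <- function(coords, threshold = NULL) {
  xy <- as.matrix(coords[, c("x", "y")])
  if (nrow(xy) < 3) stop("need at least 3 points")
  t_min <- truncation_threshold(coords)
  if (is.null(threshold)) threshold <- t_min
  if (threshold < t_min) {
    warning(sprintf(
      "threshold %.6g leaves the neighbour graph disconnected (minimum %.6g)",
      threshold, t_min))
  }
  D <- as.matrix(dist(xy))
  D[D > threshold] <- 4 * threshold
  n <- nrow(D)
  A <- -0.5 * D^2
  G <- A - matrix(rowMeans(A), n, n) -
    matrix(colMeans(A), n, n, byrow = TRUE) + mean(A)
  eig <- eigen(G, symmetric = TRUE)
  keep <- eig$values > 1e-10 * max(eig$values)
  vec <- eig$vectors[, keep, drop = FALSE]
  colnames(vec) <- paste0("PCNM", seq_len(ncol(vec)))
  rownames(vec) <- rownames(coords)
  structure(list(vectors = vec, values = eig$values[keep],
                 threshold = threshold),
            class = "pcnm_basis")
}

#' @export
print.pcnm_basis <- function(x, ...) {
  cat(sprintf("PCNM basis: %d positive axes over %d sites (truncation %.4g m)\n",
              ncol(x$vectors), nrow(x$vectors), x$threshold))
  invisible(x)
}

#' Forward selection of spatial eigenvectors by permutation tests
#'
#' Two-stage forward selection of PCNM axes as constraints of a CCA of the
#' community, in the spirit of Blanchet, Legendre and Borcard's remedy for
#' the type-I inflation of naive stepwise selection:
#'
#' 1. a *global* permutation pseudo-F test of all candidate axes together;
#'    when it is not significant at `alpha`, nothing is selected;
#' 2. greedy admission: at each step the candidate adding the most
#'    constrained inertia (conditional on the axes already selected) is
#'    tested with a permutation pseudo-F test under row permutation of the
#'    reduced-model residuals, and admitted when `p < alpha`; selection
#'    stops at the first rejection or when no candidate adds inertia.
#'
#' Ties in added inertia break to the lowest candidate index, so selection
#' is deterministic given the random seed. The stopping rule is
#' significance-only; no adjusted-R-squared ceiling is applied.
#'
#' @param community occurrence matrix (species x islands).
#' @param candidates `pcnm_basis` object, or a numeric matrix of candidate
#'   axes (islands x axes).
#' @param alpha admission significance level (default 0.05); `alpha = 1`
#'   admits every candidate that adds inertia, without testing.
#' @param n_perm permutations per test (default 199).
#' @return list with `selected` (column names in order of admission),
#'   `log` (data frame: step, axis, added_inertia, pseudo_F, p),
#'   `global_p` (p-value of the global test, `NA` when skipped), and
#'   `vectors` (matrix of the selected axes).
#' @export
forward_select <- function(community, candidates, alpha = 0.05, n_perm = 199) {
  V <- if (inherits(candidates, "pcnm_basis")) candidates$vectors
       else as.matrix(candidates)
  if (ncol(V) == 0) stop("no candidate axes")
  m <- as_occurrence_matrix(community)
  if (!is.null(rownames(V)) && all(colnames(m) %in% rownames(V))) {
    V <- V[colnames(m), , drop = FALSE]
  } else if (nrow(V) != ncol(m)) {
    stop("candidate axes do not match the island set")
  }
  empty <- colSums(m) == 0
  if (any(empty)) {
    warning(sprintf("dropping %d empty island(s) before selection", sum(empty)))
    m <- m[, !empty, drop = FALSE]
    V <- V[!empty, , drop = FALSE]
  }
  prep <- cca_prepare(m, V)
  Q <- prep$Qbar                     # residualized as axes are admitted
  U <- prep$Xw                       # weighted centred candidates, ditto
  n <- prep$n_sites

  empty_result <- function(global_p) {
    list(selected = character(0),
         log = data.frame(step = integer(), axis = character(),
                          added_inertia = numeric(), pseudo_F = numeric(),
                          p = numeric()),
         global_p = global_p,
         vectors = V[, integer(0), drop = FALSE])
  }
  if (sum(Q^2) <= 1e-12) return(empty_result(NA_real_))

  # constrained inertia added by each single (already residualized) axis
  added_inertia <- function(Qm, Um, cols) {
    nrm2 <- colSums(Um[, cols, drop = FALSE]^2)
    proj <- crossprod(Um[, cols, drop = FALSE], Qm)   # k x species
    con <- rowSums(proj^2) / pmax(nrm2, 1e-300)
    con[nrm2 < 1e-12] <- 0
    con
  }

  global_p <- NA_real_
  if (alpha < 1) {
    # a saturated candidate set leaves no residual df; fall through to the
    # stepwise tests in that case
    global <- tryCatch(cca_permutation_test(m, V, n_perm = n_perm),
                       error = function(e) NULL)
    if (!is.null(global)) {
      global_p <- global$p
      if (global_p >= alpha) return(empty_result(global_p))
    }
  }

  remaining <- seq_len(ncol(V))
  selected <- integer(0)
  log <- list()
  repeat {
    if (length(remaining) == 0) break
    con <- added_inertia(Q, U, remaining)
    if (all(con <= 1e-12)) break
    best_idx <- which.max(con)       # first maximum: lowest-index tie-break
    best <- remaining[best_idx]
    df_resid <- n - 1 - length(selected) - 1
    if (df_resid < 1) break
    tot <- sum(Q^2)
    f_stat <- function(conv) conv / ((tot - conv) / df_resid)
    F_best <- f_stat(con[best_idx])
    if (alpha >= 1) {
      p <- NA_real_
    } else {
      u_best <- U[, best, drop = FALSE]
      F_perm <- vapply(seq_len(n_perm), function(i) {
        Qp <- Q[sample.int(n), , drop = FALSE]
        f_stat(added_inertia(Qp, u_best, 1L))
      }, numeric(1))
      p <- (1 + sum(F_perm >= F_best)) / (n_perm + 1)
      if (p >= alpha) break
    }
    # admit: residualize community and candidates on the admitted axis
    u <- U[, best]
    u2 <- sum(u^2)
    Q <- Q - u %*% crossprod(u, Q) / u2
    U <- U - u %*% crossprod(u, U) / u2
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    log[[length(log) + 1L]] <- data.frame(
      step = length(selected), axis = colnames(V)[best],
      added_inertia = con[best_idx], pseudo_F = F_best, p = p,
      stringsAsFactors = FALSE)
  }
  log_df <- if (length(log)) do.call(rbind, log) else
    data.frame(step = integer(), axis = character(),
               added_inertia = numeric(), pseudo_F = numeric(), p = numeric())
  list(selected = colnames(V)[selected], log = log_df, global_p = global_p,
       vectors = V[, selected, drop = FALSE])
}
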