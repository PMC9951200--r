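#' Jaccard distance between two binary assemblage vectors
#'
#' `JD = 1 - C / (A + B + C)` where `C` is the number of shared species and
#' `A`, `B` the numbers unique to each island. The distance is undefined
#' (returned as `NA`) when both assemblages are empty.
#'
#' @param occ_i,occ_j binary vectors of equal length.
#' @return Jaccard distance in `[0, 1]`, or `NA` for two empty assemblages.
#' @export
jaccard_distance <- function(occ_i, occ_j) {
  stopifnot(length(occ_i) == length(occ_j))
  u <- sum(occ_i == 1 | occ_j == 1)
  if (u == 0) return(NA_real_)
  1 - sum(occ_i == 1 & occ_j == 1) / u
}

#' Pairwise Jaccard beta diversity over all island pairs
#'
#' Computes the full symmetric matrix of Jaccard distances between island
#' columns of an occurrence matrix: `n*(n-1)/2` distinct pair values for
#' `n` islands. Pairs of two empty islands are undefined and returned as
#' `NA` (a pair of one empty and one occupied island has distance 1).
#'
#' @param matrix occurrence matrix (species x islands).
#' @return symmetric numeric matrix with zero diagonal, `NA` marking
#'   undefined pairs, island ids as dimnames.
#' @export
pairwise_beta <- function(matrix) {
  m <- as_occurrence_matrix(matrix)
  if (ncol(m) < 2) stop("need at least 2 islands")
  shared <- crossprod(m)                      # C
  tot <- colSums(m)
  union <- outer(tot, tot, "+") - shared      # A + B + C
  d <- 1 - shared / union
  d[union == 0] <- NA_real_
  diag(d) <- 0
  dimnames(d) <- list(colnames(m), colnames(m))
  d
}

#' Upper-triangle pair values of a distance matrix
#'
#' @param d symmetric distance matrix (possibly with `NA` masked pairs).
#' @param drop_na drop undefined pairs (default `TRUE`).
#' @return numeric vector of pair values.
#' @export
pair_values <- function(d, drop_na = TRUE) {
  v <- d[upper.tri(d)]
  if (drop_na) v <- v[!is.na(v)]
  v
}

#' Mean beta diversity over defined island pairs
#'
#' Arithmetic mean of the defined (non-`NA`) upper-triangle values. When no
#' pair is defined (every pair joins two empty islands, as can happen in
#' equiprobable null matrices of sparse taxa) the result is `NA` with all
#' pairs counted as masked.
#'
#' @param d symmetric beta-diversity matrix from [pairwise_beta()].
#' @return mean pair value (or `NA`); the number of masked pairs is
#'   attached as attribute `"n_masked"`.
#' @export
mean_beta <- function(d) {
  v <- d[upper.tri(d)]
  n_masked <- sum(is.na(v))
  out <- if (n_masked == length(v)) NA_real_ else mean(v, na.rm = TRUE)
  attr(out, "n_masked") <- n_masked
  out
}

#' Six binary null models for occurrence matrices
#'
#' Randomizes a binary species-by-island matrix under one of six schemes
#' named by their row (species) and column (island) constraints, each
#' letter being E (equiprobable), P (proportional to the observed margin)
#' or F (fixed margin):
#'
#' * `EE` - the grand total of presences is scattered uniformly over
#'   distinct cells;
#' * `EF` - each island keeps its richness; species are drawn uniformly;
#' * `PE` - presences are scattered with species weights proportional to
#'   observed occurrence frequencies, islands equiprobable;
#' * `PF` - each island keeps its richness; species are drawn without
#'   replacement with probability proportional to occurrence frequency;
#' * `FE` - each species keeps its occurrence frequency; islands drawn
#'   uniformly;
#' * `FF` - both margins fixed exactly; sampled by curveball trades.
#'
#' All six schemes preserve the grand total of presences. For `FF` the
#' matrix is burned in with `10 * nrow` curveball trades (a trade picks two
#' species rows and swaps a random subset of their exclusive islands),
#' which samples uniformly from the set of matrices with both margins
#' fixed.
#'
#' @param matrix occurrence matrix.
#' @param model one of `"EE"`, `"EF"`, `"PE"`, `"PF"`, `"FE"`, `"FF"`.
#' @param burn_in number of curveball trades for `FF`
#'   (default `10 * nrow(matrix)`).
#' @return randomized occurrence matrix with the same dimnames.
#' @references The curveball algorithm: Strona et al. (2014) Nature
#'   Communications 5, 4114.
#' @export
randomize <- function(matrix, model = c("EE", "EF", "PE", "PF", "FE", "FF"),
                      burn_in = NULL) {
  model <- match.arg(model)
  m <- as_occurrence_matrix(matrix)
  f <- sum(m)
  if (f < 1) stop("matrix has no presences")
  ns <- nrow(m); ni <- ncol(m)
  rt <- rowSums(m); ct <- colSums(m)
  out <- array(0L, dim(m), dimnames = dimnames(m))
  switch(model,
    EE = {
      out[sample.int(ns * ni, f)] <- 1L
    },
    FE = {
      for (i in seq_len(ns)) if (rt[i] > 0) {
        out[i, sample.int(ni, rt[i])] <- 1L
      }
    },
    EF = {
      for (j in seq_len(ni)) if (ct[j] > 0) {
        out[sample.int(ns, ct[j]), j] <- 1L
      }
    },
    PE = {
      w <- rep(rt, times = ni)  # cell weight = its species' frequency
      out[sample.int(ns * ni, f, prob = w)] <- 1L
    },
    PF = {
      for (j in seq_len(ni)) if (ct[j] > 0) {
        out[sample.int(ns, ct[j], prob = rt), j] <- 1L
      }
    },
    FF = {
      out <- curveball(m, n_trades = burn_in %||% (10L * ns))
    }
  )
  out
}

# Curveball trades on a binary matrix: uniform sampling of the set of
# matrices with both margins fixed, given enough trades.
curveball <- function(m, n_trades) {
  ni <- ncol(m)
  rows <- apply(m, 1, function(r) which(r == 1L), simplify = FALSE)
  ns <- length(rows)
  if (ns < 2) return(m)
  for (k in seq_len(n_trades)) {
    ab <- sample.int(ns, 2L)
    a <- rows[[ab[1]]]; b <- rows[[ab[2]]]
    shared <- intersect(a, b)
    only_a <- setdiff(a, shared); only_b <- setdiff(b, shared)
    pool <- c(only_a, only_b)
    if (length(only_a) == 0 || length(only_b) == 0) next
    pool <- pool[sample.int(length(pool))]
    rows[[ab[1]]] <- c(shared, pool[seq_along(only_a)])
    rows[[ab[2]]] <- c(shared, pool[length(only_a) + seq_along(only_b)])
  }
  out <- array(0L, dim(m), dimnames = dimnames(m))
  for (i in seq_len(ns)) out[i, rows[[i]]] <- 1L
  out
}

#' Null distribution of a matrix statistic under a null model
#'
#' Generates `n` randomized matrices under `model` and evaluates a plug-in
#' statistic (default: mean Jaccard beta diversity) on each. Replicates on
#' which the statistic is undefined (e.g. mean beta of a matrix whose
#' islands are all empty in pairs) are recorded and excluded.
#'
#' For `FF`, a single curveball chain is used: the burn-in is
#' `10 * nrow` trades and successive samples are separated by `nrow`
#' thinning trades.
#'
#' @param matrix occurrence matrix.
#' @param model null model name (see [randomize()]).
#' @param n number of randomizations (default 1000).
#' @param statistic function of an occurrence matrix returning a scalar.
#' @return object of class `null_distribution`: list with `values`
#'   (defined statistic values), `n`, `n_undefined`, `model`.
#' @export
null_distribution <- function(matrix, model, n = 1000,
                              statistic = function(m) mean_beta(pairwise_beta(m))) {
  if (n < 2) stop("need at least 2 randomizations")
  m <- as_occurrence_matrix(matrix)
  vals <- numeric(n)
  if (model == "FF") {
    cur <- randomize(m, "FF")            # burn-in
    thin <- max(1L, nrow(m))
    for (i in seq_len(n)) {
      cur <- curveball(cur, thin)
      vals[i] <- as.numeric(statistic(cur))
    }
  } else {
    for (i in seq_len(n)) {
      vals[i] <- as.numeric(statistic(randomize(m, model)))
    }
  }
  defined <- !is.na(vals)
  if (!any(defined)) {
    stop(sprintf("statistic undefined for all %d '%s' replicates", n, model))
  }
  structure(list(values = vals[defined], n = n,
                 n_undefined = sum(!defined), model = model),
            class = "null_distribution")
}

#' Compare an observed statistic with a null distribution
#'
#' One-sample t-test of the null values against the observed value as the
#' reference, plus the standardized effect size
#' `SES = (observed - mean(null)) / sd(null)`.
#'
#' @param observed observed statistic value.
#' @param null_values numeric vector of null replicate values (or a
#'   `null_distribution` object).
#' @return list with `observed`, `expected_mean`, `expected_sd`, `t`, `df`,
#'   `p`, `ses`, `n_valid`, and `degenerate` (TRUE when the null values
#'   have zero variance).
#' @export
compare_observed <- function(observed, null_values) {
  if (inherits(null_values, "null_distribution")) {
    null_values <- null_values$values
  }
  null_values <- null_values[!is.na(null_values)]
  n <- length(null_values)
  if (n < 2) stop("need at least 2 defined null values")
  mu <- mean(null_values); s <- sd(null_values)
  if (s == 0) {
    equal <- isTRUE(all.equal(mu, observed))
    return(list(observed = observed, expected_mean = mu, expected_sd = 0,
                t = if (equal) 0 else Inf, df = n - 1,
                p = if (equal) 1 else 0,
                ses = if (equal) 0 else Inf * sign(observed - mu),
                n_valid = n, degenerate = TRUE))
  }
  tt <- t.test(null_values, mu = observed)
  list(observed = observed, expected_mean = mu, expected_sd = s,
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, ses = (observed - mu) / s, n_valid = n,
       degenerate = FALSE)
}

#' Compare beta-diversity distributions between two taxa
#'
#' Welch two-sample t-test on the defined pair values of two beta-diversity
#' matrices (e.g. mosses versus liverworts over the same islands). Pair
#' values within a distance matrix are not independent; the test is the
#' conventional descriptive comparison, not a corrected one.
#'
#' @param d1,d2 beta-diversity matrices from [pairwise_beta()].
#' @return list with `mean1`, `mean2`, `t`, `df`, `p`.
#' @export
compare_beta_between_taxa <- function(d1, d2) {
  v1 <- pair_values(d1); v2 <- pair_values(d2)
  if (length(v1) < 2 || length(v2) < 2) {
    stop("each matrix needs at least 2 defined pair values")
  }
  tt <- t.test(v1, v2)
  list(mean1 = mean(v1), mean2 = mean(v2), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

#' Observed-versus-null beta diversity for one taxon
#'
#' Convenience wrapper running [pairwise_beta()], [null_distribution()] and
#' [compare_observed()] for a set of null models, mirroring one row of the
#' standard observed/expected beta-diversity table.
#'
#' @param matrix occurrence matrix for one taxon.
#' @param models null model names (default all six).
#' @param n randomizations per model (default 1000).
#' @return data frame with one row per model: observed, expected mean/sd,
#'   t, df, p, SES, n_valid, n_undefined.
#' @export
beta_null_table <- function(matrix, models = c("EE", "EF", "PE", "PF", "FE", "FF"),
                            n = 1000) {
  obs <- as.numeric(mean_beta(pairwise_beta(matrix)))
  rows <- lapply(models, function(mod) {
    nd <- tryCatch(null_distribution(matrix, mod, n = n), error = function(e) NULL)
    if (is.null(nd)) {
      return(data.frame(model = mod, observed = obs, expected_mean = NA,
                        expected_sd = NA, t = NA, df = NA, p = NA, ses = NA,
                        n_valid = 0, n_undefined = n))
    }
    cmp <- compare_observed(obs, nd)
    data.frame(model = mod, observed = obs,
               expected_mean = cmp$expected_mean, expected_sd = cmp$expected_sd,
               t = cmp$t, df = cmp$df, p = cmp$p, ses = cmp$ses,
               n_valid = cmp$n_valid, n_undefined = nd$n_undefined)
  })
  do.call(rbind, rows)
}
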