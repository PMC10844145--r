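#' Conditional-independence tests for lagged ROI series
#'
#' Tests `x_i(t - lag)` independent of `x_j(t)` given a conditioning set `Z`
#' of (node, lag) pairs, on a concatenated panel. Three regimes are
#' available:
#'
#' * `parcorr` — linear partial correlation: Pearson correlation of the OLS
#'   residuals of the two target columns on `[intercept, Z]`; two-sided
#'   block-shuffle permutation significance.
#' * `gpdc` — Gaussian-process regression of each target on `Z` (radial basis
#'   function plus white-noise kernel, hyperparameters by marginal-likelihood
#'   maximisation) followed by distance correlation of the residual pair;
#'   one-sided block-shuffle permutation significance. With empty `Z` the
#'   residuals are the centred variables themselves.
#' * `cmiknn` — nearest-neighbour conditional mutual information
#'   (Frenzel-Pompe estimator, maximum-norm balls) on rank-transformed
#'   columns, with a local permutation null that shuffles the lagged source
#'   only among samples with nearby `Z`, preserving the X-Z dependence;
#'   one-sided.
#'
#' Block-shuffle permutation (rather than an i.i.d. shuffle) preserves the
#' autocorrelation of BOLD series under the null; the block length defaults
#' to the smallest lag at which the residual autocorrelation falls below
#' `2/sqrt(n)` (clamped to `[1, n/20]`).
#'
#' @param data A `bg_concat` series (or a plain numeric matrix with named
#'   columns).
#' @param i,j Source and target ROI (label or column index). The source is
#'   taken at `t - lag`, the target at `t`.
#' @param lag Non-negative integer lag of the source.
#' @param conds Conditioning set: a data frame / tibble with columns `node`
#'   and `lag`, a list of `c(node, lag)` pairs, or `NULL`.
#' @param method One of `"parcorr"`, `"gpdc"`, `"cmiknn"`.
#' @param alpha Significance level recorded with the result (default 0.01).
#' @param n_permutations Number of permutations (default 500, minimum 99).
#' @param block_length Permutation block length, or `NULL` for the automatic
#'   rule.
#' @param seed Integer seed for the permutation draws (required).
#' @param k Nearest-neighbour count for `cmiknn`; default
#'   `max(5, floor(0.1 n))`, the large-`k` testing regime.
#' @param max_samples For `gpdc`/`cmiknn`, subsample (a seeded contiguous
#'   window) to at most this many rows (default 500) to bound the quadratic
#'   cost; `Inf` disables.
#' @param tau_max Alignment horizon: the first `max(tau_max, lags used)`
#'   samples are dropped so all lagged columns align (default: largest lag in
#'   the test).
#' @param mask_boundaries Exclude rows whose lag window crosses a block
#'   boundary (default `FALSE`; the boundary smoothing exists to make joins
#'   benign).
#' @return A `bg_ci_result`: list with `statistic`, `p_value`, `residuals`
#'   (for `parcorr`/`gpdc`), `n_effective`, `method`, and the test spec.
#' @examples
#' set.seed(1)
#' m <- cbind(A = rnorm(300), B = rnorm(300))
#' m[-1, "B"] <- m[-1, "B"] + 0.6 * m[-300, "A"]
#' ci_test(m, "A", "B", lag = 1, method = "parcorr", seed = 1)
#' @export
ci_test <- function(data, i, j, lag = 0L, conds = NULL,
                    method = c("parcorr", "gpdc", "cmiknn"),
                    alpha = 0.01, n_permutations = 500L,
                    block_length = NULL, seed = NULL,
                    k = NULL, max_samples = 500L,
                    tau_max = NULL, mask_boundaries = FALSE) {
  method <- match.arg(method)
  if (is.null(seed)) stop("`seed` is required (no implicit entropy)")
  if (n_permutations < 99) stop("n_permutations must be >= 99")
  d <- lagged_design(data, i, j, lag, conds, tau_max, mask_boundaries)
  out <- switch(method,
    parcorr = parcorr_engine(d, n_permutations, block_length, seed),
    gpdc = gpdc_engine(d, n_permutations, block_length, seed, max_samples),
    cmiknn = cmiknn_engine(d, n_permutations, seed, k, max_samples)
  )
  structure(c(out, list(method = method, i = i, j = j, lag = lag,
                        conds = d$conds, alpha = alpha)),
            class = "bg_ci_result")
}

#' @export
print.bg_ci_result <- function(x, ...) {
  cz <- if (nrow(x$conds)) {
    paste(sprintf("%s(-%d)", x$conds$node, x$conds$lag), collapse = ", ")
  } else "{}"
  cat(sprintf("<%s CI test: %s(t-%d) _||_ %s(t) | %s>\n  statistic = %.4f, p = %.4g, n = %d\n",
              x$method, x$i, x$lag, x$j, cz, x$statistic, x$p_value,
              x$n_effective))
  invisible(x)
}

# ---- design construction ---------------------------------------------------

as_conds <- function(conds) {
  if (is.null(conds) || (is.data.frame(conds) && nrow(conds) == 0)) {
    return(tibble::tibble(node = character(), lag = integer()))
  }
  if (is.data.frame(conds)) {
    return(tibble::tibble(node = as.character(conds$node),
                          lag = as.integer(conds$lag)))
  }
  tibble::tibble(node = purrr::map_chr(conds, function(p) as.character(p[[1]])),
                 lag = purrr::map_int(conds, function(p) as.integer(p[[2]])))
}

concat_matrix <- function(data) {
  if (is.matrix(data)) return(data)
  rois <- roi_labels(data)
  as.matrix(data[rois])
}

lagged_design <- function(data, i, j, lag, conds, tau_max = NULL,
                          mask_boundaries = FALSE) {
  M <- concat_matrix(data)
  conds <- as_conds(conds)
  resolve <- function(v) if (is.numeric(v)) colnames(M)[v] else as.character(v)
  i <- resolve(i); j <- resolve(j); conds$node <- resolve(conds$node)
  if (any(conds$node == i & conds$lag == lag)) {
    stop("conditioning set must not contain the source (i, lag)")
  }
  if (any(conds$node == j & conds$lag == 0)) {
    stop("conditioning set must not contain the target (j, 0)")
  }
  tmax <- max(lag, conds$lag, tau_max %||% 0L, 0L)
  n <- nrow(M)
  rows <- (tmax + 1):n
  if (mask_boundaries && !is.null(attr(data, "boundaries"))) {
    b <- attr(data, "boundaries")
    bad <- vapply(rows, function(t) any(b > t - tmax & b <= t), logical(1))
    rows <- rows[!bad]
  }
  Z <- if (nrow(conds)) {
    vapply(seq_len(nrow(conds)),
           function(q) M[rows - conds$lag[q], conds$node[q]],
           numeric(length(rows)))
  } else matrix(numeric(0), nrow = length(rows), ncol = 0)
  list(x = M[rows - lag, i], y = M[rows, j], Z = Z, conds = conds,
       n = length(rows))
}

# ---- engines ---------------------------------------------------------------

ols_residuals <- function(y, Z) {
  X <- cbind(1, Z)
  f <- qr(X)
  if (f$rank < ncol(X)) {
    warning("rank-deficient conditioning set; dropping collinear columns")
    X <- X[, f$pivot[seq_len(f$rank)], drop = FALSE]
    f <- qr(X)
  }
  as.numeric(qr.resid(f, y))
}

parcorr_engine <- function(d, n_perm, block_length, seed) {
  if (d$n < 3 + ncol(d$Z)) stop("n_effective too small for |Z| = ", ncol(d$Z))
  rx <- ols_residuals(d$x, d$Z)
  ry <- ols_residuals(d$y, d$Z)
  stat <- cor(rx, ry)
  L <- block_length %||% auto_block_length(rx)
  if (L >= d$n) stop("block_length must be < n")
  perms <- with_seed(seed,
                     pearson_blockperm_cpp(rx, ry, block_starts(d$n, L),
                                           n_perm))
  p <- (1 + sum(abs(perms) >= abs(stat))) / (1 + n_perm)
  list(statistic = stat, p_value = p, residuals = list(x = rx, y = ry),
       n_effective = d$n, block_length = L)
}

gpdc_engine <- function(d, n_perm, block_length, seed, max_samples) {
  d <- subsample_design(d, max_samples, seed)
  sx <- scale(d$x)[, 1]
  sy <- scale(d$y)[, 1]
  if (ncol(d$Z) > 0) {
    Zs <- scale(d$Z)
    rx <- gp_regress_residuals(Zs, sx)
    ry <- gp_regress_residuals(Zs, sy)
  } else {
    rx <- sx
    ry <- sy
  }
  stat <- dcor_stat_cpp(rx, ry)
  L <- block_length %||% auto_block_length(rx)
  if (L >= d$n) stop("block_length must be < n")
  perms <- with_seed(seed,
                     dcor_blockperm_cpp(rx, ry, block_starts(d$n, L),
                                        n_perm))
  p <- (1 + sum(perms >= stat)) / (1 + n_perm)
  list(statistic = stat, p_value = p, residuals = list(x = rx, y = ry),
       n_effective = d$n, block_length = L)
}

cmiknn_engine <- function(d, n_perm, seed, k, max_samples) {
  d <- subsample_design(d, max_samples, seed)
  n <- d$n
  k <- k %||% max(5L, floor(0.1 * n))
  if (n < 10 * k) stop("n_effective < 10 k; use a larger sample or smaller k")
  u <- function(v) rank(v, ties.method = "average") / (length(v) + 1)
  x <- u(d$x); y <- u(d$y)
  Z <- if (ncol(d$Z)) apply(d$Z, 2, u) else d$Z
  stat <- cmi_knn_stat_cpp(x, y, Z, k)
  # empty Z: block-shuffle null (preserves autocorrelation); otherwise the
  # local permutation scheme preserving the X-Z dependence
  L <- auto_block_length(x)
  perms <- with_seed(seed,
                     cmi_local_perm_cpp(x, y, Z, k, k_perm = 10L, n_perm,
                                        block_starts(n, L)))
  p <- (1 + sum(perms >= stat)) / (1 + n_perm)
  list(statistic = stat, p_value = p, residuals = NULL,
       n_effective = n, k = k, block_length = L)
}

# Contiguous seeded window keeps the autocorrelation structure the
# block-shuffle null relies on.
subsample_design <- function(d, max_samples, seed) {
  if (!is.finite(max_samples) || d$n <= max_samples) return(d)
  start <- with_seed(seed + 13L,
                     sample.int(d$n - as.integer(max_samples) + 1L, 1))
  rows <- start:(start + max_samples - 1)
  list(x = d$x[rows], y = d$y[rows], Z = d$Z[rows, , drop = FALSE],
       conds = d$conds, n = as.integer(max_samples))
}

# ---- permutation machinery -------------------------------------------------

#' Permutation null distribution for a bivariate statistic
#'
#' Computes a permutation p-value for `stat_fn(values_to_permute, fixed)`
#' under either a block-shuffle scheme (contiguous blocks of the permuted
#' vector reordered uniformly at random, preserving autocorrelation) or the
#' local scheme used by the CMI test (values swapped only among samples whose
#' `z` coordinates are near neighbours).
#'
#' @param values_to_permute,fixed Numeric vectors of equal length.
#' @param stat_fn Function of two vectors returning a scalar statistic.
#' @param scheme `"block_shuffle"` or `"local"`.
#' @param n_permutations Number of permutations (minimum 99).
#' @param block_length Block length for the shuffle; `NULL` for the automatic
#'   rule (smallest lag with |acf| below `2/sqrt(n)`, clamped to `[1, n/20]`).
#' @param seed Integer seed.
#' @param two_sided Compare `|T|` (default) or `T` against the null.
#' @param z Matrix of conditioning coordinates (local scheme only).
#' @param k_perm Neighbour count for the local scheme (default 10).
#' @return The permutation p-value, with the permuted statistics in
#'   attribute `"perms"` and the block length used in `"block_length"`.
#' @export
permutation_null <- function(values_to_permute, fixed, stat_fn = cor,
                             scheme = c("block_shuffle", "local"),
                             n_permutations = 500L, block_length = NULL,
                             seed = 1L, two_sided = TRUE, z = NULL,
                             k_perm = 10L) {
  scheme <- match.arg(scheme)
  if (n_permutations < 99) stop("n_permutations must be >= 99")
  n <- length(values_to_permute)
  obs <- stat_fn(values_to_permute, fixed)
  if (scheme == "block_shuffle") {
    L <- block_length %||% auto_block_length(values_to_permute)
    if (L >= n) stop("block_length must be < n")
    perms <- if (identical(stat_fn, cor)) {
      with_seed(seed,
                pearson_blockperm_cpp(values_to_permute, fixed,
                                      block_starts(n, L), n_permutations))
    } else {
      idx <- with_seed(seed, block_perm_indices(n, L, n_permutations))
      apply(idx, 1, function(r) stat_fn(values_to_permute[r], fixed))
    }
  } else {
    L <- NA_integer_
    zm <- if (is.null(z)) matrix(numeric(0), n, 0) else as.matrix(z)
    perms <- with_seed(seed, vapply(seq_len(n_permutations), function(r) {
      stat_fn(local_permute(values_to_permute, zm, k_perm), fixed)
    }, numeric(1)))
  }
  p <- if (two_sided) (1 + sum(abs(perms) >= abs(obs))) / (1 + n_permutations)
  else (1 + sum(perms >= obs)) / (1 + n_permutations)
  structure(p, perms = perms, statistic = obs, block_length = L)
}

# Smallest lag at which |acf| drops below 2/sqrt(n), clamped to [1, n/20].
auto_block_length <- function(v) {
  n <- length(v)
  # the result is clamped to n/20, so longer lags never matter
  maxlag <- max(1L, min(n - 1L, ceiling(n / 20)))
  a <- stats::acf(v, lag.max = maxlag, plot = FALSE)$acf[-1]
  thr <- 2 / sqrt(n)
  below <- which(abs(a) < thr)
  L <- if (length(below)) below[1] else maxlag
  max(1L, min(L, floor(n / 20)))
}

block_starts <- function(n, L) as.integer(seq(1L, n, by = L))

# (n_perm x n) matrix of 1-based indices: contiguous blocks of length L in
# uniformly random order (generic stat_fn path).
block_perm_indices <- function(n, L, n_perm) {
  starts <- seq(1L, n, by = L)
  blocks <- lapply(starts, function(s) s:min(s + L - 1L, n))
  nb <- length(blocks)
  t(vapply(seq_len(n_perm), function(r) {
    unlist(blocks[sample.int(nb)], use.names = FALSE)
  }, integer(n)))
}

# R-side local permutation (mirrors the C++ scheme; used by the exported
# permutation_null and by tests).
local_permute <- function(x, z, k_perm = 10L) {
  n <- length(x)
  if (ncol(z) == 0) return(x[sample.int(n)])
  nb <- t(vapply(seq_len(n), function(i) {
    d <- apply(abs(z - matrix(z[i, ], n, ncol(z), byrow = TRUE)), 1, max)
    d[i] <- Inf
    order(d)[seq_len(min(k_perm, n - 1))]
  }, integer(min(k_perm, n - 1))))
  used <- logical(n)
  out <- numeric(n)
  for (i in sample.int(n)) {
    cand <- nb[i, sample.int(ncol(nb))]
    free <- cand[!used[cand]]
    if (length(free)) {
      j <- free[1]
      used[j] <- TRUE
    } else {
      j <- cand[1]
    }
    out[i] <- x[j]
  }
  out
}

# Evaluate `expr` under a temporary RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Distance correlation (V-statistic)
#'
#' The biased double-centering form, matching the classical definition; used
#' as the GPDC statistic and handy for direct checks.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Distance correlation in `[0, 1]`.
#' @export
dcor <- function(x, y) dcor_stat_cpp(as.numeric(x), as.numeric(y))

#' kNN (conditional) mutual information estimate
#'
#' Frenzel-Pompe nearest-neighbour estimator with maximum-norm balls, in
#' nats. With `z = NULL` this is the KSG mutual-information estimator. Inputs
#' are rank-transformed to uniform scores first, making the estimate exactly
#' invariant under strictly monotone transforms.
#'
#' @param x,y Numeric vectors.
#' @param z Optional matrix of conditioning columns.
#' @param k Neighbour count (default `max(5, floor(0.1 n))`; use a small `k`
#'   such as 5-10 when the goal is estimation rather than testing).
#' @return CMI estimate in nats (can be slightly negative).
#' @export
cmi_knn <- function(x, y, z = NULL, k = NULL) {
  n <- length(x)
  k <- k %||% max(5L, floor(0.1 * n))
  u <- function(v) rank(v, ties.method = "average") / (length(v) + 1)
  zm <- if (is.null(z)) matrix(numeric(0), n, 0) else apply(as.matrix(z), 2, u)
  cmi_knn_stat_cpp(u(x), u(y), zm, as.integer(k))
}
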