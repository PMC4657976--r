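#' Prepare a community table for co-inertia coupling
#'
#' Applies a log(x+1) transform to damp dominance, then centres each taxon
#' column under uniform row weights 1/n. The two tables of a pair are
#' prepared identically so their hyperspaces stay commensurate. The total
#' inertia of the prepared matrix is the weighted sum of its squared entries,
#' i.e. the sum of per-column variances with divisor n.
#'
#' @param x An abundance table with at least 2 sites.
#' @return A list with `X` (centred matrix), `row_weights`, `inertia`.
#' @export
prepare_table <- function(x) {
  m <- abundance_matrix(as_abundance(x))
  if (nrow(m) < 2) abort("co-inertia preparation needs at least 2 sites")
  X <- log1p(m)
  X <- sweep(X, 2, colMeans(X), "-")
  n <- nrow(X)
  list(X = X, row_weights = rep(1 / n, n), inertia = sum(X^2) / n)
}

#' Co-inertia analysis of paired community tables
#'
#' Couples the two prepared tables through the weighted cross-covariance
#' matrix \eqn{W = X^\top D Y} (D = diagonal of uniform row weights). The
#' SVD of W yields the co-inertia axes; the total co-inertia is
#' \eqn{\|W\|_F^2}. The global association strength is the RV coefficient
#' \deqn{RV = \mathrm{tr}(C_{ab} C_{ba}) /
#'   \sqrt{\mathrm{tr}(C_{aa}^2)\,\mathrm{tr}(C_{bb}^2)},}
#' the multivariate generalisation of a squared Pearson correlation, lying
#' in [0, 1] and equal to 1 when the two prepared tables span identical
#' configurations.
#'
#' @param pair A `paired_tables` object (see [align_tables()]).
#' @return An object of class `coinertia`.
#' @export
coinertia_fit <- function(pair) {
  stopifnot(inherits(pair, "paired_tables"))
  pa <- prepare_table(pair$a)
  pb <- prepare_table(pair$b)
  if (nrow(pa$X) < 3) abort("co-inertia needs at least 3 shared sites")
  if (pa$inertia <= 0 || pb$inertia <= 0) {
    abort("zero inertia in one table: RV undefined")
  }
  n <- nrow(pa$X)
  W <- crossprod(pa$X, pb$X) / n
  Caa <- crossprod(pa$X) / n
  Cbb <- crossprod(pb$X) / n
  rv <- sum(W^2) / sqrt(sum(Caa^2) * sum(Cbb^2))
  sv <- svd(W)
  keep <- which(sv$d^2 > max(sv$d[1]^2, .Machine$double.eps) * 1e-12)
  structure(list(
    RV = rv,
    total_coinertia = sum(W^2),
    inertia_a = pa$inertia,
    inertia_b = pb$inertia,
    singular_values = sv$d,
    site_scores_a = pa$X %*% sv$u[, keep, drop = FALSE],
    site_scores_b = pb$X %*% sv$v[, keep, drop = FALSE],
    n_sites = n
  ), class = "coinertia")
}

#' @export
print.coinertia <- function(x, ...) {
  cat("Co-inertia analysis of", x$n_sites, "paired sites\n")
  cat(sprintf("  RV coefficient   %.4f\n", x$RV))
  cat(sprintf("  total co-inertia %.4f\n", x$total_coinertia))
  invisible(x)
}

#' Permutation test of the RV coefficient
#'
#' Re-computes RV after randomly permuting whole site rows of the second
#' (fungal) table, breaking the site pairing while preserving each table's
#' internal structure. `p = (1 + #\{RV* >= RV_obs\}) / (1 + B)`.
#'
#' @param pair A `paired_tables` object.
#' @param B Number of permutations (>= 99; default 5999).
#' @param seed Optional integer seed.
#' @return A tibble with `statistic`, `observed`, `B`, `p_value`, `seed`.
#' @export
rv_permutation_test <- function(pair, B = 5999, seed = NULL) {
  stopifnot(inherits(pair, "paired_tables"))
  if (B < 99) abort("`B` must be at least 99")
  pa <- prepare_table(pair$a)
  pb <- prepare_table(pair$b)
  n <- nrow(pa$X)
  if (n < 4) warn("fewer than 4 sites: the permutation null is very coarse")
  denom <- sqrt(sum((crossprod(pa$X) / n)^2) * sum((crossprod(pb$X) / n)^2))
  rv_of <- function(Y) sum((crossprod(pa$X, Y) / n)^2) / denom
  obs <- rv_of(pb$X)
  run <- function() {
    sum(vapply(seq_len(B), function(b) {
      rv_of(pb$X[sample(n), , drop = FALSE]) >= obs - 1e-12
    }, logical(1)))
  }
  exceed <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  tibble::tibble(statistic = "RV", observed = obs, B = B,
                 p_value = (1 + exceed) / (1 + B),
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' @export
tidy.coinertia <- function(x, ...) {
  tibble::tibble(
    axis = seq_along(x$singular_values),
    singular_value = x$singular_values,
    coinertia = x$singular_values^2,
    prop_coinertia = x$singular_values^2 / sum(x$singular_values^2)
  )
}

#' @export
glance.coinertia <- function(x, ...) {
  tibble::tibble(RV = x$RV, total_coinertia = x$total_coinertia,
                 inertia_a = x$inertia_a, inertia_b = x$inertia_b,
                 n_sites = x$n_sites)
}
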