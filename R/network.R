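#' Spearman rank correlation of two abundance vectors
#'
#' Pearson correlation of midrank-transformed values (average ranks for
#' ties). Undefined when either vector is constant.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return Correlation in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  if (length(x) < 3) abort("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("constant vector: Spearman correlation undefined")
  cor(x, y, method = "spearman")
}

# column-wise midranks, standardised so that crossprod(Za, Zb)/(n-1) is the
# Spearman correlation matrix; constant columns become NA
rank_standardize <- function(m) {
  R <- apply(m, 2, rank)
  s <- apply(R, 2, sd)
  Z <- sweep(R, 2, colMeans(R), "-")
  Z <- sweep(Z, 2, s, "/")
  Z[, s == 0] <- NA_real_
  Z
}

#' Pairwise Spearman permutation screen between two community tables
#'
#' Computes the Spearman correlation of every (beetle taxon, fungal taxon)
#' pair across the shared sites and a two-sided permutation p-value for each.
#' In every permutation replicate one shared random reordering of the fungal
#' table's site rows is applied and all pair correlations are recomputed, so
#' each site keeps its composition and the pairwise nulls stay jointly
#' consistent ("sampling within rows" of the site-by-pair layout). P-values
#' use the add-one convention; with B permutations the smallest attainable
#' p is 1/(B+1) (1e-4 at the conventional B = 10000). A parametric
#' t-approximation p-value is reported alongside for diagnostic comparison.
#' Benjamini-Hochberg q-values are computed jointly across all tested pairs.
#'
#' Taxa should be occupancy-filtered first (the field convention is
#' presence on at least 5 sampling units, see [filter_occupancy()]).
#' Constant-across-sites taxa have no rank information; their pairs are
#' returned with `NA` statistics and are excluded from the BH family.
#'
#' @param pair A `paired_tables` object (`a` = beetles, `b` = fungi).
#' @param B Number of permutations (>= 99; default 10000). Ignored when
#'   `exhaustive = TRUE`.
#' @param seed Optional integer seed.
#' @param exhaustive Enumerate all n! site permutations instead of sampling
#'   (only allowed for n <= 8); the p-value is then the exact tail
#'   proportion `#\{|rho*| >= |rho_obs|\} / n!`.
#' @return A tibble with one row per pair: `beetle_id`, `fungus_id`, `rho`,
#'   `p_raw`, `p_param`, `q`; attributes `n_pairs_tested`, `B`, `seed`,
#'   `n_sites`.
#' @export
pairwise_spearman <- function(pair, B = 10000, seed = NULL, exhaustive = FALSE) {
  stopifnot(inherits(pair, "paired_tables"))
  ma <- abundance_matrix(pair$a)
  mb <- abundance_matrix(pair$b)
  n <- nrow(ma)
  if (n < 3) abort("need at least 3 shared sites")
  if (!exhaustive && B < 99) abort("`B` must be at least 99")
  Za <- rank_standardize(ma)
  Zb <- rank_standardize(mb)
  obs <- crossprod(Za, Zb) / (n - 1)
  aobs <- abs(obs)

  perms <- NULL
  if (exhaustive) {
    if (n > 8) abort("exhaustive enumeration limited to n <= 8 sites")
    perms <- all_permutations(n)
    B <- nrow(perms)
  }
  run <- function() {
    exceed <- matrix(0, nrow(obs), ncol(obs))
    for (b in seq_len(B)) {
      idx <- if (exhaustive) perms[b, ] else sample(n)
      exceed <- exceed + (abs(crossprod(Za, Zb[idx, , drop = FALSE]) / (n - 1)) >=
                            aobs - 1e-12)
    }
    exceed
  }
  exceed <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  p_raw <- if (exhaustive) exceed / B else (1 + exceed) / (1 + B)

  tstat <- obs * sqrt((n - 2) / pmax(1 - obs^2, .Machine$double.eps))
  p_param <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p_param <- pmin(p_param, 1)

  out <- tidyr::expand_grid(beetle_id = colnames(ma), fungus_id = colnames(mb)) |>
    dplyr::mutate(
      rho = as.numeric(obs[cbind(.data$beetle_id, .data$fungus_id)]),
      p_raw = as.numeric(p_raw[cbind(.data$beetle_id, .data$fungus_id)]),
      p_param = as.numeric(p_param[cbind(.data$beetle_id, .data$fungus_id)])
    )
  out$p_raw[is.na(out$rho)] <- NA_real_
  out$q <- NA_real_
  ok <- !is.na(out$p_raw)
  out$q[ok] <- bh_adjust(out$p_raw[ok])
  attr(out, "n_pairs_tested") <- sum(ok)
  attr(out, "B") <- B
  attr(out, "seed") <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  attr(out, "n_sites") <- n
  out
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment applied jointly across one family of p-values:
#' \eqn{q_{(i)} = \min_{j \ge i} m\,p_{(j)}/j}, capped at 1. Output is
#' componentwise at least the input and preserves the p-value ordering.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Build a signed bipartite association network
#'
#' Keeps every pair with `q <= threshold_q`, signs each edge by its
#' correlation, and orders edges by decreasing |rho| (the conventional
#' presentation order). The empty network is legitimate.
#'
#' @param stats A pair-statistics tibble from [pairwise_spearman()].
#' @param threshold_q Corrected-significance cutoff (default 0.1, the
#'   conventional exploratory level).
#' @return A tibble of class `assoc_network` with columns `fungus_id`,
#'   `beetle_id`, `rho`, `p_raw`, `q`, `sign` and attributes
#'   `n_pairs_tested`, `threshold_q`, `B`, `seed`.
#' @export
build_network <- function(stats, threshold_q = 0.1) {
  need <- c("beetle_id", "fungus_id", "rho", "p_raw", "q")
  missing <- setdiff(need, names(stats))
  if (length(missing)) abort(paste0("missing columns: ", paste(missing, collapse = ", ")))
  edges <- stats |>
    dplyr::filter(!is.na(.data$q), .data$q <= threshold_q) |>
    dplyr::mutate(sign = ifelse(.data$rho > 0, "positive", "negative")) |>
    dplyr::arrange(dplyr::desc(abs(.data$rho))) |>
    dplyr::select("fungus_id", "beetle_id", "rho", "p_raw", "q", "sign")
  attr(edges, "n_pairs_tested") <- attr(stats, "n_pairs_tested") %||% sum(!is.na(stats$q))
  attr(edges, "threshold_q") <- threshold_q
  attr(edges, "B") <- attr(stats, "B")
  attr(edges, "seed") <- attr(stats, "seed")
  class(edges) <- unique(c("assoc_network", class(edges)))
  edges
}

#' @export
tidy.assoc_network <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.assoc_network <- function(x, ...) {
  tibble::tibble(
    n_edges = nrow(x),
    n_positive = sum(x$sign == "positive"),
    n_negative = sum(x$sign == "negative"),
    n_pairs_tested = attr(x, "n_pairs_tested") %||% NA_integer_,
    threshold_q = attr(x, "threshold_q") %||% NA_real_,
    B = attr(x, "B") %||% NA_integer_
  )
}
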