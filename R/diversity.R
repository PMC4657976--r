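#' Exponential Shannon diversity (effective number of species)
#'
#' The exponential of Shannon entropy (natural log), i.e. the Hill number of
#' order 1: the number of equally common species that would give the same
#' entropy as the observed abundance distribution. Equals richness exactly
#' when counts are uniform, and 1 for a single species.
#'
#' @param counts Nonnegative abundance vector; zeros are ignored.
#' @return Effective species number (>= 1).
#' @examples
#' exp_shannon(c(10, 10, 10, 10)) # 4
#' @export
exp_shannon <- function(counts) {
  if (!is.numeric(counts) || any(counts < 0)) abort("`counts` must be nonnegative numbers")
  if (sum(counts) <= 0) abort("all-zero abundance vector: diversity undefined")
  exp(vegan::diversity(counts, index = "shannon", base = exp(1)))
}

#' Per-site diversity profiles
#'
#' @param x An abundance table.
#' @return A tibble with one row per site: `site_id`, `richness`,
#'   `shannon` (entropy, nats), `exp_shannon`. Sites with zero totals get
#'   richness 0 and `NA` diversities.
#' @export
diversity_profile <- function(x) {
  m <- abundance_matrix(as_abundance(x))
  h <- unname(vegan::diversity(m, "shannon"))
  h[rowSums(m) == 0] <- NA_real_
  tibble::tibble(
    site_id = rownames(m),
    richness = as.integer(rowSums(m > 0)),
    shannon = h,
    exp_shannon = exp(h)
  )
}

#' Individual-based rarefaction
#'
#' Expected species richness in a random subsample of `m` individuals drawn
#' without replacement from a pooled abundance vector, computed from the
#' hypergeometric closed form
#' \eqn{E[S_m] = S - \sum_i \binom{N - n_i}{m} / \binom{N}{m}}.
#'
#' @param counts Pooled nonnegative abundance vector.
#' @param m Subsample size(s), each in `[1, sum(counts)]`.
#' @return Expected richness, one value per element of `m`.
#' @examples
#' rarefy_individual(c(5, 5), 2) # 1.5556
#' @export
rarefy_individual <- function(counts, m) {
  if (sum(counts) <= 0) abort("all-zero abundance vector")
  N <- sum(counts)
  if (any(m < 1 | m > N)) abort(paste0("`m` must lie in [1, ", N, "]"))
  as.numeric(suppressWarnings(vegan::rarefy(matrix(counts, nrow = 1), sample = m)))
}

#' Individual-based rarefaction curve with bootstrap confidence band
#'
#' The expected value at each abscissa comes from the hypergeometric closed
#' form; the confidence band is a percentile bootstrap over repeated random
#' subsamples without replacement (seeded). The terminal point of the curve
#' equals the observed richness.
#'
#' @param counts Pooled abundance vector.
#' @param steps Number of evenly spaced subsample sizes (the total is always
#'   included).
#' @param replicates Bootstrap replicates per point.
#' @param conf Confidence level of the percentile band.
#' @param seed Optional integer seed.
#' @return A tibble of class `rarefaction_curve` with columns `m`,
#'   `expected`, `ci_low`, `ci_high`.
#' @export
rarefaction_curve <- function(counts, steps = 20, replicates = 1000,
                              conf = 0.95, seed = NULL) {
  N <- sum(counts)
  if (N < 1) abort("all-zero abundance vector")
  ms <- unique(sort(c(1L, round(seq(1, N, length.out = steps)), N)))
  expected <- rarefy_individual(counts, ms)
  units <- rep(seq_along(counts), times = counts)
  boot <- function() {
    vapply(ms, function(mm) {
      reps <- vapply(seq_len(replicates), function(b) {
        length(unique(sample(units, mm)))
      }, numeric(1))
      stats::quantile(reps, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    }, numeric(2))
  }
  qs <- if (is.null(seed)) boot() else withr::with_seed(seed, boot())
  out <- tibble::tibble(m = ms, expected = expected,
                        ci_low = pmin(qs[1, ], expected),
                        ci_high = pmax(qs[2, ], expected))
  class(out) <- c("rarefaction_curve", class(out))
  out
}

#' Sample-based rarefaction
#'
#' Mean pooled richness over random subsets of `k` sites. All
#' \eqn{\binom{n}{k}} subsets are enumerated exactly when there are at most
#' `max_exact` of them; otherwise `replicates` random subsets are drawn.
#'
#' @param x An abundance table.
#' @param k Number of sites, `1 <= k <=` number of sites in `x`.
#' @param replicates Monte-Carlo subsets when enumeration is infeasible.
#' @param max_exact Enumeration cutoff on the number of subsets.
#' @param seed Optional integer seed.
#' @return Mean expected richness (a single number).
#' @export
rarefy_samples <- function(x, k, replicates = 200, max_exact = 10000, seed = NULL) {
  m <- abundance_matrix(as_abundance(x))
  n <- nrow(m)
  if (k < 1 || k > n) abort(paste0("`k` must lie in [1, ", n, "]"))
  pooled_richness <- function(idx) sum(colSums(m[idx, , drop = FALSE]) > 0)
  if (choose(n, k) <= max_exact) {
    subsets <- combn(n, k, simplify = FALSE)
    return(mean(vapply(subsets, pooled_richness, numeric(1))))
  }
  draw <- function() {
    mean(vapply(seq_len(replicates), function(b) {
      pooled_richness(sample(n, k))
    }, numeric(1)))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Kruskal-Wallis test of a per-site quantity across groups
#'
#' Tie-corrected Kruskal-Wallis rank-sum test (chi-square approximation),
#' e.g. of per-site species richness across regions.
#'
#' @param values Numeric vector of per-site values.
#' @param groups Group labels, same length as `values`.
#' @return A tibble with `statistic` (H), `df` and `p_value`.
#' @export
kruskal_richness_test <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) abort("need at least 2 non-empty groups")
  if (any(table(droplevels(groups)) == 0)) abort("each group needs at least one observation")
  if (length(unique(values)) == 1) {
    # every observation tied: no rank variation, H = 0 by convention
    return(tibble::tibble(statistic = 0,
                          df = nlevels(droplevels(groups)) - 1,
                          p_value = 1))
  }
  k <- kruskal.test(values, droplevels(groups))
  tibble::tibble(statistic = unname(k$statistic), df = unname(k$parameter),
                 p_value = k$p.value)
}

#' Cross-region taxon overlap summary
#'
#' Pools sites by region, forms each region's taxon presence set, and
#' reports how many taxa occur in every region, as a percentage of total
#' richness (1 decimal, matching conventional reporting). Taxa with no
#' occurrences anywhere are excluded from the total.
#'
#' @param x An abundance table.
#' @param meta Site metadata with `region`.
#' @return A list with `per_region` (tibble: region, richness), `n_shared`,
#'   `total_richness`, `pct_shared`.
#' @export
region_overlap_summary <- function(x, meta) {
  m <- abundance_matrix(as_abundance(x))
  meta <- validate_metadata(meta)
  reg <- meta$region[match(rownames(m), meta$site_id)]
  if (anyNA(reg)) abort("every site needs a metadata record with a region")
  if (length(unique(reg)) < 2) abort("need at least 2 regions")
  m <- m[, colSums(m) > 0, drop = FALSE]
  sets <- lapply(split(seq_len(nrow(m)), reg), function(idx) {
    colnames(m)[colSums(m[idx, , drop = FALSE]) > 0]
  })
  shared <- Reduce(intersect, sets)
  total <- ncol(m)
  list(
    per_region = tibble::tibble(region = names(sets),
                                richness = lengths(sets)),
    n_shared = length(shared),
    total_richness = total,
    pct_shared = round(100 * length(shared) / total, 1)
  )
}

#' Per-stratum species and individual tallies
#'
#' For each vertical stratum, counts the species observed and the
#' individuals captured there, with percentages against the pooled totals.
#' Species percentages are computed against total pooled richness; strata
#' share species, so these percentages can sum to more than 100.
#'
#' @param x An abundance table.
#' @param meta Site metadata with `stratum`.
#' @return A tibble with one row per stratum: `stratum`, `species`,
#'   `pct_species`, `individuals`, `pct_individuals` (percentages rounded to
#'   1 decimal).
#' @export
stratum_summary <- function(x, meta) {
  m <- abundance_matrix(as_abundance(x))
  meta <- validate_metadata(meta)
  str <- meta$stratum[match(rownames(m), meta$site_id)]
  if (anyNA(str)) abort("every site needs a metadata record with a stratum")
  total_sp <- sum(colSums(m) > 0)
  total_ind <- sum(m)
  purrr::map_dfr(split(seq_len(nrow(m)), str), function(idx) {
    sub <- m[idx, , drop = FALSE]
    tibble::tibble(
      species = sum(colSums(sub) > 0),
      pct_species = round(100 * sum(colSums(sub) > 0) / total_sp, 1),
      individuals = sum(sub),
      pct_individuals = round(100 * sum(sub) / total_ind, 1)
    )
  }, .id = "stratum")
}
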