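# brute-force oracle: row-weighted least squares via explicit normal
# equations, fitted values only
ne_fit <- function(design, Q) {
  if (ncol(design) == 0) return(Q * 0)
  G <- crossprod(design)
  design %*% solve(G, crossprod(design, Q))
}

test_that("chi-square standardisation reproduces the contingency decomposition", {
  # independent 2x2 table: zero residuals, zero inertia
  s0 <- chi_square_standardize(toy_abund(matrix(1, 2, 2)))
  expect_equal(s0$total_inertia, 0)
  expect_equal(max(abs(s0$Q)), 0)

  # diagonal 2x2 table: inertia = chi-square / N = 1
  s1 <- chi_square_standardize(toy_abund(rbind(c(2, 0), c(0, 2))))
  expect_equal(s1$total_inertia, 1)

  # inertia equals Pearson chi-square / N on random tables; weighted
  # row/column means of Q vanish
  set.seed(11)
  for (i in 1:10) {
    m <- matrix(rpois(12, 6) + 1, 3, 4)
    st <- chi_square_standardize(toy_abund(m))
    chi2 <- suppressWarnings(stats::chisq.test(m)$statistic)
    expect_equal(st$total_inertia, unname(chi2) / sum(m), tolerance = 1e-10)
    expect_lt(max(abs(colSums(sqrt(outer(st$row_weights, st$col_weights)) * st$Q))), 1e-10)
    expect_equal(sum(st$row_weights), 1)
    expect_equal(sum(st$col_weights), 1)
  }

  expect_error(chi_square_standardize(toy_abund(rbind(c(1, 0), c(2, 0)))),
               "zero column marginal")
})

test_that("partial CCA decomposes inertia exactly and matches oracles", {
  set.seed(21)
  m <- matrix(rpois(24, 5) + 1, 6, 4,
              dimnames = list(paste0("s", 1:6), paste0("t", 1:4)))
  meta <- tibble::tibble(
    site_id = paste0("s", 1:6),
    region = rep(c("R1", "R2"), each = 3),
    management = c("unm", "ext", "acf", "unm", "ext", "acf"),
    stratum = rep(c("canopy", "ground"), 3),
    plot = paste0("p", 1:6)
  )
  fit <- cca_partial(as_abundance(m), meta)

  # closure: conditioned + constrained + residual = total
  expect_equal(fit$conditioned_inertia + fit$constrained_inertia + fit$residual_inertia,
               fit$total_inertia, tolerance = 1e-8)

  # normal-equation oracle on the same weighted designs
  std <- chi_square_standardize(as_abundance(m))
  r <- std$row_weights
  dummy <- function(v) {
    d <- stats::model.matrix(~ factor(v) - 1)
    sqrt(r) * sweep(d, 2, colSums(d * r), "-")
  }
  Z <- dummy(meta$region)
  Qres <- std$Q - ne_fit(Z[, 1, drop = FALSE], std$Q)
  X <- cbind(dummy(meta$management)[, 1:2], dummy(meta$stratum)[, 1, drop = FALSE])
  Xres <- X - ne_fit(Z[, 1, drop = FALSE], X)
  fitted <- ne_fit(Xres, Qres)
  oracle_eig <- svd(fitted)$d^2
  oracle_eig <- oracle_eig[oracle_eig > 1e-12]
  expect_equal(fit$eigenvalues, oracle_eig, tolerance = 1e-8)
  expect_equal(fit$constrained_inertia, sum(oracle_eig), tolerance = 1e-8)

  # independent cross-check against the reference constrained-ordination
  # implementation
  vf <- vegan::cca(m ~ management + stratum + Condition(region),
                   data = as.data.frame(meta))
  expect_equal(unname(fit$eigenvalues), unname(vf$CCA$eig), tolerance = 1e-8)
  expect_equal(fit$conditioned_inertia, vf$pCCA$tot.chi, tolerance = 1e-8)
  expect_equal(fit$residual_inertia, vf$CA$tot.chi, tolerance = 1e-8)

  # tidy/glance surface
  td <- tidy(fit)
  expect_setequal(td$term, c("management", "stratum", "Condition", "Residual"))
  expect_equal(glance(fit)$total_inertia, fit$total_inertia)
})

test_that("degenerate designs collapse the right way", {
  set.seed(31)
  m <- matrix(rpois(32, 4) + 1, 8, 4,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:4)))
  meta <- tibble::tibble(
    site_id = paste0("s", 1:8),
    region = rep(c("R1", "R2"), each = 4),
    management = rep(c("unm", "ext"), 4),
    stratum = rep(c("canopy", "ground"), each = 4),
    plot = paste0("p", 1:8)
  )
  # condition identical to a constraint: that term is fully absorbed
  meta2 <- dplyr::mutate(meta, stratum = ifelse(region == "R1", "canopy", "ground"))
  expect_warning(
    fit2 <- cca_partial(as_abundance(m), meta2, constraints = "stratum", condition = "region"),
    "aliased"
  )
  expect_lt(fit2$constrained_inertia, 1e-10)

  # no condition: ordinary CCA, conditioned inertia zero
  fit3 <- cca_partial(as_abundance(m), meta, constraints = c("management", "stratum"),
                      condition = NULL)
  expect_equal(fit3$conditioned_inertia, 0)
  expect_equal(fit3$constrained_inertia + fit3$residual_inertia, fit3$total_inertia,
               tolerance = 1e-10)
  vf3 <- vegan::cca(m ~ management + stratum, data = as.data.frame(meta))
  expect_equal(unname(fit3$eigenvalues), unname(vf3$CCA$eig), tolerance = 1e-8)
})

test_that("permutation p-values respect bounds and column-order invariance", {
  set.seed(41)
  m <- matrix(rpois(40, 5) + 1, 8, 5,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:5)))
  meta <- tibble::tibble(
    site_id = paste0("s", 1:8),
    region = rep(c("R1", "R2"), each = 4),
    management = rep(c("unm", "ext"), 4),
    stratum = rep(c("canopy", "canopy", "ground", "ground"), 2),
    plot = paste0("p", 1:8)
  )
  fit <- cca_partial(as_abundance(m), meta)
  an <- anova_permutation(fit, B = 99, seed = 5)
  expect_true(all(an$p_value >= 1 / 100 & an$p_value <= 1))
  expect_equal(an$term, c("management", "stratum"))

  # invariance to taxon column order
  perm_cols <- c(3, 1, 5, 2, 4)
  fitp <- cca_partial(as_abundance(m[, perm_cols]), meta)
  anp <- anova_permutation(fitp, B = 99, seed = 5)
  expect_equal(anp$p_value, an$p_value)
  expect_equal(anp$pseudo_F, an$pseudo_F, tolerance = 1e-10)
})

test_that("the permutation test is calibrated under the null and powered under signal", {
  # type-I error: constraints independent of community structure
  pvals <- vapply(1:60, function(s) {
    g <- generate_paired_communities(null_scenario(s))
    x <- g$pair$a
    fit <- cca_partial(x, g$meta, constraints = "stratum", condition = NULL)
    anova_permutation(fit, B = 199, seed = s + 100)$p_value[1]
  }, numeric(1))
  rate <- mean(pvals <= 0.05)
  expect_gte(rate, 0.0)
  expect_lte(rate, 0.15) # binomial 95% band around 0.05 with 60 replicates

  # power: strong planted stratum structure is detected
  strong <- function(s) community_scenario(
    n_regions = 1, plots_per_region = 8, beetle_pool_size = 45,
    fungal_pool_size = 15, region_effect = 0,
    stratum_effect_beetles = 2.5, management_effect_fungi = 0, seed = s
  )
  p_str <- vapply(1:12, function(s) {
    g <- generate_paired_communities(strong(s))
    fit <- cca_partial(g$pair$a, g$meta, constraints = "stratum", condition = NULL)
    anova_permutation(fit, B = 199, seed = s + 500)$p_value[1]
  }, numeric(1))
  expect_gte(mean(p_str <= 0.01), 0.9)
})
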