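test_that("Spearman rho matches the rank closed form", {
  x <- c(1, 2, 3, 4)
  expect_equal(spearman_rho(x, x), 1)
  expect_equal(spearman_rho(x, rev(x)), -1)
  # no ties: 1 - 6 sum(d^2) / (n(n^2-1)) = 1 - 12/60
  expect_equal(spearman_rho(x, c(1, 3, 2, 4)), 0.8)
  expect_error(spearman_rho(x, c(1, 2, 3)), "equal length")
  expect_error(spearman_rho(c(2, 2, 2, 2), x), "constant")
  # midranks under ties agree with the reference implementation
  set.seed(5)
  for (i in 1:10) {
    a <- rpois(12, 3)
    b <- rpois(12, 3)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman_rho(a, b), cor(a, b, method = "spearman"))
  }
})

test_that("pairwise permutation p-values match exhaustive enumeration at n = 4", {
  set.seed(19)
  ma <- matrix(c(3, 1, 4, 2, 5, 9, 2, 6), 4, 2,
               dimnames = list(paste0("s", 1:4), c("b1", "b2")))
  mb <- matrix(c(2, 7, 1, 8, 3, 3, 5, 1), 4, 2,
               dimnames = list(paste0("s", 1:4), c("f1", "f2")))
  pair <- suppressWarnings(align_tables(as_abundance(ma), as_abundance(mb)))
  st <- pairwise_spearman(pair, exhaustive = TRUE)
  expect_equal(attr(st, "B"), 24)

  # brute-force oracle: enumerate the 24 row permutations directly
  perms <- rbind(
    c(1,2,3,4), c(1,2,4,3), c(1,3,2,4), c(1,3,4,2), c(1,4,2,3), c(1,4,3,2),
    c(2,1,3,4), c(2,1,4,3), c(2,3,1,4), c(2,3,4,1), c(2,4,1,3), c(2,4,3,1),
    c(3,1,2,4), c(3,1,4,2), c(3,2,1,4), c(3,2,4,1), c(3,4,1,2), c(3,4,2,1),
    c(4,1,2,3), c(4,1,3,2), c(4,2,1,3), c(4,2,3,1), c(4,3,1,2), c(4,3,2,1)
  )
  for (i in seq_len(nrow(st))) {
    xa <- ma[, st$beetle_id[i]]
    xb <- mb[, st$fungus_id[i]]
    obs <- cor(xa, xb, method = "spearman")
    tail_p <- mean(apply(perms, 1, function(ix) {
      abs(cor(xa, xb[ix], method = "spearman")) >= abs(obs) - 1e-12
    }))
    expect_equal(st$p_raw[i], tail_p, tolerance = 1e-12)
    expect_equal(st$rho[i], obs, tolerance = 1e-12)
  }
})

test_that("a self-paired taxon attains the minimal p-value region", {
  set.seed(23)
  v <- rpois(12, 8) + seq_len(12) # distinct values, no ties
  ma <- matrix(v, 12, 1, dimnames = list(paste0("s", 1:12), "b1"))
  mb <- matrix(v, 12, 1, dimnames = list(paste0("s", 1:12), "f1"))
  pair <- suppressWarnings(align_tables(as_abundance(ma), as_abundance(mb)))
  st <- pairwise_spearman(pair, B = 999, seed = 1)
  expect_equal(st$rho, 1)
  expect_lte(st$p_raw, 3 / 1000)
})

test_that("the pairwise test holds its nominal size on independent data", {
  # pooled rejection rate at p <= 0.05 across simulated null pairs
  rej <- 0
  tot <- 0
  for (s in 1:15) {
    g <- generate_paired_communities(null_scenario(s))
    out <- screen_network(g, B = 499, seed = s + 70)
    rej <- rej + sum(out$stats$p_raw <= 0.05, na.rm = TRUE)
    tot <- tot + attr(out$stats, "n_pairs_tested")
  }
  expect_gt(rej / tot, 0.02)
  expect_lt(rej / tot, 0.08)
})

test_that("parametric t-approximation p-values track the permutation ones", {
  # rho = 0 -> p = 1; |rho| -> 1 pins the minimum
  n <- 16
  t_of <- function(r) r * sqrt((n - 2) / (1 - r^2))
  expect_equal(2 * pt(abs(t_of(0)), n - 2, lower.tail = FALSE), 1)
  # rho = 0.8, n = 16: t = 4.99, p about 2e-4
  expect_equal(t_of(0.8), 4.99, tolerance = 0.01)
  expect_lt(2 * pt(t_of(0.8), n - 2, lower.tail = FALSE), 5e-4)

  g <- generate_paired_communities(null_scenario(42))
  out <- screen_network(g, B = 1999, seed = 11)
  st <- out$stats[!is.na(out$stats$rho) & abs(out$stats$rho) <= 0.7, ]
  moderate <- st[st$p_param > 0.01 & st$p_param < 0.9, ]
  ratio <- moderate$p_raw / moderate$p_param
  # agreement within a factor of 2 for the bulk of moderate correlations
  expect_gt(mean(ratio > 0.5 & ratio < 2), 0.9)
})

test_that("Benjamini-Hochberg adjustment is a valid step-up", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\(0, 1\\]")
  set.seed(6)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_equal(order(q[order(p)]), seq_along(p)) # rank preserving
})

test_that("network construction thresholds, signs and orders edges", {
  stats <- tibble::tibble(
    beetle_id = c("Microscydmus minimus", "Atomaria linearis", "Xyleborus saxeseni", "x"),
    fungus_id = c("MOTU4 Hypoxylon rubiginosum", "MOTU2 Candida sp.",
                  "MOTU4 Hypoxylon rubiginosum", "MOTU9"),
    rho = c(0.7977, 0.7742, -0.7688, 0.2),
    p_raw = c(1e-4, 1e-4, 2e-4, 0.4),
    q = c(0.01, 0.01, 0.015, 0.9)
  )
  net <- build_network(stats, threshold_q = 0.1)
  expect_equal(nrow(net), 3L)
  # presentation order: decreasing |rho|, the strongest association first
  expect_equal(net$fungus_id[1], "MOTU4 Hypoxylon rubiginosum")
  expect_equal(net$beetle_id[1], "Microscydmus minimus")
  expect_equal(net$rho[1], 0.7977)
  expect_equal(net$sign, c("positive", "positive", "negative"))
  # bipartite: every edge joins one fungus and one beetle
  g <- as_igraph(net)
  cls <- igraph::vertex_attr(g, "taxon_class")
  ends <- igraph::ends(g, igraph::E(g))
  lookup <- stats::setNames(cls, igraph::vertex_attr(g, "name"))
  expect_true(all(apply(ends, 1, function(e) setequal(lookup[e], c("fungus", "beetle")))))

  # all q above threshold: empty network is allowed
  expect_equal(nrow(build_network(stats, threshold_q = 0.001)), 0L)

  # threshold monotonicity
  expect_lte(nrow(build_network(stats, threshold_q = 0.012)),
             nrow(build_network(stats, threshold_q = 0.1)))

  # the edge set equals a brute-force recomputation from p_raw + BH
  g2 <- generate_paired_communities(null_scenario(
    3, data.frame(beetle_id = sprintf("B%03d", 1:3),
                  fungus_id = sprintf("MOTU%02d", 1:3), target_rho = 0.9)))
  out <- screen_network(g2, B = 999, seed = 77)
  ok <- !is.na(out$stats$p_raw)
  qq <- bh_adjust(out$stats$p_raw[ok])
  manual <- out$stats[ok, ][qq <= 0.1, c("beetle_id", "fungus_id")]
  expect_setequal(pair_key(out$net$beetle_id, out$net$fungus_id),
                  pair_key(manual$beetle_id, manual$fungus_id))
})

test_that("the network autoplot renders with and without edges", {
  stats <- tibble::tibble(beetle_id = "b", fungus_id = "f", rho = 0.9,
                          p_raw = 0.001, q = 0.05)
  expect_s3_class(autoplot(build_network(stats)), "ggplot")
  expect_s3_class(autoplot(build_network(stats, threshold_q = 0.01)), "ggplot")
})
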