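#' Describe a synthetic paired-community scenario
#'
#' The generator emulates the deadwood-enrichment design: a small number of
#' geographic regions, forest plots under three management classes (`unm`,
#' `ext`, `acf`), two vertical strata per plot (`canopy`, `ground`), beetle
#' counts from flight-interception traps with a long-tailed
#' (negative-binomial over a log-series rank-abundance backbone) distribution
#' and many singletons, and fungal MOTU sequence counts normalised to a fixed
#' sequencing depth per sample. Regional species pools overlap only partially.
#' Known beetle-fungus associations can be planted with a rank-targeted
#' Gaussian copula so that downstream recovery can be scored against ground
#' truth.
#'
#' @param n_regions Number of regions (default 3, labelled `R1`, `R2`, ...).
#' @param plots_per_region Integer vector (recycled) giving forest plots per
#'   region; managements are assigned to plots round-robin over
#'   `unm`, `ext`, `acf`. Default `c(5, 6, 5)`: 16 plots, 32 plot-by-stratum
#'   sampling units.
#' @param beetle_pool_size,fungal_pool_size Total taxon pool sizes.
#' @param cross_region_shared_fraction Fraction of each pool present in every
#'   region (the remainder is split evenly among regions as exclusives).
#' @param fisher_alpha Shape of the log-series rank-abundance backbone for
#'   beetles; smaller values give steeper dominance and more singletons.
#' @param beetle_site_mean Expected number of beetle individuals per sampling
#'   unit before factor effects.
#' @param beetle_dispersion Negative-binomial size parameter for beetle
#'   counts (small = overdispersed).
#' @param fungal_depth Sequences retained per fungal sample (default 26).
#' @param region_effect,stratum_effect_beetles,management_effect_fungi
#'   Standard deviations (log scale) of taxon-specific mean shifts per factor
#'   level; 0 switches the effect off.
#' @param planted_pairs Tibble/data frame with columns `beetle_id`,
#'   `fungus_id`, `target_rho` (|rho| <= 1), or `NULL`.
#' @param seed Integer seed; the whole generation is a single reproducible
#'   RNG stream.
#' @return A `community_scenario` list.
#' @export
community_scenario <- function(n_regions = 3,
                               plots_per_region = c(5, 6, 5),
                               beetle_pool_size = 120,
                               fungal_pool_size = 40,
                               cross_region_shared_fraction = 0.15,
                               fisher_alpha = 8,
                               beetle_site_mean = 220,
                               beetle_dispersion = 0.7,
                               fungal_depth = 26,
                               region_effect = 0.8,
                               stratum_effect_beetles = 0.8,
                               management_effect_fungi = 0.8,
                               planted_pairs = NULL,
                               seed = 1L) {
  stopifnot(n_regions >= 1, beetle_pool_size >= 1, fungal_pool_size >= 1)
  if (cross_region_shared_fraction < 0 || cross_region_shared_fraction > 1) {
    abort("`cross_region_shared_fraction` must be in [0, 1]")
  }
  if (fungal_depth <= 0) abort("`fungal_depth` must be a positive integer")
  if (!is.null(planted_pairs)) {
    planted_pairs <- tibble::as_tibble(planted_pairs)
    stopifnot(all(c("beetle_id", "fungus_id", "target_rho") %in% names(planted_pairs)))
    if (any(abs(planted_pairs$target_rho) > 1)) abort("|target_rho| must be <= 1")
    if (nrow(planted_pairs) > beetle_pool_size || nrow(planted_pairs) > fungal_pool_size) {
      abort("more planted pairs than taxa in a pool")
    }
  }
  out <- list(
    n_regions = as.integer(n_regions),
    plots_per_region = as.integer(rep_len(plots_per_region, n_regions)),
    beetle_pool_size = as.integer(beetle_pool_size),
    fungal_pool_size = as.integer(fungal_pool_size),
    cross_region_shared_fraction = cross_region_shared_fraction,
    fisher_alpha = fisher_alpha,
    beetle_site_mean = beetle_site_mean,
    beetle_dispersion = beetle_dispersion,
    fungal_depth = as.integer(fungal_depth),
    region_effect = region_effect,
    stratum_effect_beetles = stratum_effect_beetles,
    management_effect_fungi = management_effect_fungi,
    planted_pairs = planted_pairs,
    seed = as.integer(seed)
  )
  class(out) <- "community_scenario"
  out
}

#' Read or write a scenario as YAML
#'
#' @param path YAML file path.
#' @return [read_scenario()] returns a `community_scenario`.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$planted_pairs)) {
    raw$planted_pairs <- dplyr::bind_rows(lapply(raw$planted_pairs, tibble::as_tibble))
  }
  do.call(community_scenario, raw)
}

#' @rdname read_scenario
#' @param scenario A `community_scenario`.
#' @export
write_scenario <- function(scenario, path) {
  x <- unclass(scenario)
  if (!is.null(x$planted_pairs)) {
    x$planted_pairs <- purrr::transpose(as.list(x$planted_pairs))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Partition a taxon pool into regional species pools
#'
#' Exactly `ceiling(fraction * pool_size)` taxa are shared by every region;
#' the remaining taxa are split as evenly as possible among regions as
#' regional exclusives, so the union over regions is the whole pool. This
#' reproduces the low cross-region overlap seen in field data (on the order
#' of 10-18 percent of taxa present in all regions).
#'
#' @param taxon_ids Character vector of pool taxon identifiers.
#' @param shared_fraction Fraction of the pool shared by all regions.
#' @param n_regions Number of regions.
#' @return A named list, one character vector of taxa per region, with the
#'   shared set as attribute `shared`.
#' @export
sample_species_pool <- function(taxon_ids, shared_fraction, n_regions) {
  if (shared_fraction < 0 || shared_fraction > 1) abort("`shared_fraction` must be in [0, 1]")
  pool <- length(taxon_ids)
  n_shared <- ceiling(shared_fraction * pool)
  if (n_shared > pool) abort("infeasible partition: shared set exceeds pool")
  shared <- taxon_ids[seq_len(n_shared)]
  rest <- setdiff(taxon_ids, shared)
  idx <- if (length(rest)) rep_len(seq_len(n_regions), length(rest)) else integer(0)
  pools <- lapply(seq_len(n_regions), function(r) c(shared, rest[idx == r]))
  names(pools) <- paste0("R", seq_len(n_regions))
  attr(pools, "shared") <- shared
  pools
}

# Log-series rank-abundance backbone: relative abundance of the i-th ranked
# species proportional to x^i / i, with x set from Fisher's alpha so that the
# expected richness matches the pool under the community mean size.
logseries_relabund <- function(pool_size, alpha) {
  x <- pool_size / (pool_size + alpha)
  i <- seq_len(pool_size)
  w <- x^i / i
  w / sum(w)
}

# Spearman target -> latent Pearson correlation for a bivariate Gaussian
# copula (Pearson, 1907 relation); exact for continuous marginals.
copula_rho <- function(target_rho) 2 * sin(pi * target_rho / 6)

# Discrete marginals tie ranks and attenuate the realised Spearman below the
# continuous-copula value, so the latent correlation is calibrated against
# the actual count marginals: a fixed Monte-Carlo population is pushed
# through the quantile transforms and the latent r is inflated until the
# realised Spearman matches the target (clamped inside the unit interval).
calibrate_copula_r <- function(target, qfun_x, qfun_y, M = 4000) {
  if (target == 0) return(0)
  z1 <- rnorm(M)
  z2 <- rnorm(M)
  realized <- function(r) {
    v <- r * z1 + sqrt(1 - r^2) * z2
    suppressWarnings(cor(qfun_x(pnorm(z1)), qfun_y(pnorm(v)), method = "spearman"))
  }
  clamp <- function(r) max(min(r, 0.999), -0.999)
  r <- clamp(copula_rho(target))
  for (it in 1:3) {
    s <- realized(r)
    if (!is.finite(s) || s * target <= 0) break
    r <- clamp(r * target / s)
  }
  r
}

#' Generate paired beetle and fungus community tables with ground truth
#'
#' Beetle counts are drawn per sampling unit (plot x stratum) from a
#' negative-binomial model whose per-taxon means follow a log-series
#' rank-abundance backbone multiplied by taxon-specific log-normal shifts per
#' region and stratum; taxa outside a region's pool are structural zeros.
#' Fungal counts are drawn per unit as a multinomial of size `fungal_depth`
#' over the regional fungal pool, with taxon-specific log-normal shifts per
#' region and management class, matching a sequence table normalised to a
#' fixed depth. Planted pairs are realised by a shared bivariate Gaussian
#' latent factor: each member's counts are produced by the quantile transform
#' of its marginal (negative binomial for the beetle, binomial within the
#' fixed depth for the fungus), so the pair's expected Spearman correlation
#' approximates `target_rho` up to tie attenuation.
#'
#' @param scenario A [community_scenario()].
#' @return A list with elements `pair` (a `paired_tables` of beetles and
#'   fungi), `meta` (site metadata tibble) and `truth` (planted pairs, effect
#'   sizes and seed).
#' @export
generate_paired_communities <- function(scenario) {
  stopifnot(inherits(scenario, "community_scenario"))
  s <- scenario
  withr::with_seed(s$seed, {
    beetle_ids <- sprintf("B%03d", seq_len(s$beetle_pool_size))
    fungus_ids <- sprintf("MOTU%02d", seq_len(s$fungal_pool_size))
    planted <- s$planted_pairs
    if (!is.null(planted)) {
      bad_b <- setdiff(planted$beetle_id, beetle_ids)
      bad_f <- setdiff(planted$fungus_id, fungus_ids)
      if (length(bad_b) || length(bad_f)) {
        abort(paste0("planted taxa not in pools: ",
                     paste(c(bad_b, bad_f), collapse = ", ")))
      }
    }

    # planted taxa must exist everywhere, so place them in the shared set
    reorder_front <- function(ids, front) c(front, setdiff(ids, front))
    if (!is.null(planted)) {
      beetle_ids <- reorder_front(beetle_ids, unique(planted$beetle_id))
      fungus_ids <- reorder_front(fungus_ids, unique(planted$fungus_id))
    }
    beetle_pools <- sample_species_pool(beetle_ids, s$cross_region_shared_fraction, s$n_regions)
    fungal_pools <- sample_species_pool(fungus_ids, s$cross_region_shared_fraction, s$n_regions)

    regions <- paste0("R", seq_len(s$n_regions))
    managements <- c("unm", "ext", "acf")
    meta <- purrr::map_dfr(seq_len(s$n_regions), function(r) {
      np <- s$plots_per_region[r]
      plots <- sprintf("%sP%02d", regions[r], seq_len(np))
      tidyr::expand_grid(plot = plots, stratum = c("canopy", "ground")) |>
        dplyr::mutate(
          region = regions[r],
          management = managements[(match(.data$plot, plots) - 1L) %% 3L + 1L],
          site_id = paste0(.data$plot, ifelse(.data$stratum == "canopy", "C", "G"))
        )
    }) |>
      dplyr::select("site_id", "region", "management", "stratum", "plot")

    n_sites <- nrow(meta)
    strata <- c("canopy", "ground")

    # taxon-specific log-normal factor shifts (matrices taxon x level)
    shift <- function(n_taxa, levels, sd) {
      m <- matrix(rnorm(n_taxa * length(levels), 0, sd), n_taxa, length(levels))
      colnames(m) <- levels
      m
    }
    b_reg <- shift(length(beetle_ids), regions, s$region_effect)
    b_str <- shift(length(beetle_ids), strata, s$stratum_effect_beetles)
    f_reg <- shift(length(fungus_ids), regions, s$region_effect)
    f_man <- shift(length(fungus_ids), managements, s$management_effect_fungi)
    rownames(b_reg) <- rownames(b_str) <- beetle_ids
    rownames(f_reg) <- rownames(f_man) <- fungus_ids

    base_b <- logseries_relabund(length(beetle_ids), s$fisher_alpha)
    names(base_b) <- beetle_ids
    base_f <- logseries_relabund(length(fungus_ids), s$fisher_alpha)
    names(base_f) <- fungus_ids

    # Latent Gaussian factors for planted pairs. Each planted fungal taxon
    # owns one latent site series; each planted beetle's latent is the
    # normalised combination of its partners' series at the copula-scale
    # correlations, so taxa may take part in several pairs (as in real
    # association tables). Counts are the quantile transforms of the
    # latents through each taxon's marginal.
    planted_f <- if (!is.null(planted)) unique(planted$fungus_id) else character(0)
    planted_b <- if (!is.null(planted)) unique(planted$beetle_id) else character(0)
    planted_b_mu <- 12
    planted_b_size <- 4
    planted_f_prob <- min(0.18, 0.5 / max(length(planted_f), 1))
    if (length(planted_f)) {
      r_cal <- vapply(planted$target_rho, function(tr) {
        calibrate_copula_r(
          tr,
          function(u) qnbinom(u, mu = planted_b_mu, size = planted_b_size),
          function(u) qbinom(u, size = s$fungal_depth, prob = planted_f_prob)
        )
      }, numeric(1))
      wf <- matrix(rnorm(n_sites * length(planted_f)), n_sites, length(planted_f),
                   dimnames = list(NULL, planted_f))
      ub <- vapply(planted_b, function(b) {
        k <- which(planted$beetle_id == b)
        r <- r_cal[k]
        lin <- as.numeric(wf[, planted$fungus_id[k], drop = FALSE] %*% r)
        v <- sum(r^2)
        if (v >= 1) lin / sqrt(v) else lin + sqrt(1 - v) * rnorm(n_sites)
      }, numeric(n_sites))
      uf <- pnorm(wf)
      ub <- matrix(pnorm(ub), n_sites, length(planted_b),
                   dimnames = list(NULL, planted_b))
    } else {
      uf <- ub <- NULL
    }

    bm <- matrix(0, n_sites, length(beetle_ids), dimnames = list(meta$site_id, beetle_ids))
    fm <- matrix(0, n_sites, length(fungus_ids), dimnames = list(meta$site_id, fungus_ids))

    # Marginal parameters for planted taxa (set above, before calibration):
    # the beetle marginal keeps good rank resolution; the fungal marginal is
    # budgeted so the expected total of planted counts stays at about half
    # the fixed sequencing depth.
    for (i in seq_len(n_sites)) {
      reg <- meta$region[i]
      str <- meta$stratum[i]
      man <- meta$management[i]

      # beetles
      in_pool <- beetle_ids %in% beetle_pools[[reg]]
      mu <- base_b * exp(b_reg[, reg] + b_str[, str])
      mu <- mu * in_pool
      mu <- mu / ifelse(sum(mu) > 0, sum(mu), 1) * s$beetle_site_mean
      cnt <- rnbinom(length(mu), mu = mu, size = s$beetle_dispersion)
      # planted beetles: quantile-transformed copula marginals
      for (b in planted_b) {
        cnt[match(b, beetle_ids)] <-
          qnbinom(ub[i, b], mu = planted_b_mu, size = planted_b_size)
      }
      bm[i, ] <- cnt

      # fungi: planted counts first (binomial quantile transform within the
      # fixed depth), remainder multinomial over the regional pool
      fcnt <- numeric(length(fungus_ids))
      for (f in planted_f) {
        fcnt[match(f, fungus_ids)] <-
          qbinom(uf[i, f], size = s$fungal_depth, prob = planted_f_prob)
      }
      if (sum(fcnt) > s$fungal_depth) {
        # extremely unlikely with few planted pairs; trim largest counts
        while (sum(fcnt) > s$fungal_depth) {
          j <- which.max(fcnt)
          fcnt[j] <- fcnt[j] - 1
        }
      }
      remaining <- s$fungal_depth - sum(fcnt)
      in_fpool <- fungus_ids %in% fungal_pools[[reg]] & !(fungus_ids %in% planted_f)
      lam <- base_f * exp(f_reg[, reg] + f_man[, man]) * in_fpool
      if (remaining > 0 && sum(lam) > 0) {
        fcnt <- fcnt + as.numeric(rmultinom(1, remaining, lam / sum(lam)))
      }
      fm[i, ] <- fcnt
    }

    truth <- list(
      planted_pairs = planted %||% tibble::tibble(beetle_id = character(0),
                                                  fungus_id = character(0),
                                                  target_rho = numeric(0)),
      effects = tibble::tibble(
        effect = c("region", "stratum_beetles", "management_fungi"),
        sd_log = c(s$region_effect, s$stratum_effect_beetles, s$management_effect_fungi)
      ),
      seed = s$seed
    )
    list(
      pair = suppressWarnings(align_tables(as_abundance(bm), as_abundance(fm), meta)),
      meta = meta,
      truth = truth
    )
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rarefy each site to a fixed sequencing depth
#'
#' Subsamples each site's counts without replacement down to `depth`
#' sequences (hypergeometric subsampling), mirroring the normalisation of a
#' clone-library sequence table to a fixed number of sequences per sample.
#' Sites whose total is already below `depth` are left unchanged and
#' reported in a warning. Taxon columns are kept even when they become
#' all-zero.
#'
#' @param x An abundance table.
#' @param depth Target per-site total (default 26).
#' @param seed Optional integer seed.
#' @return An abundance tibble whose qualifying rows sum exactly to `depth`.
#' @export
normalize_depth <- function(x, depth = 26, seed = NULL) {
  if (depth <= 0) abort("`depth` must be a positive integer")
  x <- as_abundance(x)
  m <- abundance_matrix(x)
  run <- function() {
    shallow <- character(0)
    for (i in seq_len(nrow(m))) {
      tot <- sum(m[i, ])
      if (tot < depth) {
        shallow <- c(shallow, rownames(m)[i])
      } else if (tot > depth) {
        units <- rep(seq_len(ncol(m)), times = m[i, ])
        keep <- sample(units, depth)
        m[i, ] <<- tabulate(keep, nbins = ncol(m))
      }
    }
    shallow
  }
  shallow <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  if (length(shallow)) {
    warn(paste0("site(s) below target depth left unrescaled: ",
                paste(shallow, collapse = ", ")))
  }
  out <- tibble::as_tibble(as.data.frame(m))
  out <- dplyr::mutate(out, site_id = rownames(m), .before = 1L)
  validate_abundance(out)
}
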