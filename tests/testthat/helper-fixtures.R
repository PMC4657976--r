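# shared fixture builders (all data generated in code)

toy_abund <- function(counts, sites = NULL, taxa = NULL) {
  counts <- as.matrix(counts)
  rownames(counts) <- sites %||% paste0("s", seq_len(nrow(counts)))
  colnames(counts) <- taxa %||% paste0("t", seq_len(ncol(counts)))
  as_abundance(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_meta <- function(site_ids, region = "R1", management = "unm",
                     stratum = "ground", plot = NULL) {
  tibble::tibble(
    site_id = site_ids,
    region = rep_len(region, length(site_ids)),
    management = rep_len(management, length(site_ids)),
    stratum = rep_len(stratum, length(site_ids)),
    plot = plot %||% paste0("p", seq_along(site_ids))
  )
}

# a table with a prescribed number of taxa at each occupancy level:
# occupancies = named-free integer vector, one entry per taxon, giving the
# number of occupied sites for that taxon
occupancy_table <- function(occupancies, n_sites) {
  m <- sapply(occupancies, function(k) c(rep(1, k), rep(0, n_sites - k)))
  colnames(m) <- paste0("t", seq_along(occupancies))
  rownames(m) <- paste0("s", seq_len(n_sites))
  as_abundance(m)
}

# scenario with one region, 8 plots (16 plot-by-stratum sites) and all
# factor effects off: the null study condition for calibration experiments
null_scenario <- function(seed, planted_pairs = NULL) {
  community_scenario(
    n_regions = 1, plots_per_region = 8,
    beetle_pool_size = 45, fungal_pool_size = 15,
    region_effect = 0, stratum_effect_beetles = 0, management_effect_fungi = 0,
    planted_pairs = planted_pairs, seed = seed
  )
}

# run the standard association screen on a generated dataset
screen_network <- function(gen, B = 999, seed = 1, min_sites = 5, threshold_q = 0.1) {
  pf <- suppressWarnings(align_tables(
    filter_occupancy(gen$pair$a, min_sites),
    filter_occupancy(gen$pair$b, min_sites)
  ))
  stats <- pairwise_spearman(pf, B = B, seed = seed)
  list(stats = stats, net = build_network(stats, threshold_q = threshold_q))
}

pair_key <- function(beetle, fungus) paste(beetle, fungus, sep = "|")
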