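#' Chi-square standardisation of a community matrix
#'
#' Converts a count table to the matrix of standardised residuals from the
#' row-by-column independence model that underlies correspondence analysis:
#' with relative frequencies \eqn{p_{ij}}, row masses \eqn{r_i} and column
#' masses \eqn{c_j},
#' \deqn{Q_{ij} = (p_{ij} - r_i c_j) / \sqrt{r_i c_j}.}
#' The squared Frobenius norm of Q is the table's total inertia, equal to
#' Pearson's chi-square statistic divided by the grand total.
#'
#' @param x An abundance table (no all-zero rows or columns).
#' @return A list with `Q` (sites x taxa matrix), `row_weights`,
#'   `col_weights`, `total_inertia`.
#' @export
chi_square_standardize <- function(x) {
  m <- abundance_matrix(as_abundance(x))
  if (sum(m) <= 0) abort("grand total must be positive")
  zr <- rownames(m)[rowSums(m) == 0]
  zc <- colnames(m)[colSums(m) == 0]
  if (length(zr)) abort(paste0("zero row marginal for site(s): ", paste(zr, collapse = ", ")))
  if (length(zc)) abort(paste0("zero column marginal for taxon(s): ", paste(zc, collapse = ", ")))
  p <- m / sum(m)
  r <- rowSums(p)
  cc <- colSums(p)
  Q <- (p - outer(r, cc)) / sqrt(outer(r, cc))
  list(Q = Q, row_weights = r, col_weights = cc, total_inertia = sum(Q^2))
}

# design matrix for site factors: dummy coding, columns weighted-centred and
# scaled by sqrt(row weights), so ordinary projections of Q on it realise
# row-weighted least squares
weighted_design <- function(meta_rows, vars, r) {
  if (!length(vars)) return(matrix(0, length(r), 0))
  mm <- do.call(cbind, lapply(vars, function(v) {
    f <- as.factor(meta_rows[[v]])
    d <- stats::model.matrix(~ f - 1)
    colnames(d) <- paste0(v, levels(f))
    d
  }))
  ctr <- sweep(mm, 2, colSums(mm * r), "-")     # weighted column means out
  sqrt(r) * ctr
}

# project the rows of Q onto the column space of the (already weighted)
# design, via pivoted QR; returns fitted matrix and the design rank
wproject <- function(design, Q) {
  if (ncol(design) == 0) return(list(fitted = Q * 0, rank = 0L))
  qrd <- qr(design)
  keep <- qrd$pivot[seq_len(qrd$rank)]
  qrd <- qr(design[, keep, drop = FALSE])
  list(fitted = qr.fitted(qrd, Q), rank = qrd$rank)
}

#' Partial canonical correspondence analysis
#'
#' Fits the constrained ordination `species ~ constraints + Condition(condition)`:
#' the chi-square standardised community matrix is first residualised on the
#' conditioning factor under row-weighted least squares, the residual is
#' projected onto the (equally residualised) constraint design, and the
#' projection is decomposed by SVD into canonical axes. Inertia decomposes
#' exactly as conditioned + constrained + residual = total.
#'
#' @param x An abundance table (all-zero rows/columns must be removed first,
#'   e.g. by [align_tables()] / dropping empty sites).
#' @param meta Site metadata covering all sites of `x`.
#' @param constraints Character vector of metadata factor names whose effect
#'   is tested, in formula order (default `c("management", "stratum")`).
#' @param condition Optional single metadata factor partialled out before the
#'   constraints (default `"region"`); use `NULL` for an unconditioned CCA.
#' @return An object of class `pcca`.
#' @export
cca_partial <- function(x, meta, constraints = c("management", "stratum"),
                        condition = "region") {
  x <- as_abundance(x)
  meta <- validate_metadata(meta)
  std <- chi_square_standardize(x)
  Q <- std$Q
  r <- std$row_weights
  rows <- meta[match(rownames(Q), meta$site_id), , drop = FALSE]
  if (anyNA(rows$site_id)) abort("metadata must cover every site in the table")
  for (v in c(constraints, condition)) {
    if (!v %in% names(rows)) abort(paste0("metadata lacks factor '", v, "'"))
    if (length(unique(rows[[v]])) < 2) {
      abort(paste0("factor '", v, "' needs at least 2 levels among these sites"))
    }
  }

  Z <- weighted_design(rows, condition, r)
  pz <- wproject(Z, Q)
  conditioned <- sum(pz$fitted^2)
  Qres <- Q - pz$fitted

  # constraint designs, residualised on the condition; columns whose
  # residual is negligible relative to their original size are aliased with
  # the condition and dropped (QR's relative tolerance would otherwise keep
  # numerically-zero directions and absorb spurious inertia)
  Xs <- lapply(constraints, function(v) {
    d <- weighted_design(rows, v, r)
    res <- d - wproject(Z, d)$fitted
    norm0 <- sqrt(colSums(d^2))
    aliased <- sqrt(colSums(res^2)) < pmax(norm0, 1) * 1e-8
    if (any(aliased)) {
      warn(paste0("aliased design column(s) dropped for term '", v, "': ",
                  paste(colnames(d)[aliased], collapse = ", ")))
    }
    res[, !aliased, drop = FALSE]
  })
  names(Xs) <- constraints

  # sequential (formula-order) decomposition
  cum_rank <- 0L
  cum_inertia <- 0
  terms <- purrr::map_dfr(seq_along(Xs), function(i) {
    Xcum <- do.call(cbind, Xs[seq_len(i)])
    pc <- wproject(Xcum, Qres)
    ti <- sum(pc$fitted^2) - cum_inertia
    df <- pc$rank - cum_rank
    cum_inertia <<- sum(pc$fitted^2)
    cum_rank <<- pc$rank
    tibble::tibble(term = constraints[i], df = df, inertia = ti)
  })

  Xall <- do.call(cbind, Xs)
  pall <- wproject(Xall, Qres)
  fitted_all <- pall$fitted
  constrained <- sum(fitted_all^2)
  residual <- std$total_inertia - conditioned - constrained
  sv <- svd(fitted_all)
  eig <- sv$d^2
  eig <- eig[eig > max(eig[1], 0) * 1e-12]
  n_eff <- nrow(Q)
  df_resid <- n_eff - 1L - pz$rank - pall$rank

  structure(list(
    terms = terms,
    total_inertia = std$total_inertia,
    conditioned_inertia = conditioned,
    constrained_inertia = constrained,
    residual_inertia = residual,
    eigenvalues = eig,
    site_scores = (sv$u %*% diag(sv$d, length(sv$d)))[, seq_along(eig), drop = FALSE] / sqrt(r),
    species_scores = sv$v[, seq_along(eig), drop = FALSE] / sqrt(std$col_weights),
    row_weights = r,
    df_residual = df_resid,
    constraints = constraints,
    condition = condition,
    Qres = Qres,
    Xs = Xs,
    meta_rows = rows
  ), class = "pcca")
}

#' @export
print.pcca <- function(x, ...) {
  cat("Partial CCA:", paste(x$constraints, collapse = " + "),
      if (!is.null(x$condition)) paste0("| Condition(", x$condition, ")") else "", "\n")
  cat(sprintf("  total inertia       %.4f\n", x$total_inertia))
  cat(sprintf("  conditioned         %.4f\n", x$conditioned_inertia))
  cat(sprintf("  constrained         %.4f\n", x$constrained_inertia))
  cat(sprintf("  residual            %.4f\n", x$residual_inertia))
  invisible(x)
}

#' ANOVA-like permutation test of partial-CCA terms
#'
#' Tests each constraint sequentially (formula order) with the pseudo-F
#' statistic \eqn{F = (I_{term}/df_{term}) / (I_{resid}/df_{resid})}. The
#' null distribution comes from permuting whole rows of the
#' condition-residualised community matrix, restricted to permutations
#' within levels of the conditioning factor (regions are held fixed under
#' the null). P-values use the add-one convention `(1 + exceedances)/(1 + B)`
#' so they can never be zero.
#'
#' @param fit A [cca_partial()] object.
#' @param B Number of permutations (>= 99; default 999).
#' @param seed Optional integer seed.
#' @return A tibble with one row per term: `term`, `df`, `inertia`,
#'   `pseudo_F`, `p_value`, plus attributes `B` and `seed`.
#' @export
anova_permutation <- function(fit, B = 999, seed = NULL) {
  stopifnot(inherits(fit, "pcca"))
  if (B < 99) abort("`B` must be at least 99")
  Qres <- fit$Qres
  Xs <- fit$Xs
  n <- nrow(Qres)
  blocks <- if (!is.null(fit$condition)) {
    split(seq_len(n), fit$meta_rows[[fit$condition]])
  } else {
    list(seq_len(n))
  }
  if (any(lengths(blocks) == 1)) {
    warn("condition block(s) of size 1 cannot be permuted; they stay fixed")
  }

  seq_stats <- function(Qr) {
    cum <- 0
    cum_rank <- 0L
    inert <- numeric(length(Xs))
    dfs <- integer(length(Xs))
    for (i in seq_along(Xs)) {
      pc <- wproject(do.call(cbind, Xs[seq_len(i)]), Qr)
      inert[i] <- sum(pc$fitted^2) - cum
      dfs[i] <- pc$rank - cum_rank
      cum <- sum(pc$fitted^2)
      cum_rank <- pc$rank
    }
    resid <- sum(Qr^2) - cum
    Fv <- (inert / dfs) / (resid / fit$df_residual)
    Fv[dfs == 0] <- NA_real_ # term fully aliased away
    list(inertia = inert, df = dfs, F = Fv)
  }

  obs <- seq_stats(Qres)
  run <- function() {
    exceed <- numeric(length(Xs))
    for (b in seq_len(B)) {
      perm <- seq_len(n)
      for (blk in blocks) if (length(blk) > 1) perm[blk] <- sample(blk)
      st <- seq_stats(Qres[perm, , drop = FALSE])
      hit <- st$F >= obs$F - 1e-12
      hit[is.na(hit)] <- FALSE
      exceed <- exceed + hit
    }
    exceed
  }
  exceed <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  out <- tibble::tibble(
    term = fit$terms$term,
    df = obs$df,
    inertia = obs$inertia,
    pseudo_F = obs$F,
    p_value = ifelse(is.na(obs$F), NA_real_, (1 + exceed) / (1 + B))
  )
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  out
}

#' @export
tidy.pcca <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$terms, component = "constrained"),
    tibble::tibble(term = "Condition", df = NA_integer_,
                   inertia = x$conditioned_inertia, component = "conditioned"),
    tibble::tibble(term = "Residual", df = x$df_residual,
                   inertia = x$residual_inertia, component = "residual")
  )
}

#' @export
glance.pcca <- function(x, ...) {
  tibble::tibble(
    total_inertia = x$total_inertia,
    conditioned_inertia = x$conditioned_inertia,
    constrained_inertia = x$constrained_inertia,
    residual_inertia = x$residual_inertia,
    n_axes = length(x$eigenvalues),
    df_residual = x$df_residual
  )
}
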