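#' Construct and validate a site-by-taxon abundance table
#'
#' An abundance table is a tibble whose first column, `site_id`, holds unique
#' site identifiers and whose remaining columns hold nonnegative counts, one
#' column per taxon. All pipeline stages (diversity, ordination, co-inertia,
#' association networks) consume this representation.
#'
#' @param x A data frame with a `site_id` column (or row names) and numeric
#'   taxon columns, or a numeric matrix with row and column names.
#' @return A validated abundance tibble (class `dwl_abund` on top of
#'   `tbl_df`).
#' @examples
#' as_abundance(matrix(c(1, 0, 0, 2), 2, 2,
#'   dimnames = list(c("s1", "s2"), c("taxA", "taxB"))))
#' @export
as_abundance <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("matrix input needs row names (sites) and column names (taxa)")
    }
    x <- tibble::as_tibble(x, rownames = "site_id")
  }
  if (!is.data.frame(x)) abort("`x` must be a data frame or named matrix")
  if (!"site_id" %in% names(x)) {
    if (tibble::has_rownames(as.data.frame(x))) {
      x <- tibble::rownames_to_column(as.data.frame(x), "site_id")
    } else {
      abort("`x` must have a `site_id` column")
    }
  }
  x <- tibble::as_tibble(x)
  x <- dplyr::relocate(x, "site_id")
  x$site_id <- as.character(x$site_id)
  validate_abundance(x)
}

validate_abundance <- function(x) {
  taxa <- setdiff(names(x), "site_id")
  if (length(taxa) < 1L) abort("abundance table needs at least one taxon column")
  if (nrow(x) < 1L) abort("abundance table needs at least one site")
  if (anyDuplicated(x$site_id)) {
    abort(paste0("duplicate site identifiers: ",
                 paste(unique(x$site_id[duplicated(x$site_id)]), collapse = ", ")))
  }
  if (anyDuplicated(taxa)) {
    abort(paste0("duplicate taxon identifiers: ",
                 paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
  }
  for (tx in taxa) {
    v <- x[[tx]]
    if (!is.numeric(v)) abort(paste0("non-numeric counts in taxon column '", tx, "'"))
    if (anyNA(v)) abort(paste0("missing counts in taxon column '", tx, "'"))
    if (any(v < 0)) {
      abort(paste0("negative count for taxon '", tx, "', site '",
                   x$site_id[which(v < 0)[1L]], "'"))
    }
  }
  class(x) <- unique(c("dwl_abund", class(x)))
  x
}

#' Extract the count matrix from an abundance table
#'
#' @param x An abundance tibble (see [as_abundance()]).
#' @return A numeric matrix, sites in rows (row names = `site_id`).
#' @export
abundance_matrix <- function(x) {
  x <- as_abundance(x)
  m <- as.matrix(x[, setdiff(names(x), "site_id"), drop = FALSE])
  rownames(m) <- x$site_id
  storage.mode(m) <- "double"
  m
}

#' Read a site-by-taxon abundance table from delimited text
#'
#' The first row must hold taxon identifiers and the first column site
#' identifiers. Counts are expected to be plain nonnegative numbers. Field
#' notebooks from the European tradition sometimes use a dot as a thousands
#' separator ("1.672" meaning 1672); such files are rejected by default
#' because silently reading them as decimals corrupts counts. Set
#' `thousands_dot = TRUE` to parse that dialect explicitly.
#'
#' @param path Path to a TSV/CSV file.
#' @param delim Field delimiter; guessed from the file extension when `NULL`
#'   (`.csv` is comma, anything else tab).
#' @param thousands_dot Parse `.` as a thousands grouping mark instead of a
#'   decimal point.
#' @param integer_counts Require integer-valued counts (the default). A cell
#'   like "1.672" then raises a parse error pointing at the thousands-dot
#'   dialect; set to `FALSE` to accept fractional abundances.
#' @return An abundance tibble.
#' @export
read_abundance <- function(path, delim = NULL, thousands_dot = FALSE,
                           integer_counts = TRUE) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(delim)) delim <- if (grepl("\\.csv$", path)) "," else "\t"
  loc <- if (thousands_dot) {
    readr::locale(decimal_mark = ",", grouping_mark = ".")
  } else {
    readr::default_locale()
  }
  raw <- readr::read_delim(path, delim = delim, locale = loc,
                           col_types = readr::cols(.default = readr::col_character()),
                           name_repair = "minimal", progress = FALSE)
  names(raw)[1L] <- "site_id"
  taxa <- names(raw)[-1L]
  if (anyDuplicated(taxa)) {
    abort(paste0("duplicate taxon identifiers in header: ",
                 paste(unique(taxa[duplicated(taxa)]), collapse = ", ")))
  }
  parsed <- raw
  for (tx in taxa) {
    v <- readr::parse_number(raw[[tx]], locale = loc)
    bad <- which(is.na(v) & !is.na(raw[[tx]]))
    if (length(bad)) {
      abort(paste0("cannot parse count at site '", raw$site_id[bad[1L]],
                   "', taxon '", tx, "': '", raw[[tx]][bad[1L]], "'"))
    }
    if (integer_counts && any(v != round(v))) {
      i <- which(v != round(v))[1L]
      abort(paste0(
        "non-integer count at site '", raw$site_id[i], "', taxon '", tx,
        "': '", raw[[tx]][i], "'. If the file uses '.' as a thousands ",
        "separator, re-read with thousands_dot = TRUE; to accept fractional ",
        "abundances set integer_counts = FALSE."))
    }
    parsed[[tx]] <- v
  }
  as_abundance(parsed)
}

#' Write an abundance table to delimited text
#'
#' @inheritParams abundance_matrix
#' @param path Output file path.
#' @param delim Field delimiter.
#' @export
write_abundance <- function(x, path, delim = "\t") {
  x <- as_abundance(x)
  readr::write_delim(x, path, delim = delim)
  invisible(path)
}

#' Read and write per-site metadata
#'
#' Metadata carries one record per site with the design factors of the
#' deadwood-enrichment layout: `region` (the geographic exploratory),
#' `management` (`unm` unmanaged, `ext` extensively managed, `acf` age-class
#' forest), `stratum` (`canopy` or `ground`) and `plot`. Sampling units are
#' plot-by-stratum combinations: one beetle trap pool and one wood drill
#' sample per unit.
#'
#' @param path Path to a TSV file with columns `site_id`, `region`,
#'   `management`, `stratum`, `plot`.
#' @return A metadata tibble.
#' @export
read_metadata <- function(path) {
  meta <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  validate_metadata(meta)
}

#' @rdname read_metadata
#' @param meta A metadata data frame.
#' @export
write_metadata <- function(meta, path) {
  meta <- validate_metadata(meta)
  readr::write_tsv(meta, path)
  invisible(path)
}

validate_metadata <- function(meta) {
  need <- c("site_id", "region", "management", "stratum", "plot")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    abort(paste0("metadata is missing columns: ", paste(missing, collapse = ", ")))
  }
  meta <- tibble::as_tibble(meta)
  if (anyDuplicated(meta$site_id)) abort("duplicate site_id in metadata")
  bad_m <- setdiff(unique(meta$management), c("unm", "ext", "acf"))
  if (length(bad_m)) abort(paste0("unknown management level(s): ", paste(bad_m, collapse = ", ")))
  bad_s <- setdiff(unique(meta$stratum), c("canopy", "ground"))
  if (length(bad_s)) abort(paste0("unknown stratum level(s): ", paste(bad_s, collapse = ", ")))
  meta
}

#' Align two abundance tables on their shared sites
#'
#' Fungal drill samples and beetle trap pools come from the same
#' plot-by-stratum sampling units but are recorded in separate tables that
#' may each contain sites the other lacks. Alignment restricts both tables to
#' the intersection of their site identifiers, in a canonical (sorted) order
#' so the result does not depend on input row order. Taxa are unchanged
#' except that columns left with no occurrences on the shared sites are
#' dropped with a warning (zero taxon marginals break the chi-square
#' standardisation downstream); all-zero site rows are retained, since a site
#' may legitimately have zero captures.
#'
#' @param a,b Abundance tables (beetles and fungi, in that order by
#'   convention).
#' @param meta Optional metadata; when supplied, every shared site must have
#'   a record.
#' @return An object of class `paired_tables`: a list with elements `a`, `b`
#'   (aligned abundance tibbles) and `shared_sites`.
#' @export
align_tables <- function(a, b, meta = NULL) {
  a <- as_abundance(a)
  b <- as_abundance(b)
  shared <- sort(intersect(a$site_id, b$site_id))
  if (length(shared) < 2L) {
    abort(paste0("tables share ", length(shared), " site(s); at least 2 required"))
  }
  if (!is.null(meta)) {
    meta <- validate_metadata(meta)
    missing <- setdiff(shared, meta$site_id)
    if (length(missing)) {
      abort(paste0("shared sites missing from metadata: ", paste(missing, collapse = ", ")))
    }
  }
  a2 <- a[match(shared, a$site_id), , drop = FALSE]
  b2 <- b[match(shared, b$site_id), , drop = FALSE]
  drop_empty <- function(t, label) {
    m <- abundance_matrix(t)
    empty <- colnames(m)[colSums(m) == 0]
    if (length(empty)) {
      warn(paste0(length(empty), " ", label, " taxa have no occurrences on the ",
                  "shared sites and were dropped: ",
                  paste(head(empty, 5L), collapse = ", "),
                  if (length(empty) > 5L) ", ..." else ""))
      t <- t[, !(names(t) %in% empty), drop = FALSE]
    }
    validate_abundance(t)
  }
  out <- list(a = drop_empty(a2, "table-a"), b = drop_empty(b2, "table-b"),
              shared_sites = shared)
  class(out) <- "paired_tables"
  out
}

#' @export
print.paired_tables <- function(x, ...) {
  cat("Paired community tables:", length(x$shared_sites), "shared sites\n")
  cat("  table a:", ncol(x$a) - 1L, "taxa\n")
  cat("  table b:", ncol(x$b) - 1L, "taxa\n")
  invisible(x)
}

#' Drop taxa observed at fewer than a minimum number of sites
#'
#' Rare taxa carry little rank information and inflate the multiple-testing
#' burden of the pairwise association screen, so taxa are screened on
#' occupancy: the number of sites with a nonzero count. The site set and the
#' order of surviving columns are unchanged. Filtering is idempotent and
#' monotone in the threshold.
#'
#' @param x An abundance table.
#' @param min_sites Minimum number of occupied sites a taxon must reach to be
#'   retained (the association screen uses 5; the ordination screen uses 3).
#' @return The filtered abundance tibble (possibly with zero taxon columns,
#'   with a warning).
#' @export
filter_occupancy <- function(x, min_sites) {
  x <- as_abundance(x)
  if (!is.numeric(min_sites) || length(min_sites) != 1L || min_sites < 1) {
    abort("`min_sites` must be a single integer >= 1")
  }
  m <- abundance_matrix(x)
  keep <- colnames(m)[colSums(m > 0) >= min_sites]
  if (length(keep) == 0L) {
    warn("no taxon reaches the occupancy threshold; returning a table with no taxon columns")
    out <- x[, "site_id", drop = FALSE]
    class(out) <- unique(c("dwl_abund", class(out)))
    return(out)
  }
  x[, c("site_id", keep), drop = FALSE]
}
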