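#' Write and read an association-network edge list
#'
#' Tab-separated with columns `fungus_id`, `beetle_id`, `rho`, `p_raw`, `q`,
#' `sign`; an empty network writes a header-only file. Reading restores a
#' network that compares equal to the written one.
#'
#' @param net An `assoc_network` (see [build_network()]).
#' @param path Output TSV path.
#' @export
write_edge_list <- function(net, path) {
  stopifnot(inherits(net, "assoc_network"))
  readr::write_tsv(tibble::as_tibble(net), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @return [read_edge_list()] returns an `assoc_network` tibble.
#' @export
read_edge_list <- function(path) {
  edges <- readr::read_tsv(path, col_types = readr::cols(
    fungus_id = readr::col_character(),
    beetle_id = readr::col_character(),
    rho = readr::col_double(),
    p_raw = readr::col_double(),
    q = readr::col_double(),
    sign = readr::col_character()
  ), progress = FALSE)
  class(edges) <- unique(c("assoc_network", class(edges)))
  edges
}

#' Convert an association network to an igraph bipartite graph
#'
#' Nodes carry `taxon_class` ("fungus" or "beetle"); edges carry `rho`,
#' `p_raw`, `q` and `sign`.
#'
#' @param net An `assoc_network`.
#' @return An `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  verts <- dplyr::bind_rows(
    tibble::tibble(name = unique(net$fungus_id), taxon_class = "fungus"),
    tibble::tibble(name = unique(net$beetle_id), taxon_class = "beetle")
  )
  igraph::graph_from_data_frame(
    d = tibble::as_tibble(net)[, c("fungus_id", "beetle_id", "rho", "p_raw", "q", "sign")],
    directed = FALSE, vertices = verts
  )
}

#' Write and read the network as GraphML
#'
#' @inheritParams write_edge_list
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname write_graphml
#' @return [read_graphml()] returns an `assoc_network` tibble rebuilt from
#'   the graph's edges.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  if (igraph::ecount(g) == 0) {
    edges <- tibble::tibble(fungus_id = character(0), beetle_id = character(0),
                            rho = numeric(0), p_raw = numeric(0), q = numeric(0),
                            sign = character(0))
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    cls <- setNames(igraph::vertex_attr(g, "taxon_class"),
                    igraph::vertex_attr(g, "name"))
    edges <- tibble::tibble(
      fungus_id = ifelse(cls[el$from] == "fungus", el$from, el$to),
      beetle_id = ifelse(cls[el$from] == "fungus", el$to, el$from),
      rho = el$rho, p_raw = el$p_raw, q = el$q, sign = el$sign
    ) |>
      dplyr::arrange(dplyr::desc(abs(.data$rho)))
  }
  class(edges) <- unique(c("assoc_network", class(edges)))
  edges
}

#' Write a JSON run report
#'
#' Records the reproducibility envelope of a network run: seed, permutation
#' count, thresholds and the package version.
#'
#' @param net An `assoc_network`.
#' @param path Output JSON path.
#' @param extra Optional named list merged into the report.
#' @export
write_run_report <- function(net, path, extra = list()) {
  rep <- c(list(
    n_edges = nrow(net),
    n_pairs_tested = attr(net, "n_pairs_tested"),
    threshold_q = attr(net, "threshold_q"),
    B = attr(net, "B"),
    seed = attr(net, "seed"),
    package_version = as.character(utils::packageVersion("deadwoodlinks"))
  ), extra)
  rep <- rep[!vapply(rep, is.null, logical(1))]
  writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}
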