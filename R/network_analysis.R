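#' Default myogenic regulatory factor set
#'
#' The MyoD- and Mef2-family transcription factors used as anchors of
#' the interaction analysis, as human symbols: MYOD1, MYOG, MYF5,
#' MYF6, MEF2A, MEF2C, MEF2D.
#'
#' @param symbols character vector of regulator symbols.
#' @return normalized, unique character vector (class `mrf_set`).
#' @export
mrf_set <- function(symbols = c("MYOD1", "MYOG", "MYF5", "MYF6",
                                "MEF2A", "MEF2C", "MEF2D")) {
  symbols <- unique(norm_symbol(symbols))
  if (length(symbols) == 0) stop_format("MRF set must be non-empty")
  structure(symbols, class = c("mrf_set", "character"))
}

#' Default mouse-to-human symbol overrides
#'
#' Uppercase transliteration covers most mouse symbols (Src -> SRC);
#' the exceptions relevant to the regulator set are listed here and can
#' be extended or replaced.
#'
#' @return named character vector, `names` = normalized source symbol,
#'   values = replacement symbol.
#' @export
default_symbol_map <- function() {
  c(MYOD = "MYOD1")
}

apply_symbol_map <- function(symbols, symbol_map) {
  if (is.null(symbol_map) || length(symbol_map) == 0) return(symbols)
  map_names <- norm_symbol(names(symbol_map))
  idx <- match(symbols, map_names)
  ifelse(is.na(idx), symbols, norm_symbol(unname(symbol_map))[idx])
}

#' Construct an undirected interaction graph
#'
#' Gene-symbol protein-interaction graph. Symbols are normalized
#' (trimmed, upper-cased), self-loops are dropped, and duplicate edges
#' — in either orientation — are collapsed; the numbers removed are
#' recorded in the object. Direction (bait/prey) is discarded:
#' interactions are treated symmetrically.
#'
#' @param edges data frame with columns `from`, `to` and optionally
#'   `source` (provenance tag per edge).
#' @return object of class `interaction_graph` with elements `edges`
#'   (tibble from/to/source, from < to), `nodes`, `n_self_loops_dropped`,
#'   `n_duplicates_dropped`.
#' @export
interaction_graph <- function(edges) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    stop_format("edges needs columns 'from' and 'to'")
  }
  if (!"source" %in% names(edges)) edges$source <- NA_character_
  edges$from <- norm_symbol(edges$from)
  edges$to <- norm_symbol(edges$to)
  keep <- !is.na(edges$from) & !is.na(edges$to) &
    edges$from != "" & edges$to != ""
  edges <- edges[keep, ]
  self <- edges$from == edges$to
  n_self <- sum(self)
  edges <- edges[!self, ]
  # canonical orientation so (a,b) and (b,a) collapse
  flip <- edges$from > edges$to
  tmp <- edges$from[flip]
  edges$from[flip] <- edges$to[flip]
  edges$to[flip] <- tmp
  key <- paste(edges$from, edges$to)
  dup <- duplicated(key)
  n_dup <- sum(dup)
  edges <- edges[!dup, c("from", "to", "source")]
  edges <- dplyr::arrange(edges, .data$from, .data$to)
  structure(list(edges = edges,
                 nodes = sort(unique(c(edges$from, edges$to))),
                 n_self_loops_dropped = n_self,
                 n_duplicates_dropped = n_dup),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph> %d nodes, %d undirected edges (%d self-loops, %d duplicates dropped)\n",
              length(x$nodes), nrow(x$edges), x$n_self_loops_dropped,
              x$n_duplicates_dropped))
  invisible(x)
}

#' Read a tab-separated interaction edge list
#'
#' Two-symbol-column TSV in the style of trimmed HPRD / BioGRID
#' exports; extra columns are ignored. A header line is auto-detected
#' (first line treated as a header when a field matches common
#' interactor/symbol column names). An optional mouse-to-human symbol
#' map is applied before insertion.
#'
#' @param path TSV path.
#' @param symbol_map optional named character vector (see
#'   [default_symbol_map()]) or a two-column data frame (from, to).
#' @param source provenance tag recorded on every edge (defaults to
#'   the file name).
#' @return an [interaction_graph()]. An empty file yields an empty
#'   graph with a warning.
#' @export
read_edge_list <- function(path, symbol_map = NULL, source = basename(path)) {
  if (!file.exists(path)) stop_format("edge list not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning(sprintf("edge list %s is empty", path))
    return(interaction_graph(tibble::tibble(from = character(),
                                            to = character(),
                                            source = character())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2)) {
    bad <- which(lengths(fields) < 2)[1]
    stop_format("edge list %s: line %d has fewer than 2 tab-separated columns",
                path, bad)
  }
  first <- norm_symbol(fields[[1]][1:2])
  header_like <- any(grepl("GENE|SYMBOL|INTERACTOR|OFFICIAL|NODE|PROTEIN",
                           first))
  if (header_like) fields <- fields[-1]
  if (length(fields) == 0) {
    warning(sprintf("edge list %s has a header but no data rows", path))
    return(interaction_graph(tibble::tibble(from = character(),
                                            to = character(),
                                            source = character())))
  }
  from <- norm_symbol(vapply(fields, `[[`, character(1), 1))
  to <- norm_symbol(vapply(fields, `[[`, character(1), 2))
  if (is.data.frame(symbol_map)) {
    symbol_map <- stats::setNames(as.character(symbol_map[[2]]),
                                  as.character(symbol_map[[1]]))
  }
  from <- apply_symbol_map(from, symbol_map)
  to <- apply_symbol_map(to, symbol_map)
  interaction_graph(tibble::tibble(from = from, to = to, source = source))
}

#' Merge interaction graphs
#'
#' Union of edge sets; per-edge provenance keeps the tag of the first
#' graph contributing the edge.
#'
#' @param ... `interaction_graph` objects.
#' @return the merged [interaction_graph()].
#' @export
merge_graphs <- function(...) {
  graphs <- list(...)
  stopifnot(length(graphs) >= 1,
            all(vapply(graphs, inherits, logical(1), "interaction_graph")))
  interaction_graph(dplyr::bind_rows(lapply(graphs, `[[`, "edges")))
}

as_igraph <- function(graph) {
  igraph::graph_from_data_frame(graph$edges[, c("from", "to")],
                                directed = FALSE,
                                vertices = graph$nodes)
}

neighbor_sets <- function(graph, nodes) {
  ig <- as_igraph(graph)
  present <- nodes %in% graph$nodes
  out <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_along(nodes)) {
    out[[i]] <- if (present[i]) {
      igraph::neighbors(ig, nodes[i]) |> names()
    } else character()
  }
  out
}

#' Classify hit kinases relative to the MRF set
#'
#' Each (kinase, MRF) pair is labelled `direct` when the graph holds an
#' edge between them, `semi_direct` when — lacking a direct edge — some
#' intermediary node is adjacent to both, and `none` otherwise.
#' Intermediaries may not themselves be query kinases or MRFs unless
#' `allow_query_intermediaries = TRUE`; all qualifying intermediaries
#' are recorded per pair, though a pair counts once regardless of
#' their number. A kinase's summary label is its strongest connection
#' over all MRFs (direct > semi_direct > unconnected); kinases without
#' any edge in the graph are flagged, mirroring the exclusion of
#' unconnected nodes from interaction maps.
#'
#' @param graph an [interaction_graph()].
#' @param kinases character vector of hit kinase symbols.
#' @param mrfs an [mrf_set()] (or character vector).
#' @param allow_query_intermediaries permit kinases/MRFs as
#'   intermediary nodes (default `FALSE`).
#' @return object of class `regulator_classification`: `pairs` (tibble
#'   kinase/mrf/connection/intermediaries list-column), `kinases`
#'   (tibble kinase/label/in_graph), `mrfs`.
#' @export
classify_regulators <- function(graph, kinases, mrfs = mrf_set(),
                                allow_query_intermediaries = FALSE) {
  stopifnot(inherits(graph, "interaction_graph"))
  kinases <- unique(norm_symbol(kinases))
  mrfs <- unique(norm_symbol(mrfs))
  overlap <- intersect(kinases, mrfs)
  if (length(overlap) > 0) {
    stop_format("kinase and MRF sets overlap: %s",
                paste(overlap, collapse = ", "))
  }
  if (length(kinases) == 0) {
    empty <- tibble::tibble(kinase = character(), mrf = character(),
                            connection = character(),
                            intermediaries = list())
    return(structure(list(pairs = empty,
                          kinases = tibble::tibble(kinase = character(),
                                                   label = character(),
                                                   in_graph = logical()),
                          mrfs = mrfs),
                     class = "regulator_classification"))
  }
  nbrs <- neighbor_sets(graph, unique(c(kinases, mrfs)))
  excluded <- if (allow_query_intermediaries) character() else c(kinases, mrfs)
  pairs <- tidyr::expand_grid(kinase = kinases, mrf = mrfs)
  conn <- character(nrow(pairs))
  inter <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    k <- pairs$kinase[i]; m <- pairs$mrf[i]
    nk <- nbrs[[k]]
    if (m %in% nk) {
      conn[i] <- "direct"
      inter[[i]] <- character()
    } else {
      via <- setdiff(intersect(nk, nbrs[[m]]), excluded)
      if (length(via) > 0) {
        conn[i] <- "semi_direct"
        inter[[i]] <- sort(via)
      } else {
        conn[i] <- "none"
        inter[[i]] <- character()
      }
    }
  }
  pairs$connection <- conn
  pairs$intermediaries <- inter
  label_of <- function(k) {
    ck <- conn[pairs$kinase == k]
    if (any(ck == "direct")) "direct"
    else if (any(ck == "semi_direct")) "semi_direct"
    else "unconnected"
  }
  kin_tbl <- tibble::tibble(
    kinase = kinases,
    label = vapply(kinases, label_of, character(1), USE.NAMES = FALSE),
    in_graph = kinases %in% graph$nodes
  )
  structure(list(pairs = pairs, kinases = kin_tbl, mrfs = mrfs),
            class = "regulator_classification")
}

#' @export
print.regulator_classification <- function(x, ...) {
  tab <- table(factor(x$kinases$label,
                      levels = c("direct", "semi_direct", "unconnected")))
  cat(sprintf("<regulator_classification> %d kinases vs %d MRFs: %d direct, %d semi-direct, %d unconnected\n",
              nrow(x$kinases), length(x$mrfs),
              tab[["direct"]], tab[["semi_direct"]], tab[["unconnected"]]))
  invisible(x)
}

#' Rank kinases, MRFs and intermediary nodes by connectivity
#'
#' Three deterministic rankings (count descending, then symbol
#' ascending): kinases by the number of MRFs they reach directly or
#' semi-directly, MRFs by the number of kinases connected to them, and
#' intermediary nodes by the number of distinct MRFs they link to hit
#' kinases. Only nonzero counts appear.
#'
#' @param classification a [classify_regulators()] result.
#' @return list of tibbles `kinase_ranking` (kinase, n_mrfs),
#'   `mrf_ranking` (mrf, n_kinases), `intermediary_ranking`
#'   (intermediary, n_mrfs, n_kinases).
#' @export
summarize_network <- function(classification) {
  stopifnot(inherits(classification, "regulator_classification"))
  pairs <- classification$pairs
  connected <- pairs[pairs$connection != "none", ]
  kin <- dplyr::count(connected, .data$kinase, name = "n_mrfs")
  kin <- dplyr::arrange(kin, dplyr::desc(.data$n_mrfs), .data$kinase)
  mrf <- dplyr::count(connected, .data$mrf, name = "n_kinases")
  mrf <- dplyr::arrange(mrf, dplyr::desc(.data$n_kinases), .data$mrf)
  semi <- pairs[pairs$connection == "semi_direct", ]
  if (nrow(semi) > 0) {
    long <- tidyr::unnest(semi[, c("kinase", "mrf", "intermediaries")],
                          "intermediaries")
    names(long)[names(long) == "intermediaries"] <- "intermediary"
    inter <- dplyr::summarise(dplyr::group_by(long, .data$intermediary),
                              n_mrfs = dplyr::n_distinct(.data$mrf),
                              n_kinases = dplyr::n_distinct(.data$kinase),
                              .groups = "drop")
    inter <- dplyr::arrange(inter, dplyr::desc(.data$n_mrfs),
                            dplyr::desc(.data$n_kinases), .data$intermediary)
  } else {
    inter <- tibble::tibble(intermediary = character(), n_mrfs = integer(),
                            n_kinases = integer())
  }
  list(kinase_ranking = kin, mrf_ranking = mrf, intermediary_ranking = inter)
}

#' Export the classified subnetwork in SIF format
#'
#' Writes the viewer-ready subnetwork: `kinase<TAB>direct<TAB>mrf`
#' lines for direct pairs and `kinase<TAB>via<TAB>intermediary` plus
#' `intermediary<TAB>via<TAB>mrf` lines for each recorded two-hop
#' path. Lines are deduplicated and sorted, so repeated exports are
#' byte-identical. A companion node-attribute TSV (`node`, `role` in
#' kinase/mrf/intermediary) is written alongside.
#'
#' @param classification a [classify_regulators()] result.
#' @param sif_path output SIF path.
#' @param node_attr_path output TSV path; default replaces the SIF
#'   extension with `_nodes.tsv`.
#' @return invisibly, the character vector of SIF lines.
#' @export
export_subnetwork <- function(classification, sif_path,
                              node_attr_path = NULL) {
  stopifnot(inherits(classification, "regulator_classification"))
  if (is.null(node_attr_path)) {
    node_attr_path <- paste0(tools::file_path_sans_ext(sif_path), "_nodes.tsv")
  }
  pairs <- classification$pairs
  lines <- character()
  nodes <- tibble::tibble(node = character(), role = character())
  for (i in seq_len(nrow(pairs))) {
    k <- pairs$kinase[i]; m <- pairs$mrf[i]
    if (pairs$connection[i] == "direct") {
      lines <- c(lines, paste(k, "direct", m, sep = "\t"))
      nodes <- dplyr::bind_rows(nodes,
                                tibble::tibble(node = c(k, m),
                                               role = c("kinase", "mrf")))
    } else if (pairs$connection[i] == "semi_direct") {
      for (v in pairs$intermediaries[[i]]) {
        lines <- c(lines, paste(k, "via", v, sep = "\t"),
                   paste(v, "via", m, sep = "\t"))
        nodes <- dplyr::bind_rows(nodes, tibble::tibble(
          node = c(k, v, m), role = c("kinase", "intermediary", "mrf")))
      }
    }
  }
  lines <- sort(unique(lines))
  writeLines(lines, sif_path)
  nodes <- dplyr::distinct(nodes)
  nodes <- dplyr::arrange(nodes, .data$role, .data$node)
  readr::write_tsv(nodes, node_attr_path, progress = FALSE)
  invisible(lines)
}

#' Read a SIF file
#'
#' @param path SIF path (`node<TAB>relation<TAB>node` lines).
#' @return tibble with columns `from`, `relation`, `to`; zero rows for
#'   an empty file.
#' @export
read_sif <- function(path) {
  if (!file.exists(path)) stop_format("SIF file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(from = character(), relation = character(),
                          to = character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 3)) {
    bad <- which(lengths(fields) != 3)[1]
    stop_format("SIF %s: line %d does not have 3 tab-separated fields",
                path, bad)
  }
  tibble::tibble(from = vapply(fields, `[[`, character(1), 1),
                 relation = vapply(fields, `[[`, character(1), 2),
                 to = vapply(fields, `[[`, character(1), 3))
}
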