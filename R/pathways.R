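# Pathway database handling, KEGG-ID matching, hypergeometric
# over-representation, and relative-betweenness impact scoring.

#' Construct a pathway database object
#'
#' @param sets named list: pathway ID -> character vector of member compound
#'   IDs.
#' @param graphs named list: pathway ID -> two-column edge data.frame
#'   (`node1`, `node2`); every set member must appear as a node.
#' @param mapping optional data.frame `name`, `kegg_id` for name matching.
#' @return Object of class `pathway_db` with a `universe` of all member IDs.
#' @export
pathway_db <- function(sets, graphs, mapping = NULL) {
  stopifnot(is.list(sets), is.list(graphs))
  if (!all(names(sets) %in% names(graphs)))
    stop("every pathway set needs a graph")
  for (p in names(sets)) {
    nodes <- unique(c(graphs[[p]]$node1, graphs[[p]]$node2))
    if (length(sets[[p]]) > 1 && !all(sets[[p]] %in% nodes))
      stop("pathway ", p, ": set members missing from graph nodes")
  }
  structure(list(sets = sets, graphs = graphs, mapping = mapping,
                 universe = unique(unlist(sets, use.names = FALSE))),
            class = "pathway_db")
}

#' @export
print.pathway_db <- function(x, ...) {
  cat(sprintf("pathway_db: %d pathways, %d compounds in universe\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a GMT file of pathway sets
#'
#' Standard GMT layout: pathway ID, description, then members, tab-separated.
#'
#' @param path file path.
#' @return Named list of member-ID character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[[`, character(1), 1))
}

#' Read per-pathway edge-list graphs from a directory
#'
#' @param dir directory of `<pathway>.tsv` files with columns node1, node2.
#' @return Named list of edge data.frames.
#' @export
read_pathway_graphs <- function(dir) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  stats::setNames(lapply(files, utils::read.delim,
                         colClasses = "character"),
                  sub("\\.tsv$", "", basename(files)))
}

#' Map metabolite names or IDs to KEGG compound IDs
#'
#' Tokens already shaped like a KEGG compound ID (`C` followed by 5 digits)
#' pass through; other tokens are matched case-insensitively against the
#' mapping table's `name` column. Unmatched items are reported, never
#' silently dropped.
#'
#' @param x character vector of names and/or IDs.
#' @param mapping data.frame with columns `name` and `kegg_id`.
#' @return List: `matched` (data.frame query, kegg_id), `unmatched`
#'   (character vector).
#' @export
match_kegg <- function(x, mapping) {
  if (is.null(mapping) || !nrow(mapping)) stop("empty mapping table")
  need_cols(mapping, c("name", "kegg_id"))
  is_id <- grepl("^C\\d{5}$", x)
  idx <- match(tolower(x), tolower(mapping$name))
  kegg <- ifelse(is_id, x, mapping$kegg_id[idx])
  ok <- !is.na(kegg)
  list(matched = data.frame(query = x[ok], kegg_id = kegg[ok],
                            stringsAsFactors = FALSE),
       unmatched = x[!ok])
}

#' Hypergeometric pathway over-representation
#'
#' One-sided upper-tail hypergeometric test per pathway -- the probability
#' of at least the observed number of hits when drawing the query from the
#' universe -- with Benjamini-Hochberg correction across pathways.
#'
#' @param query character vector of compound IDs; members outside the
#'   universe are dropped with a warning.
#' @param db a `pathway_db`.
#' @param universe_override optional character vector replacing the database
#'   universe (e.g. the measured compounds).
#' @return data.frame: pathway, size, hits, p, fdr, hit_ids (comma-joined).
#' @export
enrich <- function(query, db, universe_override = NULL) {
  if (!length(query)) stop("empty query")
  universe <- if (is.null(universe_override)) db$universe
              else unique(universe_override)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query compound(s) outside the universe dropped")
    query <- setdiff(query, outside)
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(db$sets), function(p) {
    members <- intersect(db$sets[[p]], universe)
    hit <- intersect(query, members)
    k <- length(hit); m <- length(members)
    pval <- stats::phyper(k - 1, m, N - m, n, lower.tail = FALSE)
    data.frame(pathway = p, size = m, hits = k, p = pval,
               hit_ids = paste(hit, collapse = ","), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), c("pathway", "size", "hits", "p", "fdr", "hit_ids")]
}

#' Topology-based pathway impact of a hit set
#'
#' Node importance is relative betweenness centrality of the undirected,
#' unweighted pathway graph; impact is the summed importance of the hit
#' nodes divided by the summed importance of all nodes. A graph whose total
#' centrality is zero (e.g. a complete graph or a single edge) has impact 0.
#'
#' @param hits character vector of compound IDs; hits absent from the graph
#'   are ignored with a warning.
#' @param graph two-column edge data.frame (`node1`, `node2`) or an igraph
#'   object.
#' @return Impact in [0, 1].
#' @export
impact <- function(hits, graph) {
  g <- if (inherits(graph, "igraph")) graph else
    igraph::graph_from_data_frame(graph[, 1:2], directed = FALSE)
  nodes <- igraph::V(g)$name
  missing <- setdiff(hits, nodes)
  if (length(missing)) {
    warning("hit(s) not in graph ignored: ", paste(missing, collapse = ", "))
    hits <- intersect(hits, nodes)
  }
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  total <- sum(btw)
  if (total == 0) return(0)
  sum(btw[hits]) / total
}

#' Per-pathway enrichment and impact report
#'
#' One record per pathway with at least one hit: hit compounds and count,
#' hypergeometric p, BH FDR (computed across all pathways before
#' filtering), and topology impact; sorted by p.
#'
#' @param query character vector of compound IDs.
#' @param db a `pathway_db`.
#' @param universe_override optional universe replacement.
#' @return data.frame: pathway, size, hits, p, fdr, impact, hit_ids.
#' @export
pathway_report <- function(query, db, universe_override = NULL) {
  if (!length(query))
    return(data.frame(pathway = character(), size = integer(),
                      hits = integer(), p = numeric(), fdr = numeric(),
                      impact = numeric(), hit_ids = character(),
                      stringsAsFactors = FALSE))
  e <- enrich(query, db, universe_override)
  e <- e[e$hits > 0, , drop = FALSE]
  e$impact <- vapply(e$pathway, function(p) {
    hit <- intersect(unique(query), db$sets[[p]])
    impact(hit, db$graphs[[p]])
  }, numeric(1))
  e[order(e$p), c("pathway", "size", "hits", "p", "fdr", "impact", "hit_ids")]
}
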