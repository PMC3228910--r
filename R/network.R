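#' Network display/filter options
#'
#' @param max_type Keep edges with best type at most this value (1-4;
#'   default 4 keeps everything).
#' @param concepts Optional character vector: keep only edges annotated with
#'   at least one of these concept phrases.
#' @param terms Optional character vector of entity keys: keep only edges
#'   touching at least one of them.
#' @param use_official_symbols If `TRUE` (default), node labels are official
#'   gene symbols where the term maps unambiguously to one gene; ambiguous
#'   or unmapped terms keep their raw term as label, with ambiguity flagged.
#' @return Object of class `network_filter`.
#' @export
network_filter <- function(max_type = 4, concepts = NULL, terms = NULL,
                           use_official_symbols = TRUE) {
  max_type <- as.integer(max_type)
  stopifnot(length(max_type) == 1, max_type >= 1, max_type <= 4)
  structure(
    list(max_type = max_type,
         concepts = if (is.null(concepts)) NULL else normalize_key(concepts),
         terms = if (is.null(terms)) NULL else normalize_key(terms),
         use_official_symbols = isTRUE(use_official_symbols)),
    class = "network_filter"
  )
}

new_network <- function(nodes, edges) {
  structure(list(nodes = nodes, edges = edges), class = "interaction_network")
}

empty_nodes <- function() {
  tibble::tibble(key = character(), label = character(), kind = character(),
                 raw_terms = character(), gene_ids = list(),
                 ambiguous = logical())
}

empty_edges <- function() {
  tibble::tibble(from = character(), to = character(), best_type = integer(),
                 support = integer(), pmids = list(), concepts = list(),
                 interaction_terms = list())
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Build an interaction network from pair summaries
#'
#' Nodes are entity terms, edges are summarized co-occurrences filtered by
#' confidence type (an edge is kept when its best type is at most
#' `filter$max_type`, so lowering the threshold restricts the view to
#' higher-confidence interactions) and optionally by concept or term.
#' Labels are mapped to official gene symbols when the gene lexicon maps
#' the term to exactly one gene; ambiguous terms keep their raw form and
#' are flagged rather than resolved.
#'
#' @param summaries Pair-summary tibble from [summarize_pairs()].
#' @param filter A [network_filter()].
#' @param gene_lexicon Optional [gene_lexicon()] used for symbol mapping;
#'   without it all labels are raw terms.
#' @return An `interaction_network`: list with `nodes` and `edges` tibbles.
#' @export
build_network <- function(summaries, filter = network_filter(),
                          gene_lexicon = NULL) {
  stopifnot(inherits(filter, "network_filter"))
  e <- summaries[summaries$best_type <= filter$max_type, , drop = FALSE]
  if (!is.null(filter$concepts) && nrow(e) > 0) {
    keep <- vapply(e$concepts, function(cc) any(filter$concepts %in% cc),
                   logical(1))
    e <- e[keep, , drop = FALSE]
  }
  if (!is.null(filter$terms) && nrow(e) > 0) {
    e <- e[e$term1 %in% filter$terms | e$term2 %in% filter$terms, ,
           drop = FALSE]
  }
  if (nrow(e) == 0) return(new_network(empty_nodes(), empty_edges()))
  keys <- sort(unique(c(e$term1, e$term2)))
  ids <- lapply(keys, function(k) {
    if (is.null(gene_lexicon)) character(0) else lexicon_lookup(gene_lexicon, k)
  })
  ambiguous <- lengths(ids) > 1
  label <- vapply(seq_along(keys), function(i) {
    if (filter$use_official_symbols && length(ids[[i]]) == 1) {
      unname(gene_lexicon$symbols[ids[[i]]])
    } else {
      keys[i]
    }
  }, character(1))
  nodes <- tibble::tibble(
    key = keys, label = label, kind = "entity", raw_terms = keys,
    gene_ids = ids, ambiguous = ambiguous
  )
  edges <- tibble::tibble(
    from = e$term1, to = e$term2, best_type = e$best_type,
    support = e$support, pmids = e$pmids, concepts = e$concepts,
    interaction_terms = e$interaction_terms
  )
  new_network(nodes, edges)
}

#' Add concept nodes to a network
#'
#' Adds one node per concept phrase annotated on any edge, connected to
#' every entity node that shares at least one co-occurrence carrying that
#' concept. Concept-to-entity edges have no confidence type of their own;
#' they are marked `kind = "concept"` on the node and carry the phrase in
#' their `concepts` field.
#'
#' @param network An `interaction_network`.
#' @return The network with concept nodes and their edges appended; a
#'   network without concept annotations is returned unchanged.
#' @export
add_concept_nodes <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  e <- network$edges
  pairs <- list()
  for (i in seq_len(nrow(e))) {
    for (ph in e$concepts[[i]]) {
      pairs[[length(pairs) + 1L]] <-
        tibble::tibble(phrase = ph, key = c(e$from[i], e$to[i]))
    }
  }
  if (length(pairs) == 0) return(network)
  links <- unique(dplyr::bind_rows(pairs))
  concept_keys <- sort(unique(links$phrase))
  cnodes <- tibble::tibble(
    key = paste0("concept:", concept_keys), label = concept_keys,
    kind = "concept", raw_terms = concept_keys,
    gene_ids = rep(list(character(0)), length(concept_keys)),
    ambiguous = FALSE
  )
  cedges <- tibble::tibble(
    from = paste0("concept:", links$phrase), to = links$key,
    best_type = NA_integer_, support = NA_integer_,
    pmids = rep(list(character(0)), nrow(links)),
    concepts = as.list(links$phrase),
    interaction_terms = rep(list(character(0)), nrow(links))
  )
  new_network(dplyr::bind_rows(network$nodes, cnodes),
              dplyr::bind_rows(network$edges, cedges))
}

#' Concept sub-network
#'
#' Restricts a network to the edges annotated with one concept phrase, plus
#' their endpoint nodes.
#'
#' @param network An `interaction_network` (entity edges; concept nodes, if
#'   present, are dropped).
#' @param phrase Concept phrase (normalized internally).
#' @return An `interaction_network`; empty (with a warning) when the phrase
#'   annotates no edge.
#' @export
concept_subnetwork <- function(network, phrase) {
  stopifnot(inherits(network, "interaction_network"))
  phrase <- normalize_key(phrase)
  e <- network$edges[network$edges$from %in%
                       network$nodes$key[network$nodes$kind == "entity"] &
                     !is.na(network$edges$best_type), , drop = FALSE]
  keep <- vapply(e$concepts, function(cc) phrase %in% cc, logical(1))
  e <- e[keep, , drop = FALSE]
  if (nrow(e) == 0) {
    warning("concept phrase not found on any edge: ", phrase, call. = FALSE)
    return(new_network(empty_nodes(), empty_edges()))
  }
  keys <- sort(unique(c(e$from, e$to)))
  new_network(network$nodes[network$nodes$key %in% keys, , drop = FALSE], e)
}

#' Export a network to GraphML, SIF or TSV
#'
#' GraphML (via igraph) carries all node and edge attributes (list-valued
#' attributes pipe-collapsed) and round-trips exactly through
#' [import_graphml()]. SIF writes `from <type> to` triples using the best
#' type as relation label. TSV writes a flat edge list.
#'
#' @param network An `interaction_network`.
#' @param path Output path.
#' @param format `"graphml"`, `"sif"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path, format = c("graphml", "sif", "tsv")) {
  stopifnot(inherits(network, "interaction_network"))
  format <- match.arg(format)
  n <- network$nodes
  e <- network$edges
  if (format == "graphml") {
    g <- igraph::make_empty_graph(n = nrow(n), directed = FALSE)
    if (nrow(n) > 0) {
      g <- igraph::set_vertex_attr(g, "name", value = n$key)
      g <- igraph::set_vertex_attr(g, "label", value = n$label)
      g <- igraph::set_vertex_attr(g, "kind", value = n$kind)
      g <- igraph::set_vertex_attr(g, "raw_terms", value = n$raw_terms)
      g <- igraph::set_vertex_attr(g, "gene_ids",
                                   value = collapse_field(n$gene_ids))
      g <- igraph::set_vertex_attr(g, "ambiguous",
                                   value = as.character(n$ambiguous))
    }
    if (nrow(e) > 0) {
      g <- igraph::add_edges(g, rbind(match(e$from, n$key),
                                      match(e$to, n$key)))
      g <- igraph::set_edge_attr(g, "best_type",
                                 value = ifelse(is.na(e$best_type), "",
                                                as.character(e$best_type)))
      g <- igraph::set_edge_attr(g, "support",
                                 value = ifelse(is.na(e$support), "",
                                                as.character(e$support)))
      g <- igraph::set_edge_attr(g, "pmids", value = collapse_field(e$pmids))
      g <- igraph::set_edge_attr(g, "concepts",
                                 value = collapse_field(e$concepts))
      g <- igraph::set_edge_attr(g, "interaction_terms",
                                 value = collapse_field(e$interaction_terms))
    }
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "sif") {
    lines <- sprintf("%s\ttype%s\t%s", e$from,
                     ifelse(is.na(e$best_type), "NA", e$best_type), e$to)
    writeLines(lines, path)
  } else {
    flat <- tibble::tibble(
      term1 = e$from, term2 = e$to, best_type = e$best_type,
      support = e$support, pmids = collapse_field(e$pmids),
      concepts = collapse_field(e$concepts),
      interaction_terms = collapse_field(e$interaction_terms)
    )
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nv <- igraph::vcount(g)
  if (nv == 0) return(new_network(empty_nodes(), empty_edges()))
  va <- function(at) igraph::vertex_attr(g, at)
  nodes <- tibble::tibble(
    key = va("name"), label = va("label"), kind = va("kind"),
    raw_terms = va("raw_terms"), gene_ids = split_field(va("gene_ids")),
    ambiguous = as.logical(va("ambiguous"))
  )
  ne <- igraph::ecount(g)
  if (ne == 0) return(new_network(nodes, empty_edges()))
  el <- igraph::as_edgelist(g, names = TRUE)
  ea <- function(at) igraph::edge_attr(g, at)
  to_int <- function(x) suppressWarnings(as.integer(x))
  edges <- tibble::tibble(
    from = el[, 1], to = el[, 2],
    best_type = to_int(ea("best_type")), support = to_int(ea("support")),
    pmids = split_field(ea("pmids")), concepts = split_field(ea("concepts")),
    interaction_terms = split_field(ea("interaction_terms"))
  )
  new_network(nodes, edges)
}
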