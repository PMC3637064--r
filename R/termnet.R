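# Sparse nearest-neighbour network of the top enriched terms: each top
# term is linked to the single other enriched term with the highest
# gene-content similarity, keeping the network readable.

#' Build the term network of the top enriched terms
#'
#' Nodes are the `top_n` terms of the table's current sort order; every
#' node contributes one undirected edge to its most similar other node
#' (gene-content similarity), duplicate pairs are merged, and ties are
#' broken by the candidate's table rank then lexicographically.
#'
#' @param table an `enrichment_table`.
#' @param similarity matrix from [term_similarity()] covering the table's
#'   terms.
#' @param top_n number of top terms to keep (default 10).
#' @return object of class `term_network` with `nodes` (term, p_value,
#'   z_score, combined_score) and `edges` (term_a, term_b, weight).
#' @export
build_term_network <- function(table, similarity, top_n = 10L) {
  stopifnot(inherits(table, "enrichment_table"))
  if (top_n < 1L) stop("top_n must be >= 1")
  if (!nrow(table)) stop("enrichment table is empty")
  missing <- setdiff(table$term, rownames(similarity))
  if (length(missing))
    stop("similarity matrix does not cover term(s): ",
         paste(utils::head(missing, 5), collapse = ", "))

  keep <- utils::head(seq_len(nrow(table)), top_n)
  nodes <- data.frame(term = table$term[keep],
                      p_value = table$p_value[keep],
                      z_score = table$z_score[keep],
                      combined_score = table$combined_score[keep],
                      stringsAsFactors = FALSE)
  terms <- nodes$term

  edges <- data.frame(term_a = character(), term_b = character(),
                      weight = numeric(), stringsAsFactors = FALSE)
  if (length(terms) >= 2L) {
    for (i in seq_along(terms)) {
      others <- terms[-i]
      sims <- similarity[terms[i], others]
      # best similarity; ties -> better table rank, then lexicographic
      best <- max(sims)
      cand <- others[sims >= best - 0]
      cand <- cand[order(match(cand, terms), cand)][1]
      pair <- sort(c(terms[i], cand))
      edges <- rbind(edges, data.frame(term_a = pair[1], term_b = pair[2],
                                       weight = similarity[terms[i], cand],
                                       stringsAsFactors = FALSE))
    }
    edges <- unique(edges)
    edges <- edges[order(edges$term_a, edges$term_b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges),
            class = "term_network")
}

#' @export
print.term_network <- function(x, ...) {
  cat(sprintf("term_network: %d nodes, %d edges\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export a term network
#'
#' Serializes a [build_term_network()] result as JSON (lossless round
#' trip via [read_network_json()]), GraphML (readable by standard graph
#' tools), or a 3-column TSV edge list.  Force-directed layout is left
#' to the consumer; edges carry the similarity weights a renderer needs.
#'
#' @param network a `term_network`.
#' @param format `"json"`, `"graphml"` or `"edge_tsv"`.
#' @param path output path, or `NULL` to return the serialized text.
#' @param seed seed stamped into the JSON metadata.
#' @return invisibly, the serialized text (character scalar).
#' @export
export_network <- function(network, format = c("json", "graphml", "edge_tsv"),
                           path = NULL, seed = 0L) {
  format <- match.arg(format)
  stopifnot(inherits(network, "term_network"))
  text <- switch(format,
    json = {
      payload <- list(meta = artifact_meta(seed, list(format = "json")),
                      nodes = network$nodes, edges = network$edges)
      as.character(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                    na = "null", pretty = TRUE))
    },
    graphml = network_graphml(network),
    edge_tsv = paste(
      c("term_a\tterm_b\tweight",
        if (nrow(network$edges))
          paste(network$edges$term_a, network$edges$term_b,
                format(network$edges$weight, digits = 15, trim = TRUE),
                sep = "\t")),
      collapse = "\n")
  )
  if (!is.null(path)) writeLines(text, path, useBytes = TRUE)
  invisible(text)
}

network_graphml <- function(network) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  for (spec in list(c("d_p", "node", "p_value", "double"),
                    c("d_w", "edge", "weight", "double"))) {
    xml2::xml_add_child(doc, "key", id = spec[1], `for` = spec[2],
                        attr.name = spec[3], attr.type = spec[4])
  }
  g <- xml2::xml_add_child(doc, "graph", id = "terms",
                           edgedefault = "undirected")
  for (i in seq_len(nrow(network$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = network$nodes$term[i])
    d <- xml2::xml_add_child(nd, "data", key = "d_p")
    xml2::xml_text(d) <- format(network$nodes$p_value[i], digits = 15)
  }
  for (i in seq_len(nrow(network$edges))) {
    ed <- xml2::xml_add_child(g, "edge",
                              source = network$edges$term_a[i],
                              target = network$edges$term_b[i])
    d <- xml2::xml_add_child(ed, "data", key = "d_w")
    xml2::xml_text(d) <- format(network$edges$weight[i], digits = 15)
  }
  as.character(doc)
}

#' Read a term network from its JSON export
#' @param source path or JSON string from `export_network(..., "json")`.
#' @return the `term_network`.
#' @export
read_network_json <- function(source) {
  payload <- jsonlite::fromJSON(source, simplifyVector = TRUE)
  nodes <- as.data.frame(payload$nodes, stringsAsFactors = FALSE)
  edges <- if (length(payload$edges))
    as.data.frame(payload$edges, stringsAsFactors = FALSE)
  else
    data.frame(term_a = character(), term_b = character(),
               weight = numeric(), stringsAsFactors = FALSE)
  for (col in c("p_value", "z_score", "combined_score"))
    if (col %in% names(nodes)) nodes[[col]] <- as.numeric(nodes[[col]])
  structure(list(nodes = nodes, edges = edges), class = "term_network")
}
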