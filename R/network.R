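# Regulatory-network assembly and Cytoscape-readable exports. The network
# is bipartite: lncRNA nodes connect only to gene nodes, edges carry the
# prediction mode (cis/trans), the supporting distance or correlation and
# the sign of the association. Sign concordance is recorded but never used
# as a filter: discordant lncRNA-target pairs (an up-regulated lncRNA with
# a decreased cis target) are biologically real.

#' Build the DE-lncRNA / DE-target regulatory network
#'
#' Keeps the edges whose two endpoints are both differentially expressed
#' (adjusted p below `padj_threshold` and call not `ns`); nodes are exactly
#' the endpoints of kept edges, so no isolated features appear. The edge
#' sign is the sign of the correlation for trans edges and the sign of the
#' fold-change concordance (`log2fc_lnc * log2fc_gene`) for cis edges.
#'
#' @param de_lnc,de_genes DE tables from [run_de()] (or any data frame with
#'   `feature_id`, `log2fc`, `padj`, `call`).
#' @param edges Edge table from [cis_targets()] / [trans_targets()] (rows
#'   may be concatenated).
#' @param padj_threshold Adjusted-p cut applied to both endpoints.
#' @return A `regulatory_network` list with `nodes` (id, kind, log2fc,
#'   call) and `edges` (lncrna_id, gene_id, mode, window, distance_bp, cor,
#'   sign).
#' @export
build_network <- function(de_lnc, de_genes, edges, padj_threshold = 0.05) {
  dangling <- c(setdiff(edges$lncrna_id, de_lnc$feature_id),
                setdiff(edges$gene_id, de_genes$feature_id))
  if (length(dangling))
    stop("edge endpoint(s) missing from the DE tables: ",
         paste(unique(dangling), collapse = ", "))
  sig <- function(de) de$feature_id[de$padj < padj_threshold & de$call != "ns"]
  keep <- edges$lncrna_id %in% sig(de_lnc) & edges$gene_id %in% sig(de_genes)
  edges <- edges[keep, , drop = FALSE]
  lfc_l <- stats::setNames(de_lnc$log2fc, de_lnc$feature_id)
  lfc_g <- stats::setNames(de_genes$log2fc, de_genes$feature_id)
  edges$sign <- if (nrow(edges)) {
    ifelse(edges$mode == "trans",
           sign(edges$cor),
           unname(sign(lfc_l[edges$lncrna_id] * lfc_g[edges$gene_id])))
  } else numeric(0)
  edges <- edges[order(edges$lncrna_id, edges$gene_id, edges$mode), , drop = FALSE]
  rownames(edges) <- NULL
  node_row <- function(ids, kind, de) {
    d <- de[match(ids, de$feature_id), ]
    data.frame(id = ids, kind = rep(kind, length(ids)), log2fc = d$log2fc,
               call = d$call, stringsAsFactors = FALSE)
  }
  nodes <- rbind(
    node_row(sort(unique(edges$lncrna_id)), "lncRNA", de_lnc),
    node_row(sort(unique(edges$gene_id)), "gene", de_genes)
  )
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}

#' Summarize a regulatory network
#'
#' @param net A `regulatory_network`.
#' @return List with `n_lnc_nodes`, `n_gene_nodes`, `n_edges`, `n_cis`,
#'   `n_trans`.
#' @export
network_summary <- function(net) {
  list(
    n_lnc_nodes = sum(net$nodes$kind == "lncRNA"),
    n_gene_nodes = sum(net$nodes$kind == "gene"),
    n_edges = nrow(net$edges),
    n_cis = sum(net$edges$mode == "cis"),
    n_trans = sum(net$edges$mode == "trans")
  )
}

#' @export
print.regulatory_network <- function(x, ...) {
  s <- network_summary(x)
  cat("regulatory_network:", s$n_lnc_nodes, "lncRNA +", s$n_gene_nodes,
      "gene nodes,", s$n_edges, "edges (", s$n_cis, "cis,", s$n_trans,
      "trans )\n")
  invisible(x)
}

#' Export a network in SIF format
#'
#' One line per edge: `lncrna_id <TAB> cis|trans <TAB> gene_id`, in stable
#' sorted order. An empty network yields an empty file.
#'
#' @param net A `regulatory_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_sif <- function(net, path) {
  e <- net$edges
  writeLines(sprintf("%s\t%s\t%s", e$lncrna_id, e$mode, e$gene_id), path)
  invisible(path)
}

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(x, digits = 17, format = "g"))
}

#' Export a network as GraphML
#'
#' Writes an attribute-complete GraphML document (node attributes `kind`,
#' `log2fc`, `call`; edge attributes `mode`, `window`, `distance_bp`,
#' `cor`, `sign`). Numeric attributes are written with 17 significant
#' digits so that [import_graphml()] reproduces the network exactly.
#'
#' @param net A `regulatory_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  doc <- xml2::xml_new_root("graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns")
  keys <- rbind(
    data.frame(id = c("kind", "log2fc", "call"), dom = "node",
               type = c("string", "double", "string")),
    data.frame(id = c("mode", "window", "distance_bp", "cor", "sign"),
               dom = "edge",
               type = c("string", "double", "double", "double", "double"))
  )
  for (i in seq_len(nrow(keys)))
    xml2::xml_add_child(doc, "key", id = keys$id[i], `for` = keys$dom[i],
                        attr.name = keys$id[i], attr.type = keys$type[i])
  g <- xml2::xml_add_child(doc, "graph", id = "G", edgedefault = "undirected")
  add_data <- function(el, key, value) {
    if (is.na(value)) return(invisible())
    d <- xml2::xml_add_child(el, "data", key = key)
    xml2::xml_set_text(d, as.character(value))
  }
  for (i in seq_len(nrow(net$nodes))) {
    nd <- xml2::xml_add_child(g, "node", id = net$nodes$id[i])
    add_data(nd, "kind", net$nodes$kind[i])
    add_data(nd, "log2fc", fmt_num(net$nodes$log2fc[i]))
    add_data(nd, "call", net$nodes$call[i])
  }
  for (i in seq_len(nrow(net$edges))) {
    ed <- xml2::xml_add_child(g, "edge",
                              source = net$edges$lncrna_id[i],
                              target = net$edges$gene_id[i])
    add_data(ed, "mode", net$edges$mode[i])
    add_data(ed, "window", fmt_num(net$edges$window[i]))
    add_data(ed, "distance_bp", fmt_num(net$edges$distance_bp[i]))
    add_data(ed, "cor", fmt_num(net$edges$cor[i]))
    add_data(ed, "sign", fmt_num(net$edges$sign[i]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Import a network from GraphML written by [export_graphml()]
#'
#' @param path GraphML file path.
#' @return A `regulatory_network`.
#' @export
import_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  get_data <- function(el, key) {
    d <- xml2::xml_find_first(el, sprintf(".//g:data[@key='%s']", key), ns)
    if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
  }
  nodes_el <- xml2::xml_find_all(doc, ".//g:graph/g:node", ns)
  nodes <- data.frame(
    id = xml2::xml_attr(nodes_el, "id"),
    kind = vapply(nodes_el, get_data, character(1), "kind"),
    log2fc = as.numeric(vapply(nodes_el, get_data, character(1), "log2fc")),
    call = vapply(nodes_el, get_data, character(1), "call"),
    stringsAsFactors = FALSE
  )
  edges_el <- xml2::xml_find_all(doc, ".//g:graph/g:edge", ns)
  edges <- data.frame(
    lncrna_id = xml2::xml_attr(edges_el, "source"),
    gene_id = xml2::xml_attr(edges_el, "target"),
    mode = vapply(edges_el, get_data, character(1), "mode"),
    window = as.numeric(vapply(edges_el, get_data, character(1), "window")),
    distance_bp = as.numeric(vapply(edges_el, get_data, character(1), "distance_bp")),
    cor = as.numeric(vapply(edges_el, get_data, character(1), "cor")),
    sign = as.numeric(vapply(edges_el, get_data, character(1), "sign")),
    stringsAsFactors = FALSE
  )
  if (length(nodes_el) == 0)
    nodes <- data.frame(id = character(0), kind = character(0),
                        log2fc = numeric(0), call = character(0))
  if (length(edges_el) == 0)
    edges <- data.frame(lncrna_id = character(0), gene_id = character(0),
                        mode = character(0), window = numeric(0),
                        distance_bp = numeric(0), cor = numeric(0),
                        sign = numeric(0))
  structure(list(nodes = nodes, edges = edges), class = "regulatory_network")
}
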