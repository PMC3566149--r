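#' Construct an interaction network object
#'
#' @param nodes Data.frame with columns `id`, `type`
#'   (type over `{miRNA, lncRNA, mRNA}`).
#' @param edges Data.frame with columns `source` (miRNA id), `target`
#'   (transcript id), `target_class` (`lncRNA`/`mRNA`), `evidence`
#'   (`predicted`/`validated`/`both`).
#' @return An `interaction_network` object.
#' @export
interaction_network <- function(nodes, edges) {
  assert_that(all(c("id", "type") %in% names(nodes)), "nodes need id/type")
  assert_that(all(c("source", "target", "target_class", "evidence") %in%
                    names(edges)),
              "edges need source/target/target_class/evidence")
  assert_that(!anyDuplicated(nodes$id), "duplicate node ids")
  assert_that(all(nodes$type %in% c("miRNA", "lncRNA", "mRNA")),
              "node type must be miRNA, lncRNA or mRNA")
  assert_that(!anyDuplicated(paste(edges$source, edges$target)),
              "duplicate (source, target) edges")
  assert_that(all(edges$source %in% nodes$id[nodes$type == "miRNA"]),
              "every edge source must be a miRNA node")
  assert_that(all(edges$target %in% nodes$id[nodes$type != "miRNA"]),
              "every edge target must be a transcript node")
  nodes <- nodes[order(nodes$type, nodes$id), , drop = FALSE]
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  tt <- table(factor(x$nodes$type, c("miRNA", "lncRNA", "mRNA")))
  cat(sprintf("interaction_network: %d miRNAs, %d lncRNAs, %d mRNAs, %d edges\n",
              tt[["miRNA"]], tt[["lncRNA"]], tt[["mRNA"]], nrow(x$edges)))
  invisible(x)
}

#' Assemble the tripartite miRNA-lncRNA-mRNA interaction network
#'
#' Combines predicted duplex hits on lncRNAs and mRNAs with externally
#' supplied validated miRNA-mRNA pairs into a single unweighted network.
#' Multiple hits of one miRNA on one transcript collapse to a single edge;
#' a pair present in both the predictions and the validated list gets
#' evidence `"both"`.
#'
#' @param lnc_hits,mrna_hits Duplex-hit data.frames (see
#'   [predict_targets()]); `lnc_hits` targets are typed lncRNA,
#'   `mrna_hits` targets mRNA.
#' @param validated Data.frame with columns `mirna_id`, `transcript_id` of
#'   validated miRNA-mRNA interactions (may be empty).
#' @return An `interaction_network`.
#' @export
build_network <- function(lnc_hits = NULL, mrna_hits = NULL, validated = NULL) {
  pick <- function(hits, class) {
    if (is.null(hits) || !nrow(hits)) {
      return(data.frame(source = character(), target = character(),
                        target_class = character(), stringsAsFactors = FALSE))
    }
    unique(data.frame(source = hits$mirna_id, target = hits$transcript_id,
                      target_class = class, stringsAsFactors = FALSE))
  }
  pred <- rbind(pick(lnc_hits, "lncRNA"), pick(mrna_hits, "mRNA"))
  dupes <- duplicated(paste(pred$source, pred$target))
  pred <- pred[!dupes, , drop = FALSE]
  pred$evidence <- rep("predicted", nrow(pred))

  if (!is.null(validated) && nrow(validated)) {
    lnc_targets <- pred$target[pred$target_class == "lncRNA"]
    clash <- validated$transcript_id %in% lnc_targets
    if (any(clash)) {
      stop_located("network class conflict", validated$transcript_id[which(clash)[1]],
                   "validated pair names a transcript typed lncRNA")
    }
    vkey <- paste(validated$mirna_id, validated$transcript_id)
    pkey <- paste(pred$source, pred$target)
    pred$evidence[pkey %in% vkey] <- "both"
    extra <- !vkey %in% pkey & !duplicated(vkey)
    if (any(extra)) {
      pred <- rbind(pred, data.frame(
        source = validated$mirna_id[extra],
        target = validated$transcript_id[extra],
        target_class = "mRNA", evidence = "validated",
        stringsAsFactors = FALSE))
    }
  }

  mir_ids <- unique(pred$source)
  nodes <- rbind(
    data.frame(id = mir_ids, type = rep("miRNA", length(mir_ids)),
               stringsAsFactors = FALSE),
    unique(data.frame(id = pred$target, type = pred$target_class,
                      stringsAsFactors = FALSE)))
  interaction_network(nodes, pred)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("source", "target"), drop = FALSE],
    directed = FALSE, vertices = net$nodes)
  g
}

#' Summary statistics of an interaction network
#'
#' @param net An `interaction_network`.
#' @return A list with `n_nodes` (named by type), `n_edges` (table by
#'   target_class x evidence), `degree` (named vector), `components`
#'   (membership vector) and `component_sizes`.
#' @export
network_stats <- function(net) {
  n_nodes <- table(factor(net$nodes$type, c("miRNA", "lncRNA", "mRNA")))
  n_edges <- table(factor(net$edges$target_class, c("lncRNA", "mRNA")),
                   factor(net$edges$evidence,
                          c("predicted", "validated", "both")))
  if (!nrow(net$nodes)) {
    return(list(n_nodes = n_nodes, n_edges = n_edges,
                degree = stats::setNames(integer(), character()),
                components = stats::setNames(integer(), character()),
                component_sizes = integer()))
  }
  g <- as_igraph(net)
  comp <- igraph::components(g)
  list(n_nodes = n_nodes,
       n_edges = n_edges,
       degree = igraph::degree(g),
       components = comp$membership,
       component_sizes = as.integer(comp$csize))
}

#' Extract the neighborhood of a node
#'
#' Induced subgraph of all nodes within the given graph distance of
#' `node_id`, with edges treated as undirected.
#'
#' @param net An `interaction_network`.
#' @param node_id Node to center on.
#' @param radius Non-negative integer graph distance.
#' @return An `interaction_network` restricted to the neighborhood.
#' @export
neighborhood <- function(net, node_id, radius) {
  assert_that(node_id %in% net$nodes$id,
              sprintf("unknown node '%s'", node_id))
  assert_that(radius >= 0, "radius must be >= 0")
  g <- as_igraph(net)
  keep <- names(igraph::ego(g, order = radius, nodes = node_id)[[1]])
  nodes <- net$nodes[net$nodes$id %in% keep, , drop = FALSE]
  edges <- net$edges[net$edges$source %in% keep &
                       net$edges$target %in% keep, , drop = FALSE]
  interaction_network(nodes, edges)
}
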