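#' Export an interaction network
#'
#' Writes the network in one of three interchange formats. TSV is the
#' canonical, diff-stable format (columns `source`, `source_type`, `target`,
#' `target_type`, `evidence`); SIF rows are
#' `source<TAB>targets<TAB>target`; GraphML carries a node `type` attribute.
#' Rows are emitted in lexicographic (source, target) order in every format.
#'
#' @param net An `interaction_network`.
#' @param path Output path.
#' @param format One of `"tsv"`, `"sif"`, `"graphml"`.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path, format = c("tsv", "sif", "graphml")) {
  if (!is.character(format) || !all(format %in% c("tsv", "sif", "graphml"))) {
    stop("unknown network format: ", paste(format, collapse = ", "),
         call. = FALSE)
  }
  format <- match.arg(format)
  e <- net$edges
  if (format == "tsv") {
    out <- data.frame(source = e$source,
                      source_type = rep("miRNA", nrow(e)),
                      target = e$target, target_type = e$target_class,
                      evidence = e$evidence, stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "sif") {
    writeLines(sprintf("%s\ttargets\t%s", e$source, e$target), path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Read an interaction network from its canonical TSV export
#'
#' Inverse of `write_network(..., format = "tsv")`.
#'
#' @param path Path to a network TSV.
#' @return An `interaction_network`.
#' @export
read_network_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  edges <- data.frame(source = df$source, target = df$target,
                      target_class = df$target_type, evidence = df$evidence,
                      stringsAsFactors = FALSE)
  mir_ids <- unique(df$source)
  nodes <- rbind(
    data.frame(id = mir_ids, type = rep("miRNA", length(mir_ids)),
               stringsAsFactors = FALSE),
    unique(data.frame(id = df$target, type = df$target_type,
                      stringsAsFactors = FALSE)))
  interaction_network(nodes, edges)
}
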