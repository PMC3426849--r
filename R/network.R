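#' Build the discriminative co-expression network (DCN)
#'
#' Directed graph with one edge signature gene -> predicted gene per
#' prediction whose confidence exceeds the threshold. Duplicate
#' (source, target) pairs are collapsed keeping the maximum confidence;
#' edges are ordered by source then target.
#'
#' @param predictions Data frame from [predict_all()].
#' @param threshold Confidence threshold (strict).
#' @return A `DiscriminativeNetwork`: list with `edges` (data frame
#'   `source`, `target`, `L`, `confidence`), `vertices`, `threshold`.
#' @export
build_dcn <- function(predictions, threshold = 0.9) {
  empty <- data.frame(source = character(), target = character(),
                      L = numeric(), confidence = numeric(),
                      stringsAsFactors = FALSE)
  e <- empty
  if (!is.null(predictions) && nrow(predictions)) {
    p <- predictions[predictions$confidence > threshold &
                       predictions$gene != predictions$signature_gene, ,
                     drop = FALSE]
    if (nrow(p)) {
      key <- paste(p$signature_gene, p$gene, sep = "\r")
      p <- p[order(key, -p$confidence), , drop = FALSE]
      p <- p[!duplicated(paste(p$signature_gene, p$gene, sep = "\r")), ,
             drop = FALSE]
      e <- data.frame(source = p$signature_gene, target = p$gene,
                      L = p$L, confidence = p$confidence,
                      stringsAsFactors = FALSE)
      e <- e[order(e$source, e$target), , drop = FALSE]
      rownames(e) <- NULL
    }
  }
  structure(list(edges = e,
                 vertices = sort(unique(c(e$source, e$target))),
                 threshold = threshold),
            class = "DiscriminativeNetwork")
}

#' @export
print.DiscriminativeNetwork <- function(x, ...) {
  cat(sprintf("DCN: %d genes, %d edges (confidence > %g)\n",
              length(x$vertices), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Directed degrees of every gene in a DCN
#'
#' High out-degree flags hub signatures; total degree flags genes
#' central to the process.
#'
#' @param network A [build_dcn()] result.
#' @return Data frame `gene`, `in_degree`, `out_degree`, `total`.
#' @export
node_degrees <- function(network) {
  v <- network$vertices
  ind <- table(factor(network$edges$target, levels = v))
  outd <- table(factor(network$edges$source, levels = v))
  data.frame(gene = v,
             in_degree = as.integer(ind),
             out_degree = as.integer(outd),
             total = as.integer(ind) + as.integer(outd),
             stringsAsFactors = FALSE, row.names = NULL)
}

dcn_to_igraph <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = TRUE,
                                vertices = network$vertices)
}

#' Export a DCN to edge-list, GraphML or SIF
#'
#' The tab-delimited edge list round-trips exactly through
#' [read_network()]; GraphML (via igraph) preserves the L and confidence
#' attributes; SIF writes one `source predicts target` line per edge.
#'
#' @param network A [build_dcn()] result.
#' @param path Output file.
#' @param format One of `"edgelist"`, `"graphml"`, `"sif"`.
#' @return The path, invisibly.
#' @export
export_network <- function(network, path, format = "edgelist") {
  if (format == "edgelist") {
    e <- network$edges
    e$L <- fmt_num(e$L); e$confidence <- fmt_num(e$confidence)
    utils::write.table(e, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else if (format == "graphml") {
    igraph::write_graph(dcn_to_igraph(network), path, format = "graphml")
  } else if (format == "sif") {
    writeLines(sprintf("%s\tpredicts\t%s",
                       network$edges$source, network$edges$target), path)
  } else stop("unknown format '", format,
              "'; supported: edgelist, graphml, sif")
  invisible(path)
}

#' @rdname export_network
#' @param threshold Confidence recorded on the reconstructed network.
#' @export
read_network <- function(path, threshold = 0) {
  e <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  net <- build_dcn(data.frame(gene = e$target, signature_gene = e$source,
                              L = e$L, confidence = e$confidence,
                              stringsAsFactors = FALSE),
                   threshold = threshold)
  net$threshold <- threshold
  net
}
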