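# The spatial residue graph: chain edges, distance edges below a cutoff,
# one round of shared-neighbour closure, and secondary-structure edge
# classes.

#' Build the spatial residue graph of a structure model
#'
#' Nodes are residues (positions 1..n in the model). Three edge layers are
#' applied in order:
#' \enumerate{
#'   \item chain: every consecutive residue pair (i, i+1);
#'   \item distance: every pair with Calpha-Calpha distance strictly below
#'     `neighbor_cutoff`;
#'   \item shared_neighbor: every pair (i, k) with a common neighbour j in
#'     the chain+distance graph. Applied exactly once, not iterated.
#' }
#' An edge created by an earlier layer keeps that layer as its `origin`.
#'
#' @param model a StructureModel
#' @param neighbor_cutoff positive distance cutoff in Angstrom. The values
#'   studied for real models are 4.0, 4.5, 5.0 and 5.5; 1.0 yields the
#'   chain-only ("linear") graph.
#' @return an object of class `ResidueGraph`: `n`, `residue_index`,
#'   and `edges` (data.frame with columns i, j (positions, i < j),
#'   distance, origin, class)
#' @export
build_graph <- function(model, neighbor_cutoff = 4.5) {
  if (!is.numeric(neighbor_cutoff) || neighbor_cutoff <= 0) {
    stop("neighbor_cutoff must be a positive distance in Angstrom")
  }
  n <- length(model$residue_index)
  if (n < 2L) stop("model must have at least 2 residues")
  D <- as.matrix(stats::dist(model$coords))
  ii <- integer(0); jj <- integer(0); org <- character(0)
  # chain layer
  ii <- seq_len(n - 1L); jj <- ii + 1L
  org <- rep("chain", n - 1L)
  # distance layer (strict <)
  close <- which(upper.tri(D) & D < neighbor_cutoff, arr.ind = TRUE)
  if (nrow(close) > 0L) {
    ischain <- close[, 2] - close[, 1] == 1L
    add <- close[!ischain, , drop = FALSE]
    ii <- c(ii, add[, 1]); jj <- c(jj, add[, 2])
    org <- c(org, rep("distance", nrow(add)))
  }
  # shared-neighbour closure, applied once over the chain+distance set
  adj <- matrix(FALSE, n, n)
  adj[cbind(ii, jj)] <- TRUE
  adj <- adj | t(adj)
  have <- adj
  for (j in seq_len(n)) {
    nb <- which(adj[j, ])
    if (length(nb) < 2L) next
    prs <- utils::combn(nb, 2L)
    for (p in seq_len(ncol(prs))) {
      a <- prs[1, p]; b <- prs[2, p]
      if (!have[a, b]) {
        have[a, b] <- have[b, a] <- TRUE
        ii <- c(ii, a); jj <- c(jj, b)
        org <- c(org, "shared_neighbor")
      }
    }
  }
  ord <- order(ii, jj)
  edges <- data.frame(i = ii[ord], j = jj[ord],
                      distance = D[cbind(ii[ord], jj[ord])],
                      origin = org[ord], class = NA_character_,
                      stringsAsFactors = FALSE)
  structure(list(n = n, residue_index = model$residue_index, edges = edges),
            class = "ResidueGraph")
}

#' @export
print.ResidueGraph <- function(x, ...) {
  cat(sprintf("ResidueGraph: %d nodes, %d edges (%s)\n", x$n, nrow(x$edges),
              paste(sprintf("%s=%d", names(table(x$edges$origin)),
                            as.integer(table(x$edges$origin))),
                    collapse = ", ")))
  invisible(x)
}

#' Classify graph edges by the secondary structure of their endpoints
#'
#' Five classes: HH (both helix), BB (both strand), HB (helix-strand),
#' CHB (coil with helix or strand), CC (both coil). The class is symmetric
#' in the endpoints.
#'
#' @param graph a ResidueGraph
#' @param ss secondary-structure string over {H,B,C}, one code per node
#' @return the graph with the `class` edge column filled
#' @export
classify_edges <- function(graph, ss) {
  codes <- strsplit(ss, "")[[1]]
  if (length(codes) != graph$n) {
    stop(sprintf("secondary-structure string length %d != %d nodes",
                 length(codes), graph$n))
  }
  if (!all(codes %in% c("H", "B", "C"))) stop("unknown secondary-structure code")
  a <- codes[graph$edges$i]; b <- codes[graph$edges$j]
  cls <- ifelse(a == "H" & b == "H", "HH",
         ifelse(a == "B" & b == "B", "BB",
         ifelse((a == "H" & b == "B") | (a == "B" & b == "H"), "HB",
         ifelse(a == "C" & b == "C", "CC", "CHB"))))
  graph$edges$class <- cls
  graph
}

# Induced subgraph on a subset of node positions, nodes renumbered to
# 1..length(nodes) preserving order. Used for component-wise computations.
subgraph_keep <- function(graph, nodes) {
  nodes <- sort(nodes)
  keep <- graph$edges$i %in% nodes & graph$edges$j %in% nodes
  e <- graph$edges[keep, , drop = FALSE]
  e$i <- match(e$i, nodes); e$j <- match(e$j, nodes)
  rownames(e) <- NULL
  structure(list(n = length(nodes),
                 residue_index = graph$residue_index[nodes], edges = e),
            class = "ResidueGraph")
}

#' Export a residue graph as an edge-list TSV
#'
#' Columns: node_i, node_j (residue indices), distance, class, origin.
#'
#' @param graph a ResidueGraph
#' @param path output file, or `NULL` to return the data.frame
#' @export
write_graph_tsv <- function(graph, path = NULL) {
  df <- data.frame(node_i = graph$residue_index[graph$edges$i],
                   node_j = graph$residue_index[graph$edges$j],
                   distance = graph$edges$distance,
                   class = graph$edges$class,
                   origin = graph$edges$origin)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}
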