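# Junction-tree machinery: min-fill triangulation, maximal clique
# enumeration (Bron-Kerbosch with pivoting) and clique-tree construction
# with a running-intersection check. All orderings are deterministic
# (lowest node index wins ties) so runs are bit-reproducible.

adjacency_from_edges <- function(n, edges) {
  adj <- matrix(FALSE, n, n)
  if (nrow(edges) > 0L) {
    adj[cbind(edges$i, edges$j)] <- TRUE
    adj <- adj | t(adj)
  }
  adj
}

#' Triangulate a residue graph (min-fill heuristic)
#'
#' Exact message passing requires a chordal graph; a distance graph need
#' not be chordal, so chord ("fill") edges are added with the min-fill
#' heuristic (eliminate the node whose neighbourhood needs fewest fill
#' edges; ties broken by lowest node index). Fill edges get
#' `origin = "fill"`; they exist only for inference validity and carry no
#' pairwise potential in the CRF.
#'
#' @param graph a ResidueGraph
#' @return the graph with fill edges appended (class `NA` until
#'   [classify_edges()] is applied) and an attribute `n_fill`
#' @export
triangulate <- function(graph) {
  n <- graph$n
  adj <- adjacency_from_edges(n, graph$edges)
  work <- adj
  alive <- rep(TRUE, n)
  fill_i <- integer(0); fill_j <- integer(0)
  for (step in seq_len(n)) {
    cand <- which(alive)
    if (length(cand) == 0L) break
    # fill count for each candidate: non-adjacent pairs among its live
    # neighbours
    fc <- vapply(cand, function(v) {
      nb <- which(work[v, ] & alive)
      if (length(nb) < 2L) return(0L)
      sub <- work[nb, nb, drop = FALSE]
      as.integer(sum(!sub[upper.tri(sub)]))
    }, integer(1))
    v <- cand[which.min(fc)]   # which.min takes the first = lowest index
    nb <- which(work[v, ] & alive)
    if (length(nb) >= 2L) {
      prs <- utils::combn(nb, 2L)
      for (p in seq_len(ncol(prs))) {
        a <- prs[1, p]; b <- prs[2, p]
        if (!work[a, b]) {
          work[a, b] <- work[b, a] <- TRUE
          if (!adj[a, b]) {
            adj[a, b] <- adj[b, a] <- TRUE
            fill_i <- c(fill_i, min(a, b)); fill_j <- c(fill_j, max(a, b))
          }
        }
      }
    }
    alive[v] <- FALSE
  }
  if (length(fill_i) > 0L) {
    add <- data.frame(i = fill_i, j = fill_j,
                      distance = rep(NA_real_, length(fill_i)),
                      origin = "fill", class = NA_character_,
                      stringsAsFactors = FALSE)
    graph$edges <- rbind(graph$edges, add)
    ord <- order(graph$edges$i, graph$edges$j)
    graph$edges <- graph$edges[ord, , drop = FALSE]
    rownames(graph$edges) <- NULL
  }
  attr(graph, "n_fill") <- length(fill_i)
  graph
}

#' Enumerate the maximal cliques of a residue graph
#'
#' Bron-Kerbosch with pivoting (works on arbitrary graphs; on the
#' triangulated graph the number of maximal cliques is at most the number
#' of nodes). Each clique is sorted by node index and the list is sorted
#' lexicographically.
#'
#' @param graph a ResidueGraph
#' @return an object of class `CliqueSet`: a list with `cliques` (list of
#'   integer vectors) and `n` (node count)
#' @export
enumerate_maximal_cliques <- function(graph) {
  n <- graph$n
  adj <- adjacency_from_edges(n, graph$edges)
  nbrs <- lapply(seq_len(n), function(v) which(adj[v, ]))
  out <- list()
  bk <- function(R, P, X) {
    if (length(P) == 0L && length(X) == 0L) {
      out[[length(out) + 1L]] <<- sort(R)
      return(invisible(NULL))
    }
    # pivot: vertex of P union X with most neighbours in P (first wins ties)
    PX <- c(P, X)
    cnt <- vapply(PX, function(u) length(intersect(nbrs[[u]], P)), integer(1))
    u <- PX[which.max(cnt)]
    for (v in setdiff(P, nbrs[[u]])) {
      bk(c(R, v), intersect(P, nbrs[[v]]), intersect(X, nbrs[[v]]))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  # lexicographic sort of the clique list
  keys <- vapply(out, function(cl) paste(sprintf("%06d", cl), collapse = ","),
                 character(1))
  out <- out[order(keys)]
  structure(list(cliques = out, n = n), class = "CliqueSet")
}

#' @export
print.CliqueSet <- function(x, ...) {
  sizes <- lengths(x$cliques)
  cat(sprintf("CliqueSet: %d maximal cliques over %d nodes (max size %d)\n",
              length(x$cliques), x$n, max(sizes)))
  invisible(x)
}

#' Build a clique tree (junction tree) from a maximal clique set
#'
#' Maximum-weight spanning forest over the clique intersection graph with
#' weight = separator size (Kruskal; ties broken by the lexicographically
#' smaller clique pair). The running intersection property is verified and
#' violation raises an internal error (it indicates a triangulation bug).
#'
#' @param cliques a CliqueSet from a chordal graph
#' @return an object of class `CliqueTree`: `cliques`, `edges`
#'   (data.frame a, b of clique ids) with `separators` (list of integer
#'   vectors), and `n` (node count)
#' @export
build_clique_tree <- function(cliques) {
  cl <- cliques$cliques
  k <- length(cl)
  if (k == 0L) stop("empty clique set")
  ea <- integer(0); eb <- integer(0); ew <- integer(0)
  if (k > 1L) {
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        s <- length(intersect(cl[[a]], cl[[b]]))
        if (s > 0L) { ea <- c(ea, a); eb <- c(eb, b); ew <- c(ew, s) }
      }
    }
  }
  ord <- order(-ew, ea, eb)
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  ta <- integer(0); tb <- integer(0)
  for (e in ord) {
    ra <- find(ea[e]); rb <- find(eb[e])
    if (ra != rb) {
      parent[ra] <- rb
      ta <- c(ta, ea[e]); tb <- c(tb, eb[e])
    }
  }
  seps <- mapply(function(a, b) intersect(cl[[a]], cl[[b]]), ta, tb,
                 SIMPLIFY = FALSE)
  tree <- structure(list(cliques = cl,
                         edges = data.frame(a = ta, b = tb),
                         separators = seps, n = cliques$n),
                    class = "CliqueTree")
  if (!check_running_intersection(tree)) {
    stop("internal error: running intersection property violated ",
         "(triangulation bug?)")
  }
  tree
}

# TRUE iff, for every node v, the cliques containing v induce a connected
# subtree of the clique forest.
check_running_intersection <- function(tree) {
  k <- length(tree$cliques)
  adj <- vector("list", k)
  if (nrow(tree$edges) > 0L) {
    for (e in seq_len(nrow(tree$edges))) {
      a <- tree$edges$a[e]; b <- tree$edges$b[e]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  for (v in seq_len(tree$n)) {
    has <- which(vapply(tree$cliques, function(cl) v %in% cl, logical(1)))
    if (length(has) <= 1L) next
    # BFS within the induced subgraph
    seen <- has[1]; queue <- has[1]
    while (length(queue) > 0L) {
      c0 <- queue[1]; queue <- queue[-1]
      nxt <- setdiff(intersect(adj[[c0]], has), seen)
      seen <- c(seen, nxt); queue <- c(queue, nxt)
    }
    if (length(seen) != length(has)) return(FALSE)
  }
  TRUE
}

#' @export
print.CliqueTree <- function(x, ...) {
  cat(sprintf("CliqueTree: %d cliques, %d tree edges over %d nodes\n",
              length(x$cliques), nrow(x$edges), x$n))
  invisible(x)
}

#' Dump cliques as a TSV (clique id, member residue indices)
#' @param cliques a CliqueSet or CliqueTree
#' @param residue_index mapping from node position to residue index
#' @param path output file or `NULL`
#' @export
write_clique_tsv <- function(cliques, residue_index = NULL, path = NULL) {
  cl <- cliques$cliques
  if (is.null(residue_index)) residue_index <- seq_len(cliques$n)
  df <- data.frame(clique_id = seq_along(cl),
                   members = vapply(cl, function(x)
                     paste(residue_index[x], collapse = ","), character(1)))
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}
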