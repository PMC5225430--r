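# GraphModelInstance: a residue graph + clique tree + feature matrix bound
# together, with every residue and every original (non-fill) edge assigned
# to exactly one "owner" clique. Ownership prevents double counting across
# overlapping cliques: the global energy is the sum of clique potentials,
# each term appearing exactly once.

#' Bind graph, clique tree and features into a CRF instance
#'
#' Every residue is owned by the smallest clique containing it; every
#' non-fill edge by the smallest clique containing both endpoints (ties
#' broken by lexicographic clique order). Fill edges from triangulation
#' carry no pairwise potential.
#'
#' @param graph a triangulated, edge-classified ResidueGraph
#' @param tree the CliqueTree of `graph`
#' @param features numeric matrix (residues x m), normalised
#' @param labels optional integer vector of true labels in {0, 1}
#' @return an object of class `GraphModelInstance`
#' @export
build_instance <- function(graph, tree, features, labels = NULL) {
  n <- graph$n
  features <- as.matrix(features)
  if (nrow(features) != n) stop("feature row count != node count")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) stop("label length != node count")
    if (!all(labels %in% c(0L, 1L, NA))) stop("labels must be 0/1 (or NA)")
  }
  cl <- tree$cliques
  k <- length(cl)
  sizes <- lengths(cl)
  # owner clique per residue: smallest containing clique, first on ties
  node_owner <- integer(n)
  for (v in seq_len(n)) {
    has <- which(vapply(cl, function(x) v %in% x, logical(1)))
    if (length(has) == 0L) stop("internal error: residue in no clique")
    node_owner[v] <- has[which.min(sizes[has])]
  }
  # owner clique per original (non-fill) edge
  ed <- graph$edges[graph$edges$origin != "fill", , drop = FALSE]
  edge_owner <- integer(nrow(ed))
  for (e in seq_len(nrow(ed))) {
    has <- which(vapply(cl, function(x)
      ed$i[e] %in% x && ed$j[e] %in% x, logical(1)))
    if (length(has) == 0L) {
      stop("internal error: graph edge contained in no clique")
    }
    edge_owner[e] <- has[which.min(sizes[has])]
  }
  # tree traversal structure: BFS from the first clique of each component
  parent <- rep(NA_integer_, k)
  adj <- vector("list", k)
  if (nrow(tree$edges) > 0L) {
    for (e in seq_len(nrow(tree$edges))) {
      a <- tree$edges$a[e]; b <- tree$edges$b[e]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
  }
  visited <- rep(FALSE, k)
  order_bfs <- integer(0)
  roots <- integer(0)
  for (r in seq_len(k)) {
    if (visited[r]) next
    roots <- c(roots, r)
    queue <- r; visited[r] <- TRUE
    while (length(queue) > 0L) {
      c0 <- queue[1]; queue <- queue[-1]
      order_bfs <- c(order_bfs, c0)
      for (nb in adj[[c0]]) {
        if (!visited[nb]) {
          visited[nb] <- TRUE
          parent[nb] <- c0
          queue <- c(queue, nb)
        }
      }
    }
  }
  # per-clique configuration matrices and index maps
  conf <- lapply(cl, function(x) binary_configs(length(x)))
  # separator index of each clique's configs within (child conf, parent conf)
  sep_in_child <- vector("list", k)
  sep_in_parent <- vector("list", k)
  sep_size <- integer(k)
  for (c0 in seq_len(k)) {
    p <- parent[c0]
    if (is.na(p)) next
    sep <- sort(intersect(cl[[c0]], cl[[p]]))
    sep_size[c0] <- length(sep)
    sep_in_child[[c0]] <- config_index(conf[[c0]], match(sep, cl[[c0]]))
    sep_in_parent[[c0]] <- config_index(conf[[p]], match(sep, cl[[p]]))
  }
  structure(list(graph = graph, tree = tree, features = features,
                 labels = labels, n = n, m = ncol(features),
                 cliques = cl, conf = conf,
                 node_owner = node_owner,
                 pair = data.frame(i = ed$i, j = ed$j, class = ed$class,
                                   owner = edge_owner,
                                   stringsAsFactors = FALSE),
                 parent = parent, order = order_bfs, roots = roots,
                 sep_in_child = sep_in_child, sep_in_parent = sep_in_parent,
                 sep_size = sep_size),
            class = "GraphModelInstance")
}

#' @export
print.GraphModelInstance <- function(x, ...) {
  cat(sprintf(paste0("GraphModelInstance: %d residues, %d features, ",
                     "%d cliques (max size %d), %d pairwise terms\n"),
              x$n, x$m, length(x$cliques), max(lengths(x$cliques)),
              nrow(x$pair)))
  invisible(x)
}

#' Build a CRF instance from a structure model in one call
#'
#' Runs the full pipeline: residue graph at the neighbour cutoff,
#' triangulation, edge classification, maximal cliques, clique tree,
#' instance assembly.
#'
#' @param model a StructureModel
#' @param features numeric matrix (residues x m), normalised
#' @param neighbor_cutoff graph cutoff in Angstrom
#' @param ss secondary-structure string; computed from the Calpha trace
#'   when `NULL`
#' @param labels optional true labels
#' @return a GraphModelInstance
#' @export
gmq_instance <- function(model, features, neighbor_cutoff = 4.5, ss = NULL,
                         labels = NULL) {
  if (is.null(ss)) ss <- assign_secondary_structure(model)
  g <- build_graph(model, neighbor_cutoff)
  g <- triangulate(g)
  g <- classify_edges(g, ss)
  cs <- enumerate_maximal_cliques(g)
  tr <- build_clique_tree(cs)
  build_instance(g, tr, features, labels)
}

# Pairwise pattern index (1..4 for 00,01,10,11) of an edge i<j given a full
# label vector: first digit is the label of the lower residue index.
pattern_index <- function(yi, yj) 1L + 2L * yi + yj

# Log factor tables for every clique under the given parameters: node
# terms for owned residues, pairwise terms (weighted by w[class]) for
# owned edges. Optionally clamps residues to fixed labels (vector with NA
# = free, 0/1 = clamped) by -Inf-ing inconsistent rows of owner cliques.
clique_factors <- function(instance, params, clamp = NULL) {
  k <- length(instance$cliques)
  node_score <- as.numeric(instance$features %*% params$lambda1)
  wE <- unname(params$w[instance$pair$class])
  if (nrow(instance$pair) > 0L && anyNA(wE)) {
    stop("edge class missing; run classify_edges() before building instances")
  }
  factors <- vector("list", k)
  for (c0 in seq_len(k)) {
    members <- instance$cliques[[c0]]
    cf <- instance$conf[[c0]]
    f <- numeric(nrow(cf))
    for (v in members[instance$node_owner[members] == c0]) {
      f <- f + cf[, match(v, members)] * node_score[v]
    }
    own_e <- which(instance$pair$owner == c0)
    for (e in own_e) {
      li <- match(instance$pair$i[e], members)
      lj <- match(instance$pair$j[e], members)
      pidx <- pattern_index(cf[, li], cf[, lj])
      f <- f + wE[e] * unname(params$omega)[pidx]
    }
    factors[[c0]] <- f
  }
  if (!is.null(clamp)) factors <- apply_clamp(instance, factors, clamp)
  factors
}

# Impose label evidence: -Inf out rows of each residue's owner clique that
# disagree with the clamped label. Running intersection propagates the
# restriction exactly through the separators.
apply_clamp <- function(instance, factors, clamp) {
  for (v in which(!is.na(clamp))) {
    c0 <- instance$node_owner[v]
    members <- instance$cliques[[c0]]
    bad <- instance$conf[[c0]][, match(v, members)] != clamp[v]
    factors[[c0]][bad] <- -Inf
  }
  factors
}

#' Log potential of one clique for a given labelling of its members
#'
#' The potential combines the node terms of residues owned by the clique
#' (sum over features of lambda weights times feature values, for label-1
#' residues) and, for each owned edge, the edge-class weight times the
#' omega weight of the pair's label pattern (00/01/10/11, lower residue
#' index first).
#'
#' @param instance a GraphModelInstance
#' @param clique_id clique index (in the tree's lexicographic order)
#' @param labels_on_clique 0/1 vector, one label per clique member (in
#'   ascending member order)
#' @param params a CRFParameters object
#' @return the log potential (a real number)
#' @export
clique_log_potential <- function(instance, clique_id, labels_on_clique,
                                 params) {
  members <- instance$cliques[[clique_id]]
  if (length(labels_on_clique) != length(members)) {
    stop("labels_on_clique must label every clique member")
  }
  cf <- matrix(as.integer(labels_on_clique), nrow = 1)
  node_score <- as.numeric(instance$features %*% params$lambda1)
  f <- 0
  for (v in members[instance$node_owner[members] == clique_id]) {
    f <- f + cf[1, match(v, members)] * node_score[v]
  }
  own_e <- which(instance$pair$owner == clique_id)
  for (e in own_e) {
    li <- match(instance$pair$i[e], members)
    lj <- match(instance$pair$j[e], members)
    f <- f + unname(params$w[instance$pair$class[e]]) *
      unname(params$omega[pattern_index(cf[1, li], cf[1, lj])])
  }
  unname(f)
}

# Global unnormalised log score (energy) of a full label vector.
label_energy <- function(instance, params, y) {
  node_score <- as.numeric(instance$features %*% params$lambda1)
  e <- sum(node_score[y == 1L])
  if (nrow(instance$pair) > 0L) {
    pidx <- pattern_index(y[instance$pair$i], y[instance$pair$j])
    e <- e + sum(unname(params$w[instance$pair$class]) *
                   unname(params$omega)[pidx])
  }
  e
}
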