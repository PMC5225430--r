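# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: superposition by quaternion search instead of the
# SVD route, clique enumeration by exhaustive subsets, chordality by
# maximum cardinality search, logistic regression by IRLS.

# Rotation matrix from a unit quaternion.
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Brute-force least-squares superposition: random quaternion search
# followed by Nelder-Mead refinement. Returns rotation, translation,
# per-pair distances and RMSD for paired coordinate sets P (moving) and
# Q (fixed).
oracle_superpose <- function(P, Q, n_start = 4000L, seed = 99L) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  obj <- function(q) {
    R <- quat_to_rot(q)
    sum((Pc %*% t(R) - Qc)^2)
  }
  set.seed(seed)
  best <- NULL; bestv <- Inf
  for (i in seq_len(n_start)) {
    q <- rnorm(4)
    v <- obj(q)
    if (v < bestv) { bestv <- v; best <- q }
  }
  fit <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-16, maxit = 20000))
  fit <- optim(fit$par, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-16, maxit = 20000))
  R <- quat_to_rot(fit$par)
  moved <- sweep(Pc %*% t(R), 2, cq, "+")
  d <- sqrt(rowSums((moved - Q)^2))
  list(rotation = R, dist = d, rmsd = sqrt(mean(d^2)))
}

# Exhaustive maximal clique enumeration over all 2^n subsets (n <= 12).
oracle_max_cliques <- function(n, edges_ij) {
  adj <- matrix(FALSE, n, n)
  if (nrow(edges_ij) > 0) {
    adj[cbind(edges_ij[, 1], edges_ij[, 2])] <- TRUE
    adj <- adj | t(adj)
  }
  is_clique <- function(s) {
    if (length(s) <= 1) return(TRUE)
    all(adj[t(combn(s, 2))])
  }
  subsets <- lapply(seq_len(2^n - 1), function(mask) {
    which(bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L)
  })
  cliques <- Filter(is_clique, subsets)
  keep <- vapply(cliques, function(s) {
    # maximal iff no vertex outside s is adjacent to all of s
    !any(vapply(setdiff(seq_len(n), s),
                function(v) all(adj[v, s]), logical(1)))
  }, logical(1))
  out <- cliques[keep]
  keys <- vapply(out, function(cl) paste(sprintf("%06d", cl), collapse = ","),
                 character(1))
  out[order(keys)]
}

# Chordality check by maximum cardinality search + perfect elimination
# verification (Tarjan-Yannakakis).
oracle_is_chordal <- function(n, edges_ij) {
  adj <- matrix(FALSE, n, n)
  if (nrow(edges_ij) > 0) {
    adj[cbind(edges_ij[, 1], edges_ij[, 2])] <- TRUE
    adj <- adj | t(adj)
  }
  weight <- rep(0L, n); order_mcs <- integer(n); placed <- rep(FALSE, n)
  for (k in n:1) {
    v <- which(!placed)[which.max(weight[!placed])]
    order_mcs[k] <- v
    placed[v] <- TRUE
    weight[adj[v, ] & !placed] <- weight[adj[v, ] & !placed] + 1L
  }
  pos <- match(seq_len(n), order_mcs)
  for (v in seq_len(n)) {
    later <- which(adj[v, ] & pos > pos[v])
    if (length(later) < 2) next
    u <- later[which.min(pos[later])]
    rest <- setdiff(later, u)
    if (!all(adj[u, rest])) return(FALSE)
  }
  TRUE
}

# Random connected "chain + extras" graph on n nodes: chain edges plus
# random extra edges with probability p.
random_chain_graph <- function(n, p = 0.3) {
  e <- cbind(seq_len(n - 1), seq_len(n - 1) + 1)
  extra <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  extra <- extra[extra[, 2] - extra[, 1] > 1, , drop = FALSE]
  pick <- runif(nrow(extra)) < p
  rbind(e, extra[pick, , drop = FALSE])
}

# Wrap an edge list into a ResidueGraph-shaped object for the clique
# engine (distance/class immaterial there).
graph_from_edges <- function(n, edges_ij, origin = "distance") {
  ord <- order(edges_ij[, 1], edges_ij[, 2])
  edges_ij <- edges_ij[ord, , drop = FALSE]
  structure(list(n = n, residue_index = seq_len(n),
                 edges = data.frame(i = edges_ij[, 1], j = edges_ij[, 2],
                                    distance = NA_real_, origin = origin,
                                    class = NA_character_,
                                    stringsAsFactors = FALSE)),
            class = "ResidueGraph")
}

# Logistic regression by hand-written IRLS (Newton) iterations.
oracle_logistic_irls <- function(X, y, tol = 1e-12, maxit = 100) {
  X1 <- cbind(1, as.matrix(X))
  b <- rep(0, ncol(X1))
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X1 %*% b)
    p <- 1 / (1 + exp(-eta))
    wt <- pmax(p * (1 - p), 1e-12)
    z <- eta + (y - p) / wt
    bn <- solve(crossprod(X1, X1 * wt), crossprod(X1, wt * z))
    if (max(abs(bn - b)) < tol) { b <- bn; break }
    b <- bn
  }
  as.numeric(b)
}

# A small random CRF instance on a toy structure, for inference tests.
random_instance <- function(n = 8, m = 3, neighbor_cutoff = 4.5,
                            ss = NULL, coupled = TRUE) {
  if (is.null(ss)) {
    ss <- paste(sample(c("H", "C"), n, replace = TRUE), collapse = "")
  }
  sm <- generate_toy_structure(n, ss, seed = sample.int(1e6, 1))
  X <- matrix(rnorm(n * m), n, m)
  inst <- gmq_instance(sm, X, neighbor_cutoff = neighbor_cutoff, ss = ss)
  params <- crf_parameters(lambda1 = rnorm(m),
                           omega = if (coupled) rnorm(4) else rep(0, 4))
  list(instance = inst, params = params, model = sm, ss = ss)
}

# Preferred-label ordering of brute-force labelings: among argmax rows,
# the MAP tie rule picks the row that prefers label 1 at the earliest
# residue.
oracle_map <- function(bf, tol = 1e-9) {
  top <- which(bf$logprob >= max(bf$logprob) - tol)
  Y <- bf$labelings[top, , drop = FALSE]
  # lexicographic preference: 1 before 0, earliest residue most significant
  key <- apply(Y, 1, function(r) paste(1 - r, collapse = ""))
  as.integer(Y[order(key)[1], ])
}
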