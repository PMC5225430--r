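# Exact inference: brute-force enumeration (the oracle route, <= 16
# residues), sum-product and max-product message passing on the clique
# tree, exact forward sampling, and prediction.

#' Brute-force label distribution by full enumeration
#'
#' Enumerates all 2^N label vectors and computes P(Y|X) = exp(E(Y)) / Z.
#' Intended as the independent oracle for message passing; refuses more
#' than 16 residues.
#'
#' @param instance a GraphModelInstance
#' @param params a CRFParameters object
#' @return list with `labelings` (2^N x N 0/1 matrix, residue 1 in column
#'   1, row r encoding r-1 in binary), `prob`, `logprob` and `logZ`
#' @export
brute_force_distribution <- function(instance, params) {
  n <- instance$n
  if (n > 16L) {
    stop(sprintf(paste0("size error: %d residues is too many for ",
                        "enumeration (max 16); use infer_marginals()"), n))
  }
  Y <- binary_configs(n)
  node_score <- as.numeric(instance$features %*% params$lambda1)
  e <- as.numeric(Y %*% node_score)
  if (nrow(instance$pair) > 0L) {
    wE <- unname(params$w[instance$pair$class])
    omega <- unname(params$omega)
    for (q in seq_len(nrow(instance$pair))) {
      pidx <- pattern_index(Y[, instance$pair$i[q]], Y[, instance$pair$j[q]])
      e <- e + wE[q] * omega[pidx]
    }
  }
  logZ <- logsumexp(e)
  list(labelings = Y, prob = exp(e - logZ), logprob = e - logZ, logZ = logZ)
}

# Message passing on the clique tree. op = "sum" gives calibrated log
# beliefs and log Z; op = "max" gives max-calibrated beliefs and the
# maximum attainable log score. `clamp` fixes individual residue labels.
calibrate <- function(instance, params, op = c("sum", "max"), clamp = NULL,
                      factors = NULL) {
  op <- match.arg(op)
  gop <- if (op == "sum") group_logsumexp else group_max
  if (is.null(factors)) {
    factors <- clique_factors(instance, params, clamp)
  } else if (!is.null(clamp)) {
    factors <- apply_clamp(instance, factors, clamp)
  }
  k <- length(factors)
  parent <- instance$parent
  ord <- instance$order
  msg_up <- vector("list", k)     # message clique -> parent, by sep index
  psi_up <- vector("list", k)     # factor + child messages (upward state)
  for (c0 in rev(ord)) {
    f <- factors[[c0]]
    for (ch in which(!is.na(parent) & parent == c0)) {
      f <- f + msg_up[[ch]][instance$sep_in_parent[[ch]]]
    }
    psi_up[[c0]] <- f
    if (!is.na(parent[c0])) {
      ng <- bitwShiftL(1L, instance$sep_size[c0])
      msg_up[[c0]] <- gop(f, instance$sep_in_child[[c0]], ng)
    }
  }
  # downward pass
  msg_down <- vector("list", k)   # message parent -> clique, by sep index
  beliefs <- vector("list", k)
  for (c0 in ord) {
    b <- psi_up[[c0]]
    if (!is.na(parent[c0])) {
      b <- b + msg_down[[c0]][instance$sep_in_child[[c0]]]
    }
    beliefs[[c0]] <- b
    for (ch in which(!is.na(parent) & parent == c0)) {
      bminus <- b - msg_up[[ch]][instance$sep_in_parent[[ch]]]
      # guard 0 * Inf style artefacts when clamped entries are -Inf
      bminus[is.nan(bminus)] <- -Inf
      ng <- bitwShiftL(1L, instance$sep_size[ch])
      msg_down[[ch]] <- gop(bminus, instance$sep_in_parent[[ch]], ng)
    }
  }
  score <- sum(vapply(instance$roots, function(r) {
    if (op == "sum") logsumexp(beliefs[[r]]) else max(beliefs[[r]])
  }, numeric(1)))
  list(beliefs = beliefs, score = score)
}

#' Per-residue marginal probabilities by sum-product message passing
#'
#' Exact marginals P(y_r = 1 | X) on the calibrated clique tree.
#'
#' @param instance a GraphModelInstance
#' @param params a CRFParameters object
#' @param details if TRUE also return clique beliefs, pairwise pattern
#'   probabilities per owned edge, and log Z
#' @return numeric vector of P(y = 1) per residue, or a list when
#'   `details = TRUE`
#' @export
infer_marginals <- function(instance, params, details = FALSE) {
  cal <- calibrate(instance, params, "sum")
  p1 <- numeric(instance$n)
  for (v in seq_len(instance$n)) {
    c0 <- instance$node_owner[v]
    b <- cal$beliefs[[c0]]
    l <- match(v, instance$cliques[[c0]])
    on <- instance$conf[[c0]][, l] == 1L
    tot <- logsumexp(b)
    p1[v] <- exp(logsumexp(b[on]) - tot)
  }
  if (!details) return(p1)
  # pairwise pattern probabilities for each owned (non-fill) edge
  npair <- nrow(instance$pair)
  pp <- matrix(0, npair, 4L, dimnames = list(NULL, .patterns))
  for (e in seq_len(npair)) {
    c0 <- instance$pair$owner[e]
    b <- cal$beliefs[[c0]]
    members <- instance$cliques[[c0]]
    cf <- instance$conf[[c0]]
    pidx <- pattern_index(cf[, match(instance$pair$i[e], members)],
                          cf[, match(instance$pair$j[e], members)])
    tot <- logsumexp(b)
    pp[e, ] <- exp(group_logsumexp(b, pidx, 4L) - tot)
  }
  logZ <- cal$score
  list(p1 = p1, pairwise = pp, logZ = logZ, beliefs = cal$beliefs)
}

#' MAP labelling by max-product message passing
#'
#' Exact maximum a posteriori label vector. Ties are broken toward label 1
#' and then toward the vector that prefers label 1 at the earliest residue
#' (decoded by clamping residues in index order and comparing the maximal
#' attainable scores, with a 1e-9 slack so that exact ties go to 1).
#'
#' @param instance a GraphModelInstance
#' @param params a CRFParameters object
#' @return integer vector of 0/1 labels
#' @export
infer_map <- function(instance, params) {
  n <- instance$n
  base <- clique_factors(instance, params)
  clamp <- rep(NA_integer_, n)
  for (v in seq_len(n)) {
    clamp[v] <- 1L
    s1 <- calibrate(instance, params, "max", clamp, factors = base)$score
    clamp[v] <- 0L
    s0 <- calibrate(instance, params, "max", clamp, factors = base)$score
    clamp[v] <- if (s1 >= s0 - 1e-9) 1L else 0L
  }
  clamp
}

#' Predict per-residue quality of one instance
#'
#' @param instance a GraphModelInstance
#' @param params a CRFParameters object
#' @return an object of class `QualityPrediction`: `map` (0/1 labels),
#'   `p1` (marginal probability of label 1), `fraction_good` (model-level
#'   fraction of label-1 residues in the MAP labelling)
#' @export
predict_quality <- function(instance, params) {
  p1 <- infer_marginals(instance, params)
  map <- infer_map(instance, params)
  structure(list(map = map, p1 = p1, fraction_good = mean(map == 1L)),
            class = "QualityPrediction")
}

#' @export
print.QualityPrediction <- function(x, ...) {
  cat(sprintf("QualityPrediction: %d residues, %.1f%% predicted good\n",
              length(x$map), 100 * x$fraction_good))
  invisible(x)
}

#' Sample label vectors from the CRF
#'
#' `method = "tree"` (default) draws exact samples by forward sampling on
#' the calibrated clique tree (root clique from its belief, then each
#' child conditioned on its separator); works for any size.
#' `method = "brute"` is the independent oracle route: inverse-CDF over
#' the full enumeration (<= 16 residues).
#'
#' @param instance a GraphModelInstance
#' @param params a CRFParameters object
#' @param nsamples number of label vectors to draw
#' @param method "tree" or "brute"
#' @return integer matrix (nsamples x n) of 0/1 labels
#' @export
sample_labels <- function(instance, params, nsamples,
                          method = c("tree", "brute")) {
  method <- match.arg(method)
  n <- instance$n
  if (method == "brute") {
    bf <- brute_force_distribution(instance, params)
    rows <- sample.int(nrow(bf$labelings), nsamples, replace = TRUE,
                       prob = bf$prob)
    return(bf$labelings[rows, , drop = FALSE])
  }
  cal <- calibrate(instance, params, "sum")
  out <- matrix(NA_integer_, nsamples, n)
  for (c0 in instance$order) {
    members <- instance$cliques[[c0]]
    cf <- instance$conf[[c0]]
    b <- cal$beliefs[[c0]]
    p <- exp(b - logsumexp(b))
    if (is.na(instance$parent[c0])) {
      rows <- sample.int(length(p), nsamples, replace = TRUE, prob = p)
    } else {
      sidx <- instance$sep_in_child[[c0]]
      sep <- sort(intersect(members, instance$cliques[[instance$parent[c0]]]))
      # separator pattern already assigned through the parent
      drawn_sep <- 1L +
        as.integer(out[, sep, drop = FALSE] %*%
                     bitwShiftL(1L, seq_along(sep) - 1L))
      rows <- integer(nsamples)
      for (sp in unique(drawn_sep)) {
        sel <- drawn_sep == sp
        ok <- which(sidx == sp)
        pc <- p[ok]
        if (sum(pc) <= 0) pc <- rep(1, length(ok))
        rows[sel] <- ok[sample.int(length(ok), sum(sel), replace = TRUE,
                                   prob = pc)]
      }
    }
    out[, members] <- cf[rows, , drop = FALSE]
  }
  out
}
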