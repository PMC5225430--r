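# Parameter training: stochastic gradient ascent on the conditional
# log-likelihood (observed minus expected sufficient statistics, with the
# expectations from exact sum-product marginals), plus the linear and
# logistic-regression baselines.

# Observed sufficient statistics of one labelled instance.
observed_stats <- function(instance, w) {
  y <- instance$labels
  if (is.null(y) || anyNA(y)) stop("instance lacks complete true labels")
  g_lambda <- colSums(instance$features[y == 1L, , drop = FALSE])
  g_omega <- numeric(4L)
  if (nrow(instance$pair) > 0L) {
    pidx <- pattern_index(y[instance$pair$i], y[instance$pair$j])
    wE <- w[instance$pair$class]
    for (p in 1:4) g_omega[p] <- sum(wE[pidx == p])
  }
  list(lambda = g_lambda, omega = g_omega)
}

# Gradient of the conditional log-likelihood of one instance w.r.t.
# (lambda1, omega): observed minus expected statistics.
crf_gradient <- function(instance, params) {
  obs <- observed_stats(instance, params$w)
  inf <- infer_marginals(instance, params, details = TRUE)
  e_lambda <- as.numeric(crossprod(instance$features, inf$p1))
  e_omega <- numeric(4L)
  if (nrow(instance$pair) > 0L) {
    wE <- params$w[instance$pair$class]
    e_omega <- as.numeric(crossprod(inf$pairwise, wE))
  }
  g <- list(lambda = obs$lambda - e_lambda, omega = obs$omega - e_omega,
            loglik = label_energy(instance, params, instance$labels) -
              inf$logZ)
  if (any(!is.finite(g$lambda)) || any(!is.finite(g$omega))) {
    stop("non-finite gradient encountered")
  }
  g
}

# Conditional log-likelihood of a labelled instance.
instance_loglik <- function(instance, params) {
  label_energy(instance, params, instance$labels) -
    calibrate(instance, params, "sum")$score
}

#' Train CRF parameters by stochastic gradient descent
#'
#' Maximises the sum over instances of log P(Y_true | X) minus an L2
#' penalty. One instance (= one structure model) per update; instance
#' order is reshuffled every epoch under the stated seed; the learning
#' rate decays as 1/sqrt(epoch). Parameters start at 0.
#'
#' @param dataset list of GraphModelInstance objects with true labels and
#'   normalised features
#' @param learning_rate base step size (default 0.05)
#' @param epochs number of passes over the dataset (default 50)
#' @param l2_penalty L2 regularisation strength (default 1e-3)
#' @param seed RNG seed for the per-epoch shuffles
#' @param w fixed edge-class weights used during training (default uniform)
#' @param average_tail if > 0, return the Polyak average of the parameter
#'   vectors at the end of the last `average_tail` epochs instead of the
#'   final iterate — damps stochastic-gradient oscillation on dense
#'   graphs, where the pairwise gradient scales with the edge count
#' @param ca_cutoff,neighbor_cutoff recorded in the returned parameters
#' @return a CRFParameters object; the per-epoch total training
#'   log-likelihood is in `meta$loglik_trace`
#' @export
train_sgd <- function(dataset, learning_rate = 0.05, epochs = 50L,
                      l2_penalty = 1e-3, seed = 1L,
                      w = stats::setNames(rep(1, 5), .edge_classes),
                      average_tail = 0L,
                      ca_cutoff = 5.0, neighbor_cutoff = 4.5) {
  stopifnot(length(dataset) > 0L)
  m <- dataset[[1]]$m
  fn <- colnames(dataset[[1]]$features) %||% paste0("f", seq_len(m))
  params <- crf_parameters(lambda1 = rep(0, m), omega = rep(0, 4), w = w,
                           feature_names = fn, ca_cutoff = ca_cutoff,
                           neighbor_cutoff = neighbor_cutoff)
  trace <- numeric(epochs)
  snaps <- vector("list", epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      lr <- learning_rate / sqrt(ep)
      for (idx in sample(length(dataset))) {
        inst <- dataset[[idx]]
        g <- tryCatch(crf_gradient(inst, params), error = function(e) {
          stop(sprintf("instance %d: %s", idx, conditionMessage(e)))
        })
        params$lambda1 <- params$lambda1 +
          lr * (g$lambda - 2 * l2_penalty * params$lambda1)
        params$omega <- params$omega +
          lr * (g$omega - 2 * l2_penalty * params$omega)
      }
      trace[ep] <- sum(vapply(dataset, instance_loglik, numeric(1),
                              params = params))
      snaps[[ep]] <- list(lambda1 = params$lambda1, omega = params$omega)
    }
  })
  if (average_tail > 0L) {
    tail_ix <- seq.int(max(1L, epochs - average_tail + 1L), epochs)
    params$lambda1 <- Reduce(`+`, lapply(snaps[tail_ix], `[[`,
                                         "lambda1")) / length(tail_ix)
    params$omega <- Reduce(`+`, lapply(snaps[tail_ix], `[[`,
                                       "omega")) / length(tail_ix)
  }
  params$meta <- list(seed = seed, epochs = epochs,
                      learning_rate = learning_rate,
                      l2_penalty = l2_penalty,
                      average_tail = as.integer(average_tail),
                      loglik_trace = trace)
  params
}

#' Linear-baseline prediction (1.0 Angstrom neighbour cutoff)
#'
#' The identical pipeline run with a neighbour cutoff of 1.0 Angstrom,
#' well below the ~3.8 Angstrom consecutive Calpha spacing, so the graph
#' reduces to chain edges plus their one-step shared-neighbour triangles
#' and carries essentially no spatial neighbourhood information.
#'
#' @param model a StructureModel
#' @param features normalised feature matrix
#' @param params a CRFParameters object (trained at the 1.0 cutoff)
#' @param ss optional secondary-structure string
#' @return a QualityPrediction
#' @export
predict_linear_baseline <- function(model, features, params, ss = NULL) {
  inst <- gmq_instance(model, features, neighbor_cutoff = 1.0, ss = ss)
  predict_quality(inst, params)
}

#' Maximum-likelihood logistic regression
#'
#' Fits P(y = 1 | x) = 1 / (1 + exp(-(b0 + x b))) by quasi-Newton ascent
#' of the exact log-likelihood (analytic gradient, convergence tolerance
#' 1e-8). Under perfect separation the likelihood has no maximiser;
#' iterations are capped with a warning.
#'
#' @param X numeric matrix (observations x features)
#' @param y 0/1 response vector
#' @param max_iter iteration cap
#' @return list with `coef` (intercept first), `converged`, `loglik`
#' @export
logistic_fit <- function(X, y, max_iter = 500L) {
  X1 <- cbind(1, as.matrix(X))
  y <- as.numeric(y)
  nll <- function(b) {
    eta <- as.numeric(X1 %*% b)
    sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta)
  }
  grad <- function(b) {
    p <- 1 / (1 + exp(-as.numeric(X1 %*% b)))
    as.numeric(crossprod(X1, p - y))
  }
  fit <- stats::optim(rep(0, ncol(X1)), nll, grad, method = "BFGS",
                      control = list(maxit = max_iter, reltol = 1e-12))
  sep_warn <- max(abs(fit$par)) > 15
  if (sep_warn) {
    warning("possible perfect separation: coefficients capped by the ",
            "iteration limit")
  }
  list(coef = fit$par, converged = fit$convergence == 0 || sep_warn,
       loglik = -fit$value)
}

#' Logistic-regression baseline for per-residue quality
#'
#' Binary classification of each residue from its features alone (no
#' neighbourhood information), thresholded at probability 0.5.
#'
#' @param train_features,train_labels stacked normalised training residues
#' @param test_features residues to classify
#' @return list with `labels` (0/1), `p1`, and the `fit`
#' @export
logistic_regression_baseline <- function(train_features, train_labels,
                                         test_features) {
  fit <- logistic_fit(train_features, train_labels)
  eta <- as.numeric(cbind(1, as.matrix(test_features)) %*% fit$coef)
  p1 <- 1 / (1 + exp(-eta))
  list(labels = as.integer(p1 >= 0.5), p1 = p1, fit = fit)
}
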