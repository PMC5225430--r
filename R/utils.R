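# Small numeric helpers shared across modules.

#' Numerically stable log-sum-exp
#' @param x numeric vector (may contain -Inf)
#' @return log(sum(exp(x)))
#' @keywords internal
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Group-wise log-sum-exp: for each group id in 1..ngroup, logsumexp of the
# x values whose group index matches. Returns a vector of length ngroup
# (-Inf for empty groups). Vectorised via rowsum() for speed.
group_logsumexp <- function(x, group, ngroup) {
  m <- max(x)
  if (!is.finite(m)) return(rep(m, ngroup))
  s <- rowsum(exp(x - m), group)
  out <- rep(-Inf, ngroup)
  out[as.integer(rownames(s))] <- m + log(s[, 1])
  out
}

# Group-wise maximum; ascending sort then overwrite, so the last (largest)
# value per group wins.
group_max <- function(x, group, ngroup) {
  o <- order(x)
  out <- rep(-Inf, ngroup)
  out[group[o]] <- x[o]
  out
}

# All binary label configurations over k variables, as a (2^k x k) 0/1
# matrix. Column j is variable j; variable 1 is the least significant bit,
# so row r encodes r-1 in binary. k = 0 gives a single empty configuration.
binary_configs <- function(k) {
  if (k == 0L) return(matrix(0L, nrow = 1L, ncol = 0L))
  n <- bitwShiftL(1L, k)
  m <- matrix(0L, nrow = n, ncol = k)
  for (j in seq_len(k)) {
    m[, j] <- bitwAnd(bitwShiftR(seq_len(n) - 1L, j - 1L), 1L)
  }
  m
}

# Index (1-based) of each row of a 0/1 configuration matrix restricted to
# columns `cols`, using the same LSB-first encoding as binary_configs().
config_index <- function(conf, cols) {
  if (length(cols) == 0L) return(rep(1L, nrow(conf)))
  pw <- bitwShiftL(1L, seq_along(cols) - 1L)
  as.integer(conf[, cols, drop = FALSE] %*% pw) + 1L
}

# Deterministic RNG scope: evaluates expr with the given seed, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Format a double so that it round-trips bit-exactly through as.numeric().
fmt_num <- function(x) sprintf("%.17g", x)
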