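# Synthetic data: toy Calpha traces with known geometry, perturbed models
# with planted per-residue errors, and datasets sampled from a CRF with
# known parameters. Every generator is a pure function of its seed.

#' Generate a toy Calpha trace with a prescribed secondary structure
#'
#' H runs get ideal alpha-helix geometry (rise 1.5 Angstrom, 100 degrees
#' per residue, radius 2.3 Angstrom), B runs extended strand geometry
#' (3.5 Angstrom rise with a small zigzag), C runs a jittered random walk;
#' consecutive Calpha spacing is 3.8 +/- 0.1 Angstrom throughout.
#'
#' @param n_residues chain length (>= 2)
#' @param ss_layout string over {H,B,C} of length `n_residues`; default
#'   all coil
#' @param seed RNG seed (fully determines the output)
#' @param model_id identifier
#' @return a StructureModel; the layout is stored as attribute `ss`
#' @export
generate_toy_structure <- function(n_residues, ss_layout = NULL, seed = 1L,
                                   model_id = "toy") {
  if (is.null(ss_layout)) ss_layout <- strrep("C", n_residues)
  codes <- strsplit(ss_layout, "")[[1]]
  if (length(codes) != n_residues) {
    stop("ss_layout length must equal n_residues")
  }
  if (!all(codes %in% c("H", "B", "C"))) {
    stop("ss_layout must use alphabet {H,B,C}")
  }
  runs <- rle(codes)
  coords <- with_seed(seed, {
    rand_unit <- function() {
      v <- stats::rnorm(3)
      v / sqrt(sum(v^2))
    }
    rand_rot <- function() {
      # QR of a random Gaussian matrix, made proper
      q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
      if (det(q) < 0) q[, 1] <- -q[, 1]
      q
    }
    segment <- function(type, len) {
      t <- seq_len(len) - 1L
      if (type == "H") {
        cbind(2.3 * cos(t * 100 * pi / 180),
              2.3 * sin(t * 100 * pi / 180),
              1.5 * t)
      } else if (type == "B") {
        # 3.5 A rise with +/-0.74 A zigzag: consecutive spacing 3.8 A
        cbind(3.5 * t, 0.74 * ifelse(t %% 2 == 0L, 1, -1), rep(0, len))
      } else {
        # turny random walk, step length 3.8 (turns keep d(i,i+2) well
        # below the extended-strand range)
        p <- matrix(0, len, 3)
        dir <- rand_unit()
        if (len > 1L) {
          for (r in 2:len) {
            dir <- 0.45 * dir + rand_unit()
            dir <- dir / sqrt(sum(dir^2))
            p[r, ] <- p[r - 1L, ] + 3.8 * dir
          }
        }
        p
      }
    }
    out <- matrix(NA_real_, n_residues, 3)
    pos <- 1L
    end <- c(0, 0, 0)
    for (s in seq_along(runs$lengths)) {
      len <- runs$lengths[s]
      seg <- segment(runs$values[s], len)
      seg <- seg %*% t(rand_rot())
      if (pos == 1L) {
        seg <- sweep(seg, 2, seg[1, ] - end)
      } else {
        seg <- sweep(seg, 2, seg[1, ] - (end + 3.8 * rand_unit()))
      }
      out[pos:(pos + len - 1L), ] <- seg
      end <- seg[len, ]
      pos <- pos + len
    }
    out
  })
  sm <- structure_model(seq_len(n_residues), rep("ALA", n_residues), coords,
                        model_id = model_id)
  attr(sm, "ss") <- ss_layout
  sm
}

#' Generate an antiparallel two-strand hairpin toy
#'
#' Two extended strands run antiparallel at `strand_sep` Angstrom with a
#' short two-residue turn, so residues i and n+1-i are spatial neighbours
#' despite being sequence-distant — the geometry that makes cliques join
#' residues of adjacent beta-strands. A small coordinate jitter
#' distinguishes models drawn with different seeds.
#'
#' @param n_residues chain length (>= 8)
#' @param strand_sep inter-strand Calpha distance in Angstrom (default
#'   4.8, typical for adjacent strands of a sheet)
#' @param jitter coordinate noise sd in Angstrom (default 0.05)
#' @param seed RNG seed
#' @return a StructureModel (attribute `ss` = all coil, since the
#'   Calpha-only strand assignment is left to the caller)
#' @export
generate_hairpin_structure <- function(n_residues, strand_sep = 4.8,
                                       jitter = 0.05, seed = 1L) {
  if (n_residues < 8L) stop("hairpin needs at least 8 residues")
  k <- (n_residues - 2L) %/% 2L
  t1 <- 0:(k - 1L)
  s1 <- cbind(3.5 * t1, 0.74 * (t1 %% 2), 0)
  turn <- rbind(c(3.5 * (k - 1L) + 2.5, 2.4, 1.2),
                c(3.5 * (k - 1L) + 2.5, strand_sep, 1.2))
  t2 <- (k - 1L):0
  s2 <- cbind(3.5 * t2, strand_sep + 0.74 * (seq_len(k) %% 2), 0)
  co <- rbind(s1, turn, s2)[seq_len(n_residues), , drop = FALSE]
  co <- with_seed(seed, co + matrix(stats::rnorm(3 * n_residues,
                                                 sd = jitter),
                                    n_residues, 3))
  sm <- structure_model(seq_len(n_residues), rep("ALA", n_residues), co,
                        model_id = "hairpin")
  attr(sm, "ss") <- strrep("C", n_residues)
  sm
}

#' Perturb a structure with planted, regionally correlated errors
#'
#' The displacement profile assigns an error magnitude (Angstrom) to every
#' residue; maximal runs of a constant magnitude form regions. Each region
#' with positive magnitude gets one shared random displacement direction,
#' plus smaller per-residue Gaussian noise, emulating the way modelling
#' errors occur in units of secondary-structure-element-sized fragments
#' rather than sporadically.
#'
#' @param native a StructureModel
#' @param displacement_profile numeric vector of magnitudes >= 0, one per
#'   residue
#' @param seed RNG seed
#' @return a perturbed StructureModel
#' @export
perturb_model <- function(native, displacement_profile, seed = 1L) {
  n <- length(native$residue_index)
  prof <- displacement_profile
  if (length(prof) != n) stop("displacement profile length mismatch")
  if (any(prof < 0)) stop("displacement magnitudes must be >= 0")
  coords <- with_seed(seed, {
    out <- native$coords
    runs <- rle(prof)
    pos <- 1L
    for (s in seq_along(runs$lengths)) {
      len <- runs$lengths[s]
      mag <- runs$values[s]
      if (mag > 0) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        idx <- pos:(pos + len - 1L)
        noise <- matrix(stats::rnorm(3 * len, sd = mag / 4), len, 3)
        out[idx, ] <- out[idx, ] +
          matrix(mag * u, len, 3, byrow = TRUE) + noise
      }
      pos <- pos + len
    }
    out
  })
  sm <- structure_model(native$residue_index, native$residue_name, coords,
                        model_id = paste0(native$model_id, "_perturbed"),
                        chain_id = native$chain_id)
  attr(sm, "ss") <- attr(native, "ss")
  sm
}

#' Specification of a synthetic CRF dataset
#'
#' @param n_models number of models to sample
#' @param n_residues residues per model
#' @param ss_layout secondary-structure layout string (shared by all
#'   models; coil segments are re-jittered per model)
#' @param mu per-feature class-conditional mean shift: feature i of a
#'   residue with label y is drawn N(mu_i * (2y - 1), sd^2). The implied
#'   true lambda difference is 2 mu / sd^2.
#' @param omega_star planted pairwise weights (00, 01, 10, 11)
#' @param w edge-class weights used when planting labels
#' @param feature_noise_sd Gaussian feature noise sd (default 1)
#' @param neighbor_cutoff graph cutoff used for planting and later training
#' @param topology "chain" (toy trace following `ss_layout`) or "hairpin"
#'   (antiparallel two-strand fold whose graph has sequence-distant
#'   spatial edges)
#' @param seed master seed
#' @return a list of class `SyntheticSpec`
#' @export
synthetic_spec <- function(n_models = 200L, n_residues = 15L,
                           ss_layout = NULL,
                           mu = c(1.0, -0.8, 0.6, -0.4, 0.2),
                           omega_star = c(0.5, -0.3, -0.3, 1.0),
                           w = stats::setNames(rep(1, 5), .edge_classes),
                           feature_noise_sd = 1.0,
                           neighbor_cutoff = 4.5,
                           topology = c("chain", "hairpin"), seed = 1L) {
  topology <- match.arg(topology)
  if (is.null(ss_layout)) {
    if (topology == "hairpin") {
      ss_layout <- strrep("C", n_residues)
    } else {
      nh <- ceiling(n_residues / 2)
      ss_layout <- paste0(strrep("H", nh), strrep("C", n_residues - nh))
    }
  }
  if (nchar(ss_layout) != n_residues) stop("ss_layout length mismatch")
  structure(list(n_models = as.integer(n_models),
                 n_residues = as.integer(n_residues),
                 ss_layout = ss_layout, mu = mu,
                 omega_star = as.numeric(omega_star), w = w,
                 feature_noise_sd = feature_noise_sd,
                 neighbor_cutoff = neighbor_cutoff, topology = topology,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Sample a synthetic dataset from a CRF with known parameters
#'
#' For each model a toy structure is generated, its residue graph and
#' clique tree built, a label vector drawn from the pairwise label field
#' (weights `omega_star`, edge-class weights `w`), and features drawn as
#' label-conditioned Gaussians N(+/- mu, sd^2). The implied posterior
#' P(Y|X) is exactly a CRF of this package's form with lambda difference
#' 2 mu / sd^2 and pairwise weights `omega_star`, enabling parameter
#' recovery experiments.
#'
#' @param spec a [synthetic_spec()]
#' @param sampler "tree" (exact forward sampling on the clique tree, any
#'   size) or "brute" (inverse-CDF over full enumeration, <= 16 residues)
#' @return list with `instances` (GraphModelInstance list, features and
#'   labels filled, features flagged normalised), `entries`
#'   ([gmq_entry()] list for the CV API) and `theta_star`
#' @export
sample_crf_dataset <- function(spec, sampler = c("tree", "brute")) {
  sampler <- match.arg(sampler)
  m <- length(spec$mu)
  prior <- crf_parameters(lambda1 = rep(0, m), omega = spec$omega_star,
                          w = spec$w,
                          neighbor_cutoff = spec$neighbor_cutoff)
  instances <- vector("list", spec$n_models)
  entries <- vector("list", spec$n_models)
  topology <- spec$topology %||% "chain"
  for (i in seq_len(spec$n_models)) {
    sm <- if (topology == "hairpin") {
      generate_hairpin_structure(spec$n_residues,
                                 seed = spec$seed + 7919L * i)
    } else {
      generate_toy_structure(spec$n_residues, spec$ss_layout,
                             seed = spec$seed + 7919L * i,
                             model_id = sprintf("synth%03d", i))
    }
    blank <- matrix(0, spec$n_residues, m,
                    dimnames = list(NULL, paste0("f", seq_len(m))))
    inst0 <- gmq_instance(sm, blank, neighbor_cutoff = spec$neighbor_cutoff,
                          ss = spec$ss_layout)
    y <- with_seed(spec$seed + 7919L * i + 1L,
                   sample_labels(inst0, prior, 1L, method = sampler))[1, ]
    X <- with_seed(spec$seed + 7919L * i + 2L, {
      matrix(stats::rnorm(spec$n_residues * m, sd = spec$feature_noise_sd),
             spec$n_residues, m) +
        outer(2 * y - 1, spec$mu)
    })
    colnames(X) <- paste0("f", seq_len(m))
    attr(X, "normalized") <- TRUE
    instances[[i]] <- build_instance(inst0$graph, inst0$tree, X, labels = y)
    entries[[i]] <- gmq_entry(sm, X, y, ss = spec$ss_layout)
  }
  list(instances = instances, entries = entries,
       theta_star = list(
         lambda_diff = 2 * spec$mu / spec$feature_noise_sd^2,
         omega = stats::setNames(spec$omega_star, .patterns),
         w = spec$w))
}

#' Write an aligned FASTA file
#'
#' @param seqs named character vector of aligned sequences (equal length,
#'   `-` gaps)
#' @param path output file
#' @export
write_msa_fasta <- function(seqs, path) {
  if (length(unique(nchar(seqs))) != 1L) stop("sequences must align")
  nm <- names(seqs) %||% paste0("seq", seq_along(seqs))
  writeLines(as.vector(rbind(paste0(">", nm), seqs)), path)
  invisible(path)
}

#' Write a feature TSV in the dialect read by [ingest_external_scores()]
#'
#' Local features get one row per residue; global features one MODEL row.
#'
#' @param values feature matrix (residues x features, named columns)
#' @param residue_index residue indices for the per-residue rows
#' @param local character vector of column names to write per residue;
#'   the rest are written once as MODEL rows (first residue's value)
#' @param path output file
#' @export
write_feature_tsv <- function(values, residue_index, local, path) {
  cols <- colnames(values)
  header <- paste(c("residue_index", cols), collapse = "\t")
  res_rows <- vapply(seq_along(residue_index), function(r) {
    vals <- ifelse(cols %in% local, fmt_num(values[r, ]), "")
    paste(c(residue_index[r], vals), collapse = "\t")
  }, character(1))
  model_vals <- ifelse(cols %in% local, "", fmt_num(values[1, ]))
  model_row <- paste(c("MODEL", model_vals), collapse = "\t")
  writeLines(c(header, res_rows, model_row), path)
  invisible(path)
}
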