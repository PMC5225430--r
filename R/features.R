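# The 25-dimensional per-residue feature vectors: schema, computed
# features (contact order, MSA column features, log/ratio transforms),
# ingestion of externally produced scores, and Z-score normalisation
# against the training distribution.

.log_floor <- 1e-6

#' The 25-feature schema
#'
#' Ordered feature names with local/global and computed/ingested flags.
#' Six features are local (per-residue); the rest are global (constant
#' across residues of a model). Externally produced scores (ANOLEA, DOPE,
#' TAP, PROCHECK, Verify3D, PRSS, SPAD, GA341, pG, ProQ) are ingested from
#' files, never recomputed; contact order, model length, the MSA column
#' features and the log/ratio transforms are computed here.
#'
#' @return data.frame with columns `name`, `local`, `computed`
#' @export
feature_schema <- function() {
  df <- data.frame(
    name = c("anolea1", "anolea2", "dope", "tap", "procheck_disallowed",
             "verify3d_local", "verify3d", "verify3d_L2", "log_verify3d_L2",
             "mutation_score", "gap_ratio", "conservation",
             "prss", "spad_local", "spad", "log_spad", "log_lspad_ratio",
             "contact_order", "relative_contact_order",
             "model_length", "aligned_length",
             "ga341", "pg", "proq_maxsub", "proq_lg"),
    local = FALSE, computed = FALSE, stringsAsFactors = FALSE)
  df$local[df$name %in% c("verify3d_local", "mutation_score", "gap_ratio",
                          "conservation", "spad_local", "log_lspad_ratio")] <- TRUE
  df$computed[df$name %in% c("verify3d_L2", "log_verify3d_L2",
                             "mutation_score", "gap_ratio", "conservation",
                             "log_spad", "log_lspad_ratio",
                             "contact_order", "relative_contact_order",
                             "model_length")] <- TRUE
  stopifnot(nrow(df) == 25L, sum(df$local) == 6L)
  df
}

#' The five-feature subset
#'
#' The reduced feature view selected by forward feature selection in
#' earlier regression work: local Verify3D, log(SPAD), log(Verify3D/L^2),
#' gap ratio and log(lSPAD/(SPAD+1)).
#'
#' @return character vector of 5 schema names
#' @export
feature_subset5 <- function() {
  c("verify3d_local", "log_spad", "log_verify3d_L2", "gap_ratio",
    "log_lspad_ratio")
}

#' Contact order of a Calpha trace
#'
#' A contact is a residue pair with Calpha-Calpha distance within
#' `contact_cutoff` and sequence separation >= 2. Contact order is the mean
#' sequence separation |i - j| over contacts; the relative version divides
#' by the chain length.
#'
#' @param model a StructureModel
#' @param contact_cutoff contact distance in Angstrom (default 8)
#' @return list with `co` (residues) and `relative_co` (dimensionless);
#'   both 0 (with a warning) when there are no contacts
#' @export
compute_contact_order <- function(model, contact_cutoff = 8.0) {
  n <- length(model$residue_index)
  D <- as.matrix(stats::dist(model$coords))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  sel <- upper.tri(D) & D <= contact_cutoff & sep >= 2L
  if (!any(sel)) {
    warning("no contacts found; contact order set to 0")
    return(list(co = 0, relative_co = 0))
  }
  co <- mean(sep[sel])
  list(co = co, relative_co = co / n)
}

#' Read an aligned FASTA multiple sequence alignment
#'
#' @param path aligned FASTA file
#' @return character matrix (sequences x columns) of upper-case letters
#'   and `-` gaps, rownames = sequence names
#' @export
read_msa <- function(path) {
  aln <- Biostrings::readBStringSet(path)
  if (length(unique(Biostrings::width(aln))) != 1L) {
    stop("format error: ragged alignment (sequences of unequal length)")
  }
  m <- do.call(rbind, strsplit(toupper(as.character(aln)), ""))
  rownames(m) <- names(aln)
  m[m == "."] <- "-"
  m
}

#' MSA column features for a target sequence
#'
#' For every alignment column where the target row holds a residue:
#' \itemize{
#'   \item mutation score: mean BLOSUM45 score over all unordered pairs of
#'     non-gap residues in the column (gaps excluded from pairing);
#'   \item gap ratio: fraction of gaps in the column;
#'   \item conservation: count of the most abundant residue type divided by
#'     the number of rows (gaps count in the denominator, never as the most
#'     abundant type).
#' }
#'
#' @param msa character matrix from [read_msa()] (or equivalent); all rows
#'   equal length
#' @param target_row row index of the target sequence
#' @return data.frame, one row per target residue, with columns
#'   `column`, `mutation_score`, `gap_ratio`, `conservation`
#' @export
compute_msa_features <- function(msa, target_row = 1L) {
  if (!is.matrix(msa)) {
    lens <- lengths(msa)
    if (length(unique(lens)) != 1L) stop("format error: ragged alignment")
    msa <- do.call(rbind, msa)
  }
  cols <- which(msa[target_row, ] != "-")
  out <- data.frame(column = cols, mutation_score = NA_real_,
                    gap_ratio = NA_real_, conservation = NA_real_)
  nrow_msa <- nrow(msa)
  for (k in seq_along(cols)) {
    col <- msa[, cols[k]]
    resid <- col[col != "-"]
    out$gap_ratio[k] <- sum(col == "-") / nrow_msa
    tab <- table(resid)
    out$conservation[k] <- max(tab) / nrow_msa
    if (length(resid) >= 2L) {
      prs <- utils::combn(resid, 2L)
      out$mutation_score[k] <- mean(blosum45(prs[1, ], prs[2, ]))
    } else {
      out$mutation_score[k] <- 0
    }
  }
  out
}

#' Fill in the derived log/ratio transforms of a raw feature table
#'
#' Computes verify3d_L2 = Verify3D / L^2, log_verify3d_L2, log_spad and
#' log_lspad_ratio = log(lSPAD / (SPAD + 1)) with natural logs. Non-positive
#' log arguments are clamped to 1e-6 with a warning.
#'
#' @param values numeric matrix (residues x features, schema column names)
#'   with verify3d, spad, spad_local and model_length present
#' @return the matrix with the four derived columns filled
#' @export
derived_transforms <- function(values) {
  need <- c("verify3d", "spad", "spad_local", "model_length")
  if (!all(need %in% colnames(values))) {
    stop("derived transforms need columns: ", paste(need, collapse = ", "))
  }
  L <- values[, "model_length"]
  clog <- function(x, what) {
    bad <- is.finite(x) & x <= 0
    if (any(bad)) {
      warning(sprintf("%d non-positive %s value(s) clamped to %g before log",
                      sum(bad), what, .log_floor))
      x[bad] <- .log_floor
    }
    log(x)
  }
  values[, "verify3d_L2"] <- values[, "verify3d"] / L^2
  values[, "log_verify3d_L2"] <- clog(values[, "verify3d_L2"], "Verify3D/L^2")
  values[, "log_spad"] <- clog(values[, "spad"], "SPAD")
  values[, "log_lspad_ratio"] <-
    clog(values[, "spad_local"] / (values[, "spad"] + 1), "lSPAD/(SPAD+1)")
  values
}

#' Ingest externally produced feature scores from a TSV file
#'
#' The file has a header whose first column is `residue_index` and whose
#' remaining columns are schema feature names. Per-residue rows are keyed
#' by residue index; rows keyed `MODEL` hold per-model (global) values that
#' are broadcast to all residues. Columns absent from the file are left
#' `NA` and flagged for mean imputation (0 after Z-scoring).
#'
#' @param path TSV file
#' @param model the StructureModel the scores belong to
#' @param schema a [feature_schema()] data.frame
#' @return numeric matrix (residues x 25) with attribute `imputed`
#'   (character vector of imputed column names)
#' @export
ingest_external_scores <- function(path, model, schema = feature_schema()) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = "character")
  if (colnames(tab)[1] != "residue_index") {
    stop("schema error: first column must be 'residue_index'")
  }
  feat_cols <- colnames(tab)[-1]
  unknown <- setdiff(feat_cols, schema$name)
  if (length(unknown) > 0L) {
    stop("schema error: unknown feature column(s): ",
         paste(unknown, collapse = ", "))
  }
  n <- length(model$residue_index)
  values <- matrix(NA_real_, n, nrow(schema),
                   dimnames = list(NULL, schema$name))
  is_model_row <- tab$residue_index == "MODEL"
  res_rows <- tab[!is_model_row, , drop = FALSE]
  if (nrow(res_rows) > 0L) {
    ridx <- as.integer(res_rows$residue_index)
    if (nrow(res_rows) != n || !setequal(ridx, model$residue_index)) {
      stop(sprintf("format error: %d residue rows for a %d-residue model",
                   nrow(res_rows), n))
    }
    pos <- match(model$residue_index, ridx)
    for (f in feat_cols) {
      v <- suppressWarnings(as.numeric(res_rows[[f]]))
      values[, f] <- v[pos]
    }
  }
  for (r in which(is_model_row)) {
    for (f in feat_cols) {
      v <- suppressWarnings(as.numeric(tab[[f]][r]))
      if (!is.na(v)) values[, f] <- v   # broadcast per-model value
    }
  }
  attr(values, "imputed") <- setdiff(schema$name, feat_cols)
  values
}

#' Assemble the raw 25-feature table of one model
#'
#' Combines ingested external scores, features computed from the structure
#' (contact order, relative contact order, model length) and from the MSA
#' (mutation score, gap ratio, conservation), then fills the derived
#' transforms. The result is a raw (unnormalised) feature matrix.
#'
#' @param model a StructureModel
#' @param external path to an external-score TSV, or a matrix from
#'   [ingest_external_scores()], or `NULL`
#' @param msa character matrix from [read_msa()], or `NULL`
#' @param msa_target_row target sequence row in the MSA
#' @param contact_cutoff contact-order contact cutoff (Angstrom)
#' @return numeric matrix (residues x 25, schema column names), attribute
#'   `imputed` listing columns that will be mean-imputed
#' @export
assemble_features <- function(model, external = NULL, msa = NULL,
                              msa_target_row = 1L, contact_cutoff = 8.0) {
  schema <- feature_schema()
  n <- length(model$residue_index)
  if (is.character(external)) {
    values <- ingest_external_scores(external, model, schema)
  } else if (is.matrix(external)) {
    values <- external
  } else {
    values <- matrix(NA_real_, n, nrow(schema),
                     dimnames = list(NULL, schema$name))
    attr(values, "imputed") <- schema$name
  }
  imputed <- attr(values, "imputed") %||% character(0)
  co <- compute_contact_order(model, contact_cutoff)
  values[, "contact_order"] <- co$co
  values[, "relative_contact_order"] <- co$relative_co
  values[, "model_length"] <- n
  imputed <- setdiff(imputed, c("contact_order", "relative_contact_order",
                                "model_length"))
  if (!is.null(msa)) {
    mf <- compute_msa_features(msa, msa_target_row)
    if (nrow(mf) != n) {
      stop(sprintf("format error: MSA maps %d target residues, model has %d",
                   nrow(mf), n))
    }
    values[, "mutation_score"] <- mf$mutation_score
    values[, "gap_ratio"] <- mf$gap_ratio
    values[, "conservation"] <- mf$conservation
    imputed <- setdiff(imputed, c("mutation_score", "gap_ratio",
                                  "conservation"))
  }
  if (all(c("verify3d", "spad", "spad_local") %in%
          colnames(values)[colSums(!is.na(values)) > 0])) {
    values <- derived_transforms(values)
    imputed <- setdiff(imputed, c("verify3d_L2", "log_verify3d_L2",
                                  "log_spad", "log_lspad_ratio"))
  }
  attr(values, "imputed") <- imputed
  values
}

#' Fit a Z-score normaliser on training residues
#'
#' Per-feature mean and population standard deviation estimated on the
#' training rows only (`NA` values are ignored; they stand for scores to
#' be mean-imputed). Zero-variance features map to 0 everywhere with a
#' warning.
#'
#' @param train numeric matrix of training residues x features
#' @return an object of class `ZScore` with `center` and `scale`
#' @export
zscore_fit <- function(train) {
  if (is.null(dim(train)) || nrow(train) == 0L) stop("empty training table")
  center <- colMeans(train, na.rm = TRUE)
  pop_sd <- apply(train, 2, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(0)
    sqrt(mean((x - mean(x))^2))
  })
  zero <- pop_sd == 0 | !is.finite(pop_sd)
  if (any(zero)) {
    warning(sprintf("%d zero-variance feature(s) mapped to 0: %s", sum(zero),
                    paste(colnames(train)[zero], collapse = ", ")))
  }
  center[!is.finite(center)] <- 0
  structure(list(center = center, scale = pop_sd), class = "ZScore")
}

#' Apply a fitted Z-score normaliser
#'
#' `NA` entries become 0 (training-set mean imputation); zero-variance
#' features become 0.
#'
#' @param fit a `ZScore` object from [zscore_fit()]
#' @param values numeric matrix, same columns as the training table
#' @return normalised matrix
#' @export
zscore_transform <- function(fit, values) {
  out <- sweep(values, 2, fit$center, "-")
  sc <- ifelse(fit$scale > 0, fit$scale, 1)
  out <- sweep(out, 2, sc, "/")
  out[, fit$scale == 0] <- 0
  out[is.na(out)] <- 0
  attr(out, "normalized") <- TRUE
  out
}

#' Fit on a training table and transform it plus any further tables
#'
#' @param train training feature matrix
#' @param ... further matrices transformed with the training fit
#' @return list with `fit`, `train`, and one element per extra table
#' @export
zscore_fit_transform <- function(train, ...) {
  fit <- zscore_fit(train)
  extra <- lapply(list(...), function(v) zscore_transform(fit, v))
  c(list(fit = fit, train = zscore_transform(fit, train)), extra)
}
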