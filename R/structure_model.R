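# Structure models: PDB parsing, Kabsch superposition, Calpha-based
# secondary structure assignment.

#' Construct a StructureModel
#'
#' A `StructureModel` is an ordered Calpha trace: one row per residue with a
#' 1-based residue index (strictly increasing), a 3-letter residue name and
#' a Calpha coordinate in Angstrom.
#'
#' @param residue_index integer vector, strictly increasing
#' @param residue_name character vector of 3-letter codes
#' @param coords numeric matrix (n x 3) of Calpha coordinates in Angstrom
#' @param model_id,chain_id identifiers
#' @return an object of class `StructureModel`
#' @export
structure_model <- function(residue_index, residue_name, coords,
                            model_id = "model", chain_id = "A") {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  n <- length(residue_index)
  if (n < 2L) stop("a StructureModel needs at least 2 residues")
  if (nrow(coords) != n || ncol(coords) != 3L) {
    stop("coords must be an n x 3 matrix matching residue_index")
  }
  if (length(residue_name) != n) stop("residue_name length mismatch")
  if (any(diff(residue_index) <= 0)) {
    stop("residue_index must be strictly increasing")
  }
  structure(list(residue_index = as.integer(residue_index),
                 residue_name = as.character(residue_name),
                 coords = coords,
                 model_id = model_id, chain_id = chain_id),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("StructureModel '%s' chain %s: %d residues (%d..%d)\n",
              x$model_id, x$chain_id, length(x$residue_index),
              min(x$residue_index), max(x$residue_index)))
  invisible(x)
}

#' @export
length.StructureModel <- function(x) length(x$residue_index)

#' Read a structure model from PDB text
#'
#' Parses ATOM records (wwPDB v3.3 fixed columns), keeps Calpha atoms of a
#' single chain, resolves alternate locations by keeping the first, and
#' ignores HETATM. Residues that appear in ATOM records but lack a CA atom
#' are dropped with a warning.
#'
#' @param pdb_text character scalar (whole file) or vector of lines
#' @param chain chain identifier; `NULL` selects the first chain seen
#' @param model_id identifier stored in the result
#' @return a [structure_model()] object
#' @export
read_model <- function(pdb_text, chain = NULL, model_id = "model") {
  lines <- if (length(pdb_text) == 1L && grepl("\n", pdb_text)) {
    strsplit(pdb_text, "\n", fixed = TRUE)[[1]]
  } else as.character(pdb_text)
  atom <- lines[startsWith(lines, "ATOM  ")]
  if (length(atom) == 0L) {
    stop("PDB parse error: no ATOM records",
         if (!is.null(chain)) sprintf(" (chain %s)", chain) else "")
  }
  bad <- which(nchar(atom) < 54L)
  if (length(bad) > 0L) {
    stop(sprintf("PDB parse error: malformed ATOM line %d (too short)",
                 match(atom[bad[1]], lines)))
  }
  fld <- function(from, to) trimws(substr(atom, from, to))
  atom_name <- fld(13, 16)
  altloc    <- substr(atom, 17, 17)
  res_name  <- fld(18, 20)
  chain_id  <- substr(atom, 22, 22)
  res_seq   <- fld(23, 26)
  icode     <- substr(atom, 27, 27)
  xyz <- cbind(as.numeric(fld(31, 38)), as.numeric(fld(39, 46)),
               as.numeric(fld(47, 54)))
  if (anyNA(xyz)) {
    stop(sprintf("PDB parse error: non-numeric coordinates at ATOM line %d",
                 match(atom[which(rowSums(is.na(xyz)) > 0)[1]], lines)))
  }
  if (is.null(chain)) chain <- chain_id[1]
  sel <- chain_id == chain
  if (!any(sel)) stop(sprintf("PDB parse error: chain %s not found", chain))
  atom_name <- atom_name[sel]; altloc <- altloc[sel]
  res_name <- res_name[sel]; res_seq <- res_seq[sel]
  icode <- icode[sel]; xyz <- xyz[sel, , drop = FALSE]

  # Residue key: (resSeq, iCode); ordering follows file order of first
  # appearance, which is the wwPDB ordering for a single chain.
  key <- paste0(res_seq, icode)
  seen <- unique(key)
  is_ca <- atom_name == "CA"
  if (!any(is_ca)) {
    stop(sprintf("PDB parse error: no CA atoms in chain %s", chain))
  }
  # First altloc of CA per residue.
  ca_first <- !duplicated(key[is_ca])
  ca_key <- key[is_ca][ca_first]
  ca_xyz <- xyz[is_ca, , drop = FALSE][ca_first, , drop = FALSE]
  ca_name <- res_name[is_ca][ca_first]
  missing_ca <- setdiff(seen, ca_key)
  if (length(missing_ca) > 0L) {
    warning(sprintf("dropping %d residue(s) without a CA atom in chain %s: %s",
                    length(missing_ca), chain,
                    paste(missing_ca, collapse = ", ")))
  }
  ord <- match(intersect(seen, ca_key), ca_key)
  ridx <- suppressWarnings(as.integer(sub("[A-Za-z ]$", "", ca_key[ord])))
  if (anyNA(ridx) || any(diff(ridx) <= 0)) {
    # Insertion codes or non-monotone numbering: fall back to positional
    # renumbering, which preserves order.
    warning("residue numbering not strictly increasing; renumbering 1..n")
    ridx <- seq_along(ord)
  }
  if (length(ord) < 2L) {
    stop(sprintf("PDB parse error: fewer than 2 CA residues in chain %s",
                 chain))
  }
  structure_model(ridx, ca_name[ord], ca_xyz[ord, , drop = FALSE],
                  model_id = model_id, chain_id = chain)
}

#' Write a StructureModel as PDB text
#'
#' Calpha-only ATOM records. An optional per-residue value can be written
#' into the B-factor column (e.g. a predicted marginal probability).
#'
#' @param model a StructureModel
#' @param path output file, or `NULL` to return the lines
#' @param bfactor optional numeric vector, length = number of residues
#' @return invisibly, the character vector of PDB lines
#' @export
write_pdb <- function(model, path = NULL, bfactor = NULL) {
  n <- length(model$residue_index)
  if (is.null(bfactor)) bfactor <- rep(0, n)
  if (length(bfactor) != n) stop("bfactor length mismatch")
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(n), model$residue_name, model$chain_id, model$residue_index,
    model$coords[, 1], model$coords[, 2], model$coords[, 3],
    1.0, bfactor, "C")
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Least-squares (Kabsch) superposition of a model onto a native structure
#'
#' The rotation/translation minimising the RMSD over the Calpha atoms of
#' residues shared (by residue index) between model and native is computed
#' by the Kabsch SVD algorithm. The per-residue Calpha-Calpha distances
#' after superposition are the local error values used for labelling.
#'
#' @param model,native StructureModel objects sharing >= 3 residue indices
#' @return an object of class `Superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3), `per_residue_distance` (one value per model
#'   residue, `NA` where the native lacks the residue), `rmsd`, and
#'   `shared` (the shared residue indices)
#' @export
superpose <- function(model, native) {
  shared <- intersect(model$residue_index, native$residue_index)
  if (length(shared) < 3L) {
    stop(sprintf("insufficient overlap: %d shared residues (need >= 3)",
                 length(shared)))
  }
  P <- model$coords[match(shared, model$residue_index), , drop = FALSE]
  Q <- native$coords[match(shared, native$residue_index), , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  H <- crossprod(Pc, Qc)            # 3x3 covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)         # rotates centred model onto native
  # x_native ~ R (x_model - cp) + cq
  trans <- as.numeric(cq - R %*% cp)
  moved <- sweep(model$coords %*% t(R), 2, trans, "+")
  idx <- match(model$residue_index, native$residue_index)
  dist <- rep(NA_real_, length(model$residue_index))
  has <- !is.na(idx)
  dd <- moved[has, , drop = FALSE] - native$coords[idx[has], , drop = FALSE]
  dist[has] <- sqrt(rowSums(dd * dd))
  rmsd <- sqrt(mean(dist[has]^2))
  structure(list(rotation = R, translation = trans,
                 per_residue_distance = dist, rmsd = rmsd, shared = shared),
            class = "Superposition")
}

#' @export
print.Superposition <- function(x, ...) {
  cat(sprintf("Superposition: %d shared residues, RMSD %.3f A\n",
              length(x$shared), x$rmsd))
  invisible(x)
}

#' Assign secondary structure from the Calpha trace
#'
#' Deterministic Calpha-only assignment into H (helix), B (strand) and C
#' (coil, i.e. anything else). A residue window starting at i is helical
#' when d(i,i+3) and d(i,i+4) match ideal alpha-helix values, and extended
#' when d(i,i+2) (and d(i,i+3) where available) match beta-strand values;
#' matched windows are smeared over their members. A precomputed
#' per-residue string can be supplied and is returned verbatim.
#'
#' @param model a StructureModel
#' @param override optional character scalar over alphabet H/B/C, one code
#'   per residue; overrides the geometric assignment
#' @return character scalar over alphabet {H, B, C}, one code per residue
#' @export
assign_secondary_structure <- function(model, override = NULL) {
  n <- length(model$residue_index)
  if (!is.null(override)) {
    codes <- strsplit(override, "")[[1]]
    if (length(codes) != n) {
      stop(sprintf("secondary-structure override length %d != %d residues",
                   length(codes), n))
    }
    if (!all(codes %in% c("H", "B", "C"))) {
      stop("secondary-structure override contains codes outside {H,B,C}")
    }
    return(override)
  }
  xyz <- model$coords
  dk <- function(k) {
    if (n <= k) return(numeric(0))
    d <- xyz[seq_len(n - k) + k, , drop = FALSE] - xyz[seq_len(n - k), , drop = FALSE]
    sqrt(rowSums(d * d))
  }
  d2 <- dk(2L); d3 <- dk(3L); d4 <- dk(4L)
  ss <- rep("C", n)
  # Helix windows: ideal alpha geometry gives d(i,i+3) ~ 5.05, d(i,i+4) ~ 6.20.
  if (n >= 5L) {
    hstart <- which(d3[seq_len(n - 4L)] >= 4.5 & d3[seq_len(n - 4L)] <= 5.6 &
                    d4 >= 5.7 & d4 <= 6.7)
    for (i in hstart) ss[i:(i + 4L)] <- "H"
  }
  # Strand windows: extended geometry gives d(i,i+2) ~ 6.7-7.2 and, where a
  # third step exists, d(i,i+3) >= 9.
  if (n >= 3L) {
    for (i in which(d2 >= 6.3 & d2 <= 7.4)) {
      if (i <= length(d3) && d3[i] < 9.0) next
      run <- i:(i + 2L)
      ss[run][ss[run] != "H"] <- "B"
    }
  }
  paste(ss, collapse = "")
}
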