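# CRF parameters: node-feature weights lambda (label-conditioned, with the
# label-0 row fixed at 0 as the reference), pairwise label-pattern weights
# omega (00, 01, 10, 11; pair ordered by ascending residue index), and
# secondary-structure edge-class weights w. Plus round-trip text I/O.

.edge_classes <- c("HH", "BB", "HB", "CHB", "CC")
.patterns <- c("00", "01", "10", "11")

#' Construct CRF parameters
#'
#' @param lambda1 numeric vector of node-feature weights for label 1
#'   (label 0 is the reference with weights fixed at 0)
#' @param omega length-4 numeric vector of pairwise pattern weights, in
#'   order 00, 01, 10, 11 (first digit = label of the lower residue index)
#' @param w named length-5 vector of edge-class weights in [0, 1] for
#'   HH, BB, HB, CHB, CC; default all 1 (uniform weighting)
#' @param feature_names names of the lambda1 entries
#' @param ca_cutoff Calpha error cutoff (Angstrom) the model is trained for
#' @param neighbor_cutoff graph neighbour cutoff (Angstrom)
#' @param meta free-form list of training metadata (seed, epochs, ...)
#' @return an object of class `CRFParameters`
#' @export
crf_parameters <- function(lambda1, omega = rep(0, 4),
                           w = stats::setNames(rep(1, 5), .edge_classes),
                           feature_names = NULL,
                           ca_cutoff = 5.0, neighbor_cutoff = 4.5,
                           meta = list()) {
  lambda1 <- as.numeric(lambda1)
  omega <- as.numeric(omega)
  if (length(omega) != 4L) stop("omega must have 4 entries (00,01,10,11)")
  names(omega) <- .patterns
  w <- w[.edge_classes]
  if (anyNA(w)) stop("w must name all five edge classes HH,BB,HB,CHB,CC")
  if (any(w < 0 | w > 1)) stop("edge-class weights must lie in [0, 1]")
  if (is.null(feature_names)) {
    feature_names <- paste0("f", seq_along(lambda1))
  }
  names(lambda1) <- feature_names
  structure(list(lambda1 = lambda1, omega = omega, w = w,
                 ca_cutoff = ca_cutoff, neighbor_cutoff = neighbor_cutoff,
                 meta = meta),
            class = "CRFParameters")
}

#' @export
print.CRFParameters <- function(x, ...) {
  cat(sprintf(paste0("CRFParameters: %d features, Calpha cutoff %.1f A, ",
                     "neighbour cutoff %.1f A\n"),
              length(x$lambda1), x$ca_cutoff, x$neighbor_cutoff))
  cat("  omega:", paste(sprintf("%s=%.4g", names(x$omega), x$omega),
                        collapse = " "), "\n")
  cat("  w:    ", paste(sprintf("%s=%.2g", names(x$w), x$w),
                        collapse = " "), "\n")
  invisible(x)
}

#' Write CRF parameters to a structured text file
#'
#' The format round-trips bit-exactly (doubles serialised with 17
#' significant digits).
#'
#' @param params a CRFParameters object
#' @param path output file
#' @export
write_crf_parameters <- function(params, path) {
  num <- function(x) paste(fmt_num(x), collapse = " ")
  meta <- params$meta
  lines <- c(
    "gmq_parameters\t1",
    paste0("feature_names\t", paste(names(params$lambda1), collapse = ",")),
    paste0("lambda1\t", num(params$lambda1)),
    paste0("omega\t", num(params$omega)),
    paste0("w\t", num(params$w)),
    paste0("ca_cutoff\t", fmt_num(params$ca_cutoff)),
    paste0("neighbor_cutoff\t", fmt_num(params$neighbor_cutoff)))
  for (k in names(meta)) {
    v <- meta[[k]]
    v <- if (is.numeric(v)) paste(fmt_num(v), collapse = " ") else
      paste(as.character(v), collapse = " ")
    lines <- c(lines, paste0("meta.", k, "\t", v))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read CRF parameters written by [write_crf_parameters()]
#' @param path parameter file
#' @return a CRFParameters object
#' @export
read_crf_parameters <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\t", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "\t"), character(1))
  if (keys[1] != "gmq_parameters") stop("not a gmq parameter file")
  get <- function(k) vals[match(k, keys)]
  nums <- function(k) as.numeric(strsplit(get(k), " ", fixed = TRUE)[[1]])
  meta_keys <- keys[startsWith(keys, "meta.")]
  meta <- lapply(meta_keys, function(k) {
    v <- strsplit(vals[match(k, keys)], " ", fixed = TRUE)[[1]]
    vn <- suppressWarnings(as.numeric(v))
    if (anyNA(vn)) v else vn
  })
  names(meta) <- sub("^meta\\.", "", meta_keys)
  crf_parameters(
    lambda1 = nums("lambda1"),
    omega = nums("omega"),
    w = stats::setNames(nums("w"), .edge_classes),
    feature_names = strsplit(get("feature_names"), ",", fixed = TRUE)[[1]],
    ca_cutoff = nums("ca_cutoff"),
    neighbor_cutoff = nums("neighbor_cutoff"),
    meta = meta)
}
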