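#' Assign the points of a CGR curve to the four quadrants
#'
#' The unit disk is split along the axes with a half-open, rotationally
#' symmetric convention: Q1 is `x > 0, y >= 0`; Q2 is `x <= 0, y > 0`; Q3 is
#' `x < 0, y <= 0`; Q4 is `x >= 0, y < 0`.  CGR points can never hit the
#' origin, so every point lands in exactly one quadrant.
#'
#' @param curve A `cgr_curve`, or an N x 2 point matrix.
#' @return A `quadrant_partition`: list with `groups` (list of 4 point
#'   matrices, Q1..Q4) and `counts` (integer vector of length 4 summing to
#'   the point count).
#' @export
assign_quadrants <- function(curve) {
  pts <- if (inherits(curve, "cgr_curve")) curve$points else as.matrix(curve)
  if (!nrow(pts)) stop("cannot partition an empty curve")
  x <- pts[, 1L]
  y <- pts[, 2L]
  q <- integer(length(x))
  q[x > 0 & y >= 0] <- 1L
  q[x <= 0 & y > 0] <- 2L
  q[x < 0 & y <= 0] <- 3L
  q[x >= 0 & y < 0] <- 4L
  if (any(q == 0L)) stop("point at the origin cannot be assigned a quadrant")
  groups <- lapply(1:4, function(k) pts[q == k, , drop = FALSE])
  structure(list(groups = groups,
                 counts = vapply(groups, nrow, integer(1))),
            class = "quadrant_partition")
}

#' Pairwise Euclidean distance matrix of a planar point set
#'
#' @param points An n x 2 numeric matrix (n >= 0).
#' @return A symmetric n x n matrix of Euclidean distances with zero
#'   diagonal; a 0 x 0 matrix for empty input.
#' @export
pairwise_distance_matrix <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n == 0L) return(matrix(numeric(0), 0L, 0L))
  if (n == 1L) return(matrix(0, 1L, 1L))
  unname(as.matrix(stats::dist(points, method = "euclidean")))
}

#' Leading eigenvalue of a symmetric non-negative matrix
#'
#' For a symmetric matrix with non-negative entries the largest eigenvalue is
#' real and non-negative (Perron-Frobenius), lying between the mean and the
#' maximum row sum.  Empty and 1 x 1 matrices return 0.  Matrices up to
#' 512 x 512 go through the dense symmetric solver; larger ones through a
#' power iteration on the (non-negative, typically irreducible) matrix with
#' convergence tolerance 1e-10.
#'
#' @param m A symmetric numeric matrix.
#' @return The largest eigenvalue (non-negative scalar).
#' @export
leading_eigenvalue <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  if (n != ncol(m)) stop("matrix must be square")
  if (n <= 1L) return(0)
  if (max(abs(m - t(m))) > 1e-8) stop("matrix must be symmetric")
  if (n <= 512L) {
    return(eigen(m, symmetric = TRUE, only.values = TRUE)$values[1L])
  }
  .power_leading_eigenvalue(m, tol = 1e-10)
}

.power_leading_eigenvalue <- function(m, tol = 1e-10, max_iter = 10000L) {
  v <- rowSums(m)
  nv <- sqrt(sum(v^2))
  if (nv == 0) return(0)
  v <- v / nv
  lambda <- 0
  for (iter in seq_len(max_iter)) {
    w <- as.numeric(m %*% v)
    lambda_new <- sum(v * w)          # Rayleigh quotient
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(0)
    v <- w / nw
    if (abs(lambda_new - lambda) <= tol * max(1, abs(lambda_new))) {
      return(lambda_new)
    }
    lambda <- lambda_new
  }
  warning("power iteration did not converge to tolerance ", tol)
  lambda
}

#' Leading-eigenvalue features of a CGR curve
#'
#' Splits the curve by quadrant, forms the pairwise Euclidean distance matrix
#' of each quadrant's points, and returns the four leading eigenvalues in
#' quadrant order Q1..Q4.  Empty and single-point quadrants contribute 0.
#' Raw eigenvalues grow with the number of points in a quadrant;
#' `normalize = "by_n"` divides each eigenvalue by its quadrant's point
#' count for length-adjusted features (default is the raw value).
#'
#' @param curve A `cgr_curve`.
#' @param normalize `"none"` (default) or `"by_n"`.
#' @return Numeric vector of length 4, named `Q1..Q4`, all entries >= 0.
#' @export
curve_features <- function(curve, normalize = c("none", "by_n")) {
  normalize <- match.arg(normalize)
  part <- assign_quadrants(curve)
  ev <- vapply(part$groups, function(pts) {
    leading_eigenvalue(pairwise_distance_matrix(pts))
  }, numeric(1))
  if (normalize == "by_n") {
    ev <- ev / pmax(part$counts, 1L)
  }
  names(ev) <- paste0("Q", 1:4)
  ev
}

#' Quadrant point frequencies of a CGR curve (FCGR baseline)
#'
#' The frequency-only ablation: the fraction of curve points falling in each
#' quadrant, discarding the within-quadrant distribution information that the
#' leading-eigenvalue features retain.
#'
#' @param curve A `cgr_curve`.
#' @return Numeric vector of length 4 (named `Q1..Q4`) summing to 1.
#' @export
fcgr_baseline_features <- function(curve) {
  part <- assign_quadrants(curve)
  freq <- part$counts / sum(part$counts)
  names(freq) <- paste0("Q", 1:4)
  freq
}

#' Feature vector of one sequence under an index catalog
#'
#' For each index in catalog order: arrange the amino acids, build the CGR
#' curve, extract the four per-quadrant features; concatenate.  A k-index
#' catalog yields a 4k-vector (632 for the full 158-index catalog).
#'
#' @param sequence Amino-acid string.
#' @param catalog An `aaindex_catalog` (filtered; see
#'   [filter_nonredundant()]).
#' @param type `"dcgr"` (leading eigenvalues, default) or `"fcgr"` (quadrant
#'   frequencies).
#' @param normalize Eigenvalue normalization, see [curve_features()];
#'   ignored for `type = "fcgr"`.
#' @param on_invalid Residue policy, see [build_cgr_curve()].
#' @param id Optional sequence id for error messages.
#' @return Named numeric vector of length `4 * length(catalog)`; names are
#'   `<accession>_Q<1..4>`.
#' @export
sequence_features <- function(sequence, catalog,
                              type = c("dcgr", "fcgr"),
                              normalize = c("none", "by_n"),
                              on_invalid = c("skip", "error"),
                              id = NULL) {
  type <- match.arg(type)
  normalize <- match.arg(normalize)
  on_invalid <- match.arg(on_invalid)
  if (!length(catalog)) stop("catalog is empty")
  arrangements <- lapply(catalog, arrange_amino_acids)
  .sequence_features_arr(sequence, arrangements, type, normalize, on_invalid, id)
}

.sequence_features_arr <- function(sequence, arrangements, type, normalize,
                                   on_invalid, id) {
  feats <- lapply(arrangements, function(arr) {
    curve <- build_cgr_curve(sequence, arr, on_invalid = on_invalid, id = id)
    if (type == "dcgr") curve_features(curve, normalize = normalize)
    else fcgr_baseline_features(curve)
  })
  out <- unlist(feats, use.names = FALSE)
  names(out) <- as.vector(t(outer(
    vapply(arrangements, attr, character(1), "accession"),
    paste0("_Q", 1:4), paste0)))
  out
}

#' Feature matrix of a sequence set
#'
#' Applies [sequence_features()] to every sequence; rows are sequences in
#' input order, columns are `<accession>_Q<1..4>` in catalog order.
#'
#' @param sequences A named character vector of amino-acid strings, or a
#'   data frame with columns `id` and `sequence` (as returned by
#'   [read_fasta()]).
#' @inheritParams sequence_features
#' @return An N x 4k numeric matrix with sequence ids as rownames.
#' @examples
#' catalog <- synthetic_catalog(3)
#' seqs <- c(a = "MKVLAWGK", b = "MKVLAWGR")
#' feature_matrix(seqs, catalog)
#' @export
feature_matrix <- function(sequences, catalog,
                           type = c("dcgr", "fcgr"),
                           normalize = c("none", "by_n"),
                           on_invalid = c("skip", "error")) {
  type <- match.arg(type)
  normalize <- match.arg(normalize)
  on_invalid <- match.arg(on_invalid)
  if (is.data.frame(sequences)) {
    stopifnot(all(c("id", "sequence") %in% names(sequences)))
    seqs <- stats::setNames(as.character(sequences$sequence),
                            as.character(sequences$id))
  } else {
    seqs <- sequences
    if (is.null(names(seqs))) {
      names(seqs) <- paste0("seq", seq_along(seqs))
    }
  }
  if (!length(catalog)) stop("catalog is empty")
  arrangements <- lapply(catalog, arrange_amino_acids)
  rows <- lapply(seq_along(seqs), function(i) {
    .sequence_features_arr(seqs[[i]], arrangements, type, normalize,
                           on_invalid, names(seqs)[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(seqs)
  out
}

#' Write / read a feature matrix as TSV
#'
#' One row per sequence; first column `sequence_id`, then one column per
#' feature (`<accession>_Q<1..4>`), full double precision so that identical
#' inputs give byte-identical files.
#'
#' @param features Numeric matrix with rownames (sequence ids).
#' @param file Path.
#' @return `write_features_tsv()` returns `file` invisibly;
#'   `read_features_tsv()` the matrix.
#' @export
write_features_tsv <- function(features, file) {
  df <- data.frame(sequence_id = rownames(features),
                   apply(features, 2, format, digits = 17),
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_features_tsv
#' @export
read_features_tsv <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}
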