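#' Principal-component reduction of a feature matrix
#'
#' Columns are mean-centered (no scaling by default, since the eigenvalue
#' features share a scale within each index) and projected onto the top
#' variance directions.  A deterministic sign convention is applied: within
#' each component the loading of largest magnitude is made positive, so runs
#' on identical input are byte-identical.
#'
#' @param features N x p numeric matrix with sequence ids as rownames.
#' @param n_components Number of components to keep; must not exceed
#'   `min(N, p)`.
#' @param scale. Logical; also divide each column by its standard deviation
#'   before projection (default `FALSE`).
#' @return A `dcgr_reduction`: list with `sequence_ids`, `components`
#'   (N x c score matrix), `explained_variance` (variances of the kept
#'   components, non-increasing), `total_variance` (sum of all column
#'   variances of the centered data) and `rotation`.
#' @examples
#' m <- matrix(rnorm(40), 8, 5, dimnames = list(letters[1:8], NULL))
#' red <- pca_reduce(m, 3)
#' red$explained_variance
#' @export
pca_reduce <- function(features, n_components, scale. = FALSE) {
  features <- as.matrix(features)
  n <- nrow(features)
  p <- ncol(features)
  if (n < 2L) stop("need at least 2 sequences for PCA")
  bound <- min(n, p)
  if (n_components < 1L || n_components > bound) {
    stop("n_components must be between 1 and min(N, p) = ", bound)
  }
  if (scale.) {
    sds <- apply(features, 2, stats::sd)
    zero <- sds == 0
    if (any(zero)) {
      warning("dropping ", sum(zero), " zero-variance column(s) before scaling")
      features <- features[, !zero, drop = FALSE]
    }
  }
  pc <- stats::prcomp(features, center = TRUE, scale. = scale.)
  k <- min(n_components, ncol(pc$rotation))
  rotation <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading of each component positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(rotation[, j]))
    if (rotation[i_max, j] < 0) {
      rotation[, j] <- -rotation[, j]
      scores[, j] <- -scores[, j]
    }
  }
  if (k < n_components) {
    # prcomp caps at min(N - 1, p) nonzero directions; pad with exact-zero
    # components so the requested dimensionality is honoured.
    pad <- n_components - k
    scores <- cbind(scores, matrix(0, n, pad))
    colnames(scores) <- paste0("PC", seq_len(n_components))
  }
  structure(list(sequence_ids = rownames(features),
                 components = scores,
                 explained_variance = c(pc$sdev^2, numeric(n_components))[
                   seq_len(n_components)],
                 total_variance = sum(pc$sdev^2),
                 rotation = rotation),
            class = "dcgr_reduction")
}

#' @export
print.dcgr_reduction <- function(x, ...) {
  cat("dcgr_reduction:", nrow(x$components), "sequences x",
      ncol(x$components), "components\n")
  ev <- x$explained_variance
  cat("explained variance fraction:",
      paste(sprintf("%.3f", ev / max(x$total_variance, .Machine$double.eps)),
            collapse = " "), "\n")
  invisible(x)
}

#' Inter-sequence distance matrix under one of four metrics
#'
#' Distances are computed between the rows of the reduced (or raw) feature
#' matrix.  Metrics: `euclidean` (L2), `manhattan` (L1), `cosine`
#' (`1 - u.v / (|u||v|)`; a zero row is an error) and `seuclidean`
#' (Euclidean after dividing each column by its sample standard deviation
#' across the rows; zero-variance columns are dropped with a warning).
#'
#' @param x A `dcgr_reduction` or a numeric matrix with row labels.
#' @param metric One of `"euclidean"`, `"manhattan"`, `"cosine"`,
#'   `"seuclidean"`.
#' @return A labeled symmetric N x N matrix with zero diagonal and a
#'   `metric` attribute.
#' @export
sequence_distances <- function(x, metric = c("euclidean", "manhattan",
                                             "cosine", "seuclidean")) {
  metric <- match.arg(metric)
  m <- if (inherits(x, "dcgr_reduction")) x$components else as.matrix(x)
  if (is.null(rownames(m)) && inherits(x, "dcgr_reduction")) {
    rownames(m) <- x$sequence_ids
  }
  if (nrow(m) < 2L) stop("need at least 2 sequences")
  d <- switch(metric,
    euclidean = as.matrix(stats::dist(m, method = "euclidean")),
    manhattan = as.matrix(stats::dist(m, method = "manhattan")),
    cosine = .cosine_distances(m),
    seuclidean = {
      sds <- apply(m, 2, stats::sd)
      zero <- sds == 0
      if (any(zero)) {
        warning("dropping ", sum(zero),
                " zero-variance column(s) for standardized Euclidean")
      }
      ms <- sweep(m[, !zero, drop = FALSE], 2, sds[!zero], `/`)
      as.matrix(stats::dist(ms, method = "euclidean"))
    })
  diag(d) <- 0
  attr(d, "metric") <- metric
  d
}

.cosine_distances <- function(m) {
  norms <- sqrt(rowSums(m^2))
  if (any(norms == 0)) {
    stop("cosine distance undefined for zero feature vector(s): ",
         paste(rownames(m)[norms == 0], collapse = ", "))
  }
  u <- m / norms
  d <- 1 - tcrossprod(u)
  d[d < 0] <- 0                      # clip numerical negatives
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Build a distance-based tree (UPGMA or neighbor joining)
#'
#' UPGMA performs average-linkage agglomeration and returns a rooted
#' ultrametric tree whose node heights are half the merge distances (so two
#' leaves at distance 2 join at height 1).  NJ is the standard
#' neighbor-joining algorithm and recovers additive distance matrices
#' exactly.  Rows/columns are re-ordered lexicographically by label before
#' clustering so that merge ties are broken deterministically by label.
#'
#' @param dist_matrix Labeled symmetric numeric matrix (e.g. from
#'   [sequence_distances()]), or a `dist` object with labels.
#' @param method `"upgma"` (default) or `"nj"`.
#' @return An [ape::phylo] tree whose tip set equals the distance labels.
#' @export
build_tree <- function(dist_matrix, method = c("upgma", "nj")) {
  method <- match.arg(method)
  m <- as.matrix(dist_matrix)
  if (any(!is.finite(m))) stop("distance matrix contains non-finite values")
  labels <- rownames(m)
  if (is.null(labels)) stop("distance matrix must carry row labels")
  n <- nrow(m)
  if (method == "nj" && n < 3L) stop("neighbor joining needs at least 3 leaves")
  if (n < 2L) stop("need at least 2 leaves")
  ord <- order(labels)
  m <- m[ord, ord, drop = FALSE]
  if (method == "upgma") {
    hc <- stats::hclust(stats::as.dist(m), method = "average")
    tree <- ape::as.phylo(hc)        # heights halved: ultrametric, rooted
  } else {
    tree <- ape::nj(stats::as.dist(m))
  }
  tree
}

#' Write a tree in Newick format
#'
#' Branch lengths are kept; labels containing whitespace, parentheses,
#' commas, colons or semicolons are replaced by underscores (the common
#' Newick dialect) before writing.
#'
#' @param tree An [ape::phylo] object.
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
write_newick <- function(tree, file) {
  stopifnot(inherits(tree, "phylo"))
  tree$tip.label <- gsub("[][[:space:](),:;'\"]+", "_", tree$tip.label)
  ape::write.tree(tree, file = file)
  invisible(file)
}

#' Write / read a labeled square distance matrix
#'
#' `write_distances_tsv()` emits a TSV with a `sequence_id` first column and
#' one column per sequence; `write_distances_phylip()` emits the square
#' PHYLIP distance format (leaf count on the first line).
#'
#' @param d Labeled symmetric numeric matrix.
#' @param file Path.
#' @return The path, invisibly (readers return the matrix).
#' @export
write_distances_tsv <- function(d, file) {
  m <- as.matrix(d)
  df <- data.frame(sequence_id = rownames(m),
                   apply(m, 2, format, digits = 17),
                   check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_distances_tsv
#' @export
read_distances_tsv <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' @rdname write_distances_tsv
#' @export
write_distances_phylip <- function(d, file) {
  m <- as.matrix(d)
  labels <- gsub("[[:space:]]+", "_", rownames(m))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(labels[i], format(m[i, ], digits = 17)),
                     collapse = "  "), con)
  }
  invisible(file)
}

#' Write the reduced feature matrix as TSV
#'
#' @param reduced A `dcgr_reduction`.
#' @param file Path.
#' @return `file`, invisibly.
#' @export
write_reduced_tsv <- function(reduced, file) {
  m <- reduced$components
  rownames(m) <- reduced$sequence_ids
  write_features_tsv(m, file)
}
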