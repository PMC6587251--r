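#' The 20 fixed vertices of the unit-circle arrangement
#'
#' Vertex `i` is `(cos(2*pi*i/20), sin(2*pi*i/20))` for `i = 1..20`, measured
#' counterclockwise from the positive x-axis, so rank 20 sits at `(1, 0)`.
#' Every arrangement uses exactly this point set; only the assignment of
#' amino acids to ranks varies with the physicochemical scale.
#'
#' @return A 20 x 2 numeric matrix with columns `x`, `y`; row `i` is the
#'   vertex of rank `i`.
#' @export
circle_vertices <- function() {
  i <- 1:20
  cbind(x = cos(2 * pi * i / 20), y = sin(2 * pi * i / 20))
}

#' Arrange the 20 amino acids on the unit circle by a physicochemical scale
#'
#' The amino acids are sorted by their scale values in ascending order; the
#' amino acid with the `i`-th smallest value is placed at vertex
#' `(cos(2*pi*i/20), sin(2*pi*i/20))`.  The scale must be complete and free
#' of ties (see [filter_nonredundant()]), otherwise the ranking - and hence
#' the arrangement - would not be unique.
#'
#' @param index A single catalog entry (list with `accession` and 20 named
#'   `values`), e.g. `catalog[[1]]`.
#' @return An `aa_arrangement`: a 20 x 2 matrix of vertex coordinates with
#'   amino-acid rownames and an `accession` attribute.
#' @examples
#' idx <- list(accession = "TOY", values = stats::setNames(1:20, AA_ALPHABET))
#' arr <- arrange_amino_acids(idx)
#' arr["Y", ]  # largest value -> rank 20 -> (1, 0)
#' @export
arrange_amino_acids <- function(index) {
  values <- index$values
  if (is.null(values) || length(values) != 20L ||
      !setequal(names(values), AA_ALPHABET)) {
    stop("index must carry 20 values named by the standard amino acids")
  }
  if (anyNA(values)) {
    stop("index ", index$accession, " has missing values; ",
         "filter the catalog before arranging")
  }
  if (anyDuplicated(values)) {
    stop("index ", index$accession, " has tied values; ",
         "filter the catalog before arranging")
  }
  ranks <- rank(values)             # ties impossible, checked above
  vertices <- circle_vertices()[ranks, , drop = FALSE]
  rownames(vertices) <- names(values)
  structure(vertices,
            accession = index$accession %||% NA_character_,
            class = c("aa_arrangement", class(vertices)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the chaos game representation curve of a protein sequence
#'
#' The curve starts at the origin (not stored) and places one point per
#' residue: point `i` is the midpoint of point `i-1` and the circle vertex of
#' residue `i`, so the first point is half the first residue's vertex.  All
#' points lie strictly inside the unit disk and never on the origin.
#'
#' Residues outside the 20-letter standard alphabet (B, J, O, U, X, Z, gaps,
#' digits) are skipped with a warning by default; `on_invalid = "error"`
#' raises instead.  Input is uppercased first.
#'
#' @param sequence Amino-acid string (character scalar).
#' @param arrangement An [arrange_amino_acids()] result.
#' @param on_invalid `"skip"` (default) or `"error"` for non-standard
#'   residues.
#' @param id Optional sequence identifier stored on the curve.
#' @return A `cgr_curve`: list with `id`, `accession`, `points` (N x 2
#'   matrix), `n` (encoded residue count) and `n_skipped`.
#' @examples
#' idx <- list(accession = "TOY", values = stats::setNames(1:20, AA_ALPHABET))
#' arr <- arrange_amino_acids(idx)
#' build_cgr_curve("MKVL", arr)$points
#' @export
build_cgr_curve <- function(sequence, arrangement,
                            on_invalid = c("skip", "error"), id = NULL) {
  on_invalid <- match.arg(on_invalid)
  stopifnot(inherits(arrangement, "aa_arrangement"))
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop("sequence must be a single character string")
  }
  residues <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  valid <- residues %in% rownames(arrangement)
  if (any(!valid)) {
    bad <- unique(residues[!valid])
    if (on_invalid == "error") {
      stop("non-standard residues in sequence", if (!is.null(id)) paste0(" ", id),
           ": ", paste(bad, collapse = ", "))
    }
    warning("skipping ", sum(!valid), " non-standard residue(s) (",
            paste(bad, collapse = ", "), ")",
            if (!is.null(id)) paste0(" in ", id))
    residues <- residues[valid]
  }
  if (!length(residues)) {
    stop("no encodable residues",
         if (!is.null(id)) paste0(" in sequence ", id))
  }
  vx <- arrangement[residues, 1L]
  vy <- arrangement[residues, 2L]
  # psi_i = (psi_{i-1} + phi_i) / 2 with psi_0 = (0, 0): a linear recursion,
  # evaluated in C by stats::filter.
  px <- as.numeric(stats::filter(vx / 2, 0.5, method = "recursive"))
  py <- as.numeric(stats::filter(vy / 2, 0.5, method = "recursive"))
  structure(list(id = id,
                 accession = attr(arrangement, "accession"),
                 points = cbind(x = px, y = py),
                 n = length(px),
                 n_skipped = sum(!valid)),
            class = "cgr_curve")
}

#' @export
print.cgr_curve <- function(x, ...) {
  cat("cgr_curve", if (!is.null(x$id)) paste0("'", x$id, "'"),
      "under index", attr(x, "accession") %||% x$accession,
      "with", x$n, "points\n")
  invisible(x)
}

#' Export a CGR curve as a TSV table
#'
#' Columns: `sequence_id`, `index_accession`, `i`, `x`, `y` - one row per
#' curve point, full double precision.
#'
#' @param curve A `cgr_curve`.
#' @param file Path to write to.
#' @return `file`, invisibly.
#' @export
write_curve_tsv <- function(curve, file) {
  df <- data.frame(sequence_id = curve$id %||% NA_character_,
                   index_accession = curve$accession %||% NA_character_,
                   i = seq_len(curve$n),
                   x = format(curve$points[, 1], digits = 17),
                   y = format(curve$points[, 2], digits = 17))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
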