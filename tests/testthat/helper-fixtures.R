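# Shared fixtures built in code.

# A complete, tie-free toy index assigning rank i to the i-th amino acid in
# alphabetical order (A smallest ... Y largest).
toy_index <- function(values = 1:20, accession = "TOY") {
  stopifnot(length(values) == 20L)
  list(accession = accession,
       description = "toy scale",
       values = stats::setNames(as.numeric(values), AA_ALPHABET),
       complete = !anyNA(values))
}

fixture_catalog <- function() {
  filter_nonredundant(read_aaindex1(
    system.file("extdata", "example_indices.aaindex1", package = "dcgr")))
}

# Random points strictly inside the unit disk (the domain of CGR points).
random_disk_points <- function(n) {
  r <- sqrt(stats::runif(n)) * 0.95
  th <- stats::runif(n, 0, 2 * pi)
  cbind(x = r * cos(th), y = r * sin(th))
}

random_protein <- function(n) {
  paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")
}

# Independent leading-eigenvalue oracle: for a symmetric non-negative matrix
# the largest eigenvalue equals the spectral radius (Perron-Frobenius), which
# the SVD exposes as the largest singular value.
svd_leading_eigenvalue <- function(m) {
  if (nrow(m) <= 1L) return(0)
  max(svd(m)$d)
}

# A minimal hand-written AAindex1 record with configurable value rows.
aaindex_record_text <- function(accession = "TEST0001",
                                row1 = sprintf("%.2f", 1:10),
                                row2 = sprintf("%.2f", 11:20)) {
  paste0("H ", accession, "\n",
         "D test record\n",
         "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V\n",
         "  ", paste(row1, collapse = "  "), "\n",
         "  ", paste(row2, collapse = "  "), "\n",
         "//\n")
}
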