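#' Parse AAindex1 flat-file records into an index catalog
#'
#' Reads zero or more records in the AAindex1 flat-file convention: each
#' record carries an `H` line (accession), a `D` line (description), an `I`
#' line announcing the amino-acid column order
#' (`A/L R/K N/M D/F C/P Q/S E/T G/W H/Y I/V`), two continuation rows of ten
#' numerical values, and a `//` terminator.  The token `NA` marks a missing
#' value and renders the index incomplete.
#'
#' @param file Path to an AAindex1 flat file.
#' @param text Optional character scalar/vector with the file content,
#'   used instead of `file` (mainly for tests).
#' @return An `aaindex_catalog`: a list of indices in file order, each a list
#'   with elements `accession`, `description`, `values` (numeric vector named
#'   by the 20 one-letter codes in alphabetical order) and `complete`
#'   (`TRUE` iff no value is `NA`).
#' @seealso [filter_nonredundant()], [write_catalog_tsv()]
#' @examples
#' cat_file <- system.file("extdata", "example_indices.aaindex1",
#'                         package = "dcgr")
#' catalog <- read_aaindex1(cat_file)
#' length(catalog)
#' @export
read_aaindex1 <- function(file, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    readLines(file, warn = FALSE)
  }
  indices <- list()
  seen <- character()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[[i]]
    if (!startsWith(line, "H")) {
      if (!nzchar(trimws(line))) { i <- i + 1L; next }
      stop("aaindex1 parse error at line ", i,
           ": expected record header 'H <accession>', got: ", line)
    }
    accession <- trimws(sub("^H", "", line))
    if (!nzchar(accession)) {
      stop("aaindex1 parse error at line ", i, ": empty accession on H line")
    }
    description <- NA_character_
    values <- NULL
    i <- i + 1L
    terminated <- FALSE
    while (i <= n) {
      line <- lines[[i]]
      if (startsWith(line, "//")) { terminated <- TRUE; i <- i + 1L; break }
      key <- substr(line, 1L, 1L)
      if (key == "D" && is.na(description)) {
        description <- trimws(sub("^D", "", line))
      } else if (key == "I") {
        if (i + 2L > n) {
          stop("aaindex1 parse error in record ", accession, " at line ", i,
               ": 'I' line not followed by two value rows")
        }
        row1 <- .parse_value_row(lines[[i + 1L]], accession, i + 1L)
        row2 <- .parse_value_row(lines[[i + 2L]], accession, i + 2L)
        values <- c(row1, row2)
        names(values) <- .aaindex_i_order
        values <- values[AA_ALPHABET]
        i <- i + 2L
      }
      i <- i + 1L
    }
    if (!terminated) {
      stop("aaindex1 parse error in record ", accession,
           ": missing '//' terminator")
    }
    if (is.null(values)) {
      stop("aaindex1 parse error in record ", accession, ": no 'I' value block")
    }
    if (accession %in% seen) {
      warning("duplicate accession ", accession, "; keeping first occurrence")
      next
    }
    seen <- c(seen, accession)
    indices[[length(indices) + 1L]] <- list(
      accession = accession,
      description = description,
      values = values,
      complete = !anyNA(values)
    )
  }
  new_aaindex_catalog(indices)
}

.parse_value_row <- function(line, accession, lineno) {
  tokens <- strsplit(trimws(line), "[[:space:]]+")[[1]]
  if (length(tokens) != 10L) {
    stop("aaindex1 parse error in record ", accession, " at line ", lineno,
         ": expected 10 values, got ", length(tokens))
  }
  vals <- suppressWarnings(as.numeric(tokens))
  bad <- is.na(vals) & tokens != "NA"
  if (any(bad)) {
    stop("aaindex1 parse error in record ", accession, " at line ", lineno,
         ": unreadable value token '", tokens[bad][1], "'")
  }
  vals
}

new_aaindex_catalog <- function(indices) {
  structure(indices, class = "aaindex_catalog")
}

#' @export
print.aaindex_catalog <- function(x, ...) {
  cat("aaindex_catalog with", length(x), "indices\n")
  if (length(x)) {
    show <- utils::head(x, 5L)
    for (idx in show) {
      cat(sprintf("  %-12s complete=%-5s %s\n", idx$accession, idx$complete,
                  substr(idx$description, 1, 50)))
    }
    if (length(x) > 5L) cat("  ...\n")
  }
  invisible(x)
}

#' @export
`[.aaindex_catalog` <- function(x, i) {
  new_aaindex_catalog(unclass(x)[i])
}

#' Accessions of a catalog
#' @param catalog An `aaindex_catalog`.
#' @return Character vector of accessions in catalog order.
#' @export
catalog_accessions <- function(catalog) {
  vapply(catalog, `[[`, character(1), "accession")
}

#' Drop redundant amino-acid indices from a catalog
#'
#' An index is redundant when two amino acids share the same value (the 20
#' values cannot then be strictly ordered, so no unique circle arrangement
#' exists).  Indices with missing values are dropped for the same reason.
#' The operation is idempotent and preserves catalog order.
#'
#' @param catalog An `aaindex_catalog`.
#' @return The filtered `aaindex_catalog`; a warning is emitted if nothing
#'   survives.
#' @examples
#' catalog <- read_aaindex1(system.file("extdata", "example_indices.aaindex1",
#'                                      package = "dcgr"))
#' filter_nonredundant(catalog)
#' @export
filter_nonredundant <- function(catalog) {
  stopifnot(inherits(catalog, "aaindex_catalog"))
  keep <- vapply(catalog, function(idx) {
    idx$complete && !anyDuplicated(idx$values)
  }, logical(1))
  out <- catalog[keep]
  if (length(catalog) && !length(out)) {
    warning("no indices survive the redundancy filter")
  }
  out
}

#' Write / read a catalog as TSV
#'
#' The dump has one row per index: `accession`, `description`, then 20
#' columns headed by the one-letter amino-acid codes in alphabetical order.
#'
#' @param catalog An `aaindex_catalog`.
#' @param file Path to write to / read from.
#' @return `write_catalog_tsv()` returns `file` invisibly;
#'   `read_catalog_tsv()` returns an `aaindex_catalog`.
#' @export
write_catalog_tsv <- function(catalog, file) {
  df <- as.data.frame(catalog)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_catalog_tsv
#' @export
read_catalog_tsv <- function(file) {
  df <- utils::read.table(file, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(c("accession", AA_ALPHABET), names(df))
  if (length(missing_cols)) {
    stop("catalog TSV is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  indices <- lapply(seq_len(nrow(df)), function(r) {
    values <- as.numeric(df[r, AA_ALPHABET])
    names(values) <- AA_ALPHABET
    list(accession = as.character(df$accession[r]),
         description = if ("description" %in% names(df))
           as.character(df$description[r]) else NA_character_,
         values = values,
         complete = !anyNA(values))
  })
  new_aaindex_catalog(indices)
}

#' @export
as.data.frame.aaindex_catalog <- function(x, ...) {
  vals <- do.call(rbind, lapply(x, `[[`, "values"))
  df <- data.frame(accession = catalog_accessions(x),
                   description = vapply(x, `[[`, character(1), "description"),
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(vals))
}
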