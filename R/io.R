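#' Read protein sequences from a FASTA file
#'
#' Multi-line (wrapped) records are concatenated, blank lines ignored and
#' residues uppercased.  The record id is the first whitespace-delimited
#' token of the header; the remainder is kept as the description.  Duplicate
#' ids and empty sequences are errors.
#'
#' @param file Path to a FASTA file.
#' @return A data frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(file) {
  set <- tryCatch(Biostrings::readAAStringSet(file),
                  error = function(e) {
                    stop("cannot parse FASTA file '", file, "': ",
                         conditionMessage(e))
                  })
  if (!length(set)) stop("no FASTA records found in '", file, "'")
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  desc <- trimws(sub("^[^[:space:]]+", "", headers))
  if (any(!nzchar(ids))) stop("FASTA record with empty id in '", file, "'")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param records Data frame with columns `id`, `sequence` (and optionally
#'   `description`), or a named character vector.
#' @param file Path to write to.
#' @param width Line-wrap width (default 60 residues).
#' @return `file`, invisibly.
#' @export
write_fasta <- function(records, file, width = 60L) {
  if (!is.data.frame(records)) {
    records <- data.frame(id = names(records),
                          sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  desc <- if ("description" %in% names(records)) records$description else ""
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    header <- if (nzchar(desc[i] %||% "")) {
      paste0(">", records$id[i], " ", desc[i])
    } else {
      paste0(">", records$id[i])
    }
    writeLines(header, con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(file)
}
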