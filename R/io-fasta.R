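#' Read a protein FASTA file into a tibble
#'
#' Wrapped sequence lines are concatenated, record order is preserved and
#' sequences are upper-cased. Residues must come from the 20 standard amino
#' acids plus X.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `id`, `sequence`, `description` (free text
#'   after the first whitespace in the header, `""` if absent).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) stop("FASTA file contains no records: ", path, call. = FALSE)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(id == "")) stop("malformed FASTA header (empty id) in ", path, call. = FALSE)
  if (anyDuplicated(id)) {
    stop("duplicate FASTA id: ", id[duplicated(id)][1], call. = FALSE)
  }
  sequence <- toupper(as.character(set))
  if (any(nchar(sequence) == 0)) {
    stop("empty sequence for record ", id[nchar(sequence) == 0][1], call. = FALSE)
  }
  assert_aa(sequence, "FASTA sequence")
  tibble(id = unname(id), sequence = unname(sequence), description = unname(desc))
}

#' Write protein records to FASTA
#'
#' @param proteins a data frame with columns `id`, `sequence` and optionally
#'   `description`.
#' @param path output file path.
#' @param width line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  desc <- if ("description" %in% names(proteins)) proteins$description else ""
  hdr <- ifelse(desc == "" | is.na(desc), proteins$id, paste(proteins$id, desc))
  set <- Biostrings::AAStringSet(setNames(proteins$sequence, hdr))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
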