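#' Read and write protein FASTA files
#'
#' Thin tibble wrappers around Biostrings.  Duplicate record ids are
#' disambiguated with a numeric suffix (with a warning) so that ids stay
#' usable as keys downstream.
#'
#' @param path FASTA file path.
#' @return `read_fasta()`: a tibble with columns `id`, `seq`;
#'   `write_fasta()`: `path`, invisibly.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids disambiguated with suffixes",
            call. = FALSE)
    ids <- make.unique(ids, sep = "_dup")
  }
  tibble::tibble(id = ids, seq = unname(as.character(set)))
}

#' @rdname read_fasta
#' @param records Tibble with columns `id` and `seq`.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("id", "seq") %in% names(records)))
  set <- Biostrings::AAStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.check_protein <- function(seq) {
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), .AA20)
  if (length(bad)) {
    stop("non-amino-acid character(s) in sequence: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(seq)
}
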