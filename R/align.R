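#' Global pairwise alignment with a reference-position map
#'
#' Needleman-Wunsch global alignment (BLOSUM62, affine gaps, gap open
#' 10 / extend 1, via Biostrings) of a query protein against a reference,
#' augmented with the column map reference position -> query position
#' that underlies reference-numbered residue reporting.
#'
#' @param query,reference Protein sequences (single strings, standard
#'   20-letter alphabet).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param matrix Substitution matrix name (a Biostrings data set).
#' @return An object of class `acr_alignment`: list with `score`,
#'   `aligned_query`, `aligned_reference` (gapped strings), and `map`
#'   (integer vector of length `nchar(reference)`; `map[i]` is the
#'   1-based query index aligned to reference position `i`, `NA` at
#'   deletions).
#' @export
global_align <- function(query, reference, gap_open = 10, gap_extend = 1,
                         matrix = "BLOSUM62") {
  if (!nzchar(query) || !nzchar(reference)) {
    stop("sequences must be nonempty", call. = FALSE)
  }
  .check_protein(query)
  .check_protein(reference)
  submat <- get(utils::data(list = matrix, package = "Biostrings",
                            envir = environment()))
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = reference, type = "global",
    substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  aq <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ar <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  map <- rep(NA_integer_, nchar(reference))
  qi <- 0L; ri <- 0L
  for (k in seq_along(aq)) {
    if (aq[k] != "-") qi <- qi + 1L
    if (ar[k] != "-") {
      ri <- ri + 1L
      if (aq[k] != "-") map[ri] <- qi
    }
  }
  structure(
    list(score = Biostrings::score(aln),
         aligned_query = paste(aq, collapse = ""),
         aligned_reference = paste(ar, collapse = ""),
         map = map, query = query, reference = reference),
    class = "acr_alignment"
  )
}

#' @export
print.acr_alignment <- function(x, ...) {
  cat("<acr_alignment> score", x$score, "| query", nchar(x$query),
      "aa vs reference", nchar(x$reference), "aa\n")
  invisible(x)
}

#' Query residue at a reference-numbered position
#'
#' Reports, for each requested reference position, the query residue and
#' its native (1-based) index under the global alignment — the operation
#' behind statements like "the Glu90 homolog is Glu68".  A reference
#' position aligned to a gap yields `NA` residue and index (a sentinel,
#' not an error).
#'
#' @param query Query protein sequence, or an existing `acr_alignment`.
#' @param ref_pos Integer vector of reference positions.
#' @param reference Reference sequence (default the packaged
#'   channelrhodopsin-2-like reference, [acr_reference()]).
#' @return A tibble with `ref_pos`, `ref_residue`, `residue`,
#'   `query_index`.
#' @export
residue_at_reference_position <- function(query, ref_pos,
                                          reference = acr_reference()) {
  aln <- if (inherits(query, "acr_alignment")) query else
    global_align(query, reference)
  if (any(ref_pos < 1 | ref_pos > nchar(aln$reference))) {
    stop("ref_pos outside the reference length", call. = FALSE)
  }
  qchars <- strsplit(aln$query, "")[[1]]
  rchars <- strsplit(aln$reference, "")[[1]]
  qi <- aln$map[ref_pos]
  tibble::tibble(
    ref_pos = as.integer(ref_pos),
    ref_residue = rchars[ref_pos],
    residue = ifelse(is.na(qi), NA_character_, qchars[qi]),
    query_index = qi
  )
}
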