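# Selectivity-filter positions in channelrhodopsin-2 (CrChR2) numbering.
# 82/83/90/97/101 are the helix-2 (and 2-3 loop) glutamates, 117 the
# helix-3 glutamine neutralised-to-positive in engineered anion mutants,
# 123 the Schiff-base counterion (homolog of bacteriorhodopsin Asp85),
# 128 the DC-pair cysteine, 242 the helix-7 position that carries a
# glutamate in all natural ACRs.
FINGERPRINT_POSITIONS <- c(82L, 83L, 90L, 97L, 101L, 117L, 123L, 128L, 242L)

# residues of the packaged reference at those positions
.REF_FINGERPRINT <- c(`82` = "E", `83` = "E", `90` = "E", `97` = "E",
                      `101` = "E", `117` = "Q", `123` = "E", `128` = "C",
                      `242` = "V")

# transmembrane region (helix 1 start .. helix 7 end) of the packaged
# reference, used for coverage and dedup identity
.REF_TM <- c(start = 34L, end = 280L)

.pkg_cache <- new.env(parent = emptyenv())

#' Packaged reference sequence in channelrhodopsin-2 numbering
#'
#' The seven-transmembrane-domain reference against which all
#' reference-numbered positions are resolved.  It is a synthetic
#' stand-in constructed for this package (the true CrChR2 sequence is
#' not redistributed here): a 300-residue 7TM-like sequence that carries
#' the authentic CrChR2 selectivity-filter residues at the fingerprint
#' positions (Glu82, Glu83, Glu90, Glu97, Glu101, Gln117, the Glu123
#' counterion, Cys128, Val242) so that all reference-numbered reporting
#' behaves as with the real protein.  Numbering is 1-based from the
#' initiator methionine; the annotated transmembrane region spans
#' positions 34-280.
#'
#' @return A single protein sequence string.
#' @export
acr_reference <- function() {
  if (is.null(.pkg_cache$reference)) {
    path <- system.file("extdata", "crchr2_synthetic_reference.fasta",
                        package = "acrtools", mustWork = TRUE)
    .pkg_cache$reference <- read_fasta(path)$seq[1]
  }
  .pkg_cache$reference
}

#' Synthetic ACR fixture sequences
#'
#' Two synthetic homolog sequences constructed from the packaged
#' reference for worked examples and tests: `GtACR1_like` mirrors the
#' reported reference-numbering relations of GtACR1 (the Glu90 homolog
#' at native position 68, Ala61/Ala75 at the 83/97 positions, position
#' 79 at the 101 position) and `ZipACR_like` mirrors ZipACR's (Glu96,
#' Asn108 and Gly114 at the 101/117/123 positions).  Note the source
#' literature refers to GtACR1 position 79 both as Gln79 and, via the
#' N79E mutant, as Asn79; the fixture uses Asn and flags the discrepancy
#' here rather than resolving it.
#'
#' @return A tibble with columns `id`, `seq`.
#' @export
acr_fixture_sequences <- function() {
  path <- system.file("extdata", "synthetic_acr_fixtures.fasta",
                      package = "acrtools", mustWork = TRUE)
  read_fasta(path)
}

#' Selectivity-filter fingerprint of a query sequence
#'
#' Aligns the query to the packaged reference and reports the residues
#' at the nine reference-numbered selectivity-filter positions together
#' with their native indices.  Queries covering less than `min_coverage`
#' of the reference transmembrane region are rejected as partial
#' sequences.
#'
#' @param query Protein sequence string.
#' @param min_coverage Minimum aligned (non-gap) fraction of the
#'   reference transmembrane region.
#' @return An object of class `acr_fingerprint`: tibble with `ref_pos`,
#'   `ref_residue`, `residue`, `query_index`, plus attributes
#'   `coverage` and `query`.
#' @export
extract_fingerprint <- function(query, min_coverage = 0.7) {
  aln <- global_align(query, acr_reference())
  tm <- seq(.REF_TM["start"], .REF_TM["end"])
  coverage <- mean(!is.na(aln$map[tm]))
  if (coverage < min_coverage) {
    stop("partial sequence: only ", round(100 * coverage), "% of the ",
         "reference transmembrane region is covered (minimum ",
         round(100 * min_coverage), "%)", call. = FALSE)
  }
  rep <- residue_at_reference_position(aln, FINGERPRINT_POSITIONS)
  stopifnot(identical(rep$ref_residue, unname(.REF_FINGERPRINT)))
  structure(rep, class = c("acr_fingerprint", class(rep)),
            coverage = coverage, query = query)
}

#' Rule-based selectivity classification from a fingerprint
#'
#' Classifies a channelrhodopsin fingerprint by the residues at the
#' 90-position, the 123 counterion position and the 242-position:
#' natural anion channels conserve the 90-glutamate, carry a glutamate
#' at the 242-position and a non-carboxylate counterion; cation channels
#' keep a carboxylate counterion; engineered anion-conducting mutants
#' neutralise or invert the 90-glutamate.  The result always carries the
#' caveat that helix-2 glutamate content alone does not predict
#' selectivity (CCRs exist with ACR-like helix-2 patterns and natural
#' ACRs exist that retain the 101-glutamate).
#'
#' @param report An `acr_fingerprint` from [extract_fingerprint()].
#' @return A list with `label` (one of `"natural-ACR-like"`,
#'   `"CCR-like"`, `"engineered-anion-like"`, `"indeterminate"`),
#'   `evidence` (character), `caveat`.
#' @export
classify_selectivity <- function(report) {
  stopifnot(inherits(report, "acr_fingerprint"))
  res <- function(p) report$residue[report$ref_pos == p]
  r90 <- res(90); r123 <- res(123); r242 <- res(242)
  carbox <- function(x) !is.na(x) && x %in% c("D", "E")
  caveat <- paste("helix-2 glutamate content alone does not predict",
                  "anion vs cation selectivity")
  if (is.na(r90) || is.na(r123) || is.na(r242)) {
    return(list(label = "indeterminate",
                evidence = "fingerprint incomplete at positions 90/123/242",
                caveat = caveat))
  }
  if (r90 != "E") {
    label <- "engineered-anion-like"
    evidence <- paste0("non-carboxylate (", r90, ") at the 90-position, ",
                       "the signature of engineered Cl--conducting mutants")
  } else if (carbox(r242) && !carbox(r123)) {
    label <- "natural-ACR-like"
    evidence <- paste0("E at the 90-position, ", r242,
                       " at the 242-position and non-carboxylate (", r123,
                       ") counterion at the 123-position")
  } else if (carbox(r123)) {
    label <- "CCR-like"
    evidence <- paste0("E at the 90-position with a carboxylate (", r123,
                       ") Schiff-base counterion")
  } else {
    label <- "indeterminate"
    evidence <- paste0("E90-position with non-carboxylate counterion but ",
                       r242, " at the 242-position")
  }
  list(label = label, evidence = evidence, caveat = caveat)
}

#' Apply point mutations to a sequence
#'
#' Mutation specs use the usual `A61E` syntax (wild-type residue,
#' position, new residue), comma-separated or as a character vector.
#' Positions are native by default; with `numbering = "reference"` they
#' are first translated through the alignment to the packaged reference.
#' The stated wild-type residue must match the sequence, otherwise a
#' validation error names the residue actually observed.
#'
#' @param seq Protein sequence string.
#' @param specs Mutation spec(s), e.g. `"A61E,A75E,N79E"`.
#' @param numbering `"native"` or `"reference"`.
#' @return The mutated sequence string.
#' @export
apply_mutations <- function(seq, specs, numbering = c("native", "reference")) {
  numbering <- match.arg(numbering)
  specs <- unlist(strsplit(specs, "[,;]\\s*"))
  m <- regmatches(specs, regexec("^([A-Y])(\\d+)([A-Y])$", specs))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) {
    stop("malformed mutation spec(s): ",
         paste(specs[bad], collapse = ", "), call. = FALSE)
  }
  chars <- strsplit(seq, "")[[1]]
  map <- if (numbering == "reference") {
    global_align(seq, acr_reference())$map
  }
  for (mm in m) {
    wt <- mm[2]; pos <- as.integer(mm[3]); new <- mm[4]
    if (numbering == "reference") {
      qpos <- map[pos]
      if (is.na(qpos)) {
        stop("reference position ", pos, " is unaligned (gap) in the query",
             call. = FALSE)
      }
      pos <- qpos
    }
    if (pos < 1 || pos > length(chars)) {
      stop("position ", pos, " outside the sequence", call. = FALSE)
    }
    if (chars[pos] != wt) {
      stop("wild-type mismatch at position ", pos, ": spec says ", wt,
           " but sequence has ", chars[pos], call. = FALSE)
    }
    chars[pos] <- new
  }
  paste(chars, collapse = "")
}
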