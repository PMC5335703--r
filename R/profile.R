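#' Build a position-specific scoring profile from a seed alignment
#'
#' Per-column amino-acid frequencies with a Laplace pseudocount,
#' converted to log-odds (log2) against a uniform background.  Columns
#' with more than 50% gaps are marked insert-tolerant and get halved gap
#' penalties, so that variable loop regions do not dominate the score.
#' This is a position-specific profile with affine gaps — the
#' lightweight counterpart of a profile HMM sufficient for recursive
#' homology search; full forward-algorithm scoring is deliberately not
#' modelled.
#'
#' @param seeds Character vector of aligned sequences (equal length,
#'   `-` for gaps), or a tibble with a `seq` column of aligned
#'   sequences.
#' @param pseudocount Laplace pseudocount (> 0).
#' @param gap_open,gap_extend Base affine gap penalties.
#' @return An object of class `acr_profile`: list with `scores` (20 x L
#'   log-odds matrix), `probs` (20 x L column probabilities),
#'   `gap_open`/`gap_extend` (per-column), `insert_tolerant`,
#'   `background`, `consensus`, `seed_ids`.
#' @export
build_profile <- function(seeds, pseudocount = 1,
                          gap_open = 10, gap_extend = 1) {
  seed_ids <- NULL
  if (is.data.frame(seeds)) {
    seed_ids <- seeds$id
    seeds <- seeds$seq
  }
  if (length(seeds) < 1) stop("empty seed set", call. = FALSE)
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  lens <- nchar(seeds)
  if (length(unique(lens)) != 1) {
    stop("ragged alignment: seed sequences have unequal aligned lengths",
         call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(seeds), ""))
  L <- ncol(mat)
  bg <- stats::setNames(rep(1 / 20, 20), .AA20)
  counts <- apply(mat, 2, function(col) {
    table(factor(col[col %in% .AA20], levels = .AA20))
  })
  probs <- sweep(counts + pseudocount, 2,
                 colSums(counts + pseudocount), "/")
  scores <- log2(probs / bg)
  gap_frac <- colMeans(mat == "-")
  tol <- gap_frac > 0.5
  consensus <- apply(probs, 2, function(p) .AA20[which.max(p)])
  structure(
    list(scores = scores, probs = probs,
         gap_open = ifelse(tol, gap_open / 2, gap_open),
         gap_extend = ifelse(tol, gap_extend / 2, gap_extend),
         insert_tolerant = tol, background = bg,
         consensus = paste(consensus, collapse = ""),
         seed_ids = seed_ids),
    class = "acr_profile"
  )
}

#' @export
print.acr_profile <- function(x, ...) {
  cat("<acr_profile>", ncol(x$scores), "columns,",
      sum(x$insert_tolerant), "insert-tolerant;",
      length(x$seed_ids %||% character()), "seed ids\n")
  invisible(x)
}

# best local profile-to-sequence alignment score (Gotoh, affine gaps),
# vectorised over sequence positions row by row
.profile_score <- function(profile, seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, .AA20)
  if (anyNA(idx)) {
    stop("non-amino-acid character(s) in candidate sequence", call. = FALSE)
  }
  L <- ncol(profile$scores)
  n <- length(idx)
  # insertion penalties (extra sequence residues): base penalties
  oi <- max(profile$gap_open); ei <- max(profile$gap_extend)
  m_prev <- ix_prev <- iy_prev <- rep(0, n + 1)
  best <- 0
  j1 <- seq_len(n) + 1
  for (i in seq_len(L)) {
    s <- profile$scores[idx, i]
    diag_best <- pmax(m_prev[j1 - 1], ix_prev[j1 - 1], iy_prev[j1 - 1])
    m_row <- c(0, pmax(0, diag_best + s))
    iy_row <- c(0, pmax(m_prev[j1] - profile$gap_open[i],
                        iy_prev[j1] - profile$gap_extend[i]))
    # ix via cummax trick: ix[j] = max(m[j-1] - oi, ix[j-1] - ei)
    a <- m_row[j1 - 1] - oi + j1 * ei
    ix_row <- c(0, cummax(a) - j1 * ei)
    best <- max(best, m_row)
    m_prev <- m_row; ix_prev <- ix_row; iy_prev <- iy_row
  }
  best
}

#' Calibrate a profile score threshold on shuffled decoys
#'
#' Scores residue-shuffled versions of the supplied sequences against
#' the profile and returns the `1 - fpr` quantile of the decoy scores —
#' the default way to set a search threshold so that the decoy
#' false-positive rate stays below `fpr`.  (Scores of this profile are
#' not comparable to bit scores of other search tools, so no universal
#' threshold is packaged.)
#'
#' @param profile An `acr_profile`.
#' @param sequences Character vector of sequences to shuffle (typically
#'   the degapped seeds).
#' @param n_shuffles Shuffles per sequence.
#' @param fpr Target decoy false-positive rate.
#' @param seed RNG seed for the shuffles.
#' @return Numeric threshold.
#' @export
calibrate_profile_threshold <- function(profile, sequences,
                                        n_shuffles = 100, fpr = 0.005,
                                        seed = 1) {
  restore <- .seeded_rng(seed)
  on.exit(restore(), add = TRUE)
  decoys <- unlist(purrr::map(sequences, function(s) {
    ch <- strsplit(gsub("-", "", s), "")[[1]]
    purrr::map_chr(seq_len(n_shuffles),
                   ~ paste(sample(ch), collapse = ""))
  }))
  scores <- vapply(decoys, function(d) .profile_score(profile, d),
                   numeric(1))
  unname(stats::quantile(scores, 1 - fpr, type = 7)) + 1e-9
}

#' Score candidate sequences against a profile
#'
#' Best local profile-to-sequence alignment score (affine-gap dynamic
#' programming) for every candidate; candidates scoring at or above the
#' threshold are flagged as hits.
#'
#' @param profile An `acr_profile` from [build_profile()].
#' @param candidates Tibble with `id` and `seq` columns (or a named
#'   character vector).
#' @param threshold Score threshold; `NULL` calibrates one from
#'   shuffled decoys of the profile consensus via
#'   [calibrate_profile_threshold()].
#' @return A tibble of all candidates with `id`, `score`, `hit`,
#'   sorted by decreasing score; attribute `threshold`.
#' @export
profile_search <- function(profile, candidates, threshold = NULL) {
  stopifnot(inherits(profile, "acr_profile"))
  if (!is.data.frame(candidates)) {
    candidates <- tibble::tibble(
      id = names(candidates) %||% paste0("seq", seq_along(candidates)),
      seq = unname(candidates)
    )
  }
  if (nrow(candidates) == 0) stop("no candidate sequences", call. = FALSE)
  if (ncol(profile$scores) == 0) stop("empty profile", call. = FALSE)
  threshold <- threshold %||%
    calibrate_profile_threshold(profile, profile$consensus)
  out <- candidates |>
    dplyr::mutate(score = purrr::map_dbl(.data$seq,
                                         ~ .profile_score(profile, .x)),
                  hit = .data$score >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    dplyr::select(dplyr::all_of(c("id", "score", "hit")))
  structure(out, class = c("acr_profile_hits", class(out)),
            threshold = threshold)
}

# star alignment: project every sequence onto the coordinate system of
# the center (longest) sequence; insertions relative to the center are
# dropped
.star_align <- function(records) {
  if (length(unique(nchar(records$seq))) == 1) return(records$seq)
  center <- records$seq[which.max(nchar(records$seq))]
  vapply(records$seq, function(s) {
    if (identical(s, center)) return(center)
    aln <- global_align(s, center)
    q <- strsplit(s, "")[[1]]
    out <- rep("-", nchar(center))
    ok <- !is.na(aln$map)
    out[which(ok)] <- q[aln$map[ok]]
    paste(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Recursive profile search
#'
#' Iterative homology search: build a profile from the confirmed set,
#' score the database, add new hits passing the threshold, and repeat
#' until a fixed point or `max_rounds`.  The confirmed set never
#' shrinks, and the procedure is deterministic given its inputs.  This
#' is the strategy by which a handful of seed sequences recovers
#' progressively more divergent family members round by round.
#'
#' @param seeds Tibble with `id`, `seq` of confirmed family members
#'   (aligned or unaligned; unaligned seeds of unequal length are
#'   star-aligned to the longest).
#' @param database Tibble with `id`, `seq` of candidate sequences.
#' @param threshold Score threshold (`NULL`: calibrated per round from
#'   shuffled decoys of the current seeds, see
#'   [calibrate_profile_threshold()]).
#' @param max_rounds Maximum number of rounds (>= 1).
#' @return An object of class `acr_search`: list with `hits` (tibble
#'   `id`, `seq`, `score`, `round`), `profile` (final), `rounds` run,
#'   `provenance` (per-round hit counts).
#' @export
recursive_search <- function(seeds, database, threshold = NULL,
                             max_rounds = 5) {
  stopifnot(max_rounds >= 1)
  confirmed <- tibble::tibble(id = seeds$id, seq = seeds$seq)
  hits <- tibble::tibble(id = character(), seq = character(),
                         score = numeric(), round = integer())
  prof <- NULL
  rounds_run <- 0
  for (k in seq_len(max_rounds)) {
    aligned <- .star_align(confirmed)
    prof <- build_profile(tibble::tibble(id = confirmed$id, seq = aligned))
    thr <- threshold %||%
      calibrate_profile_threshold(prof, gsub("-", "", aligned))
    pool <- database[!database$id %in% c(confirmed$id, hits$id), ,
                     drop = FALSE]
    rounds_run <- k
    if (nrow(pool) == 0) break
    sc <- profile_search(prof, pool, thr)
    new <- sc[sc$hit, , drop = FALSE]
    if (nrow(new) == 0) break
    new_seq <- pool$seq[match(new$id, pool$id)]
    hits <- dplyr::bind_rows(
      hits,
      tibble::tibble(id = new$id, seq = new_seq, score = new$score,
                     round = k)
    )
    confirmed <- dplyr::bind_rows(
      confirmed, tibble::tibble(id = new$id, seq = new_seq)
    )
  }
  provenance <- hits |>
    dplyr::count(.data$round, name = "new_hits")
  structure(list(hits = hits, profile = prof, rounds = rounds_run,
                 provenance = provenance),
            class = "acr_search")
}

#' @export
print.acr_search <- function(x, ...) {
  cat("<acr_search>", nrow(x$hits), "hits over", x$rounds, "round(s)\n")
  invisible(x)
}

#' Remove partial and near-identical sequences
#'
#' Mirrors the manual curation step of a transcriptome screen: drop
#' sequences covering less than `min_coverage` of the reference
#' transmembrane region (partial transcripts), then, within each source
#' transcriptome, collapse pairs whose identity over the aligned
#' transmembrane region reaches `identity_threshold` — these are
#' assembly variants differing only at the termini — keeping the
#' longest.  The same pair coming from different sources is kept.
#'
#' @param hits Tibble with `id`, `seq` and optionally `source`
#'   (sequences without a source are treated as unique sources, with a
#'   warning).
#' @param min_coverage Minimum aligned fraction of the reference
#'   transmembrane region.
#' @param identity_threshold Transmembrane identity at or above which
#'   two same-source sequences are collapsed.
#' @return The filtered tibble, with a `dropped` attribute naming the
#'   removed ids and the reason.
#' @export
dedup_and_filter <- function(hits, min_coverage = 0.7,
                             identity_threshold = 0.99) {
  stopifnot(all(c("id", "seq") %in% names(hits)))
  hits <- tibble::as_tibble(hits)
  if (!"source" %in% names(hits) || anyNA(hits$source)) {
    warning("missing source label(s): treating those sequences as ",
            "unique sources", call. = FALSE)
    if (!"source" %in% names(hits)) hits$source <- NA_character_
    miss <- is.na(hits$source)
    hits$source[miss] <- paste0(".unique_", which(miss))
  }
  tm <- seq(.REF_TM["start"], .REF_TM["end"])
  ref <- acr_reference()
  profs <- purrr::map(hits$seq, function(s) {
    aln <- global_align(s, ref)
    q <- strsplit(s, "")[[1]]
    qi <- aln$map[tm]
    ifelse(is.na(qi), NA_character_, q[qi])
  })
  coverage <- purrr::map_dbl(profs, ~ mean(!is.na(.x)))
  dropped <- tibble::tibble(id = character(), reason = character())
  keep <- coverage >= min_coverage
  if (any(!keep)) {
    dropped <- dplyr::bind_rows(dropped, tibble::tibble(
      id = hits$id[!keep], reason = "partial sequence"
    ))
  }
  hits2 <- hits[keep, , drop = FALSE]
  profs2 <- profs[keep]
  drop_idx <- logical(nrow(hits2))
  for (src in unique(hits2$source)) {
    grp <- which(hits2$source == src)
    if (length(grp) < 2) next
    # keep longest first within the group
    grp <- grp[order(-nchar(hits2$seq[grp]))]
    for (a in seq_along(grp)[-1]) {
      i <- grp[a]
      if (drop_idx[i]) next
      for (b in seq_len(a - 1)) {
        j <- grp[b]
        if (drop_idx[j]) next
        both <- !is.na(profs2[[i]]) & !is.na(profs2[[j]])
        if (!any(both)) next
        ident <- mean(profs2[[i]][both] == profs2[[j]][both])
        if (ident >= identity_threshold) {
          drop_idx[i] <- TRUE
          dropped <- dplyr::bind_rows(dropped, tibble::tibble(
            id = hits2$id[i],
            reason = paste0("near-identical to ", hits2$id[j],
                            " from the same source")
          ))
          break
        }
      }
    }
  }
  out <- hits2[!drop_idx, , drop = FALSE]
  structure(out, dropped = dropped)
}

#' Write / read a profile as a documented text format
#'
#' Plain-text serialisation: a header with the alphabet and per-column
#' gap parameters, followed by the 20 x L log-odds matrix in TSV form.
#'
#' @param profile An `acr_profile`.
#' @param path File path.
#' @return `write_profile()`: `path` invisibly; `read_profile()`: the
#'   profile.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# acrtools profile v1",
    paste0("alphabet\t", paste(.AA20, collapse = "")),
    paste0("gap_open\t", paste(profile$gap_open, collapse = "\t")),
    paste0("gap_extend\t", paste(profile$gap_extend, collapse = "\t")),
    paste0("insert_tolerant\t",
           paste(as.integer(profile$insert_tolerant), collapse = "\t")),
    paste0("consensus\t", profile$consensus)
  ), con)
  utils::write.table(profile$scores, con, sep = "\t",
                     col.names = FALSE, row.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[2:6], "\t")
  scores <- utils::read.table(text = lines[-(1:6)], sep = "\t",
                              row.names = 1)
  scores <- as.matrix(scores)
  colnames(scores) <- NULL
  probs <- 2^scores / 20
  structure(
    list(scores = scores, probs = sweep(probs, 2, colSums(probs), "/"),
         gap_open = as.numeric(hdr[[2]][-1]),
         gap_extend = as.numeric(hdr[[3]][-1]),
         insert_tolerant = as.logical(as.integer(hdr[[4]][-1])),
         background = stats::setNames(rep(1 / 20, 20), .AA20),
         consensus = hdr[[5]][2], seed_ids = NULL),
    class = "acr_profile"
  )
}
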