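# shorter consensus keeps the DP affordable while preserving structure
short_ref <- substr(acr_reference(), 1, 150)

test_that("profile columns are normalized and favour the seed residues", {
  prof <- build_profile(rep("ACDE", 3))
  expect_equal(colSums(prof$probs), rep(1, 4))
  # the observed residue has the maximal log-odds in its column
  chars <- c("A", "C", "D", "E")
  for (j in 1:4) {
    expect_equal(names(which.max(prof$scores[, j])), chars[j])
  }
  expect_error(build_profile(c("ACDE", "ACD")), "ragged")
})

test_that("gappy columns become insert-tolerant with reduced penalties", {
  prof <- build_profile(c("AC-E", "A--E", "ACDE"))
  expect_equal(prof$insert_tolerant, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(prof$gap_open[3], prof$gap_open[1] / 2)
})

test_that("seeds outscore their shuffles against the profile", {
  set.seed(17)
  fam <- generate_synthetic_family(short_ref, 0.1, n = 4, seed = 31)
  prof <- build_profile(fam$seq)
  seed_score <- profile_search(prof, fam[1, ], threshold = -Inf)$score
  shuffles <- vapply(1:30, function(i) {
    s <- paste(sample(strsplit(fam$seq[1], "")[[1]]), collapse = "")
    profile_search(prof, tibble::tibble(id = "sh", seq = s),
                   threshold = -Inf)$score
  }, numeric(1))
  expect_true(all(seed_score > shuffles))
})

test_that("an infinite threshold yields no hits and empty profiles error", {
  fam <- generate_synthetic_family(short_ref, 0.1, n = 3, seed = 41)
  prof <- build_profile(fam$seq)
  res <- profile_search(prof, fam, threshold = Inf)
  expect_equal(sum(res$hit), 0)
  expect_equal(nrow(res), 3)
  expect_error(profile_search(prof, fam[0, ]), "no candidate")
})

test_that("planted homologs separate perfectly from shuffled decoys", {
  seeds <- generate_synthetic_family(short_ref, 0.15, n = 5, seed = 51)
  db <- generate_synthetic_family(short_ref, 0.4, n = 10, n_decoys = 100,
                                  seed = 52)
  prof <- build_profile(seeds$seq)
  res <- profile_search(prof, db)
  lab <- db$label[match(res$id, db$id)]
  expect_gt(min(res$score[lab == "homolog"]),
            max(res$score[lab == "decoy"]))
  # AUROC of the score as a homolog detector is exactly 1
  pos <- res$score[lab == "homolog"]; neg <- res$score[lab == "decoy"]
  auroc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_equal(auroc, 1)
  # the calibrated default threshold admits every homolog and at most
  # a stray decoy or two at the tail of the shuffle distribution
  expect_equal(sum(res$hit & lab == "homolog"), 10)
  expect_lte(sum(res$hit & lab == "decoy"), 2)
})

test_that("one-round recursive search equals plain search plus dedup", {
  seeds <- generate_synthetic_family(short_ref, 0.1, n = 3, seed = 61)
  db <- generate_synthetic_family(short_ref, 0.3, n = 5, n_decoys = 20,
                                  seed = 62)
  db$id <- paste0("db_", db$id)
  rs <- recursive_search(seeds, db, threshold = 100, max_rounds = 1)
  ps <- profile_search(build_profile(seeds$seq), db, threshold = 100)
  expect_setequal(rs$hits$id, ps$id[ps$hit])
  expect_true(all(rs$hits$round == 1))
})

test_that("recursive search is monotone and idempotent at its fixed point", {
  seeds <- generate_synthetic_family(short_ref, 0.1, n = 3, seed = 71)
  db <- generate_synthetic_family(short_ref, 0.3, n = 6, n_decoys = 10,
                                  seed = 72)
  db$id <- paste0("db_", db$id)
  r2 <- recursive_search(seeds, db, threshold = 100, max_rounds = 2)
  r5 <- recursive_search(seeds, db, threshold = 100, max_rounds = 5)
  # the confirmed set never shrinks: later rounds contain earlier hits
  expect_true(all(r2$hits$id %in% r5$hits$id))
  # fixed point: once nothing new is added, extra rounds change nothing
  expect_equal(r5$hits, recursive_search(seeds, db, threshold = 100,
                                         max_rounds = 8)$hits)
})

test_that("a far homolog tier is only reached after profile refresh", {
  near <- generate_synthetic_family(short_ref, 0.1, n = 5, seed = 82)
  # far tier: chained divergence through one of the unconfirmed near
  # homologs, so the far sequences only become reachable once that
  # intermediate joins the profile
  far <- generate_synthetic_family(near$seq[4], 0.3, n = 3, seed = 83)
  far$id <- sub("homolog", "far", far$id)
  seeds <- near[1:3, c("id", "seq")]
  db <- dplyr::bind_rows(near[4:5, ], far)
  # threshold just above what the seed-only profile gives the far tier
  s1 <- profile_search(build_profile(seeds$seq), db, threshold = -Inf)
  lab <- ifelse(grepl("far", s1$id), "far", "near")
  thr <- max(s1$score[lab == "far"]) + 5
  rs <- recursive_search(seeds, db, threshold = thr, max_rounds = 4)
  far_rounds <- rs$hits$round[grepl("far", rs$hits$id)]
  near_rounds <- rs$hits$round[!grepl("far", rs$hits$id)]
  expect_true(all(near_rounds == 1))
  expect_gt(length(far_rounds), 0)
  expect_true(all(far_rounds >= 2))
})

test_that("dedup removes partials and same-source near-duplicates only", {
  ref <- acr_reference()
  fam <- generate_synthetic_family(ref, 0.05, n = 2, seed = 91)
  twin <- fam$seq[1]  # identical duplicate, same source
  frag <- substr(fam$seq[2], 1, 120)  # partial
  hits <- tibble::tibble(
    id = c("a", "a_twin", "b", "b_othersrc", "frag"),
    seq = c(fam$seq[1], twin, fam$seq[2], fam$seq[2], frag),
    source = c("T1", "T1", "T2", "T3", "T1")
  )
  out <- dedup_and_filter(hits)
  expect_setequal(out$id, c("a", "b", "b_othersrc"))
  dropped <- attr(out, "dropped")
  expect_match(dropped$reason[dropped$id == "frag"], "partial")
  expect_match(dropped$reason[dropped$id == "a_twin"], "near-identical")
  # missing source labels warn and are kept as unique sources
  expect_warning(out2 <- dedup_and_filter(hits[, c("id", "seq")]),
                 "source")
  expect_equal(nrow(out2), 4)
})

test_that("profiles survive text serialisation", {
  fam <- generate_synthetic_family(short_ref, 0.1, n = 3, seed = 95)
  prof <- build_profile(fam$seq)
  path <- withr::local_tempfile(fileext = ".txt")
  write_profile(prof, path)
  back <- read_profile(path)
  expect_equal(back$scores, prof$scores, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$gap_open, unname(prof$gap_open))
  sc1 <- profile_search(prof, fam[1, ], threshold = -Inf)$score
  sc2 <- profile_search(back, fam[1, ], threshold = -Inf)$score
  expect_equal(sc1, sc2, tolerance = 1e-6)
})
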