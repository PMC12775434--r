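# The triage funnel: novelty filter, leader clustering, shortlist, and
# the staged pipeline.

test_that("novelty filter uses a strict cutoff and annotates max Tc", {
  smi <- fixture_smiles()
  lib <- screen_library(names(smi), unname(smi))
  # a known active identical to s01: Tc = 1 -> removed
  out <- novelty_filter(lib, known_actives = "c1ccccc1CCO", tc_cutoff = 0.5)
  expect_false("s01" %in% out$molecules$id)
  expect_true(all(out$molecules$max_tc_to_known <= 0.5))

  # strictness: a molecule sitting exactly at the cutoff is retained
  fps <- morgan_fp(lib)
  self <- novelty_filter(lib, known_actives = unname(smi["s10"]),
                         tc_cutoff = 1.0, fps = fps)
  expect_true("s10" %in% self$molecules$id)  # Tc = 1.0 is not > 1.0

  expect_warning(novelty_filter(lib, character(0)), "identity")
})

test_that("leader clustering honours its contract and matches brute force", {
  smi <- fixture_smiles()
  fps <- morgan_fp(smi)
  set.seed(42)
  scores <- rnorm(length(smi))
  ids <- names(smi)
  for (cutoff in c(0.3, 0.5, 0.7)) {
    cl <- leader_cluster(fps, scores, ids = ids, tc_cutoff = cutoff)
    # contract: representative in members, best score among members
    for (k in seq_len(nrow(cl))) {
      mem <- cl$member_ids[[k]]
      expect_true(cl$representative_id[k] %in% mem)
      expect_equal(cl$representative_score[k],
                   min(scores[match(mem, ids)]))
      # every member within cutoff of its representative
      ri <- match(cl$representative_id[k], ids)
      for (m in mem)
        expect_gt(tanimoto(fps[match(m, ids)], fps[ri]) + (m == cl$representative_id[k]),
                  cutoff)
    }
    # representatives pairwise <= cutoff similar
    reps <- match(cl$representative_id, ids)
    if (length(reps) > 1)
      for (i in seq_along(reps)[-1])
        for (j in seq_len(i - 1))
          expect_lte(tanimoto(fps[reps[i]], fps[reps[j]]), cutoff)
    # equals the independent brute-force oracle
    oracle <- oracle_leader_cluster(fps$bits, scores, ids, cutoff)
    expect_equal(sort(cl$representative_id), sort(ids[oracle$rep_idx]))
    oracle_members <- split(ids, oracle$assign)
    expect_setequal(
      vapply(cl$member_ids, function(m) paste(sort(m), collapse = "|"), ""),
      vapply(oracle_members, function(m) paste(sort(m), collapse = "|"), ""))
  }
})

test_that("degenerate clustering inputs behave as stated", {
  # n copies of one molecule -> a single cluster of size n
  fps <- morgan_fp(setNames(rep("c1ccccc1CCO", 5), paste0("m", 1:5)))
  cl <- leader_cluster(fps, scores = c(3, 1, 2, 5, 4))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$size, 5)
  expect_equal(cl$representative_id, "m2")  # best (lowest) score

  # mutually dissimilar molecules -> all singletons
  div <- c(a = "CCCCCCCC", b = "c1ccccc1c1ccccc1", c = "OCC(O)C(O)CO")
  fpd <- morgan_fp(div)
  cld <- leader_cluster(fpd, scores = c(1, 2, 3))
  expect_equal(nrow(cld), 3)
  expect_true(all(cld$size == 1))
})

test_that("shortlist selection is ordered and order-invariant", {
  clusters <- data.frame(representative_id = c("x", "y", "z"),
                         representative_score = c(-40, -35, -30),
                         size = c(3L, 1L, 2L))
  sl <- build_shortlist(clusters, n = 2)
  expect_equal(sl$id, c("x", "y"))
  sl_all <- build_shortlist(clusters, n = 1500)
  expect_equal(nrow(sl_all), 3)
  # shuffled cluster input -> identical shortlist
  sh <- build_shortlist(clusters[c(3, 1, 2), ], n = 2)
  expect_equal(sh$id, sl$id)
  expect_error(build_shortlist(clusters, n = 0), "positive")
})

test_that("the funnel applies stages in order with monotone survivor counts", {
  sc <- make_screen(n_molecules = 400, n_actives = 30,
                    score_advantage = 2, seed = 11)
  cfg <- funnel_config(top_n_scores = 150, shortlist_n = 40)
  known <- c("c1ccsc1C(=O)NCCO")   # resembles the planted chemotype
  sl <- run_funnel(sc$library, known_actives = known, config = cfg)
  counts <- attr(sl, "stage_counts")
  expect_equal(unname(counts["input"]), 400)
  expect_true(all(diff(counts[c("input", "top_n", "interference",
                                "novelty")]) <= 0))
  expect_lte(counts["clusters"], counts["novelty"])
  expect_lte(nrow(sl), 40)
  expect_false(any(duplicated(sl$id)))
  expect_true(all(diff(sl$score_total) >= 0))  # best first

  # determinism and input-order invariance
  sl2 <- run_funnel(sc$library, known_actives = known, config = cfg)
  expect_identical(sl$id, sl2$id)
  perm <- sample(length(sc$library))
  lib_shuf <- screen_library(sc$library$molecules$id[perm],
                             sc$library$molecules$smiles[perm],
                             records = sc$library$records[rev(seq_len(400)), ])
  sl3 <- run_funnel(lib_shuf, known_actives = known, config = cfg)
  expect_identical(sl$id, sl3$id)
})

test_that("a library of all-interference molecules yields an empty shortlist", {
  lib <- screen_library(c("q1", "q2"),
                        c("O=C1C=CC(=O)C=C1", "O=C1CSC(=S)N1"),
                        records = data.frame(
                          molecule_id = c("q1", "q2"),
                          score_total = c(-10, -9)))
  sl <- run_funnel(lib, config = funnel_config(top_n_scores = 10,
                                               shortlist_n = 10))
  expect_equal(nrow(sl), 0)
  expect_equal(unname(attr(sl, "stage_counts")["interference"]), 0)
})

test_that("planted-signal screens enrich the shortlist in actives", {
  sc <- make_screen(n_molecules = 2000, n_actives = 40,
                    score_advantage = 2, seed = 5)
  cfg <- funnel_config(top_n_scores = 200, shortlist_n = 60)
  sl <- run_funnel(sc$library, config = cfg)
  hits <- sum(sc$truth$active[match(sl$id, sc$truth$id)])
  # one-sided test against the hypergeometric draw of nrow(sl) from the
  # library (40 actives / 2000)
  pval <- stats::phyper(hits - 1, 40, 2000 - 40, nrow(sl),
                        lower.tail = FALSE)
  expect_lt(pval, 0.01)
})

test_that("with zero planted signal the shortlist is unbiased in actives", {
  # chemistry fixed once; score randomization repeated 1000 times
  sc <- make_screen(n_molecules = 150, n_actives = 15,
                    score_advantage = 0, seed = 9)
  fps <- morgan_fp(sc$library)
  ids <- sc$library$molecules$id
  active <- sc$truth$active[match(ids, sc$truth$id)]
  set.seed(99)
  tot_hits <- 0; tot_n <- 0
  for (t in 1:1000) {
    scores <- rnorm(150)
    cl <- leader_cluster(fps, scores, ids = ids, tc_cutoff = 0.5)
    sl <- build_shortlist(cl, n = 20)
    tot_hits <- tot_hits + sum(active[match(sl$id, ids)])
    tot_n <- tot_n + nrow(sl)
  }
  frac <- tot_hits / tot_n
  p <- 15 / 150
  se <- sqrt(p * (1 - p) / tot_n)
  # clustering may slightly reweight chemotypes; allow 5 se plus a small
  # structural margin around the library fraction
  expect_lt(abs(frac - p), 5 * se + 0.02)
})
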