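# The post-docking triage funnel: top-N extraction, interference and
# novelty filtering, score-ordered leader clustering, shortlist building.

#' Funnel configuration
#'
#' Defaults mirror a full-scale campaign: the top 300,000 scorers are
#' triaged, similarity cutoffs of 0.5 are used for both novelty exclusion
#' (strict `>`) and leader clustering, and the top 1500 cluster
#' representatives form the shortlist.
#'
#' @param top_n_scores number of best-scoring molecules entering triage.
#' @param novelty_tc_cutoff molecules with max Tanimoto to a known active
#'   strictly greater than this are excluded.
#' @param cluster_tc_cutoff leader-clustering similarity cutoff.
#' @param shortlist_n number of cluster representatives retained.
#' @param interference_smarts data frame of interference patterns
#'   (`id`, `smarts`).
#' @param fp_radius,fp_nbits Morgan fingerprint parameters.
#' @return a `funnel_config` list.
#' @export
funnel_config <- function(top_n_scores = 300000, novelty_tc_cutoff = 0.5,
                          cluster_tc_cutoff = 0.5, shortlist_n = 1500,
                          interference_smarts = pains_patterns(),
                          fp_radius = 2, fp_nbits = 2048) {
  stopifnot(top_n_scores > 0, shortlist_n > 0,
            novelty_tc_cutoff >= 0, novelty_tc_cutoff <= 1,
            cluster_tc_cutoff >= 0, cluster_tc_cutoff <= 1)
  structure(list(top_n_scores = top_n_scores,
                 novelty_tc_cutoff = novelty_tc_cutoff,
                 cluster_tc_cutoff = cluster_tc_cutoff,
                 shortlist_n = shortlist_n,
                 interference_smarts = interference_smarts,
                 fp_radius = fp_radius, fp_nbits = fp_nbits),
            class = "funnel_config")
}

#' Novelty filter against known actives
#'
#' Excludes molecules whose maximal Tanimoto similarity to any known
#' active is strictly greater than `tc_cutoff`. Retained molecules are
#' annotated with their max Tc (`max_tc_to_known` column).
#'
#' @param library a `screen_library`.
#' @param known_actives character vector of SMILES (or a `screen_library`).
#' @param tc_cutoff exclusion cutoff (strict `>`; default 0.5).
#' @param fps,active_fps optional precomputed fingerprints.
#' @return the filtered, annotated library.
#' @export
novelty_filter <- function(library, known_actives, tc_cutoff = 0.5,
                           fps = NULL, active_fps = NULL) {
  known <- if (is(known_actives, "screen_library"))
    known_actives$molecules$smiles else known_actives
  if (is.null(known) || !length(known)) {
    warning("no known actives supplied: novelty filter is the identity")
    library$molecules$max_tc_to_known <- NA_real_
    return(library)
  }
  if (!length(library)) {
    library$molecules$max_tc_to_known <- numeric(0)
    return(library)
  }
  if (is.null(fps)) fps <- morgan_fp(library)
  if (is.null(active_fps))
    active_fps <- morgan_fp(known, radius = fps$radius, nbits = fps$nbits)
  mtc <- tc_max(fps, active_fps)
  keep <- mtc <= tc_cutoff
  library$molecules$max_tc_to_known <- mtc
  library$molecules <- library$molecules[keep, , drop = FALSE]
  if (!is.null(library$records))
    library$records <- library$records[
      library$records$molecule_id %in% library$molecules$id, , drop = FALSE]
  library
}

#' Score-ordered leader clustering on fingerprints
#'
#' Molecules are processed best score first (ties broken by lexicographic
#' id). Each molecule joins the first existing cluster whose representative
#' has Tanimoto similarity strictly greater than `tc_cutoff` to it,
#' otherwise it founds a new cluster. Hence every member is `> tc_cutoff`
#' similar to its representative, representatives are pairwise
#' `<= tc_cutoff` similar, and each representative carries the best score
#' of its cluster.
#'
#' @param fps an `fp_set` for the molecules.
#' @param scores numeric scores, lower is better.
#' @param ids molecule identifiers (default from `fps`).
#' @param tc_cutoff similarity cutoff (default 0.5).
#' @return data frame with one row per cluster: `representative_id`,
#'   `representative_score`, `size`, and list column `member_ids`; ordered
#'   by representative score.
#' @export
leader_cluster <- function(fps, scores, ids = fps$ids, tc_cutoff = 0.5) {
  stopifnot(length(scores) == length(fps$bits),
            length(ids) == length(fps$bits))
  if (any(!is.finite(scores))) stop("scores must be finite")
  n <- length(scores)
  if (n == 0)
    return(data.frame(representative_id = character(),
                      representative_score = numeric(), size = integer()))
  ord <- order(scores, ids)
  nbits <- fps$nbits
  cap <- 64L
  m <- matrix(0, nrow = nbits, ncol = cap)  # rep bit matrix, creation order
  pc <- numeric(cap)
  nreps <- 0L
  rep_row <- integer(0)
  assign <- integer(n)
  for (i in ord) {
    bits <- fps$bits[[i]]
    joined <- 0L
    if (nreps > 0 && length(bits)) {
      inter <- colSums(m[bits, seq_len(nreps), drop = FALSE])
      tc <- inter / (pc[seq_len(nreps)] + length(bits) - inter)
      hit <- which(tc > tc_cutoff)
      if (length(hit)) joined <- hit[1]
    }
    if (joined == 0L) {
      nreps <- nreps + 1L
      if (nreps > cap) {
        cap2 <- cap * 2L
        m2 <- matrix(0, nrow = nbits, ncol = cap2)
        m2[, seq_len(cap)] <- m
        m <- m2; pc <- c(pc, numeric(cap2 - cap)); cap <- cap2
      }
      if (length(bits)) m[bits, nreps] <- 1
      pc[nreps] <- length(bits)
      rep_row[nreps] <- i
      joined <- nreps
    }
    assign[i] <- joined
  }
  members <- split(ids[ord], assign[ord])  # ord-order within cluster
  members <- members[as.character(seq_len(nreps))]
  out <- data.frame(representative_id = ids[rep_row],
                    representative_score = scores[rep_row],
                    size = lengths(members),
                    stringsAsFactors = FALSE)
  out$member_ids <- unname(members)
  out
}

#' Build the ranked shortlist from clusters
#'
#' Representatives sorted best score first (ties by id); the first
#' `min(n, #clusters)` are retained with their annotations.
#'
#' @param clusters data frame from [leader_cluster()].
#' @param n shortlist size (default 1500).
#' @param molecules optional molecule table (`id`, `smiles`, and optionally
#'   `max_tc_to_known`) used to annotate the shortlist.
#' @return a `shortlist` data frame: `rank`, `id`, `smiles`, `score_total`,
#'   `cluster_size`, `max_tc_to_known`, `flags`.
#' @export
build_shortlist <- function(clusters, n = 1500, molecules = NULL) {
  if (n <= 0) stop("shortlist size must be positive")
  ord <- order(clusters$representative_score, clusters$representative_id)
  top <- clusters[ord, , drop = FALSE][seq_len(min(n, nrow(clusters))), ,
                                       drop = FALSE]
  k <- nrow(top)
  out <- data.frame(
    rank = seq_len(k),
    id = top$representative_id,
    smiles = rep_len(NA_character_, k),
    score_total = top$representative_score,
    cluster_size = top$size,
    max_tc_to_known = rep_len(NA_real_, k),
    flags = rep_len("", k),
    stringsAsFactors = FALSE)
  if (!is.null(molecules) && nrow(out)) {
    j <- match(out$id, molecules$id)
    out$smiles <- molecules$smiles[j]
    if ("max_tc_to_known" %in% names(molecules))
      out$max_tc_to_known <- molecules$max_tc_to_known[j]
  }
  rownames(out) <- NULL
  class(out) <- c("shortlist", "data.frame")
  out
}

#' Run the full post-docking triage funnel
#'
#' Stages, in order: take the `top_n_scores` best `score_total` records,
#' remove interference (PAINS) matches, remove molecules too similar to
#' known actives, leader-cluster the survivors, and keep the top
#' `shortlist_n` cluster representatives. Per-stage survivor counts are
#' reported on the `"stage_counts"` attribute.
#'
#' @param library a `screen_library` with dock records.
#' @param known_actives character vector of SMILES of known ligands
#'   (or `NULL` to skip the novelty stage).
#' @param config a [funnel_config()].
#' @return a `shortlist` with attribute `"stage_counts"`.
#' @export
run_funnel <- function(library, known_actives = NULL,
                       config = funnel_config()) {
  if (is.null(library$records)) stop("library has no dock records")
  counts <- c(input = length(library))

  rec <- library$records
  ord <- order(rec$score_total, rec$molecule_id)
  rec <- rec[ord, , drop = FALSE]
  rec <- rec[seq_len(min(config$top_n_scores, nrow(rec))), , drop = FALSE]
  lib <- new_screen_library(
    library$molecules[match(rec$molecule_id, library$molecules$id), ,
                      drop = FALSE],
    records = rec, provenance = library$provenance)
  counts["top_n"] <- length(lib)

  lib <- interference_filter(lib, config$interference_smarts)
  counts["interference"] <- length(lib)

  if (!is.null(known_actives) && length(known_actives) && length(lib)) {
    fps <- morgan_fp(lib, radius = config$fp_radius, nbits = config$fp_nbits)
    lib <- novelty_filter(lib, known_actives, config$novelty_tc_cutoff,
                          fps = fps)
  } else {
    lib$molecules$max_tc_to_known <- rep(NA_real_, nrow(lib$molecules))
  }
  counts["novelty"] <- length(lib)

  if (length(lib)) {
    fps <- morgan_fp(lib, radius = config$fp_radius, nbits = config$fp_nbits)
    sc <- lib$records$score_total[match(lib$molecules$id,
                                        lib$records$molecule_id)]
    clusters <- leader_cluster(fps, sc, ids = lib$molecules$id,
                               tc_cutoff = config$cluster_tc_cutoff)
  } else {
    clusters <- data.frame(representative_id = character(),
                           representative_score = numeric(),
                           size = integer())
  }
  counts["clusters"] <- nrow(clusters)

  sl <- build_shortlist(clusters, config$shortlist_n,
                        molecules = lib$molecules)
  counts["shortlist"] <- nrow(sl)
  attr(sl, "stage_counts") <- counts
  sl
}
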