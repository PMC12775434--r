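# Decoy-set generation and retrospective enrichment metrics used to
# calibrate a docking setup before a prospective screen.

#' Default property-matching tolerance bands for decoy selection
#'
#' @param mw molecular-weight band in Da.
#' @param clogp cLogP band.
#' @param hbd,hba,rotatable_bonds count bands.
#' @param charge_exact require identical net formal charge.
#' @return named list of bands.
#' @export
decoy_bands <- function(mw = 25, clogp = 1.0, hbd = 1, hba = 1,
                        rotatable_bonds = 1, charge_exact = TRUE) {
  list(mw = mw, clogp = clogp, hbd = hbd, hba = hba,
       rotatable_bonds = rotatable_bonds, charge_exact = charge_exact)
}

in_band <- function(pool, ref, band, shift = 0) {
  d <- abs(pool - ref)
  if (shift == 0) d <= band else d > band & d <= 2 * band
}

#' Generate decoy sets for a list of actives
#'
#' Three modes: `matched` draws pool molecules inside per-property
#' tolerance bands around each active; `perturbed` draws from a band ring
#' shifted outward by one band width (counts widened by one, charge
#' unconstrained); `extrema` draws from the joint property tails of the
#' pool (top/bottom deciles of MW and cLogP). Sampling is without
#' replacement across the whole set and seeded. Actives are never decoys
#' (canonical-structure check).
#'
#' @param actives character vector of active SMILES (named by id) or a
#'   `screen_library`.
#' @param pool a `screen_library` to draw decoys from.
#' @param mode `"matched"`, `"perturbed"` or `"extrema"`.
#' @param n_per_active decoys requested per active.
#' @param seed integer seed.
#' @param bands [decoy_bands()].
#' @param pool_properties,active_properties optional precomputed property
#'   tables.
#' @return a `decoy_set`: list with `mode`, `decoys` (data frame of id,
#'   smiles and properties), `source_actives`, `shortfall`.
#' @export
generate_decoys <- function(actives, pool,
                            mode = c("matched", "perturbed", "extrema"),
                            n_per_active = 50, seed = 1,
                            bands = decoy_bands(),
                            pool_properties = NULL,
                            active_properties = NULL) {
  mode <- match.arg(mode)
  act_smi <- lib_smiles(actives)
  pool <- ensure_canonical(pool)
  act_can <- canonical_smiles(unname(act_smi))
  if (is.null(pool_properties)) pool_properties <- compute_properties(pool)
  pp <- pool_properties[match(pool$molecules$id, pool_properties$id), ]
  eligible_all <- !(pool$molecules$cansmi %in% act_can)

  set.seed(seed)
  chosen <- character(0)
  shortfall <- setNames(integer(length(act_smi)), names(act_smi))

  if (mode == "extrema") {
    qs_mw <- quantile(pp$mw, c(0.1, 0.9))
    qs_lp <- quantile(pp$clogp, c(0.1, 0.9))
    tails <- (pp$mw <= qs_mw[1] | pp$mw >= qs_mw[2] |
                pp$clogp <= qs_lp[1] | pp$clogp >= qs_lp[2]) & eligible_all
    want <- n_per_active * length(act_smi)
    ids <- pool$molecules$id[tails]
    chosen <- if (length(ids) > want) sample(ids, want) else ids
    if (length(ids) < want) {
      warning("extrema decoy pool shortfall: wanted ", want, ", got ",
              length(ids))
      shortfall[] <- ceiling((want - length(ids)) / length(act_smi))
    }
  } else {
    if (is.null(active_properties))
      active_properties <- compute_properties(act_smi)
    ap <- active_properties
    shift <- if (mode == "perturbed") 1 else 0
    avail <- eligible_all
    for (i in seq_along(act_smi)) {
      ok <- in_band(pp$mw, ap$mw[i], bands$mw, shift) &
        in_band(pp$clogp, ap$clogp[i], bands$clogp, shift)
      if (mode == "matched") {
        ok <- ok & abs(pp$hbd - ap$hbd[i]) <= bands$hbd &
          abs(pp$hba - ap$hba[i]) <= bands$hba &
          abs(pp$rotatable_bonds - ap$rotatable_bonds[i]) <=
            bands$rotatable_bonds
        if (isTRUE(bands$charge_exact))
          ok <- ok & pp$net_charge == ap$net_charge[i]
      } else {
        ok <- ok & abs(pp$hbd - ap$hbd[i]) <= bands$hbd + 1 &
          abs(pp$hba - ap$hba[i]) <= bands$hba + 1 &
          abs(pp$rotatable_bonds - ap$rotatable_bonds[i]) <=
            bands$rotatable_bonds + 1
      }
      cand <- which(ok & avail)
      take <- min(n_per_active, length(cand))
      if (take < n_per_active)
        shortfall[i] <- n_per_active - take
      if (take > 0) {
        pick <- if (length(cand) == 1) cand else sample(cand, take)
        avail[pick] <- FALSE
        chosen <- c(chosen, pool$molecules$id[pick])
      }
    }
    if (any(shortfall > 0))
      warning("decoy shortfall for ", sum(shortfall > 0), " active(s): ",
              paste0(names(shortfall)[shortfall > 0], " (-",
                     shortfall[shortfall > 0], ")", collapse = ", "))
  }
  j <- match(chosen, pool$molecules$id)
  decoys <- cbind(pool$molecules[j, c("id", "smiles", "cansmi")],
                  pp[match(chosen, pp$id),
                     c("mw", "clogp", "hbd", "hba", "rotatable_bonds",
                       "net_charge")])
  rownames(decoys) <- NULL
  structure(list(mode = mode, decoys = decoys,
                 source_actives = names(act_smi), shortfall = shortfall),
            class = "decoy_set")
}

#' @export
print.decoy_set <- function(x, ...) {
  cat("decoy_set:", nrow(x$decoys), "decoys, mode", x$mode, "for",
      length(x$source_actives), "actives\n")
  invisible(x)
}

#' Enrichment of actives over decoys
#'
#' Computes the enrichment factor at the top 1% of the pooled ranking
#' (EF1%) and the adjusted logAUC: the area under the ROC curve plotted on
#' a log10 false-positive-rate axis from `lambda` (default 0.1%) to 100%,
#' normalized to 100, minus the random-ranking baseline (14.46 points at
#' the default `lambda`). Lower scores rank better; ties are broken
#' pessimistically for actives (decoys rank first at equal score). Both
#' metrics are rank-based and hence invariant to any strictly monotone
#' transform of the scores.
#'
#' @param scored_actives,scored_decoys numeric score vectors.
#' @param top_frac top fraction for the enrichment factor (default 0.01).
#' @param lambda lower FPR limit of the log-scaled ROC area
#'   (default 0.001, i.e. 0.1%).
#' @param higher_is_better negate scores that are higher-is-better.
#' @return an `enrichment_result`: `ef1`, `adjusted_logauc` (percentage
#'   points), `logauc`, `n_actives`, `n_decoys`.
#' @export
enrichment <- function(scored_actives, scored_decoys, top_frac = 0.01,
                       lambda = 0.001, higher_is_better = FALSE) {
  if (!length(scored_actives) || !length(scored_decoys))
    stop("both score lists must be non-empty")
  a <- as.numeric(scored_actives); d <- as.numeric(scored_decoys)
  if (higher_is_better) { a <- -a; d <- -d }
  if (length(unique(c(a, d))) == 1)
    warning("all scores identical; metrics computed under pessimistic ties")
  na <- length(a); nd <- length(d)

  score <- c(d, a)
  is_active <- c(rep(0L, nd), rep(1L, na))
  ord <- order(score, is_active)   # ties: decoys first (pessimistic)
  act_pos <- which(is_active[ord] == 1L)

  n_top <- max(1L, floor(top_frac * (na + nd)))
  ef <- (sum(act_pos <= n_top) / na) / top_frac

  # decoys ranked above each active, in ranking order
  fpr <- (act_pos - seq_len(na)) / nd
  fpr <- pmax(fpr, lambda)
  # step-function TPR integrated against d log10(FPR)
  xs <- c(fpr, 1)
  tpr <- seq_len(na) / na
  auc <- sum(tpr * (log10(xs[-1]) - log10(xs[-length(xs)])))
  logauc <- 100 * auc / log10(1 / lambda)
  random <- 100 * ((1 - lambda) / log(10)) / log10(1 / lambda)
  structure(list(ef1 = ef, adjusted_logauc = logauc - random,
                 logauc = logauc, n_actives = na, n_decoys = nd,
                 lambda = lambda),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment: EF1%% = %.2f, adjusted logAUC = %.2f (%d actives, %d decoys)\n",
    x$ef1, x$adjusted_logauc, x$n_actives, x$n_decoys))
  invisible(x)
}
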