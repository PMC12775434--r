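# Pharmacological screen analysis: normalization, two-addition
# agonist/antagonist classification, 4PL concentration-response fitting,
# potency ratios, and brain-to-plasma exposure.

#' Normalize a raw assay signal to buffer (0%) and reference (100%)
#'
#' `100 * (raw - buffer) / (reference - buffer)`. Affine-invariant: a
#' common affine rescaling of all three signals leaves the percent
#' unchanged. Responses above 100% are not clipped.
#'
#' @param raw,buffer,reference raw signals (vectors recycle).
#' @return percent response.
#' @export
normalize_response <- function(raw, buffer, reference) {
  if (any(reference == buffer))
    stop("reference equals buffer: normalization undefined")
  100 * (raw - buffer) / (reference - buffer)
}

#' Primary-screen configuration
#'
#' @param agonist_threshold percent response in the agonist-mode step at
#'   or above which a compound is an agonist (default 25).
#' @param antagonist_suppression percent of the expected EC80 response
#'   below which the second-step response counts as suppressed
#'   (default 50).
#' @param ec80_percent expected second-step response, as percent of the
#'   reference maximum, produced by the EC80 reference addition
#'   (default 80).
#' @return a `screen_config` list.
#' @export
screen_config <- function(agonist_threshold = 25,
                          antagonist_suppression = 50,
                          ec80_percent = 80) {
  stopifnot(agonist_threshold > 0, agonist_threshold <= 100,
            antagonist_suppression > 0, antagonist_suppression <= 100)
  structure(list(agonist_threshold = agonist_threshold,
                 antagonist_suppression = antagonist_suppression,
                 ec80_percent = ec80_percent),
            class = "screen_config")
}

#' Two-addition agonist/antagonist classification
#'
#' First addition: test compound (agonist mode); second addition: an EC80
#' concentration of the reference agonist (antagonist mode). A compound is
#' an agonist iff its first-step response reaches the agonist threshold.
#' Otherwise it is an antagonist iff the second-step response is
#' suppressed below the configured fraction of the expected EC80 response;
#' else inactive. A blunted second step never demotes an agonist: after
#' strong activation the receptor is desensitized, so a second agonist
#' addition produces little response.
#'
#' @param plates data frame with columns `compound_id`, `step1_response`,
#'   `step2_response`, `buffer_response`, `reference_response`
#'   (raw signals).
#' @param config a [screen_config()].
#' @return data frame `compound_id`, `step1_pct`, `step2_pct_of_ec80`,
#'   `class` (factor: agonist/antagonist/inactive).
#' @export
classify_two_step <- function(plates, config = screen_config()) {
  need <- c("compound_id", "step1_response", "step2_response",
            "buffer_response", "reference_response")
  stopifnot(all(need %in% names(plates)))
  s1 <- normalize_response(plates$step1_response, plates$buffer_response,
                           plates$reference_response)
  s2 <- normalize_response(plates$step2_response, plates$buffer_response,
                           plates$reference_response)
  s2rel <- 100 * s2 / config$ec80_percent
  cls <- ifelse(s1 >= config$agonist_threshold, "agonist",
                ifelse(s2rel < config$antagonist_suppression,
                       "antagonist", "inactive"))
  data.frame(compound_id = plates$compound_id, step1_pct = s1,
             step2_pct_of_ec80 = s2rel,
             class = factor(cls, levels = c("agonist", "antagonist",
                                            "inactive")),
             stringsAsFactors = FALSE)
}

# Four-parameter logistic on log10 concentration.
fpl <- function(logc, bottom, top, logec50, hill) {
  bottom + (top - bottom) / (1 + 10^((logec50 - logc) * hill))
}

#' Fit a four-parameter logistic concentration-response curve
#'
#' Least-squares fit of
#' `response = bottom + (top - bottom) / (1 + 10^((logEC50 - log10 c) * hill))`
#' (the log(agonist) versus response model with variable slope).
#' Replicates at a concentration are averaged before fitting.
#' Multi-start Levenberg-Marquardt local optimization with seeded,
#' data-driven starting points; non-convergence returns the best-found
#' parameters with `converged = FALSE`, never an exception.
#'
#' @param concentration molar concentrations (strictly positive).
#' @param response percent responses (same length).
#' @param seed integer seed for the start jitter.
#' @param n_starts number of random starts (default 5).
#' @return a `fit_result`: `ec50`, `log_ec50`, `top`, `bottom`, `hill`,
#'   `se` (named vector), `converged`, `rss`, `n`.
#' @export
fit_crc <- function(concentration, response, seed = 1, n_starts = 5) {
  stopifnot(length(concentration) == length(response),
            all(concentration > 0))
  agg <- tapply(response, concentration, mean)
  conc <- as.numeric(names(agg))
  resp <- as.numeric(agg)
  if (length(conc) < 4)
    stop("need at least 4 distinct concentrations to fit a 4PL")
  lc <- log10(conc)
  df <- data.frame(lc = lc, resp = resp)

  set.seed(seed)
  mid <- (max(resp) + min(resp)) / 2
  lec_guess <- lc[which.min(abs(resp - mid))]
  starts <- list(list(bottom = min(resp), top = max(resp),
                      logec50 = lec_guess, hill = 1))
  for (k in seq_len(max(0, n_starts - 1))) {
    starts[[k + 1]] <- list(
      bottom = min(resp) + rnorm(1, 0, 2),
      top = max(resp) + rnorm(1, 0, 2),
      logec50 = runif(1, min(lc), max(lc)),
      hill = runif(1, 0.5, 2.5))
  }
  best <- NULL
  best_rss <- Inf
  for (st in starts) {
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      resp ~ fpl(lc, bottom, top, logec50, hill),
      data = df, start = st,
      control = minpack.lm::nls.lm.control(maxiter = 300))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (rss < best_rss) { best <- fit; best_rss <- rss }
  }
  if (is.null(best)) {
    # fall back to a derivative-free search; flagged unconverged
    obj <- function(p) sum((resp - fpl(lc, p[1], p[2], p[3], p[4]))^2)
    o <- optim(c(min(resp), max(resp), lec_guess, 1), obj)
    pars <- setNames(o$par, c("bottom", "top", "logec50", "hill"))
    res <- list(ec50 = 10^pars[["logec50"]],
                log_ec50 = pars[["logec50"]],
                top = pars[["top"]], bottom = pars[["bottom"]],
                hill = pars[["hill"]],
                se = setNames(rep(NA_real_, 4),
                              c("bottom", "top", "logec50", "hill")),
                converged = FALSE, rss = o$value, n = length(resp))
    class(res) <- "fit_result"
    return(res)
  }
  co <- stats::coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e)
                   setNames(rep(NA_real_, 4), names(co)))
  res <- list(ec50 = 10^co[["logec50"]], log_ec50 = co[["logec50"]],
              top = co[["top"]], bottom = co[["bottom"]],
              hill = co[["hill"]], se = se,
              converged = isTRUE(best$convInfo$isConv) ||
                is.null(best$convInfo),
              rss = best_rss, n = length(resp))
  class(res) <- "fit_result"
  res
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "4PL fit: EC50 = %.3g M (log10 %.3f), top %.1f, bottom %.1f, hill %.2f%s\n",
    x$ec50, x$log_ec50, x$top, x$bottom, x$hill,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Potency ratio of two fitted curves
#'
#' `EC50(a) / EC50(b)`: how many fold weaker compound `a` is than `b`.
#'
#' @param fit_a,fit_b converged [fit_crc()] results.
#' @return fold ratio.
#' @export
potency_ratio <- function(fit_a, fit_b) {
  if (!isTRUE(fit_a$converged) || !isTRUE(fit_b$converged))
    stop("potency ratio requires converged fits")
  fit_a$ec50 / fit_b$ec50
}

#' Brain-to-plasma exposure ratio (Kp,brain)
#'
#' Measured concentrations are corrected for sample preparation (plasma
#' diluted 1:2, so x3; brain homogenized 1:4 w:v, so x4) and the total
#' brain-to-plasma ratio is computed. With vectors of per-animal
#' concentrations, `kp` holds per-animal ratios and `kp_mean` their mean;
#' `kp_ratio_of_means` is the ratio of the group means.
#'
#' @param c_brain_raw measured brain homogenate concentration(s), uM.
#' @param c_plasma_raw measured diluted-plasma concentration(s), uM.
#' @param brain_factor homogenate correction factor (default 4).
#' @param plasma_factor plasma dilution correction factor (default 3).
#' @return a `pk_result`: `c_brain`, `c_plasma` (corrected), `kp`,
#'   `kp_mean`, `kp_sd`, `kp_ratio_of_means`.
#' @export
kp_brain <- function(c_brain_raw, c_plasma_raw, brain_factor = 4,
                     plasma_factor = 3) {
  stopifnot(length(c_brain_raw) == length(c_plasma_raw),
            all(c_brain_raw >= 0))
  if (any(c_plasma_raw <= 0))
    stop("plasma concentration must be positive")
  cb <- brain_factor * c_brain_raw
  cp <- plasma_factor * c_plasma_raw
  kp <- cb / cp
  structure(list(c_brain = cb, c_plasma = cp, kp = kp,
                 kp_mean = mean(kp), kp_sd = if (length(kp) > 1) sd(kp)
                 else NA_real_,
                 kp_ratio_of_means = mean(cb) / mean(cp)),
            class = "pk_result")
}

#' @export
print.pk_result <- function(x, ...) {
  cat(sprintf("Kp,brain: mean %.3f (ratio of means %.3f, n = %d)\n",
              x$kp_mean, x$kp_ratio_of_means, length(x$kp)))
  invisible(x)
}
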