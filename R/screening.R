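# Batch bidirectional screening: run every exposure against the outcome,
# tier results with per-group Bonferroni thresholds, and classify causal
# direction with reverse MR.

#' Bonferroni-corrected significance threshold
#'
#' alpha / n_tests, with n_tests the (effective) number of independent
#' traits tested in a group — e.g. 0.05/731 = 6.84e-5 for a 731-trait
#' immune panel, or 0.05/146 at the genus level of a microbial catalogue.
#'
#' @param alpha base significance level.
#' @param n_tests number of tests (>= 1).
#' @return The corrected threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1) {
    .mr_error("n_tests must be a positive integer", "mr_domain_error")
  }
  alpha / n_tests
}

#' Classify one exposure-outcome screen result
#'
#' Tiers: \code{bonferroni_significant} when the IVW p-value is below the
#' per-group threshold; \code{suggestive} when below 0.05 but above it;
#' \code{null} otherwise. The consistency flag requires the IVW effect
#' direction to agree with the weighted-median and MR-Egger directions.
#' Pairs failing the MR-PRESSO global test or the Egger intercept test at
#' 0.05 are downgraded to \code{null} with a reason code (horizontal
#' pleiotropy undermines the IV assumptions). Single-instrument (Wald
#' ratio) results can reach at most the suggestive tier.
#'
#' @param ivw_p,ivw_beta primary IVW p-value and effect.
#' @param wme_beta,egger_beta weighted-median and Egger slopes (NA when
#'   unavailable).
#' @param group_threshold Bonferroni threshold for the exposure's group.
#' @param presso_global_p,egger_intercept_p pleiotropy-test p-values
#'   (NA skips the downgrade).
#' @param single_instrument Wald-ratio-only pair?
#' @return List with \code{tier}, \code{consistency} and \code{reason}.
#' @export
classify_screen <- function(ivw_p, ivw_beta, wme_beta = NA_real_,
                            egger_beta = NA_real_, group_threshold = 0.05,
                            presso_global_p = NA_real_,
                            egger_intercept_p = NA_real_,
                            single_instrument = FALSE) {
  signs <- c(wme_beta, egger_beta)
  consistency <- if (all(is.na(signs))) {
    NA
  } else {
    all(sign(signs[!is.na(signs)]) == sign(ivw_beta))
  }
  reason <- "none"
  if (!is.na(presso_global_p) && presso_global_p < 0.05) {
    reason <- "presso_global"
  } else if (!is.na(egger_intercept_p) && egger_intercept_p < 0.05) {
    reason <- "egger_intercept"
  }
  tier <- if (reason != "none") {
    "null"
  } else if (is.na(ivw_p) || ivw_p >= 0.05) {
    "null"
  } else if (!single_instrument && ivw_p < group_threshold) {
    "bonferroni_significant"
  } else {
    "suggestive"
  }
  if (single_instrument) reason <- paste0(reason, ";single_instrument")
  list(tier = tier, consistency = consistency,
       reason = sub("^none;", "", reason))
}

#' Reverse Mendelian randomization
#'
#' Re-runs the estimator battery with the original outcome as exposure,
#' selecting its instruments at the conventional relaxed reverse threshold
#' (p < 5e-5, clumping unchanged). A non-significant reverse IVW supports
#' a unidirectional (forward) causal interpretation.
#'
#' @param outcome_as_exposure,original_exposure \code{summary_stats}
#'   objects with roles swapped.
#' @param ld optional \code{\link{ld_matrix}}.
#' @param config \code{\link{selection_config}}; default uses
#'   \code{p_threshold = 5e-5}.
#' @param ... passed to \code{\link{mr_fit}} (e.g. \code{seed},
#'   \code{n_boot}).
#' @return An \code{\link{mr_fit}}.
#' @export
reverse_mr <- function(outcome_as_exposure, original_exposure, ld = NULL,
                       config = selection_config(p_threshold = 5e-5), ...) {
  ins <- select_instruments(outcome_as_exposure, original_exposure,
                            ld = ld, config = config)
  mr_fit(ins, ...)
}

#' Causal-direction classification from forward and reverse results
#'
#' A pure function of the forward tier and the reverse IVW p-value:
#' forward-null pairs get \code{"none"}; otherwise \code{"forward_only"}
#' when the reverse p-value is >= 0.05 and \code{"bidirectional"} when the
#' reverse analysis is itself significant. Only \code{forward_only} pairs
#' qualify for mediation analysis.
#'
#' @param forward_tier tier string from \code{\link{classify_screen}}.
#' @param reverse_ivw_p reverse-direction IVW p-value (NA if the reverse
#'   analysis could not run).
#' @return One of \code{"forward_only"}, \code{"bidirectional"},
#'   \code{"none"}.
#' @export
direction_filter <- function(forward_tier, reverse_ivw_p) {
  if (forward_tier == "null") return("none")
  if (is.na(reverse_ivw_p) || reverse_ivw_p >= 0.05) "forward_only"
  else "bidirectional"
}

#' Screen a collection of exposures against one outcome
#'
#' Runs instrument selection, the estimator battery and (optionally)
#' diagnostics for every exposure, computes per-group Bonferroni
#' thresholds from the number of exposures in each group (or an externally
#' supplied effective number), and tiers each pair. Exposures whose
#' instrument selection empties are recorded as skipped rows rather than
#' raising. Output rows are ordered by exposure id, and reruns with the
#' same seed and configuration are identical.
#'
#' @param exposures list of \code{summary_stats}.
#' @param outcome a \code{summary_stats}.
#' @param ld optional \code{\link{ld_matrix}} shared by all exposures.
#' @param config \code{\link{selection_config}}.
#' @param n_effective optional named vector mapping group labels to an
#'   externally computed effective number of independent traits; groups
#'   not named default to the count of exposures carrying that label.
#' @param alpha base significance level for the Bonferroni thresholds.
#' @param diagnostics run Cochran's Q and the Egger intercept test (and
#'   use the intercept in classification)?
#' @param presso_n_sim MR-PRESSO simulations per exposure; 0 (default)
#'   skips MR-PRESSO during screening.
#' @param seed base RNG seed; per-exposure seeds are derived from it.
#' @param n_boot bootstrap replicates for the weighted-median SE.
#' @return A data.frame of class \code{mr_screen}, one row per exposure:
#'   estimates for the primary methods, diagnostic p-values, tier,
#'   consistency flag and status.
#' @export
batch_screen <- function(exposures, outcome, ld = NULL,
                         config = selection_config(), n_effective = NULL,
                         alpha = 0.05, diagnostics = TRUE,
                         presso_n_sim = 0, seed = 1, n_boot = 200) {
  stopifnot(is.list(exposures))
  if (length(exposures) == 0) {
    return(structure(data.frame(), class = c("mr_screen", "data.frame")))
  }
  ids <- vapply(exposures, function(e) e$trait_id, character(1))
  groups <- vapply(exposures, function(e) e$group, character(1))
  ord <- order(ids)
  exposures <- exposures[ord]; ids <- ids[ord]; groups <- groups[ord]

  group_n <- table(groups)
  thr <- vapply(names(group_n), function(g) {
    n <- if (!is.null(n_effective) && g %in% names(n_effective)) {
      n_effective[[g]]
    } else {
      as.integer(group_n[[g]])
    }
    bonferroni_threshold(alpha, n)
  }, numeric(1))

  rows <- vector("list", length(exposures))
  for (i in seq_along(exposures)) {
    exp_i <- exposures[[i]]
    row <- data.frame(
      exposure_id = ids[i], group = groups[i],
      group_threshold = thr[[groups[i]]], n_snp = NA_integer_,
      beta_ivw = NA_real_, se_ivw = NA_real_, p_ivw = NA_real_,
      or_ivw = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
      beta_wme = NA_real_, beta_egger = NA_real_,
      q_p = NA_real_, egger_intercept_p = NA_real_,
      presso_global_p = NA_real_,
      tier = "null", consistency = NA, reason = "none",
      status = "ok", stringsAsFactors = FALSE)
    res <- tryCatch({
      ins <- select_instruments(exp_i, outcome, ld = ld, config = config)
      fit <- suppressWarnings(
        mr_fit(ins, methods = c("ivw_re", "ivw_fe", "egger",
                                "weighted_median"),
               n_boot = n_boot, seed = seed + i))
      list(ins = ins, fit = fit)
    }, mr_empty_instruments_error = function(e) {
      row$status <<- paste0("skipped:", e$stage %||% "selection")
      NULL
    })
    if (!is.null(res)) {
      fit <- res$fit
      e <- fit$estimates
      pick <- function(m, col) {
        v <- e[[col]][e$method == m]
        if (length(v) == 0) NA_real_ else v
      }
      primary <- if (fit$n_snp == 1) "wald" else "ivw_re"
      row$n_snp <- fit$n_snp
      row$beta_ivw <- pick(primary, "beta")
      row$se_ivw <- pick(primary, "se")
      row$p_ivw <- pick(primary, "pvalue")
      row$or_ivw <- pick(primary, "or")
      row$ci_low <- pick(primary, "ci_low")
      row$ci_high <- pick(primary, "ci_high")
      row$beta_wme <- pick("weighted_median", "beta")
      row$beta_egger <- pick("egger", "beta")
      if (diagnostics && fit$n_snp >= 2) {
        row$q_p <- cochran_q(fit$data)$pvalue
      }
      if (diagnostics && !is.null(fit$egger_intercept)) {
        row$egger_intercept_p <- fit$egger_intercept$pvalue
      }
      if (presso_n_sim > 0 && fit$n_snp >= 4) {
        pr <- tryCatch(
          mr_presso(fit$data, n_sim = presso_n_sim, seed = seed + i),
          mr_error = function(e) NULL)
        if (!is.null(pr)) row$presso_global_p <- pr$global_p
      }
      cls <- classify_screen(
        ivw_p = row$p_ivw, ivw_beta = row$beta_ivw,
        wme_beta = row$beta_wme, egger_beta = row$beta_egger,
        group_threshold = row$group_threshold,
        presso_global_p = row$presso_global_p,
        egger_intercept_p = if (diagnostics) row$egger_intercept_p
                            else NA_real_,
        single_instrument = fit$n_snp == 1)
      row$tier <- cls$tier
      row$consistency <- cls$consistency
      row$reason <- cls$reason
    }
    rows[[i]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("mr_screen", "data.frame")
  out
}
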