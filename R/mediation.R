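# Two-step mediation MR: product-of-coefficients decomposition of a total
# causal effect into a direct path and a path through a mediator.

#' Product-of-coefficients effect decomposition
#'
#' Given the total exposure->outcome effect, the exposure->mediator effect
#' (b1) and the mediator->outcome effect (b2), the mediated (indirect)
#' effect is b1 * b2 and the direct effect is total - indirect, so
#' direct + indirect = total holds exactly by construction. The indirect
#' SE uses the delta method, sqrt(b1^2 se2^2 + b2^2 se1^2), with a
#' two-sided normal p-value. The proportion mediated indirect/total can be
#' negative (inconsistent mediation: the mediated path opposes the total
#' effect); a flag marks that situation and no absolute-value convention
#' is applied.
#'
#' @param total total exposure->outcome log-odds effect.
#' @param b1 exposure->mediator effect.
#' @param se1 its standard error.
#' @param b2 mediator->outcome effect.
#' @param se2 its standard error.
#' @param se_total optional SE of the total effect (reported, not used in
#'   the decomposition).
#' @return An object of class \code{mr_mediation}: list with \code{total},
#'   \code{b1}, \code{b2}, \code{indirect}, \code{direct},
#'   \code{proportion} (NA with \code{proportion_defined = FALSE} when
#'   total = 0), \code{se_indirect}, \code{p_indirect} and
#'   \code{inconsistent} (sign-discordant mediation flag).
#' @examples
#' # a protective total effect with a risk-increasing mediated path
#' mr_decompose(total = -1.026, b1 = 0.676, se1 = 0.12,
#'              b2 = 0.097, se2 = 0.044)
#' @export
mr_decompose <- function(total, b1, se1 = NA_real_, b2, se2 = NA_real_,
                         se_total = NA_real_) {
  stopifnot(is.finite(total), is.finite(b1), is.finite(b2))
  indirect <- b1 * b2
  direct <- total - indirect
  defined <- total != 0
  proportion <- if (defined) indirect / total else NA_real_
  se_indirect <- if (is.na(se1) || is.na(se2)) {
    NA_real_
  } else {
    stopifnot(se1 >= 0, se2 >= 0)
    sqrt(b1^2 * se2^2 + b2^2 * se1^2)
  }
  p_indirect <- if (is.na(se_indirect)) {
    NA_real_
  } else if (se_indirect == 0) {
    if (indirect == 0) 1 else 0
  } else {
    2 * stats::pnorm(-abs(indirect / se_indirect))
  }
  structure(
    list(total = total, se_total = se_total, b1 = b1, se1 = se1,
         b2 = b2, se2 = se2, indirect = indirect, direct = direct,
         proportion = proportion, proportion_defined = defined,
         se_indirect = se_indirect, p_indirect = p_indirect,
         inconsistent = defined && indirect != 0 &&
           sign(indirect) != sign(total)),
    class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, digits = 3, ...) {
  cat("Two-step MR mediation decomposition\n")
  if (!is.null(x$exposure_id)) {
    cat(sprintf("  %s -> %s -> %s\n", x$exposure_id, x$mediator_id,
                x$outcome_id))
  }
  cat(sprintf("  total    % .*f\n", digits, x$total))
  cat(sprintf("  b1       % .*f   b2 % .*f\n", digits, x$b1, digits, x$b2))
  cat(sprintf("  indirect % .*f (se %.3g, p = %.3g)\n", digits, x$indirect,
              x$se_indirect, x$p_indirect))
  cat(sprintf("  direct   % .*f\n", digits, x$direct))
  if (x$proportion_defined) {
    cat(sprintf("  proportion mediated %.4f (%.1f%%)\n", x$proportion,
                100 * x$proportion))
  } else {
    cat("  proportion mediated undefined (total effect is zero)\n")
  }
  if (isTRUE(x$inconsistent)) {
    cat("  note: inconsistent mediation (mediated path opposes the total effect)\n")
  }
  invisible(x)
}

#' Proportion of the total effect carried by the mediated path
#'
#' @param indirect mediated effect (b1 * b2).
#' @param total total effect; zero makes the proportion undefined.
#' @return List with \code{fraction} and \code{percent}; both NA when
#'   \code{total} is zero.
#' @export
mediation_proportion <- function(indirect, total) {
  if (total == 0) {
    return(list(fraction = NA_real_, percent = NA_real_, defined = FALSE))
  }
  list(fraction = indirect / total, percent = 100 * indirect / total,
       defined = TRUE)
}

#' Two-step mediation Mendelian randomization
#'
#' Estimates the three legs of an exposure -> mediator -> outcome system
#' from summary statistics and decomposes the total effect:
#' \itemize{
#'   \item total: exposure->outcome IVW on the exposure's instruments;
#'   \item b1: exposure->mediator IVW on the same instruments;
#'   \item b2: mediator->outcome effect, either univariable IVW on the
#'     mediator's own instruments (default) or the conditional mediator
#'     coefficient from multivariable IVW on the union of instruments.
#' }
#' In the univariable mode, SNPs associated with the exposure at the
#' exposure threshold are excluded from the mediator's instrument set:
#' instruments inherited from the exposure estimate total/b1 rather than
#' b2 and would contaminate the second stage. (In typical applications the
#' two GWAS instrument panels are effectively disjoint already.)
#'
#' Eligibility: both the exposure and the mediator should have a
#' unidirectional (forward-only) causal relationship with the outcome, as
#' established by \code{\link{direction_filter}}; supply
#' \code{directions} to have this checked.
#'
#' @param exposure,mediator,outcome \code{summary_stats} objects.
#' @param ld optional \code{\link{ld_matrix}}.
#' @param config \code{\link{selection_config}} for all legs.
#' @param b2_mode \code{"univariable"} (default) or \code{"mvmr"}.
#' @param directions optional named list/vector with entries
#'   \code{exposure} and \code{mediator} holding
#'   \code{\link{direction_filter}} results; any value other than
#'   \code{"forward_only"} raises a precondition error naming the leg.
#' @param seed RNG seed for bootstrap-based leg estimators.
#' @param n_boot bootstrap replicates for median/mode SEs in the leg fits.
#' @return An \code{mr_mediation} object (see \code{\link{mr_decompose}})
#'   with the three leg fits attached as \code{fits} and trait ids as
#'   \code{exposure_id}, \code{mediator_id}, \code{outcome_id}.
#' @export
two_step_mediation <- function(exposure, mediator, outcome, ld = NULL,
                               config = selection_config(),
                               b2_mode = c("univariable", "mvmr"),
                               directions = NULL, seed = 1, n_boot = 200) {
  b2_mode <- match.arg(b2_mode)
  if (!is.null(directions)) {
    for (leg in c("exposure", "mediator")) {
      d <- directions[[leg]]
      if (!is.null(d) && !identical(d, "forward_only")) {
        .mr_error(sprintf(
          "mediation requires a forward-only %s -> outcome relationship (got '%s')",
          leg, d), "mr_precondition_error", leg = leg)
      }
    }
  }

  ins_exp_out <- select_instruments(exposure, outcome, ld = ld,
                                    config = config)
  fit_total <- mr_fit(ins_exp_out, methods = c("ivw_re", "ivw_fe", "egger",
                                               "weighted_median",
                                               "simple_mode",
                                               "weighted_mode"),
                      n_boot = n_boot, seed = seed)
  total_est <- .primary_estimate(fit_total)

  ins_exp_med <- select_instruments(exposure, mediator, ld = ld,
                                    config = config)
  fit_b1 <- mr_fit(ins_exp_med, methods = c("ivw_re", "ivw_fe"),
                   n_boot = n_boot, seed = seed + 1)
  b1_est <- .primary_estimate(fit_b1)

  if (b2_mode == "univariable") {
    med_own <- .drop_exposure_instruments(mediator, exposure,
                                          config$p_threshold)
    ins_med_out <- select_instruments(med_own, outcome, ld = ld,
                                      config = config)
    fit_b2 <- mr_fit(ins_med_out, methods = c("ivw_re", "ivw_fe", "egger",
                                              "weighted_median",
                                              "simple_mode",
                                              "weighted_mode"),
                     n_boot = n_boot, seed = seed + 2)
    b2_est <- .primary_estimate(fit_b2)
  } else {
    med_ids <- tryCatch(
      select_instruments(mediator, outcome, ld = ld, config = config)$rsid,
      mr_empty_instruments_error = function(e) character(0))
    union_ids <- union(ins_exp_out$rsid, med_ids)
    exp_sub <- exposure
    exp_sub$data <- exposure$data[exposure$data$rsid %in% union_ids, ,
                                  drop = FALSE]
    h3 <- harmonize(exp_sub, outcome, mediator = mediator,
                    palindrome_policy = config$palindrome_policy)
    mv <- mr_mvmr_ivw(retained(h3))
    fit_b2 <- mv
    b2_est <- list(beta = mv$beta[mv$term == "mediator"],
                   se = mv$se[mv$term == "mediator"])
  }

  out <- mr_decompose(total = total_est$beta, b1 = b1_est$beta,
                      se1 = b1_est$se, b2 = b2_est$beta, se2 = b2_est$se,
                      se_total = total_est$se)
  out$exposure_id <- exposure$trait_id
  out$mediator_id <- mediator$trait_id
  out$outcome_id <- outcome$trait_id
  out$b2_mode <- b2_mode
  out$fits <- list(total = fit_total, b1 = fit_b1, b2 = fit_b2)
  out
}

.primary_estimate <- function(fit) {
  e <- fit$estimates
  m <- if ("ivw_re" %in% e$method) "ivw_re" else e$method[1]
  list(beta = e$beta[e$method == m], se = e$se[e$method == m])
}

# Remove from the mediator's summary statistics any SNP associated with
# the exposure at the exposure threshold (those instruments estimate
# total/b1, not b2, in the second-stage regression).
.drop_exposure_instruments <- function(mediator, exposure, p_threshold) {
  ed <- exposure$data
  exp_snps <- ed$rsid[!is.na(ed$pvalue) & ed$pvalue < p_threshold]
  out <- mediator
  out$data <- mediator$data[!(mediator$data$rsid %in% exp_snps), ,
                            drop = FALSE]
  if (nrow(out$data) == 0) {
    .mr_error(sprintf(
      "no mediator SNPs left for '%s' after excluding exposure instruments",
      mediator$trait_id), "mr_empty_instruments_error", stage = "mediator_own")
  }
  out
}
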