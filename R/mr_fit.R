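# The central model-fitting interface: fit a battery of MR estimators to a
# harmonized instrument set and return a classed object with the usual
# accessor methods.

#' Fit two-sample Mendelian randomization estimators
#'
#' Runs the requested causal estimators on a harmonized instrument set and
#' collects them in a single fitted-model object. With a single instrument
#' only the Wald ratio is available and is used regardless of
#' \code{methods}. The inverse-variance-weighted estimate (multiplicative
#' random effects, \code{ivw_re}) is the primary method; the fixed-effect
#' variant is also always informative to inspect under homogeneity.
#'
#' @param h a \code{harmonized_set} or \code{instrument_set} (only retained
#'   rows are used).
#' @param methods character vector among \code{"ivw_re"}, \code{"ivw_fe"},
#'   \code{"egger"}, \code{"weighted_median"}, \code{"simple_mode"},
#'   \code{"weighted_mode"}. Methods whose instrument-count requirement is
#'   not met are skipped silently.
#' @param n_boot parametric-bootstrap replicates for the median and mode
#'   SEs (default 5000).
#' @param seed RNG seed for the bootstrap; required when a bootstrap-based
#'   method is requested with more than two instruments.
#' @param phi mode-estimator bandwidth multiplier.
#' @return An object of class \code{mr_fit}: list with \code{estimates}
#'   (an \code{mr_estimate} data.frame, one row per method),
#'   \code{egger_intercept} (or NULL), \code{data} (the retained
#'   instruments), \code{n_snp}, and ids carried over from \code{h}.
#' @seealso \code{\link{cochran_q}}, \code{\link{mr_presso}},
#'   \code{\link{leave_one_out}}
#' @examples
#' study <- simulate_study(simulation_config(theta = 0.3, seed = 1))
#' ins <- select_instruments(study$exposure, study$outcome, ld = study$ld)
#' fit <- mr_fit(ins, seed = 2, n_boot = 200)
#' fit
#' @export
mr_fit <- function(h, methods = c("ivw_re", "ivw_fe", "egger",
                                  "weighted_median", "simple_mode",
                                  "weighted_mode"),
                   n_boot = 5000, seed = NULL, phi = 1) {
  ids <- list(exposure_id = attr(h, "exposure_id"),
              outcome_id = attr(h, "outcome_id"))
  counts <- attr(h, "counts")
  hd <- .get_h(h)
  j <- nrow(hd)
  if (j == 0) .mr_error("no retained instruments", "mr_arity_error")

  rows <- list()
  egger_res <- NULL
  if (j == 1) {
    rows$wald <- mr_wald_ratio(hd$beta_exp, hd$se_exp,
                               hd$beta_out, hd$se_out)
  } else {
    need_boot <- any(c("weighted_median", "simple_mode",
                       "weighted_mode") %in% methods) && j >= 3
    if (need_boot && is.null(seed)) {
      .mr_error("a bootstrap seed is required for median/mode estimators",
                "mr_config_error")
    }
    for (m in methods) {
      res <- switch(m,
        ivw_re = mr_ivw(hd, mode = "random"),
        ivw_fe = mr_ivw(hd, mode = "fixed"),
        egger = if (j >= 3) {
          egger_res <- mr_egger(hd)
          egger_res$slope
        },
        weighted_median = if (j >= 3) {
          mr_weighted_median(hd, n_boot = n_boot, seed = seed)
        },
        simple_mode = if (j >= 3) {
          mr_mode(hd, weighted = FALSE, phi = phi, n_boot = n_boot,
                  seed = seed)
        },
        weighted_mode = if (j >= 3) {
          mr_mode(hd, weighted = TRUE, phi = phi, n_boot = n_boot,
                  seed = seed)
        },
        .mr_error(sprintf("unknown method '%s'", m), "mr_config_error"))
      if (!is.null(res)) rows[[m]] <- res
    }
  }
  est <- do.call(rbind, rows)
  rownames(est) <- NULL
  structure(
    list(estimates = est, egger_intercept = egger_res$intercept,
         data = hd, n_snp = j, counts = counts,
         exposure_id = ids$exposure_id, outcome_id = ids$outcome_id),
    class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Two-sample MR: %s -> %s (%d instruments)\n\n",
              x$exposure_id %||% "exposure",
              x$outcome_id %||% "outcome", x$n_snp))
  e <- x$estimates
  tab <- data.frame(
    Method = .method_label(e$method),
    OR = sprintf("%.*f", digits, e$or),
    `95% CI` = sprintf("%.*f~%.*f", digits, e$ci_low, digits, e$ci_high),
    P = signif(e$pvalue, 3),
    check.names = FALSE)
  print(tab, row.names = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.method_label <- function(m) {
  lab <- c(wald = "Wald ratio", ivw_fe = "IVW (fixed)",
           ivw_re = "IVW", egger = "MR Egger",
           weighted_median = "Weighted median",
           simple_mode = "Simple mode", weighted_mode = "Weighted mode",
           mvmr_ivw = "MVMR IVW")
  out <- lab[m]
  out[is.na(out)] <- m[is.na(out)]
  unname(out)
}

#' @export
summary.mr_fit <- function(object, ...) {
  q <- if (object$n_snp >= 2) cochran_q(object$data) else NULL
  structure(list(fit = object, q = q,
                 intercept = object$egger_intercept),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$q)) {
    cat(sprintf("\nCochran's Q = %.3f on %d df (p = %.3g)\n",
                x$q$q, x$q$df, x$q$pvalue))
  }
  if (!is.null(x$intercept)) {
    cat(sprintf("Egger intercept = %.4g (se %.4g, p = %.3g)\n",
                x$intercept$estimate, x$intercept$se, x$intercept$pvalue))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  e <- object$estimates
  out <- cbind(e$beta - z * e$se, e$beta + z * e$se)
  dimnames(out) <- list(e$method,
                        sprintf("%.1f %%", c((1 - level) / 2,
                                             1 - (1 - level) / 2) * 100))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' Scatter plot of instrument effects with fitted estimator lines
#'
#' @param x an \code{mr_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.mr_fit <- function(x, ...) {
  d <- x$data
  flip <- sign(d$beta_exp); flip[flip == 0] <- 1
  bx <- d$beta_exp * flip; by <- d$beta_out * flip
  graphics::plot(bx, by, pch = 19,
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome", ...)
  graphics::segments(bx, by - .z975 * d$se_out, bx, by + .z975 * d$se_out,
                     col = "grey60")
  e <- x$estimates
  cols <- stats::setNames(seq_len(nrow(e)) + 1, e$method)
  for (m in e$method) {
    b <- e$beta[e$method == m]
    if (m == "egger" && !is.null(x$egger_intercept)) {
      graphics::abline(x$egger_intercept$estimate, b, col = cols[m])
    } else {
      graphics::abline(0, b, col = cols[m])
    }
  }
  graphics::legend("topleft", legend = .method_label(e$method),
                   col = cols, lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}
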