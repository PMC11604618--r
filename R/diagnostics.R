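# Heterogeneity, pleiotropy, outlier and influence diagnostics.

#' Cochran's Q heterogeneity test
#'
#' Q = sum over instruments of w_j (ratio_j - beta_ivw_fe)^2, with
#' inverse-variance weights over the Wald ratios; under homogeneity Q is
#' chi-square with J - 1 degrees of freedom. P < 0.05 indicates potential
#' heterogeneity among SNP-level estimates.
#'
#' @inheritParams mr_ivw
#' @return An object of class \code{mr_q}: list with \code{q}, \code{df},
#'   \code{pvalue} and per-SNP \code{contributions} (which sum to Q).
#' @export
cochran_q <- function(h) {
  h <- .get_h(h)
  j <- nrow(h)
  if (j < 2) {
    .mr_error("Cochran's Q needs at least 2 instruments", "mr_arity_error")
  }
  wr <- .wald_ratios(h)
  w <- 1 / wr$se^2
  beta <- sum(w * wr$ratio) / sum(w)
  contrib <- w * (wr$ratio - beta)^2
  q <- sum(contrib)
  structure(list(q = q, df = j - 1L,
                 pvalue = stats::pchisq(q, df = j - 1, lower.tail = FALSE),
                 contributions = contrib),
            class = "mr_q")
}

#' @export
print.mr_q <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.4f on %d df, p = %.4g\n",
              x$q, x$df, x$pvalue))
  invisible(x)
}

#' Egger intercept test for directional pleiotropy
#'
#' @param e an \code{\link{mr_egger}} result.
#' @param alpha flag threshold (default 0.05).
#' @return List with the intercept \code{estimate}, \code{se},
#'   \code{pvalue} and \code{flag} (\code{TRUE} when p < alpha, i.e.
#'   directional horizontal pleiotropy detected).
#' @export
egger_intercept_test <- function(e, alpha = 0.05) {
  stopifnot(inherits(e, "mr_egger"))
  list(estimate = e$intercept$estimate, se = e$intercept$se,
       pvalue = e$intercept$pvalue, flag = e$intercept$pvalue < alpha)
}

#' MR-PRESSO: global pleiotropy test, outlier detection, distortion test
#'
#' The global test measures the leave-one-out residual sum of squares
#' RSSobs = sum_j w_j (beta_out_j - b_(-j) * beta_exp_j)^2, where b_(-j) is
#' the IVW slope excluding instrument j and w_j = 1/se_out_j^2, and
#' compares it against \code{n_sim} parametric simulations under the
#' no-pleiotropy model (beta_out drawn around the leave-one-out
#' prediction, beta_exp around its observed value). P-values use the
#' add-one rule (never zero; lower bound 1/(n_sim + 1)). Per-SNP outlier
#' p-values come from the simulated distribution of each SNP's own
#' residual term, Bonferroni-adjusted by J; the corrected estimate is IVW
#' on the non-outliers. The distortion test compares the raw and
#' outlier-corrected estimates against displacements obtained by removing
#' equally many randomly chosen non-outliers (1000 draws); it is reported
#' as experimental.
#'
#' @inheritParams mr_ivw
#' @param n_sim simulated datasets for the global/outlier tests
#'   (>= 1000; 10000 is a reasonable production setting).
#' @param seed RNG seed (required; identical seed gives identical output).
#' @param outlier_alpha threshold on the Bonferroni-adjusted per-SNP
#'   p-value.
#' @param mode IVW variant used for the corrected estimate.
#' @return An object of class \code{mr_presso}: list with
#'   \code{global_rss}, \code{global_p}, \code{n_sim}, \code{outliers}
#'   (data.frame of flagged indices, rsids and adjusted p-values),
#'   \code{corrected} (IVW \code{mr_estimate} on non-outliers, or NULL if
#'   nothing was flagged) and \code{distortion_p}.
#' @export
mr_presso <- function(h, n_sim = 1000, seed, outlier_alpha = 0.05,
                      mode = "random") {
  h <- .get_h(h)
  j <- nrow(h)
  if (j < 4) {
    .mr_error("MR-PRESSO needs at least 4 instruments", "mr_arity_error")
  }
  if (n_sim < 1000) {
    .mr_error("MR-PRESSO needs n_sim >= 1000", "mr_config_error")
  }
  bx <- h$beta_exp; by <- h$beta_out
  w <- 1 / h$se_out^2
  s1 <- sum(w * bx * by); s2 <- sum(w * bx^2)
  b_loo <- (s1 - w * bx * by) / (s2 - w * bx^2)
  term_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(term_obs)

  sim <- .with_seed(seed, {
    bx_s <- matrix(stats::rnorm(n_sim * j, mean = rep(bx, each = n_sim),
                                sd = rep(h$se_exp, each = n_sim)),
                   nrow = n_sim)
    by_s <- matrix(stats::rnorm(n_sim * j,
                                mean = rep(b_loo * bx, each = n_sim),
                                sd = rep(h$se_out, each = n_sim)),
                   nrow = n_sim)
    wm <- matrix(w, nrow = n_sim, ncol = j, byrow = TRUE)
    s1_s <- rowSums(wm * bx_s * by_s)
    s2_s <- rowSums(wm * bx_s^2)
    b_loo_s <- (s1_s - wm * bx_s * by_s) / (s2_s - wm * bx_s^2)
    term_s <- wm * (by_s - b_loo_s * bx_s)^2
    list(rss = rowSums(term_s), term = term_s)
  })
  global_p <- (1 + sum(sim$rss >= rss_obs)) / (n_sim + 1)

  p_snp <- (1 + colSums(sim$term >= matrix(term_obs, nrow = n_sim,
                                           ncol = j, byrow = TRUE))) /
    (n_sim + 1)
  p_adj <- pmin(1, p_snp * j)
  out_idx <- which(p_adj < outlier_alpha)
  rsids <- if (is.null(h$rsid)) rep(NA_character_, j) else h$rsid
  outliers <- data.frame(index = out_idx, rsid = rsids[out_idx],
                         p_adjusted = p_adj[out_idx])
  if (length(out_idx) == j) {
    .mr_error("every instrument flagged as outlier; no corrected estimate",
              "mr_degenerate_correction_error")
  }

  corrected <- NULL
  distortion_p <- NA_real_
  if (length(out_idx) > 0) {
    keep <- setdiff(seq_len(j), out_idx)
    corrected <- mr_ivw(h[keep, , drop = FALSE], mode = mode)
    raw <- mr_ivw(h, mode = mode)
    if (corrected$beta != 0 && length(keep) > length(out_idx)) {
      d_obs <- (raw$beta - corrected$beta) / abs(corrected$beta)
      n_draw <- 1000
      d_sim <- .with_seed(seed + 1L, {
        vapply(seq_len(n_draw), function(b) {
          drop_b <- sample(keep, length(out_idx))
          fit_b <- mr_ivw(h[setdiff(seq_len(j), drop_b), , drop = FALSE],
                          mode = mode)
          (raw$beta - fit_b$beta) / abs(fit_b$beta)
        }, numeric(1))
      })
      distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_draw + 1)
    }
  }

  structure(list(global_rss = rss_obs, global_p = global_p, n_sim = n_sim,
                 p_snp_adjusted = p_adj, outliers = outliers,
                 corrected = corrected, distortion_p = distortion_p),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO global test: RSS = %.4f, p = %.4g (%d simulations)\n",
              x$global_rss, x$global_p, x$n_sim))
  if (nrow(x$outliers) == 0) {
    cat("  no outliers detected\n")
  } else {
    cat(sprintf("  %d outlier(s): %s\n", nrow(x$outliers),
                paste(x$outliers$rsid, collapse = ", ")))
    cat(sprintf("  distortion p = %.4g (experimental)\n", x$distortion_p))
    cat("  outlier-corrected ")
    print(x$corrected)
  }
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the IVW effect excluding each instrument in turn; a
#' materially different estimate after one exclusion indicates that SNP
#' drives the association. The full-set estimate is appended as reference
#' row \code{"All"}.
#'
#' @inheritParams mr_ivw
#' @param mode IVW variant (default the primary random-effects).
#' @return A data.frame of class \code{mr_loo}, forest-plot-ready: columns
#'   \code{excluded}, \code{n_snp}, \code{beta}, \code{se}, \code{pvalue},
#'   \code{or}, \code{ci_low}, \code{ci_high}.
#' @export
leave_one_out <- function(h, mode = "random") {
  h <- .get_h(h)
  j <- nrow(h)
  if (j < 3) {
    .mr_error("leave-one-out needs at least 3 instruments", "mr_arity_error")
  }
  rows <- lapply(seq_len(j), function(i) {
    fit <- mr_ivw(h[-i, , drop = FALSE], mode = mode)
    fit$method <- NULL
    cbind(excluded = h$rsid[i] %||% as.character(i), fit)
  })
  all_fit <- mr_ivw(h, mode = mode)
  all_fit$method <- NULL
  out <- rbind(do.call(rbind, rows), cbind(excluded = "All", all_fit))
  rownames(out) <- NULL
  class(out) <- c("mr_loo", "data.frame")
  out
}
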