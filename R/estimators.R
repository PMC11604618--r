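# Causal-effect estimators on harmonized instrument sets.
#
# All estimates are returned on the log-odds scale together with the
# exponentiated odds ratio and its 95% CI. Per-SNP Wald ratios use the
# first-order standard error se_out/|beta_exp| (exposure-side variance
# ignored), the standard two-sample convention.

.z975 <- stats::qnorm(0.975)

# Run code under a temporary RNG state seeded by `seed`, restoring the
# caller's stream afterwards. seed = NULL runs in the ambient stream.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.mr_estimate <- function(method, beta, se, n_snp, pvalue = NULL,
                         df = NULL) {
  if (is.null(pvalue)) {
    z <- beta / se
    pvalue <- if (!is.null(df)) {
      2 * stats::pt(-abs(z), df = df)
    } else {
      2 * stats::pnorm(-abs(z))
    }
    pvalue[se == 0 & beta == 0] <- 1
  }
  or <- to_odds_ratio(beta, se)
  structure(
    data.frame(method = method, n_snp = n_snp, beta = beta, se = se,
               pvalue = pvalue, or = or$or, ci_low = or$ci_low,
               ci_high = or$ci_high, stringsAsFactors = FALSE),
    class = c("mr_estimate", "data.frame"))
}

.get_h <- function(h, need_med = FALSE) {
  if (inherits(h, "harmonized_set")) h <- retained(h)
  stopifnot(is.data.frame(h),
            all(c("beta_exp", "se_exp", "beta_out", "se_out") %in% names(h)))
  if (need_med && is.null(h$beta_med)) {
    .mr_error("mediator betas required but absent", "mr_config_error")
  }
  h
}

.wald_ratios <- function(h) {
  list(ratio = h$beta_out / h$beta_exp,
       se = h$se_out / abs(h$beta_exp))
}

#' Convert a log-odds effect to an odds ratio with 95% CI
#'
#' @param beta log-odds effect.
#' @param se its standard error (\code{>= 0}).
#' @return List with \code{or}, \code{ci_low}, \code{ci_high}
#'   (\code{exp(beta -+ 1.96 se)}).
#' @export
to_odds_ratio <- function(beta, se) {
  stopifnot(all(se >= 0))
  list(or = exp(beta), ci_low = exp(beta - .z975 * se),
       ci_high = exp(beta + .z975 * se))
}

#' Log-odds effect implied by a printed odds ratio
#'
#' Inverse of \code{\link{to_odds_ratio}}: the natural logarithm of the OR.
#' @param or odds ratio (\code{> 0}).
#' @return log-odds beta.
#' @export
beta_from_or <- function(or) {
  stopifnot(all(or > 0))
  log(or)
}

#' Wald ratio estimate from a single instrument
#'
#' beta_out / beta_exp with first-order standard error
#' se_out / |beta_exp|; two-sided normal p-value.
#'
#' @param beta_exp,se_exp SNP-exposure association.
#' @param beta_out,se_out SNP-outcome association.
#' @return A one-row \code{mr_estimate} data.frame.
#' @export
mr_wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (beta_exp == 0) {
    .mr_error("degenerate instrument: beta_exp = 0", "mr_domain_error")
  }
  .mr_estimate("wald", beta_out / beta_exp, se_out / abs(beta_exp),
               n_snp = 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of beta_out on beta_exp through the origin with
#' weights 1/se_out^2 — equivalently the inverse-variance meta-analysis of
#' the per-SNP Wald ratios. The fixed-effect SE is sqrt(1/sum(w)); the
#' multiplicative random-effects variant inflates it by
#' max(1, sqrt(Q/(J-1))) where Q is Cochran's Q, so it is never smaller
#' than the fixed-effect SE.
#'
#' @param h a \code{harmonized_set} (retained rows are used) or a
#'   data.frame with \code{beta_exp}, \code{se_exp}, \code{beta_out},
#'   \code{se_out}.
#' @param mode \code{"random"} (multiplicative random effects, the primary
#'   variant) or \code{"fixed"}.
#' @return A one-row \code{mr_estimate} data.frame (method \code{ivw_re} or
#'   \code{ivw_fe}).
#' @export
mr_ivw <- function(h, mode = c("random", "fixed")) {
  mode <- match.arg(mode)
  h <- .get_h(h)
  j <- nrow(h)
  min_j <- if (mode == "fixed") 1L else 2L
  if (j < min_j) {
    .mr_error(sprintf("IVW (%s) needs at least %d instrument(s), got %d",
                      mode, min_j, j), "mr_arity_error")
  }
  wr <- .wald_ratios(h)
  w <- 1 / wr$se^2
  beta <- sum(w * wr$ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  if (mode == "random") {
    q <- sum(w * (wr$ratio - beta)^2)
    se <- se * max(1, sqrt(q / (j - 1)))
  }
  .mr_estimate(if (mode == "fixed") "ivw_fe" else "ivw_re", beta, se,
               n_snp = j)
}

#' MR-Egger regression
#'
#' Weighted least squares of beta_out on beta_exp with a free intercept and
#' weights 1/se_out^2, after orienting instruments so every beta_exp is
#' non-negative. The slope is the pleiotropy-corrected causal estimate; a
#' nonzero intercept indicates directional horizontal pleiotropy.
#' Coefficient SEs are inflated by max(1, residual standard deviation)
#' (multiplicative random effects, truncated at 1); p-values use Student-t
#' with J - 2 degrees of freedom.
#'
#' @inheritParams mr_ivw
#' @return An object of class \code{mr_egger}: list with \code{slope} (a
#'   one-row \code{mr_estimate}) and \code{intercept} (list of
#'   \code{estimate}, \code{se}, \code{pvalue}).
#' @export
mr_egger <- function(h) {
  h <- .get_h(h)
  j <- nrow(h)
  if (j < 3) {
    .mr_error(sprintf("MR-Egger needs at least 3 instruments, got %d", j),
              "mr_arity_error")
  }
  flip <- sign(h$beta_exp)
  flip[flip == 0] <- 1
  bx <- h$beta_exp * flip
  by <- h$beta_out * flip
  w <- 1 / h$se_out^2
  # closed-form weighted normal equations
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  if (det <= 0) .mr_error("degenerate Egger design", "mr_domain_error")
  slope <- (sw * swxy - swx * swy) / det
  inter <- (swxx * swy - swx * swxy) / det
  resid <- by - inter - slope * bx
  sigma2 <- sum(w * resid^2) / (j - 2)
  scale <- max(1, sqrt(sigma2))
  se_slope <- sqrt(sw / det) * scale
  se_inter <- sqrt(swxx / det) * scale
  structure(
    list(slope = .mr_estimate("egger", slope, se_slope, n_snp = j,
                              df = j - 2),
         intercept = list(
           estimate = inter, se = se_inter,
           pvalue = 2 * stats::pt(-abs(inter / se_inter), df = j - 2)),
         n_snp = j),
    class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  cat("MR-Egger regression\n")
  print(x$slope)
  cat(sprintf("  intercept %.4g (se %.4g, p = %.3g)\n",
              x$intercept$estimate, x$intercept$se, x$intercept$pvalue))
  invisible(x)
}

# Weighted median of values x with weights w: linear interpolation of the
# weighted CDF (cumulative weight up to j minus w_j/2) at 0.5.
.weighted_median_core <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  stats::approx(cum, x, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted median estimate
#'
#' The 0.5 quantile of the inverse-variance-weighted distribution of Wald
#' ratios, consistent when at least half the instrument weight comes from
#' valid instruments. The SE is a parametric bootstrap: exposure and
#' outcome betas are resampled from their stated normal distributions,
#' the weighted median recomputed, and its standard deviation taken.
#'
#' @inheritParams mr_ivw
#' @param n_boot bootstrap replicates (default 5000).
#' @param seed RNG seed for the bootstrap (required).
#' @return A one-row \code{mr_estimate} data.frame.
#' @export
mr_weighted_median <- function(h, n_boot = 5000, seed) {
  h <- .get_h(h)
  j <- nrow(h)
  if (j < 3) {
    .mr_error(sprintf("weighted median needs at least 3 instruments, got %d",
                      j), "mr_arity_error")
  }
  wr <- .wald_ratios(h)
  est <- .weighted_median_core(wr$ratio, 1 / wr$se^2)
  boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(j, h$beta_exp, h$se_exp)
      by <- stats::rnorm(j, h$beta_out, h$se_out)
      r <- by / bx
      sw <- h$se_out / abs(bx)
      .weighted_median_core(r, 1 / sw^2)
    }, numeric(1))
  })
  .mr_estimate("weighted_median", est, stats::sd(boot), n_snp = j)
}

# Gaussian kernel density of ratios at grid points; weights sum to 1.
.mode_core <- function(ratios, w, bw, n_grid = 512) {
  grid <- seq(min(ratios) - 3 * bw, max(ratios) + 3 * bw,
              length.out = n_grid)
  dens <- vapply(grid, function(x) {
    sum(w * stats::dnorm((x - ratios) / bw)) / bw
  }, numeric(1))
  grid[which.max(dens)]
}

.mode_bandwidth <- function(ratios, phi) {
  s <- stats::sd(ratios)
  madn <- stats::mad(ratios)  # mad/0.6745, R's default scaling
  phi * 0.9 * min(s, madn) * length(ratios)^(-1 / 5)
}

#' Mode-based estimate (simple or weighted)
#'
#' The argmax of a normal-kernel density over the Wald ratios, evaluated on
#' a 512-point grid spanning the ratios plus/minus three bandwidths.
#' Weights are uniform (simple mode) or inverse-variance (weighted mode);
#' the bandwidth is phi * 0.9 * min(sd, MAD/0.6745) * J^(-1/5). Consistent
#' when the largest cluster of instruments is valid. SE by parametric
#' bootstrap as in \code{\link{mr_weighted_median}}. When every ratio is
#' identical the bandwidth is zero and that ratio is returned with SE 0.
#'
#' @inheritParams mr_weighted_median
#' @param weighted use inverse-variance weights (\code{TRUE}, the weighted
#'   mode) or uniform weights (simple mode).
#' @param phi bandwidth multiplier (default 1).
#' @return A one-row \code{mr_estimate} data.frame.
#' @export
mr_mode <- function(h, weighted = TRUE, phi = 1, n_boot = 5000, seed) {
  h <- .get_h(h)
  j <- nrow(h)
  if (j < 3) {
    .mr_error(sprintf("mode estimator needs at least 3 instruments, got %d",
                      j), "mr_arity_error")
  }
  method <- if (weighted) "weighted_mode" else "simple_mode"
  wr <- .wald_ratios(h)
  bw <- .mode_bandwidth(wr$ratio, phi)
  if (bw == 0) {
    return(.mr_estimate(method, wr$ratio[1], 0, n_snp = j, pvalue = NA_real_))
  }
  weight_of <- function(se_wald) {
    w <- if (weighted) 1 / se_wald^2 else rep(1, length(se_wald))
    w / sum(w)
  }
  est <- .mode_core(wr$ratio, weight_of(wr$se), bw)
  boot <- .with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(j, h$beta_exp, h$se_exp)
      by <- stats::rnorm(j, h$beta_out, h$se_out)
      r <- by / bx
      sw <- h$se_out / abs(bx)
      bwb <- .mode_bandwidth(r, phi)
      if (bwb == 0) r[1] else .mode_core(r, weight_of(sw), bwb)
    }, numeric(1))
  })
  .mr_estimate(method, est, stats::sd(boot), n_snp = j)
}

#' Multivariable IVW (exposure and mediator jointly)
#'
#' Weighted least squares of beta_out on (beta_exp, beta_med) without
#' intercept, weights 1/se_out^2, giving the conditional (direct) effect of
#' each trait given the other. Coefficient SEs use the multiplicative
#' random-effects inflation max(1, residual sd); p-values from Student-t
#' with J - 2 df.
#'
#' @param h a \code{harmonized_set} carrying \code{beta_med} and
#'   \code{se_med}.
#' @param condition_limit condition number above which the design is
#'   declared collinear.
#' @return A two-row \code{mr_estimate} data.frame with a \code{term}
#'   column (\code{"exposure"}, \code{"mediator"}).
#' @export
mr_mvmr_ivw <- function(h, condition_limit = 1e8) {
  h <- .get_h(h, need_med = TRUE)
  j <- nrow(h)
  if (j < 3) {
    .mr_error(sprintf("MVMR needs at least 3 instruments, got %d", j),
              "mr_arity_error")
  }
  w <- 1 / h$se_out^2
  x <- cbind(exposure = h$beta_exp, mediator = h$beta_med)
  xs <- sqrt(w) * x
  live <- colSums(xs^2) > 0
  if (!any(live)) {
    .mr_error("all instrument effects are zero", "mr_domain_error")
  }
  if (all(live) && kappa(xs, exact = TRUE) > condition_limit) {
    .mr_error("exposure and mediator instrument effects are collinear",
              "mr_collinearity_error")
  }
  # an identically-zero column is orthogonal to everything: drop it from
  # the solve and report NA for its conditional effect
  xtx <- crossprod(xs[, live, drop = FALSE])
  xty <- crossprod(xs[, live, drop = FALSE], sqrt(w) * h$beta_out)
  coefs <- ses <- c(exposure = NA_real_, mediator = NA_real_)
  sol <- drop(solve(xtx, xty))
  coefs[live] <- sol
  resid <- h$beta_out - drop(x[, live, drop = FALSE] %*% sol)
  sigma2 <- sum(w * resid^2) / (j - 2)
  ses[live] <- sqrt(diag(solve(xtx))) * max(1, sqrt(sigma2))
  pv <- 2 * stats::pt(-abs(coefs / ses), df = j - 2)
  out <- structure(
    data.frame(method = "mvmr_ivw", n_snp = j, beta = unname(coefs),
               se = unname(ses), pvalue = unname(pv),
               or = exp(unname(coefs)),
               ci_low = exp(unname(coefs) - .z975 * unname(ses)),
               ci_high = exp(unname(coefs) + .z975 * unname(ses)),
               stringsAsFactors = FALSE),
    class = c("mr_estimate", "data.frame"))
  out$term <- c("exposure", "mediator")
  out
}
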