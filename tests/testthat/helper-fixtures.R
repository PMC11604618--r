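# Shared fixtures and independent oracles for the test suite.

# Minimal harmonized data.frame accepted by the estimators.
make_h <- function(beta_exp, se_exp, beta_out, se_out,
                   beta_med = NULL, se_med = NULL,
                   rsid = sprintf("rs%03d", seq_along(beta_exp))) {
  h <- data.frame(rsid = rsid, beta_exp = beta_exp, se_exp = se_exp,
                  beta_out = beta_out, se_out = se_out,
                  stringsAsFactors = FALSE)
  if (!is.null(beta_med)) {
    h$beta_med <- beta_med
    h$se_med <- se_med
  }
  h
}

# Summary-stats builder with sensible defaults.
make_stats <- function(rsid, effect_allele, other_allele, beta, se,
                       pvalue = 2 * pnorm(-abs(beta / se)),
                       eaf = 0.3, chrom = 1,
                       pos = seq_along(rsid) * 1e5, n = 1000,
                       trait_id = "trait", group = "all") {
  summary_stats(
    data.frame(rsid = rsid, chrom = chrom, pos = pos,
               effect_allele = effect_allele, other_allele = other_allele,
               eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n,
               stringsAsFactors = FALSE),
    trait_id = trait_id, group = group)
}

# --- independent oracles -------------------------------------------------

# IVW via R's weighted regression machinery (through the origin).
oracle_ivw_fixed <- function(h) {
  fit <- lm(beta_out ~ 0 + beta_exp, data = h, weights = 1 / h$se_out^2)
  s <- summary(fit)
  list(beta = unname(coef(fit)[1]),
       se = unname(s$coefficients[1, 2]) / s$sigma)
}

# Egger via lm(); coefficient SEs rescaled to the max(1, sigma) convention.
oracle_egger <- function(h) {
  flip <- ifelse(h$beta_exp < 0, -1, 1)
  d <- data.frame(bx = h$beta_exp * flip, by = h$beta_out * flip)
  fit <- lm(by ~ bx, data = d, weights = 1 / h$se_out^2)
  s <- summary(fit)
  scale <- max(1, s$sigma) / s$sigma
  list(slope = unname(coef(fit)["bx"]),
       intercept = unname(coef(fit)["(Intercept)"]),
       se_slope = unname(s$coefficients["bx", 2]) * scale,
       se_intercept = unname(s$coefficients["(Intercept)", 2]) * scale)
}

# MVMR via lm() without intercept.
oracle_mvmr <- function(h) {
  fit <- lm(beta_out ~ 0 + beta_exp + beta_med, data = h,
            weights = 1 / h$se_out^2)
  s <- summary(fit)
  scale <- max(1, s$sigma) / s$sigma
  list(coefs = unname(coef(fit)),
       ses = unname(s$coefficients[, 2]) * scale)
}

# Weighted median by explicit scan of the weighted CDF (no approx()).
oracle_weighted_median <- function(x, w) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord] / sum(w)
  cum <- cumsum(w) - w / 2
  if (0.5 <= cum[1]) return(x[1])
  n <- length(x)
  if (0.5 >= cum[n]) return(x[n])
  j <- max(which(cum <= 0.5))
  x[j] + (x[j + 1] - x[j]) * (0.5 - cum[j]) / (cum[j + 1] - cum[j])
}

# Mode by brute-force dense-grid kernel density argmax.
oracle_mode <- function(ratios, w, bw, n_grid = 1e5) {
  w <- w / sum(w)
  grid <- seq(min(ratios) - 3 * bw, max(ratios) + 3 * bw,
              length.out = n_grid)
  dens <- vapply(grid, function(g) sum(w * dnorm((g - ratios) / bw)) / bw,
                 numeric(1))
  grid[which.max(dens)]
}

# Harmonization category for one exposure/outcome allele configuration,
# by direct enumeration of the matching rules.
oracle_harmonize_case <- function(ea, oa, tea, toa) {
  comp <- function(a) chartr("ACGT", "TGCA", a)
  if (oa == comp(ea)) {
    if ((tea == ea && toa == oa) || (tea == oa && toa == ea)) {
      return("palindromic")
    }
    return("allele_mismatch")
  }
  if (tea == ea && toa == oa) return("keep")
  if (tea == oa && toa == ea) return("flip")
  if (comp(tea) == ea && comp(toa) == oa) return("keep")
  if (comp(tea) == oa && comp(toa) == ea) return("flip")
  "allele_mismatch"
}
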