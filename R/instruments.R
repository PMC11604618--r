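# Instrument selection: p-value threshold, greedy LD clumping, palindrome
# exclusion (via harmonize) and F-statistic filtering.

#' Instrument-selection configuration
#'
#' Defaults follow common two-sample MR practice for molecular/microbial
#' exposures: genome-wide-suggestive exposure threshold p < 1e-5, clumping
#' at r-squared < 0.001 within a 10,000 kb window, and a minimum
#' F-statistic of 10 to guard against weak-instrument bias. Reverse-MR
#' analyses conventionally relax the exposure threshold to 5e-5.
#'
#' @param p_threshold exposure significance cutoff (strict \code{<}).
#' @param clump_r2 r-squared above or at which a nearby SNP is removed.
#' @param clump_kb clumping window, kilobases.
#' @param f_min minimum F-statistic (strict \code{>}).
#' @param palindrome_policy passed to \code{\link{harmonize}}.
#' @param ld_fallback what \code{\link{clump}} does without an LD matrix:
#'   \code{"assume_independent"} keeps all SNPs with a warning;
#'   \code{"distance_only"} prunes by the kb window alone.
#' @return A list of class \code{selection_config}.
#' @export
selection_config <- function(p_threshold = 1e-5, clump_r2 = 0.001,
                             clump_kb = 10000, f_min = 10,
                             palindrome_policy = "exclude",
                             ld_fallback = c("assume_independent",
                                             "distance_only")) {
  ld_fallback <- match.arg(ld_fallback)
  stopifnot(p_threshold > 0, p_threshold < 1,
            clump_r2 > 0, clump_r2 <= 1,
            clump_kb > 0, f_min > 0)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_kb = clump_kb, f_min = f_min,
                 palindrome_policy = palindrome_policy,
                 ld_fallback = ld_fallback),
            class = "selection_config")
}

#' Instrument strength F-statistic
#'
#' F = beta^2 / se^2, the squared Wald z of the SNP-exposure association;
#' values above 10 are conventionally taken to exclude weak-instrument bias.
#'
#' @param beta,se SNP-exposure effect and its standard error (vectorized).
#' @return Non-negative F value(s).
#' @export
f_statistic <- function(beta, se) {
  if (any(!is.finite(se)) || any(se <= 0)) {
    .mr_error("standard error must be positive", "mr_domain_error")
  }
  beta^2 / se^2
}

#' Greedy LD clumping
#'
#' SNPs are ordered by ascending p-value (ties broken by lexical rsid); the
#' best remaining SNP is retained and all others on the same chromosome
#' within \code{clump_kb} whose r-squared with it is at or above
#' \code{clump_r2} are removed. Cross-chromosome pairs and pairs beyond the
#' window are never pruned, regardless of recorded r-squared. The result is
#' invariant to input order.
#'
#' @param snps data.frame with columns \code{rsid}, \code{chrom},
#'   \code{pos}, \code{pvalue}.
#' @param ld optional \code{\link{ld_matrix}}; if absent the configured
#'   \code{ld_fallback} policy applies.
#' @param config a \code{\link{selection_config}}.
#' @return Character vector of retained rsids, in retention order.
#' @export
clump <- function(snps, ld = NULL, config = selection_config()) {
  stopifnot(is.data.frame(snps))
  if (nrow(snps) == 0) return(character(0))
  ord <- order(snps$pvalue, snps$rsid)
  snps <- snps[ord, , drop = FALSE]
  if (is.null(ld) && config$ld_fallback == "assume_independent") {
    warning("no LD matrix supplied; assuming instruments independent",
            call. = FALSE)
    return(snps$rsid)
  }
  if (!is.null(ld)) {
    stopifnot(inherits(ld, "ld_matrix"))
  }
  window_bp <- config$clump_kb * 1000
  retained <- character(0)
  alive <- rep(TRUE, nrow(snps))
  for (i in seq_len(nrow(snps))) {
    if (!alive[i]) next
    retained <- c(retained, snps$rsid[i])
    alive[i] <- FALSE
    cand <- which(alive)
    if (length(cand) == 0) break
    same_chr <- !is.na(snps$chrom[cand]) & !is.na(snps$chrom[i]) &
      snps$chrom[cand] == snps$chrom[i]
    near <- same_chr & abs(snps$pos[cand] - snps$pos[i]) <= window_bp
    if (!any(near)) next
    hit <- cand[near]
    if (is.null(ld)) {
      # distance_only fallback: prune by window alone
      alive[hit] <- FALSE
    } else {
      pair_ok <- snps$rsid[hit] %in% ld$rsids & snps$rsid[i] %in% ld$rsids
      if (any(!pair_ok)) {
        bad <- snps$rsid[hit][!pair_ok][1]
        .mr_error(sprintf("LD matrix lacks pair (%s, %s)",
                          snps$rsid[i], bad),
                  "mr_config_error")
      }
      r2 <- ld$r2[snps$rsid[i], snps$rsid[hit]]
      alive[hit[r2 >= config$clump_r2]] <- FALSE
    }
  }
  retained
}

#' Select genetic instruments for an exposure
#'
#' Applies, in order: exposure p-value thresholding, greedy LD clumping,
#' harmonization against the outcome (palindromic variants excluded under
#' the default policy), and the F-statistic filter. Per-stage survivor
#' counts are recorded so reported instrument numbers match the analyzed
#' set.
#'
#' @param exposure,outcome \code{\link{summary_stats}} objects.
#' @param ld optional \code{\link{ld_matrix}} for clumping.
#' @param config a \code{\link{selection_config}}.
#' @return An \code{instrument_set}: a \code{harmonized_set} restricted to
#'   the selected instruments with an \code{f_stat} column, plus attribute
#'   \code{counts} (\code{n_after_p}, \code{n_after_clump},
#'   \code{n_after_palindrome}, \code{n_after_f}).
#' @export
select_instruments <- function(exposure, outcome, ld = NULL,
                               config = selection_config()) {
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"),
            inherits(config, "selection_config"))
  ed <- exposure$data
  sig <- ed[!is.na(ed$pvalue) & ed$pvalue < config$p_threshold, ,
            drop = FALSE]
  counts <- c(n_after_p = nrow(sig), n_after_clump = NA_integer_,
              n_after_palindrome = NA_integer_, n_after_f = NA_integer_)
  if (nrow(sig) == 0) {
    .mr_error(sprintf(
      "no instruments for '%s' below p threshold %g",
      exposure$trait_id, config$p_threshold),
      "mr_empty_instruments_error", stage = "p_threshold")
  }
  kept <- clump(sig, ld = ld, config = config)
  counts["n_after_clump"] <- length(kept)

  exp_sub <- exposure
  exp_sub$data <- ed[ed$rsid %in% kept, , drop = FALSE]
  h <- harmonize(exp_sub, outcome,
                 palindrome_policy = config$palindrome_policy)
  hr <- retained(h)
  counts["n_after_palindrome"] <- nrow(hr)
  if (nrow(hr) == 0) {
    .mr_error(sprintf("no instruments for '%s' survive harmonization",
                      exposure$trait_id),
              "mr_empty_instruments_error", stage = "harmonize")
  }
  hr$f_stat <- f_statistic(hr$beta_exp, hr$se_exp)
  hr <- hr[hr$f_stat > config$f_min, , drop = FALSE]
  counts["n_after_f"] <- nrow(hr)
  if (nrow(hr) == 0) {
    .mr_error(sprintf("no instruments for '%s' with F > %g",
                      exposure$trait_id, config$f_min),
              "mr_empty_instruments_error", stage = "f_filter")
  }
  rownames(hr) <- NULL
  structure(hr,
            exposure_id = exposure$trait_id,
            outcome_id = outcome$trait_id,
            counts = counts,
            class = c("instrument_set", "harmonized_set", "data.frame"))
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %s -> %s (%d SNPs)\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"), nrow(x)))
  cn <- attr(x, "counts")
  cat(sprintf("  p-threshold %d -> clump %d -> harmonize %d -> F filter %d\n",
              cn["n_after_p"], cn["n_after_clump"],
              cn["n_after_palindrome"], cn["n_after_f"]))
  invisible(x)
}
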