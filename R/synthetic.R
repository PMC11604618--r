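# Synthetic GWAS summary statistics with known ground truth.
#
# The simulator emulates the statistical structure of the study design the
# package targets: a modest-n quantitative exposure GWAS (microbial
# abundance), a mediator GWAS (immune cell trait) and a large case/control
# outcome GWAS on the log-odds scale, linked by a mediation chain
#   exposure --theta--> outcome,  exposure --b1--> mediator --b2--> outcome,
# so the marginal exposure->outcome slope is total = theta + b1 * b2.
# Summary statistics are simulated directly (no individual-level
# genotypes): two-sample MR consumes only per-SNP betas and SEs.

#' Simulation configuration
#'
#' Defaults emulate the scale of the motivating data: exposure GWAS
#' n = 5959 (a Finnish metagenomic cohort), mediator GWAS n = 3757 (an
#' immune-trait cohort), and a binary outcome with 1748 cases and 454600
#' controls whose log-odds SEs come from
#' \code{\link{binary_outcome_se}}. Instrument true effects are drawn as
#' |gamma| ~ Normal(0.4, 0.08) with random sign, giving strong instruments
#' (mean F well above 100 at these sample sizes); minor allele frequencies
#' are uniform on [0.05, 0.5].
#'
#' @param n_snp instruments per trait: a single number, or a length-3
#'   vector (exposure, mediator, outcome direct instruments). Each trait's
#'   own instruments are disjoint SNP sets, as in real GWAS panels.
#' @param n_exp,n_med exposure / mediator GWAS sample sizes.
#' @param n_case,n_control outcome case/control counts (used for the
#'   outcome SE scale).
#' @param n_out optional quantitative-trait outcome sample size; when
#'   given it overrides the case/control SE model.
#' @param theta true direct exposure->outcome effect (log-odds).
#' @param b1_true,b2_true mediator-path effects (exposure->mediator,
#'   mediator->outcome).
#' @param theta_rev true outcome->exposure effect through the outcome's
#'   own instruments (nonzero makes the system bidirectional).
#' @param gamma_mean,gamma_sd distribution of |instrument effect|; signs
#'   are random.
#' @param gamma_fixed optional explicit vector of exposure-instrument
#'   effects, overriding the distribution.
#' @param maf_range minor-allele-frequency range.
#' @param pleiotropy list: \code{type} in \code{"none"},
#'   \code{"balanced"} (alpha ~ N(0, tau^2)), \code{"directional"}
#'   (alpha ~ N(mu, tau^2)) or \code{"inside_violating"} (alpha correlated
#'   rho with the instrument strength); fields \code{mu}, \code{tau},
#'   \code{rho}. Applies to the exposure's instruments.
#' @param n_outlier,outlier_displacement planted outliers among the
#'   exposure instruments: count and displacement in outcome-SE units.
#' @param palindromic_frac fraction of SNPs given an A/T or C/G allele
#'   pair.
#' @param flip_frac fraction of SNPs whose alleles are swapped (with beta
#'   sign and frequency complemented) in the outcome and mediator tables,
#'   to exercise harmonization.
#' @param ld_blocks optional list of \code{list(size =, r2 =)}; each block
#'   attaches \code{size - 1} proxy SNPs to one exposure instrument with
#'   the given within-block r-squared.
#' @param seed integer seed driving all randomness.
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_snp = 50, n_exp = 5959, n_med = 3757,
                              n_case = 1748, n_control = 454600,
                              n_out = NULL, theta = 0.3, b1_true = 0,
                              b2_true = 0, theta_rev = 0,
                              gamma_mean = 0.4, gamma_sd = 0.08,
                              gamma_fixed = NULL,
                              maf_range = c(0.05, 0.5),
                              pleiotropy = list(type = "none", mu = 0,
                                                tau = 0, rho = 0),
                              n_outlier = 0, outlier_displacement = 0,
                              palindromic_frac = 0.1, flip_frac = 0.2,
                              ld_blocks = NULL, seed = 1) {
  if (length(n_snp) == 1) n_snp <- rep(n_snp, 3)
  stopifnot(length(n_snp) == 3, all(n_snp >= 0), n_snp[1] >= 1,
            n_exp >= 2, n_med >= 2, n_case >= 1, n_control >= 1,
            gamma_sd >= 0, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            palindromic_frac >= 0, palindromic_frac <= 1,
            flip_frac >= 0, flip_frac <= 1, n_outlier >= 0)
  pleiotropy <- utils::modifyList(list(type = "none", mu = 0, tau = 0,
                                       rho = 0), pleiotropy)
  stopifnot(pleiotropy$type %in% c("none", "balanced", "directional",
                                   "inside_violating"),
            pleiotropy$tau >= 0)
  if (n_outlier > n_snp[1]) {
    .mr_error("n_outlier exceeds the number of exposure instruments",
              "mr_config_error")
  }
  structure(list(n_snp = n_snp, n_exp = n_exp, n_med = n_med,
                 n_case = n_case, n_control = n_control, n_out = n_out,
                 theta = theta, b1_true = b1_true, b2_true = b2_true,
                 theta_rev = theta_rev, gamma_mean = gamma_mean,
                 gamma_sd = gamma_sd, gamma_fixed = gamma_fixed,
                 maf_range = maf_range, pleiotropy = pleiotropy,
                 n_outlier = n_outlier,
                 outlier_displacement = outlier_displacement,
                 palindromic_frac = palindromic_frac,
                 flip_frac = flip_frac, ld_blocks = ld_blocks,
                 seed = seed),
            class = "simulation_config")
}

#' Approximate log-odds standard error for a binary-trait GWAS
#'
#' se = 1 / sqrt(2 p (1 - p) * N * phi (1 - phi)) with p the effect-allele
#' frequency, N the total sample size and phi the case fraction — the
#' usual large-sample approximation for a per-allele logistic effect.
#'
#' @param n_case,n_control case and control counts.
#' @param maf effect-allele frequency (vectorized).
#' @return Standard error(s).
#' @export
binary_outcome_se <- function(n_case, n_control, maf) {
  n <- n_case + n_control
  phi <- n_case / n
  1 / sqrt(2 * maf * (1 - maf) * n * phi * (1 - phi))
}

.quantitative_se <- function(n, maf) 1 / sqrt(2 * maf * (1 - maf) * n)

# Non-palindromic ordered allele pairs.
.nonpal_pairs <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
.pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate a full exposure/mediator/outcome summary-statistics system
#'
#' Generates one SNP panel holding each trait's own instruments (disjoint
#' sets), with per-SNP minor allele frequencies, allele-frequency-dependent
#' standard errors, observed betas drawn around the true marginal effects,
#' normal p-values, a block-diagonal LD matrix, and optional pleiotropy,
#' planted outliers, palindromic variants and allele flips. The full
#' generating truth is recorded so every downstream estimand can be
#' checked analytically (e.g. \code{truth$total = theta + b1 * b2}).
#'
#' True marginal effects: for an exposure instrument with effect gamma the
#' exposure, mediator and outcome means are gamma, b1 * gamma and
#' (theta + b1 * b2) * gamma + alpha (alpha the pleiotropic effect); a
#' mediator instrument with effect delta contributes (0, delta,
#' b2 * delta); an outcome instrument with effect omega contributes
#' (theta_rev * omega, 0, omega).
#'
#' @param config a \code{\link{simulation_config}}.
#' @return An object of class \code{synthetic_study}: list with
#'   \code{exposure}, \code{mediator}, \code{outcome}
#'   (\code{summary_stats}), \code{ld} (\code{\link{ld_matrix}}),
#'   \code{truth} (generating parameters, per-SNP effects and bookkeeping)
#'   and \code{config}.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, .simulate_study_impl(config))
}

.simulate_study_impl <- function(cf) {
  n_a <- cf$n_snp[1]; n_b <- cf$n_snp[2]; n_c <- cf$n_snp[3]

  draw_effects <- function(n) {
    if (n == 0) return(numeric(0))
    sample(c(-1, 1), n, replace = TRUE) *
      abs(stats::rnorm(n, cf$gamma_mean, cf$gamma_sd))
  }
  gamma <- if (!is.null(cf$gamma_fixed)) {
    stopifnot(length(cf$gamma_fixed) == n_a)
    cf$gamma_fixed
  } else {
    draw_effects(n_a)
  }
  delta <- draw_effects(n_b)
  omega <- draw_effects(n_c)

  set <- rep(c("exposure", "mediator", "outcome"), times = c(n_a, n_b, n_c))
  n_tot <- n_a + n_b + n_c
  rsid <- sprintf("rs%05d", seq_len(n_tot))
  chrom <- ((seq_len(n_tot) - 1) %% 22) + 1
  pos <- 1e6 + ((seq_len(n_tot) - 1) %/% 22) * 2.5e7
  maf <- stats::runif(n_tot, cf$maf_range[1], cf$maf_range[2])

  # pleiotropic direct effects for the exposure's instruments
  alpha <- numeric(n_a)
  pl <- cf$pleiotropy
  if (n_a > 0 && pl$type != "none" && (pl$tau > 0 || pl$mu != 0)) {
    if (pl$type == "balanced") {
      alpha <- stats::rnorm(n_a, 0, pl$tau)
    } else if (pl$type == "directional") {
      alpha <- stats::rnorm(n_a, pl$mu, pl$tau)
    } else {  # inside_violating: alpha correlated with instrument strength
      zg <- if (stats::sd(gamma) > 0) {
        (gamma - mean(gamma)) / stats::sd(gamma)
      } else {
        numeric(n_a)
      }
      alpha <- pl$tau * (pl$rho * zg +
                           sqrt(max(0, 1 - pl$rho^2)) * stats::rnorm(n_a))
    }
  }

  total <- cf$theta + cf$b1_true * cf$b2_true
  mu_exp <- c(gamma, rep(0, n_b), cf$theta_rev * omega)
  mu_med <- c(cf$b1_true * gamma, delta, rep(0, n_c))
  mu_out <- c(total * gamma + alpha, cf$b2_true * delta, omega)

  # LD blocks: attach proxies to the first exposure instruments
  block_of <- rep(NA_integer_, n_tot)
  if (!is.null(cf$ld_blocks)) {
    if (length(cf$ld_blocks) > n_a) {
      .mr_error("more LD blocks than exposure instruments",
                "mr_config_error")
    }
    for (bi in seq_along(cf$ld_blocks)) {
      blk <- cf$ld_blocks[[bi]]
      size <- blk$size; r2 <- blk$r2
      stopifnot(size >= 1, r2 >= 0, r2 <= 1)
      if (size == 1) next
      r <- sqrt(r2)
      idx <- bi  # index SNP
      k <- size - 1
      block_of[idx] <- bi
      rsid <- c(rsid, sprintf("rs%05d_p%d", idx, seq_len(k)))
      chrom <- c(chrom, rep(chrom[idx], k))
      pos <- c(pos, pos[idx] + seq_len(k) * 1e4)
      maf <- c(maf, rep(maf[idx], k))
      mu_exp <- c(mu_exp, rep(r * mu_exp[idx], k))
      mu_med <- c(mu_med, rep(r * mu_med[idx], k))
      mu_out <- c(mu_out, rep(r * mu_out[idx], k))
      set <- c(set, rep("proxy", k))
      block_of <- c(block_of, rep(bi, k))
    }
  }
  n_all <- length(rsid)

  se_exp <- .quantitative_se(cf$n_exp, maf)
  se_med <- .quantitative_se(cf$n_med, maf)
  se_out <- if (!is.null(cf$n_out)) {
    .quantitative_se(cf$n_out, maf)
  } else {
    binary_outcome_se(cf$n_case, cf$n_control, maf)
  }

  beta_exp <- stats::rnorm(n_all, mu_exp, se_exp)
  beta_med <- stats::rnorm(n_all, mu_med, se_med)
  beta_out <- stats::rnorm(n_all, mu_out, se_out)

  # planted outliers among the exposure instruments (largest-index first
  # for determinism of the recorded set)
  outlier_idx <- integer(0)
  if (cf$n_outlier > 0) {
    outlier_idx <- sample(seq_len(n_a), cf$n_outlier)
    beta_out[outlier_idx] <- beta_out[outlier_idx] +
      cf$outlier_displacement * se_out[outlier_idx]
  }

  # allele pairs: a configured fraction palindromic
  n_pal <- round(cf$palindromic_frac * n_all)
  is_pal <- rep(FALSE, n_all)
  if (n_pal > 0) is_pal[sample(n_all, n_pal)] <- TRUE
  alleles <- matrix("", n_all, 2)
  alleles[is_pal, ] <- .pal_pairs[sample(nrow(.pal_pairs), sum(is_pal),
                                         replace = TRUE), , drop = FALSE]
  alleles[!is_pal, ] <- .nonpal_pairs[sample(nrow(.nonpal_pairs),
                                             sum(!is_pal), replace = TRUE),
                                      , drop = FALSE]

  make_table <- function(beta, se, flip) {
    ea <- alleles[, 1]; oa <- alleles[, 2]; eaf <- maf; b <- beta
    if (any(flip)) {
      ea[flip] <- alleles[flip, 2]; oa[flip] <- alleles[flip, 1]
      b[flip] <- -b[flip]; eaf[flip] <- 1 - eaf[flip]
    }
    # clamp to the smallest representable p so extreme z-scores survive
    # the (0, 1] validity check
    data.frame(rsid = rsid, chrom = chrom, pos = pos,
               effect_allele = ea, other_allele = oa, eaf = eaf,
               beta = b, se = se,
               pvalue = pmax(2 * stats::pnorm(-abs(b / se)), 1e-300),
               stringsAsFactors = FALSE)
  }
  n_flip <- round(cf$flip_frac * n_all)
  flip_out <- rep(FALSE, n_all)
  if (n_flip > 0) flip_out[sample(n_all, n_flip)] <- TRUE
  flip_med <- rep(FALSE, n_all)
  if (n_flip > 0) flip_med[sample(n_all, n_flip)] <- TRUE

  d_exp <- make_table(beta_exp, se_exp, rep(FALSE, n_all))
  d_exp$n <- cf$n_exp
  d_med <- make_table(beta_med, se_med, flip_med)
  d_med$n <- cf$n_med
  d_out <- make_table(beta_out, se_out, flip_out)
  d_out$n <- if (!is.null(cf$n_out)) cf$n_out else cf$n_case + cf$n_control

  # block-diagonal LD matrix
  r2m <- diag(n_all)
  if (!is.null(cf$ld_blocks)) {
    for (bi in seq_along(cf$ld_blocks)) {
      members <- which(!is.na(block_of) & block_of == bi)
      if (length(members) > 1) {
        r2m[members, members] <- cf$ld_blocks[[bi]]$r2
        diag(r2m)[members] <- 1
      }
    }
  }

  truth <- list(
    theta = cf$theta, b1 = cf$b1_true, b2 = cf$b2_true, total = total,
    theta_rev = cf$theta_rev, gamma = gamma, delta = delta, omega = omega,
    alpha = alpha, maf = maf, set = set,
    outlier_idx = outlier_idx, outlier_rsid = rsid[outlier_idx],
    outlier_displacement = cf$outlier_displacement,
    palindromic_rsid = rsid[is_pal],
    flipped_outcome_rsid = rsid[flip_out],
    flipped_mediator_rsid = rsid[flip_med],
    mu_exp = mu_exp, mu_med = mu_med, mu_out = mu_out,
    se_exp = se_exp, se_med = se_med, se_out = se_out,
    seed = cf$seed)

  structure(
    list(exposure = summary_stats(d_exp, trait_id = "sim_exposure",
                                  group = "simulated"),
         mediator = summary_stats(d_med, trait_id = "sim_mediator",
                                  group = "simulated"),
         outcome = summary_stats(d_out, trait_id = "sim_outcome",
                                 group = "simulated"),
         ld = ld_matrix(r2m, rsid),
         truth = truth, config = cf),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cf <- x$config
  cat(sprintf(
    "Synthetic GWAS study: %d/%d/%d instruments (exposure/mediator/outcome)\n",
    cf$n_snp[1], cf$n_snp[2], cf$n_snp[3]))
  cat(sprintf("  theta = %g, b1 = %g, b2 = %g (total = %g), seed = %d\n",
              cf$theta, cf$b1_true, cf$b2_true, x$truth$total, cf$seed))
  invisible(x)
}

#' Plant additional outliers into a simulated study
#'
#' Shifts the outcome betas of \code{k} randomly chosen exposure
#' instruments by \code{displacement} outcome-SE units and records their
#' identities in the truth. With \code{k = 0} or zero displacement the
#' study's statistics are unchanged.
#'
#' @param study a \code{\link{simulate_study}} result.
#' @param k number of outliers (\code{<=} exposure instruments).
#' @param displacement shift in outcome-SE units.
#' @param seed RNG seed for the index draw.
#' @return The modified \code{synthetic_study}.
#' @export
plant_outliers <- function(study, k, displacement, seed) {
  stopifnot(inherits(study, "synthetic_study"))
  n_a <- study$config$n_snp[1]
  if (k > n_a) {
    .mr_error("k exceeds the number of exposure instruments",
              "mr_config_error")
  }
  if (k == 0) return(study)
  idx <- .with_seed(seed, sample(seq_len(n_a), k))
  od <- study$outcome$data
  pick <- match(sprintf("rs%05d", idx), od$rsid)
  od$beta[pick] <- od$beta[pick] + displacement * od$se[pick]
  od$pvalue[pick] <- pmax(2 * stats::pnorm(-abs(od$beta[pick] / od$se[pick])),
                          1e-300)
  study$outcome$data <- od
  study$truth$outlier_idx <- sort(union(study$truth$outlier_idx, idx))
  study$truth$outlier_rsid <- sprintf("rs%05d", study$truth$outlier_idx)
  study$truth$outlier_displacement <- displacement
  study
}

#' Write a simulated study to disk as plain text
#'
#' Emits exposure/mediator/outcome summary TSVs, the LD matrix TSV and the
#' ground truth as JSON into \code{dir}.
#'
#' @param study a \code{synthetic_study}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             mediator = file.path(dir, "mediator.tsv"),
             outcome = file.path(dir, "outcome.tsv"),
             ld = file.path(dir, "ld.tsv"),
             truth = file.path(dir, "truth.json"))
  write_results(study$exposure$data, paths["exposure"], "tsv")
  write_results(study$mediator$data, paths["mediator"], "tsv")
  write_results(study$outcome$data, paths["outcome"], "tsv")
  write_ld_matrix(study$ld, paths["ld"])
  jsonlite::write_json(study$truth, paths["truth"], digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(paths)
}
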