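# Reading, validating and harmonizing GWAS summary statistics.

# Canonical GWAS-SSF column vocabulary; a user-supplied column_map translates
# file dialects onto these names.
.canonical_cols <- c(
  rsid = "rsid", chromosome = "chrom", base_pair_location = "pos",
  effect_allele = "effect_allele", other_allele = "other_allele",
  effect_allele_frequency = "eaf", beta = "beta", standard_error = "se",
  p_value = "pvalue", n = "n"
)
.required_cols <- c("rsid", "effect_allele", "other_allele",
                    "beta", "standard_error", "p_value")

.mr_error <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "mr_error")))
}

.complement <- function(a) chartr("ACGT", "TGCA", a)

.is_palindromic <- function(ea, oa) oa == .complement(ea)

#' Construct a validated summary-statistics object
#'
#' Bundles a per-SNP association table with trait metadata. Rows violating
#' the per-record invariants (single-letter A/C/G/T alleles, effect allele
#' distinct from the other allele, positive standard error, p-value in
#' (0, 1], allele frequency in [0, 1] when present) are dropped and counted;
#' duplicated rsids are resolved first-occurrence-wins.
#'
#' @param data data.frame with columns \code{rsid}, \code{effect_allele},
#'   \code{other_allele}, \code{beta}, \code{se}, \code{pvalue} and
#'   optionally \code{chrom}, \code{pos}, \code{eaf}, \code{n}.
#' @param trait_id,trait_name identifiers for the trait.
#' @param group grouping label (e.g. a taxonomic level such as
#'   \code{"genus"}, or an immune panel name), used for per-group
#'   multiple-testing thresholds.
#' @return An object of class \code{summary_stats}: a list with elements
#'   \code{trait_id}, \code{trait_name}, \code{group}, \code{data} (the
#'   validated table) and \code{drop_log} (named counts of removed rows).
#' @export
summary_stats <- function(data, trait_id = "trait", trait_name = trait_id,
                          group = "all") {
  stopifnot(is.data.frame(data))
  for (col in c("chrom", "pos", "eaf", "n")) {
    if (is.null(data[[col]])) data[[col]] <- NA
  }
  miss <- setdiff(c("rsid", "effect_allele", "other_allele",
                    "beta", "se", "pvalue"), names(data))
  if (length(miss) > 0) {
    .mr_error(sprintf("missing required column(s): %s",
                      paste(miss, collapse = ", ")),
              "mr_config_error")
  }
  data$rsid <- as.character(data$rsid)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("beta", "se", "pvalue", "eaf", "pos", "n")) {
    data[[col]] <- suppressWarnings(as.numeric(data[[col]]))
  }

  drop_log <- c(bad_allele = 0L, se_nonpositive = 0L, bad_pvalue = 0L,
                bad_eaf = 0L, bad_beta = 0L, duplicate_rsid = 0L)
  ok_allele <- data$effect_allele %in% c("A", "C", "G", "T") &
    data$other_allele %in% c("A", "C", "G", "T") &
    data$effect_allele != data$other_allele
  drop_log["bad_allele"] <- sum(!ok_allele)
  ok_se <- !is.na(data$se) & data$se > 0
  drop_log["se_nonpositive"] <- sum(ok_allele & !ok_se)
  ok_p <- !is.na(data$pvalue) & data$pvalue > 0 & data$pvalue <= 1
  drop_log["bad_pvalue"] <- sum(ok_allele & ok_se & !ok_p)
  ok_eaf <- is.na(data$eaf) | (data$eaf >= 0 & data$eaf <= 1)
  drop_log["bad_eaf"] <- sum(ok_allele & ok_se & ok_p & !ok_eaf)
  ok_beta <- is.finite(data$beta)
  drop_log["bad_beta"] <- sum(ok_allele & ok_se & ok_p & ok_eaf & !ok_beta)

  keep <- ok_allele & ok_se & ok_p & ok_eaf & ok_beta
  data <- data[keep, , drop = FALSE]
  dup <- duplicated(data$rsid)
  drop_log["duplicate_rsid"] <- sum(dup)
  data <- data[!dup, , drop = FALSE]
  rownames(data) <- NULL

  if (nrow(data) == 0) {
    .mr_error(sprintf("no valid rows for trait '%s'", trait_id),
              "mr_empty_input_error")
  }
  structure(
    list(trait_id = trait_id, trait_name = trait_name, group = group,
         data = data[, c("rsid", "chrom", "pos", "effect_allele",
                         "other_allele", "eaf", "beta", "se",
                         "pvalue", "n")],
         drop_log = drop_log),
    class = "summary_stats"
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s, group '%s')\n",
              x$trait_id, x$trait_name, x$group))
  cat(sprintf("  %d variants; %d rows dropped at read time\n",
              nrow(x$data), sum(x$drop_log)))
  invisible(x)
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Accepts tab- or comma-delimited tables with a header. Columns are mapped
#' onto the canonical GWAS-SSF vocabulary (\code{rsid}, \code{chromosome},
#' \code{base_pair_location}, \code{effect_allele}, \code{other_allele},
#' \code{effect_allele_frequency}, \code{beta}, \code{standard_error},
#' \code{p_value}, \code{n}); \code{column_map} translates other dialects,
#' as \code{c(file_column = "canonical_name")}. Alleles are upper-cased and
#' rows failing validation are dropped and counted (see
#' \code{\link{summary_stats}}).
#'
#' @param path file path.
#' @param column_map optional named character vector mapping file column
#'   names to canonical names.
#' @param trait_id,trait_name,group trait metadata (default: file base name).
#' @param sep field delimiter; \code{NULL} autodetects tab vs comma from the
#'   header line.
#' @return A \code{\link{summary_stats}} object.
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               trait_id = sub("\\.[^.]*$", "", basename(path)),
                               trait_name = trait_id, group = "all",
                               sep = NULL) {
  if (!file.exists(path)) {
    .mr_error(sprintf("file not found: %s", path), "mr_io_error")
  }
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (!is.null(column_map)) {
    idx <- match(names(column_map), names(raw))
    if (anyNA(idx)) {
      .mr_error(sprintf("column_map names absent from file: %s",
                        paste(names(column_map)[is.na(idx)], collapse = ", ")),
                "mr_config_error")
    }
    names(raw)[idx] <- unname(column_map)
  }
  # canonical -> internal names (files already using internal names pass
  # through untouched)
  hit <- match(names(.canonical_cols), names(raw))
  names(raw)[stats::na.omit(hit)] <- unname(.canonical_cols)[!is.na(hit)]
  need <- unname(.canonical_cols[.required_cols])
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    canon <- names(.canonical_cols)[match(miss, .canonical_cols)]
    .mr_error(sprintf("required column(s) missing: %s",
                      paste(canon, collapse = ", ")),
              "mr_config_error")
  }
  summary_stats(raw, trait_id = trait_id, trait_name = trait_name,
                group = group)
}

#' Harmonize effect alleles across exposure and outcome summary statistics
#'
#' Aligns outcome (and, optionally, mediator) associations to the exposure's
#' effect allele, SNP by SNP. Matching alleles are kept as-is; swapped
#' alleles sign-flip the beta and replace the allele frequency by its
#' complement; alleles matching only after strand complementation
#' (A<->T, C<->G) are complemented first, then the same rules apply.
#' Palindromic variants (allele pair A/T or C/G), whose strand cannot be
#' resolved from the alleles, are excluded under the default policy;
#' \code{"eaf_infer"} instead aligns them by allele frequency, dropping only
#' those whose frequency is uninformative (within [0.42, 0.58] on either
#' side, or missing). Irreconcilable allele pairs are dropped with reason
#' \code{allele_mismatch}; exposure SNPs absent from the outcome carry
#' \code{missing_in_outcome}.
#'
#' @param exposure,outcome \code{\link{summary_stats}} objects.
#' @param mediator optional third \code{summary_stats} aligned the same way
#'   (SNPs absent from it are dropped with reason
#'   \code{missing_in_mediator}).
#' @param palindrome_policy \code{"exclude"} (default) or \code{"eaf_infer"}.
#' @return A \code{harmonized_set}: a data.frame with one row per exposure
#'   rsid shared with (or missing from) the outcome, columns
#'   \code{beta_exp}/\code{se_exp}/\code{pvalue_exp},
#'   \code{beta_out}/\code{se_out}/\code{pvalue_out} (and \code{_med}
#'   columns when a mediator is given), flags \code{palindromic} and
#'   \code{allele_flipped}, and \code{dropped_reason} (\code{"none"} for
#'   retained rows). Trait ids are kept as attributes.
#' @export
harmonize <- function(exposure, outcome, mediator = NULL,
                      palindrome_policy = c("exclude", "eaf_infer")) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"))
  ed <- exposure$data
  od <- outcome$data
  shared <- intersect(ed$rsid, od$rsid)
  if (length(shared) == 0) {
    .mr_error(sprintf("no shared rsids between '%s' and '%s'",
                      exposure$trait_id, outcome$trait_id),
              "mr_empty_overlap_error",
              exposure_id = exposure$trait_id,
              outcome_id = outcome$trait_id)
  }

  h <- ed[, c("rsid", "chrom", "pos", "effect_allele", "other_allele")]
  names(h)[4:5] <- c("effect_allele", "other_allele")
  h$eaf_exp <- ed$eaf
  h$beta_exp <- ed$beta
  h$se_exp <- ed$se
  h$pvalue_exp <- ed$pvalue
  h$n_exp <- ed$n
  h$palindromic <- .is_palindromic(h$effect_allele, h$other_allele)
  h$allele_flipped <- FALSE
  h$dropped_reason <- ifelse(h$rsid %in% shared, "none",
                             "missing_in_outcome")

  al <- .align_trait(h, od, palindrome_policy)
  h$beta_out <- al$beta
  h$se_out <- al$se
  h$pvalue_out <- al$pvalue
  h$eaf_out <- al$eaf
  h$allele_flipped <- al$flipped
  h$dropped_reason <- ifelse(h$dropped_reason == "none", al$reason,
                             h$dropped_reason)

  if (!is.null(mediator)) {
    stopifnot(inherits(mediator, "summary_stats"))
    md <- mediator$data
    in_med <- h$rsid %in% md$rsid
    am <- .align_trait(h, md, palindrome_policy)
    h$beta_med <- am$beta
    h$se_med <- am$se
    h$pvalue_med <- am$pvalue
    h$dropped_reason <- ifelse(
      h$dropped_reason != "none", h$dropped_reason,
      ifelse(!in_med, "missing_in_mediator",
             ifelse(am$reason != "none", am$reason, "none")))
  }

  rownames(h) <- NULL
  structure(h,
            exposure_id = exposure$trait_id,
            outcome_id = outcome$trait_id,
            mediator_id = if (is.null(mediator)) NULL else mediator$trait_id,
            class = c("harmonized_set", "data.frame"))
}

# Align one trait's betas to the exposure alleles in h. Returns aligned
# beta/se/pvalue/eaf, flip flags and a per-row dropped reason ("none" when
# alignable). Rows absent from the trait get NA and reason "none" (the
# caller assigns missing_* reasons).
.align_trait <- function(h, td, palindrome_policy) {
  m <- match(h$rsid, td$rsid)
  n <- nrow(h)
  out <- list(beta = rep(NA_real_, n), se = rep(NA_real_, n),
              pvalue = rep(NA_real_, n), eaf = rep(NA_real_, n),
              flipped = rep(FALSE, n), reason = rep("none", n))
  for (i in seq_len(n)) {
    j <- m[i]
    if (is.na(j)) next
    ea <- h$effect_allele[i]; oa <- h$other_allele[i]
    tea <- td$effect_allele[j]; toa <- td$other_allele[j]
    beta <- td$beta[j]; eaf <- td$eaf[j]
    if (h$palindromic[i]) {
      # swap and strand-complement are indistinguishable from the alleles
      if (!(identical(c(tea, toa), c(ea, oa)) ||
            identical(c(tea, toa), c(oa, ea)))) {
        out$reason[i] <- "allele_mismatch"; next
      }
      if (palindrome_policy == "exclude") {
        out$reason[i] <- "palindromic"; next
      }
      eaf_e <- h$eaf_exp[i]
      if (is.na(eaf_e) || is.na(eaf) ||
          (eaf_e >= 0.42 && eaf_e <= 0.58) ||
          (eaf >= 0.42 && eaf <= 0.58)) {
        out$reason[i] <- "palindromic"; next
      }
      # align by frequency: minor/major orientation must agree
      if ((eaf_e < 0.5) != (eaf < 0.5)) {
        beta <- -beta; eaf <- 1 - eaf; out$flipped[i] <- TRUE
      }
    } else {
      if (tea == ea && toa == oa) {
        # direct match
      } else if (tea == oa && toa == ea) {
        beta <- -beta; eaf <- if (is.na(eaf)) NA_real_ else 1 - eaf
        out$flipped[i] <- TRUE
      } else if (.complement(tea) == ea && .complement(toa) == oa) {
        # opposite strand, same orientation
      } else if (.complement(tea) == oa && .complement(toa) == ea) {
        beta <- -beta; eaf <- if (is.na(eaf)) NA_real_ else 1 - eaf
        out$flipped[i] <- TRUE
      } else {
        out$reason[i] <- "allele_mismatch"; next
      }
    }
    out$beta[i] <- beta
    out$se[i] <- td$se[j]
    out$pvalue[i] <- td$pvalue[j]
    out$eaf[i] <- eaf
  }
  out
}

#' Retained rows of a harmonized set
#'
#' @param h a \code{harmonized_set}.
#' @return The subset of rows with \code{dropped_reason == "none"}.
#' @export
retained <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  out <- h[h$dropped_reason == "none", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s\n",
              attr(x, "exposure_id"), attr(x, "outcome_id")))
  kept <- sum(x$dropped_reason == "none")
  cat(sprintf("  %d SNPs retained, %d dropped\n", kept, nrow(x) - kept))
  if (kept < nrow(x)) {
    tab <- table(x$dropped_reason[x$dropped_reason != "none"])
    cat(paste(sprintf("    %s: %d", names(tab), tab), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write result tables to TSV or JSON
#'
#' Values round-trip through \code{\link{read_results}} to at least 12
#' significant digits; column order is preserved deterministically.
#'
#' @param records a data.frame of results.
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @export
write_results <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  records <- as.data.frame(records)
  if (format == "tsv") {
    out <- records
    for (col in names(out)) {
      if (is.numeric(out[[col]])) {
        out[[col]] <- sapply(out[[col]], function(v)
          if (is.na(v)) NA_character_ else format(v, digits = 15))
      }
    }
    ok <- tryCatch({
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) .mr_error(sprintf("cannot write '%s'", path), "mr_io_error")
  } else {
    ok <- tryCatch({
      jsonlite::write_json(records, path, dataframe = "rows", digits = NA,
                           na = "null")
      TRUE
    }, error = function(e) FALSE)
    if (!ok) .mr_error(sprintf("cannot write '%s'", path), "mr_io_error")
  }
  invisible(NULL)
}

#' Read a results table written by \code{\link{write_results}}
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @return data.frame.
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  }
}

#' LD matrix constructor
#'
#' @param r2 square numeric matrix of pairwise squared correlations.
#' @param rsids variant identifiers (default: dimnames of \code{r2}).
#' @return An \code{ld_matrix}: list with \code{rsids} and \code{r2}.
#' @export
ld_matrix <- function(r2, rsids = rownames(r2)) {
  r2 <- as.matrix(r2)
  if (is.null(rsids)) .mr_error("LD matrix needs rsids", "mr_config_error")
  stopifnot(nrow(r2) == ncol(r2), length(rsids) == nrow(r2))
  if (any(abs(r2 - t(r2)) > 1e-8)) {
    .mr_error("LD matrix not symmetric", "mr_config_error")
  }
  if (any(r2 < -1e-12 | r2 > 1 + 1e-12)) {
    .mr_error("LD r-squared values outside [0, 1]", "mr_config_error")
  }
  if (any(abs(diag(r2) - 1) > 1e-8)) {
    .mr_error("LD matrix diagonal must be 1", "mr_config_error")
  }
  dimnames(r2) <- list(rsids, rsids)
  structure(list(rsids = as.character(rsids), r2 = r2),
            class = "ld_matrix")
}

#' Read / write an LD matrix as a TSV square matrix
#'
#' The file carries rsids as both header row and first column.
#' @param path file path.
#' @return \code{read_ld_matrix}: an \code{\link{ld_matrix}}.
#' @export
read_ld_matrix <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                         check.names = FALSE)
  ld_matrix(as.matrix(m), rownames(m))
}

#' @rdname read_ld_matrix
#' @param ld an \code{\link{ld_matrix}}.
#' @export
write_ld_matrix <- function(ld, path) {
  stopifnot(inherits(ld, "ld_matrix"))
  m <- as.data.frame(ld$r2)
  utils::write.table(cbind(rsid = ld$rsids, m), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
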