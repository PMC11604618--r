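test_that("a well-formed table reads back with all records intact", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(rsid = c("rs1", "rs2", "rs3"), chromosome = 1,
                   base_pair_location = c(100, 200, 300),
                   effect_allele = c("A", "C", "G"),
                   other_allele = c("G", "T", "A"),
                   effect_allele_frequency = 0.2, beta = c(0.1, -0.2, 0.05),
                   standard_error = 0.02, p_value = c(1e-6, 1e-7, 0.3),
                   n = 5000)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- read_summary_stats(path, trait_id = "t1")
  expect_s3_class(ss, "summary_stats")
  expect_equal(nrow(ss$data), 3)
  expect_equal(ss$data$beta, df$beta)
  expect_equal(sum(ss$drop_log), 0)
})

test_that("invalid rows are dropped and counted; alleles are upper-cased", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(rsid = c("rs1", "rs2", "rs3"), effect_allele = c("a", "C", "G"),
                   other_allele = c("g", "T", "A"), beta = 0.1,
                   standard_error = c(0.02, 0, 0.02), p_value = 1e-6)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ss <- read_summary_stats(path)
  expect_equal(nrow(ss$data), 2)
  expect_equal(unname(ss$drop_log["se_nonpositive"]), 1L)
  expect_equal(ss$data$effect_allele[1], "A")
  expect_equal(ss$data$other_allele[1], "G")
})

test_that("comma-delimited files autodetect and column maps rename dialects", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(SNP = c("rs1", "rs2"), A1 = c("A", "C"), A2 = c("G", "T"),
                   b = c(0.1, 0.2), SE = 0.05, P = 1e-6)
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  ss <- read_summary_stats(path, column_map = c(
    SNP = "rsid", A1 = "effect_allele", A2 = "other_allele",
    b = "beta", SE = "se", P = "pvalue"))
  expect_equal(ss$data$rsid, c("rs1", "rs2"))
  expect_equal(ss$data$beta, c(0.1, 0.2))
})

test_that("a missing required column is a configuration error naming it", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(rsid = "rs1", effect_allele = "A", other_allele = "G",
                   beta = 0.1, p_value = 1e-6)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_summary_stats(path), "standard_error",
               class = "mr_config_error")
})

test_that("duplicated rsids resolve first-occurrence-wins", {
  ss <- make_stats(c("rs1", "rs1"), c("A", "A"), c("G", "G"),
                   beta = c(0.1, 0.9), se = 0.02, pvalue = 1e-6)
  expect_equal(nrow(ss$data), 1)
  expect_equal(ss$data$beta, 0.1)
  expect_equal(unname(ss$drop_log["duplicate_rsid"]), 1L)
})

test_that("swapped outcome alleles flip the beta and the frequency", {
  exp <- make_stats("rs1", "A", "G", beta = 0.10, se = 0.02)
  out <- make_stats("rs1", "G", "A", beta = 0.05, se = 0.03, eaf = 0.7)
  h <- harmonize(exp, out)
  r <- retained(h)
  expect_equal(r$beta_out, -0.05)
  expect_true(r$allele_flipped)
  expect_equal(r$eaf_out, 0.3)
})

test_that("palindromic SNPs are excluded under the default policy", {
  exp <- make_stats(c("rs1", "rs2"), c("A", "A"), c("T", "G"),
                    beta = 0.1, se = 0.02)
  out <- make_stats(c("rs1", "rs2"), c("A", "A"), c("T", "G"),
                    beta = 0.05, se = 0.03)
  h <- harmonize(exp, out)
  expect_equal(h$dropped_reason[h$rsid == "rs1"], "palindromic")
  expect_equal(h$dropped_reason[h$rsid == "rs2"], "none")
})

test_that("strand-complement alleles are recognized, with and without swap", {
  exp <- make_stats(c("rs1", "rs2"), c("A", "A"), c("G", "G"),
                    beta = 0.1, se = 0.02)
  # rs1 reported on the opposite strand (T/C ~ A/G); rs2 opposite strand
  # and swapped (C/T ~ G/A)
  out <- make_stats(c("rs1", "rs2"), c("T", "C"), c("C", "T"),
                    beta = 0.05, se = 0.03)
  r <- retained(harmonize(exp, out))
  expect_equal(r$beta_out[r$rsid == "rs1"], 0.05)
  expect_false(r$allele_flipped[r$rsid == "rs1"])
  expect_equal(r$beta_out[r$rsid == "rs2"], -0.05)
  expect_true(r$allele_flipped[r$rsid == "rs2"])
})

test_that("every outcome allele configuration matches the enumeration oracle", {
  bases <- c("A", "C", "G", "T")
  for (ea_oa in list(c("A", "G"), c("C", "T"), c("A", "T"), c("C", "G"))) {
    for (tea in bases) for (toa in setdiff(bases, tea)) {
      expected <- oracle_harmonize_case(ea_oa[1], ea_oa[2], tea, toa)
      exp <- make_stats("rs1", ea_oa[1], ea_oa[2], beta = 0.1, se = 0.02)
      out <- make_stats("rs1", tea, toa, beta = 0.05, se = 0.03)
      h <- harmonize(exp, out)
      got <- if (h$dropped_reason == "none") {
        if (h$allele_flipped) "flip" else "keep"
      } else {
        h$dropped_reason
      }
      expect_equal(got, expected,
                   label = sprintf("%s/%s vs %s/%s -> %s",
                                   ea_oa[1], ea_oa[2], tea, toa, got))
    }
  }
})

test_that("eaf_infer aligns unambiguous palindromes and drops ambiguous ones", {
  exp <- make_stats(c("rs1", "rs2"), c("A", "A"), c("T", "T"),
                    beta = 0.1, se = 0.02, eaf = c(0.2, 0.5))
  out <- make_stats(c("rs1", "rs2"), c("A", "A"), c("T", "T"),
                    beta = 0.05, se = 0.03, eaf = c(0.75, 0.5))
  h <- harmonize(exp, out, palindrome_policy = "eaf_infer")
  r1 <- h[h$rsid == "rs1", ]
  expect_equal(r1$dropped_reason, "none")
  expect_equal(r1$beta_out, -0.05)  # frequencies on opposite sides of 0.5
  expect_true(r1$allele_flipped)
  expect_equal(h$dropped_reason[h$rsid == "rs2"], "palindromic")
})

test_that("harmonization accounts for every exposure rsid exactly once", {
  exp <- make_stats(c("rs1", "rs2", "rs3", "rs4"),
                    c("A", "A", "A", "C"), c("G", "T", "G", "G"),
                    beta = 0.1, se = 0.02)
  out <- make_stats(c("rs1", "rs2", "rs3"), c("A", "A", "C"),
                    c("G", "T", "A"), beta = 0.05, se = 0.03)
  h <- harmonize(exp, out)
  expect_setequal(h$rsid, exp$data$rsid)
  expect_equal(anyDuplicated(h$rsid), 0)
  expect_equal(h$dropped_reason[h$rsid == "rs3"], "allele_mismatch")
  expect_equal(h$dropped_reason[h$rsid == "rs4"], "missing_in_outcome")
  # retained + dropped-with-reason covers the rsid intersection
  inter <- intersect(exp$data$rsid, out$data$rsid)
  hi <- h[h$rsid %in% inter, ]
  expect_equal(sum(hi$dropped_reason == "none") +
                 sum(hi$dropped_reason != "none"), length(inter))
})

test_that("harmonization is an involution under allele swap with negation", {
  set.seed(42)
  n <- 12
  bases <- list(c("A", "G"), c("C", "T"), c("G", "T"), c("A", "C"))
  pick <- sample(4, n, replace = TRUE)
  ea <- vapply(pick, function(i) bases[[i]][1], character(1))
  oa <- vapply(pick, function(i) bases[[i]][2], character(1))
  rs <- sprintf("rs%02d", 1:n)
  exp <- make_stats(rs, ea, oa, beta = rnorm(n), se = 0.02, eaf = 0.25,
                    pvalue = 1e-4)
  out <- make_stats(rs, ea, oa, beta = rnorm(n), se = 0.03, eaf = 0.25,
                    pvalue = 1e-4)
  swapped <- make_stats(rs, oa, ea, beta = -out$data$beta, se = 0.03,
                        eaf = 0.75, pvalue = 1e-4)
  r1 <- retained(harmonize(exp, out))
  r2 <- retained(harmonize(exp, swapped))
  expect_equal(r2$beta_out, r1$beta_out)
  expect_equal(r2$rsid, r1$rsid)
})

test_that("empty rsid overlap raises an error naming both traits", {
  exp <- make_stats("rs1", "A", "G", beta = 0.1, se = 0.02,
                    trait_id = "flora")
  out <- make_stats("rs2", "A", "G", beta = 0.1, se = 0.02,
                    trait_id = "disease")
  expect_error(harmonize(exp, out), "flora.*disease",
               class = "mr_empty_overlap_error")
})

test_that("result tables round-trip through TSV and JSON to 12 digits", {
  est <- do.call(rbind, lapply(1:5, function(i) {
    mr_wald_ratio(0.1 * i + 1 / 3, 0.01, 0.02 * i + 1 / 7, 0.005)
  }))
  for (fmt in c("tsv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_results(est, path, format = fmt)
    back <- read_results(path, format = fmt)
    expect_equal(names(back), names(est))
    for (col in c("beta", "se", "pvalue", "or")) {
      expect_equal(back[[col]], est[[col]], tolerance = 1e-12)
    }
  }
})

test_that("an empty collection writes a header-only TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  empty <- mr_wald_ratio(0.5, 0.05, 0.1, 0.02)[0, ]
  write_results(empty, path, format = "tsv")
  lines <- readLines(path)
  expect_length(lines, 1)
  back <- read_results(path, format = "tsv")
  expect_equal(nrow(back), 0)
})

test_that("LD matrices validate and round-trip through TSV", {
  r2 <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("rs1", "rs2"),
                                                     c("rs1", "rs2")))
  ld <- ld_matrix(r2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(ld, path)
  back <- read_ld_matrix(path)
  expect_equal(back$r2, ld$r2)
  expect_error(ld_matrix(matrix(c(1, 2, 2, 1), 2,
                                dimnames = list(c("a", "b"), c("a", "b")))),
               class = "mr_config_error")
})
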