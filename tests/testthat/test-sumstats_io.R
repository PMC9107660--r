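test_that("read_sumstats reads well-formed files and derives z", {
  df <- toy_sumstats_df()
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("SNP", "CHR", "BP", "A1", "A2", "BETA", "SE", "N"))
  s <- read_sumstats(path)
  expect_s3_class(s, "sumstats")
  expect_equal(nrow(s), 3L)
  # z absent from the file: derived as beta/se row by row
  expect_equal(s$z, df$beta / df$se)
  # missing pval recomputed from |z| under the two-sided normal
  expect_equal(s$pval, 2 * pnorm(-abs(df$beta / df$se)))

  # missing mandatory column is a configuration error
  write.table(df[, -6], path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = c("SNP", "CHR", "BP", "A1", "A2", "SE", "N"))
  expect_error(read_sumstats(path), "mandatory column")
})

test_that("rows with non-positive se are dropped with a message", {
  df <- toy_sumstats_df()
  df$se[2] <- 0
  expect_message(s <- sumstats(df), "dropping 1")
  expect_equal(s$rsid, c("rs1", "rs3"))
})

test_that("write/read round trip preserves fields to 1e-12", {
  df <- toy_sumstats_df()
  df$eaf <- c(0.21, 0.47, 0.83)
  s <- sumstats(df, trait_label = "t1")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(s, path)
  s2 <- read_sumstats(path, trait_label = "t1")
  for (col in c("beta", "se", "pval", "z", "eaf", "n")) {
    expect_equal(s2[[col]], s[[col]], tolerance = 1e-12)
  }
  expect_identical(s2$rsid, s$rsid)
})

test_that("qc_sumstats drops non-rs labels and all duplicate copies, idempotently", {
  df <- rbind(toy_sumstats_df(),
              data.frame(rsid = c("chr7:123", "rs1"), chrom = c(7L, 1L),
                         pos = c(123L, 1001L), a1 = c("A", "T"), a2 = c("C", "C"),
                         beta = c(0.01, 0.2), se = c(0.01, 0.05),
                         n = c(10000, 10000)))
  s <- sumstats(df)
  q <- qc_sumstats(s)
  # rs1 duplicated -> both copies removed; chr7:123 has no rs label
  expect_setequal(q$rsid, c("rs2", "rs3"))
  rep <- attr(q, "qc_report")
  expect_equal(unname(rep["no_rs_label"]), 1)
  expect_equal(unname(rep["duplicated"]), 2)
  # idempotence (same records; the second QC report is all-clean)
  q2 <- qc_sumstats(q)
  expect_equal(as.data.frame(q2), as.data.frame(q), ignore_attr = TRUE)
  expect_equal(unname(attr(q2, "qc_report")[c("no_rs_label", "duplicated")]),
               c(0, 0))
  # all rows removed is an input error
  bad <- sumstats(within(toy_sumstats_df(), rsid <- paste0("x", 1:3)))
  expect_error(qc_sumstats(bad), "all rows removed")
})

test_that("exclude_region removes the window, is idempotent, no-ops off-chromosome", {
  df <- toy_sumstats_df()
  df$chrom <- c(6L, 6L, 6L)
  df$pos <- c(30e6, 40e6, 24e6)
  s <- sumstats(df)
  e <- exclude_region(s, 6, 25e6, 34e6) # default MHC-style window
  expect_setequal(e$rsid, c("rs2", "rs3"))
  expect_equal(as.data.frame(exclude_region(e, 6, 25e6, 34e6)), as.data.frame(e))
  # window on another chromosome leaves everything
  expect_equal(nrow(exclude_region(s, 7, 25e6, 34e6)), 3L)
})

test_that("harmonize_pair aligns alleles, flips swapped effects, drops palindromes", {
  e <- sumstats(data.frame(
    rsid = c("rs1", "rs2", "rs3", "rs4"), chrom = 1L,
    pos = c(1e3, 2e3, 3e3, 4e3),
    a1 = c("G", "A", "G", "C"), a2 = c("T", "T", "T", "A"),
    beta = c(0.10, 0.10, 0.05, 0.07), se = 0.01, n = 1e4
  ))
  o <- sumstats(data.frame(
    rsid = c("rs1", "rs2", "rs3", "rs4"), chrom = 1L,
    pos = c(1e3, 2e3, 3e3, 4e3),
    a1 = c("T", "A", "G", "C"), a2 = c("G", "T", "C", "A"),
    beta = c(0.05, 0.04, 0.03, 0.02), se = 0.01, n = 1e4
  ))
  h <- harmonize_pair(e, o)
  # rs2 palindromic (A/T) removed; rs3 irreconcilable (G/T vs G/C) removed
  expect_setequal(h$exposure$rsid, c("rs1", "rs4"))
  # rs1 alleles swapped in the outcome: beta sign-flipped and aligned
  i <- which(h$outcome$rsid == "rs1")
  expect_equal(h$outcome$beta[i], -0.05)
  expect_equal(h$outcome$a1[i], "G")
  # swapping the argument order keeps the SNP set with reciprocal alignment:
  # the exposure's rs1 effect is now flipped onto the outcome's strand
  h2 <- harmonize_pair(o, e)
  expect_setequal(h2$exposure$rsid, h$exposure$rsid)
  expect_equal(h2$outcome$beta[h2$outcome$rsid == "rs1"], -0.10)
})
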