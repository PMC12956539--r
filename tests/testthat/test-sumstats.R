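test_that("well-formed TSV parses into typed records", {
  assoc <- make_assoc(c("rs1", "rs2", "rs3"), beta = c(0.2, -0.1, 0.05),
                      se = 0.04)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(assoc, path)
  out <- read_sumstats(path, role = "outcome")
  expect_equal(nrow(out), 3L)
  expect_equal(out$variant_id, c("rs1", "rs2", "rs3"))
  expect_equal(out$beta, signif(assoc$beta, 6))
})

test_that("row-level violations are collected with line numbers", {
  assoc <- make_assoc(c("rs1", "rs2", "rs3"), beta = c(0.2, 0.1, 0.3),
                      se = 0.04)
  assoc$se[2] <- 0
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(assoc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_sumstats(path, role = "outcome"),
               "line 3.*nonpositive SE")
  assoc$se[2] <- 0.04
  assoc$pvalue[3] <- 1.5
  utils::write.table(assoc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_sumstats(path, role = "outcome"),
               "p-value outside")
})

test_that("missing required columns are a format error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(variant_id = "rs1", beta = 0.1), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_sumstats(path, role = "outcome"), "missing required")
})

test_that("write/read round trip is lossless at 6 significant digits", {
  set.seed(11)
  assoc <- make_assoc(sprintf("rs%d", 1:8), beta = rnorm(8, 0, 0.3),
                      se = 0.0123456789, eaf = runif(8))
  exp <- exposure_dataset("GENE1", "CD4_NC", assoc)
  path <- withr::local_tempfile(fileext = ".tsv.gz")
  write_sumstats(exp, path)
  back <- read_sumstats(path, role = "exposure")
  expect_length(back, 1L)
  ds <- back[[1]]
  expect_equal(ds$gene, "GENE1")
  expect_equal(ds$cell_type, "CD4_NC")
  expect_equal(ds$associations$beta, signif(assoc$beta, 6))
  expect_equal(ds$associations$eaf, signif(assoc$eaf, 6))
  # a second round trip changes nothing further
  path2 <- withr::local_tempfile(fileext = ".tsv.gz")
  write_sumstats(ds, path2)
  back2 <- read_sumstats(path2, role = "exposure")[[1]]
  expect_equal(back2$associations, ds$associations)
})

test_that("column-name mapping resolves non-standard headers", {
  assoc <- make_assoc("rs1", beta = 0.2, se = 0.04)
  names(assoc)[names(assoc) == "variant_id"] <- "SNP"
  names(assoc)[names(assoc) == "pvalue"] <- "P"
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(assoc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out <- read_sumstats(path, role = "outcome",
                       col_map = c(variant_id = "SNP", pvalue = "P"))
  expect_equal(out$variant_id, "rs1")
})

test_that("swapped outcome alleles are aligned by negating beta", {
  exp <- exposure_dataset("G1", "NK", make_assoc("rs1", 0.5, 0.05,
                                                 effect_allele = "A",
                                                 other_allele = "G"))
  out <- make_assoc("rs1", 0.2, 0.02, effect_allele = "G",
                    other_allele = "A", eaf = 0.7)
  h <- harmonize(exp, out)
  expect_equal(nrow(h$data), 1L)
  expect_equal(h$data$beta_out, -0.2)
  expect_equal(h$data$eaf_out, 0.3)
})

test_that("palindromic variants follow the configured policy", {
  exp <- exposure_dataset("G1", "NK", make_assoc("rs1", 0.5, 0.05,
                                                 effect_allele = "A",
                                                 other_allele = "T",
                                                 eaf = 0.50))
  out <- make_assoc("rs1", 0.2, 0.02, effect_allele = "A",
                    other_allele = "T", eaf = 0.1)
  # drop policy: always dropped
  h <- harmonize(exp, out, palindrome_policy = "drop")
  expect_equal(nrow(h$data), 0L)
  expect_equal(h$dropped$reason, "ambiguous palindrome")
  # freq policy but exposure eaf inside the ambiguity band: still dropped
  h <- harmonize(exp, out, palindrome_policy = "freq", freq_tolerance = 0.08)
  expect_equal(h$dropped$reason, "ambiguous palindrome")
  # freq policy with informative frequencies: discordant -> strand flip
  exp2 <- exposure_dataset("G1", "NK", make_assoc("rs1", 0.5, 0.05,
                                                  effect_allele = "A",
                                                  other_allele = "T",
                                                  eaf = 0.9))
  h2 <- harmonize(exp2, out, palindrome_policy = "freq",
                  freq_tolerance = 0.08)
  expect_equal(nrow(h2$data), 1L)
  expect_equal(h2$data$beta_out, -0.2)
  expect_equal(h2$data$eaf_out, 0.9)
})

test_that("irreconcilable alleles are dropped with a reason", {
  exp <- exposure_dataset("G1", "NK", make_assoc("rs1", 0.5, 0.05,
                                                 effect_allele = "A",
                                                 other_allele = "G"))
  out <- make_assoc("rs1", 0.2, 0.02, effect_allele = "C",
                    other_allele = "A")
  h <- harmonize(exp, out)
  expect_equal(nrow(h$data), 0L)
  expect_equal(h$dropped$reason, "allele mismatch")
})

test_that("zero overlap raises an empty-overlap error", {
  exp <- exposure_dataset("G1", "NK", make_assoc("rs1", 0.5, 0.05))
  out <- make_assoc("rs99", 0.2, 0.02)
  expect_error(harmonize(exp, out), "empty overlap")
})

test_that("harmonization is idempotent on an aligned pair", {
  set.seed(21)
  exp <- exposure_dataset("G1", "NK",
                          make_assoc(sprintf("rs%d", 1:5),
                                     beta = rnorm(5), se = 0.05,
                                     effect_allele = "A",
                                     other_allele = "G", eaf = 0.25))
  out <- make_assoc(sprintf("rs%d", 1:5), beta = rnorm(5), se = 0.02,
                    effect_allele = "A", other_allele = "G", eaf = 0.25)
  h1 <- harmonize(exp, out)
  # feed the harmonized orientation back through as if re-read
  out2 <- out
  out2$beta <- h1$data$beta_out
  out2$eaf <- h1$data$eaf_out
  h2 <- harmonize(exp, out2)
  expect_equal(h2$data, h1$data)
  expect_equal(nrow(h2$dropped), 0L)
})

test_that("harmonization is invariant to outcome allele orientation", {
  set.seed(22)
  ids <- sprintf("rs%d", 1:6)
  exp <- exposure_dataset("G1", "NK",
                          make_assoc(ids, beta = rnorm(6), se = 0.05,
                                     effect_allele = "A",
                                     other_allele = "G", eaf = 0.25))
  out <- make_assoc(ids, beta = rnorm(6), se = 0.02, effect_allele = "A",
                    other_allele = "G", eaf = 0.2)
  flipped <- out
  flipped$effect_allele <- out$other_allele
  flipped$other_allele <- out$effect_allele
  flipped$beta <- -out$beta
  flipped$eaf <- 1 - out$eaf
  h1 <- harmonize(exp, out)
  h2 <- harmonize(exp, flipped)
  expect_equal(h2$data, h1$data)
})

test_that("harmonized output and dropped audit are written to disk", {
  exp <- exposure_dataset("G1", "NK",
                          make_assoc(c("rs1", "rs2"), c(0.5, 0.3), 0.05))
  out <- make_assoc(c("rs1", "rs2"), c(0.2, 0.1), 0.02,
                    effect_allele = c("A", "C"), other_allele = c("G", "A"))
  h <- harmonize(exp, out)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_harmonized(h, path)
  written <- utils::read.delim(path)
  expect_equal(nrow(written), 1L)
  audit <- utils::read.delim(paste0(sub("\\.tsv$", "", path),
                                    ".dropped.tsv"))
  expect_equal(audit$reason, "allele mismatch")
})
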