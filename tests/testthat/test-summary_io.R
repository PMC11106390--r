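test_that("reading a valid delimited table parses all rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  d <- rbind(variant_row("rs1"), variant_row("rs2", beta = -0.2),
             variant_row("rs3", eaf = 0.8))
  names(d) <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P", "N")
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_summary_table(path, trait_name = "demo")
  expect_s3_class(tab, "summary_stats")
  expect_equal(n_variants(tab), 3)
  expect_true(all(tab$tally == 0))

  # comma-separated variant of the same content is auto-detected
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.table(d, path2, sep = ",", quote = FALSE, row.names = FALSE)
  expect_equal(read_summary_table(path2)$data, tab$data)
})

test_that("invalid rows are dropped and tallied; duplicates keep first", {
  tab <- make_table(list(
    variant_row("rs1", beta = 0.5),
    variant_row("rs1", beta = 0.9),     # duplicate, second occurrence
    variant_row("rs2", se = 0),          # invalid se
    variant_row("rs3", pval = 0),        # invalid p
    variant_row("rs4", eaf = 1.2),       # invalid eaf
    variant_row("rs5", effect_allele = "A", other_allele = "A")
  ))
  expect_equal(n_variants(tab), 1)
  expect_equal(tab$data$beta, 0.5)  # first-wins
  expect_equal(unname(tab$tally[c("duplicate", "invalid_se", "invalid_pval",
                                  "invalid_eaf", "invalid_alleles")]),
               c(1L, 1L, 1L, 1L, 1L))
})

test_that("missing mandatory columns and empty files are hard errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("SNP\tCHR\tPOS", path)
  expect_error(read_summary_table(path), "missing mandatory column")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), path2)
  expect_error(read_summary_table(path2), "empty")
})

test_that("harmonization aligns swapped, complemented and matching alleles", {
  ex <- make_table(list(
    variant_row("rs1", effect_allele = "A", other_allele = "G", beta = 0.10),
    variant_row("rs2", effect_allele = "C", other_allele = "T", beta = 0.20),
    variant_row("rs3", effect_allele = "A", other_allele = "G", beta = 0.30),
    variant_row("rs4", effect_allele = "A", other_allele = "G", beta = 0.40)
  ))
  ou <- make_table(list(
    variant_row("rs1", effect_allele = "G", other_allele = "A", beta = 0.05),
    variant_row("rs2", effect_allele = "C", other_allele = "T", beta = 0.07),
    variant_row("rs3", effect_allele = "T", other_allele = "C", beta = 0.09),  # strand complement
    variant_row("rs4", effect_allele = "A", other_allele = "C", beta = 0.11)   # irreconcilable
  ), trait_type = "binary")
  h <- harmonize(ex, ou)
  expect_equal(h$by[h$snp_id == "rs1"], -0.05)  # swapped -> sign inverted
  expect_true(h$flipped[h$snp_id == "rs1"])
  expect_equal(h$eaf_outcome[h$snp_id == "rs1"], 0.7)
  expect_equal(h$by[h$snp_id == "rs2"], 0.07)   # identical orientation
  expect_false(h$flipped[h$snp_id == "rs2"])
  expect_equal(h$by[h$snp_id == "rs3"], 0.09)   # complement, same orientation
  expect_false(h$kept[h$snp_id == "rs4"])
  expect_equal(h$drop_reason[h$snp_id == "rs4"], "allele_mismatch")
})

test_that("palindromic variants resolve by frequency or drop as ambiguous", {
  ex <- make_table(list(
    variant_row("rs1", effect_allele = "A", other_allele = "T", eaf = 0.50),
    variant_row("rs2", effect_allele = "A", other_allele = "T", eaf = 0.10),
    variant_row("rs3", effect_allele = "C", other_allele = "G", eaf = 0.20),
    variant_row("rs4", effect_allele = "A", other_allele = "T", eaf = NA)
  ))
  ou <- make_table(list(
    variant_row("rs1", effect_allele = "A", other_allele = "T", eaf = 0.50),
    variant_row("rs2", effect_allele = "T", other_allele = "A", eaf = 0.88, beta = 0.04),
    variant_row("rs3", effect_allele = "C", other_allele = "G", eaf = 0.22, beta = 0.06),
    variant_row("rs4", effect_allele = "A", other_allele = "T", eaf = 0.10)
  ), trait_type = "binary")
  h <- harmonize(ex, ou)
  expect_false(h$kept[h$snp_id == "rs1"])
  expect_equal(h$drop_reason[h$snp_id == "rs1"], "ambiguous_palindrome")
  # rs2: frequencies disagree in sign -> flipped
  expect_true(h$kept[h$snp_id == "rs2"] && h$flipped[h$snp_id == "rs2"])
  expect_equal(h$by[h$snp_id == "rs2"], -0.04)
  # rs3: frequencies agree -> kept as-is
  expect_true(h$kept[h$snp_id == "rs3"] && !h$flipped[h$snp_id == "rs3"])
  expect_false(h$kept[h$snp_id == "rs4"])
  expect_equal(h$drop_reason[h$snp_id == "rs4"], "missing_eaf_palindromic")
  expect_true(all(h$palindromic))
})

test_that("harmonization is idempotent and sign-invariant, counts conserved", {
  set.seed(11)
  rows_ex <- lapply(1:12, function(i) {
    al <- list(c("A", "G"), c("C", "T"), c("A", "T"))[[1 + i %% 3]]
    variant_row(sprintf("rs%d", i), effect_allele = al[1],
                other_allele = al[2], eaf = runif(1, 0.05, 0.4),
                beta = rnorm(1, 0, 0.1))
  })
  rows_ou <- lapply(1:12, function(i) {
    r <- rows_ex[[i]]
    if (i %% 2 == 0) {  # swap allele order and flip effect
      tmp <- r$effect_allele
      r$effect_allele <- r$other_allele; r$other_allele <- tmp
      r$beta <- -rnorm(1, 0, 0.05); r$eaf <- 1 - r$eaf
    } else {
      r$beta <- rnorm(1, 0, 0.05)
    }
    r
  })
  ex <- make_table(rows_ex, "ex")
  ou <- make_table(rows_ou, "ou", "binary")
  h1 <- harmonize(ex, ou)
  # count conservation
  expect_equal(sum(h1$kept) + sum(!h1$kept), length(intersect(ex$data$snp_id, ou$data$snp_id)))

  # idempotence: rebuild the outcome from the aligned output; nothing changes
  k <- kept_instruments(h1)
  ou2_rows <- lapply(seq_len(nrow(k)), function(i) {
    exr <- ex$data[ex$data$snp_id == k$snp_id[i], ]
    variant_row(k$snp_id[i], effect_allele = exr$effect_allele,
                other_allele = exr$other_allele, eaf = k$eaf_outcome[i],
                beta = k$by[i], se = k$sy[i], n = k$ny[i])
  })
  ex_k <- ex; ex_k$data <- ex$data[ex$data$snp_id %in% k$snp_id, ]
  h2 <- harmonize(ex_k, make_table(ou2_rows, "ou2", "binary"))
  expect_true(all(h2$kept))
  expect_false(any(h2$flipped))
  expect_equal(h2$by[match(k$snp_id, h2$snp_id)], k$by)

  # sign invariance: flipping outcome alleles AND beta sign changes nothing
  ou3_rows <- lapply(rows_ou, function(r) {
    tmp <- r$effect_allele
    r$effect_allele <- r$other_allele; r$other_allele <- tmp
    r$beta <- -r$beta; r$eaf <- 1 - r$eaf
    r
  })
  h3 <- harmonize(ex, make_table(ou3_rows, "ou3", "binary"))
  expect_equal(h3$kept, h1$kept)
  expect_equal(h3$by, h1$by)
  expect_equal(h3$eaf_outcome, h1$eaf_outcome)
})

test_that("results tables round-trip through delimited text", {
  rows <- data.frame(exposure = "taxonA", outcome = "HL",
                     method = "ivw_fixed", n_snp = 12L,
                     beta = 0.123456789, se = 0.0456789123,
                     or = exp(0.123456789), ci_low = 1.01, ci_high = 1.24,
                     pval = 3.2e-5, stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results_table(rows, path)
  back <- read_results_table(path)
  expect_equal(nrow(back), 1)
  for (col in c("beta", "se", "or", "pval")) {
    expect_equal(signif(back[[col]], 6), signif(rows[[col]], 6))
  }
  # empty rows -> header-only file
  write_results_table(rows[0, ], path)
  expect_length(readLines(path), 1)
  expect_error(write_results_table(rows, file.path(tempdir(), "nope", "x", "y.tsv")),
               "cannot open")
})
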