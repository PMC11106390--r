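test_that("p-value thresholding is strict and order-preserving", {
  tab <- make_table(list(
    variant_row("rs1", pval = 1e-6),
    variant_row("rs2", pval = 1e-4),
    variant_row("rs3", pval = 1e-5)   # exactly at the threshold
  ))
  out <- threshold_select(tab, 1e-5)
  expect_equal(out$data$snp_id, "rs1")
})

test_that("thresholding an empty table yields an empty table", {
  tab <- make_table(list(variant_row("rs1", pval = 0.5)))
  empty <- threshold_select(tab, 1e-5)
  expect_equal(n_variants(empty), 0)
  expect_equal(n_variants(threshold_select(empty, 1e-5)), 0)
})

test_that("clumping keeps the lead variant and respects the distance gate", {
  ld <- data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.5)
  near <- make_table(list(
    variant_row("rs1", pos = 1e6, pval = 1e-8),
    variant_row("rs2", pos = 1e6 + 5000, pval = 1e-6)
  ))
  out <- ld_clump(near, ld, clump_r2 = 0.001, clump_kb = 10000)
  expect_equal(out$data$snp_id, "rs1")

  # below the r2 cut: both kept
  ld2 <- data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.0005)
  expect_setequal(ld_clump(near, ld2)$data$snp_id, c("rs1", "rs2"))

  # outside the window: both kept even at r2 = 0.9
  far <- make_table(list(
    variant_row("rs1", pos = 1e6, pval = 1e-8),
    variant_row("rs2", pos = 1e6 + 20000 * 1000, pval = 1e-6)
  ))
  ld3 <- data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.9)
  expect_setequal(ld_clump(far, ld3)$data$snp_id, c("rs1", "rs2"))

  # missing position excluded with a warning
  nopos <- make_table(list(variant_row("rs1"), variant_row("rs2", pos = NA)))
  expect_warning(out <- ld_clump(nopos, NULL), "missing position")
  expect_equal(out$data$snp_id, "rs1")
})

test_that("clumping matches brute-force greedy enumeration and its contract", {
  for (seed in 1:25) {
    set.seed(seed)
    J <- sample(3:20, 1)
    d <- do.call(rbind, lapply(seq_len(J), function(i) {
      variant_row(sprintf("rs%02d", i),
                  chrom = as.character(sample(1:3, 1)),
                  pos = sample(seq(1e5, 5e7, by = 1e5), 1),
                  pval = 10^runif(1, -10, -5))
    }))
    prs <- t(combn(d$snp_id, 2))
    ld <- data.frame(snp_a = prs[, 1], snp_b = prs[, 2],
                     r2 = ifelse(runif(nrow(prs)) < 0.3,
                                 runif(nrow(prs), 0.001, 1), 0),
                     stringsAsFactors = FALSE)
    tab <- summary_stats(d, "x")
    got <- ld_clump(tab, ld, clump_r2 = 0.001, clump_kb = 10000)
    r2_of <- mrflow:::ld_lookup_fun(ld)
    expect_equal(sort(got$data$snp_id),
                 oracle_clump(d, r2_of, 0.001, 10000))
    # contract: no retained pair on the same chromosome, within the
    # window, at or above the r2 cut
    g <- got$data
    if (nrow(g) > 1) {
      for (i in 1:(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
        violating <- g$chrom[i] == g$chrom[j] &&
          abs(g$pos[i] - g$pos[j]) <= 1e7 &&
          r2_of(g$snp_id[i], g$snp_id[j]) >= 0.001
        expect_false(violating)
      }
    }
  }
})

test_that("variance explained and F-statistic match hand-evaluated values", {
  expect_equal(variance_explained(0, 5), 0)
  expect_equal(variance_explained(0.5, 1), 0.5)
  expect_equal(variance_explained(0.25, 0.2), 0.015, tolerance = 1e-12)
  expect_equal(variance_explained(0.25, 0.2), variance_explained(0.75, 0.2))
  expect_true(is.na(variance_explained(NA, 0.2)))
  expect_error(variance_explained(1.2, 0.1), "eaf")

  expect_equal(f_statistic(0, 100), 0)
  expect_equal(f_statistic(0.015, 1000), 0.015 * 998 / 0.985, tolerance = 1e-12)
  expect_equal(f_statistic(0.01, 18340), 0.01 * 18338 / 0.99, tolerance = 1e-12)
  expect_error(f_statistic(1, 100), "r2")
  # strict monotonicity in r2 and n
  r2s <- sort(runif(20, 0, 0.5))
  expect_true(all(diff(f_statistic(r2s, 1000)) > 0))
  expect_true(all(diff(f_statistic(0.01, c(100, 1000, 10000))) > 0))
})

test_that("instrument filtering removes confounders and weak instruments", {
  # eaf 0.3, n 10000: F < 10 iff beta^2 < ~ r2m/(0.42) with r2m = 10/10008
  tab <- make_table(list(
    variant_row("rs1", beta = 0.2),             # strong
    variant_row("rs2", beta = 0.04),            # weak (F ~ 6.7)
    variant_row("rs3", beta = 0.5),             # strong but confounder
    variant_row("rs4", beta = 0.2, eaf = NA)    # incomputable -> weak
  ))
  cfg <- selection_config(confounder_snps = "rs3")
  out <- filter_instruments(tab, cfg)
  expect_equal(out$table$data$snp_id, "rs1")
  m <- out$metrics
  expect_equal(m$reason[m$snp_id == "rs2"], "weak")
  expect_equal(m$reason[m$snp_id == "rs3"], "confounder")
  expect_equal(m$reason[m$snp_id == "rs4"], "weak")
  expect_true(m$f_stat[m$snp_id == "rs1"] > 10)

  # boundary: F just below 10 is removed
  b <- sqrt((10 / 10008) / (1 - 10 / 10008) / (2 * 0.3 * 0.7)) * 0.999
  tabb <- make_table(list(variant_row("rs9", beta = b)))
  expect_equal(n_variants(filter_instruments(tabb, cfg)$table), 0)

  # all pass -> identity
  strong <- make_table(list(variant_row("rs1", beta = 0.2),
                            variant_row("rs2", beta = 0.3)))
  expect_equal(filter_instruments(strong, cfg)$table$data, strong$data)
})

test_that("confounder and weak-instrument filters commute", {
  tab <- make_table(list(
    variant_row("rs1", beta = 0.2), variant_row("rs2", beta = 0.04),
    variant_row("rs3", beta = 0.5), variant_row("rs4", beta = 0.03)
  ))
  both <- filter_instruments(tab, selection_config(confounder_snps = "rs3"))
  # weak-first
  weak_first <- filter_instruments(tab, selection_config())$table
  then_conf <- weak_first$data[!weak_first$data$snp_id %in% "rs3", ]
  # confounder-first
  conf_first <- tab; conf_first$data <- tab$data[tab$data$snp_id != "rs3", ]
  then_weak <- filter_instruments(conf_first, selection_config())$table$data
  expect_equal(both$table$data$snp_id, then_conf$snp_id)
  expect_equal(both$table$data$snp_id, then_weak$snp_id)
})

test_that("Steiger filtering keeps exposure-to-outcome variants with a Fisher-z p", {
  h <- make_insts(bx = c(0.2, 0.1, 0.1), by = c(0.01, 0.1, 0.005),
                  eaf = c(0.3, 0.3, 0.3))
  st <- steiger_filter(h, exposure_n = 1000, outcome_n = 2000)
  m <- st$metrics
  # rs002 has r2_outcome == r2_exposure (same eaf, |beta|): strict rule excludes
  expect_equal(m$steiger_direction, c(TRUE, FALSE, TRUE))
  expect_equal(st$kept$snp_id, c("rs001", "rs003"))

  # oracle: hand Fisher-z computation for the first variant
  r2x <- 2 * 0.3 * 0.7 * 0.2^2
  r2y <- 2 * 0.3 * 0.7 * 0.01^2
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) / sqrt(1 / 997 + 1 / 1997)
  expect_equal(m$steiger_p[1], 2 * pnorm(-abs(z)), tolerance = 1e-12)

  # outcome eaf missing falls back to the exposure side
  h2 <- make_insts(bx = 0.2, by = 0.01)
  h2$eaf_outcome <- NA_real_
  st2 <- steiger_filter(h2)
  expect_equal(st2$metrics$r2_outcome, 2 * 0.3 * 0.7 * 0.01^2)
})
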