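#' Configuration for the synthetic two-sample GWAS generator
#'
#' Defines the generative model for a matched pair of exposure and
#' outcome summary-statistics tables with known ground truth. Defaults
#' mirror a microbiome-abundance exposure GWAS (n = 18,340) against a
#' large case-control lymphoma outcome GWAS (n = 325,496): per-variant
#' standard errors follow sampling theory on a standardized trait,
#' `se = 1 / sqrt(2 * eaf * (1 - eaf) * n)`, so the variance-explained
#' formula is exact on the synthetic data.
#'
#' @param theta True causal effect (log odds ratio per exposure unit).
#' @param j_snps Number of independent true instruments.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param eaf_range Uniform sampling interval for allele frequencies,
#'   within (0, 1).
#' @param bx_sd Spread of true exposure effects; effects are drawn as
#'   `|N(0, bx_sd)|` (the effect allele is reported as the
#'   exposure-increasing allele, the usual convention).
#' @param f_floor Instruments are redrawn until their expected
#'   F-statistic reaches this floor (default 30); set to 0 to allow weak
#'   instruments.
#' @param pleio_mean,pleio_sd Moments of the per-variant direct
#'   (pleiotropic) outcome effects: directional when `pleio_mean != 0`,
#'   balanced when only `pleio_sd > 0`.
#' @param pleio_fraction Fraction of instruments receiving a pleiotropic
#'   effect.
#' @param outlier_ids Indices (into the instrument list) of variants to
#'   turn into gross outliers.
#' @param outlier_shift Additive shift applied to the outcome effect of
#'   each outlier.
#' @param n_null_snps Background variants with no exposure association.
#' @param ld_blocks Optional list of `c(size, r2)` pairs; each block
#'   emits `size` co-located correlated variants (listed in the LD table
#'   at the given r-squared) to exercise clumping.
#' @param palindromic_fraction Fraction of instruments assigned A/T
#'   alleles (others are A/G).
#' @param se_x_scale,se_y_scale Multipliers on the sampling noise added
#'   to the observed effects (reported standard errors are unchanged);
#'   0 gives the noise-free limit in which every Wald ratio equals theta.
#' @param seed RNG seed.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(theta = 0, j_snps = 50, n_exposure = 18340,
                              n_outcome = 325496, eaf_range = c(0.1, 0.9),
                              bx_sd = 0.1, f_floor = 30,
                              pleio_mean = 0, pleio_sd = 0,
                              pleio_fraction = 0,
                              outlier_ids = integer(), outlier_shift = 0,
                              n_null_snps = 0, ld_blocks = NULL,
                              palindromic_fraction = 0,
                              se_x_scale = 1, se_y_scale = 1,
                              seed = 20240507) {
  if (!(length(eaf_range) == 2L && eaf_range[1] > 0 && eaf_range[2] < 1 &&
        eaf_range[1] <= eaf_range[2])) {
    stop("eaf_range must lie strictly inside (0, 1)")
  }
  stopifnot(j_snps >= 1, n_exposure > 2, n_outcome > 2,
            pleio_fraction >= 0, pleio_fraction <= 1,
            palindromic_fraction >= 0, palindromic_fraction <= 1,
            n_null_snps >= 0)
  structure(as.list(environment()), class = "simulation_config")
}

# Sampling-theory standard error on a standardized trait.
theoretical_se <- function(eaf, n) 1 / sqrt(2 * eaf * (1 - eaf) * n)

# Draw |N(0, sd)| truncated so the expected F-statistic reaches f_floor.
draw_strong_bx <- function(k, sd, eaf, n, f_floor) {
  bx <- abs(stats::rnorm(k, 0, sd))
  if (f_floor <= 0) return(bx)
  for (iter in 1:200) {
    r2 <- variance_explained(eaf, bx)
    f <- f_statistic(r2, n)
    weak <- f < f_floor
    if (!any(weak)) return(bx)
    bx[weak] <- abs(stats::rnorm(sum(weak), 0, sd))
  }
  # pathological configs (tiny bx_sd): pin the stragglers at the floor
  r2_min <- f_floor / (n - 2 + f_floor)
  weak <- f_statistic(variance_explained(eaf, bx), n) < f_floor
  bx[weak] <- sqrt(r2_min / (2 * eaf[weak] * (1 - eaf[weak]))) * 1.01
  bx
}

#' Simulate matched two-sample GWAS summary statistics
#'
#' Generates an exposure table, an outcome table, a pairwise LD table and
#' a ground-truth sidecar under the instrumental-variable model
#' `by_j = theta * bx_j + alpha_j + noise`: per-variant frequencies are
#' uniform on `eaf_range`, standard errors follow sampling theory,
#' observed effects add Gaussian sampling noise, a configurable subset of
#' instruments carries pleiotropic effects `alpha_j ~ N(pleio_mean,
#' pleio_sd)`, designated outliers have their outcome effect shifted, and
#' background null variants carry no exposure signal. Roughly half the
#' outcome records are emitted with swapped allele order (effect sign
#' inverted, frequency complemented) so harmonization is exercised
#' end-to-end; instruments are spaced more than 10 Mb apart so only
#' explicit LD blocks clump together.
#'
#' @param cfg A [simulation_config()].
#' @return List: `exposure` and `outcome` (`summary_stats`), `truth`
#'   (data frame: `snp_id`, `role`, `bx_true`, `alpha`, `is_outlier`;
#'   attribute `theta`), `ld` (data frame `snp_a`, `snp_b`, `r2`).
#' @export
simulate_two_sample <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  local_seed(cfg$seed, {
    J <- cfg$j_snps
    block_sizes <- vapply(cfg$ld_blocks %||% list(), function(b) as.integer(b[1]), integer(1))
    n_block <- sum(block_sizes)
    n_total <- J + n_block + cfg$n_null_snps
    snp_id <- sprintf("rs%06d", seq_len(n_total))
    role <- c(rep("instrument", J), rep("ld_block", n_block),
              rep("null", cfg$n_null_snps))

    eaf <- stats::runif(n_total, cfg$eaf_range[1], cfg$eaf_range[2])
    se_x <- theoretical_se(eaf, cfg$n_exposure)
    se_y <- theoretical_se(eaf, cfg$n_outcome)

    bx_true <- numeric(n_total)
    idx_inst <- seq_len(J)
    bx_true[idx_inst] <- draw_strong_bx(J, cfg$bx_sd, eaf[idx_inst],
                                        cfg$n_exposure, cfg$f_floor)
    # LD-block members share their block's true signal
    chrom <- character(n_total)
    pos <- numeric(n_total)
    chrom[idx_inst] <- as.character(((idx_inst - 1) %% 22) + 1)
    pos[idx_inst] <- 25e6 * (((idx_inst - 1) %/% 22) + 1)
    ld <- data.frame(snp_a = character(), snp_b = character(),
                     r2 = numeric(), stringsAsFactors = FALSE)
    if (n_block > 0) {
      at <- J
      for (b in seq_along(cfg$ld_blocks)) {
        size <- as.integer(cfg$ld_blocks[[b]][1])
        r2 <- as.numeric(cfg$ld_blocks[[b]][2])
        members <- at + seq_len(size)
        bx_true[members] <- draw_strong_bx(1, cfg$bx_sd, eaf[members][1],
                                           cfg$n_exposure, cfg$f_floor)
        chrom[members] <- paste0("B", b)
        pos[members] <- 1e6 + (seq_len(size) - 1) * 1e4
        prs <- utils::combn(members, 2)
        ld <- rbind(ld, data.frame(snp_a = snp_id[prs[1, ]],
                                   snp_b = snp_id[prs[2, ]], r2 = r2,
                                   stringsAsFactors = FALSE))
        at <- at + size
      }
    }
    if (cfg$n_null_snps > 0) {
      idx_null <- (J + n_block) + seq_len(cfg$n_null_snps)
      chrom[idx_null] <- as.character(((idx_null - 1) %% 22) + 1)
      pos[idx_null] <- 200e6 + 25e6 * (((idx_null - 1) %/% 22) + 1)
    }

    alpha <- numeric(n_total)
    n_pleio <- round(cfg$pleio_fraction * J)
    if (n_pleio > 0) {
      pleio_idx <- sample(idx_inst, n_pleio)
      alpha[pleio_idx] <- stats::rnorm(n_pleio, cfg$pleio_mean, cfg$pleio_sd)
    }
    is_outlier <- rep(FALSE, n_total)
    if (length(cfg$outlier_ids) > 0) {
      oi <- if (is.character(cfg$outlier_ids)) {
        match(cfg$outlier_ids, snp_id)
      } else as.integer(cfg$outlier_ids)
      is_outlier[oi] <- TRUE
    }

    bx_obs <- bx_true + cfg$se_x_scale * stats::rnorm(n_total) * se_x
    by_mean <- cfg$theta * bx_true + alpha
    by_obs <- by_mean + cfg$se_y_scale * stats::rnorm(n_total) * se_y
    by_obs[is_outlier] <- by_obs[is_outlier] + cfg$outlier_shift

    p_of <- function(b, s) pmax(2 * stats::pnorm(-abs(b / s)), 1e-300)

    n_palin <- round(cfg$palindromic_fraction * J)
    ea <- rep("A", n_total)
    oa <- rep("G", n_total)
    if (n_palin > 0) {
      palin_idx <- sample(idx_inst, n_palin)
      oa[palin_idx] <- "T"
    }

    exposure_df <- data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = ea, other_allele = oa, eaf = eaf,
      beta = bx_obs, se = se_x, pval = p_of(bx_obs, se_x),
      n = cfg$n_exposure, stringsAsFactors = FALSE
    )
    # emit half the outcome rows with swapped allele order so that
    # harmonization has real work to do
    swap <- stats::runif(n_total) < 0.5
    outcome_df <- data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = ifelse(swap, oa, ea),
      other_allele = ifelse(swap, ea, oa),
      eaf = ifelse(swap, 1 - eaf, eaf),
      beta = ifelse(swap, -by_obs, by_obs), se = se_y,
      pval = p_of(by_obs, se_y), n = cfg$n_outcome,
      stringsAsFactors = FALSE
    )

    truth <- data.frame(snp_id = snp_id, role = role, bx_true = bx_true,
                        alpha = alpha, is_outlier = is_outlier,
                        stringsAsFactors = FALSE)
    attr(truth, "theta") <- cfg$theta

    list(
      exposure = summary_stats(exposure_df, "synthetic_exposure",
                               "quantitative"),
      outcome = summary_stats(outcome_df, "synthetic_outcome", "binary"),
      truth = truth, ld = ld
    )
  })
}

#' Write a synthetic fixture directory
#'
#' Materializes one simulated dataset as plain-text files: exposure.tsv,
#' outcome.tsv, ld.tsv, confounders.txt (empty placeholder), truth.tsv
#' and config.yaml. Re-reading the tables with [read_summary_table()]
#' reproduces the in-memory objects; identical seeds produce identical
#' files.
#'
#' @param cfg A [simulation_config()].
#' @param directory Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(cfg, directory) {
  sim <- simulate_two_sample(cfg)
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  write_gwas <- function(tab, path) {
    d <- tab$data
    names(d) <- unname(default_column_map()[names(d)])
    utils::write.table(format(d, digits = 15, trim = TRUE, scientific = NA),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths <- file.path(directory, c("exposure.tsv", "outcome.tsv", "ld.tsv",
                                  "confounders.txt", "truth.tsv",
                                  "config.yaml"))
  write_gwas(sim$exposure, paths[1])
  write_gwas(sim$outcome, paths[2])
  utils::write.table(sim$ld, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(character(), paths[4])
  utils::write.table(format(sim$truth, digits = 15, trim = TRUE),
                     paths[5], sep = "\t", quote = FALSE, row.names = FALSE)
  cfg_out <- unclass(cfg)
  cfg_out$ld_blocks <- lapply(cfg_out$ld_blocks, as.numeric)
  yaml::write_yaml(cfg_out, paths[6])
  invisible(paths)
}
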