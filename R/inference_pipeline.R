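#' Per-taxonomic-level Bonferroni configuration
#'
#' Number of independent tests at each taxonomic rank, used to adjust the
#' significance threshold per level: phylum 9, class 15, order 20, family
#' 32, genus 119 tests, at a base alpha of 0.05.
#'
#' @param phylum,class,order,family,genus Test counts per rank.
#' @param alpha Base significance level.
#' @return List of class `bonferroni_config`.
#' @export
bonferroni_config <- function(phylum = 9, class = 15, order = 20,
                              family = 32, genus = 119, alpha = 0.05) {
  counts <- c(phylum = phylum, class = class, order = order,
              family = family, genus = genus)
  stopifnot(all(counts > 0), alpha > 0, alpha < 1)
  structure(list(counts = counts, alpha = alpha),
            class = "bonferroni_config")
}

#' Choose the primary causal estimator from the sensitivity diagnostics
#'
#' The fixed-effects IVW estimate is the principal result when neither
#' heterogeneity nor directional pleiotropy is detected. A significant
#' Egger intercept (directional pleiotropy) promotes MR-Egger to primary;
#' otherwise a significant Cochran's Q (heterogeneity) promotes the
#' weighted median (with random-effects IVW reported alongside).
#' Pleiotropy takes precedence when both are significant. With fewer than
#' three instruments the rule degenerates: random-effects IVW under
#' heterogeneity, otherwise fixed-effects IVW (and the Wald ratio when
#' only one instrument exists).
#'
#' @param sens A `sensitivity_report` (or any list with `q_p` and
#'   `egger_intercept_p`).
#' @param alpha Significance level for both diagnostics (default 0.05).
#' @param n_snp Instrument count; controls the degenerate branches.
#' @return One of `"wald_ratio"`, `"ivw_fixed"`, `"ivw_random"`,
#'   `"weighted_median"`, `"egger"`.
#' @export
select_primary_method <- function(sens, alpha = 0.05, n_snp = Inf) {
  if (n_snp == 1L) return("wald_ratio")
  q_sig <- !is.na(sens$q_p) && sens$q_p < alpha
  i_sig <- !is.na(sens$egger_intercept_p) && sens$egger_intercept_p < alpha
  if (n_snp < 3L) {
    return(if (q_sig) "ivw_random" else "ivw_fixed")
  }
  if (i_sig) return("egger")
  if (q_sig) return("weighted_median")
  "ivw_fixed"
}

#' Classify the evidence strength of one association
#'
#' The primary p-value is compared with the level-specific Bonferroni
#' threshold `alpha / n_tests(level)`: below it the association is
#' `"significant"`; between it and the unadjusted alpha it is
#' `"suggestive"`; at or above alpha it is `"none"`.
#'
#' @param primary_p Primary method's p-value.
#' @param level Taxonomic rank: one of `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`.
#' @param cfg A [bonferroni_config()].
#' @return `"significant"`, `"suggestive"` or `"none"`.
#' @export
classify_evidence <- function(primary_p, level, cfg = bonferroni_config()) {
  level <- match.arg(level, names(cfg$counts))
  if (is.na(primary_p)) return("none")
  adj <- cfg$alpha / cfg$counts[[level]]
  if (primary_p < adj) "significant"
  else if (primary_p < cfg$alpha) "suggestive"
  else "none"
}

#' Declare a taxon-level exposure
#'
#' Attaches a taxonomic rank to an exposure summary-statistics table so
#' the batch pipeline can apply the rank-specific Bonferroni threshold.
#'
#' @param table A `summary_stats` object for the taxon's abundance GWAS.
#' @param level Taxonomic rank (`"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`).
#' @param taxon_name Optional display name; defaults to the table's trait
#'   name.
#' @return List of class `taxon_exposure`.
#' @export
taxon_exposure <- function(table, level, taxon_name = NULL) {
  level <- match.arg(level, c("phylum", "class", "order", "family", "genus"))
  stopifnot(inherits(table, "summary_stats"))
  structure(list(taxon_name = taxon_name %||% table$trait_name,
                 level = level, table = table),
            class = "taxon_exposure")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pipeline configuration
#'
#' All tunable parameters of the per-pair analysis in one object.
#'
#' @param selection A [selection_config()].
#' @param bonferroni A [bonferroni_config()].
#' @param k_sim MR-PRESSO replicates (default 1000).
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param alpha Significance level for diagnostics and the MR-PRESSO
#'   stopping rule.
#' @param ld Optional LD table (data frame `snp_a`, `snp_b`, `r2`).
#' @param steiger Apply the Steiger directionality filter (default TRUE;
#'   applied before MR-PRESSO).
#' @param seed Global seed; per-pair seeds are derived from it and the
#'   pair labels.
#' @return List of class `mr_config`.
#' @export
mr_config <- function(selection = selection_config(),
                      bonferroni = bonferroni_config(),
                      k_sim = 1000, n_boot = 1000, alpha = 0.05,
                      ld = NULL, steiger = TRUE, seed = 20240507) {
  structure(list(selection = selection, bonferroni = bonferroni,
                 k_sim = k_sim, n_boot = n_boot, alpha = alpha,
                 ld = ld, steiger = steiger, seed = seed),
            class = "mr_config")
}

#' Run the full two-sample MR analysis for one exposure-outcome pair
#'
#' Stages: p-value thresholding, LD clumping, confounder and
#' weak-instrument filtering, allele harmonization, Steiger
#' directionality filtering, recursive MR-PRESSO outlier removal, causal
#' estimation with every applicable method, sensitivity diagnostics,
#' primary-method selection and evidence classification. Per-stage
#' instrument counts and drop reasons are returned in `stage_counts`.
#'
#' @param exposure A [taxon_exposure()] (or a bare `summary_stats`, which
#'   is treated as genus level).
#' @param outcome A `summary_stats` object for the outcome GWAS.
#' @param cfg An [mr_config()].
#' @return List of class `pair_result`: `exposure`, `outcome`, `level`,
#'   `status` (`"ok"` or `"no_instruments"`), `estimates` (data frame),
#'   `sensitivity` (a `sensitivity_report`), `primary_method`,
#'   `primary_p`, `evidence`, `instruments` (final harmonized set),
#'   `stage_counts`.
#' @export
run_pair <- function(exposure, outcome, cfg = mr_config()) {
  if (inherits(exposure, "summary_stats")) {
    exposure <- taxon_exposure(exposure, "genus")
  }
  stopifnot(inherits(exposure, "taxon_exposure"),
            inherits(outcome, "summary_stats"))
  seed <- pair_seed(cfg$seed, exposure$taxon_name, outcome$trait_name)
  counts <- c(input = n_variants(exposure$table))

  tab <- threshold_select(exposure$table, cfg$selection$p_threshold)
  counts["after_threshold"] <- n_variants(tab)
  tab <- ld_clump(tab, cfg$ld, cfg$selection$clump_r2, cfg$selection$clump_kb)
  counts["after_clump"] <- n_variants(tab)
  fi <- filter_instruments(tab, cfg$selection)
  tab <- fi$table
  counts["after_strength_filter"] <- n_variants(tab)

  empty <- function() {
    structure(list(exposure = exposure$taxon_name,
                   outcome = outcome$trait_name, level = exposure$level,
                   status = "no_instruments", estimates = NULL,
                   sensitivity = NULL, primary_method = NA_character_,
                   primary_p = NA_real_, evidence = "none",
                   instruments = NULL, stage_counts = counts),
              class = "pair_result")
  }
  if (n_variants(tab) == 0L) return(empty())

  harm <- harmonize(tab, outcome, cfg$selection$palindrome_eaf_limit)
  insts <- kept_instruments(harm)
  counts["after_harmonize"] <- nrow(insts)
  if (nrow(insts) == 0L) return(empty())

  if (isTRUE(cfg$steiger)) {
    st <- steiger_filter(insts)
    insts <- st$kept
    counts["after_steiger"] <- nrow(insts)
    if (nrow(insts) == 0L) return(empty())
  }

  presso <- presso_recursive(insts, k_sim = cfg$k_sim, seed = seed,
                             alpha = cfg$alpha)
  insts <- presso$insts
  counts["after_presso"] <- nrow(insts)
  if (nrow(insts) == 0L) return(empty())

  estimates <- estimate_all(insts, n_boot = cfg$n_boot, seed = seed)
  sens <- sensitivity_report(insts, run_presso = FALSE)
  sens$presso_global_p <- presso$global_p
  sens$presso_outliers <- presso$removed
  sens$presso_estimate <- presso$estimate
  sens$presso_sd <- presso$sd
  sens$presso_p <- presso$p
  sens$presso_status <- presso$status

  J <- nrow(insts)
  primary <- select_primary_method(sens, alpha = cfg$alpha, n_snp = J)
  if (primary == "ivw_random" || (primary == "weighted_median" &&
                                  !is.na(sens$q_p) && sens$q_p < cfg$alpha)) {
    # heterogeneity: report random-effects IVW alongside
    if (J >= 2L && !"ivw_random" %in% estimates$method) {
      estimates <- rbind(estimates,
                         estimates_to_frame(list(ivw(insts, "multiplicative_random"))))
    }
  }
  primary_p <- estimates$pval[estimates$method == primary][1]
  evidence <- classify_evidence(primary_p, exposure$level, cfg$bonferroni)

  structure(list(exposure = exposure$taxon_name,
                 outcome = outcome$trait_name, level = exposure$level,
                 status = "ok", estimates = estimates, sensitivity = sens,
                 primary_method = primary, primary_p = primary_p,
                 evidence = evidence, instruments = insts,
                 stage_counts = counts),
            class = "pair_result")
}

#' @export
print.pair_result <- function(x, ...) {
  cat(sprintf("<pair_result> %s -> %s (%s): %s\n", x$exposure, x$outcome,
              x$level, x$status))
  if (x$status == "ok") {
    pr <- x$estimates[x$estimates$method == x$primary_method, ]
    cat(sprintf("  primary %s: OR %.3f [%.3f, %.3f], p=%.3g, nSNP=%d -> %s\n",
                x$primary_method, pr$or, pr$ci_low, pr$ci_high, pr$pval,
                pr$n_snp, x$evidence))
  }
  invisible(x)
}

#' Flatten one pair result into results-table rows
#'
#' One row per estimator, carrying the sensitivity columns alongside.
#'
#' @param pr A `pair_result`.
#' @return Data frame (0 rows for failed pairs).
#' @export
pair_result_rows <- function(pr) {
  if (pr$status != "ok") {
    return(data.frame(exposure = pr$exposure, outcome = pr$outcome,
                      level = pr$level, method = NA_character_,
                      n_snp = 0L, beta = NA_real_, se = NA_real_,
                      pval = NA_real_, or = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, primary = FALSE,
                      evidence = "none", q_value = NA_real_,
                      q_p = NA_real_, egger_intercept = NA_real_,
                      egger_intercept_p = NA_real_,
                      presso_global_p = NA_real_, presso_n_removed = 0L,
                      status = pr$status, stringsAsFactors = FALSE))
  }
  est <- pr$estimates
  s <- pr$sensitivity
  data.frame(exposure = pr$exposure, outcome = pr$outcome,
             level = pr$level, method = est$method, n_snp = est$n_snp,
             beta = est$beta, se = est$se, pval = est$pval, or = est$or,
             ci_low = est$ci_low, ci_high = est$ci_high,
             primary = est$method == pr$primary_method,
             evidence = ifelse(est$method == pr$primary_method,
                               pr$evidence, NA_character_),
             q_value = s$q_value, q_p = s$q_p,
             egger_intercept = s$egger_intercept,
             egger_intercept_p = s$egger_intercept_p,
             presso_global_p = s$presso_global_p,
             presso_n_removed = length(s$presso_outliers),
             status = pr$status, stringsAsFactors = FALSE)
}

#' Run a batch of exposures against a batch of outcomes
#'
#' One [run_pair()] per exposure-outcome combination; failures in a pair
#' are recorded and the batch continues. Optionally writes the results
#' table plus plot-ready scatter (per-instrument effects with fitted
#' lines) and leave-one-out tables to `output_dir`. Deterministic given
#' `cfg$seed`.
#'
#' @param exposures List of [taxon_exposure()] objects.
#' @param outcomes List of `summary_stats` outcome tables.
#' @param cfg An [mr_config()].
#' @param output_dir Optional directory for `results.tsv`, `scatter.tsv`,
#'   `loo.tsv`.
#' @return List: `pairs` (all `pair_result` objects), `results` (flat
#'   data frame), `scatter`, `loo`.
#' @export
run_batch <- function(exposures, outcomes, cfg = mr_config(),
                      output_dir = NULL) {
  stopifnot(length(exposures) >= 1L, length(outcomes) >= 1L)
  if (inherits(exposures, "taxon_exposure")) exposures <- list(exposures)
  if (inherits(outcomes, "summary_stats")) outcomes <- list(outcomes)
  pairs <- list()
  for (ex in exposures) {
    for (ou in outcomes) {
      pr <- tryCatch(run_pair(ex, ou, cfg), error = function(e) {
        structure(list(exposure = if (inherits(ex, "taxon_exposure")) ex$taxon_name else ex$trait_name,
                       outcome = ou$trait_name, level = NA_character_,
                       status = paste0("error: ", conditionMessage(e)),
                       estimates = NULL, sensitivity = NULL,
                       primary_method = NA_character_,
                       primary_p = NA_real_, evidence = "none",
                       instruments = NULL, stage_counts = c()),
                  class = "pair_result")
      })
      pairs[[length(pairs) + 1L]] <- pr
    }
  }
  results <- do.call(rbind, lapply(pairs, pair_result_rows))
  scatter <- do.call(rbind, lapply(pairs, function(pr) {
    if (pr$status != "ok" || is.null(pr$instruments)) return(NULL)
    h <- pr$instruments
    fits <- pr$estimates[, c("method", "beta", "egger_intercept")]
    data.frame(exposure = pr$exposure, outcome = pr$outcome,
               snp_id = h$snp_id, bx = h$bx, sx = h$sx, by = h$by,
               sy = h$sy,
               fitted = paste(sprintf("%s:slope=%.6g,intercept=%.6g",
                                      fits$method, fits$beta,
                                      ifelse(is.na(fits$egger_intercept), 0,
                                             fits$egger_intercept)),
                              collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  loo <- do.call(rbind, lapply(pairs, function(pr) {
    if (pr$status != "ok" || is.null(pr$sensitivity$loo)) return(NULL)
    cbind(data.frame(exposure = pr$exposure, outcome = pr$outcome,
                     stringsAsFactors = FALSE), pr$sensitivity$loo)
  }))
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_results_table(results, file.path(output_dir, "results.tsv"))
    if (!is.null(scatter)) {
      write_results_table(scatter, file.path(output_dir, "scatter.tsv"))
    }
    if (!is.null(loo)) {
      write_results_table(loo, file.path(output_dir, "loo.tsv"))
    }
  }
  list(pairs = pairs, results = results, scatter = scatter, loo = loo)
}
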