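#' Cochran's Q heterogeneity test
#'
#' Weighted sum of squared deviations of the per-instrument Wald ratios
#' from the fixed-effects IVW estimate, weights `bx^2 / sy^2`. Under
#' homogeneity Q is chi-squared with J - 1 degrees of freedom; a
#' significant Q indicates the instruments disagree about the causal
#' effect (heterogeneity, possibly from pleiotropy).
#'
#' @param insts Harmonized instruments (J >= 2 kept rows).
#' @return List with `q`, `df`, `p`.
#' @export
cochran_q <- function(insts) {
  h <- instrument_matrix(insts)
  J <- nrow(h)
  if (J < 2L) stop("Cochran's Q requires at least 2 instruments")
  if (any(h$bx == 0)) stop("Q undefined when any bx = 0")
  w <- h$bx^2 / h$sy^2
  ratio <- h$by / h$bx
  beta <- sum(w * ratio) / sum(w)
  q <- sum(w * (ratio - beta)^2)
  df <- J - 1L
  list(q = q, df = df, p = stats::pchisq(q, df = df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Re-exports the intercept fields of [mr_egger()]: a non-zero intercept
#' indicates that the instruments' mean direct (pleiotropic) effect on
#' the outcome differs from zero. Two-sided t-test with J - 2 degrees of
#' freedom.
#'
#' @param insts Harmonized instruments (J >= 3 kept rows).
#' @return List with `intercept`, `se`, `p`.
#' @export
egger_intercept_test <- function(insts) {
  e <- mr_egger(insts)
  list(intercept = e$intercept, se = e$intercept_se, p = e$intercept_p)
}

# Shared MR-PRESSO machinery: observed leave-one-out residual sum of
# squares plus its parametric null distribution, with per-instrument
# terms retained for the outlier test. Weights are 1/sy^2 and expected
# outcome effects come from the IVW estimate excluding each instrument,
# as in the original method.
presso_core <- function(h, k_sim, seed) {
  J <- nrow(h)
  wr <- h$bx^2 / h$sy^2
  ratio <- h$by / h$bx
  s1 <- sum(wr * ratio)
  s0 <- sum(wr)
  beta_loo <- (s1 - wr * ratio) / (s0 - wr)
  obs_terms <- (h$by - beta_loo * h$bx)^2 / h$sy^2
  rss_obs <- sum(obs_terms)

  sim <- local_seed(seed, {
    BX <- matrix(stats::rnorm(J * k_sim, h$bx, h$sx), J, k_sim)
    BY <- matrix(stats::rnorm(J * k_sim, beta_loo * h$bx, h$sy), J, k_sim)
    WR <- BX^2 / h$sy^2
    RATIO <- BY / BX
    WRR <- WR * RATIO
    S1 <- matrix(colSums(WRR), J, k_sim, byrow = TRUE)
    S0 <- matrix(colSums(WR), J, k_sim, byrow = TRUE)
    BL <- (S1 - WRR) / (S0 - WR)
    (BY - BL * BX)^2 / h$sy^2
  })
  rss_sim <- colSums(sim)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (k_sim + 1)
  outlier_p <- (1 + rowSums(sim >= obs_terms)) / (k_sim + 1)
  list(rss_obs = rss_obs, global_p = global_p,
       obs_terms = obs_terms, outlier_p = outlier_p)
}

#' MR-PRESSO global test
#'
#' Residual-sum-of-squares test for horizontal pleiotropy: the observed
#' statistic `sum((by_j - beta_(-j) * bx_j)^2 / sy_j^2)` (with
#' `beta_(-j)` the IVW estimate excluding instrument j) is compared
#' against `k_sim` parametric replicates drawn under the no-pleiotropy
#' model. The Monte-Carlo p-value uses the (1 + x) / (K + 1) convention,
#' so it is never exactly zero and is floored at 1 / (K + 1).
#'
#' @param insts Harmonized instruments (J >= 4 kept rows).
#' @param k_sim Number of null replicates (>= 100; default 1000).
#' @param seed RNG seed.
#' @return List with `rss_obs`, `p`, `k_sim`.
#' @export
presso_global <- function(insts, k_sim = 1000, seed = 20240507) {
  h <- instrument_matrix(insts)
  if (nrow(h) < 4L) {
    return(list(rss_obs = NA_real_, p = NA_real_, k_sim = k_sim,
                status = "not_evaluated"))
  }
  stopifnot(k_sim >= 100)
  core <- presso_core(h, k_sim, seed)
  list(rss_obs = core$rss_obs, p = core$global_p, k_sim = k_sim,
       status = "ok")
}

#' MR-PRESSO per-instrument outlier test
#'
#' Each instrument's observed weighted squared residual is compared
#' against its own simulated null distribution (the same replicates as
#' the global test). Significance is assessed after Bonferroni correction
#' across the J instruments.
#'
#' @inheritParams presso_global
#' @param alpha Family-wise significance level for the Bonferroni flag.
#' @return Data frame: `snp_id`, `obs_term`, `p`, `p_bonferroni`,
#'   `outlier` (logical).
#' @export
presso_outlier <- function(insts, k_sim = 1000, seed = 20240507, alpha = 0.05) {
  h <- instrument_matrix(insts)
  J <- nrow(h)
  if (J < 4L) stop("MR-PRESSO outlier test requires at least 4 instruments")
  core <- presso_core(h, k_sim, seed)
  p_bonf <- pmin(1, core$outlier_p * J)
  data.frame(snp_id = h$snp_id, obs_term = core$obs_terms,
             p = core$outlier_p, p_bonferroni = p_bonf,
             outlier = p_bonf < alpha, stringsAsFactors = FALSE)
}

#' Recursive MR-PRESSO outlier removal
#'
#' Runs the global test; while it is significant (p <= alpha), removes
#' the single instrument with the smallest outlier p-value (ties broken
#' by the larger weighted residual) and re-runs the global test on the
#' remainder, until the global p exceeds alpha or fewer than four
#' instruments remain (`status = "exhausted"`). Returns the
#' outlier-corrected IVW estimate on the final set.
#'
#' @inheritParams presso_global
#' @param alpha Stopping level for the global test (default 0.05).
#' @return List: `insts` (final instrument set), `removed` (ids in removal
#'   order), `trace` (data frame: step, snp_id removed, global p before
#'   removal, outlier p), `global_p` (final), `estimate`, `sd`, `p`
#'   (outlier-corrected IVW on the final set), `status`
#'   (`"ok"`, `"exhausted"`, or `"not_evaluated"`).
#' @export
presso_recursive <- function(insts, k_sim = 1000, seed = 20240507, alpha = 0.05) {
  h <- instrument_matrix(insts)
  trace <- data.frame(step = integer(), snp_id = character(),
                      global_p = numeric(), outlier_p = numeric(),
                      stringsAsFactors = FALSE)
  corrected_ivw <- function(hh) {
    if (nrow(hh) >= 2L) {
      e <- ivw(hh, "fixed")
      list(estimate = e$beta, sd = e$se, p = e$pval)
    } else if (nrow(hh) == 1L) {
      e <- wald_ratio(hh)
      list(estimate = e$beta, sd = e$se, p = e$pval)
    } else {
      list(estimate = NA_real_, sd = NA_real_, p = NA_real_)
    }
  }
  if (nrow(h) < 4L) {
    cc <- corrected_ivw(h)
    return(list(insts = h, removed = character(), trace = trace,
                global_p = NA_real_, estimate = cc$estimate, sd = cc$sd,
                p = cc$p, status = "not_evaluated"))
  }
  removed <- character()
  step <- 0L
  status <- "ok"
  repeat {
    step_seed <- (as.numeric(seed) + 1000003 * step) %% 2147483629
    core <- presso_core(h, k_sim, step_seed)
    if (core$global_p > alpha) break
    if (nrow(h) - 1L < 4L) {
      status <- "exhausted"
      break
    }
    ord <- order(core$outlier_p, -core$obs_terms)
    worst <- ord[1]
    trace <- rbind(trace, data.frame(step = step + 1L,
                                     snp_id = h$snp_id[worst],
                                     global_p = core$global_p,
                                     outlier_p = core$outlier_p[worst],
                                     stringsAsFactors = FALSE))
    removed <- c(removed, h$snp_id[worst])
    h <- h[-worst, , drop = FALSE]
    step <- step + 1L
  }
  cc <- corrected_ivw(h)
  rownames(h) <- NULL
  list(insts = h, removed = removed, trace = trace,
       global_p = core$global_p, estimate = cc$estimate, sd = cc$sd,
       p = cc$p, status = status)
}

#' Leave-one-out IVW analysis
#'
#' Re-estimates the fixed-effects IVW causal effect J times, each time
#' omitting one instrument, to flag instruments that disproportionately
#' drive the overall estimate.
#'
#' @param insts Harmonized instruments (J >= 3 kept rows).
#' @return Data frame keyed by the left-out id: `snp_id`, `beta`, `se`,
#'   `pval`, `or`, `ci_low`, `ci_high`.
#' @export
leave_one_out <- function(insts) {
  h <- instrument_matrix(insts)
  J <- nrow(h)
  if (J < 3L) stop("leave-one-out requires at least 3 instruments")
  out <- do.call(rbind, lapply(seq_len(J), function(j) {
    e <- ivw(h[-j, , drop = FALSE], "fixed")
    data.frame(snp_id = h$snp_id[j], beta = e$beta, se = e$se,
               pval = e$pval, or = e$or_, ci_low = e$ci_low,
               ci_high = e$ci_high, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Assemble the full sensitivity report for one instrument set
#'
#' Convenience wrapper computing Cochran's Q, the Egger intercept test,
#' the recursive MR-PRESSO diagnostics and the leave-one-out table, with
#' graceful degradation when too few instruments are available for a
#' given diagnostic (its fields are NA).
#'
#' @param insts Harmonized instruments.
#' @param k_sim MR-PRESSO replicates.
#' @param seed RNG seed for MR-PRESSO.
#' @param alpha Significance level for the recursive stopping rule.
#' @param run_presso Set `FALSE` to skip MR-PRESSO (e.g. when it has been
#'   run upstream of estimation).
#' @return List of class `sensitivity_report` with fields `q_value`,
#'   `q_df`, `q_p`, `egger_intercept`, `egger_intercept_se`,
#'   `egger_intercept_p`, `presso_global_p`, `presso_outliers`,
#'   `presso_estimate`, `presso_sd`, `presso_p`, `presso_status`, `loo`.
#' @export
sensitivity_report <- function(insts, k_sim = 1000, seed = 20240507,
                               alpha = 0.05, run_presso = TRUE) {
  h <- instrument_matrix(insts)
  J <- nrow(h)
  rep_ <- list(q_value = NA_real_, q_df = NA_integer_, q_p = NA_real_,
               egger_intercept = NA_real_, egger_intercept_se = NA_real_,
               egger_intercept_p = NA_real_,
               presso_global_p = NA_real_, presso_outliers = character(),
               presso_estimate = NA_real_, presso_sd = NA_real_,
               presso_p = NA_real_, presso_status = "not_evaluated",
               loo = NULL)
  if (J >= 2L) {
    q <- cochran_q(h)
    rep_$q_value <- q$q; rep_$q_df <- q$df; rep_$q_p <- q$p
  }
  if (J >= 3L) {
    e <- egger_intercept_test(h)
    rep_$egger_intercept <- e$intercept
    rep_$egger_intercept_se <- e$se
    rep_$egger_intercept_p <- e$p
    rep_$loo <- leave_one_out(h)
  }
  if (run_presso && J >= 4L) {
    pr <- presso_recursive(h, k_sim = k_sim, seed = seed, alpha = alpha)
    rep_$presso_global_p <- pr$global_p
    rep_$presso_outliers <- pr$removed
    rep_$presso_estimate <- pr$estimate
    rep_$presso_sd <- pr$sd
    rep_$presso_p <- pr$p
    rep_$presso_status <- pr$status
  }
  class(rep_) <- "sensitivity_report"
  rep_
}
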