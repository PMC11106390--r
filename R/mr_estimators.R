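#' @keywords internal
new_mr_estimate <- function(method, beta, se, pval, n_snp, extra = list()) {
  z <- stats::qnorm(0.975)
  structure(
    c(list(method = method, beta = beta, se = se, pval = pval,
           or_ = exp(beta),
           ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
           n_snp = n_snp),
      extra),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: beta=%.4g (se %.4g), OR=%.4g [%.4g, %.4g], p=%.3g, nSNP=%d\n",
              x$method, x$beta, x$se, x$or_, x$ci_low, x$ci_high,
              x$pval, x$n_snp))
  invisible(x)
}

# Pull (bx, sx, by, sy) from a harmonized data frame, kept rows only.
instrument_matrix <- function(insts) {
  h <- if (inherits(insts, "harmonized")) kept_instruments(insts) else insts
  stopifnot(all(c("bx", "sx", "by", "sy") %in% names(h)))
  h
}

#' Wald ratio causal estimate from a single instrument
#'
#' `beta = by / bx`, with the first-order standard error `sy / |bx|`
#' (uncertainty in the exposure association is ignored, the usual NOME
#' simplification). Two-sided normal p-value.
#'
#' @param inst One harmonized instrument (1-row data frame with `bx`,
#'   `by`, `sy`).
#' @return An `mr_estimate` with method `"wald_ratio"`.
#' @export
wald_ratio <- function(inst) {
  h <- instrument_matrix(inst)
  stopifnot(nrow(h) == 1L)
  if (h$bx == 0) stop("Wald ratio undefined for bx = 0")
  beta <- h$by / h$bx
  se <- h$sy / abs(h$bx)
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("wald_ratio", beta, se, p, 1L)
}

#' Inverse-variance-weighted causal estimate
#'
#' Combines per-instrument Wald ratios `by/bx` with weights
#' `bx^2 / sy^2` (the inverse first-order ratio variances). The fixed-
#' effects standard error is `sqrt(1 / sum(w))`; the multiplicative
#' random-effects model inflates it by `sqrt(Q / (J - 1))`, floored at 1,
#' where Q is Cochran's heterogeneity statistic. Two-sided normal p-value.
#'
#' @param insts Harmonized instruments (J >= 2 kept rows).
#' @param effects_model `"fixed"` or `"multiplicative_random"`.
#' @return An `mr_estimate` (method `"ivw_fixed"` or `"ivw_random"`) with
#'   `q`, `q_df`, `q_p` in the extra fields.
#' @export
ivw <- function(insts, effects_model = c("fixed", "multiplicative_random")) {
  effects_model <- match.arg(effects_model)
  h <- instrument_matrix(insts)
  J <- nrow(h)
  if (J < 2L) stop("IVW requires at least 2 instruments; use wald_ratio()")
  if (any(h$bx == 0)) stop("IVW undefined when any bx = 0")
  w <- h$bx^2 / h$sy^2
  ratio <- h$by / h$bx
  beta <- sum(w * ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- sum(w * (ratio - beta)^2)
  q_df <- J - 1L
  q_p <- stats::pchisq(q, df = q_df, lower.tail = FALSE)
  if (effects_model == "fixed") {
    se <- se_fixed
    method <- "ivw_fixed"
  } else {
    se <- se_fixed * max(1, sqrt(q / q_df))
    method <- "ivw_random"
  }
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate(method, beta, se, p, J,
                  extra = list(q = q, q_df = q_df, q_p = q_p))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome associations on the exposure
#' associations with an unconstrained intercept, weights `1 / sy^2`.
#' Instruments are first oriented so every exposure effect is positive
#' (pairs with `bx < 0` have both signs flipped). The slope estimates the
#' causal effect; a non-zero intercept indicates directional horizontal
#' pleiotropy. Standard errors are the fixed-effect (unit residual
#' variance) values inflated by the residual scale when it exceeds 1
#' (multiplicative random effects); p-values use a t-distribution with
#' J - 2 degrees of freedom.
#'
#' @param insts Harmonized instruments (J >= 3 kept rows).
#' @return An `mr_estimate` (method `"egger"`) with `intercept`,
#'   `intercept_se`, `intercept_p` and `residual_scale` in the extras.
#' @export
mr_egger <- function(insts) {
  h <- instrument_matrix(insts)
  J <- nrow(h)
  if (J < 3L) stop("MR-Egger requires at least 3 instruments")
  flip <- h$bx < 0
  bx <- ifelse(flip, -h$bx, h$bx)
  by <- ifelse(flip, -h$by, h$by)
  w <- 1 / h$sy^2
  if (stats::var(bx) == 0) stop("no slope identifiable: zero exposure-effect variance")
  fit <- stats::lm(by ~ bx, weights = w)
  coefs <- stats::coef(fit)
  # fixed (unit-variance) covariance of the WLS coefficients
  X <- cbind(1, bx)
  xtwx_inv <- solve(crossprod(X, w * X))
  se_unit <- sqrt(diag(xtwx_inv))
  sigma <- sqrt(sum(w * stats::residuals(fit)^2) / (J - 2))
  infl <- max(1, sigma)
  slope_se <- unname(se_unit[2]) * infl
  int_se <- unname(se_unit[1]) * infl
  slope_p <- unname(2 * stats::pt(-abs(coefs[2] / slope_se), df = J - 2))
  int_p <- unname(2 * stats::pt(-abs(coefs[1] / int_se), df = J - 2))
  new_mr_estimate("egger", unname(coefs[2]), slope_se, slope_p, J,
                  extra = list(intercept = unname(coefs[1]),
                               intercept_se = int_se,
                               intercept_p = int_p,
                               residual_scale = sigma))
}

#' Weighted-median point estimate of a set of ratio estimates
#'
#' Orders the ratios, forms cumulative midpoint weights
#' `S_j = cumsum(w)_j - w_j / 2` (weights normalized to sum 1), and
#' linearly interpolates the ratio at S = 0.5. With equal weights this is
#' the interpolated sample median.
#'
#' @param ratios Numeric vector of per-instrument causal ratios.
#' @param weights Positive weights, same length.
#' @return The weighted-median estimate.
#' @export
weighted_median_estimate <- function(ratios, weights) {
  stopifnot(length(ratios) == length(weights), all(weights > 0))
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  below <- max(which(s < 0.5))
  r[below] + (r[below + 1] - r[below]) * (0.5 - s[below]) / (s[below + 1] - s[below])
}

# Parametric bootstrap of an estimator of (bx, by) -> scalar, resampling
# both association vectors from normals with their stated standard errors.
bootstrap_se <- function(h, point_fun, n_boot, seed) {
  if (n_boot < 2L) return(NA_real_)
  J <- nrow(h)
  est <- local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(J, h$bx, h$sx)
      by <- stats::rnorm(J, h$by, h$sy)
      point_fun(bx, by)
    }, numeric(1))
  })
  stats::sd(est)
}

#' Weighted-median causal estimate
#'
#' Median of the per-instrument Wald ratios weighted by `bx^2 / sy^2`,
#' consistent when instruments carrying at least half the weight are
#' valid. The standard error is estimated by parametric bootstrap:
#' both association vectors are resampled from normals with their stated
#' standard errors and the estimator recomputed. Two-sided normal p.
#'
#' @param insts Harmonized instruments (J >= 3 kept rows).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap (default 20240507).
#' @return An `mr_estimate` (method `"weighted_median"`) with `n_boot` in
#'   the extras.
#' @export
weighted_median <- function(insts, n_boot = 1000, seed = 20240507) {
  h <- instrument_matrix(insts)
  J <- nrow(h)
  if (J < 3L) stop("weighted median requires at least 3 instruments")
  point <- function(bx, by) {
    weighted_median_estimate(by / bx, bx^2 / h$sy^2)
  }
  beta <- point(h$bx, h$by)
  se <- bootstrap_se(h, point, n_boot, seed)
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate("weighted_median", beta, se, p, J,
                  extra = list(n_boot = n_boot))
}

#' Mode of a set of ratio estimates by kernel density
#'
#' Normal-kernel weighted density of the ratios with the modified
#' Silverman bandwidth
#' `h = phi * 0.9 * min(sd, IQR/1.349) * J^(-1/5)`, evaluated on a fixed
#' 512-point grid spanning `[min - 3h, max + 3h]`; returns the grid
#' argmax. Degenerate spreads (zero bandwidth) fall back to the standard
#' deviation, and to the common value when all ratios coincide.
#'
#' @param ratios Numeric vector of per-instrument causal ratios.
#' @param weights Positive weights (normalized internally).
#' @param bandwidth_factor Multiplier phi on the Silverman bandwidth
#'   (default 1).
#' @param n_grid Grid size (default 512).
#' @return The mode estimate.
#' @export
mode_point_estimate <- function(ratios, weights = rep(1, length(ratios)),
                                bandwidth_factor = 1, n_grid = 512) {
  stopifnot(length(ratios) == length(weights), bandwidth_factor > 0)
  w <- weights / sum(weights)
  J <- length(ratios)
  spread <- min(stats::sd(ratios), stats::IQR(ratios) / 1.349)
  if (!is.finite(spread) || spread <= 0) spread <- stats::sd(ratios)
  if (!is.finite(spread) || spread <= 0) return(ratios[1])
  h <- bandwidth_factor * 0.9 * spread * J^(-1 / 5)
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = n_grid)
  dens <- outer(grid, ratios, function(g, r) stats::dnorm(g, r, h)) %*% w
  grid[which.max(dens)]
}

#' Simple- or weighted-mode causal estimate
#'
#' The mode of the per-instrument Wald-ratio distribution, consistent when
#' the largest group of instruments shares the same (valid) ratio. Weights
#' are uniform (simple mode) or `bx^2 / sy^2` (weighted mode). Standard
#' error by parametric bootstrap as in [weighted_median()]; two-sided
#' normal p.
#'
#' @param insts Harmonized instruments (J >= 3 kept rows).
#' @param weighted Use inverse-variance weights (`TRUE`) or uniform
#'   weights (`FALSE`).
#' @param bandwidth_factor Bandwidth multiplier phi (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Bootstrap seed (default 20240507).
#' @return An `mr_estimate` (method `"weighted_mode"` or `"simple_mode"`).
#' @export
mode_estimator <- function(insts, weighted = TRUE, bandwidth_factor = 1,
                           n_boot = 1000, seed = 20240507) {
  h <- instrument_matrix(insts)
  J <- nrow(h)
  if (J < 3L) stop("mode estimator requires at least 3 instruments")
  point <- function(bx, by) {
    w <- if (weighted) bx^2 / h$sy^2 else rep(1, J)
    mode_point_estimate(by / bx, w, bandwidth_factor = bandwidth_factor)
  }
  beta <- point(h$bx, h$by)
  se <- bootstrap_se(h, point, n_boot, seed)
  p <- 2 * stats::pnorm(-abs(beta / se))
  new_mr_estimate(if (weighted) "weighted_mode" else "simple_mode",
                  beta, se, p, J,
                  extra = list(n_boot = n_boot, bandwidth_factor = bandwidth_factor))
}

#' Run every applicable causal estimator on an instrument set
#'
#' A single instrument admits only the Wald ratio; two instruments admit
#' inverse-variance weighting (per-instrument Wald ratios are attached);
#' three or more admit the full set of five estimators: IVW (fixed
#' effects), MR-Egger, weighted median, simple mode and weighted mode.
#'
#' @param insts Harmonized instruments (kept rows are used).
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param seed Bootstrap seed.
#' @return Data frame, one row per estimate: `method`, `n_snp`, `beta`,
#'   `se`, `pval`, `or`, `ci_low`, `ci_high`, `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_p` (NA except for Egger).
#' @export
estimate_all <- function(insts, n_boot = 1000, seed = 20240507) {
  h <- instrument_matrix(insts)
  J <- nrow(h)
  if (J == 0L) stop("no instruments supplied")
  ests <- if (J == 1L) {
    list(wald_ratio(h))
  } else if (J == 2L) {
    list(ivw(h, "fixed"))
  } else {
    list(
      ivw(h, "fixed"),
      mr_egger(h),
      weighted_median(h, n_boot = n_boot, seed = seed),
      mode_estimator(h, weighted = FALSE, n_boot = n_boot, seed = seed),
      mode_estimator(h, weighted = TRUE, n_boot = n_boot, seed = seed)
    )
  }
  estimates_to_frame(ests)
}

#' @keywords internal
estimates_to_frame <- function(ests) {
  get_or_na <- function(e, f) if (is.null(e[[f]])) NA_real_ else e[[f]]
  out <- do.call(rbind, lapply(ests, function(e) {
    data.frame(method = e$method, n_snp = e$n_snp, beta = e$beta,
               se = e$se, pval = e$pval, or = e$or_,
               ci_low = e$ci_low, ci_high = e$ci_high,
               egger_intercept = get_or_na(e, "intercept"),
               egger_intercept_se = get_or_na(e, "intercept_se"),
               egger_intercept_p = get_or_na(e, "intercept_p"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
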