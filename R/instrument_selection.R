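#' Instrument-selection configuration
#'
#' Bundles the selection thresholds: genome-wide-suggestive p-value cut,
#' LD clumping window and r-squared cut, weak-instrument F bound, and an
#' optional list of variants to exclude as confounder-associated.
#'
#' @param p_threshold Keep variants with exposure p-value strictly below
#'   this (default 1e-5).
#' @param clump_r2 Clumping r-squared cut (default 0.001): within the
#'   window, variants correlated at or above this with a better-ranked
#'   variant are removed.
#' @param clump_kb Clumping window in kilobases (default 10000).
#' @param f_min Weak-instrument bound: variants with F strictly below this
#'   are removed (default 10).
#' @param confounder_snps Character vector of variant ids to exclude
#'   (e.g. known associations with outcome confounders).
#' @param palindrome_eaf_limit Passed through to [harmonize()].
#' @return List of class `selection_config`.
#' @export
selection_config <- function(p_threshold = 1e-5, clump_r2 = 0.001,
                             clump_kb = 10000, f_min = 10,
                             confounder_snps = character(),
                             palindrome_eaf_limit = 0.42) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            clump_r2 >= 0, clump_r2 <= 1, clump_kb > 0)
  structure(
    list(p_threshold = p_threshold, clump_r2 = clump_r2,
         clump_kb = clump_kb, f_min = f_min,
         confounder_snps = as.character(confounder_snps),
         palindrome_eaf_limit = palindrome_eaf_limit),
    class = "selection_config"
  )
}

#' Select variants below a p-value threshold
#'
#' Strict inequality: a variant with p exactly equal to the threshold is
#' excluded. Original row order is preserved.
#'
#' @param table A `summary_stats` object.
#' @param p_threshold Upper bound (exclusive) on the p-value.
#' @return A `summary_stats` object with the passing records.
#' @export
threshold_select <- function(table, p_threshold = 1e-5) {
  stopifnot(inherits(table, "summary_stats"))
  table$data <- table$data[table$data$pval < p_threshold, , drop = FALSE]
  rownames(table$data) <- NULL
  table
}

#' Load a pairwise LD table from delimited text
#'
#' Three columns (snp_a, snp_b, r2), tab- or comma-separated, with or
#' without header. The symmetric closure is applied: each pair is
#' look-up-able in either order. Unlisted pairs are treated as r2 = 0.
#'
#' @param path File path.
#' @return Data frame with columns `snp_a`, `snp_b`, `r2`.
#' @export
read_ld_table <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  has_header <- grepl("snp", first, ignore.case = TRUE)
  ld <- utils::read.table(path, header = has_header, sep = sep,
                          stringsAsFactors = FALSE)
  names(ld) <- c("snp_a", "snp_b", "r2")
  ld$snp_a <- as.character(ld$snp_a)
  ld$snp_b <- as.character(ld$snp_b)
  ld$r2 <- as.numeric(ld$r2)
  ld
}

# Build a fast pairwise r2 lookup from an (snp_a, snp_b, r2) data frame.
# Returns function(a, b) -> r2, symmetric, 0 for unlisted pairs, 1 on the
# diagonal.
ld_lookup_fun <- function(ld) {
  if (is.null(ld) || nrow(ld) == 0L) {
    return(function(a, b) if (a == b) 1 else 0)
  }
  env <- new.env(hash = TRUE, size = 2L * nrow(ld))
  for (i in seq_len(nrow(ld))) {
    assign(paste(ld$snp_a[i], ld$snp_b[i], sep = "\r"), ld$r2[i], envir = env)
    assign(paste(ld$snp_b[i], ld$snp_a[i], sep = "\r"), ld$r2[i], envir = env)
  }
  function(a, b) {
    if (a == b) return(1)
    key <- paste(a, b, sep = "\r")
    if (exists(key, envir = env, inherits = FALSE)) {
      get(key, envir = env, inherits = FALSE)
    } else 0
  }
}

#' Greedy LD clumping of a summary-statistics table
#'
#' Variants are ranked by p-value (ties broken by id, lexicographically).
#' The best remaining variant is kept and every unkept variant on the same
#' chromosome within `clump_kb` kilobases whose r-squared with it is at
#' least `clump_r2` is removed; this repeats until no variants remain.
#' The retained set contains no pair that is simultaneously on the same
#' chromosome, within the window, and correlated at or above the cut.
#'
#' @param table A `summary_stats` object.
#' @param ld Pairwise LD: a data frame with columns `snp_a`, `snp_b`, `r2`
#'   (see [read_ld_table()]), or `NULL` for no LD (all pairs r2 = 0).
#' @param clump_r2 r-squared cut (pairs at or above it clump together).
#' @param clump_kb Window in kilobases.
#' @return A `summary_stats` object with the clumped (independent) set.
#' @export
ld_clump <- function(table, ld = NULL, clump_r2 = 0.001, clump_kb = 10000) {
  stopifnot(inherits(table, "summary_stats"))
  d <- table$data
  no_pos <- !is.finite(d$pos)
  if (any(no_pos)) {
    warning("excluding ", sum(no_pos), " variant(s) with missing position")
    d <- d[!no_pos, , drop = FALSE]
  }
  if (nrow(d) <= 1L) {
    table$data <- d
    rownames(table$data) <- NULL
    return(table)
  }
  r2_of <- if (is.function(ld)) ld else ld_lookup_fun(ld)
  ord <- order(d$pval, d$snp_id)
  window_bp <- clump_kb * 1000
  removed <- rep(FALSE, nrow(d))
  keep <- rep(FALSE, nrow(d))
  for (i in ord) {
    if (removed[i]) next
    keep[i] <- TRUE
    same_chr <- which(!removed & !keep & d$chrom == d$chrom[i] &
                        abs(d$pos - d$pos[i]) <= window_bp)
    for (j in same_chr) {
      if (r2_of(d$snp_id[i], d$snp_id[j]) >= clump_r2) removed[j] <- TRUE
    }
  }
  table$data <- d[keep, , drop = FALSE]
  rownames(table$data) <- NULL
  table
}

#' Variance in the exposure explained by one variant
#'
#' R-squared under Hardy-Weinberg on a standardized trait:
#' `2 * eaf * (1 - eaf) * beta^2`. Symmetric in `eaf` and `1 - eaf`.
#' Missing frequency yields `NA` (the variant cannot be scored and must be
#' excluded by the caller).
#'
#' @param eaf Effect-allele frequency in \[0, 1\]; vectorized.
#' @param beta Per-allele effect; vectorized.
#' @return Fraction of variance explained.
#' @export
#' @examples
#' variance_explained(0.25, 0.2)  # 0.015
variance_explained <- function(eaf, beta) {
  bad <- !is.na(eaf) & (eaf < 0 | eaf > 1)
  if (any(bad)) stop("eaf must lie in [0, 1]")
  2 * eaf * (1 - eaf) * beta^2
}

#' Instrument-strength F-statistic
#'
#' `F = r2 * (n - 2) / (1 - r2)`, strictly increasing in both arguments.
#' Values below 10 conventionally flag weak instruments.
#'
#' @param r2 Variance explained, in \[0, 1); vectorized.
#' @param n Sample size (> 2); vectorized.
#' @return F value.
#' @export
#' @examples
#' f_statistic(0.015, 1000)  # ~15.198
f_statistic <- function(r2, n) {
  if (any(r2 >= 1, na.rm = TRUE)) stop("r2 must be < 1")
  if (any(r2 < 0, na.rm = TRUE)) stop("r2 must be >= 0")
  r2 * (n - 2) / (1 - r2)
}

#' Remove confounder-associated and weak instruments
#'
#' Applies, after thresholding and clumping: (1) exclusion of variants on
#' the supplied confounder list; (2) exclusion of variants whose F cannot
#' be computed (missing frequency) or falls strictly below `f_min`.
#' Per-variant metrics (r2, F) are reported for all inputs together with
#' the removal reason.
#'
#' @param table A `summary_stats` object (already thresholded/clumped).
#' @param cfg A [selection_config()].
#' @return List with `table` (filtered `summary_stats`) and `metrics`
#'   (data frame: `snp_id`, `r2`, `f_stat`, `kept`, `reason`).
#' @export
filter_instruments <- function(table, cfg = selection_config()) {
  stopifnot(inherits(table, "summary_stats"))
  d <- table$data
  r2 <- variance_explained(d$eaf, d$beta)
  f <- ifelse(is.na(r2), NA_real_, f_statistic(r2, d$n))
  reason <- character(nrow(d))
  confounder <- d$snp_id %in% cfg$confounder_snps
  weak <- !confounder & (is.na(f) | f < cfg$f_min)
  reason[weak] <- "weak"
  reason[confounder] <- "confounder"
  keep <- !confounder & !weak
  metrics <- data.frame(snp_id = d$snp_id, r2 = r2, f_stat = f,
                        kept = keep, reason = reason,
                        stringsAsFactors = FALSE)
  table$data <- d[keep, , drop = FALSE]
  rownames(table$data) <- NULL
  list(table = table, metrics = metrics)
}

#' Steiger directionality filter
#'
#' For each harmonized instrument, compares the variance explained in the
#' exposure with the variance explained in the outcome (both via
#' [variance_explained()] on each side's frequency and effect; the
#' exposure frequency substitutes when the outcome frequency is missing).
#' The causal direction is called exposure-to-outcome only when the
#' exposure r-squared strictly exceeds the outcome r-squared; other
#' variants are excluded. A two-sided p-value for the difference of the
#' implied correlations is computed by Fisher z-transform.
#'
#' @param insts A `harmonized` data frame (kept rows are used).
#' @param exposure_n,outcome_n Optional scalar sample sizes overriding the
#'   per-variant `nx` / `ny` columns.
#' @return List with `kept` (instruments passing the filter) and `metrics`
#'   (data frame: `snp_id`, `r2_exposure`, `r2_outcome`,
#'   `steiger_direction`, `steiger_p`).
#' @export
steiger_filter <- function(insts, exposure_n = NULL, outcome_n = NULL) {
  h <- kept_instruments(insts)
  nx <- if (is.null(exposure_n)) h$nx else rep(exposure_n, nrow(h))
  ny <- if (is.null(outcome_n)) h$ny else rep(outcome_n, nrow(h))
  eaf_y <- ifelse(is.na(h$eaf_outcome), h$eaf_exposure, h$eaf_outcome)
  r2x <- variance_explained(h$eaf_exposure, h$bx)
  r2y <- variance_explained(eaf_y, h$by)
  direction <- !is.na(r2x) & !is.na(r2y) & r2x > r2y
  # Fisher z two-sample test on the implied correlations
  zx <- atanh(pmin(sqrt(pmax(r2x, 0)), 1 - 1e-12))
  zy <- atanh(pmin(sqrt(pmax(r2y, 0)), 1 - 1e-12))
  zse <- sqrt(1 / (nx - 3) + 1 / (ny - 3))
  z <- (zx - zy) / zse
  p <- 2 * stats::pnorm(-abs(z))
  metrics <- data.frame(snp_id = h$snp_id, r2_exposure = r2x,
                        r2_outcome = r2y, steiger_direction = direction,
                        steiger_p = p, stringsAsFactors = FALSE)
  kept <- h[direction, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, metrics = metrics)
}

#' Read a confounder-variant exclusion list
#'
#' One variant id per line; blank lines and `#` comments ignored.
#'
#' @param path File path.
#' @return Character vector of variant ids.
#' @export
read_confounder_list <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}
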