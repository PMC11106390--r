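#' Default column mapping for GWAS summary-statistics tables
#'
#' Maps the internal field names used throughout the package to the column
#' headers expected in input files. Override individual entries to read
#' tables with other header conventions.
#'
#' @return Named character vector: internal field -> column header.
#' @export
#' @examples
#' default_column_map()
default_column_map <- function() {
  c(
    snp_id = "SNP", chrom = "CHR", pos = "POS",
    effect_allele = "EA", other_allele = "OA", eaf = "EAF",
    beta = "BETA", se = "SE", pval = "P", n = "N"
  )
}

#' Construct a summary-statistics table object
#'
#' Light container for one trait's per-variant associations. Rows violating
#' the per-variant invariants (se > 0, p in (0,1], eaf in \[0,1\] when
#' present, distinct alleles, n > 2) are dropped and tallied; duplicated
#' variant identifiers keep the first occurrence.
#'
#' @param data Data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param trait_name Non-empty trait label.
#' @param trait_type `"quantitative"` or `"binary"` (binary traits carry
#'   log odds-ratio effects).
#' @return Object of class `summary_stats`: list with `trait_name`,
#'   `trait_type`, `data` (validated data frame) and `tally` (named counts
#'   of dropped rows by reason).
#' @export
summary_stats <- function(data, trait_name, trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  if (!is.character(trait_name) || length(trait_name) != 1L || !nzchar(trait_name)) {
    stop("trait_name must be a non-empty string")
  }
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  data$snp_id <- as.character(data$snp_id)
  data$chrom <- as.character(data$chrom)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    data[[col]] <- suppressWarnings(as.numeric(data[[col]]))
  }

  tally <- c(invalid_se = 0L, invalid_pval = 0L, invalid_eaf = 0L,
             invalid_alleles = 0L, invalid_n = 0L, invalid_beta = 0L,
             duplicate = 0L)
  bad_se <- !is.finite(data$se) | data$se <= 0
  bad_p <- !is.finite(data$pval) | data$pval <= 0 | data$pval > 1
  bad_eaf <- !is.na(data$eaf) & (data$eaf < 0 | data$eaf > 1)
  bad_al <- !nzchar(data$effect_allele) | !nzchar(data$other_allele) |
    data$effect_allele == data$other_allele
  bad_n <- !is.finite(data$n) | data$n <= 2
  bad_beta <- !is.finite(data$beta)
  tally["invalid_se"] <- sum(bad_se)
  drop <- bad_se
  tally["invalid_pval"] <- sum(bad_p & !drop); drop <- drop | bad_p
  tally["invalid_eaf"] <- sum(bad_eaf & !drop); drop <- drop | bad_eaf
  tally["invalid_alleles"] <- sum(bad_al & !drop); drop <- drop | bad_al
  tally["invalid_n"] <- sum(bad_n & !drop); drop <- drop | bad_n
  tally["invalid_beta"] <- sum(bad_beta & !drop); drop <- drop | bad_beta
  data <- data[!drop, , drop = FALSE]

  dup <- duplicated(data$snp_id)
  tally["duplicate"] <- sum(dup)
  data <- data[!dup, , drop = FALSE]
  rownames(data) <- NULL

  structure(
    list(trait_name = trait_name, trait_type = trait_type,
         data = data, tally = tally),
    class = "summary_stats"
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("<summary_stats> %s (%s): %d variants\n",
              x$trait_name, x$trait_type, nrow(x$data)))
  dropped <- x$tally[x$tally > 0]
  if (length(dropped) > 0) {
    cat("  dropped:", paste(sprintf("%s=%d", names(dropped), dropped),
                            collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of variants in a summary-statistics table
#' @param x A `summary_stats` object.
#' @export
n_variants <- function(x) nrow(x$data)

#' Read a GWAS summary-statistics table from delimited text
#'
#' The delimiter (tab or comma) is auto-detected from the header line.
#' Invalid rows are dropped and tallied as in [summary_stats()].
#'
#' @param path File path.
#' @param column_map Named character vector mapping internal field names to
#'   file column headers; see [default_column_map()].
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param trait_name Trait label; defaults to the file name without
#'   extension.
#' @return A `summary_stats` object.
#' @export
read_summary_table <- function(path, column_map = default_column_map(),
                               trait_type = c("quantitative", "binary"),
                               trait_name = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file does not exist: ", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) stop("empty file: ", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "", quote = "\"")
  full_map <- default_column_map()
  full_map[names(column_map)] <- column_map
  missing_cols <- full_map[!full_map %in% names(raw)]
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  data <- raw[, unname(full_map)]
  names(data) <- names(full_map)
  if (is.null(trait_name)) {
    trait_name <- sub("\\.[^.]*$", "", basename(path))
  }
  summary_stats(data, trait_name = trait_name, trait_type = trait_type)
}

# Strand complement for single-base alleles; multi-base (indel) alleles are
# never complemented.
complement_allele <- function(a) {
  ifelse(nchar(a) == 1L, chartr("ACGT", "TGCA", a), a)
}

is_palindromic_pair <- function(a1, a2) {
  nchar(a1) == 1L & nchar(a2) == 1L & a2 == complement_allele(a1) & a1 != a2
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association of every shared variant to the exposure's
#' effect allele. Swapped alleles invert the outcome effect sign (and
#' complement the outcome frequency); alleles reported on the opposite
#' strand are complemented first. Palindromic variants (A/T or C/G) cannot
#' be resolved from allele labels: their orientation is inferred by
#' comparing effect-allele frequencies, and only when both minor-allele
#' frequencies are below `palindrome_eaf_limit`; otherwise the variant is
#' dropped as `ambiguous_palindrome`. Irreconcilable allele sets are
#' dropped as `allele_mismatch`. Indel alleles are compared literally.
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param palindrome_eaf_limit Minor-allele-frequency bound below which a
#'   palindromic variant's strand is considered inferable (default 0.42,
#'   i.e. frequencies in \[0.42, 0.58\] are uninformative).
#' @return Data frame of class `harmonized`, one row per shared variant:
#'   `snp_id`, exposure effect/se (`bx`, `sx`), aligned outcome effect/se
#'   (`by`, `sy`), `eaf_exposure`, `eaf_outcome`, sample sizes `nx`, `ny`,
#'   `chrom`, `pos`, flags `palindromic`, `flipped`, `kept`, and
#'   `drop_reason` (empty when kept).
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42) {
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))
  ex <- exposure$data
  ou <- outcome$data
  if (nrow(ex) == 0L || nrow(ou) == 0L) stop("both tables must be non-empty")
  shared <- intersect(ex$snp_id, ou$snp_id)
  ex <- ex[match(shared, ex$snp_id), , drop = FALSE]
  ou <- ou[match(shared, ou$snp_id), , drop = FALSE]

  n <- length(shared)
  by <- ou$beta
  eaf_y <- ou$eaf
  flipped <- logical(n)
  kept <- rep(TRUE, n)
  reason <- character(n)
  palin <- is_palindromic_pair(ex$effect_allele, ex$other_allele)

  for (i in seq_len(n)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    indel <- any(nchar(c(ea_x, oa_x, ea_y, oa_y)) > 1L)

    if (palin[i]) {
      # allele labels cannot distinguish strand; require the same allele set
      # and infer orientation from frequencies
      if (!setequal(c(ea_y, oa_y), c(ea_x, oa_x))) {
        kept[i] <- FALSE; reason[i] <- "allele_mismatch"; next
      }
      fx <- ex$eaf[i]; fy <- ou$eaf[i]
      if (is.na(fx) || is.na(fy)) {
        kept[i] <- FALSE; reason[i] <- "missing_eaf_palindromic"; next
      }
      if (min(fx, 1 - fx) >= palindrome_eaf_limit ||
          min(fy, 1 - fy) >= palindrome_eaf_limit) {
        kept[i] <- FALSE; reason[i] <- "ambiguous_palindrome"; next
      }
      if ((fx < 0.5) != (fy < 0.5)) {
        by[i] <- -by[i]; eaf_y[i] <- 1 - fy; flipped[i] <- TRUE
      }
      next
    }

    matched <- FALSE
    for (comp in c(FALSE, TRUE)) {
      if (comp && indel) break
      a <- if (comp) complement_allele(ea_y) else ea_y
      b <- if (comp) complement_allele(oa_y) else oa_y
      if (a == ea_x && b == oa_x) {
        matched <- TRUE
        break
      }
      if (a == oa_x && b == ea_x) {
        by[i] <- -by[i]
        if (!is.na(eaf_y[i])) eaf_y[i] <- 1 - eaf_y[i]
        flipped[i] <- TRUE
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      kept[i] <- FALSE; reason[i] <- "allele_mismatch"
    }
  }

  out <- data.frame(
    snp_id = shared,
    bx = ex$beta, sx = ex$se,
    by = by, sy = ou$se,
    eaf_exposure = ex$eaf, eaf_outcome = eaf_y,
    nx = ex$n, ny = ou$n,
    chrom = ex$chrom, pos = ex$pos,
    palindromic = palin, flipped = flipped,
    kept = kept, drop_reason = reason,
    stringsAsFactors = FALSE
  )
  class(out) <- c("harmonized", "data.frame")
  out
}

#' Keep only the retained rows of a harmonized instrument set
#' @param h A `harmonized` data frame from [harmonize()].
#' @return The subset with `kept == TRUE`.
#' @export
kept_instruments <- function(h) {
  out <- h[h$kept, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an analysis results table as delimited text
#'
#' Writes tab-separated text with a header. Numeric columns survive a
#' round trip to at least 6 significant digits (values are written at full
#' double precision).
#'
#' @param rows Data frame of result records.
#' @param path Output path.
#' @export
write_results_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  con <- tryCatch(suppressWarnings(file(path, "w")), error = function(e) {
    stop("cannot open path for writing: ", path)
  })
  on.exit(close(con))
  utils::write.table(format(rows, digits = 15, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path File path.
#' @return Data frame.
#' @export
read_results_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read an analysis configuration file
#'
#' YAML key-value file selecting input paths, column maps and trait types,
#' plus any pipeline parameter overrides (e.g. `p_threshold`, `clump_kb`).
#'
#' @param path Path to a YAML file.
#' @return Named list of settings.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  yaml::read_yaml(path)
}
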