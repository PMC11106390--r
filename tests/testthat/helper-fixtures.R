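# Programmatic fixtures used across the suite.

# Minimal valid variant row with overridable fields.
variant_row <- function(snp_id = "rs1", chrom = "1", pos = 1e6,
                        effect_allele = "A", other_allele = "G",
                        eaf = 0.3, beta = 0.1, se = 0.01, pval = 1e-6,
                        n = 10000) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pval = pval, n = n,
             stringsAsFactors = FALSE)
}

make_table <- function(rows, trait_name = "trait",
                       trait_type = "quantitative") {
  summary_stats(do.call(rbind, rows), trait_name, trait_type)
}

# Bare harmonized instrument set from effect vectors (all kept).
make_insts <- function(bx, by, sx = rep(0.01, length(bx)),
                       sy = rep(0.02, length(bx)),
                       eaf = rep(0.3, length(bx)),
                       nx = 18340, ny = 325496) {
  J <- length(bx)
  out <- data.frame(
    snp_id = sprintf("rs%03d", seq_len(J)),
    bx = bx, sx = sx, by = by, sy = sy,
    eaf_exposure = eaf, eaf_outcome = eaf,
    nx = rep(nx, length.out = J), ny = rep(ny, length.out = J),
    chrom = rep("1", J), pos = seq_len(J) * 1e6,
    palindromic = rep(FALSE, J), flipped = rep(FALSE, J),
    kept = rep(TRUE, J), drop_reason = rep("", J),
    stringsAsFactors = FALSE
  )
  class(out) <- c("harmonized", "data.frame")
  out
}

# Random small harmonized instance for oracle comparisons.
random_insts <- function(J, seed) {
  set.seed(seed)
  make_insts(
    bx = runif(J, 0.05, 0.3) * sample(c(-1, 1), J, replace = TRUE),
    by = rnorm(J, 0, 0.05),
    sx = runif(J, 0.005, 0.02),
    sy = runif(J, 0.005, 0.05)
  )
}

# Independent oracle: IVW(fixed) as weighted regression of by on bx
# through the origin with weights 1/sy^2.
oracle_ivw_origin <- function(h) {
  w <- 1 / h$sy^2
  sum(w * h$bx * h$by) / sum(w * h$bx^2)
}

# Independent oracle: weighted normal-equations solve for the Egger fit
# (after bx > 0 orientation), returning c(intercept, slope).
oracle_egger_ne <- function(h) {
  flip <- h$bx < 0
  bx <- ifelse(flip, -h$bx, h$bx)
  by <- ifelse(flip, -h$by, h$by)
  w <- 1 / h$sy^2
  X <- cbind(1, bx)
  unname(solve(t(X) %*% (w * X), t(X) %*% (w * by))[, 1])
}

# Independent brute-force greedy clumping on plain vectors.
oracle_clump <- function(d, r2_of, clump_r2, clump_kb) {
  ord <- order(d$pval, d$snp_id)
  d <- d[ord, , drop = FALSE]
  kept <- character()
  removed <- character()
  for (i in seq_len(nrow(d))) {
    id <- d$snp_id[i]
    if (id %in% removed) next
    kept <- c(kept, id)
    for (j in seq_len(nrow(d))) {
      jd <- d$snp_id[j]
      if (jd == id || jd %in% removed || jd %in% kept) next
      if (d$chrom[j] == d$chrom[i] &&
          abs(d$pos[j] - d$pos[i]) <= clump_kb * 1000 &&
          r2_of(id, jd) >= clump_r2) {
        removed <- c(removed, jd)
      }
    }
  }
  sort(kept)
}
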