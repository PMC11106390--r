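# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's state afterwards so seeded helpers do not perturb the
# global stream.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit seed for one exposure/outcome pair, derived from the
# global seed and the pair labels (polynomial string hash mod 2^31 - 27,
# a prime), so batch runs are reproducible per pair and overall.
pair_seed <- function(global_seed, exposure_name, outcome_name) {
  m <- 2147483629
  acc <- as.numeric(global_seed) %% m
  for (ch in utf8ToInt(paste(exposure_name, outcome_name, sep = "\r"))) {
    acc <- (acc * 131 + ch) %% m
  }
  as.integer(acc)
}
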