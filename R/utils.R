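# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random state. All simulator randomness flows through this.
.with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# 1-based inclusive span intersection (vectorised).
.span_overlap <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

# GRanges over the genomic spans of a model data frame; used as the
# interval index behind overlap queries.
.models_granges <- function(models, levels = NULL) {
  if (nrow(models) == 0L) return(GenomicRanges::GRanges())
  if (is.null(levels)) levels <- unique(models$scaffold)
  GenomicRanges::GRanges(
    seqnames = factor(models$scaffold, levels = levels),
    ranges = IRanges::IRanges(start = models$start, end = models$end)
  )
}
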