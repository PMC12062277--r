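#' @importFrom rlang abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm rbinom runif median coef lm predict sd cor setNames
#' @importFrom utils head modifyList
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards (no global side effects).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Derive a child seed from a base seed and a stream index, kept inside the
# 32-bit integer range.
child_seed <- function(seed, k) {
  # double arithmetic: products stay well under 2^53, result under 2^31
  as.integer((as.numeric(seed) * 1000003 + as.numeric(k) * 7919) %% 2147480017)
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}
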