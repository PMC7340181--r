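# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All exported stochastic functions go
# through this so a single integer seed determines every draw.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic child seeds derived from a parent seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "pctsim_config_error", ...)
}

abort_instability <- function(step, unit) {
  rlang::abort(
    sprintf(
      "Control loop diverged at step %d (unit %s): |signal| exceeded 1e9.",
      step, unit
    ),
    class = "pctsim_instability_error",
    step = step, unit = unit
  )
}

check_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || (finite && !is.finite(x))) {
    abort_config(sprintf("`%s` must be a single finite number.", name))
  }
  as.numeric(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Signals larger than this are treated as divergence rather than oscillation.
.instability_limit <- 1e9
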