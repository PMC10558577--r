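# Internal helpers shared across the package.

# Classed error so callers/tests can distinguish failure modes
# (format, cardinality, geometry, anisotropy, value, insufficiency,
# domain, state, config).
isz_error <- function(message, class) {
  stop(errorCondition(message, class = c(class, "implantsize_error")))
}

isz_warning <- function(message, class) {
  warning(warningCondition(message, class = c(class, "implantsize_warning")))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. seed = NULL leaves the RNG alone.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

# Half-up decimal rounding used for display, matching how the benchmark
# table prints its metrics (round() would round half to even).
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    isz_error(sprintf("`%s` must be a single non-negative integer", name),
              "implant_config_error")
  }
  as.integer(x)
}
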