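# Internal seeding helpers. All stochastic code in the package runs inside
# with_seed() so the caller's RNG state is never disturbed and every stage is
# reproducible from one global seed.

# Evaluate expr with a temporary RNG state seeded by `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage, per-unit seed fan-out from a global seed.
# Stage codes: 1 schedule, 2 boluses, 3 sensor, 4 population, 5 training,
# 6 misc/test. Kept below 2^31 - 1.
derive_seed <- function(global, stage, index) {
  s <- (as.double(global) * 100003 + as.double(stage) * 1009 +
          as.double(index)) %% 2147483587
  as.integer(s) + 1L
}

# clamp helper
.clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
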