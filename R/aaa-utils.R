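# Derive a child RNG seed from a base seed and a string label, keeping the
# result in the 32-bit signed range R's set.seed() accepts.
derive_seed <- function(seed, label) {
  h <- 0
  for (k in utf8ToInt(label)) h <- (h * 31 + k) %% 2147483587L
  as.integer((as.numeric(seed) %% 2147483587 * 7919 + h + 1) %% 2147483587)
}

# Evaluate an expression under a local RNG state seeded from (seed, label),
# restoring the caller's RNG stream afterwards.
with_seed <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(derive_seed(seed, label))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_wm <- function(...) stop(sprintf(...), call. = FALSE)

MAP_LABELS <- c("FA", "MD", "AxD", "RD", "MO")
RISK_FACTORS <- c("hypertension", "diabetes", "hypercholesterolemia",
                  "obesity", "smoking")
COG_TESTS <- c("reaction_time", "trail_making_a", "symbol_digit",
               "numeric_memory", "pairs_matching", "trail_making_b",
               "fluid_intelligence")
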