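# Internal numeric helpers shared across modules.

# Round half away from zero (symmetric around 0), unlike base round()'s
# round-half-to-even.  Used before every float -> int16 cast.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards.  Keeps frame generation deterministic and independent
# of access order.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a per-frame seed from a run seed and frame index, kept inside the
# 32-bit signed range R requires.
frame_seed <- function(run_seed, i) {
  as.integer((as.numeric(run_seed) * 7919 + as.numeric(i) * 104729) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
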