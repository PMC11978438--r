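# Internal helpers shared across modules.

# Deterministic derivation of child seeds from a master seed.  Uses a Lehmer
# multiplicative congruential step; all intermediate products stay below 2^53
# so the arithmetic is exact in doubles, and results stay below 2^31 so they
# are valid R integer seeds.
lcg_next <- function(s) {
  (16807 * (s %% 2147483646) + 1) %% 2147483647
}

# derive_seed(master, i, j, ...) mixes each index in turn; used so that
# (master seed, grid index, realization index) -> per-run seed is reproducible
# regardless of execution order.
derive_seed <- function(seed, ...) {
  s <- abs(as.numeric(seed)) %% 2147483647
  s <- lcg_next(s)
  for (i in c(...)) {
    s <- lcg_next((s + abs(as.numeric(i))) %% 2147483647)
  }
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}
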