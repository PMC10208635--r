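# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Derive a child seed from a base seed and an index; stays inside the
# 32-bit integer range R's set.seed() accepts.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647L)
}

stop_arcpulse <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "arcpulse_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ESTRUS_STAGES <- c("proestrus", "estrus", "metestrus", "diestrus")
AGING_PHASES  <- c("reproductive", "regular", "irregular", "acyclic")
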