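# Internal helpers shared across stages.

#' @keywords internal
"_PACKAGE"

# Round half away from zero for positive x (R's round() is banker's rounding;
# the partition arithmetic here needs 0.5 -> 1).
round_half_up <- function(x) floor(x + 0.5)

# Deterministic seed fan-out: every stage/restart/fold derives its own RNG seed
# from the user seed plus integer tags, via a Lehmer-style recurrence modulo
# 2^31 - 1.  Keeps all derived seeds valid 32-bit integers.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- (as.double(seed) %% 2147483647)
  if (s <= 0) s <- s + 2147483646
  for (k in tags) {
    s <- (s * 48271 + as.double(k) + 1) %% 2147483647
    if (s == 0) s <- 1
  }
  as.integer(s)
}

# Evaluate `code` under set.seed(seed) without clobbering the caller's RNG
# stream.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = env, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }, add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# 31-bit rolling hash of a character scalar; used to stamp output files with
# the configuration that produced them (no timestamps, so reruns are
# byte-identical).
config_hash <- function(txt) {
  stopifnot(is.character(txt), length(txt) == 1L)
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# Full-precision numeric formatting for text output; survives a read-back
# round trip bit-exactly.
num_chr <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v == floor(v) && abs(v) < 1e15) return(sprintf("%.0f", v))
    sprintf("%.17g", v)
  }, character(1))
  out
}

stop2 <- function(...) stop(..., call. = FALSE)
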