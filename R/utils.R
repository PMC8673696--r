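## Internal helpers: seeded evaluation, logging, tiny hashing.

# Evaluate expr under a fixed RNG seed without disturbing the caller's RNG.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

.log <- function(fmt, ...) message(sprintf(paste0("[mmglam] ", fmt), ...))

# Polynomial rolling hash of a character scalar, as 8 hex digits; used to
# fingerprint configurations in run manifests (kept within exact double
# integer arithmetic).
.confHash <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Periodic Hann window.
.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

.rmsOf <- function(x) sqrt(mean(x^2))
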