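# Internal numeric helpers shared across modules.

# Round half away from zero. base::round() rounds half to even, which would make
# LUT golden values depend on the parity of the integer part; grey levels are
# non-negative so this is floor(x + 0.5) on the package's domain, but the
# symmetric form is kept for safety.
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

# Clip to the representable grey range [0, fmax].
.clipGrey <- function(x, fmax) pmin(pmax(x, 0), fmax)

.isWholeNumber <- function(x, tol = 1e-8) all(abs(x - round(x)) < tol)

# fmax must be 2^b - 1 for a positive integer b.
.isValidFmax <- function(fmax) {
  if (length(fmax) != 1L || is.na(fmax) || fmax < 1) return(FALSE)
  b <- log2(fmax + 1)
  abs(b - round(b)) < 1e-9
}

# Order-sensitive polynomial rolling hash (mod 2^31 - 1) over an integer
# vector, returned as a hex string. Used to fingerprint holdout splits so a
# paired comparison can refuse summaries built on different splits.
.hashInts <- function(v) {
  m <- 2147483647
  h <- 17
  for (x in as.numeric(v)) {
    h <- (h * 31 + (x %% m)) %% m
  }
  sprintf("%08x", as.integer(h))
}

# Derive independent child seeds from one base seed without touching the
# caller's RNG state. Kept below 2^31 so they are valid R integer seeds.
.spawnSeeds <- function(baseSeed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(baseSeed))
  sample.int(2147483646L, n)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
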