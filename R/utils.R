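# Internal helpers: classed error conditions, seeded evaluation, and small
# numeric utilities shared across modules.

# Raise a classed error so callers can distinguish failure modes
# (e.g. zfcardio_no_object, zfcardio_no_beat) with tryCatch.
zf_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("zfcardio_", class), "zfcardio_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# Evaluate expr with a local RNG state seeded by `seed`; the caller's
# .Random.seed is restored afterwards so simulations never perturb the
# session RNG stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    zf_stop("bad_argument", "'%s' must be a single positive number", name)
  invisible(x)
}

# Centred moving average of odd-ish width w (w >= 1); edges use the
# partial window so the series keeps its length and no phase shift occurs.
moving_average <- function(x, w) {
  w <- max(1L, as.integer(w))
  if (w == 1L) return(x)
  n <- length(x)
  half <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
}

# Eigen-decomposition of the symmetric 2x2 matrix [cxx cxy; cxy cyy],
# returned as eigenvalues (decreasing) plus the orientation of the leading
# eigenvector in [0, pi). Closed form avoids eigen() overhead in per-frame
# loops.
eigen2x2 <- function(cxx, cyy, cxy) {
  tr2 <- (cxx + cyy) / 2
  d <- sqrt(((cxx - cyy) / 2)^2 + cxy^2)
  l1 <- tr2 + d
  l2 <- tr2 - d
  theta <- 0.5 * atan2(2 * cxy, cxx - cyy)
  theta <- theta %% pi
  list(l1 = l1, l2 = l2, theta = theta)
}

# Round half-up to `digits` decimals (so 71.45 -> 71.5), unlike base
# round()'s round-half-even. A tiny epsilon absorbs binary representation
# error in quotients like 100*20/28.
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

fmt_num <- function(x) sprintf("%.17g", x)
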