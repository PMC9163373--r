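`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' One global pipeline seed fans out to per-stage seeds so any stage can
#' be rerun in isolation with the same stream.  The derivation hashes the
#' stage name (FNV-1a, 32-bit) and folds it into the seed modulo
#' 2^31 - 1, keeping the result a valid positive R integer.
#'
#' @param seed global integer seed.
#' @param stage stage name string.
#' @return Integer seed in `[1, 2^31 - 1]`.
#' @export
derive_seed <- function(seed, stage) {
  h <- fnv1a32(charToRaw(stage))
  as.integer((as.double(seed) * 48271 + h) %% 2147483646) + 1L
}

# sequential 32-bit FNV-1a over a raw vector, returned as a double in
# [0, 2^32); the multiply is split 16/16 to stay inside double precision
fnv1a32 <- function(bytes) {
  h <- 2166136261
  p <- 16777619
  for (b in as.integer(bytes)) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  h
}

# hex digest of a file or character scalar (for run manifests); the
# 32-bit value arrives as a double, so format it in two 16-bit halves
fnv1a_hex <- function(x) {
  bytes <- if (file.exists(x %||% "")) readBin(x, "raw", file.size(x))
           else charToRaw(enc2utf8(x))
  h <- fnv1a32(bytes)
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# --- truncated normal ------------------------------------------------------

# moments of N(mu, sigma) truncated to [a, b]
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  Z <- stats::pnorm(be) - stats::pnorm(al)
  d <- (stats::dnorm(al) - stats::dnorm(be)) / Z
  m <- mu + sigma * d
  v <- sigma^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / Z - d^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

# find parent (mu, sigma) whose [a, b]-truncation has the target moments
calibrate_truncnorm <- function(mean, sd, min, max) {
  obj <- function(p) {
    mo <- truncnorm_moments(p[1], exp(p[2]), min, max)
    (mo$mean - mean)^2 + (mo$sd - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

# rejection sampler for the truncated normal
rtrunc_norm <- function(n, mu, sigma, a, b) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n - length(out), mu, sigma)
    out <- c(out, x[x >= a & x <= b])
  }
  out
}

fh_log <- function(...) {
  if (isTRUE(getOption("famhx.verbose", FALSE))) message(...)
}
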