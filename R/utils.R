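# Internal helpers shared across modules.

# Deterministic 32-bit seed derived from a global seed and a stage/subject tag.
# Keeps every stage independently reproducible from one run-level seed.
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  bytes <- utf8ToInt(paste0(tag, ":", format(seed, scientific = FALSE)))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  as.integer(h)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Welch power spectral density from Hann-windowed periodograms. `average`
# "median" (per frequency bin, across segments) resists transient artifacts
# such as blinks; "mean" is the classical Welch estimate.
# Returns data.frame(freq, psd) with psd in input-units^2 / Hz.
welchPSD <- function(x, rate, segLength = NULL, overlap = 0.5,
                     average = c("mean", "median")) {
  average <- match.arg(average)
  n <- length(x)
  if (is.null(segLength)) segLength <- min(n, as.integer(4 * rate))
  if (n < segLength) stop("signal shorter than one Welch segment")
  step <- max(1L, as.integer(segLength * (1 - overlap)))
  starts <- seq(1L, n - segLength + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(segLength) / (segLength + 1)))
  u <- sum(w^2)
  nf <- segLength %/% 2L + 1L
  per <- matrix(0, nf, length(starts))
  for (k in seq_along(starts)) {
    seg <- x[starts[k]:(starts[k] + segLength - 1L)]
    seg <- (seg - mean(seg)) * w
    X <- stats::fft(seg)[seq_len(nf)]
    per[, k] <- (Mod(X)^2) / (u * rate)
  }
  psd <- if (average == "median" && length(starts) > 1L)
    apply(per, 1, stats::median) else rowMeans(per)
  # one-sided: double all bins except DC (and Nyquist when segLength even)
  dbl <- rep(2, nf); dbl[1] <- 1
  if (segLength %% 2L == 0L) dbl[nf] <- 1
  data.frame(freq = (seq_len(nf) - 1L) * rate / segLength, psd = psd * dbl)
}

robustZ <- function(x) {
  med <- stats::median(x)
  s <- stats::mad(x)
  if (s <= .Machine$double.eps) s <- stats::sd(x)
  if (s <= .Machine$double.eps) return(rep(0, length(x)))
  (x - med) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
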