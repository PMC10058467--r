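# Internal numerical and RNG helpers.

.MOD31 <- 2147483647  # 2^31 - 1; derived seeds must stay below R's integer max

#' Derive a reproducible substream seed from a root seed
#'
#' Mixes the root seed with an arbitrary sequence of integer or character
#' tokens (stage names, participant/movie indices, shuffle counters) into a
#' deterministic integer in [0, 2^31 - 2]. All randomness in the package flows
#' from one root seed through this scheme, so any cell of a large resampling
#' experiment can be recomputed in isolation.
#'
#' @param root integer root seed.
#' @param ... tokens (numbers or strings) identifying the substream.
#' @return an integer seed.
#' @export
mixSeed <- function(root, ...) {
  toks <- list(...)
  h <- as.numeric(root) %% .MOD31
  for (tk in toks) {
    if (is.character(tk)) tk <- utf8ToInt(paste(tk, collapse = ""))
    for (v in as.numeric(tk)) {
      h <- (h * 69069 + (v %% .MOD31) + 1) %% .MOD31
    }
  }
  as.integer(h)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Centered moving average with shrinking (partial) windows at the edges.
movingAverage <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 0L) return(x)
  half_l <- floor((w - 1) / 2)
  half_r <- (w - 1) - half_l
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - half_l, 1L)
  hi <- pmin(i + half_r, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Centered sliding minimum (partial windows at the edges), monotonic-deque
# algorithm, O(n). Used for the running-minimum tonic estimate.
runningMin <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 0L) return(x)
  half_l <- floor((w - 1) / 2)
  half_r <- (w - 1) - half_l
  out <- numeric(n)
  dq <- integer(n)  # indices of candidate minima, values increasing
  head <- 1L; tail <- 0L
  j <- 0L
  for (i in seq_len(n)) {
    hi <- min(n, i + half_r)
    lo <- max(1L, i - half_l)
    while (j < hi) {
      j <- j + 1L
      while (tail >= head && x[dq[tail]] >= x[j]) tail <- tail - 1L
      tail <- tail + 1L
      dq[tail] <- j
    }
    while (dq[head] < lo) head <- head + 1L
    out[i] <- x[dq[head]]
  }
  out
}

# Sums of x over windows [starts[k], starts[k] + w - 1].
rollingWindowSums <- function(x, w, starts) {
  cs <- c(0, cumsum(x))
  cs[starts + w] - cs[starts]
}

stopifnot_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0", name), call. = FALSE)
  invisible(x)
}
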