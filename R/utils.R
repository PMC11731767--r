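# Internal numerical / bookkeeping helpers shared across modules.

#' Derive a labeled child seed from a master seed
#'
#' One master seed is split into per-generator streams by a fixed, labeled
#' derivation so that each component of a synthetic session is individually
#' reproducible regardless of the order in which components are generated.
#'
#' @param seed Master integer seed.
#' @param label Character stream label (e.g. `"trajectory"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)^2) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h * 9349 + 1) %% 2147483647)
}

# run a thunk under a derived seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Analytic signal by the FFT construction: zero out negative frequencies,
# double positive ones.  Mod() of the result is the instantaneous envelope.
# The input is reflection-padded to a highly composite length (factors 2/3/5)
# so the FFT stays O(n log n) for awkward lengths, then truncated back.
analytic_signal <- function(x) {
  n0 <- length(x)
  if (n0 < 2L) stop("signal too short for analytic transform")
  m <- stats::nextn(n0, c(2L, 3L, 5L))
  if (m > n0) {
    pad <- m - n0
    x <- c(x, rev(x)[seq_len(pad)])
  }
  out <- analytic_core(x)[seq_len(n0)]
  out
}

analytic_core <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Gaussian smoothing with a unit-mass kernel; output has the input's length.
gaussian_smooth <- function(x, sd_samples, radius = ceiling(4 * sd_samples)) {
  if (sd_samples <= 0) return(x)
  k <- stats::dnorm(seq(-radius, radius), sd = sd_samples)
  k <- k / sum(k)
  n <- length(x)
  xp <- c(rep(x[1L], radius), x, rep(x[n], radius))
  out <- stats::filter(xp, k, sides = 2L)
  as.numeric(out[(radius + 1L):(radius + n)])
}

# --- interval algebra ------------------------------------------------------
# Intervals are data.frames with columns t_start, t_end (seconds).

empty_intervals <- function() {
  data.frame(t_start = numeric(0), t_end = numeric(0))
}

# TRUE for each point t that falls inside any [t_start, t_end) interval
in_intervals <- function(t, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) return(rep(FALSE, length(t)))
  o <- order(intervals$t_start)
  s <- intervals$t_start[o]
  e <- intervals$t_end[o]
  idx <- findInterval(t, s)
  idx > 0L & t < e[pmax(idx, 1L)]
}

# does each interval in a intersect any interval in b?
intervals_overlap_any <- function(a, b) {
  if (nrow(a) == 0L) return(logical(0))
  if (nrow(b) == 0L) return(rep(FALSE, nrow(a)))
  vapply(seq_len(nrow(a)), function(i) {
    any(a$t_start[i] < b$t_end & a$t_end[i] > b$t_start)
  }, logical(1))
}

# contiguous runs of TRUE in a logical vector -> matrix of (first, last) indices
logical_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(first = starts[keep], last = ends[keep])
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
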