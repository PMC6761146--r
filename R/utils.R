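#' Convert a current/voltage pair to conductance
#'
#' Ohm's law with the unit convention used throughout the package:
#' currents in pA, voltages in mV, conductances in pS, so
#' G\[pS\] = 1000 * |I\[pA\]| / |V\[mV\]|. The factor 1000 lives here once.
#'
#' @param i_pa current in pA.
#' @param v_mv holding potential in mV (non-zero).
#' @return conductance in pS (always positive).
#' @export
conductance_ps <- function(i_pa, v_mv) {
  if (any(v_mv == 0)) stop("conductance undefined at v_mv = 0")
  1000 * abs(i_pa) / abs(v_mv)
}

# Deterministic child-seed derivation: keeps every derived seed a positive
# 32-bit integer so set.seed() never overflows. Exact in double arithmetic
# because all intermediates stay below 2^53.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  m <- 2147483647
  s <- seed %% m
  for (k in seq_along(idx)) {
    s <- (s * 48271 + idx[k] * 2654435) %% m
  }
  as.integer(s %% (m - 2L) + 1L)
}

# Run code under a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Local-maximum finder with topographic prominence, on a numeric vector.
# Plateaus are collapsed to their centre index. Returns a data.frame
# (index, height, prominence) sorted by index.
find_peaks <- function(y) {
  n <- length(y)
  if (n < 3) return(data.frame(index = integer(), height = numeric(),
                               prominence = numeric()))
  # candidate peaks: strictly above the nearest differing neighbour each side
  idx <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (y[i] > y[i - 1]) {
      j <- i
      while (j < n && y[j + 1] == y[i]) j <- j + 1
      if (j < n && y[j + 1] < y[i]) {
        idx <- c(idx, as.integer(floor((i + j) / 2)))
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  if (!length(idx)) return(data.frame(index = integer(), height = numeric(),
                                      prominence = numeric()))
  prom <- vapply(idx, function(p) {
    h <- y[p]
    left_min <- h
    saddle_l <- NA_real_
    for (k in seq(p - 1, 1)) {
      if (y[k] > h) { saddle_l <- left_min; break }
      left_min <- min(left_min, y[k])
    }
    if (is.na(saddle_l)) saddle_l <- left_min
    right_min <- h
    saddle_r <- NA_real_
    if (p < n) {
      for (k in seq(p + 1, n)) {
        if (y[k] > h) { saddle_r <- right_min; break }
        right_min <- min(right_min, y[k])
      }
    }
    if (is.na(saddle_r)) saddle_r <- right_min
    h - max(saddle_l, saddle_r)
  }, numeric(1))
  data.frame(index = idx, height = y[idx], prominence = prom)
}

# Rolling mean and SD over fixed-width windows inside one contiguous segment,
# via cumulative sums (O(n)). Returns list(mean, sd) of length n - w + 1.
rolling_stats <- function(x, w) {
  n <- length(x)
  if (w > n) return(list(mean = numeric(0), sd = numeric(0)))
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  s <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
  s2 <- cs2[(w + 1):(n + 1)] - cs2[1:(n - w + 1)]
  m <- s / w
  v <- pmax(0, (s2 - s^2 / w) / max(1, w - 1))
  list(mean = m, sd = sqrt(v))
}
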