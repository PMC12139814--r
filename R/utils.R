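# Internal helpers shared across modules.

# Evaluate an expression with a temporary RNG state seeded from `seed`,
# restoring the caller's .Random.seed afterwards so generators are
# reproducible without clobbering user RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(x)
}

# Count events per half-open 1-min bin [k, k+1) over [from_min, to_min).
# times are in seconds relative to injection.
bin_counts_min <- function(times_s, from_min, to_min) {
  edges <- seq(from_min, to_min)
  n <- length(edges) - 1L
  t_min <- times_s / 60
  idx <- floor(t_min - from_min) + 1L
  keep <- t_min >= from_min & t_min < to_min
  counts <- tabulate(idx[keep], nbins = n)
  names(counts) <- edges[-length(edges)]
  counts
}

# Mean of a uniformly sampled signal per half-open 1-min bin; partial
# trailing bin dropped.
bin_mean_min <- function(t_s, x, from_min = NULL) {
  if (is.null(from_min)) from_min <- floor(min(t_s) / 60)
  t_min <- t_s / 60
  idx <- floor(t_min - from_min)
  nmax <- max(idx) + 1L
  s <- tapply(x, factor(idx, levels = 0:(nmax - 1L)), mean)
  n_per <- tabulate(idx + 1L, nbins = nmax)
  # drop trailing bin if it has fewer samples than the modal bin size
  n_mode <- as.integer(names(which.max(table(n_per[n_per > 0]))))
  keep <- seq_len(nmax)
  if (n_per[nmax] < n_mode) keep <- keep[-nmax]
  out <- as.numeric(s[keep])
  names(out) <- from_min + keep - 1L
  out
}

# Trapezoidal integral of piecewise-linear (t, y) restricted to [a, b],
# interpolating at the window edges. Values outside the observed span are
# handled per `boundary`: "extend" holds the nearest observation constant,
# "zero" anchors with 0 at the window edge.
trapz_window <- function(t, y, a, b, boundary = c("extend", "zero")) {
  boundary <- match.arg(boundary)
  if (a >= b) stop("window must have a < b", call. = FALSE)
  o <- order(t); t <- t[o]; y <- y[o]
  edge_val <- function(tt) {
    if (tt <= t[1]) return(if (boundary == "extend") y[1] else 0)
    if (tt >= t[length(t)]) return(if (boundary == "extend") y[length(y)] else 0)
    approx(t, y, xout = tt)$y
  }
  inside <- t > a & t < b
  tt <- c(a, t[inside], b)
  yy <- c(edge_val(a), y[inside], edge_val(b))
  sum(diff(tt) * (head(yy, -1) + tail(yy, -1)) / 2)
}

# Strict local maxima/minima indices of a numeric vector (plateaus excluded).
local_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(0), min = integer(0)))
  d <- diff(x)
  up <- d > 0
  dn <- d < 0
  i <- 2:(n - 1)
  list(max = i[up[i - 1] & dn[i]], min = i[dn[i - 1] & up[i]])
}
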