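#' Construct a taper set
#'
#' Low-level constructor wrapping a matrix of tapers (one per column). Most
#' users should call [make_slepian_tapers()]; this constructor exists so
#' that non-Slepian tapers (for example a rectangular taper, which turns the
#' multitaper estimator into the ordinary periodogram) can be injected.
#'
#' @param tapers numeric matrix, `n_samples` rows by `K` columns, each
#'   column unit Euclidean norm.
#' @param time_half_bandwidth the dimensionless time-half-bandwidth product
#'   NW, or `NA` for non-Slepian tapers.
#' @param concentrations optional per-taper fraction of spectral energy
#'   inside the design band.
#' @return An object of class `taper_set` with fields `tapers`, `n_samples`,
#'   `k`, `time_half_bandwidth`, `concentrations`.
#' @export
taper_set <- function(tapers, time_half_bandwidth = NA_real_,
                      concentrations = NULL) {
  tapers <- as.matrix(tapers)
  if (!is.numeric(tapers) || nrow(tapers) < 2L) {
    stop("`tapers` must be a numeric matrix with >= 2 rows", call. = FALSE)
  }
  norms <- sqrt(colSums(tapers^2))
  if (any(abs(norms - 1) > 1e-8)) {
    stop("each taper must have unit Euclidean norm", call. = FALSE)
  }
  structure(
    list(tapers = tapers, n_samples = nrow(tapers), k = ncol(tapers),
         time_half_bandwidth = time_half_bandwidth,
         concentrations = concentrations),
    class = "taper_set"
  )
}

#' @export
print.taper_set <- function(x, ...) {
  cat(sprintf("<taper_set> K = %d tapers, N = %d samples, NW = %s\n",
              x$k, x$n_samples, format(x$time_half_bandwidth)))
  if (!is.null(x$concentrations)) {
    cat("  concentrations:", paste(signif(x$concentrations, 7), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' A unit-norm rectangular taper set
#'
#' With this single taper the multitaper spectrum estimator reduces to the
#' ordinary periodogram.
#'
#' @param n_samples taper length.
#' @return A [taper_set()] with one constant column `1/sqrt(n_samples)`.
#' @export
rectangular_taper <- function(n_samples) {
  taper_set(matrix(1 / sqrt(n_samples), nrow = n_samples, ncol = 1L))
}

#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` discrete prolate spheroidal sequences of length
#' `n_samples` with time-half-bandwidth product NW, ordered by decreasing
#' spectral concentration in the band `|f| <= W` with `W = NW / n_samples`
#' cycles per sample. By default `k = 2 NW - 1` tapers are returned, the
#' count conventionally used with the multitaper spectrum estimator.
#'
#' The sequences are eigenvectors of the classical symmetric tridiagonal
#' matrix that commutes with the band-concentration kernel; the leading
#' eigenvalues are located by Sturm-sequence bisection and the eigenvectors
#' by inverse iteration with a final Rayleigh-Ritz refinement, which keeps
#' the tapers orthonormal to machine precision even at large `n_samples`.
#' Per-taper band concentrations are evaluated afterwards on a zero-padded
#' FFT grid. Results are cached per `(n_samples, NW, k)` within a session.
#'
#' @param n_samples sequence length (>= 8).
#' @param time_half_bandwidth NW >= 1 (dimensionless). Bandwidth in Hz for a
#'   signal sampled at `fs` is `NW * fs / n_samples`.
#' @param k number of tapers; default `2 * NW - 1`.
#' @return A [taper_set()] with concentrations filled in.
#' @examples
#' ts <- make_slepian_tapers(256, 3)
#' ts$k                       # 5 tapers
#' max(abs(crossprod(ts$tapers) - diag(ts$k)))   # orthonormal
#' @export
make_slepian_tapers <- function(n_samples, time_half_bandwidth, k = NULL) {
  stopifnot_scalar_number(n_samples, "n_samples", positive = TRUE)
  stopifnot_scalar_number(time_half_bandwidth, "time_half_bandwidth",
                          positive = TRUE)
  n_samples <- as.integer(n_samples)
  if (n_samples < 8L) stop("`n_samples` must be >= 8", call. = FALSE)
  nw <- time_half_bandwidth
  if (nw < 1) stop("`time_half_bandwidth` must be >= 1", call. = FALSE)
  k_max <- as.integer(round(2 * nw - 1))
  if (is.null(k)) k <- k_max
  k <- as.integer(k)
  if (k < 1L || k > k_max) {
    stop(sprintf("`k` must be in 1..%d (= 2 NW - 1)", k_max), call. = FALSE)
  }
  if (nw >= n_samples / 2) {
    stop("`time_half_bandwidth` too large for `n_samples`", call. = FALSE)
  }

  key <- sprintf("dpss_%d_%s_%d", n_samples, format(nw, digits = 12), k)
  if (!is.null(.gf_cache[[key]])) return(.gf_cache[[key]])

  V <- dpss_eigenvectors(n_samples, nw / n_samples, k)
  conc <- apply(V, 2, taper_concentration, w = nw / n_samples)
  out <- taper_set(V, time_half_bandwidth = nw, concentrations = conc)
  .gf_cache[[key]] <- out
  out
}

# Eigenvectors of the Slepian tridiagonal matrix for the k largest
# eigenvalues (eigenvalue order matches band-concentration order).
dpss_eigenvectors <- function(n, w, k) {
  i <- 0:(n - 1)
  dv <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  ev <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  e2 <- ev^2

  # Sturm count, vectorised over candidate points x
  sturm_count <- function(x) {
    cnt <- integer(length(x))
    d <- dv[1] - x
    cnt <- cnt + (d < 0)
    for (j in 2:n) {
      d <- dv[j] - x - e2[j - 1] / d
      bad <- abs(d) < 1e-300
      if (any(bad)) d[bad] <- -1e-300
      cnt <- cnt + (d < 0)
    }
    cnt
  }

  rad <- c(0, ev) + c(ev, 0)
  lo0 <- min(dv - rad)
  hi0 <- max(dv + rad)
  lo <- rep(lo0, k)
  hi <- rep(hi0, k)
  target <- n - seq_len(k)  # count(x) <= target  <=>  x below j-th largest
  scale <- max(abs(lo0), abs(hi0))
  for (iter in 1:80) {
    mid <- (lo + hi) / 2
    below <- sturm_count(mid) <= target
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < 1e-10 * scale) break
  }
  theta <- (lo + hi) / 2

  tri_mult <- function(v) dv * v + c(ev * v[-1], 0) + c(0, ev * v[-n])

  V <- matrix(0, n, k)
  start <- with_seed(871543L, matrix(rnorm(n * k), n, k))
  for (j in seq_len(k)) {
    A <- Matrix::bandSparse(
      n, n, k = c(-1L, 0L, 1L),
      diagonals = list(ev, dv - theta[j] + 1e-8 * max(abs(theta[j]), 1), ev)
    )
    v <- start[, j]
    for (it in 1:4) {
      v <- as.numeric(Matrix::solve(A, v))
      if (j > 1L) {
        prev <- V[, seq_len(j - 1L), drop = FALSE]
        v <- v - prev %*% crossprod(prev, v)
      }
      v <- v / sqrt(sum(v^2))
    }
    V[, j] <- v
  }

  # Rayleigh-Ritz: diagonalise the projected operator so near-degenerate
  # pairs cannot remain mixed, then order by decreasing eigenvalue.
  Q <- qr.Q(qr(V))
  H <- crossprod(Q, apply(Q, 2, tri_mult))
  eh <- eigen((H + t(H)) / 2, symmetric = TRUE)
  V <- Q %*% eh$vectors[, order(eh$values, decreasing = TRUE), drop = FALSE]

  # sign convention: symmetric tapers have positive mean, antisymmetric
  # tapers a positive leading half-sum
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) > 1e-7) {
      if (s < 0) V[, j] <- -V[, j]
    } else if (sum(V[seq_len(n %/% 2), j]) < 0) {
      V[, j] <- -V[, j]
    }
  }
  V
}

#' Fraction of a taper's spectral energy inside `|f| <= w`
#'
#' @param v numeric taper.
#' @param w band half-width in cycles per sample.
#' @param pad zero-padding factor for the FFT energy integral.
#' @return scalar in (0, 1].
#' @export
taper_concentration <- function(v, w, pad = 64) {
  n <- length(v)
  nfft <- next_pow2(n * pad)
  p <- Mod(fft(c(v, numeric(nfft - n))))^2
  f <- (0:(nfft - 1)) / nfft
  f[f > 0.5] <- f[f > 0.5] - 1
  sum(p[abs(f) <= w]) / sum(p)
}
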