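#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computes the first `k` DPSS tapers of length `n` with time-bandwidth
#' product `nw`, via the eigenvectors of the standard symmetric tridiagonal
#' matrix. Tapers are unit-norm and sign-fixed so that each taper has a
#' nonnegative mean (even orders) or a nonnegative initial slope (odd
#' orders), the usual convention.
#'
#' @param n Taper length in samples.
#' @param nw Time-bandwidth product (window length times half-bandwidth).
#' @param k Number of tapers; default `floor(2 * nw - 1)`.
#' @return An `n` x `k` matrix, one taper per column, unit Euclidean norm.
#' @export
dpss_tapers <- function(n, nw, k = max(1L, floor(2 * nw - 1))) {
  if (n < 2) stop("taper length must be >= 2")
  if (nw <= 0 || nw >= n / 2) stop("nw must lie in (0, n/2)")
  if (k < 1 || k > n) stop("invalid taper count")
  key <- paste(n, nw, k, sep = "_")
  cached <- .dpss_cache[[key]]
  if (!is.null(cached)) return(cached)
  w <- nw / n
  i <- 0:(n - 1)
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  diag_off <- (1:(n - 1)) * (n - (1:(n - 1))) / 2
  tm <- matrix(0, n, n)
  tm[cbind(i + 1, i + 1)] <- diag_main
  tm[cbind(1:(n - 1), 2:n)] <- diag_off
  tm[cbind(2:n, 1:(n - 1))] <- diag_off
  ev <- eigen(tm, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (j %% 2 == 1) {
      if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
    } else {
      slope <- sum(tap[, j] * i)
      if (slope < 0) tap[, j] <- -tap[, j]
    }
  }
  .dpss_cache[[key]] <- tap
  tap
}

.dpss_cache <- new.env(parent = emptyenv())

#' Multitaper cross-spectral density
#'
#' Welch-multitaper hybrid estimator: the recording is cut into
#' non-overlapping windows of `window_s` seconds, each window is demeaned,
#' tapered with DPSS tapers of half-bandwidth `taper_bandwidth`, Fourier
#' transformed, and the per-frequency channel cross-products are averaged
#' over all windows and tapers. The result is one-sided (0 to Nyquist) with
#' interior bins doubled, so the diagonal sums over frequency bins to the
#' channel variance (Parseval).
#'
#' @param rec A `ts_recording`.
#' @param window_s Window length in seconds (default 1 s, giving 1 Hz bins).
#' @param freq_resolution Spacing of the frequency grid in Hz; defaults to
#'   `1 / window_s`. Finer grids are obtained by zero padding and must not
#'   exceed the taper bandwidth.
#' @param taper_bandwidth Half-bandwidth of spectral smoothing in Hz
#'   (default 2.5 Hz).
#' @return A `cross_spectrum`: list with `freqs` (Hz, ascending), `S`
#'   (channels x channels x frequencies complex array, Hermitian per
#'   frequency), `n_avg` (windows times tapers) and `labels`.
#' @export
compute_csd <- function(rec, window_s = 1, freq_resolution = 1 / window_s,
                        taper_bandwidth = 2.5) {
  stopifnot(inherits(rec, "ts_recording"))
  fs <- rec$fs
  win_len <- round(window_s * fs)
  if (nrow(rec$data) < 2 * win_len)
    stop("recording too short: need at least 2 windows of ", window_s, " s")
  if (freq_resolution > taper_bandwidth + 1e-12)
    stop("freq_resolution must not exceed taper_bandwidth")
  nfft <- round(fs / freq_resolution)
  if (nfft < win_len) stop("freq_resolution finer than fs/window length required")
  if (nfft %% 2 == 1) nfft <- nfft + 1
  nw <- window_s * taper_bandwidth
  k_tap <- max(1L, floor(2 * nw - 1))
  tapers <- dpss_tapers(win_len, nw, k_tap)

  nchan <- ncol(rec$data)
  n_win <- floor(nrow(rec$data) / win_len)
  nfreq <- nfft %/% 2 + 1
  S <- array(0 + 0i, dim = c(nchan, nchan, nfreq))
  # window index matrix: win_len x n_win per channel
  idx <- matrix(seq_len(win_len * n_win), nrow = win_len)
  chunk <- max(1L, min(n_win, floor(4e6 / (nfft * nchan))))
  starts <- seq(1L, n_win, by = chunk)
  for (k in seq_len(k_tap)) {
    h <- tapers[, k]
    for (s0 in starts) {
      wsel <- s0:min(s0 + chunk - 1L, n_win)
      nb <- length(wsel)
      # build win_len x (nchan*nb) matrix of tapered, demeaned windows
      seg <- matrix(0, nrow = nfft, ncol = nchan * nb)
      for (ci in seq_len(nchan)) {
        block <- matrix(rec$data[as.vector(idx[, wsel]), ci], nrow = win_len)
        block <- sweep(block, 2, colMeans(block), "-") * h
        seg[seq_len(win_len), (ci - 1L) * nb + seq_len(nb)] <- block
      }
      X <- stats::mvfft(seg)[seq_len(nfreq), , drop = FALSE]
      for (f in seq_len(nfreq)) {
        Z <- matrix(X[f, ], nrow = nb)          # windows x channels
        A <- Re(Z); B <- Im(Z)
        # t(Z)* conj(Z) accumulated with real BLAS
        S[, , f] <- S[, , f] +
          (crossprod(A) + crossprod(B)) + 1i * (crossprod(B, A) - crossprod(A, B))
      }
    }
  }
  n_avg <- n_win * k_tap
  S <- S / (n_avg * nfft)
  # one-sided: double interior bins (not DC, not Nyquist)
  if (nfreq > 2) S[, , 2:(nfreq - 1)] <- 2 * S[, , 2:(nfreq - 1)]
  freqs <- (0:(nfreq - 1)) * fs / nfft
  structure(list(freqs = freqs, S = S, n_avg = n_avg, labels = rec$labels,
                 fs = fs),
            class = "cross_spectrum")
}

#' @export
print.cross_spectrum <- function(x, ...) {
  cat(sprintf("<cross_spectrum> %d channels, %d bins (%g-%g Hz), n_avg=%d\n",
              dim(x$S)[1], length(x$freqs), min(x$freqs), max(x$freqs),
              x$n_avg))
  invisible(x)
}

#' Restrict a cross-spectrum to a channel subset
#' @param csd A `cross_spectrum`.
#' @param labels Channel labels to keep, in order.
#' @return A `cross_spectrum` over the selected channels.
#' @export
csd_subset <- function(csd, labels) {
  ii <- match(labels, csd$labels)
  if (anyNA(ii)) stop("unknown channel(s): ",
                      paste(labels[is.na(ii)], collapse = ", "))
  csd$S <- csd$S[ii, ii, , drop = FALSE]
  csd$labels <- csd$labels[ii]
  csd
}

#' Magnitude-squared coherence spectrum
#'
#' `|S_ij(f)|^2 / (S_ii(f) S_jj(f))`, the frequency-resolved linear
#' association between channels `i` and `j`, in `[0, 1]`.
#'
#' @param csd A `cross_spectrum`.
#' @param i,j Channel labels or indices, `i != j`.
#' @return Numeric vector in `[0, 1]` with a `"freqs"` attribute.
#' @export
coherence <- function(csd, i, j) {
  ii <- .chan_index(csd, i); jj <- .chan_index(csd, j)
  if (ii == jj) stop("coherence requires two distinct channels")
  sii <- Re(csd$S[ii, ii, ]); sjj <- Re(csd$S[jj, jj, ])
  bad <- which(sii <= 0 | sjj <= 0)
  if (length(bad))
    stop(sprintf("zero auto-spectrum for channel %s at %g Hz",
                 ifelse(sii[bad[1]] <= 0, csd$labels[ii], csd$labels[jj]),
                 csd$freqs[bad[1]]))
  coh <- Mod(csd$S[ii, jj, ])^2 / (sii * sjj)
  coh <- pmin(pmax(coh, 0), 1)
  attr(coh, "freqs") <- csd$freqs
  coh
}

.chan_index <- function(csd, ch) {
  if (is.character(ch)) {
    ii <- match(ch, csd$labels)
    if (is.na(ii)) stop("unknown channel: ", ch)
    ii
  } else as.integer(ch)
}
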