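#' Epoched multichannel signal container
#'
#' @param data numeric array channels x epochs x samples, or a list of
#'   epochs x samples matrices (one per channel).
#' @param sample_rate_hz sampling rate (default 250).
#' @param epoch_seconds epoch length in seconds (default 2).
#' @export
epoched_signal <- function(data, sample_rate_hz = 250, epoch_seconds = 2) {
  if (is.list(data)) {
    data <- aperm(simplify2array(data), c(3, 1, 2))
  }
  if (length(dim(data)) != 3L) stop("data must be channels x epochs x samples")
  expected <- sample_rate_hz * epoch_seconds
  if (dim(data)[3] != expected) {
    stop("samples per epoch (", dim(data)[3], ") != sample_rate * epoch_seconds (",
         expected, ")")
  }
  structure(list(data = data, sample_rate_hz = sample_rate_hz,
                 epoch_seconds = epoch_seconds),
            class = "epoched_signal")
}

#' Binarize a signal epoch around its mean
#'
#' Samples strictly above the epoch mean map to 1, all others (including
#' ties) to 0.
#'
#' @param x numeric vector of samples.
#' @return integer vector of 0/1.
#' @export
binarize_epoch <- function(x) {
  if (length(x) == 0L) stop("empty epoch")
  if (any(!is.finite(x))) stop("non-finite samples")
  as.integer(x > mean(x))
}

#' Lempel-Ziv 1976 complexity of a binary sequence
#'
#' Returns the number of words in the LZ76 exhaustive-history parse: the
#' sequence is scanned left to right and a new word is closed each time the
#' current extension is no longer a substring of all the preceding material.
#' The dictionary size is a standard temporal-diversity (entropy proxy)
#' measure for binarized neural signals.
#'
#' @param b vector of 0/1 (or a character string of "0"/"1").
#' @return integer parse count (>= 1).
#' @export
lz76 <- function(b) {
  if (is.character(b)) b <- as.integer(strsplit(b, "")[[1]])
  if (length(b) == 0L) stop("empty sequence")
  if (!all(b %in% c(0L, 1L))) stop("non-binary input")
  s <- as.integer(b)
  n <- length(s)
  # exhaustive-history parse (Lempel & Ziv 1976, complexity c(n)).
  # i: history length; k: current match length; kmax: longest match so far
  cplx <- 1L
  i <- 0L; k <- 1L; kmax <- 1L; pos <- 1L
  if (n == 1L) return(1L)
  repeat {
    if (s[i + k] == s[pos + k]) {
      k <- k + 1L
      if (pos + k > n) {
        cplx <- cplx + 1L
        break
      }
    } else {
      if (k > kmax) kmax <- k
      i <- i + 1L
      if (i == pos) {
        cplx <- cplx + 1L
        pos <- pos + kmax
        if (pos + 1L > n) break
        i <- 0L; k <- 1L; kmax <- 1L
      } else {
        k <- 1L
      }
    }
  }
  cplx
}

#' Per-epoch channel-averaged signal diversity
#'
#' For every epoch, each channel is mean-binarized ([binarize_epoch()]) and
#' its LZ76 dictionary size computed; the per-epoch value is the mean over
#' channels. No normalization is applied to the counts.
#'
#' @param sig an [epoched_signal()].
#' @return object of class `diversity_series`: list with `values`
#'   (per-epoch means), `epoch_seconds`, and `aligned` (NULL until
#'   [hrf_align()] is applied).
#' @export
diversity_series <- function(sig) {
  d <- sig$data
  nch <- dim(d)[1]; nep <- dim(d)[2]
  vals <- vapply(seq_len(nep), function(e) {
    mean(vapply(seq_len(nch),
                function(ch) lz76(binarize_epoch(d[ch, e, ])),
                numeric(1)))
  }, numeric(1))
  structure(list(values = vals, epoch_seconds = sig$epoch_seconds,
                 aligned = NULL),
            class = "diversity_series")
}

#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style shape: response gamma peaking at 6 s, undershoot gamma peaking
#' at 16 s with ratio 1/6, 32 s support, unit peak.
#'
#' @param dt sampling interval in seconds.
#' @param duration kernel length in seconds (default 32).
#' @param peak,undershoot,ratio shape parameters.
#' @return numeric kernel sampled at `dt`.
#' @export
canonical_hrf <- function(dt, duration = 32, peak = 6, undershoot = 16,
                          ratio = 1 / 6) {
  t <- seq(0, duration, by = dt)
  # gamma densities with shape/scale chosen so modes sit at `peak`/`undershoot`
  h <- stats::dgamma(t, shape = peak, scale = 1) -
    ratio * stats::dgamma(t, shape = undershoot, scale = 1)
  h / max(h)
}

#' Align a diversity series to the fMRI volume grid
#'
#' Convolves the epoch-rate series with a canonical HRF sampled at the epoch
#' rate (full convolution truncated to the series length), then block-
#' averages onto the volume grid. With 2-s epochs at TR = 2 s the mapping is
#' one-to-one (epoch k to volume k).
#'
#' @param ds a `diversity_series` (or plain numeric vector with
#'   `epoch_seconds` supplied).
#' @param tr_seconds repetition time of the target grid.
#' @param n_volumes target length.
#' @param epoch_seconds needed if `ds` is a bare vector.
#' @param hrf optional kernel; default [canonical_hrf()] at the epoch rate.
#' @return the input `diversity_series` with `$aligned` filled (or, for a
#'   bare vector input, the aligned numeric vector).
#' @export
hrf_align <- function(ds, tr_seconds = 2, n_volumes,
                      epoch_seconds = NULL, hrf = NULL) {
  bare <- !inherits(ds, "diversity_series")
  vals <- if (bare) as.numeric(ds) else ds$values
  ep <- if (bare) {
    if (is.null(epoch_seconds)) stop("epoch_seconds required for bare vector")
    epoch_seconds
  } else ds$epoch_seconds
  if (is.null(hrf)) hrf <- canonical_hrf(dt = ep)
  if (length(vals) < length(hrf)) stop("series shorter than HRF kernel")
  conv <- stats::convolve(vals, rev(hrf), type = "open")[seq_along(vals)]
  fac <- tr_seconds / ep
  if (abs(fac - round(fac)) > 1e-9 || fac < 1) {
    stop("TR must be an integer multiple of the epoch length")
  }
  fac <- as.integer(round(fac))
  nfull <- length(conv) %/% fac
  vol <- colMeans(matrix(conv[seq_len(nfull * fac)], nrow = fac))
  if (length(vol) < n_volumes) {
    stop("series too short for ", n_volumes, " volumes")
  }
  vol <- vol[seq_len(n_volumes)]
  if (bare) return(vol)
  ds$aligned <- vol
  ds
}
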