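# Translation-only registration of a two-channel time series by
# cross-correlation against the first frame, computed via FFT on the
# summed-channel image, with subpixel refinement by parabolic
# interpolation of the correlation peak.

cross_correlation_shift <- function(ref, img) {
  # shift (dx, dy) that moves `img` onto `ref`
  n <- dim(ref)
  R <- stats::fft(ref - mean(ref))
  I <- stats::fft(img - mean(img))
  cc <- Re(stats::fft(R * Conj(I), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # parabolic subpixel refinement along each axis
  refine <- function(i, axis) {
    get <- function(k) {
      idx <- pk; idx[axis] <- ((idx[axis] - 1 + k) %% n[axis]) + 1
      cc[idx[1], idx[2]]
    }
    y0 <- get(-1); y1 <- get(0); y2 <- get(1)
    den <- y0 - 2 * y1 + y2
    if (den == 0) 0 else 0.5 * (y0 - y2) / den
  }
  wrap <- function(v, m) ifelse(v > m / 2, v - m, v)
  dy <- wrap(pk[1] - 1 + refine(pk, 1), n[1])
  dx <- wrap(pk[2] - 1 + refine(pk, 2), n[2])
  c(dx = unname(dx), dy = unname(dy))
}

# integer translation of a matrix, padding with the matrix edge value
shift_matrix <- function(m, dx, dy, fill = NULL) {
  n <- dim(m)
  if (is.null(fill)) fill <- stats::median(m[c(1, n[1]), ])
  out <- matrix(fill, n[1], n[2])
  src_r <- seq_len(n[1]) - dy; src_c <- seq_len(n[2]) - dx
  ok_r <- src_r >= 1 & src_r <= n[1]; ok_c <- src_c >= 1 & src_c <= n[2]
  out[ok_r, ok_c] <- m[src_r[ok_r], src_c[ok_c]]
  out
}

#' Register a time-lapse stack by translation
#'
#' Estimates a per-frame translation against the first frame by FFT
#' cross-correlation of the summed-channel image (with parabolic subpixel
#' refinement), then applies the rounded shift identically to both
#' channels.  A frame with zero variance cannot be registered; its shift
#' is carried forward from the previous frame.
#'
#' @param stack An `image_stack` with at least two frames.
#' @return The stack with aligned frames and an added `estimated_shifts`
#'   matrix (columns `dx`, `dy`; the displacement of each frame relative
#'   to the first, before correction).
#' @export
register_stack <- function(stack) {
  if (length(stack$frames) < 2) stop("need at least 2 frames to register")
  ref <- stack$frames[[1]]$cfp + stack$frames[[1]]$yfp
  est <- matrix(0, length(stack$frames), 2,
                dimnames = list(NULL, c("dx", "dy")))
  for (i in seq_along(stack$frames)[-1]) {
    img <- stack$frames[[i]]$cfp + stack$frames[[i]]$yfp
    if (stats::var(as.vector(img)) == 0) {
      warning(sprintf("frame %d has zero variance; carrying shift forward", i))
      est[i, ] <- est[i - 1, ]
    } else {
      est[i, ] <- -cross_correlation_shift(ref, img)
    }
    dxi <- round(est[i, 1]); dyi <- round(est[i, 2])
    if (dxi != 0 || dyi != 0) {
      stack$frames[[i]]$cfp <- shift_matrix(stack$frames[[i]]$cfp, -dxi, -dyi)
      stack$frames[[i]]$yfp <- shift_matrix(stack$frames[[i]]$yfp, -dxi, -dyi)
    }
  }
  stack$estimated_shifts <- est
  stack
}
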