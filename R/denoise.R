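#' Marchenko-Pastur PCA denoising with noise mapping
#'
#' Slides a local window over the 4-D series; in each window the voxel x
#' volume (Casorati) matrix is eigen-decomposed and eigenvalues compatible
#' with the Marchenko-Pastur bulk of pure noise are suppressed. The noise
#' level sigma is estimated per window from the mean of the bulk eigenvalues
#' and accumulated into a per-voxel sigma map. Overlapping windows are
#' averaged with uniform weights.
#'
#' The number of signal components p is the smallest p for which the spread
#' of the remaining eigenvalues fits the Marchenko-Pastur support width
#' `4 sigma^2 sqrt((R - p) / M)` (M window voxels, R = min(M, n_volumes));
#' the denoised window keeps only the top-p principal components.
#'
#' @param dataset A [dwi_dataset()].
#' @param window Length-3 odd integers, the sliding-window extent per axis
#'   (default 5 x 5 x 5). A window with fewer voxels than volumes triggers a
#'   warning (sigma estimation degrades).
#' @param stride Positive integer step of the sliding window (1 = fully
#'   overlapping). Windows are always placed flush with the far edge so
#'   every voxel is covered.
#' @return A list with `dataset` (denoised [dwi_dataset()]) and `noise_map`
#'   (3-D sigma array, same spatial shape).
#' @export
mppca_denoise <- function(dataset, window = c(5, 5, 5), stride = 1L) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  window <- rep(as.integer(window), length.out = 3)
  if (any(window %% 2L == 0L)) stop("window extents must be odd")
  dims <- dim(dataset$signal)[1:3]
  nv <- dim(dataset$signal)[4]
  if (any(window > dims))
    stop("window ", paste(window, collapse = "x"),
         " larger than image ", paste(dims, collapse = "x"))
  m <- prod(window)
  if (m < nv)
    warning("window holds ", m, " voxels for ", nv,
            " volumes; sigma estimation is unreliable below one voxel ",
            "per volume")
  sig <- dataset$signal
  dim(sig) <- c(prod(dims), nv)
  acc <- matrix(0, prod(dims), nv)
  cnt <- numeric(prod(dims))
  sig_acc <- numeric(prod(dims))

  starts <- function(n, w) {
    s <- seq.int(1L, max(1L, n - w + 1L), by = stride)
    if (s[length(s)] != n - w + 1L) s <- c(s, n - w + 1L)
    s
  }
  sx <- starts(dims[1], window[1])
  sy <- starts(dims[2], window[2])
  sz <- starts(dims[3], window[3])
  ox <- seq_len(window[1]) - 1L
  oy <- seq_len(window[2]) - 1L
  oz <- seq_len(window[3]) - 1L
  for (z0 in sz) for (y0 in sy) for (x0 in sx) {
    idx3 <- as.vector(outer(outer(x0 + ox,
                                  (y0 + oy - 1L) * dims[1], "+"),
                            (z0 + oz - 1L) * dims[1] * dims[2], "+"))
    X <- sig[idx3, , drop = FALSE]
    res <- mp_denoise_matrix(X, m)
    acc[idx3, ] <- acc[idx3, ] + res$X
    cnt[idx3] <- cnt[idx3] + 1
    sig_acc[idx3] <- sig_acc[idx3] + res$sigma
  }
  den <- acc / cnt
  noise <- sig_acc / cnt
  dim(den) <- c(dims, nv)
  dim(noise) <- dims
  list(dataset = dwi_dataset(den, dataset$scheme, dataset$voxel_size,
                             dataset$slice_axis),
       noise_map = noise)
}

## Core per-window step: X is an M x N Casorati matrix (voxels x volumes).
mp_denoise_matrix <- function(X, m) {
  n <- ncol(X)
  r <- min(m, n)
  C <- crossprod(X) / m              # N x N, eigenvalues of the covariance
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)          # descending
  p_sel <- r - 1L
  sig2 <- vals[r]
  for (p in 0:(r - 1L)) {
    tail_vals <- vals[(p + 1L):r]
    s2 <- mean(tail_vals)
    if (vals[p + 1L] - vals[r] <= 4 * sqrt((r - p) / m) * s2) {
      p_sel <- p
      sig2 <- s2
      break
    }
  }
  if (p_sel == 0L) {
    Xhat <- matrix(0, nrow(X), n)
  } else {
    V <- e$vectors[, seq_len(p_sel), drop = FALSE]
    Xhat <- X %*% V %*% t(V)
  }
  list(X = Xhat, sigma = sqrt(sig2), p = p_sel)
}

#' Mean noise sigma over a region
#'
#' @param noise_map 3-D sigma array from [mppca_denoise()].
#' @param mask Logical array of the same shape (or integer indices).
#' @return Scalar mean sigma over the mask.
#' @export
sigma_in_roi <- function(noise_map, mask) {
  v <- noise_map[mask]
  if (length(v) == 0) stop("empty mask: no voxels to average sigma over")
  mean(v)
}
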