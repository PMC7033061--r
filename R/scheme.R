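#' Diffusion gradient scheme
#'
#' A gradient scheme pairs one b-value (s/mm^2) with one gradient direction
#' per acquired volume. Directions of diffusion-weighted volumes (b > 0) must
#' be unit vectors; b = 0 volumes may carry a zero vector.
#'
#' @param bvalues Numeric vector of non-negative b-values, one per volume.
#' @param directions 3 x n numeric matrix of gradient directions (columns),
#'   one per volume.
#' @return An object of class `gradient_scheme` with elements `bvalues` and
#'   `directions`.
#' @export
gradient_scheme <- function(bvalues, directions) {
  bvalues <- as.numeric(bvalues)
  directions <- as.matrix(directions)
  if (nrow(directions) != 3L)
    stop("`directions` must be a 3 x n matrix (columns are directions)")
  if (length(bvalues) != ncol(directions))
    stop("one b-value and one direction per volume: got ",
         length(bvalues), " b-values and ", ncol(directions), " directions")
  if (any(!is.finite(bvalues)) || any(bvalues < 0))
    stop("b-values must be finite and non-negative")
  nrm <- sqrt(colSums(directions^2))
  dw <- bvalues > 0
  if (any(abs(nrm[dw] - 1) > 1e-6))
    stop("directions for b > 0 volumes must have unit norm (tolerance 1e-6)")
  structure(list(bvalues = bvalues, directions = directions),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  tab <- table(x$bvalues)
  cat("Gradient scheme:", length(x$bvalues), "volumes,",
      length(tab), "b-shells\n")
  cat(paste0("  b = ", names(tab), " (", as.integer(tab), "x)"), sep = "\n")
  invisible(x)
}

#' Number of volumes in a scheme
#' @param scheme A [gradient_scheme()].
#' @return Integer volume count.
#' @export
n_volumes <- function(scheme) length(scheme$bvalues)

## Quasi-uniform unit vectors on the upper hemisphere: golden-angle spiral,
## then a seeded random rotation so distinct shells get distinct sets.
spiral_directions <- function(n) {
  i <- seq_len(n)
  z <- (i - 0.5) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  rbind(r * cos(phi), r * sin(phi), z)
}

random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## Deterministic sub-seed for a named random substream.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 1009) %% 2147483629 + 1)
}

#' Multi-shell upper-leg acquisition scheme
#'
#' Builds the 56-volume, 10-shell scheme used throughout the package:
#' b = 0 (1 volume), 1 (8), 5 (3), 10 (3), 20 (3), 50 (3), 100 (3), 200 (10),
#' 400 (10), 600 (12) s/mm^2. Per-shell directions are quasi-uniform unit
#' vectors (golden-angle hemisphere spiral under a seeded random rotation);
#' the scheme is deterministic for a fixed seed.
#'
#' @param seed Integer seed controlling the per-shell direction sets.
#' @return A [gradient_scheme()] with 56 volumes.
#' @export
paper_scheme <- function(seed = 1L) {
  shells <- c(`0` = 1L, `1` = 8L, `5` = 3L, `10` = 3L, `20` = 3L, `50` = 3L,
              `100` = 3L, `200` = 10L, `400` = 10L, `600` = 12L)
  stopifnot(sum(shells) == 56L)
  with_seed(substream_seed(seed, "scheme"), {
    bvals <- numeric(0)
    dirs <- matrix(numeric(0), 3, 0)
    for (k in seq_along(shells)) {
      b <- as.numeric(names(shells)[k])
      n <- shells[[k]]
      if (b == 0) {
        d <- matrix(0, 3, n)
      } else {
        d <- random_rotation() %*% spiral_directions(n)
        d <- sweep(d, 2, sqrt(colSums(d^2)), "/")
      }
      bvals <- c(bvals, rep(b, n))
      dirs <- cbind(dirs, d)
    }
    gradient_scheme(bvals, dirs)
  })
}

#' IVIM parameter set
#'
#' The four parameters of the bi-exponential intravoxel incoherent motion
#' model: non-diffusion-weighted signal S0, perfusion fraction f, tissue
#' diffusivity D and pseudo-diffusivity Dp (both mm^2/s).
#'
#' @param s0 Non-diffusion-weighted signal (arbitrary units).
#' @param f Perfusion fraction in \[0, 1\].
#' @param d Tissue diffusivity, mm^2/s.
#' @param dp Pseudo-diffusivity, mm^2/s; must satisfy `dp >= d`.
#' @param converged Logical fit flag (TRUE for constructed parameters).
#' @return An object of class `ivim_params`.
#' @export
ivim_params <- function(s0 = 1, f = 0.05, d = 0.003, dp = 0.1,
                        converged = TRUE) {
  if (f < 0 || f > 1) stop("perfusion fraction f must lie in [0, 1]")
  if (d < 0) stop("tissue diffusivity d must be non-negative")
  if (dp < d) stop("pseudo-diffusivity dp must be >= d")
  structure(list(s0 = s0, f = f, d = d, dp = dp, converged = converged),
            class = "ivim_params")
}

#' Single-voxel diffusion tensor
#'
#' @param d Named numeric vector of the 6 unique tensor elements
#'   `c(dxx, dyy, dzz, dxy, dxz, dyz)` in mm^2/s, or a symmetric 3 x 3 matrix.
#' @param s0 Non-diffusion-weighted signal.
#' @return An object of class `tensor_voxel` with elements `d` (length-6
#'   vector) and `s0`.
#' @export
tensor_voxel <- function(d, s0 = 1) {
  if (is.matrix(d)) {
    if (!isTRUE(all.equal(d, t(d), tolerance = 1e-10)))
      stop("tensor matrix must be symmetric")
    d <- c(d[1, 1], d[2, 2], d[3, 3], d[1, 2], d[1, 3], d[2, 3])
  }
  if (length(d) != 6L) stop("tensor needs 6 unique elements")
  names(d) <- c("dxx", "dyy", "dzz", "dxy", "dxz", "dyz")
  structure(list(d = d, s0 = s0), class = "tensor_voxel")
}

## 6-vector -> symmetric 3x3
tensor_matrix <- function(d) {
  matrix(c(d[1], d[4], d[5],
           d[4], d[2], d[6],
           d[5], d[6], d[3]), 3, 3)
}

#' Forward IVIM-DTI signal model
#'
#' Predicts the diffusion-weighted signal for one voxel under the
#' bi-exponential IVIM model with an anisotropic tissue compartment:
#' \deqn{S(b, g) = S_0 [ f e^{-b D_p} + (1 - f) e^{-b g^T D g} ]}
#' At b = 0 the prediction equals S0. The perfusion compartment is isotropic.
#'
#' @param tensor A [tensor_voxel()] describing the tissue compartment. Its
#'   `s0` is ignored; S0 comes from `ivim`.
#' @param ivim An [ivim_params()] carrying S0, f and Dp.
#' @param scheme A [gradient_scheme()].
#' @return Numeric vector with one non-negative signal per volume.
#' @export
predict_signal <- function(tensor, ivim, scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  b <- scheme$bvalues
  g <- scheme$directions
  nrm <- sqrt(colSums(g^2))
  if (any(b > 0 & abs(nrm - 1) > 1e-6))
    stop("non-unit direction paired with b > 0")
  d <- tensor$d
  qf <- d[1] * g[1, ]^2 + d[2] * g[2, ]^2 + d[3] * g[3, ]^2 +
    2 * (d[4] * g[1, ] * g[2, ] + d[5] * g[1, ] * g[3, ] +
           d[6] * g[2, ] * g[3, ])
  ivim$s0 * (ivim$f * exp(-b * ivim$dp) + (1 - ivim$f) * exp(-b * qf))
}
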