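#' Default phantom configuration
#'
#' Tunable knobs of the synthetic bilateral upper-leg phantom. Muscles are
#' rendered as 14 parallel tubes (7 per leg) on the DTI grid; per-muscle
#' tensor eigenvalues are drawn within one published SD of the
#' perfusion-corrected reference values in [thigh_dti_reference()], fiber
#' directions lie near the slice axis, and every muscle carries an isotropic
#' perfusion compartment.
#'
#' @param s0 Non-diffusion-weighted muscle signal, arbitrary units.
#' @param f Perfusion fraction given to every muscle (overridable per
#'   muscle via `muscle_overrides`).
#' @param dp Pseudo-diffusivity of the perfusion compartment, mm^2/s.
#' @param fiber_dispersion_deg Maximum tilt of a muscle's principal fiber
#'   direction away from the slice axis, degrees.
#' @param roi_radius In-plane tube radius in voxels.
#' @param ring_radius Distance of the 6 outer tubes from the leg centre,
#'   voxels.
#' @param voxel_size Voxel edge lengths in mm.
#' @param muscle_overrides Named list: per muscle code (e.g. `"BFL"`), a list
#'   with any of `evals` (length-3, mm^2/s), `f`, `dp`.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(s0 = 100, f = 0.05, dp = 0.05,
                           fiber_dispersion_deg = 15,
                           roi_radius = 3.2, ring_radius = 8,
                           voxel_size = c(3, 3, 5),
                           muscle_overrides = list()) {
  structure(list(s0 = s0, f = f, dp = dp,
                 fiber_dispersion_deg = fiber_dispersion_deg,
                 roi_radius = roi_radius, ring_radius = ring_radius,
                 voxel_size = voxel_size,
                 muscle_overrides = muscle_overrides),
            class = "phantom_config")
}

## In-plane centres of 7 tubes per leg: one central + 6 on a ring.
leg_centres <- function(centre, ring_radius) {
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  rbind(c(centre[1], centre[2]),
        cbind(centre[1] + ring_radius * cos(ang),
              centre[2] + ring_radius * sin(ang)))
}

#' Generate the ground-truth phantom
#'
#' Builds the label volume and per-muscle ground truth (tensor eigenvalues,
#' fiber direction, perfusion parameters) for a bilateral leg phantom.
#' Deterministic for a fixed seed.
#'
#' @param n_slices Number of slices along the slice axis (default 30).
#' @param in_plane_shape Length-2 in-plane matrix size (default 64 x 48).
#' @param seed Integer seed.
#' @param config A [phantom_config()].
#' @return An object of class `phantom_truth`: `label_volume` (3-D integer
#'   array), `muscles` (data.frame with label, code, l1..l3 in mm^2/s, fiber
#'   direction, f, dp), `s0`, `config`, `seed`.
#' @export
generate_phantom <- function(n_slices = 30, in_plane_shape = c(64, 48),
                             seed = 1L, config = phantom_config()) {
  nx <- in_plane_shape[1]; ny <- in_plane_shape[2]
  rr <- config$ring_radius; rad <- config$roi_radius
  margin <- rr + rad + 1.5
  if (nx / 4 < margin || ny / 2 < margin || n_slices < 3)
    stop("shape ", nx, " x ", ny, " x ", n_slices,
         " too small to host 14 separated muscle tubes")
  lab_map <- muscle_label_map()
  centres <- rbind(leg_centres(c(nx * 0.25, ny * 0.5), rr),
                   leg_centres(c(nx * 0.75, ny * 0.5), rr))
  labels <- array(0L, dim = c(nx, ny, n_slices))
  xg <- matrix(seq_len(nx), nx, ny)
  yg <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  plane <- matrix(0L, nx, ny)
  for (l in 1:14) {
    inside <- (xg - centres[l, 1])^2 + (yg - centres[l, 2])^2 <= rad^2
    if (any(plane[inside] != 0L)) stop("muscle tubes overlap; enlarge shape")
    plane[inside] <- l
  }
  for (z in seq_len(n_slices)) labels[, , z] <- plane

  ref <- thigh_dti_reference()
  ref <- ref[ref$mode == "ivim", ]
  disp <- config$fiber_dispersion_deg * pi / 180
  muscles <- with_seed(substream_seed(seed, "phantom"), {
    out <- lapply(1:14, function(l) {
      code <- lab_map$code[l]
      r <- ref[ref$code == code, ]
      ev <- 1e-3 * sort(c(r$l1 + stats::runif(1, -1, 1) * r$l1_sd,
                          r$l2 + stats::runif(1, -1, 1) * r$l2_sd,
                          r$l3 + stats::runif(1, -1, 1) * r$l3_sd),
                        decreasing = TRUE)
      theta <- stats::runif(1, 0, disp)
      phi <- stats::runif(1, 0, 2 * pi)
      fib <- c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
      ov <- config$muscle_overrides[[code]]
      if (!is.null(ov$evals)) ev <- sort(ov$evals, decreasing = TRUE)
      f <- if (!is.null(ov$f)) ov$f else config$f
      dp <- if (!is.null(ov$dp)) ov$dp else config$dp
      data.frame(label = l, code = code, l1 = ev[1], l2 = ev[2], l3 = ev[3],
                 fx = fib[1], fy = fib[2], fz = fib[3], f = f, dp = dp)
    })
    do.call(rbind, out)
  })
  if (any(muscles$l3 <= 0)) stop("non-positive eigenvalue in phantom truth")
  if (any(muscles$f < 0 | muscles$f > 0.3))
    stop("phantom perfusion fraction must lie in [0, 0.3]")
  if (any(muscles$dp <= muscles$l1))
    stop("pseudo-diffusivity must exceed the largest eigenvalue")
  structure(list(label_volume = labels, muscles = muscles, s0 = config$s0,
                 config = config, seed = seed),
            class = "phantom_truth")
}

#' Ground-truth MD per muscle
#' @param truth A `phantom_truth`.
#' @return Named numeric vector, MD in mm^2/s per muscle code.
#' @export
truth_md <- function(truth) {
  stats::setNames((truth$muscles$l1 + truth$muscles$l2 + truth$muscles$l3) / 3,
                  truth$muscles$code)
}

## Full tensor (6-vector) of one muscle row: eigenbasis around the fiber.
muscle_tensor <- function(row) {
  e1 <- c(row$fx, row$fy, row$fz)
  e1 <- e1 / sqrt(sum(e1^2))
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  D <- row$l1 * tcrossprod(e1) + row$l2 * tcrossprod(e2) +
    row$l3 * tcrossprod(e3)
  tensor_voxel(D)
}

#' Render the noiseless phantom signal
#'
#' Evaluates the forward IVIM-DTI model ([predict_signal()]) for every muscle
#' voxel; background voxels are zero.
#'
#' @param truth A `phantom_truth` from [generate_phantom()].
#' @param scheme A [gradient_scheme()].
#' @return A [dwi_dataset()].
#' @export
render_noiseless <- function(truth, scheme) {
  dims <- dim(truth$label_volume)
  nv <- n_volumes(scheme)
  sig <- matrix(0, prod(dims), nv)
  for (i in seq_len(nrow(truth$muscles))) {
    row <- truth$muscles[i, ]
    sv <- predict_signal(muscle_tensor(row),
                         ivim_params(truth$s0, row$f, row$l2, row$dp),
                         scheme)
    idx <- which(truth$label_volume == row$label)
    sig[idx, ] <- matrix(sv, length(idx), nv, byrow = TRUE)
  }
  dim(sig) <- c(dims, nv)
  dwi_dataset(sig, scheme, voxel_size = truth$config$voxel_size)
}

#' Add Rician noise to a dataset
#'
#' Replaces each value S by `sqrt((S + n1)^2 + n2^2)` with n1, n2 independent
#' zero-mean Gaussians of standard deviation `sigma` — the magnitude-MRI
#' noise model. Deterministic per seed; `sigma = 0` returns the input
#' unchanged.
#'
#' @param dataset A [dwi_dataset()].
#' @param sigma Noise standard deviation, signal units.
#' @param seed Integer seed.
#' @return A [dwi_dataset()].
#' @export
add_rician_noise <- function(dataset, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(dataset)
  s <- dataset$signal
  noisy <- with_seed(substream_seed(seed, "rician"), {
    n1 <- stats::rnorm(length(s), 0, sigma)
    n2 <- stats::rnorm(length(s), 0, sigma)
    sqrt((s + n1)^2 + n2^2)
  })
  dim(noisy) <- dim(s)
  dwi_dataset(noisy, dataset$scheme, dataset$voxel_size, dataset$slice_axis)
}

#' Generate a paired-session phantom
#'
#' Emulates a two-visit test-retest acquisition: one nominal ground-truth
#' phantom, with each session's tensor eigenvalues multiplied per muscle by
#' an independent `1 + eps`, `eps ~ N(0, between_session_cv)` (so the SD of
#' the paired session difference is `sqrt(2) * cv` times the nominal value),
#' and independent Rician noise per session. The noise level is set so that
#' the mean b = 0 muscle signal over sigma equals `snr_target`
#' (`snr_target = Inf` gives noiseless sessions).
#'
#' @param n_slices,in_plane_shape,config Passed to [generate_phantom()].
#' @param scheme A [gradient_scheme()]; default [paper_scheme()] from the
#'   same seed.
#' @param snr_target Target b = 0 SNR inside muscle (> 0, may be `Inf`).
#' @param between_session_cv Coefficient of variation of the per-muscle
#'   session-2 diffusivity perturbation (>= 0).
#' @param seed Integer root seed; phantom, session effect and the two noise
#'   realizations use named substreams derived from it.
#' @return An object of class `session_pair`: `session1`, `session2`
#'   ([dwi_dataset()]s), `truth` (nominal), `truth1`, `truth2` (per-session
#'   perturbed truths), `sigma`, `seed`.
#' @export
generate_session_pair <- function(n_slices = 30, in_plane_shape = c(64, 48),
                                  snr_target = 40, between_session_cv = 0.03,
                                  seed = 1L, config = phantom_config(),
                                  scheme = paper_scheme(seed)) {
  stopifnot(snr_target > 0, between_session_cv >= 0)
  truth <- generate_phantom(n_slices, in_plane_shape, seed, config)
  eps <- with_seed(substream_seed(seed, "session-effect"),
                   matrix(stats::rnorm(28, 0, between_session_cv), 14, 2))
  perturb <- function(k) {
    tr <- truth
    tr$muscles[, c("l1", "l2", "l3")] <-
      truth$muscles[, c("l1", "l2", "l3")] * (1 + eps[, k])
    tr
  }
  truth1 <- perturb(1)
  truth2 <- perturb(2)
  sigma <- if (is.finite(snr_target)) truth$s0 / snr_target else 0
  s1 <- render_noiseless(truth1, scheme)
  s2 <- render_noiseless(truth2, scheme)
  if (sigma > 0) {
    s1 <- add_rician_noise(s1, sigma, substream_seed(seed, "noise-s1"))
    s2 <- add_rician_noise(s2, sigma, substream_seed(seed, "noise-s2"))
  }
  structure(list(session1 = s1, session2 = s2, truth = truth,
                 truth1 = truth1, truth2 = truth2, sigma = sigma,
                 seed = seed),
            class = "session_pair")
}
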