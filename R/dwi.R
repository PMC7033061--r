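#' 4-D diffusion-weighted dataset
#'
#' Couples a 4-D signal array (x, y, z, volume) with its gradient scheme and
#' voxel geometry. The 4th-axis length must equal the scheme's volume count
#' and all values must be finite.
#'
#' @param signal 4-D numeric array, non-negative, arbitrary units.
#' @param scheme A [gradient_scheme()].
#' @param voxel_size Length-3 numeric, voxel edge lengths in mm.
#' @param slice_axis Index of the through-slice image axis (default 3,
#'   axial acquisition).
#' @return An object of class `dwi_dataset`.
#' @export
dwi_dataset <- function(signal, scheme, voxel_size = c(3, 3, 5),
                        slice_axis = 3L) {
  if (length(dim(signal)) != 4L)
    stop("`signal` must be a 4-D array (x, y, z, volume)")
  if (dim(signal)[4] != n_volumes(scheme))
    stop("4th axis length (", dim(signal)[4],
         ") must equal scheme volume count (", n_volumes(scheme), ")")
  if (any(!is.finite(signal))) stop("signal values must all be finite")
  structure(list(signal = signal, scheme = scheme,
                 voxel_size = as.numeric(voxel_size),
                 slice_axis = as.integer(slice_axis)),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$signal)
  cat("DWI dataset:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "volumes; voxel size",
      paste(x$voxel_size, collapse = " x "), "mm\n")
  invisible(x)
}

#' Read / write a DWI dataset in NIfTI + FSL bval/bvec form
#'
#' `write_dwi()` stores the 4-D signal as NIfTI-1 with the voxel size in the
#' header, plus FSL-dialect sidecars: a one-row whitespace-separated `.bval`
#' file and a three-row `.bvec` file. `read_dwi()` reverses it; the
#' round-trip reproduces the signal bit-exactly (float storage) and the
#' scheme to 1e-6.
#'
#' @param dataset A [dwi_dataset()].
#' @param path_nifti Path of the NIfTI image (`.nii` or `.nii.gz`).
#' @param path_bval,path_bvec Paths of the b-value / b-vector sidecars;
#'   default to `path_nifti` with extensions swapped.
#' @return `read_dwi()` returns a [dwi_dataset()]; `write_dwi()` invisibly
#'   returns the three paths.
#' @export
write_dwi <- function(dataset, path_nifti,
                      path_bval = sidecar_path(path_nifti, "bval"),
                      path_bvec = sidecar_path(path_nifti, "bvec")) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  img <- RNifti::asNifti(dataset$signal)
  RNifti::pixdim(img) <- c(dataset$voxel_size, 1)
  RNifti::writeNifti(img, path_nifti, datatype = "double")
  writeLines(paste(format(dataset$scheme$bvalues, trim = TRUE,
                          scientific = FALSE), collapse = " "), path_bval)
  bv <- apply(dataset$scheme$directions, 1,
              function(r) paste(formatC(r, digits = 10, format = "g"),
                                collapse = " "))
  writeLines(bv, path_bvec)
  invisible(c(path_nifti, path_bval, path_bvec))
}

#' @rdname write_dwi
#' @param slice_axis Through-slice axis passed to [dwi_dataset()].
#' @export
read_dwi <- function(path_nifti, path_bval = sidecar_path(path_nifti, "bval"),
                     path_bvec = sidecar_path(path_nifti, "bvec"),
                     slice_axis = 3L) {
  for (p in c(path_nifti, path_bval, path_bvec))
    if (!file.exists(p)) stop("file not found: ", p)
  img <- RNifti::readNifti(path_nifti)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop("expected a 4-D image, got ", length(dim(arr)), "-D: ", path_nifti)
  bvals <- scan(path_bval, quiet = TRUE)
  bvec_rows <- readLines(path_bvec)
  bvec_rows <- bvec_rows[nzchar(trimws(bvec_rows))]
  if (length(bvec_rows) != 3L)
    stop("bvec file must have exactly 3 rows: ", path_bvec)
  dirs <- do.call(rbind, lapply(bvec_rows,
                                function(r) scan(text = r, quiet = TRUE)))
  if (length(bvals) != dim(arr)[4])
    stop("bval count (", length(bvals), ") does not match image volume ",
         "count (", dim(arr)[4], "): ", path_bval)
  if (ncol(dirs) != length(bvals))
    stop("bvec column count does not match bval count: ", path_bvec)
  vox <- RNifti::pixdim(img)[1:3]
  dwi_dataset(arr, gradient_scheme(bvals, dirs), voxel_size = vox,
              slice_axis = slice_axis)
}

sidecar_path <- function(path_nifti, ext) {
  base <- sub("\\.nii(\\.gz)?$", "", path_nifti)
  paste0(base, ".", ext)
}

#' Write a 3-D map as NIfTI
#' @param map 3-D numeric or integer array.
#' @param path Output path.
#' @param voxel_size Length-3 voxel size in mm.
#' @return Invisibly, `path`.
#' @export
write_map <- function(map, path, voxel_size = c(3, 3, 5)) {
  img <- RNifti::asNifti(map)
  RNifti::pixdim(img) <- c(voxel_size, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}
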