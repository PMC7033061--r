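## Shift a logical 3-D array by +/-1 along one axis, padding with FALSE.
shift_mask <- function(m, axis, by) {
  out <- array(FALSE, dim(m))
  n <- dim(m)[axis]
  if (n <= abs(by)) return(out)
  src <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  dst <- src
  src[[axis]] <- if (by > 0) 1:(n - by) else (1 - by):n
  dst[[axis]] <- if (by > 0) (1 + by):n else 1:(n + by)
  out <- do.call(`[<-`, c(list(out), dst, list(do.call(`[`, c(list(m), src)))))
  out
}

#' Erode a 3-D mask by one voxel (6-connected)
#'
#' A voxel survives if it and all six face neighbours are inside the mask;
#' voxels on the array border are removed.
#'
#' @param mask Logical 3-D array.
#' @return Logical 3-D array.
#' @export
erode_mask <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  out <- mask
  for (axis in 1:3) for (by in c(-1L, 1L))
    out <- out & shift_mask(mask, axis, by)
  out
}

#' Condition a muscle mask: erosion and middle-slice restriction
#'
#' Reproduces the ROI conditioning of the analysis chain: the binary mask of
#' one label is eroded one voxel (3-D, 6-connected) to guard against
#' boundary partial-volume voxels, then restricted to the `n_middle`
#' contiguous slices centred on the slice-axis midpoint (starting slice
#' `floor((n_slices - n_middle) / 2)`, 0-based).
#'
#' @param labels 3-D integer label array.
#' @param label The label id to extract.
#' @param n_middle Number of central slices to keep (default 20; all slices
#'   kept if the image has fewer).
#' @param slice_axis Through-slice axis (default 3).
#' @return Logical 3-D mask (possibly empty; callers must check).
#' @export
condition_mask <- function(labels, label, n_middle = 20L, slice_axis = 3L) {
  mask <- labels == label
  if (!any(mask)) stop("label ", label, " absent from label volume")
  mask <- erode_mask(mask)
  nz <- dim(mask)[slice_axis]
  if (nz > n_middle) {
    start0 <- floor((nz - n_middle) / 2)
    keep <- (start0 + 1):(start0 + n_middle)
    sel <- rep(list(quote(expr = )), 3)
    sel[[slice_axis]] <- setdiff(seq_len(nz), keep)
    mask <- do.call(`[<-`, c(list(mask), sel, list(FALSE)))
  }
  mask
}

#' Per-region SNR
#'
#' SNR of a muscle ROI: mean b = 0 signal over the mask divided by the mean
#' noise sigma over the mask.
#'
#' @param b0 3-D b = 0 signal array.
#' @param noise_map 3-D sigma array.
#' @param mask Logical 3-D mask, non-empty.
#' @return Scalar SNR (Inf with a warning when sigma is zero).
#' @export
roi_snr <- function(b0, noise_map, mask) {
  if (!any(mask)) stop("empty mask: cannot compute ROI SNR")
  s <- mean(b0[mask])
  sg <- mean(noise_map[mask])
  if (sg == 0) {
    warning("zero noise sigma in ROI: SNR is infinite")
    return(Inf)
  }
  s / sg
}

#' Per-muscle records for one session
#'
#' Computes, for every muscle label, the conditioned mask, its SNR and the
#' mean DTI indices over the mask for each fitted mode.
#'
#' @param subject Subject identifier.
#' @param session Session index (1 or 2).
#' @param labels 3-D integer label array.
#' @param results Named list of `tensor_result` objects, e.g.
#'   `list(standard = ..., ivim = ...)`.
#' @param noise_map 3-D sigma array.
#' @param b0 3-D b = 0 signal array.
#' @param label_map Data.frame mapping labels to muscle codes
#'   (default [muscle_label_map()]).
#' @param n_middle Central slices kept (default 20).
#' @param snr_threshold Muscles with SNR below this are marked excluded
#'   (default 20).
#' @return Data.frame with one row per muscle x mode: subject, session,
#'   muscle, side, code, mode, voxels, snr, included, and mean `l1`, `l2`,
#'   `l3`, `md`, `fa`.
#' @export
session_records <- function(subject, session, labels, results, noise_map, b0,
                            label_map = muscle_label_map(), n_middle = 20L,
                            snr_threshold = 20) {
  rows <- list()
  for (i in seq_len(nrow(label_map))) {
    lab <- label_map$label[i]
    mask <- condition_mask(labels, lab, n_middle)
    nvox <- sum(mask)
    snr <- if (nvox > 0) roi_snr(b0, noise_map, mask) else NA_real_
    for (mode in names(results)) {
      res <- results[[mode]]
      means <- if (nvox > 0) {
        vapply(c("l1", "l2", "l3", "md", "fa"),
               function(p) mean(res[[p]][mask], na.rm = TRUE), numeric(1))
      } else {
        stats::setNames(rep(NA_real_, 5), c("l1", "l2", "l3", "md", "fa"))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject = subject, session = session,
        muscle = label_map$muscle[i], side = label_map$side[i],
        code = label_map$code[i], mode = mode, voxels = nvox, snr = snr,
        included = !is.na(snr) && snr >= snr_threshold,
        l1 = means[["l1"]], l2 = means[["l2"]], l3 = means[["l3"]],
        md = means[["md"]], fa = means[["fa"]])
    }
  }
  do.call(rbind, rows)
}

#' Pair-wise SNR exclusion
#'
#' Applies the SNR inclusion rule (`included <=> snr >= threshold`) and the
#' pair-wise drop: a muscle contributes to repeatability only when both of
#' its sessions are included, so exclusion of either session removes the
#' pair.
#'
#' @param records Data.frame with at least `subject`, `session`, `code`,
#'   `snr` columns (e.g. from [session_records()] or [muscle_table()]).
#' @param snr_threshold SNR inclusion threshold (default 20).
#' @return The records with recomputed `included` and a new `pair_included`
#'   column.
#' @export
apply_snr_exclusion <- function(records, snr_threshold = 20) {
  records$included <- !is.na(records$snr) & records$snr >= snr_threshold
  key <- interaction(records$subject, records$code, drop = TRUE)
  ok <- tapply(records$included, key, all)
  records$pair_included <- as.vector(ok[key])
  records
}

#' Exclusion bookkeeping summary
#'
#' Counts records and SNR-based exclusions the way a test-retest study
#' reports them: total muscle records (subjects x muscles x sessions),
#' excluded records, exclusion percentage, complete muscle pairs remaining
#' and the records they contain.
#'
#' @param records Data.frame from [apply_snr_exclusion()] (one row per
#'   subject x session x muscle; deduplicated over `mode` if present).
#' @return A list: `n_records`, `n_excluded`, `pct_excluded` (one decimal),
#'   `n_pairs_remaining`, `n_records_remaining`.
#' @export
exclusion_summary <- function(records) {
  if ("mode" %in% names(records))
    records <- records[records$mode == records$mode[1], ]
  n <- nrow(records)
  n_exc <- sum(!records$included)
  key <- interaction(records$subject, records$code, drop = TRUE)
  pairs_ok <- tapply(records$included, key, all)
  list(n_records = n,
       n_excluded = n_exc,
       pct_excluded = round(100 * n_exc / n, 1),
       n_pairs_remaining = sum(pairs_ok),
       n_records_remaining = sum(records$included &
                                   as.vector(pairs_ok[key])))
}

#' Per-muscle table across a cohort
#'
#' Assembles the per-muscle records of every subject and session into one
#' table and applies the pair-wise SNR exclusion.
#'
#' @param subject_sessions A list; each element is a list with fields
#'   `subject`, `session`, `labels`, `results`, `noise_map`, `b0` as in
#'   [session_records()].
#' @param label_map,n_middle,snr_threshold Passed through.
#' @return Data.frame of records with `included` and `pair_included`.
#' @export
muscle_table <- function(subject_sessions, label_map = muscle_label_map(),
                         n_middle = 20L, snr_threshold = 20) {
  recs <- lapply(subject_sessions, function(ss)
    session_records(ss$subject, ss$session, ss$labels, ss$results,
                    ss$noise_map, ss$b0, label_map, n_middle, snr_threshold))
  apply_snr_exclusion(do.call(rbind, recs), snr_threshold)
}

#' Nearest-neighbour down-sampling of a high-resolution label volume
#'
#' Maps externally supplied segmentation labels drawn on a finer anatomical
#' grid onto the DTI grid by sampling the nearest source voxel centre.
#'
#' @param labels 3-D integer array on the source grid.
#' @param target_dim Length-3 target grid size.
#' @return 3-D integer array of size `target_dim`.
#' @export
resample_labels_nn <- function(labels, target_dim) {
  src <- dim(labels)
  ix <- pmin(src[1], pmax(1, round((seq_len(target_dim[1]) - 0.5) *
                                     src[1] / target_dim[1] + 0.5)))
  iy <- pmin(src[2], pmax(1, round((seq_len(target_dim[2]) - 0.5) *
                                     src[2] / target_dim[2] + 0.5)))
  iz <- pmin(src[3], pmax(1, round((seq_len(target_dim[3]) - 0.5) *
                                     src[3] / target_dim[3] + 0.5)))
  labels[ix, iy, iz, drop = FALSE]
}
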