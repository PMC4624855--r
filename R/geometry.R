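#' @title Trajectory geometry: superposition, RMSD, RMSF
#' @description Least-squares rigid-body superposition (Kabsch algorithm,
#'   proper rotations only) and the series statistics built on it: RMSD over
#'   frames, split RMSD of complex components, and residue RMSF.
#' @name trajectory-geometry
NULL

#' Kabsch superposition of two coordinate sets
#'
#' Finds the proper rotation and translation minimising the (optionally
#' weighted) RMSD between `mobile` and `reference`. Reflections are excluded,
#' so chirality is preserved.
#'
#' @param mobile,reference n x 3 coordinate matrices, Angstrom
#' @param weights optional non-negative per-point weights
#' @return list with `rotation` (3 x 3, det = +1), `translation` (length 3;
#'   the transform is `y = rotation %*% x + translation`), and `rmsd` (A)
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  n <- nrow(mobile)
  if (n != nrow(reference))
    rlang::abort("coordinate sets differ in size", class = "pcnmd_mismatch_error")
  if (n < 3)
    rlang::abort("need at least 3 points for superposition",
                 class = "pcnmd_degenerate_geometry")
  w <- if (is.null(weights)) rep(1, n) else weights
  w <- w / sum(w)
  cm_m <- colSums(mobile * w)
  cm_r <- colSums(reference * w)
  xm <- sweep(mobile, 2, cm_m)
  xr <- sweep(reference, 2, cm_r)
  sv_ref <- svd(xr)$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1))
    rlang::abort("reference points are (near-)collinear",
                 class = "pcnmd_degenerate_geometry")
  h <- t(xm * w) %*% xr
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- xm %*% t(rot)
  rmsd <- sqrt(sum(w * rowSums((fitted - xr)^2)))
  list(rotation = rot, translation = as.vector(cm_r - rot %*% cm_m),
       rmsd = rmsd)
}

apply_transform <- function(xyz, transform) {
  sweep(xyz %*% t(transform$rotation), 2, transform$translation, "+")
}

plain_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

#' RMSD time series of an ensemble
#'
#' Each frame is superposed onto the reference structure over `fit_sel`
#' (removing overall translation and rotation) and the RMSD is then computed
#' over `calc_sel`.
#'
#' @param ensemble a `pcn_ensemble`
#' @param fit_sel selection (expression or `pcn_selection`) used for fitting
#' @param calc_sel selection the RMSD is computed over (default: `fit_sel`)
#' @param units "A" (Angstrom) or "nm"
#' @return tibble with columns `time_ps`, `rmsd`
#' @export
rmsd_series <- function(ensemble, fit_sel = "name CA", calc_sel = fit_sel,
                        units = c("A", "nm")) {
  units <- match.arg(units)
  fit_idx <- selection_indices(ensemble$reference, fit_sel)
  calc_idx <- selection_indices(ensemble$reference, calc_sel)
  if (length(fit_idx) == 0 || length(calc_idx) == 0)
    rlang::abort("empty selection", class = "pcnmd_selection_empty")
  ref <- coords(ensemble$reference)
  vals <- vapply(seq_len(n_frames(ensemble)), function(i) {
    xyz <- ensemble$frames[i, , , drop = TRUE]
    tf <- kabsch_superpose(xyz[fit_idx, , drop = FALSE],
                           ref[fit_idx, , drop = FALSE])
    plain_rmsd(apply_transform(xyz[calc_idx, , drop = FALSE], tf),
               ref[calc_idx, , drop = FALSE])
  }, 0)
  if (units == "nm") vals <- vals * 0.1
  out <- tibble::tibble(time_ps = ensemble$times, rmsd = vals)
  attr(out, "units") <- units
  out
}

#' Split RMSD of the components of a complex
#'
#' Each component is independently fitted to its own reference coordinates
#' and RMSD'd, so the complex RMSD is not the sum of the split series: a
#' component can sit rigidly on its own frame while moving relative to its
#' partner.
#'
#' @inheritParams rmsd_series
#' @param sel_a,sel_b disjoint selections defining the two components
#' @return tibble with columns `time_ps`, `component`, `rmsd`
#' @export
split_rmsd <- function(ensemble, sel_a, sel_b, units = c("A", "nm")) {
  units <- match.arg(units)
  ia <- selection_indices(ensemble$reference, sel_a)
  ib <- selection_indices(ensemble$reference, sel_b)
  if (length(intersect(ia, ib)) > 0)
    rlang::abort("component selections overlap", class = "pcnmd_overlap")
  name_of <- function(s, fallback)
    if (inherits(s, "pcn_selection")) s$expression else
      if (is.character(s)) s else fallback
  out <- lapply(list(A = ia, B = ib), function(idx) {
    rmsd_series(ensemble, fit_sel = idx, calc_sel = idx, units = units)
  })
  dplyr::bind_rows(
    dplyr::mutate(out$A, component = name_of(sel_a, "A"), .after = "time_ps"),
    dplyr::mutate(out$B, component = name_of(sel_b, "B"), .after = "time_ps"))
}

#' Residue root-mean-square fluctuation
#'
#' `RMSF_i = sqrt(mean_t |x_i(t) - <x_i>|^2)`. With `fit = TRUE` frames are
#' first superposed onto the time-average structure (two superposition /
#' re-averaging passes, starting from the reference), removing rigid-body
#' motion. The per-residue value is the value of the residue's alpha-carbon.
#'
#' @param ensemble a `pcn_ensemble` with at least 2 frames
#' @param sel atom selection over which fluctuations are computed
#' @param fit superpose frames onto the time-average structure first?
#' @param per_residue collapse to one row per residue (its CA)?
#' @return tibble with columns `chain`, `res_seq`, `res_name`, `name`, `rmsf`
#' @export
rmsf <- function(ensemble, sel = "name CA", fit = TRUE, per_residue = TRUE) {
  if (n_frames(ensemble) < 2)
    rlang::abort("RMSF needs at least 2 frames",
                 class = "pcnmd_insufficient_frames")
  idx <- selection_indices(ensemble$reference, sel)
  if (length(idx) == 0)
    rlang::abort("empty selection", class = "pcnmd_selection_empty")
  f <- n_frames(ensemble)
  xs <- lapply(seq_len(f), function(i)
    ensemble$frames[i, idx, , drop = TRUE])
  if (fit && length(idx) >= 3) {
    ref <- coords(ensemble$reference)[idx, , drop = FALSE]
    for (pass in 1:2) {
      xs <- lapply(xs, function(x)
        apply_transform(x, kabsch_superpose(x, ref)))
      ref <- Reduce(`+`, xs) / f
    }
  }
  avg <- Reduce(`+`, xs) / f
  msf <- Reduce(`+`, lapply(xs, function(x) rowSums((x - avg)^2))) / f
  at <- ensemble$reference$atoms[idx, , drop = FALSE]
  out <- tibble::tibble(chain = at$chain, res_seq = at$res_seq,
                        res_name = at$res_name, name = at$name,
                        rmsf = sqrt(msf))
  if (per_residue) {
    out <- out[out$name == "CA", , drop = FALSE]
    if (nrow(out) == 0)
      rlang::abort("selection contains no alpha-carbons; use per_residue = FALSE",
                   class = "pcnmd_missing_atom")
  }
  out
}
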