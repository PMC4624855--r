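#' @title Essential dynamics: covariance PCA and cosine content
#' @description Principal component analysis of the covariance matrix of
#'   trajectory coordinates (after rigid-body superposition), eigenvector
#'   projections, and the cosine-content diagnostic of conformational
#'   sampling: projections resembling low-order cosines indicate random
#'   diffusive motion rather than converged sampling, with 0.5 the
#'   conventional cut-off.
#' @name essential-dynamics
NULL

#' Covariance PCA of a trajectory
#'
#' Frames are superposed onto the reference over `sel`, the covariance matrix
#' of the centred 3N coordinate vectors is diagonalised, and projections
#' `p_k(t) = (x(t) - <x>) . v_k` are returned along with per-component
#' variance fractions and cosine contents. Mass-unweighted, alpha-carbon
#' coordinates by default.
#'
#' @param ensemble a `pcn_ensemble` with at least 2 frames
#' @param sel atom selection (expression or `pcn_selection`)
#' @param fit superpose frames on the reference before the covariance?
#' @return a `pcn_pca` object: `eigenvalues` (descending, A^2), `eigenvectors`
#'   (3N x K orthonormal columns), `projections` (F x K, A),
#'   `variance_fraction`, `cosine_content`, `times`
#' @export
pca_trajectory <- function(ensemble, sel = "name CA", fit = TRUE) {
  if (n_frames(ensemble) < 2)
    rlang::abort("PCA needs at least 2 frames",
                 class = "pcnmd_insufficient_frames")
  idx <- selection_indices(ensemble$reference, sel)
  if (length(idx) == 0)
    rlang::abort("empty selection", class = "pcnmd_selection_empty")
  f <- n_frames(ensemble)
  ref <- coords(ensemble$reference)[idx, , drop = FALSE]
  rows <- lapply(seq_len(f), function(i) {
    x <- ensemble$frames[i, idx, , drop = TRUE]
    if (fit && length(idx) >= 3)
      x <- apply_transform(x, kabsch_superpose(x, ref))
    as.vector(t(x))
  })
  x <- do.call(rbind, rows)
  xc <- sweep(x, 2, colMeans(x))
  cv <- crossprod(xc) / (f - 1)
  eig <- eigen(cv, symmetric = TRUE)
  values <- pmax(eig$values, 0)
  proj <- xc %*% eig$vectors
  cc <- rep(NA_real_, ncol(proj))
  for (k in seq_along(cc)) {
    cc[k] <- if (values[k] > 1e-12 * max(values, 1e-300))
      cosine_content(proj[, k], times = ensemble$times) else NA_real_
  }
  structure(list(eigenvalues = values, eigenvectors = eig$vectors,
                 projections = proj,
                 variance_fraction = values / sum(values),
                 cosine_content = cc, times = ensemble$times,
                 n_atoms = length(idx)),
            class = "pcn_pca")
}

#' @export
print.pcn_pca <- function(x, ...) {
  k <- min(6, length(x$eigenvalues))
  cat(sprintf("<pcn_pca> %d frames x %d coordinates\n",
              nrow(x$projections), ncol(x$projections)))
  cat(sprintf("  leading variance fractions: %s\n",
              paste(sprintf("%.3f", x$variance_fraction[1:k]), collapse = " ")))
  cat(sprintf("  cosine content (PC1, PC2): %.3f, %.3f  [cut-off 0.5]\n",
              x$cosine_content[1], x$cosine_content[2]))
  invisible(x)
}

#' @describeIn pca_trajectory per-component summary: eigenvalue, variance
#'   fraction, cumulative variance, cosine content
#' @param x a `pcn_pca` object
#' @param ... unused
#' @method tidy pcn_pca
#' @export
tidy.pcn_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 variance_fraction = x$variance_fraction,
                 cumulative_variance = cumsum(x$variance_fraction),
                 cosine_content = x$cosine_content)
}

#' @describeIn pca_trajectory one-row summary: frames, coordinates, total
#'   variance, components needed for 99% variance, PC1/PC2 cosine content
#' @method glance pcn_pca
#' @export
glance.pcn_pca <- function(x, ...) {
  tibble::tibble(n_frames = nrow(x$projections),
                 n_coordinates = ncol(x$projections),
                 total_variance = sum(x$eigenvalues),
                 n_components_99 = which(cumsum(x$variance_fraction) >= 0.99)[1],
                 cosine_content_pc1 = x$cosine_content[1],
                 cosine_content_pc2 = x$cosine_content[2])
}

#' Long table of principal-component projections
#' @param pca a `pcn_pca`
#' @param components which components to include
#' @return tibble with columns `time_ps`, `component`, `projection`
#' @export
pca_projections <- function(pca, components = 1:2) {
  components <- components[components <= ncol(pca$projections)]
  dplyr::bind_rows(lapply(components, function(k)
    tibble::tibble(time_ps = pca$times, component = k,
                   projection = pca$projections[, k])))
}

#' Write the two extreme-projection frames along one component
#'
#' A two-model PDB holding the frames with minimal and maximal projection on
#' the chosen component: a lightweight stand-in for porcupine plots or PC
#' animations when inspecting a collective motion.
#'
#' @param pca a `pcn_pca`
#' @param ensemble the ensemble the PCA came from
#' @param component component number
#' @param file output path
#' @return invisibly, the two frame indices written
#' @export
write_extreme_frames <- function(pca, ensemble, component = 1, file) {
  p <- pca$projections[, component]
  pick <- c(which.min(p), which.max(p))
  lines <- unlist(lapply(seq_along(pick), function(m) {
    body <- write_pdb(frame_structure(ensemble, pick[m]))
    body <- body[!grepl("^END", body)]
    c(sprintf("MODEL     %4d", m), body, "ENDMDL")
  }))
  writeLines(c(lines, "END"), file)
  invisible(pick)
}

#' Cosine content of a projection series
#'
#' `c_i = (2/T) (integral cos(i pi t/T) p(t) dt)^2 / integral p(t)^2 dt`,
#' evaluated by trapezoid quadrature on the sampled, mean-centred series.
#' A value near 1 means the projection looks like the i-th cosine mode, the
#' signature of random diffusion; values below 0.5 are conventionally read
#' as satisfactory sampling.
#'
#' @param p numeric projection series (>= 4 samples)
#' @param times optional sample times; defaults to an even unit grid
#' @param order cosine order `i >= 1`
#' @return value in `[0, 1]`
#' @export
cosine_content <- function(p, times = NULL, order = 1) {
  stopifnot(order >= 1)
  n <- length(p)
  if (n < 4)
    rlang::abort("need at least 4 samples", class = "pcnmd_insufficient_frames")
  t <- if (is.null(times)) seq_len(n) - 1 else as.numeric(times)
  if (length(t) != n)
    rlang::abort("times length mismatch", class = "pcnmd_mismatch_error")
  p <- p - mean(p)
  denom <- trapezoid(t, p^2)
  if (denom <= 0)
    rlang::abort("cosine content undefined for an all-zero series",
                 class = "pcnmd_undefined_content")
  span <- t[n] - t[1]
  num <- trapezoid(t, cos(order * pi * (t - t[1]) / span) * p)
  min(1, (2 / span) * num^2 / denom)
}
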