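#' @title Synthetic structures, ensembles and benchmark graphs
#' @description Generators with known ground truth: ideal backbones (helix,
#'   strand, coil, two-domain), ensembles with static / harmonic / diffusive
#'   motion, and planted-partition random graphs. Every generator is
#'   deterministic given its seed, so fixtures double as reproducible test
#'   inputs for geometry, network and clustering code.
#' @name fixtures
NULL

# poly-alanine decoration around a CA trace: N, CA, C, O, CB per residue.
# Local frames are approximate; only CA positions carry the designed geometry.
decorate_backbone <- function(ca, chain) {
  n <- nrow(ca)
  tangent <- ca
  tangent[1, ] <- ca[min(2, n), ] - ca[1, ]
  if (n > 1) tangent[n, ] <- ca[n, ] - ca[n - 1, ]
  if (n > 2) tangent[2:(n - 1), ] <- ca[3:n, ] - ca[1:(n - 2), ]
  tangent <- tangent / sqrt(rowSums(tangent^2))
  up <- cbind(-tangent[, 2], tangent[, 1], rep(0.7, n))
  up <- up - tangent * rowSums(up * tangent)
  up <- up / sqrt(rowSums(up^2))
  side <- cbind(tangent[, 2] * up[, 3] - tangent[, 3] * up[, 2],
                tangent[, 3] * up[, 1] - tangent[, 1] * up[, 3],
                tangent[, 1] * up[, 2] - tangent[, 2] * up[, 1])
  pos <- list(N = ca - 1.2 * tangent + 0.8 * up,
              CA = ca,
              C = ca + 1.2 * tangent + 0.8 * up,
              O = ca + 1.6 * tangent + 1.9 * up,
              CB = ca - 1.5 * side + 0.3 * up)
  elements <- c(N = "N", CA = "C", C = "C", O = "O", CB = "C")
  rows <- lapply(seq_len(n), function(i) {
    tibble::tibble(name = names(pos), x = vapply(pos, function(p) p[i, 1], 0),
                   y = vapply(pos, function(p) p[i, 2], 0),
                   z = vapply(pos, function(p) p[i, 3], 0),
                   res_seq = i, element = unname(elements[names(pos)]))
  })
  at <- dplyr::bind_rows(rows)
  tibble::tibble(serial = seq_len(nrow(at)), name = at$name, alt = "",
                 res_name = "ALA", chain = chain, res_seq = at$res_seq,
                 i_code = "", x = at$x, y = at$y, z = at$z,
                 occupancy = 1, b = 0, element = at$element, is_het = FALSE)
}

helix_trace <- function(n, rise = 1.5, twist_deg = 100, radius = 2.3) {
  theta <- (seq_len(n) - 1) * twist_deg * pi / 180
  cbind(radius * cos(theta), radius * sin(theta), rise * (seq_len(n) - 1))
}

#' Generate an ideal synthetic backbone
#'
#' Residues are poly-alanine with N, CA, C, O, CB atoms so that surface-area
#' and interface code sees realistic atom counts. Kinds:
#' \describe{
#'   \item{helix}{alpha-helix: rise 1.5 A/residue, 100 deg twist, 2.3 A
#'     radius, giving consecutive CA-CA distances of ~3.8 A and the classic
#'     contact signature (contacts only at sequence separations 2-4 under a
#'     4-8 A band).}
#'   \item{strand}{extended zigzag with 3.8 A CA-CA steps.}
#'   \item{coil}{persistent random walk with 3.8 A steps (seeded).}
#'   \item{two_domain}{two helical domains joined by a 4-residue extended
#'     linker spanning a >= 12 A inter-domain gap; domain membership
#'     (1, NA for linker, 2) is stored in `attr(, "domain")`.}
#' }
#'
#' @param kind one of "helix", "strand", "coil", "two_domain"
#' @param n_residues number of residues (>= 2)
#' @param seed RNG seed (used by "coil" only)
#' @param chain chain identifier
#' @return a `pcn_structure`
#' @export
make_backbone <- function(kind = c("helix", "strand", "coil", "two_domain"),
                          n_residues, seed = 1, chain = "A") {
  kind <- match.arg(kind)
  if (n_residues < 2)
    rlang::abort("n_residues must be >= 2", class = "pcnmd_size_error")
  domain <- rep(1L, n_residues)
  ca <- switch(kind,
    helix = helix_trace(n_residues),
    strand = cbind(3.3 * (seq_len(n_residues) - 1),
                   0.94 * (-1)^(seq_len(n_residues)), 0),
    coil = with_seed(seed, {
      steps <- matrix(rnorm(3 * (n_residues - 1)), ncol = 3)
      # persistence: blend each step with the previous direction
      for (i in seq_len(nrow(steps))[-1])
        steps[i, ] <- 0.6 * steps[i - 1, ] + steps[i, ]
      steps <- 3.8 * steps / sqrt(rowSums(steps^2))
      rbind(0, apply(steps, 2, cumsum))
    }),
    two_domain = {
      if (n_residues < 12)
        rlang::abort("two_domain needs at least 12 residues",
                     class = "pcnmd_size_error")
      n_link <- 4L
      n1 <- (n_residues - n_link) %/% 2L
      n2 <- n_residues - n_link - n1
      d1 <- helix_trace(n1)
      d2 <- helix_trace(n2)
      # place domain 2 so its first CA sits 5 x 3.8 A along +x from the last
      # CA of domain 1; the 4 linker residues interpolate the straight span
      shift <- d1[n1, ] + c(5 * 3.8, 0, 0) - d2[1, ]
      d2 <- sweep(d2, 2, shift, "+")
      lam <- seq_len(n_link) / (n_link + 1)
      linker <- outer(1 - lam, d1[n1, ]) + outer(lam, d2[1, ])
      domain <- c(rep(1L, n1), rep(NA_integer_, n_link), rep(2L, n2))
      rbind(d1, linker, d2)
    })
  out <- new_structure(decorate_backbone(ca, chain))
  attr(out, "domain") <- domain
  out
}

#' Concatenate structures (e.g. to build a multi-chain complex)
#' @param ... `pcn_structure` objects
#' @return a single `pcn_structure`; atom serials are renumbered
#' @export
combine_structures <- function(...) {
  parts <- list(...)
  stopifnot(all(vapply(parts, is_structure, TRUE)))
  at <- dplyr::bind_rows(lapply(parts, function(s) s$atoms))
  at$serial <- seq_len(nrow(at))
  new_structure(at)
}

#' Translate a structure by a fixed vector
#' @param structure a `pcn_structure`
#' @param shift length-3 numeric vector, Angstrom
#' @return translated `pcn_structure`
#' @export
translate_structure <- function(structure, shift) {
  set_coords(structure, sweep(coords(structure), 2, shift, "+"))
}

#' Generate a synthetic trajectory ensemble around a base structure
#'
#' Motions:
#' \describe{
#'   \item{static}{identical frames (RMSF is exactly zero).}
#'   \item{harmonic}{`x(t) = x0 + A sin(2 pi n_periods t/T) v` along one fixed
#'     random unit mode `v` of all 3N coordinates; essentially all covariance
#'     ends up in the first principal component. Two full periods are sampled
#'     by default so the projection is nearly orthogonal to the half-period
#'     cosine used by the sampling diagnostic.}
#'   \item{diffusive}{cumulative Gaussian steps of sd `noise_sigma` per
#'     coordinate: random diffusion, whose leading principal component has
#'     high cosine content.}
#' }
#'
#' @param base a `pcn_structure`
#' @param n_frames number of frames (>= 1)
#' @param motion "static", "harmonic" or "diffusive"
#' @param noise_sigma step sd (diffusive) or mode amplitude (harmonic), A
#' @param seed RNG seed
#' @param time_start,time_step frame time origin and spacing, ps
#' @param n_periods full sine periods spanned by a harmonic trajectory
#' @return a `pcn_ensemble`
#' @export
make_ensemble <- function(base, n_frames,
                          motion = c("static", "harmonic", "diffusive"),
                          noise_sigma = 0.5, seed = 1,
                          time_start = 0, time_step = 10, n_periods = 2) {
  motion <- match.arg(motion)
  stopifnot(is_structure(base), n_frames >= 1, noise_sigma >= 0)
  x0 <- coords(base)
  a <- nrow(x0)
  frames <- array(NA_real_, c(n_frames, a, 3))
  disp <- with_seed(seed, switch(motion,
    static = lapply(seq_len(n_frames), function(i) matrix(0, a, 3)),
    harmonic = {
      v <- matrix(rnorm(3 * a), a, 3)
      v <- v / sqrt(sum(v^2))
      tau <- if (n_frames == 1) 0 else (seq_len(n_frames) - 1) / (n_frames - 1)
      lapply(seq_len(n_frames), function(i)
        noise_sigma * sin(2 * pi * n_periods * tau[i]) * v)
    },
    diffusive = {
      acc <- matrix(0, a, 3)
      lapply(seq_len(n_frames), function(i) {
        if (i > 1) acc <<- acc + matrix(rnorm(3 * a, sd = noise_sigma), a, 3)
        acc
      })
    }))
  for (i in seq_len(n_frames)) frames[i, , ] <- x0 + disp[[i]]
  new_ensemble(base, frames,
               time_start + time_step * (seq_len(n_frames) - 1))
}

#' Planted-partition benchmark graph
#'
#' Bernoulli edges with within-block probability `p_in` and between-block
#' probability `p_out`; symmetric, no self-loops. The planted block labels
#' (0-based) are stored in `attr(, "true_labels")` for recovery benchmarks.
#'
#' @param sizes integer vector of block sizes
#' @param p_in,p_out edge probabilities, `0 <= p_out < p_in <= 1`
#' @param seed RNG seed
#' @return a `pcn_network`
#' @export
planted_partition_graph <- function(sizes, p_in, p_out, seed = 1) {
  if (!(p_out >= 0 && p_in <= 1 && p_out < p_in))
    rlang::abort("need 0 <= p_out < p_in <= 1",
                 class = "pcnmd_parameter_error")
  n <- sum(sizes)
  labels <- rep(seq_along(sizes) - 1L, sizes)
  adj <- matrix(0L, n, n)
  with_seed(seed, {
    for (i in seq_len(n - 1)) {
      j <- (i + 1):n
      p <- ifelse(labels[j] == labels[i], p_in, p_out)
      e <- as.integer(runif(length(j)) < p)
      adj[i, j] <- e
      adj[j, i] <- e
    }
  })
  nodes <- tibble::tibble(index = seq_len(n), chain = "A",
                          res_seq = seq_len(n), i_code = "",
                          res_name = "ALA")
  net <- new_network(nodes, adj)
  attr(net, "true_labels") <- labels
  net
}
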