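test_that("superposition recovers rigid motions exactly", {
  set.seed(1)
  x <- matrix(rnorm(30), ncol = 3)
  rot90z <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE)
  y <- sweep(x %*% t(rot90z), 2, c(5, 5, 5), "+")
  fit <- kabsch_superpose(y, x)
  expect_lt(fit$rmsd, 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  # transform really maps mobile onto reference
  expect_equal(pcnmd:::apply_transform(y, fit), x, tolerance = 1e-8)
})

test_that("kabsch matches a rotation-grid search oracle on a perturbed set", {
  x <- matrix(c(0, 0, 0, 1.5, 0, 0, 0, 2, 0, 0.5, 0.5, 1.8), ncol = 3,
              byrow = TRUE)
  y <- x
  y[4, ] <- y[4, ] + c(1, 0, 0)  # displace one point by 1 A
  fit <- kabsch_superpose(y, x)
  # independent oracle: centred RMSD minimised over Euler-angle rotations,
  # coarse grid then local refinement
  xc <- sweep(x, 2, colMeans(x)); yc <- sweep(y, 2, colMeans(y))
  euler <- function(a) {
    cz <- cos(a[1]); sz <- sin(a[1]); cy <- cos(a[2]); sy <- sin(a[2])
    cx <- cos(a[3]); sx <- sin(a[3])
    matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
      matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  }
  obj <- function(a) sqrt(mean(rowSums((yc %*% t(euler(a)) - xc)^2)))
  grid <- seq(0, 2 * pi, length.out = 13)[-13]
  best <- c(0, 0, 0); best_val <- obj(best)
  for (a1 in grid) for (a2 in grid) for (a3 in grid) {
    v <- obj(c(a1, a2, a3))
    if (v < best_val) { best <- c(a1, a2, a3); best_val <- v }
  }
  ref <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))$value
  expect_equal(fit$rmsd, ref, tolerance = 1e-4)
})

test_that("superposition agrees with an established reference implementation", {
  set.seed(7)
  for (i in 1:5) {
    a <- matrix(rnorm(36), ncol = 3)
    b <- a + matrix(rnorm(36, sd = 0.3), ncol = 3)
    ours <- kabsch_superpose(b, a)$rmsd
    theirs <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b)), fit = TRUE)
    expect_equal(ours, theirs, tolerance = 5e-3)  # bio3d rounds to 3 digits
  }
})

test_that("degenerate geometries are rejected", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               class = "pcnmd_degenerate_geometry")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line + rnorm(15, sd = 1e-12), line),
               class = "pcnmd_degenerate_geometry")
})

test_that("rmsd series is zero for static and rigidly moved ensembles", {
  b <- make_backbone("helix", 10)
  stat <- make_ensemble(b, 5, "static")
  expect_equal(rmsd_series(stat, "name CA")$rmsd, rep(0, 5), tolerance = 1e-10)
  set.seed(3)
  x0 <- pcnmd:::coords(b)
  frames <- lapply(1:6, function(i)
    sweep(x0 %*% t(random_rotation()), 2, rnorm(3, sd = 10), "+"))
  rigid <- ensemble_from_frames(b, frames)
  expect_equal(rmsd_series(rigid, "name CA")$rmsd, rep(0, 6),
               tolerance = 1e-8)
})

test_that("rmsd series equals a direct per-frame superposition oracle", {
  b <- make_backbone("helix", 8)
  ens <- make_ensemble(b, 12, "diffusive", noise_sigma = 0.4, seed = 6)
  sel <- select_atoms(b, "name CA")
  series <- rmsd_series(ens, sel)$rmsd
  oracle <- vapply(1:12, function(i) {
    kabsch_superpose(ens$frames[i, sel$indices, ],
                     pcnmd:::coords(b)[sel$indices, ])$rmsd
  }, 0)
  expect_equal(series, oracle, tolerance = 1e-8)
  expect_equal(series[1], 0, tolerance = 1e-12)
  # nm mode is exactly 0.1 x Angstrom mode
  expect_identical(rmsd_series(ens, sel, units = "nm")$rmsd, series * 0.1)
})

test_that("split RMSD is local to each component", {
  dimer <- combine_structures(make_backbone("helix", 8, chain = "V"),
                              translate_structure(
                                make_backbone("helix", 8, chain = "W"),
                                c(25, 0, 0)))
  x0 <- pcnmd:::coords(dimer)
  iw <- select_atoms(dimer, "chain W")$indices
  set.seed(8)
  frames <- lapply(1:5, function(i) {
    x <- x0
    x[iw, ] <- x[iw, ] + matrix(rnorm(length(iw) * 3, sd = 0.5), ncol = 3)
    x
  })
  ens <- ensemble_from_frames(dimer, frames)
  sp <- split_rmsd(ens, "chain V and name CA", "chain W and name CA")
  a <- sp$rmsd[sp$component == "chain V and name CA"]
  b <- sp$rmsd[sp$component == "chain W and name CA"]
  expect_equal(a, rep(0, 5), tolerance = 1e-10)
  expect_true(all(b[-1] > 0))
  # whole-complex rigid motion leaves both series at zero
  rigid <- ensemble_from_frames(dimer, lapply(1:4, function(i)
    sweep(x0 %*% t(random_rotation()), 2, c(i, 0, 0), "+")))
  sp0 <- split_rmsd(rigid, "chain V and name CA", "chain W and name CA")
  expect_equal(sp0$rmsd, rep(0, 8), tolerance = 1e-8)
  expect_error(split_rmsd(ens, "chain V", "chain V,W"),
               class = "pcnmd_overlap")
})

test_that("split RMSD equals plain RMSD of each component sub-ensemble", {
  dimer <- combine_structures(make_backbone("helix", 7, chain = "V"),
                              translate_structure(
                                make_backbone("strand", 7, chain = "W"),
                                c(25, 0, 0)))
  ens <- make_ensemble(dimer, 10, "diffusive", noise_sigma = 0.3, seed = 12)
  sp <- split_rmsd(ens, "chain V and name CA", "chain W and name CA")
  for (ch in c("V", "W")) {
    sub <- subset_ensemble(ens, sprintf("chain %s and name CA", ch))
    direct <- rmsd_series(sub, seq_len(7))$rmsd
    expect_equal(sp$rmsd[grepl(ch, sp$component)], direct, tolerance = 1e-10)
  }
})

test_that("rmsf matches the closed form for isotropic Gaussian noise", {
  b <- make_backbone("helix", 10)
  sigma <- 0.2
  x0 <- pcnmd:::coords(b)
  set.seed(21)
  fr <- array(rep(x0, each = 2000), c(2000, nrow(x0), 3)) +
    array(rnorm(2000 * nrow(x0) * 3, sd = sigma), c(2000, nrow(x0), 3))
  ens <- new_ensemble(b, fr, seq_len(2000))
  rf <- rmsf(ens, "name CA", fit = FALSE)
  expect_equal(mean(rf$rmsf), sigma * sqrt(3), tolerance = 0.05)
})

test_that("rmsf is local and rejects single-frame input", {
  b <- make_backbone("strand", 6)
  x0 <- pcnmd:::coords(b)
  ica <- select_atoms(b, "name CA")$indices
  moved <- ica[3]
  frames <- lapply(1:40, function(i) {
    x <- x0
    x[moved, ] <- x[moved, ] + c(sin(i), 0, 0)
    x
  })
  ens <- ensemble_from_frames(b, frames)
  rf <- rmsf(ens, "name CA", fit = FALSE)
  expect_true(rf$rmsf[3] > 0)
  expect_equal(rf$rmsf[-3], rep(0, 5), tolerance = 1e-12)
  one <- ensemble_from_frames(b, frames[1])
  expect_error(rmsf(one, "name CA"), class = "pcnmd_insufficient_frames")
})

test_that("geometry is invariant under global rigid motion of the input", {
  b <- make_backbone("helix", 9)
  ens <- make_ensemble(b, 8, "diffusive", noise_sigma = 0.3, seed = 5)
  set.seed(9)
  rot <- random_rotation(); shift <- c(4, -7, 2)
  moved_frames <- lapply(1:8, function(i)
    sweep(ens$frames[i, , ] %*% t(rot), 2, shift, "+"))
  moved <- ensemble_from_frames(
    pcnmd:::set_coords(b, sweep(pcnmd:::coords(b) %*% t(rot), 2, shift, "+")),
    moved_frames)
  expect_equal(rmsd_series(ens, "name CA")$rmsd,
               rmsd_series(moved, "name CA")$rmsd, tolerance = 1e-8)
  expect_equal(rmsf(ens, "name CA")$rmsf, rmsf(moved, "name CA")$rmsf,
               tolerance = 1e-8)
})
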