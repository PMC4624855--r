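pair_structure <- function(d, chain_b = "B") {
  # one CA atom in each of two chains separated by d along x
  new_structure(dplyr::bind_rows(
    atoms_tbl("CA", 0, 0, 0, chain = "A", res_seq = 1, element = "C"),
    atoms_tbl("CA", d, 0, 0, chain = chain_b, res_seq = 1, element = "C")))
}

static_ens <- function(s, f = 3) make_ensemble(s, f, "static")

test_that("the 3.5 A contact cutoff is inclusive", {
  close <- interface_contacts(static_ens(pair_structure(3.4)),
                              "chain A", "chain B")
  expect_equal(close$mean, 1)
  expect_equal(close$sd, 0)
  afar <- interface_contacts(static_ens(pair_structure(3.6)),
                             "chain A", "chain B")
  expect_equal(afar$mean, 0)
  exact <- interface_contacts(static_ens(pair_structure(3.5)),
                              "chain A", "chain B")
  expect_equal(exact$mean, 1)
})

test_that("frame-varying contacts average to fractional means", {
  s <- new_structure(dplyr::bind_rows(
    atoms_tbl(c("CA", "CB"), c(0, 0), c(0, 1), 0, chain = "A",
              res_seq = c(1, 1), element = c("C", "C")),
    atoms_tbl(c("CA", "CB"), c(3, 3), c(0, 1), 0, chain = "B",
              res_seq = c(1, 1), element = c("C", "C"))))
  x0 <- pcnmd:::coords(s)
  f1 <- x0                            # all four cross pairs within 3.5 A
  f2 <- x0; f2[4, ] <- c(50, 50, 50)  # only 2 pairs in range
  ens <- ensemble_from_frames(s, list(f2, f1))
  ct <- interface_contacts(ens, "chain A", "chain B", cutoff = 3.5)
  expect_equal(ct$per_frame$n_contacts, c(2L, 4L))
  expect_equal(ct$mean, 3)
  expect_equal(ct$sd, 1)
  g <- glance(ct)
  expect_equal(g$mean, 3); expect_equal(g$sd, 1)
})

test_that("contact counting is symmetric and guards disjointness", {
  td <- combine_structures(make_backbone("strand", 4, chain = "A"),
                           translate_structure(
                             make_backbone("strand", 4, chain = "B"),
                             c(0, 5, 0)))
  ens <- make_ensemble(td, 4, "diffusive", noise_sigma = 0.2, seed = 2)
  ab <- interface_contacts(ens, "chain A", "chain B")
  ba <- interface_contacts(ens, "chain B", "chain A")
  expect_equal(ab$per_frame$n_contacts, ba$per_frame$n_contacts)
  expect_error(interface_contacts(ens, "chain A", "chain A,B"),
               class = "pcnmd_overlap")
  # residue mode collapses atom pairs to residue pairs
  res <- interface_contacts(ens, "chain A", "chain B", mode = "residues")
  expect_true(all(res$per_frame$n_contacts <= ab$per_frame$n_contacts))
})

hb_structure <- function(d_no = 2.9, h_angle_linear = TRUE) {
  # donor N (chain A) with hydrogen, acceptor O (chain B) along x
  hx <- if (h_angle_linear) c(1, 0, 0) else c(0, 1, 0)
  new_structure(dplyr::bind_rows(
    atoms_tbl(c("N", "H"), c(0, hx[1]), c(0, hx[2]), c(0, hx[3]),
              chain = "A", res_seq = c(10, 10), res_name = "TYR",
              element = c("N", "H")),
    atoms_tbl("O", d_no, 0, 0, chain = "B", res_seq = 93, res_name = "GLU",
              element = "O")))
}

test_that("hydrogen bonds require both distance and linearity", {
  good <- detect_hbonds(static_ens(hb_structure(2.9)), "chain A", "chain B")
  expect_equal(nrow(good), 1)
  expect_equal(good$occupancy, 1)
  expect_equal(good$label, "Tyr10/Glu93")
  expect_equal(good$donor_name, "N")
  expect_equal(good$acceptor_name, "O")
  none_far <- detect_hbonds(static_ens(hb_structure(3.6)),
                            "chain A", "chain B")
  expect_equal(nrow(none_far), 0)
  bent <- detect_hbonds(static_ens(hb_structure(2.9, h_angle_linear = FALSE)),
                        "chain A", "chain B")
  expect_equal(nrow(bent), 0)
})

test_that("occupancy counts satisfying frames and filters low-frequency bonds", {
  s <- hb_structure(2.9)
  x0 <- pcnmd:::coords(s)
  frames <- lapply(1:10, function(i) {
    x <- x0
    if (i > 2) x[3, 1] <- 9  # acceptor pulled away in 8 of 10 frames
    x
  })
  ens <- ensemble_from_frames(s, frames)
  filtered <- detect_hbonds(ens, "chain A", "chain B")
  expect_equal(nrow(filtered), 0)  # occupancy 0.2 below the 0.5 default
  all_bonds <- detect_hbonds(ens, "chain A", "chain B", occupancy_min = 0)
  expect_equal(all_bonds$occupancy, 0.2)
})

test_that("heavy-atom mode applies when no hydrogens exist", {
  s <- new_structure(dplyr::bind_rows(
    atoms_tbl("N", 0, 0, 0, chain = "A", res_seq = 31, res_name = "HIS",
              element = "N"),
    atoms_tbl("O", 3.2, 0, 0, chain = "B", res_seq = 89, res_name = "GLU",
              element = "O")))
  hb <- detect_hbonds(static_ens(s), "chain A", "chain B")
  expect_equal(nrow(hb), 1)
  expect_equal(hb$label, "His31/Glu89")
  expect_error(detect_hbonds(static_ens(s), "chain A", "chain B",
                             mode = "hydrogen"),
               class = "pcnmd_missing_atom")
  carbon_only <- new_structure(atoms_tbl(c("CA", "CA"), c(0, 3), 0, 0,
                                         chain = c("A", "B"),
                                         res_seq = c(1, 1),
                                         element = c("C", "C")))
  expect_warning(hb0 <- detect_hbonds(static_ens(carbon_only),
                                      "chain A", "chain B"),
                 "polar")
  expect_equal(nrow(hb0), 0)
})
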