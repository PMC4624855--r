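min_atom_line <- function(serial = 1, name = "CA", res = "ALA", chain = "A",
                          res_seq = 1, x = 1, y = 2, z = 3, occ = 1,
                          b = 0, alt = " ", element = "C") {
  sprintf("ATOM  %5d %-4s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, paste0(" ", name), alt, res, chain, res_seq, x, y, z,
          occ, b, element)
}

test_that("a minimal ATOM record parses to one atom and one residue", {
  s <- read_pdb(min_atom_line())
  expect_s3_class(s, "pcn_structure")
  expect_equal(nrow(s$atoms), 1)
  expect_equal(nrow(residues(s)), 1)
  expect_equal(s$atoms$name, "CA")
  expect_equal(unname(unlist(s$atoms[, c("x", "y", "z")])), c(1, 2, 3))
})

test_that("alternate locations keep the highest occupancy, ties keep A", {
  two <- c(min_atom_line(1, occ = 0.4, alt = "A"),
           min_atom_line(2, occ = 0.6, alt = "B"))
  s <- read_pdb(two)
  expect_equal(nrow(s$atoms), 1)
  expect_equal(s$atoms$alt, "B")
  tie <- c(min_atom_line(1, occ = 0.5, alt = "B"),
           min_atom_line(2, occ = 0.5, alt = "A"))
  expect_equal(read_pdb(tie)$atoms$alt, "A")
})

test_that("malformed coordinates fail with the line number", {
  bad <- c(min_atom_line(), sub("   2.000", "  oops  ", min_atom_line(2)))
  expect_error(read_pdb(bad), "line 2", class = "pcnmd_parse_error")
  expect_error(read_pdb("REMARK nothing here"), class = "pcnmd_empty_input")
})

test_that("element symbols are inferred from atom names when absent", {
  lines <- c(min_atom_line(1, name = "NZ", element = "  "),
             min_atom_line(2, name = "OD1", element = "  "))
  s <- read_pdb(lines)
  expect_equal(s$atoms$element, c("N", "O"))
})

test_that("read/write round trip preserves atoms, names and coordinates", {
  h <- make_backbone("helix", 12)
  back <- read_pdb(write_pdb(h))
  expect_equal(nrow(back$atoms), nrow(h$atoms))
  expect_equal(back$atoms$name, h$atoms$name)
  expect_equal(back$atoms$res_seq, h$atoms$res_seq)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               round(as.matrix(h$atoms[, c("x", "y", "z")]), 3),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("HETATM records are parsed but excluded from residue accounting", {
  lines <- c(min_atom_line(),
             sub("^ATOM  ", "HETATM", min_atom_line(2, name = "O", res = "HOH",
                                                    res_seq = 90,
                                                    element = "O")))
  s <- read_pdb(lines)
  expect_equal(nrow(s$atoms), 2)
  expect_true(any(s$atoms$is_het))
  expect_equal(nrow(residues(s)), 1)
})

test_that("selection grammar resolves chains, residue ranges and names", {
  pep <- make_backbone("helix", 10)
  expect_length(select_atoms(pep, "name CA")$indices, 10)
  expect_length(select_atoms(pep, "resid 3-5 and name CA")$indices, 3)
  dimer <- combine_structures(make_backbone("helix", 8, chain = "V"),
                              translate_structure(
                                make_backbone("helix", 8, chain = "W"),
                                c(30, 0, 0)))
  expect_length(select_atoms(dimer, "chain V,W and name CA")$indices, 16)
  expect_length(select_atoms(dimer, "chain W and name CA")$indices, 8)
})

test_that("selections are order-stable, idempotent, and reject bad grammar", {
  pep <- make_backbone("strand", 6)
  a <- select_atoms(pep, "name CA,CB")$indices
  expect_equal(a, sort(unique(a)))
  expect_equal(select_atoms(pep, "name CA,CB")$indices, a)
  expect_error(select_atoms(pep, "resid 5-3"), class = "pcnmd_selection_syntax")
  expect_error(select_atoms(pep, "within 5 of name CA"),
               class = "pcnmd_selection_syntax")
  expect_warning(select_atoms(pep, "chain Q"), "no atoms")
})

test_that("multi-model round trip recovers frames and stride times", {
  base <- make_backbone("helix", 6)
  ens <- make_ensemble(base, 4, "diffusive", noise_sigma = 0.4, seed = 3)
  tmp <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(ens, tmp)
  back <- read_multimodel_pdb(tmp, time_start = 0, time_step = 10)
  expect_equal(n_frames(back), 4)
  expect_equal(back$times, c(0, 10, 20, 30))
  expect_equal(back$frames, ens$frames, tolerance = 1e-3)
  # identical models give identical frames
  stat <- make_ensemble(base, 3, "static")
  write_multimodel_pdb(stat, tmp)
  back2 <- read_multimodel_pdb(tmp)
  expect_equal(back2$frames[1, , ], back2$frames[3, , ])
})

test_that("atom-count mismatch across models names the model", {
  base <- make_backbone("helix", 3)
  ens <- make_ensemble(base, 2, "static")
  tmp <- tempfile(fileext = ".pdb")
  write_multimodel_pdb(ens, tmp)
  lines <- readLines(tmp)
  drop <- utils::tail(grep("^ATOM", lines), 1)
  writeLines(lines[-drop], tmp)
  expect_error(read_multimodel_pdb(tmp), "model 2",
               class = "pcnmd_mismatch_error")
})

test_that("per-residue b-factor values land on every atom of the residue", {
  h <- make_backbone("helix", 5)
  out <- write_pdb_with_bfactor(h, data.frame(chain = "A", res_seq = 2,
                                              value = -129))
  atom_lines <- grep("^ATOM", out, value = TRUE)
  res2 <- grep(" A   2 ", atom_lines, value = TRUE)
  expect_length(res2, 5)
  expect_true(all(grepl("-129.00", res2, fixed = TRUE)))
  others <- setdiff(atom_lines, res2)
  expect_true(all(grepl("  0.00", others, fixed = TRUE)))
})

test_that("b-factor annotation round-trips and rejects bad input", {
  h <- make_backbone("strand", 4)
  vals <- data.frame(chain = "A", res_seq = c(1, 3), value = c(-171, -190))
  back <- read_pdb(write_pdb_with_bfactor(h, vals))
  expect_equal(unique(back$atoms$b[back$atoms$res_seq == 1]), -171)
  expect_equal(unique(back$atoms$b[back$atoms$res_seq == 3]), -190)
  expect_equal(unique(back$atoms$b[back$atoms$res_seq == 2]), 0)
  # geometry unchanged apart from b-factors
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               round(as.matrix(h$atoms[, c("x", "y", "z")]), 3),
               ignore_attr = TRUE, tolerance = 1e-9)
  expect_error(write_pdb_with_bfactor(h, data.frame(chain = "A", res_seq = 1,
                                                    value = 1e5)),
               class = "pcnmd_format_overflow")
  expect_error(write_pdb_with_bfactor(h, data.frame(chain = "B", res_seq = 1,
                                                    value = 1)),
               class = "pcnmd_mapping_error")
  all_zero <- read_pdb(write_pdb_with_bfactor(h, data.frame(chain = character(),
                                                            res_seq = integer(),
                                                            value = numeric())))
  expect_true(all(all_zero$atoms$b == 0))
})
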