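#' @title Structures, ensembles and PDB input/output
#' @description Readers and writers for single- and multi-model PDB files
#'   (fixed-column v3.3 layout, parsed through bio3d), the typed structure /
#'   ensemble containers used across the package, atom selections, and
#'   b-factor annotation for per-residue values.
#' @name structure-io
NULL

# ---- containers -------------------------------------------------------------

#' Build a structure from an atom table
#'
#' Columns: `serial`, `name`, `alt`, `res_name`, `chain`, `res_seq`,
#' `i_code`, `x`, `y`, `z`, `occupancy`, `b`, `element`, `is_het`; missing
#' bookkeeping columns get sensible defaults. Mostly useful for constructing
#' small test systems in code.
#'
#' @param atoms data frame of atom records
#' @return a `pcn_structure`
#' @export
new_structure <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  atoms <- tibble::as_tibble(atoms)
  defaults <- list(serial = seq_len(nrow(atoms)), alt = "", i_code = "",
                   occupancy = 1, b = 0, is_het = FALSE)
  for (k in names(defaults))
    if (!k %in% names(atoms)) atoms[[k]] <- defaults[[k]]
  if (!"element" %in% names(atoms))
    atoms$element <- infer_element(rep(NA_character_, nrow(atoms)), atoms$name)
  need <- c("serial", "name", "alt", "res_name", "chain", "res_seq", "i_code",
            "x", "y", "z", "occupancy", "b", "element", "is_het")
  if (!all(need %in% names(atoms)))
    rlang::abort(sprintf("missing atom columns: %s",
                         paste(setdiff(need, names(atoms)), collapse = ", ")),
                 class = "pcnmd_schema_error")
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    rlang::abort("coordinates must be finite", class = "pcnmd_schema_error")
  structure(list(atoms = atoms[, need]), class = "pcn_structure")
}

#' Test / coerce structure objects
#' @param x object
#' @return logical scalar
#' @export
is_structure <- function(x) inherits(x, "pcn_structure")

#' @export
print.pcn_structure <- function(x, ...) {
  res <- residues(x)
  cat(sprintf("<pcn_structure> %d atoms, %d protein residues, chains: %s\n",
              nrow(x$atoms), nrow(res),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Atom table of a structure
#' @param x a `pcn_structure`
#' @param ... unused
#' @method as_tibble pcn_structure
#' @export
as_tibble.pcn_structure <- function(x, ...) x$atoms

#' Protein residue table of a structure
#'
#' One row per protein (non-HETATM) residue in atom order, keyed by
#' (chain, res_seq, i_code). `has_ca` marks residues possessing an
#' alpha-carbon; `node` is the sequential 1-based index over CA-bearing
#' residues used by the contact-network layer.
#'
#' @param structure a `pcn_structure`
#' @return tibble with columns chain, res_seq, i_code, res_name, has_ca, node
#' @export
residues <- function(structure) {
  stopifnot(is_structure(structure))
  at <- structure$atoms[!structure$atoms$is_het, , drop = FALSE]
  if (nrow(at) == 0) {
    return(tibble::tibble(chain = character(), res_seq = integer(),
                          i_code = character(), res_name = character(),
                          has_ca = logical(), node = integer()))
  }
  key <- paste(at$chain, at$res_seq, at$i_code, sep = "|")
  keep <- !duplicated(key)
  res <- tibble::tibble(chain = at$chain[keep], res_seq = at$res_seq[keep],
                        i_code = at$i_code[keep], res_name = at$res_name[keep])
  ca <- at$name == "CA" & at$element == "C"
  res$has_ca <- paste(res$chain, res$res_seq, res$i_code, sep = "|") %in% key[ca]
  res$node <- NA_integer_
  res$node[res$has_ca] <- seq_len(sum(res$has_ca))
  res
}

coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

set_coords <- function(structure, xyz) {
  structure$atoms$x <- xyz[, 1]
  structure$atoms$y <- xyz[, 2]
  structure$atoms$z <- xyz[, 3]
  structure
}

#' Build an ensemble from a reference structure and a frame array
#'
#' @param reference a `pcn_structure`
#' @param frames F x A x 3 coordinate array (frames x atoms x xyz), Angstrom
#' @param times frame times in ps, strictly increasing
#' @return a `pcn_ensemble`
#' @export
new_ensemble <- function(reference, frames, times) {
  stopifnot(is_structure(reference), length(dim(frames)) == 3)
  if (dim(frames)[2] != nrow(reference$atoms))
    rlang::abort("frame atom count does not match reference",
                 class = "pcnmd_mismatch_error")
  if (length(times) != dim(frames)[1])
    rlang::abort("times length does not match frame count",
                 class = "pcnmd_mismatch_error")
  if (length(times) > 1 && any(diff(times) <= 0))
    rlang::abort("times must be strictly increasing",
                 class = "pcnmd_mismatch_error")
  structure(list(reference = reference, frames = frames, times = as.numeric(times)),
            class = "pcn_ensemble")
}

#' @rdname is_structure
#' @export
is_ensemble <- function(x) inherits(x, "pcn_ensemble")

#' @export
print.pcn_ensemble <- function(x, ...) {
  cat(sprintf("<pcn_ensemble> %d frames x %d atoms, t = %g..%g ps\n",
              dim(x$frames)[1], dim(x$frames)[2],
              min(x$times), max(x$times)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble a `pcn_ensemble`
#' @return integer
#' @export
n_frames <- function(ensemble) dim(ensemble$frames)[1]

#' Extract one frame of an ensemble as a structure
#' @param ensemble a `pcn_ensemble`
#' @param i frame index (1-based)
#' @return `pcn_structure`
#' @export
frame_structure <- function(ensemble, i) {
  stopifnot(i >= 1, i <= n_frames(ensemble))
  set_coords(ensemble$reference, ensemble$frames[i, , , drop = TRUE])
}

#' Restrict an ensemble to a selection of atoms
#' @param ensemble a `pcn_ensemble`
#' @param selection a `pcn_selection` (or integer atom indices)
#' @return `pcn_ensemble` over the selected atoms only
#' @export
subset_ensemble <- function(ensemble, selection) {
  idx <- selection_indices(ensemble$reference, selection)
  ref <- new_structure(ensemble$reference$atoms[idx, , drop = FALSE])
  new_ensemble(ref, ensemble$frames[, idx, , drop = FALSE], ensemble$times)
}

# ---- PDB text scanning ------------------------------------------------------

pdb_source_lines <- function(file) {
  if (length(file) == 1 && !grepl("\n", file) && file.exists(file))
    return(readLines(file, warn = FALSE))
  unlist(strsplit(file, "\n", fixed = TRUE))
}

# coordinate-column sanity check before handing text to the parser, so that
# malformed records are reported with their line number
check_coord_fields <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    for (start in c(31, 39, 47)) {
      field <- substr(lines[i], start, start + 7)
      if (is.na(suppressWarnings(as.numeric(field))))
        rlang::abort(sprintf("malformed coordinate field at line %d: '%s'",
                             i, field),
                     class = "pcnmd_parse_error")
    }
  }
  invisible(sum(rec))
}

infer_element <- function(elesy, name) {
  out <- toupper(trimws(elesy))
  blank <- is.na(out) | out == ""
  if (any(blank)) {
    guess <- toupper(sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1", name[blank]))
    out[blank] <- guess
  }
  out
}

# resolve alternate locations: keep the highest-occupancy copy, ties -> 'A'
# (alphabetically first altLoc). Returns row indices to keep, in file order.
altloc_keep <- function(df) {
  key <- paste(df$chain, df$resno, df$insert, df$resid, df$elety, sep = "|")
  ord <- order(key, -ifelse(is.na(df$o), 1, df$o),
               ifelse(is.na(df$alt), "", df$alt))
  keep <- ord[!duplicated(key[ord])]
  sort(keep)
}

bio3d_to_atoms <- function(atom_df) {
  tibble::tibble(
    serial = as.integer(atom_df$eleno),
    name = trimws(atom_df$elety),
    alt = ifelse(is.na(atom_df$alt), "", atom_df$alt),
    res_name = trimws(atom_df$resid),
    chain = ifelse(is.na(atom_df$chain), "", atom_df$chain),
    res_seq = as.integer(atom_df$resno),
    i_code = ifelse(is.na(atom_df$insert), "", atom_df$insert),
    x = atom_df$x, y = atom_df$y, z = atom_df$z,
    occupancy = ifelse(is.na(atom_df$o), 1, atom_df$o),
    b = ifelse(is.na(atom_df$b), 0, atom_df$b),
    element = infer_element(atom_df$elesy, trimws(atom_df$elety)),
    is_het = atom_df$type == "HETATM"
  )
}

# ---- readers ----------------------------------------------------------------

#' Read a single-model PDB file
#'
#' Fixed-column PDB v3.3 parsing (through [bio3d::read.pdb()]). Alternate
#' locations are resolved by keeping the highest-occupancy copy (ties go to
#' altLoc 'A'); missing element symbols are inferred from the first alphabetic
#' character of the atom name. HETATM records are retained in the atom table
#' (flagged `is_het`) but excluded from residue and network accounting.
#'
#' @param file path to a PDB file, or PDB content as a character string /
#'   vector of lines
#' @return a `pcn_structure`
#' @export
read_pdb <- function(file) {
  lines <- pdb_source_lines(file)
  n_rec <- check_coord_fields(lines)
  if (n_rec == 0)
    rlang::abort("no ATOM/HETATM records found", class = "pcnmd_empty_input")
  if (sum(grepl("^MODEL", lines)) > 1)
    rlang::abort("multiple MODEL blocks; use read_multimodel_pdb()",
                 class = "pcnmd_parse_error")
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, rm.alt = FALSE, verbose = FALSE)
  atoms <- bio3d_to_atoms(pdb$atom)
  atoms <- atoms[altloc_keep(pdb$atom), , drop = FALSE]
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    rlang::abort("non-finite coordinates after parsing",
                 class = "pcnmd_parse_error")
  new_structure(atoms)
}

#' Read a multi-model PDB file as a trajectory ensemble
#'
#' Every MODEL block must contain the same atoms in the same order. The first
#' model becomes the reference structure; frame times are assigned from
#' `time_start` and `time_step` (ps), matching trajectory frames written at a
#' fixed stride.
#'
#' @inheritParams read_pdb
#' @param time_start time of the first frame, ps
#' @param time_step frame spacing, ps
#' @return a `pcn_ensemble`
#' @export
read_multimodel_pdb <- function(file, time_start = 0, time_step = 10) {
  lines <- pdb_source_lines(file)
  check_coord_fields(lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0)
    rlang::abort("no MODEL blocks; use read_pdb() for single structures",
                 class = "pcnmd_parse_error")
  # per-model record counts from the raw text so mismatches name the model
  bounds <- c(model_starts, length(lines) + 1L)
  counts <- vapply(seq_along(model_starts), function(m) {
    blk <- lines[bounds[m]:(bounds[m + 1] - 1L)]
    blk <- blk[seq_len(match(TRUE, grepl("^ENDMDL", blk), nomatch = length(blk)))]
    sum(grepl("^(ATOM  |HETATM)", blk))
  }, integer(1))
  if (length(unique(counts)) > 1) {
    bad <- which(counts != counts[1])[1]
    rlang::abort(sprintf(
      "atom-count mismatch across models: model %d has %d atoms, model 1 has %d",
      bad, counts[bad], counts[1]), class = "pcnmd_mismatch_error")
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  atoms <- bio3d_to_atoms(pdb$atom)
  keep <- altloc_keep(pdb$atom)
  atoms <- atoms[keep, , drop = FALSE]
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  f <- nrow(xyz)
  a <- ncol(xyz) / 3
  frames <- array(NA_real_, c(f, length(keep), 3))
  for (k in 1:3) frames[, , k] <- xyz[, (keep - 1) * 3 + k, drop = FALSE]
  reference <- set_coords(new_structure(atoms), frames[1, , , drop = TRUE])
  times <- time_start + time_step * (seq_len(f) - 1)
  new_ensemble(reference, frames, times)
}

# ---- selections -------------------------------------------------------------

#' Select atoms of a structure
#'
#' Expression grammar: clauses joined with `and`, each one of
#' `chain <id>[,<id>...]`, `resid <a>[-<b>]`, `name <atom>[,<atom>...]`.
#' For example `"chain V,W and name CA"` picks the alpha-carbons of a
#' two-chain dimer. The result is a deterministic, sorted, duplicate-free
#' atom index list; an empty result is allowed but flagged with a warning.
#'
#' @param structure a `pcn_structure`
#' @param expression selection expression string
#' @return a `pcn_selection` carrying the expression and resolved indices
#' @export
select_atoms <- function(structure, expression) {
  stopifnot(is_structure(structure))
  at <- structure$atoms
  keep <- rep(TRUE, nrow(at))
  clauses <- strsplit(trimws(expression), "\\s+and\\s+")[[1]]
  if (length(clauses) == 0 || any(clauses == ""))
    rlang::abort("empty selection expression", class = "pcnmd_selection_syntax")
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    if (length(tok) != 2)
      rlang::abort(sprintf("cannot parse selection clause '%s'", cl),
                   class = "pcnmd_selection_syntax")
    arg <- tok[2]
    keep <- keep & switch(tok[1],
      chain = at$chain %in% strsplit(arg, ",", fixed = TRUE)[[1]],
      name = at$name %in% strsplit(arg, ",", fixed = TRUE)[[1]],
      resid = {
        m <- regmatches(arg, regexec("^(-?[0-9]+)(?:-(-?[0-9]+))?$", arg))[[1]]
        if (length(m) == 0)
          rlang::abort(sprintf("bad residue range '%s'", arg),
                       class = "pcnmd_selection_syntax")
        a <- as.integer(m[2])
        b <- if (m[3] == "") a else as.integer(m[3])
        if (b < a)
          rlang::abort(sprintf("descending residue range '%s'", arg),
                       class = "pcnmd_selection_syntax")
        at$res_seq >= a & at$res_seq <= b
      },
      rlang::abort(sprintf("unknown selection keyword '%s'", tok[1]),
                   class = "pcnmd_selection_syntax")
    )
  }
  idx <- which(keep)
  if (length(idx) == 0)
    rlang::warn(sprintf("selection '%s' matched no atoms", expression))
  structure(list(expression = expression, indices = idx),
            class = "pcn_selection")
}

selection_indices <- function(structure, selection) {
  if (inherits(selection, "pcn_selection")) return(selection$indices)
  if (is.character(selection)) return(select_atoms(structure, selection)$indices)
  as.integer(selection)
}

#' @export
print.pcn_selection <- function(x, ...) {
  cat(sprintf("<pcn_selection> '%s': %d atoms\n", x$expression,
              length(x$indices)))
  invisible(x)
}

# ---- writers ----------------------------------------------------------------

#' Write a structure to PDB
#' @param structure a `pcn_structure`
#' @param file output path; if `NULL` the PDB text lines are returned instead
#' @return the PDB text lines, invisibly when `file` is given
#' @export
write_pdb <- function(structure, file = NULL) {
  at <- structure$atoms
  tmp <- if (is.null(file)) tempfile(fileext = ".pdb") else file
  bio3d::write.pdb(file = tmp,
                   xyz = as.vector(t(coords(structure))),
                   type = ifelse(at$is_het, "HETATM", "ATOM"),
                   eleno = at$serial, elety = at$name, resid = at$res_name,
                   chain = at$chain, resno = at$res_seq, insert = at$i_code,
                   alt = ifelse(at$alt == "", NA, at$alt),
                   o = at$occupancy, b = at$b, elesy = at$element)
  if (is.null(file)) {
    on.exit(unlink(tmp))
    return(readLines(tmp, warn = FALSE))
  }
  invisible(readLines(tmp, warn = FALSE))
}

#' Write an ensemble as a multi-model PDB
#' @param ensemble a `pcn_ensemble`
#' @param file output path
#' @return invisibly, the number of models written
#' @export
write_multimodel_pdb <- function(ensemble, file) {
  f <- n_frames(ensemble)
  lines <- unlist(lapply(seq_len(f), function(i) {
    body <- write_pdb(frame_structure(ensemble, i))
    body <- body[!grepl("^END", body)]
    c(sprintf("MODEL     %4d", i), body, "ENDMDL")
  }))
  writeLines(c(lines, "END"), file)
  invisible(f)
}

#' Set per-residue b-factor values
#'
#' Every atom of a listed residue receives that residue's value; atoms of
#' unlisted residues get 0. This is the mechanism used to visualise
#' per-residue energy decompositions in molecular viewers.
#'
#' @param structure a `pcn_structure`
#' @param values data frame with columns `chain`, `res_seq` and `value`
#'   (an `i_code` column is honoured when present)
#' @return the structure with updated b-factors
#' @export
set_residue_bfactor <- function(structure, values) {
  stopifnot(is_structure(structure))
  values <- as.data.frame(values)
  if (!all(c("chain", "res_seq", "value") %in% names(values)))
    rlang::abort("values needs columns chain, res_seq, value",
                 class = "pcnmd_schema_error")
  if (nrow(values) > 0 &&
      (any(values$value < -999.99) || any(values$value > 9999.99)))
    rlang::abort("b-factor value outside [-999.99, 9999.99] cannot be formatted",
                 class = "pcnmd_format_overflow")
  icode <- if ("i_code" %in% names(values)) values$i_code else
    rep("", nrow(values))
  at <- structure$atoms
  atom_key <- paste(at$chain, at$res_seq, at$i_code, sep = "|")
  val_key <- paste(values$chain, values$res_seq, icode, sep = "|")
  missing <- setdiff(val_key, atom_key)
  if (length(missing) > 0)
    rlang::abort(sprintf("residues not present in structure: %s",
                         paste(missing, collapse = ", ")),
                 class = "pcnmd_mapping_error")
  b <- rep(0, nrow(at))
  hit <- match(atom_key, val_key)
  b[!is.na(hit)] <- values$value[hit[!is.na(hit)]]
  structure$atoms$b <- b
  structure
}

#' Write a PDB with per-residue values in the b-factor field
#'
#' @inheritParams set_residue_bfactor
#' @param file optional output path
#' @return PDB text lines (invisibly when `file` is given)
#' @export
write_pdb_with_bfactor <- function(structure, values, file = NULL) {
  write_pdb(set_residue_bfactor(structure, values), file = file)
}
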