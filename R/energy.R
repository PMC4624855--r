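#' @title Binding-energy bookkeeping and per-residue annotation
#' @description Combines per-term MM-PBSA-style energies of a complex and
#'   its two parts into the binding ledger
#'   `Delta = complex - (receptor + ligand)`, and writes per-residue
#'   decomposition energies into PDB b-factors for 3D visualisation. The
#'   vacuum force-field and polar-solvation terms are ingested from external
#'   engines, never computed here; because the entropic term is omitted the
#'   total is labelled `dE_binding`, not a free energy.
#' @name energy-ledger
NULL

as_term_table <- function(x, what = "terms") {
  if (is.numeric(x) && !is.null(names(x)))
    x <- tibble::tibble(term = names(x), energy = unname(x))
  x <- tibble::as_tibble(x)
  if (!all(c("term", "energy") %in% names(x)))
    rlang::abort(sprintf("%s needs columns term, energy", what),
                 class = "pcnmd_schema_error")
  if (anyDuplicated(x$term))
    rlang::abort(sprintf("duplicated term in %s", what),
                 class = "pcnmd_schema_error")
  x[, c("term", "energy")]
}

#' Read a per-term energy TSV
#'
#' Schema: tab-separated with a header line `term  complex  receptor  ligand`
#' (kJ/mol) and optional `#` comment lines.
#'
#' @param file path
#' @return tibble with those four columns
#' @export
read_energy_table <- function(file) {
  x <- tibble::as_tibble(read.delim(file, comment.char = "#"))
  need <- c("term", "complex", "receptor", "ligand")
  if (!all(need %in% names(x)))
    rlang::abort("energy table needs columns term, complex, receptor, ligand",
                 class = "pcnmd_schema_error")
  x[, need]
}

#' Binding-energy ledger from per-term energies
#'
#' For every term, `Delta = complex - (receptor + ligand)`; the total
#' `dE_binding` is the sum of the per-term deltas (single-trajectory scheme,
#' entropy not included). The three inputs must carry identical term sets:
#' a missing term is an error, never a silent zero.
#'
#' @param complex_terms,receptor_terms,ligand_terms named numeric vectors or
#'   data frames with columns `term`, `energy` (kJ/mol); alternatively pass
#'   a [read_energy_table()] tibble as `complex_terms`
#' @return a `pcn_binding` object; `tidy()` gives the per-term ledger,
#'   `glance()` the total
#' @export
binding_energy <- function(complex_terms, receptor_terms = NULL,
                           ligand_terms = NULL) {
  if (is.null(receptor_terms) && is.data.frame(complex_terms) &&
      all(c("term", "complex", "receptor", "ligand") %in%
          names(complex_terms))) {
    tab <- complex_terms
    complex_terms <- setNames(tab$complex, tab$term)
    receptor_terms <- setNames(tab$receptor, tab$term)
    ligand_terms <- setNames(tab$ligand, tab$term)
  }
  cx <- as_term_table(complex_terms, "complex_terms")
  rc <- as_term_table(receptor_terms, "receptor_terms")
  lg <- as_term_table(ligand_terms, "ligand_terms")
  miss <- function(a, b, who)
    if (length(d <- setdiff(a$term, b$term)) > 0)
      rlang::abort(sprintf("term(s) %s missing from %s",
                           paste(d, collapse = ", "), who),
                   class = "pcnmd_schema_error")
  miss(cx, rc, "receptor_terms"); miss(cx, lg, "ligand_terms")
  miss(rc, cx, "complex_terms"); miss(lg, cx, "complex_terms")
  rc <- rc[match(cx$term, rc$term), ]
  lg <- lg[match(cx$term, lg$term), ]
  ledger <- tibble::tibble(term = cx$term, complex = cx$energy,
                           receptor = rc$energy, ligand = lg$energy,
                           delta = cx$energy - (rc$energy + lg$energy))
  structure(list(terms = ledger, dE_binding = sum(ledger$delta)),
            class = "pcn_binding")
}

#' @export
print.pcn_binding <- function(x, ...) {
  cat("<pcn_binding> per-term ledger (kJ/mol), delta = complex - (receptor + ligand)\n")
  print(as.data.frame(x$terms), row.names = FALSE)
  cat(sprintf("dE_binding = %.3f kJ/mol (entropy not included)\n",
              x$dE_binding))
  invisible(x)
}

#' @describeIn binding_energy per-term ledger table
#' @param x a `pcn_binding`
#' @param ... unused
#' @method tidy pcn_binding
#' @export
tidy.pcn_binding <- function(x, ...) x$terms

#' @describeIn binding_energy one-row total
#' @method glance pcn_binding
#' @export
glance.pcn_binding <- function(x, ...) {
  tibble::tibble(dE_binding = x$dE_binding, n_terms = nrow(x$terms))
}

#' Annotate a structure with per-residue decomposition energies
#'
#' Writes each residue's energy contribution (kJ/mol) into the b-factor of
#' all its atoms (unlisted residues get 0), the standard trick for mapping an
#' energy decomposition onto a 3D structure in a molecular viewer: negative,
#' stabilising contributions can then be coloured against destabilising
#' ones.
#'
#' @param structure a `pcn_structure`
#' @param residue_energies data frame with columns `chain`, `res_seq` and
#'   `energy` (kJ/mol)
#' @return the annotated `pcn_structure`
#' @export
annotate_decomposition <- function(structure, residue_energies) {
  residue_energies <- as.data.frame(residue_energies)
  if (!all(c("chain", "res_seq", "energy") %in% names(residue_energies)))
    rlang::abort("residue_energies needs columns chain, res_seq, energy",
                 class = "pcnmd_schema_error")
  vals <- data.frame(chain = residue_energies$chain,
                     res_seq = residue_energies$res_seq,
                     value = residue_energies$energy)
  if ("i_code" %in% names(residue_energies))
    vals$i_code <- residue_energies$i_code
  set_residue_bfactor(structure, vals)
}

#' Read a per-residue energy TSV (`chain  res_seq  energy_kj_mol`)
#' @param file path
#' @return tibble with columns `chain`, `res_seq`, `energy`
#' @export
read_residue_energies <- function(file) {
  x <- tibble::as_tibble(read.delim(file, comment.char = "#"))
  if ("energy_kj_mol" %in% names(x)) names(x)[names(x) == "energy_kj_mol"] <- "energy"
  if (!all(c("chain", "res_seq", "energy") %in% names(x)))
    rlang::abort("needs columns chain, res_seq, energy(_kj_mol)",
                 class = "pcnmd_schema_error")
  x
}
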