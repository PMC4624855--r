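#' @title Solvent-accessible surface area and solvation terms
#' @description Shrake-Rupley SASA (golden-spiral sphere sampling with a
#'   water-sized probe), the Eisenberg-McLachlan atomic-solvation-parameter
#'   estimate of the solvation free energy used as a contact-network
#'   descriptor, and the surface-tension apolar term of MM-PBSA bookkeeping.
#' @name solvation
NULL

# Bondi van der Waals radii, Angstrom
bondi_radii <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
                 P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

#' Solvation / SASA parameter set
#'
#' Atomic solvation parameters (Delta sigma, cal/(mol A^2)) follow the
#' Eisenberg-McLachlan atom classes: apolar carbon +16, neutral N/O -6,
#' carboxylate oxygen -24, charged nitrogen -50, sulfur +21. Radii default to
#' the Bondi set with a 1.4 A probe and 960 sphere points (about 1% area
#' error on an isolated sphere).
#'
#' @param dsigma named vector of per-class solvation parameters,
#'   cal/(mol A^2); classes `C`, `N/O`, `O-`, `N+`, `S`
#' @param probe_radius probe radius, A
#' @param n_points sphere sample points per atom
#' @param radii named per-element radii, A (merged over the Bondi defaults)
#' @return list of class `pcn_solvation_params`
#' @export
solvation_params <- function(dsigma = c(C = 16, `N/O` = -6, `O-` = -24,
                                        `N+` = -50, S = 21),
                             probe_radius = 1.4, n_points = 960,
                             radii = NULL) {
  stopifnot(probe_radius > 0, n_points >= 12)
  r <- bondi_radii
  if (!is.null(radii)) r[toupper(names(radii))] <- radii
  if (any(r <= 0)) rlang::abort("radii must be positive",
                                class = "pcnmd_parameter_error")
  structure(list(dsigma = dsigma, probe_radius = probe_radius,
                 n_points = as.integer(n_points), radii = r),
            class = "pcn_solvation_params")
}

golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  theta <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(theta), rho * sin(theta), z)
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Each atom's sphere is expanded by the probe radius and sampled with a
#' golden-spiral point set; the accessible area is the unoccluded point
#' fraction times the expanded-sphere area.
#'
#' @param structure a `pcn_structure` with element assignments
#' @param probe probe radius, A
#' @param n_points sphere sample points per atom
#' @param radii optional named per-element radius overrides, A
#' @param include_het include HETATM atoms?
#' @return tibble with one row per atom: `serial`, `name`, `chain`,
#'   `res_seq`, `res_name`, `element`, `area` (A^2); the total is
#'   `sum(.$area)`
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960, radii = NULL,
                 include_het = FALSE) {
  stopifnot(is_structure(structure), probe > 0)
  at <- structure$atoms
  if (!include_het) at <- at[!at$is_het, , drop = FALSE]
  rset <- bondi_radii
  if (!is.null(radii)) rset[toupper(names(radii))] <- radii
  r <- rset[at$element]
  if (any(is.na(r)))
    rlang::abort(sprintf("no radius for element(s): %s",
                         paste(unique(at$element[is.na(r)]), collapse = ", ")),
                 class = "pcnmd_radius_error")
  xyz <- as.matrix(at[, c("x", "y", "z")])
  n <- nrow(xyz)
  sphere <- golden_spiral(n_points)
  rexp <- r + probe
  area <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (rexp[i] + rexp)^2 & seq_len(n) != i)
    if (length(nb) == 0) {
      area[i] <- 4 * pi * rexp[i]^2
      next
    }
    pts <- sweep(sphere * rexp[i], 2, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- rowSums(sweep(pts[free, , drop = FALSE], 2, xyz[j, ])^2)
      free[free] <- dj2 >= rexp[j]^2
    }
    area[i] <- 4 * pi * rexp[i]^2 * sum(free) / n_points
  }
  tibble::tibble(serial = at$serial, name = at$name, chain = at$chain,
                 res_seq = at$res_seq, res_name = at$res_name,
                 element = at$element, area = area)
}

# Eisenberg-McLachlan atom class from element, atom name and residue
solvation_class <- function(element, name, res_name) {
  cls <- rep(NA_character_, length(element))
  cls[element == "C"] <- "C"
  cls[element == "S"] <- "S"
  no <- element %in% c("N", "O")
  cls[no] <- "N/O"
  cls[element == "O" &
      ((res_name == "ASP" & name %in% c("OD1", "OD2")) |
       (res_name == "GLU" & name %in% c("OE1", "OE2")) |
       name == "OXT")] <- "O-"
  cls[element == "N" &
      ((res_name == "LYS" & name == "NZ") |
       (res_name == "ARG" & name %in% c("NE", "NH1", "NH2")))] <- "N+"
  cls[element == "H"] <- "H"  # folded into heavy atoms: zero contribution
  cls
}

#' Eisenberg-McLachlan solvation free energy
#'
#' `dG_solv = sum_atoms Delta-sigma(class) * ASA(atom)`, in kcal/mol: a
#' quantitative descriptor of protein stability in water, used here as the
#' chemical-physical companion to the topological network descriptors.
#' Hydrogens contribute no term of their own (united-atom convention).
#'
#' @param structure a `pcn_structure`
#' @param params a [solvation_params()] list
#' @return kcal/mol
#' @export
solvation_free_energy <- function(structure, params = solvation_params()) {
  stopifnot(inherits(params, "pcn_solvation_params"))
  areas <- sasa(structure, probe = params$probe_radius,
                n_points = params$n_points,
                radii = params$radii)
  cls <- solvation_class(areas$element, areas$name, areas$res_name)
  if (any(is.na(cls))) {
    bad <- areas[is.na(cls), , drop = FALSE]
    rlang::abort(sprintf("unclassifiable atom(s): %s",
                         paste(sprintf("%s %s:%d %s", bad$name, bad$chain,
                                       bad$res_seq, bad$res_name),
                               collapse = ", ")),
                 class = "pcnmd_classification_error")
  }
  ds <- c(params$dsigma, H = 0)
  sum(ds[cls] * areas$area) / 1000
}

#' Apolar solvation term from a total SASA
#'
#' `G_apolar = gamma * SASA` with the surface-tension constant
#' `gamma = 0.022 kJ/(mol A^2)` by default; the hydrophobic-effect part of a
#' solvation free energy. Binding buries interface area, so the apolar term
#' of binding (complex minus parts) is negative for any docked pair.
#'
#' @param total_sasa total solvent-accessible surface area, A^2
#' @param gamma surface tension, kJ/(mol A^2)
#' @return kJ/mol
#' @export
apolar_term <- function(total_sasa, gamma = 0.022) {
  if (any(total_sasa < 0))
    rlang::abort("SASA cannot be negative", class = "pcnmd_domain_error")
  gamma * total_sasa
}
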