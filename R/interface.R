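#' @title Protein-protein interface statistics
#' @description Per-frame atomic contact counts between two groups (minimum
#'   distance semantics: the non-integer frame means reported for complexes,
#'   e.g. 480.7 +/- 0.5, arise from averaging pair counts over frames) and
#'   geometric hydrogen-bond detection with per-bond trajectory occupancy.
#' @name interface
NULL

cross_dist2 <- function(a, b) {
  outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
}

#' Interface contact counts over a trajectory
#'
#' Counts, per frame, atom pairs (one atom per group) within `cutoff`;
#' optionally collapses to residue pairs in contact. Contact counting is
#' symmetric in the two groups.
#'
#' @param ensemble a `pcn_ensemble`
#' @param group_a,group_b disjoint atom selections
#' @param cutoff contact distance, A (default 3.5)
#' @param mode "atoms" counts atom pairs (minimum-distance tool semantics);
#'   "residues" counts residue pairs with any atom pair in range
#' @return a `pcn_contacts` object; `tidy()` gives the per-frame series and
#'   `glance()` the mean +/- sd summary
#' @export
interface_contacts <- function(ensemble, group_a, group_b, cutoff = 3.5,
                               mode = c("atoms", "residues")) {
  mode <- match.arg(mode)
  ia <- selection_indices(ensemble$reference, group_a)
  ib <- selection_indices(ensemble$reference, group_b)
  if (length(intersect(ia, ib)) > 0)
    rlang::abort("interface groups overlap", class = "pcnmd_overlap")
  if (length(ia) == 0 || length(ib) == 0)
    rlang::abort("empty selection", class = "pcnmd_selection_empty")
  at <- ensemble$reference$atoms
  res_a <- paste(at$chain[ia], at$res_seq[ia], at$i_code[ia], sep = "|")
  res_b <- paste(at$chain[ib], at$res_seq[ib], at$i_code[ib], sep = "|")
  counts <- vapply(seq_len(n_frames(ensemble)), function(f) {
    xyz <- ensemble$frames[f, , , drop = TRUE]
    hit <- cross_dist2(xyz[ia, , drop = FALSE],
                       xyz[ib, , drop = FALSE]) <= cutoff^2
    if (mode == "atoms") sum(hit)
    else {
      pairs <- which(hit, arr.ind = TRUE)
      length(unique(paste(res_a[pairs[, 1]], res_b[pairs[, 2]], sep = "::")))
    }
  }, 0)
  structure(list(per_frame = tibble::tibble(time_ps = ensemble$times,
                                            n_contacts = as.integer(counts)),
                 mean = mean(counts),
                 sd = sqrt(mean((counts - mean(counts))^2)),
                 cutoff = cutoff, mode = mode),
            class = "pcn_contacts")
}

#' @export
print.pcn_contacts <- function(x, ...) {
  cat(sprintf("<pcn_contacts> %s within %.2f A: %.1f +/- %.1f over %d frames\n",
              if (x$mode == "atoms") "atom pairs" else "residue pairs",
              x$cutoff, x$mean,
              ifelse(is.na(x$sd), 0, x$sd), nrow(x$per_frame)))
  invisible(x)
}

#' @describeIn interface_contacts per-frame contact counts
#' @param x a `pcn_contacts`
#' @param ... unused
#' @method tidy pcn_contacts
#' @export
tidy.pcn_contacts <- function(x, ...) x$per_frame

#' @describeIn interface_contacts one-row mean/sd summary
#' @method glance pcn_contacts
#' @export
glance.pcn_contacts <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd,
                 min = min(x$per_frame$n_contacts),
                 max = max(x$per_frame$n_contacts),
                 n_frames = nrow(x$per_frame),
                 cutoff = x$cutoff, mode = x$mode)
}

title_case_res <- function(res_name, res_seq) {
  paste0(substr(res_name, 1, 1),
         tolower(substr(res_name, 2, nchar(res_name))), res_seq)
}

#' Hydrogen bonds across an interface, with occupancy
#'
#' Donors are N/O atoms; in hydrogen mode a bound hydrogen (within 1.25 A in
#' the reference frame) must exist, and a frame counts iff the
#' donor-acceptor distance is at most `d_max` and the D-H...A angle deviates
#' from linearity by at most `angle_max` degrees. In heavy-atom mode (used
#' automatically when the structure carries no hydrogens) only the distance
#' criterion applies. Occupancy is the fraction of frames satisfying the
#' criteria; bonds at or above `occupancy_min` are reported, sorted by
#' occupancy, labelled "Donor-residue/Acceptor-residue" (e.g. Tyr101/Glu93).
#'
#' @param ensemble a `pcn_ensemble`
#' @param group_a,group_b disjoint atom selections; donors of each group are
#'   paired with acceptors of the other
#' @param d_max donor-acceptor distance cut-off, A
#' @param angle_max maximal D-H...A deviation from linear, degrees
#' @param occupancy_min minimal occupancy reported ("high frequency")
#' @param mode "auto", "hydrogen" or "heavy"
#' @return tibble of bonds: donor/acceptor identity columns, `occupancy`,
#'   `label`
#' @export
detect_hbonds <- function(ensemble, group_a, group_b, d_max = 3.5,
                          angle_max = 30, occupancy_min = 0.5,
                          mode = c("auto", "hydrogen", "heavy")) {
  mode <- match.arg(mode)
  ia <- selection_indices(ensemble$reference, group_a)
  ib <- selection_indices(ensemble$reference, group_b)
  if (length(intersect(ia, ib)) > 0)
    rlang::abort("interface groups overlap", class = "pcnmd_overlap")
  at <- ensemble$reference$atoms
  polar <- function(idx) idx[at$element[idx] %in% c("N", "O")]
  pa <- polar(ia); pb <- polar(ib)
  empty <- tibble::tibble(donor_chain = character(), donor_res_seq = integer(),
                          donor_res_name = character(), donor_name = character(),
                          acceptor_chain = character(),
                          acceptor_res_seq = integer(),
                          acceptor_res_name = character(),
                          acceptor_name = character(),
                          occupancy = numeric(), label = character())
  if (length(pa) == 0 || length(pb) == 0) {
    rlang::warn("no polar (N/O) atoms in one of the groups")
    return(empty)
  }
  hyd <- which(at$element == "H")
  use_h <- mode == "hydrogen" || (mode == "auto" && length(hyd) > 0)
  if (mode == "hydrogen" && length(hyd) == 0)
    rlang::abort("hydrogen mode requested but the structure has no hydrogens",
                 class = "pcnmd_missing_atom")
  ref <- coords(ensemble$reference)
  bound_h <- if (use_h) {
    lapply(seq_len(nrow(at)), function(i) {
      if (!at$element[i] %in% c("N", "O")) return(integer(0))
      d2 <- rowSums(sweep(ref[hyd, , drop = FALSE], 2, ref[i, ])^2)
      hyd[d2 <= 1.25^2]
    })
  }
  donors_of <- function(idx) if (!use_h) idx else
    idx[vapply(idx, function(i) length(bound_h[[i]]) > 0, TRUE)]
  cand <- rbind(
    expand.grid(donor = donors_of(pa), acceptor = pb),
    expand.grid(donor = donors_of(pb), acceptor = pa))
  if (!use_h) {
    # without hydrogens donor/acceptor roles are indistinguishable: keep each
    # unordered pair once
    key <- paste(pmin(cand$donor, cand$acceptor),
                 pmax(cand$donor, cand$acceptor))
    cand <- cand[!duplicated(key), , drop = FALSE]
  }
  if (nrow(cand) == 0) {
    rlang::warn("no donor atoms found")
    return(empty)
  }
  f <- n_frames(ensemble)
  hits <- matrix(FALSE, nrow(cand), f)
  cosmax <- cos((180 - angle_max) * pi / 180)
  for (fr in seq_len(f)) {
    xyz <- ensemble$frames[fr, , , drop = TRUE]
    dvec <- xyz[cand$donor, , drop = FALSE] - xyz[cand$acceptor, , drop = FALSE]
    ok <- rowSums(dvec^2) <= d_max^2
    if (use_h) {
      for (q in which(ok)) {
        hs <- bound_h[[cand$donor[q]]]
        # D-H...A angle at the hydrogen; take the most linear bound H
        cosang <- vapply(hs, function(h) {
          u <- xyz[cand$donor[q], ] - xyz[h, ]
          v <- xyz[cand$acceptor[q], ] - xyz[h, ]
          sum(u * v) / sqrt(sum(u^2) * sum(v^2))
        }, 0)
        ok[q] <- any(cosang <= cosmax)
      }
    }
    hits[, fr] <- ok
  }
  occ <- rowMeans(hits)
  keep <- which(occ >= occupancy_min)
  if (length(keep) == 0) return(empty)
  d <- cand$donor[keep]; a <- cand$acceptor[keep]
  out <- tibble::tibble(
    donor_chain = at$chain[d], donor_res_seq = at$res_seq[d],
    donor_res_name = at$res_name[d], donor_name = at$name[d],
    acceptor_chain = at$chain[a], acceptor_res_seq = at$res_seq[a],
    acceptor_res_name = at$res_name[a], acceptor_name = at$name[a],
    occupancy = occ[keep],
    label = paste0(title_case_res(at$res_name[d], at$res_seq[d]), "/",
                   title_case_res(at$res_name[a], at$res_seq[a])))
  dplyr::arrange(out, dplyr::desc(.data$occupancy))
}
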