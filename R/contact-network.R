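#' @title Protein contact networks and their descriptors
#' @description Residue interaction graphs on alpha-carbons: an edge joins two
#'   residues whose CA-CA distance falls within a band (default 4-8 A,
#'   inclusive) chosen to capture van der Waals packing while excluding
#'   covalent neighbours, plus the global descriptors used to follow a
#'   trajectory: average degree, average shortest path, graph energy and
#'   Eisenberg-McLachlan solvation free energy.
#' @name contact-network
NULL

new_network <- function(nodes, adjacency) {
  adjacency <- (adjacency != 0) * 1L
  stopifnot(nrow(adjacency) == ncol(adjacency),
            nrow(nodes) == nrow(adjacency))
  if (any(diag(adjacency) != 0)) stop("self-loops are not allowed")
  if (any(adjacency != t(adjacency))) stop("adjacency must be symmetric")
  structure(list(nodes = tibble::as_tibble(nodes), adjacency = adjacency),
            class = "pcn_network")
}

#' @rdname is_structure
#' @export
is_network <- function(x) inherits(x, "pcn_network")

#' Build a network from a plain adjacency matrix
#'
#' For benchmark graphs that do not come from a structure; nodes get
#' synthetic identities (chain "A", sequential residue numbers).
#'
#' @param adjacency symmetric 0/1 matrix without self-loops
#' @param nodes optional node table (`index`, `chain`, `res_seq`, `i_code`,
#'   `res_name`)
#' @return a `pcn_network`
#' @export
network_from_adjacency <- function(adjacency, nodes = NULL) {
  n <- nrow(adjacency)
  if (is.null(nodes))
    nodes <- tibble::tibble(index = seq_len(n), chain = "A",
                            res_seq = seq_len(n), i_code = "",
                            res_name = "ALA")
  new_network(nodes, adjacency)
}

#' @export
print.pcn_network <- function(x, ...) {
  cat(sprintf("<pcn_network> %d nodes, %d edges\n",
              nrow(x$nodes), n_edges(x)))
  invisible(x)
}

#' Number of edges of a contact network
#' @param net a `pcn_network`
#' @return integer
#' @export
n_edges <- function(net) sum(net$adjacency) / 2

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected")
}

#' Build the alpha-carbon contact network of a structure
#'
#' Nodes are the protein residues' alpha-carbons, indexed sequentially in
#' atom order across chains. An edge joins nodes `i`, `j` iff
#' `dmin <= |CA_i - CA_j| <= dmax` (inclusive) and `|i - j| >= 2`: pairs
#' adjacent in sequence are excluded explicitly, not just via the distance
#' floor, because the graph is meant to represent non-covalent contacts only.
#' Consecutive indices across a chain break are not covalently bonded and may
#' form edges. HETATM records never contribute nodes.
#'
#' @param structure a `pcn_structure`; every protein residue must have an
#'   alpha-carbon
#' @param dmin,dmax distance band, Angstrom (defaults 4 and 8)
#' @return a `pcn_network`
#' @export
build_contact_network <- function(structure, dmin = 4, dmax = 8) {
  stopifnot(is_structure(structure), dmin > 0, dmin < dmax)
  res <- residues(structure)
  if (any(!res$has_ca)) {
    bad <- res[!res$has_ca, ]
    rlang::abort(sprintf("residue(s) lacking an alpha-carbon: %s",
                         paste(sprintf("%s:%d%s %s", bad$chain, bad$res_seq,
                                       bad$i_code, bad$res_name),
                               collapse = ", ")),
                 class = "pcnmd_missing_atom")
  }
  at <- structure$atoms
  ca <- at[!at$is_het & at$name == "CA" & at$element == "C", , drop = FALSE]
  # one CA per residue (altLocs resolved at parse time); keep first otherwise
  key <- paste(ca$chain, ca$res_seq, ca$i_code, sep = "|")
  ca <- ca[!duplicated(key), , drop = FALSE]
  n <- nrow(ca)
  d <- as.matrix(dist(as.matrix(ca[, c("x", "y", "z")])))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  adj <- (d >= dmin & d <= dmax & sep >= 2) * 1L
  nodes <- tibble::tibble(index = seq_len(n), chain = ca$chain,
                          res_seq = ca$res_seq, i_code = ca$i_code,
                          res_name = ca$res_name)
  new_network(nodes, adj)
}

#' Average degree of a contact network
#'
#' Mean number of contacts per residue; identically `2 * n_edges / n_nodes`.
#'
#' @param net a `pcn_network`
#' @return numeric scalar
#' @export
average_degree <- function(net) {
  stopifnot(is_network(net))
  if (nrow(net$nodes) == 0)
    rlang::abort("empty graph", class = "pcnmd_empty_graph")
  mean(rowSums(net$adjacency))
}

#' Average shortest-path length
#'
#' Mean unweighted (hop-count) shortest-path length over all unordered
#' reachable node pairs. On a disconnected graph the average is taken within
#' components, and the `connected` attribute of the result is `FALSE`.
#'
#' @param net a `pcn_network` with at least 2 nodes and 1 edge
#' @return numeric scalar with attribute `connected`
#' @export
average_shortest_path <- function(net) {
  stopifnot(is_network(net), nrow(net$nodes) >= 2)
  if (n_edges(net) == 0)
    rlang::abort("no paths exist in an edgeless graph",
                 class = "pcnmd_no_path")
  g <- as_igraph(net)
  out <- igraph::mean_distance(g, directed = FALSE, unconnected = TRUE)
  attr(out, "connected") <- igraph::is_connected(g)
  out
}

#' Graph energy
#'
#' Sum of the absolute eigenvalues of the adjacency matrix: a global
#' connectivity descriptor coupling graph structure to the interaction
#' pattern of the molecule.
#'
#' @param net a `pcn_network`
#' @return numeric scalar (0 for an edgeless graph)
#' @export
graph_energy <- function(net) {
  stopifnot(is_network(net))
  if (nrow(net$nodes) == 0)
    rlang::abort("empty graph", class = "pcnmd_empty_graph")
  if (n_edges(net) == 0) return(0)
  sum(abs(eigen(net$adjacency, symmetric = TRUE, only.values = TRUE)$values))
}

#' All four network descriptors of one structure
#'
#' @param structure a `pcn_structure`
#' @param dmin,dmax contact band, Angstrom
#' @param solvation compute the Eisenberg-McLachlan solvation term? (the
#'   SASA evaluation dominates the cost)
#' @param solv_params a [solvation_params()] list
#' @return one-row tibble: `n_nodes`, `n_edges`, `adeg`, `asp`,
#'   `graph_energy`, `dG_solv` (kcal/mol, `NA` when `solvation = FALSE`),
#'   `connected`
#' @export
network_descriptors <- function(structure, dmin = 4, dmax = 8,
                                solvation = TRUE,
                                solv_params = solvation_params()) {
  net <- build_contact_network(structure, dmin, dmax)
  asp <- if (n_edges(net) > 0) average_shortest_path(net) else NA_real_
  conn <- isTRUE(attr(asp, "connected"))
  tibble::tibble(
    n_nodes = nrow(net$nodes),
    n_edges = n_edges(net),
    adeg = average_degree(net),
    asp = as.numeric(asp),
    graph_energy = graph_energy(net),
    dG_solv = if (solvation)
      solvation_free_energy(structure, solv_params) else NA_real_,
    connected = conn)
}

#' Per-frame network descriptors of an ensemble
#'
#' Recomputes the contact network and its descriptors on every frame,
#' aligned to the frame times, e.g. over 100 frames taken at a 10 ps stride
#' from the tail of a production run.
#'
#' @param ensemble a `pcn_ensemble` with at least 2 frames
#' @inheritParams network_descriptors
#' @return tibble with columns `time_ps`, `adeg`, `asp`, `graph_energy`,
#'   `dG_solv`, `n_nodes`, `n_edges`, `connected`
#' @export
descriptor_series <- function(ensemble, dmin = 4, dmax = 8, solvation = TRUE,
                              solv_params = solvation_params()) {
  if (n_frames(ensemble) < 2)
    rlang::abort("descriptor series needs at least 2 frames",
                 class = "pcnmd_insufficient_frames")
  rows <- lapply(seq_len(n_frames(ensemble)), function(i) {
    row <- tryCatch(
      network_descriptors(frame_structure(ensemble, i), dmin, dmax,
                          solvation = solvation, solv_params = solv_params),
      error = function(e) {
        rlang::abort(sprintf("frame %d: %s", i, conditionMessage(e)),
                     class = class(e)[1])
      })
    dplyr::mutate(row, time_ps = ensemble$times[i], .before = 1)
  })
  dplyr::bind_rows(rows)
}

# ---- edge-list / node-table interchange ------------------------------------

#' Write a network as edge-list and node-table TSVs
#' @param net a `pcn_network`
#' @param edges_file,nodes_file output paths (either may be `NULL` to skip)
#' @return invisibly, `net`
#' @export
write_network <- function(net, edges_file, nodes_file = NULL) {
  if (!is.null(edges_file)) {
    e <- which(upper.tri(net$adjacency) & net$adjacency == 1, arr.ind = TRUE)
    edges <- data.frame(node_i = e[, 1], node_j = e[, 2])
    edges <- edges[order(edges$node_i, edges$node_j), , drop = FALSE]
    write.table(edges, edges_file, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  if (!is.null(nodes_file))
    write.table(as.data.frame(net$nodes), nodes_file, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(net)
}

#' Read a network from an edge-list TSV (plus optional node table)
#' @param edges_file TSV with columns `node_i`, `node_j` (1-based indices)
#' @param nodes_file optional node table TSV as written by [write_network()]
#' @return a `pcn_network`
#' @export
read_network <- function(edges_file, nodes_file = NULL) {
  e <- read.delim(edges_file, comment.char = "#")
  nodes <- if (!is.null(nodes_file))
    tibble::as_tibble(read.delim(nodes_file, comment.char = "#"))
  else {
    n <- max(e$node_i, e$node_j)
    tibble::tibble(index = seq_len(n), chain = "A", res_seq = seq_len(n),
                   i_code = "", res_name = "UNK")
  }
  adj <- matrix(0L, nrow(nodes), nrow(nodes))
  adj[cbind(e$node_i, e$node_j)] <- 1L
  adj[cbind(e$node_j, e$node_i)] <- 1L
  new_network(nodes, adj)
}
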