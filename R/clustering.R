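#' @title Spectral partitioning of contact networks
#' @description Splits a residue contact graph into functional modules via
#'   the symmetric normalised Laplacian embedding plus k-means, flags
#'   "whisker" residues whose cluster differs from both sequence neighbours
#'   (the signature of a long-range contact), and lays the partition out as
#'   the node-by-cluster occupancy grid used for partition colour maps.
#' @name network-clustering
NULL

#' Spectral partition of a contact network
#'
#' Embedding: `L = I - D^{-1/2} A D^{-1/2}`; nodes are represented by the k
#' eigenvectors of smallest eigenvalue, rows normalised to unit length, and
#' clustered by k-means (25 restarts under the given seed, so the result is
#' deterministic). Labels are 0-based and canonicalised by first appearance
#' along the sequence. The Laplacian spectrum is kept in the result so the
#' eigengap can guide the choice of k; no automatic model selection is done
#' (two clusters suit a single compact dimer, four a two-body complex).
#'
#' @param net a `pcn_network` with at least one edge
#' @param k number of clusters (2..n_nodes)
#' @param seed RNG seed for k-means restarts
#' @return a `pcn_partition`: `labels` (0-based integer per node), `k`,
#'   `seed`, `whiskers` (node indices), `nodes`, `laplacian_eigenvalues`
#' @export
spectral_partition <- function(net, k, seed = 0) {
  stopifnot(is_network(net))
  n <- nrow(net$nodes)
  if (k < 2 || k > n)
    rlang::abort(sprintf("k must be in [2, %d]", n), class = "pcnmd_size_error")
  if (n_edges(net) == 0)
    rlang::abort("cannot partition an edgeless graph",
                 class = "pcnmd_no_structure")
  ncomp <- igraph::count_components(as_igraph(net))
  if (ncomp > k)
    rlang::abort(sprintf(
      "graph has %d connected components but k = %d; raise k to at least %d or partition components separately",
      ncomp, k, ncomp), class = "pcnmd_size_error")
  a <- net$adjacency
  deg <- rowSums(a)
  dis <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  lap <- diag(n) - a * tcrossprod(dis)
  eig <- eigen((lap + t(lap)) / 2, symmetric = TRUE)
  emb <- eig$vectors[, n:(n - k + 1), drop = FALSE]  # k smallest
  norms <- sqrt(rowSums(emb^2))
  emb <- emb / ifelse(norms > 0, norms, 1)
  km <- with_seed(seed, {
    tryCatch(kmeans(emb, centers = k, nstart = 25, iter.max = 100),
             error = function(e)
               kmeans(emb, centers = k, nstart = 25, iter.max = 100,
                      algorithm = "Lloyd"))
  })
  raw <- km$cluster
  labels <- as.integer(match(raw, unique(raw)) - 1L)
  part <- structure(list(labels = labels, k = as.integer(k),
                         seed = as.integer(seed), nodes = net$nodes,
                         laplacian_eigenvalues = rev(eig$values)),
                    class = "pcn_partition")
  part$whiskers <- find_whiskers(part)
  part
}

#' @export
print.pcn_partition <- function(x, ...) {
  cat(sprintf("<pcn_partition> %d nodes into k = %d clusters (sizes: %s); %d whisker(s)\n",
              length(x$labels), x$k,
              paste(tabulate(x$labels + 1L, x$k), collapse = ", "),
              length(x$whiskers)))
  gaps <- diff(x$laplacian_eigenvalues[seq_len(min(8, length(x$labels)))])
  cat("  leading Laplacian eigengaps:",
      paste(sprintf("%.3f", gaps), collapse = " "), "\n")
  invisible(x)
}

#' @describeIn spectral_partition per-node table: `index`, `chain`,
#'   `res_seq`, `res_name`, `cluster`, `whisker`
#' @param x a `pcn_partition`
#' @param ... unused
#' @method tidy pcn_partition
#' @export
tidy.pcn_partition <- function(x, ...) {
  dplyr::mutate(x$nodes[, c("index", "chain", "res_seq", "res_name")],
                cluster = x$labels,
                whisker = .data$index %in% x$whiskers)
}

#' Find whisker nodes of a partition
#'
#' A node is a whisker iff its cluster label differs from the labels of both
#' of its sequence neighbours within the same chain (at chain ends, from its
#' single neighbour): an isolated label shift marking a long-range contact.
#' A partition whose labels form sequence-contiguous blocks has none.
#'
#' @param partition a `pcn_partition`, or a plain label vector
#' @param chains optional chain id per node when `partition` is a vector
#' @return integer vector of node indices (1-based)
#' @export
find_whiskers <- function(partition, chains = NULL) {
  if (inherits(partition, "pcn_partition")) {
    labels <- partition$labels
    chains <- partition$nodes$chain
  } else {
    labels <- partition
    if (is.null(chains)) chains <- rep("A", length(labels))
  }
  n <- length(labels)
  if (n == 0) return(integer(0))
  out <- logical(n)
  for (ch in unique(chains)) {
    pos <- which(chains == ch)
    lab <- labels[pos]
    m <- length(pos)
    if (m == 1) next
    differs_prev <- c(TRUE, lab[-1] != lab[-m])
    differs_next <- c(lab[-m] != lab[-1], TRUE)
    w <- differs_prev & differs_next
    w[1] <- lab[1] != lab[2]
    w[m] <- lab[m] != lab[m - 1]
    out[pos] <- w
  }
  which(out)
}

#' Partition colour-map grid
#'
#' Lays the partition out as a nodes x k occupancy matrix: row per node in
#' sequence order, column per cluster, exactly one occupied cell per row.
#' Unoccupied cells are the map background; whisker nodes are flagged for
#' the renderer.
#'
#' @param partition a `pcn_partition`
#' @return a `pcn_partition_map`: `matrix` (nodes x k, 0/1), `whiskers`,
#'   `legend` (cluster to colour index)
#' @export
partition_map <- function(partition) {
  stopifnot(inherits(partition, "pcn_partition"))
  n <- length(partition$labels)
  m <- matrix(0L, n, partition$k)
  m[cbind(seq_len(n), partition$labels + 1L)] <- 1L
  structure(list(matrix = m, whiskers = partition$whiskers,
                 legend = setNames(seq_len(partition$k) - 1L,
                                   paste0("cluster_", seq_len(partition$k) - 1L)),
                 nodes = partition$nodes),
            class = "pcn_partition_map")
}

#' @export
print.pcn_partition_map <- function(x, ...) {
  cat(sprintf("<pcn_partition_map> %d nodes x %d clusters, %d whisker(s)\n",
              nrow(x$matrix), ncol(x$matrix), length(x$whiskers)))
  invisible(x)
}

#' Partition colour-map plot
#' @param object a `pcn_partition_map`
#' @param ... unused
#' @method autoplot pcn_partition_map
#' @export
autoplot.pcn_partition_map <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::mutate(tibble::as_tibble(object$matrix, .name_repair = ~
                    paste0("cluster_", seq_along(.x) - 1L)),
                  node = seq_len(nrow(object$matrix))),
    -"node", names_to = "cluster", values_to = "occupied")
  df$occupied <- factor(ifelse(df$occupied == 1, sub("^cluster_", "", df$cluster),
                               "background"))
  df$whisker <- df$node %in% object$whiskers & df$occupied != "background"
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$node,
                                   fill = .data$occupied)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$whisker, , drop = FALSE],
                        shape = 4, size = 0.8, colour = "white") +
    ggplot2::scale_fill_manual(
      values = c(background = "#10104a",
                 setNames(scales_hue(ncol(object$matrix)),
                          as.character(seq_len(ncol(object$matrix)) - 1L)))) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "cluster", y = "node (sequence order)",
                  fill = "cluster", title = "Partition colour map")
}

scales_hue <- function(n) grDevices::hcl(h = seq(15, 375, length.out = n + 1)[-1],
                                         c = 100, l = 65)
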