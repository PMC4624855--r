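# shared helpers: tiny structure builders, independent graph oracles,
# random rigid motions

atoms_tbl <- function(name, x, y, z, chain = "A", res_seq = seq_along(name),
                      res_name = "ALA", element = NULL) {
  tb <- tibble::tibble(name = name, chain = chain, res_seq = as.integer(res_seq),
                       res_name = res_name, x = x, y = y, z = z)
  if (!is.null(element)) tb$element <- element
  tb
}

# one CA pseudo-atom per residue at the given coordinates
ca_structure <- function(xyz, chain = "A") {
  xyz <- as.matrix(xyz)
  new_structure(atoms_tbl(rep("CA", nrow(xyz)), xyz[, 1], xyz[, 2], xyz[, 3],
                          chain = chain, element = rep("C", nrow(xyz))))
}

# ensemble with frames supplied as a list of A x 3 matrices
ensemble_from_frames <- function(reference, frame_list, time_step = 10) {
  fr <- array(NA_real_, c(length(frame_list), nrow(frame_list[[1]]), 3))
  for (i in seq_along(frame_list)) fr[i, , ] <- frame_list[[i]]
  new_ensemble(reference, fr, time_step * (seq_along(frame_list) - 1))
}

random_rotation <- function() {
  m <- matrix(rnorm(9), 3)
  qr_d <- qr(m)
  r <- qr.Q(qr_d)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

# independent BFS average-shortest-path oracle (reachable unordered pairs)
bfs_asp_oracle <- function(adj) {
  n <- nrow(adj)
  total <- 0; pairs <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] == 1 & is.na(dist))
      dist[nb] <- dist[v] + 1L
      queue <- c(queue, nb)
    }
    reach <- which(!is.na(dist) & seq_len(n) != s)
    total <- total + sum(dist[reach])
    pairs <- pairs + length(reach)
  }
  total / pairs  # ordered pairs cancel: same as unordered average
}

# graph energy oracle via singular values (for symmetric A these are the
# absolute eigenvalues)
svd_energy_oracle <- function(adj) sum(svd(adj)$d)

random_network <- function(n, p, seed) {
  planted_partition_graph(n, p_in = p, p_out = 0, seed = seed)
}

path_graph <- function(n) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1L
  network_from_adjacency(adj)
}

star_graph <- function(n) {
  adj <- matrix(0L, n, n)
  adj[1, 2:n] <- adj[2:n, 1] <- 1L
  network_from_adjacency(adj)
}

complete_graph <- function(n) network_from_adjacency(1 - diag(n))
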