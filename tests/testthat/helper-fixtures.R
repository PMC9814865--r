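# small fixture graphs built in code

two_site_chain <- function() rxn_network(rbind(c(1, 2)), 2)

path3 <- function() rxn_network(rbind(c(1, 2), c(2, 3)), 3)

# random connected graph: spanning tree + extra random edges
random_connected_graph <- function(n, extra = n %/% 2) {
  stopifnot(n >= 2)
  edges <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  pool <- t(combn(n, 2))
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  avail <- pool[!(key(pool) %in% key(edges)), , drop = FALSE]
  if (extra > 0 && nrow(avail) > 0) {
    take <- sample.int(nrow(avail), min(extra, nrow(avail)))
    edges <- rbind(edges, avail[take, , drop = FALSE])
  }
  rxn_network(edges, n, target = sample.int(n, 1L))
}

# independent union-find component counter (oracle for the percolation
# builder; deliberately avoids igraph)
largest_component_size_uf <- function(n_vertices, edges) {
  edges <- matrix(as.integer(edges), ncol = 2)
  parent <- seq_len(n_vertices)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (i in seq_len(nrow(edges))) {
    a <- find(edges[i, 1]); b <- find(edges[i, 2])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n_vertices), find, 1L)
  max(tabulate(roots, n_vertices))
}

new_samples_for_test <- function(times, censored = rep(FALSE, length(times))) {
  confinedrxn:::new_rxn_samples(
    tibble::tibble(walker_id = seq_along(times), time = times,
                   censored = censored),
    list(kind = "test"))
}
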