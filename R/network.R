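#' Discrete state space for a random walk with one reactive site
#'
#' An `rxn_network` is a connected, simple, undirected graph with a common
#' per-edge jump rate `w` and one designated reactive (target) site, always
#' re-indexed to site 1.  The walker waits an exponential time of rate
#' `nu_i = w * degree(i)` at site `i` and then jumps to a uniformly chosen
#' neighbour.  Because the waiting time is inversely proportional to the
#' degree, the stationary distribution is uniform, `q_i = 1/N`, which is the
#' setting in which the Kac mean return time `N / nu_0` is exact.
#'
#' @param edges two-column integer matrix of site pairs (1-based).
#' @param n_sites number of sites `N`.
#' @param target index of the reactive site in the supplied labelling; the
#'   constructor relabels it to 1.
#' @param rate per-edge jump rate `w` (inverse time), default 1.
#' @param family optional character tag recording how the network was built.
#' @param meta optional list of construction parameters (kept for
#'   [exponents_for()]).
#'
#' @return An object of class `rxn_network` with fields `n_sites`, `edges`,
#'   `rate`, `target` (always 1), `degree`, `family`, `meta`.
#' @export
rxn_network <- function(edges, n_sites, target = 1L, rate = 1,
                        family = "custom", meta = list()) {
  edges <- matrix(as.integer(edges), ncol = 2)
  n_sites <- as.integer(n_sites)
  target <- as.integer(target)
  stopifnot(n_sites >= 1, target >= 1, target <= n_sites, rate > 0)
  if (any(edges < 1L | edges > n_sites)) stop("edge endpoint out of range")
  if (any(edges[, 1] == edges[, 2])) stop("self-loops are not allowed")
  # relabel so that the target is site 1
  if (target != 1L) {
    relab <- seq_len(n_sites)
    relab[c(1L, target)] <- c(target, 1L)
    edges[] <- relab[edges]
    target <- 1L
  }
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  if (anyDuplicated(key)) stop("duplicate edges are not allowed")
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n_sites)
  if (any(deg == 0L)) stop("network must be connected (isolated site found)")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::components(g)$no != 1L) stop("network must be connected")
  structure(
    list(n_sites = n_sites, edges = edges, rate = rate, target = 1L,
         degree = deg, family = family, meta = meta),
    class = "rxn_network"
  )
}

#' @export
print.rxn_network <- function(x, ...) {
  cat("<rxn_network> ", x$family, ": N = ", x$n_sites, ", edges = ",
      nrow(x$edges), ", target degree nu0 = ", x$rate * x$degree[x$target],
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.rxn_network <- function(x, ...) {
  tibble(from = x$edges[, 1], to = x$edges[, 2], rate = x$rate)
}

#' Total exit rate at each site
#' @param net an [rxn_network].
#' @return numeric vector `nu_i = w * degree(i)`.
#' @export
site_exit_rates <- function(net) net$rate * net$degree

as_igraph <- function(net) igraph::graph_from_edgelist(net$edges, directed = FALSE)

# ---- builders -------------------------------------------------------------

#' Vicsek fractal of functionality f
#'
#' Iterative star construction: generation 1 is a central site bonded to `f`
#' peripheral sites; each following generation attaches `f` copies of the
#' current structure at the peripheral apexes, corner to corner (for even
#' `f` the copy is attached by the apex antipodal to its outward one, which
#' matches the geometric aggregation picture).  The result is a tree with
#' `N = (f+1)^g` sites; the target is the central site.
#'
#' @param f functionality, `f >= 3`.
#' @param g generation, `g >= 1`.
#' @return an [rxn_network] (family `"vicsek"`).
#' @export
build_vicsek <- function(f, g) {
  f <- as.integer(f); g <- as.integer(g)
  if (f < 3L) stop("functionality f must be >= 3")
  if (g < 1L) stop("generation g must be >= 1")
  n <- f + 1L
  edges <- cbind(1L, 2L:n)          # star: centre 1, leaves 2..f+1
  corners <- 2L:n                   # corner i points in direction i
  for (gen in seq_len(g - 1L)) {
    att <- (seq_len(f) + f %/% 2L - 1L) %% f + 1L  # attaching corner of copy i
    new_edges <- edges
    new_corners <- integer(f)
    for (i in seq_len(f)) {
      off <- i * n
      new_edges <- rbind(new_edges, edges + off,
                         c(corners[i], corners[att[i]] + off))
      new_corners[i] <- corners[i] + off
    }
    edges <- new_edges
    corners <- new_corners
    n <- n * (f + 1L)
  }
  rxn_network(edges, n, target = 1L, family = "vicsek",
              meta = list(f = f, g = g, corners = corners))
}

#' Dual Sierpinski gasket
#'
#' Sites are the elementary upward triangles of the generation-`g` Sierpinski
#' gasket; two sites are bonded when the triangles share a corner.  Built
#' recursively: three copies of the previous generation joined by one bond
#' between each pair of copies.  `N = 3^g`; the target is one apex site
#' (degree 2).
#'
#' @param g generation, `g >= 1`.
#' @return an [rxn_network] (family `"dual_sierpinski"`).
#' @export
build_dual_sierpinski <- function(g) {
  g <- as.integer(g)
  if (g < 1L) stop("generation g must be >= 1")
  edges <- cbind(c(1L, 2L, 1L), c(2L, 3L, 3L))
  corners <- 1:3
  n <- 3L
  for (gen in seq_len(g - 1L)) {
    offs <- (0:2) * n
    new_edges <- do.call(rbind, lapply(offs, function(o) edges + o))
    for (i in 1:2) for (j in (i + 1):3) {
      new_edges <- rbind(new_edges,
                         c(corners[j] + offs[i], corners[i] + offs[j]))
    }
    corners <- corners + offs
    edges <- new_edges
    n <- 3L * n
  }
  rxn_network(edges, n, target = corners[1], family = "dual_sierpinski",
              meta = list(g = g))
}

#' Largest cluster of a 2D bond-percolation lattice
#'
#' Each bond of the `L x L` square lattice is retained independently with
#' probability `retain`; the largest connected component is returned.  The
#' target is the retained site nearest the lattice centre (ties broken by
#' lowest index), a reproducible convention.
#'
#' @param L lattice side, `L >= 4`.
#' @param retain bond retention probability in (0, 1].
#' @param seed optional integer seed (applied with [set.seed()]).
#' @return an [rxn_network] (family `"percolation2d"`).
#' @export
build_percolation <- function(L, retain, seed = NULL) {
  L <- as.integer(L)
  if (L < 4L) stop("lattice side L must be >= 4")
  if (retain <= 0 || retain > 1) stop("retain must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  idx <- function(i, j) (i - 1L) * L + j
  i <- rep(seq_len(L), each = L); j <- rep(seq_len(L), L)
  right <- cbind(idx(i, j), idx(i, j + 1L))[j < L, , drop = FALSE]
  down <- cbind(idx(i, j), idx(i + 1L, j))[i < L, , drop = FALSE]
  all_edges <- rbind(right, down)
  keep <- runif(nrow(all_edges)) < retain
  edges <- all_edges[keep, , drop = FALSE]
  if (nrow(edges) == 0L) stop("no bonds retained; largest component is empty")
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, L * L - igraph::vcount(g)))
  comp <- igraph::components(g)
  big <- which.max(comp$csize)
  members <- which(comp$membership == big)
  if (length(members) < 10L) {
    stop("largest percolation component has fewer than 10 sites; ",
         "increase L or retain")
  }
  sub <- edges[comp$membership[edges[, 1]] == big, , drop = FALSE]
  relab <- integer(L * L)
  relab[members] <- seq_along(members)
  ctr <- (L + 1) / 2
  rows <- (members - 1L) %/% L + 1L
  cols <- (members - 1L) %% L + 1L
  d2 <- (rows - ctr)^2 + (cols - ctr)^2
  target_old <- members[order(d2, members)[1]]
  rxn_network(cbind(relab[sub[, 1]], relab[sub[, 2]]), length(members),
              target = relab[target_old], family = "percolation2d",
              meta = list(L = L, retain = retain, seed = seed))
}

#' Periodic hypercubic lattice
#'
#' A `side^dim` lattice with periodic boundaries, a standard noncompact
#' (for `dim = 3`) discrete state space.  The target is an arbitrary site
#' (site 1); all sites are equivalent by translation invariance.
#'
#' @param side number of sites per dimension, `side >= 3`.
#' @param dim spatial dimension.
#' @return an [rxn_network] (family `"lattice_torus"`).
#' @export
build_lattice_torus <- function(side, dim = 3L) {
  side <- as.integer(side); dim <- as.integer(dim)
  if (side < 3L) stop("side must be >= 3 (periodic images would coincide)")
  if (dim < 1L) stop("dim must be >= 1")
  N <- side^dim
  coords <- arrayInd(seq_len(N), rep(side, dim)) - 1L
  edges <- NULL
  for (d in seq_len(dim)) {
    nb <- coords
    nb[, d] <- (nb[, d] + 1L) %% side
    to <- as.integer(nb %*% side^(seq_len(dim) - 1L)) + 1L
    edges <- rbind(edges, cbind(seq_len(N), to))
  }
  rxn_network(edges, N, target = 1L, family = "lattice_torus",
              meta = list(side = side, dim = dim))
}

# ---- descriptors ----------------------------------------------------------

#' Chemical distance from an origin site
#'
#' Breadth-first (hop-count) distance from `origin` to every site.
#'
#' @param net an [rxn_network].
#' @param origin site index (default: the target).
#' @return a tibble with columns `site`, `distance`.
#' @export
chemical_distance <- function(net, origin = net$target) {
  stopifnot(origin >= 1, origin <= net$n_sites)
  d <- as.integer(igraph::distances(as_igraph(net), v = origin))
  tibble(site = seq_len(net$n_sites), distance = d)
}

#' Sites at a given chemical distance from the target
#' @param net an [rxn_network].
#' @param r chemical distance.
#' @return integer vector of site indices.
#' @export
sites_at_distance <- function(net, r) {
  cd <- chemical_distance(net)
  out <- cd$site[cd$distance == r]
  if (length(out) == 0L) stop("no site at chemical distance ", r)
  out
}

#' Scaling exponents of the standard network families
#'
#' Literature values of the fractal dimension `d_f` (number of sites grows
#' as `R^d_f`) and the walk dimension `d_w` (mean-square displacement grows
#' as `t^{2/d_w}`): Vicsek fractals `d_f = ln(f+1)/ln 3`,
#' `d_w = ln(3(f+1))/ln 3`; dual Sierpinski gasket `d_f = ln 3 / ln 2`,
#' `d_w = ln 5 / ln 2`; 2D critical percolation `d_f = 91/48`,
#' `d_w = 2.878`.  Measured exponents may be substituted via `d_f`/`d_w`.
#'
#' @param family one of `"vicsek"`, `"dual_sierpinski"`, `"percolation2d"`,
#'   or an [rxn_network] built by the corresponding constructor.
#' @param f functionality (Vicsek only).
#' @param d_f,d_w optional overrides.
#' @return an object of class `scaling_exponents`: list with `d_f`, `d_w`,
#'   `nu = d_f/d_w` and the compactness flag (`d_w > d_f`).
#' @export
exponents_for <- function(family, f = NULL, d_f = NULL, d_w = NULL) {
  if (inherits(family, "rxn_network")) {
    f <- family$meta$f
    family <- family$family
  }
  if (is.null(d_f) || is.null(d_w)) {
    known <- switch(family,
      vicsek = {
        if (is.null(f)) stop("Vicsek exponents need the functionality f")
        c(log(f + 1) / log(3), log(3 * (f + 1)) / log(3))
      },
      dual_sierpinski = c(log(3) / log(2), log(5) / log(2)),
      percolation2d = c(91 / 48, 2.878),
      stop("unknown family: ", family)
    )
    if (is.null(d_f)) d_f <- known[1]
    if (is.null(d_w)) d_w <- known[2]
  }
  stopifnot(d_f > 0, d_w > 0)
  structure(list(d_f = d_f, d_w = d_w, nu = d_f / d_w, compact = d_w > d_f),
            class = "scaling_exponents")
}

#' @export
print.scaling_exponents <- function(x, ...) {
  cat(sprintf("<scaling_exponents> d_f = %.4f, d_w = %.4f, nu = %.4f (%s)\n",
              x$d_f, x$d_w, x$nu,
              if (x$compact) "compact" else "noncompact"))
  invisible(x)
}

# ---- edge-list I/O --------------------------------------------------------

#' Read/write a network as a tab-separated edge list
#'
#' The on-disk format is two 0-based integer columns preceded by a header
#' line `# n_sites=<N> target=<idx> rate=<w>`.  The round trip is lossless.
#'
#' @param net an [rxn_network].
#' @param path file path.
#' @return `write_edgelist` returns `net` invisibly; `read_edgelist` returns
#'   an [rxn_network].
#' @export
write_edgelist <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n_sites=%d target=%d rate=%.17g",
                     net$n_sites, net$target - 1L, net$rate), con)
  write.table(net$edges - 1L, con, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  invisible(net)
}

#' @rdname write_edgelist
#' @export
read_edgelist <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec(
    "^# n_sites=([0-9]+) target=([0-9]+) rate=([0-9.eE+-]+)$", hdr))[[1]]
  if (length(m) != 4L) stop("malformed edge-list header: ", hdr)
  edges <- as.matrix(read.table(path, skip = 1L, sep = "\t")) + 1L
  rxn_network(edges, as.integer(m[2]), target = as.integer(m[3]) + 1L,
              rate = as.numeric(m[4]), family = "file")
}

# CSR adjacency used by the compiled walkers (0-based)
adjacency_csr <- function(net) {
  both <- rbind(net$edges, net$edges[, 2:1])
  ord <- order(both[, 1], both[, 2])
  list(offsets = c(0L, cumsum(net$degree)),
       neigh = both[ord, 2] - 1L)
}
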