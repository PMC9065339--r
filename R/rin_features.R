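#' Build a residue interaction network
#'
#' Nodes are the polymer residues of the structure; an undirected, unweighted
#' edge joins two residues whose representative distance is at most `cutoff`
#' and whose sequence separation is at least `min_seq_separation`. Under
#' `"c_alpha"` mode the representative distance is the C-alpha--C-alpha
#' distance; under `"any_atom"` it is the minimum over all atom pairs.
#' Residues on different chains have no sequence constraint. Defaults follow
#' the common C-alpha RIN convention: 7.0 Angstrom cutoff, adjacent residues
#' allowed.
#'
#' @param s A `complex_structure`.
#' @param mode `"c_alpha"` (default) or `"any_atom"`.
#' @param cutoff Contact cutoff in Angstrom; defaults to 7.0 for
#'   `"c_alpha"`, 5.0 for `"any_atom"`.
#' @param min_seq_separation Minimum |residue-number difference| within a
#'   chain for an edge; default 1 (adjacent residues allowed).
#' @param on_missing_ca `"warn"` (default: residue kept as an isolated node)
#'   or `"error"` when a residue lacks a C-alpha atom in `"c_alpha"` mode.
#' @return A `residue_graph`: list with `nodes` (tibble of residue keys),
#'   `adj` (symmetric logical adjacency matrix, no self-edges),
#'   `contact_rule` and `structure_id`.
#' @export
build_rin <- function(s, mode = c("c_alpha", "any_atom"), cutoff = NULL,
                      min_seq_separation = 1,
                      on_missing_ca = c("warn", "error")) {
  stopifnot(inherits(s, "complex_structure"))
  mode <- match.arg(mode)
  on_missing_ca <- match.arg(on_missing_ca)
  cutoff <- cutoff %||% if (mode == "c_alpha") 7.0 else 5.0
  stopifnot(cutoff > 0)
  nodes <- s$residues
  n <- nrow(nodes)
  if (n < 2) abort("need at least 2 polymer residues to build a network")

  pa <- protein_atoms(s)
  key <- function(df) paste(df$chain, df$resnum, df$icode, sep = "\r")
  node_key <- key(nodes)

  if (mode == "c_alpha") {
    ca <- pa[pa$atom_name == "CA", ]
    idx <- match(node_key, key(ca))
    if (anyNA(idx)) {
      missing <- nodes[is.na(idx), ]
      msg <- paste0(nrow(missing), " residue(s) lack a C-alpha atom; ",
                    "kept as isolated node(s)")
      if (on_missing_ca == "error") abort(msg) else warn(msg)
    }
    xyz <- matrix(NA_real_, n, 3)
    xyz[!is.na(idx), ] <- coords(ca)[idx[!is.na(idx)], , drop = FALSE]
    d2 <- outer_sqdist(xyz, xyz)
    within <- !is.na(d2) & d2 <= cutoff^2
  } else {
    within <- matrix(FALSE, n, n)
    atom_node <- match(key(pa), node_key)
    d2a <- outer_sqdist(coords(pa), coords(pa))
    hit <- which(d2a <= cutoff^2, arr.ind = TRUE)
    ui <- atom_node[hit[, 1]]
    vi <- atom_node[hit[, 2]]
    keep <- !is.na(ui) & !is.na(vi)
    within[cbind(ui[keep], vi[keep])] <- TRUE
  }

  same_chain <- outer(nodes$chain, nodes$chain, "==")
  sep <- abs(outer(nodes$resnum, nodes$resnum, "-"))
  sep_ok <- !same_chain | sep >= min_seq_separation
  adj <- within & sep_ok
  diag(adj) <- FALSE
  adj <- adj | t(adj)

  g <- list(
    nodes = nodes,
    adj = adj,
    contact_rule = list(mode = mode, cutoff = cutoff,
                        min_seq_separation = min_seq_separation),
    structure_id = s$structure_id
  )
  class(g) <- "residue_graph"
  g
}

#' Construct a residue graph from an adjacency matrix
#'
#' Mainly useful for analysing arbitrary graphs with the topology metrics,
#' e.g. in simulation studies.
#'
#' @param adj Symmetric logical/0-1 matrix; the diagonal is ignored.
#' @param nodes Optional node tibble (defaults to numbered residues).
#' @param structure_id Identifier; default `"graph"`.
#' @return A `residue_graph`.
#' @export
rin_from_adjacency <- function(adj, nodes = NULL, structure_id = "graph") {
  adj <- as.matrix(adj) != 0
  stopifnot(nrow(adj) == ncol(adj))
  if (!isSymmetric(adj)) abort("adjacency matrix must be symmetric")
  diag(adj) <- FALSE
  n <- nrow(adj)
  nodes <- nodes %||% tibble(chain = "A", resnum = seq_len(n), icode = "",
                             resname = "ALA")
  g <- list(nodes = nodes, adj = adj,
            contact_rule = list(mode = "custom", cutoff = NA_real_,
                                min_seq_separation = NA_integer_),
            structure_id = structure_id)
  class(g) <- "residue_graph"
  g
}

#' @export
print.residue_graph <- function(x, ...) {
  cat("<residue_graph> ", x$structure_id, ": ", nrow(x$adj), " nodes, ",
      sum(x$adj) / 2, " edges (", x$contact_rule$mode, ", cutoff ",
      x$contact_rule$cutoff, " A)\n", sep = "")
  invisible(x)
}

adj_of <- function(g) {
  if (inherits(g, "residue_graph")) g$adj else {
    rin_from_adjacency(g)$adj
  }
}

# BFS distances from every node; Inf for unreachable. O(n * (n + m)).
bfs_distances <- function(adj) {
  n <- nrow(adj)
  nbrs <- apply(adj, 1, which, simplify = FALSE)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    lev <- 0
    while (length(frontier)) {
      lev <- lev + 1
      nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
      nxt <- nxt[is.infinite(dist[nxt])]
      dist[nxt] <- lev
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  d
}

#' Betweenness centrality
#'
#' For each node u, the sum over unordered pairs \{s, t\} (s, t both distinct
#' from u) of the fraction of shortest s--t paths that pass through u.
#' Shortest paths are unweighted; pairs in different components contribute
#' zero. Computed with Brandes' dependency-accumulation algorithm.
#'
#' @param g A `residue_graph` or adjacency matrix.
#' @return Numeric vector, one value per node.
#' @export
rin_betweenness <- function(g) {
  adj <- adj_of(g)
  n <- nrow(adj)
  nbrs <- apply(adj, 1, which, simplify = FALSE)
  cb <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    frontier <- s
    while (length(frontier)) {
      order_visited <- c(order_visited, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in nbrs[[v]]) {
          if (dist[w] < 0) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) cb[w] <- cb[w] + delta[w]
    }
  }
  cb / 2
}

#' Closeness centrality
#'
#' (n_c - 1) / sum of shortest-path distances to the other nodes of the
#' node's connected component, where n_c is the component size. On a
#' connected graph this is the usual (n - 1) / total geodesic distance.
#' Isolated nodes score 0.
#'
#' @inheritParams rin_betweenness
#' @return Numeric vector, one value per node.
#' @export
rin_closeness <- function(g) {
  d <- bfs_distances(adj_of(g))
  vapply(seq_len(nrow(d)), function(u) {
    reach <- is.finite(d[u, ])
    nc <- sum(reach)            # component size incl. u
    if (nc <= 1) return(0)
    (nc - 1) / sum(d[u, reach])
  }, numeric(1))
}

graph_components <- function(adj) {
  # component id per node, numbered by smallest member index
  n <- nrow(adj)
  nbrs <- apply(adj, 1, which, simplify = FALSE)
  comp <- integer(n)
  k <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0) next
    k <- k + 1L
    frontier <- s
    comp[s] <- k
    while (length(frontier)) {
      nxt <- unique(unlist(nbrs[frontier], use.names = FALSE))
      nxt <- nxt[comp[nxt] == 0]
      comp[nxt] <- k
      frontier <- nxt
    }
  }
  comp
}

#' Eigenvector centrality
#'
#' Components of the principal eigenvector of the adjacency matrix,
#' nonnegative and L2-normalised. Each connected component's dominant
#' eigenpair is computed by power iteration on the shifted matrix A + I
#' (same eigenvectors as A, strictly positive spectrum, so bipartite
#' components cannot stall convergence), uniform start vector. On a
#' disconnected graph the spectrally dominant component carries the
#' eigenvector and all other nodes score 0; when two components tie (equal
#' largest eigenvalue, e.g. isomorphic components), the one containing the
#' earliest node receives the mass.
#'
#' @inheritParams rin_betweenness
#' @param tol Convergence tolerance on the iterate change; default 1e-10.
#' @param max_iter Maximum iterations per component; default 1000.
#' @return Numeric vector, one value per node.
#' @export
rin_eigenvector <- function(g, tol = 1e-10, max_iter = 1000) {
  adj <- adj_of(g)
  n <- nrow(adj)
  if (sum(adj) == 0) {
    warn("graph has no edges; eigenvector centrality is all zero")
    return(numeric(n))
  }
  comp <- graph_components(adj)
  best <- list(lambda = -Inf, x = NULL, idx = NULL)
  for (k in sort(unique(comp))) {
    idx <- which(comp == k)
    if (length(idx) < 2) next                    # isolated node: lambda 0
    a <- adj[idx, idx, drop = FALSE] * 1
    diag(a) <- diag(a) + 1                       # shift: A + I
    m <- length(idx)
    x <- rep(1 / sqrt(m), m)
    lambda <- NA_real_
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      y <- as.vector(a %*% x)
      lambda <- sum(x * y) - 1                   # Rayleigh quotient of A
      y <- y / sqrt(sum(y^2))
      if (max(abs(y - x)) < tol) {
        x <- y
        converged <- TRUE
        break
      }
      x <- y
    }
    if (!converged) {
      abort(paste0("eigenvector centrality did not converge in ", max_iter,
                   " iterations (component of node ", idx[1], ")"))
    }
    # strict improvement required: ties keep the earlier component
    if (lambda > best$lambda + 1e-9) {
      best <- list(lambda = lambda, x = x, idx = idx)
    }
  }
  out <- numeric(n)
  out[best$idx] <- best$x
  out
}

#' Eccentricity
#'
#' Maximum shortest-path distance (in hops) from a node to any node
#' reachable from it; 0 for an isolated node.
#'
#' @inheritParams rin_betweenness
#' @return Integer-valued numeric vector.
#' @export
rin_eccentricity <- function(g) {
  d <- bfs_distances(adj_of(g))
  apply(d, 1, function(row) {
    f <- row[is.finite(row)]
    if (length(f) <= 1) 0 else max(f)
  })
}

#' Degree
#'
#' Number of edges incident to each node.
#'
#' @inheritParams rin_betweenness
#' @return Integer-valued numeric vector.
#' @export
rin_degree <- function(g) {
  rowSums(adj_of(g) * 1)
}

#' Local clustering coefficient
#'
#' Fraction of realised edges among each node's neighbours:
#' (edges among neighbours) / (d(d-1)/2). Nodes with degree below 2 score 0.
#'
#' @inheritParams rin_betweenness
#' @return Numeric vector in \[0, 1\].
#' @export
rin_clustering <- function(g) {
  a <- adj_of(g) * 1
  d <- rowSums(a)
  tri <- diag(a %*% a %*% a)   # 2 * (#edges among neighbours of u)
  out <- ifelse(d >= 2, tri / (d * (d - 1)), 0)
  as.vector(out)
}

#' Average nearest-neighbour degree
#'
#' Mean degree over a node's neighbours; 0 for a degree-0 node.
#'
#' @inheritParams rin_betweenness
#' @return Numeric vector.
#' @export
rin_avg_neighbor_degree <- function(g) {
  a <- adj_of(g) * 1
  d <- rowSums(a)
  s <- as.vector(a %*% d)
  ifelse(d > 0, s / d, 0)
}

#' All seven topology descriptors per residue
#'
#' Assembles the per-residue network descriptors in their fixed column order:
#' betweenness, closeness, eigenvector centrality, eccentricity, degree,
#' clustering coefficient, average nearest-neighbour degree.
#'
#' @inheritParams rin_betweenness
#' @param tol,max_iter Passed to [rin_eigenvector()].
#' @return A tibble: residue keys (when the graph carries them) followed by
#'   the 7 feature columns of `feature_columns("rin")`.
#' @export
rin_topology <- function(g, tol = 1e-10, max_iter = 1000) {
  adj <- adj_of(g)
  ec <- if (sum(adj) == 0) {
    suppressWarnings(rin_eigenvector(g, tol, max_iter))
  } else {
    rin_eigenvector(g, tol, max_iter)
  }
  feat <- tibble(
    betweenness = rin_betweenness(g),
    closeness = rin_closeness(g),
    eigenvector = ec,
    eccentricity = rin_eccentricity(g),
    degree = rin_degree(g),
    clustering = rin_clustering(g),
    avg_neighbor_degree = rin_avg_neighbor_degree(g)
  )
  if (inherits(g, "residue_graph")) {
    bind_cols(
      tibble(structure_id = g$structure_id),
      g$nodes[, intersect(c("chain", "resnum", "icode", "resname"),
                          names(g$nodes))],
      feat
    )
  } else {
    feat
  }
}

#' Write a residue graph as a plain edge list
#'
#' Two residue keys (`chain:resnum:icode`) per line, one line per edge.
#'
#' @param g A `residue_graph`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "residue_graph"))
  keys <- paste(g$nodes$chain, g$nodes$resnum, g$nodes$icode, sep = ":")
  e <- which(upper.tri(g$adj) & g$adj, arr.ind = TRUE)
  writeLines(paste(keys[e[, 1]], keys[e[, 2]]), path)
  invisible(path)
}
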