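# Independent brute-force oracles. These deliberately avoid the package's
# algorithms: distances and shortest-path counts come from adjacency-matrix
# powers, the eigenvector from a dense eigendecomposition, AUC from explicit
# pair counting.

oracle_dist <- function(adj) {
  a <- (adj != 0) * 1
  diag(a) <- 0
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  pw <- diag(n)
  for (k in seq_len(n)) {
    pw <- pw %*% a
    newly <- pw > 0 & is.infinite(d)
    d[newly] <- k
  }
  d
}

# number of shortest s-t paths = number of walks of length dist(s,t)
oracle_sigma <- function(adj) {
  a <- (adj != 0) * 1
  diag(a) <- 0
  n <- nrow(a)
  d <- oracle_dist(adj)
  pows <- vector("list", n + 1)
  pows[[1]] <- diag(n)
  for (k in seq_len(n)) pows[[k + 1]] <- pows[[k]] %*% a
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (is.finite(d[s, t])) sigma[s, t] <- pows[[d[s, t] + 1]][s, t]
  }
  sigma
}

oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_dist(adj)
  sg <- oracle_sigma(adj)
  cb <- numeric(n)
  for (u in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == u || t == u || is.infinite(d[s, t])) next
      if (is.finite(d[s, u]) && is.finite(d[u, t]) &&
          d[s, u] + d[u, t] == d[s, t]) {
        tot <- tot + sg[s, u] * sg[u, t] / sg[s, t]
      }
    }
    cb[u] <- tot
  }
  cb
}

oracle_closeness <- function(adj) {
  d <- oracle_dist(adj)
  sapply(seq_len(nrow(d)), function(u) {
    reach <- is.finite(d[u, ])
    if (sum(reach) <= 1) return(0)
    (sum(reach) - 1) / sum(d[u, reach])
  })
}

oracle_eccentricity <- function(adj) {
  d <- oracle_dist(adj)
  apply(d, 1, function(r) {
    f <- r[is.finite(r)]
    if (length(f) <= 1) 0 else max(f)
  })
}

# dense eigendecomposition per connected component; the spectrally dominant
# component carries the vector, ties resolved to the earliest component
oracle_eigenvector <- function(adj) {
  a <- (adj != 0) * 1
  diag(a) <- 0
  n <- nrow(a)
  if (sum(a) == 0) return(numeric(n))
  d <- oracle_dist(adj)
  comp_of <- rep(NA_integer_, n)
  k <- 0
  for (s in seq_len(n)) {
    if (!is.na(comp_of[s])) next
    k <- k + 1
    comp_of[is.finite(d[s, ])] <- k
  }
  best_lambda <- -Inf
  out <- numeric(n)
  for (kk in sort(unique(comp_of))) {
    idx <- which(comp_of == kk)
    if (length(idx) < 2) next
    e <- eigen(a[idx, idx, drop = FALSE], symmetric = TRUE)
    lam <- max(e$values)
    if (lam > best_lambda + 1e-9) {
      best_lambda <- lam
      v <- e$vectors[, which.max(e$values)]
      if (sum(v) < 0) v <- -v
      v <- pmax(v, 0)          # clip eigendecomposition noise
      out <- numeric(n)
      out[idx] <- v / sqrt(sum(v^2))
    }
  }
  out
}

oracle_clustering <- function(adj) {
  a <- (adj != 0) * 1
  diag(a) <- 0
  n <- nrow(a)
  sapply(seq_len(n), function(u) {
    nb <- which(a[u, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      links <- links + a[nb[i], nb[j]]
    }
    links / (k * (k - 1) / 2)
  })
}

oracle_ann <- function(adj) {
  a <- (adj != 0) * 1
  diag(a) <- 0
  deg <- rowSums(a)
  sapply(seq_len(nrow(a)), function(u) {
    nb <- which(a[u, ] > 0)
    if (length(nb) == 0) 0 else mean(deg[nb])
  })
}

oracle_topology <- function(adj) {
  cbind(
    betweenness = oracle_betweenness(adj),
    closeness = oracle_closeness(adj),
    eigenvector = oracle_eigenvector(adj),
    eccentricity = oracle_eccentricity(adj),
    degree = rowSums((adj != 0) * 1),
    clustering = oracle_clustering(adj),
    avg_neighbor_degree = oracle_ann(adj)
  )
}

random_er_adj <- function(n, p, seed) {
  withr::with_seed(seed, {
    a <- matrix(0, n, n)
    a[upper.tri(a)] <- as.numeric(stats::runif(n * (n - 1) / 2) < p)
    a + t(a)
  })
}

# all-pairs atom-distance scan for site labels
oracle_site_labels <- function(s, entity_id, cutoff = 6.5) {
  pa <- s$atoms[s$atoms$is_protein, ]
  la <- s$atoms[s$atoms$is_hetero & s$atoms$entity_id == entity_id, ]
  res <- s$residues
  lab <- integer(nrow(res))
  for (i in seq_len(nrow(res))) {
    ra <- pa[pa$chain == res$chain[i] & pa$resnum == res$resnum[i] &
               pa$icode == res$icode[i], ]
    hit <- FALSE
    for (j in seq_len(nrow(ra))) {
      for (k in seq_len(nrow(la))) {
        d <- sqrt((ra$x[j] - la$x[k])^2 + (ra$y[j] - la$y[k])^2 +
                    (ra$z[j] - la$z[k])^2)
        if (d <= cutoff) { hit <- TRUE; break }
      }
      if (hit) break
    }
    lab[i] <- as.integer(hit)
  }
  lab
}

oracle_auc <- function(truth, score) {
  pos <- score[truth == 1]
  neg <- score[truth == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

rotate_structure <- function(s, angles = c(0.3, 1.1, -0.7),
                             shift = c(5, -3, 12)) {
  rx <- function(t) matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)),
                           3, byrow = TRUE)
  rz <- function(t) matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1),
                           3, byrow = TRUE)
  rot <- rx(angles[1]) %*% rz(angles[2]) %*% rx(angles[3])
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(rot)
  s$atoms$x <- xyz[, 1] + shift[1]
  s$atoms$y <- xyz[, 2] + shift[2]
  s$atoms$z <- xyz[, 3] + shift[3]
  s
}
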