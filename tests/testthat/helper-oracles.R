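# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, grids, and hand-rolled structures.

# numeric grid integration of the Gaussian union density
# integrand: 1 - prod_i (1 - p * exp(-alpha_i |r - c_i|^2))
grid_union_volume <- function(coords, alpha, p, spacing = 0.15, pad = 4) {
  lo <- apply(coords, 2, min) - pad
  hi <- apply(coords, 2, max) + pad
  xs <- seq(lo[1], hi[1], by = spacing)
  ys <- seq(lo[2], hi[2], by = spacing)
  zs <- seq(lo[3], hi[3], by = spacing)
  total <- 0
  for (z in zs) {
    g <- expand.grid(x = xs, y = ys)
    acc <- rep(1, nrow(g))
    for (i in seq_len(nrow(coords))) {
      d2 <- (g$x - coords[i, 1])^2 + (g$y - coords[i, 2])^2 +
        (z - coords[i, 3])^2
      acc <- acc * (1 - p * exp(-alpha[i] * d2))
    }
    total <- total + sum(1 - acc)
  }
  total * spacing^3
}

# grid moments of the order-2 (pairwise-truncated) Gaussian density
grid_density_moment <- function(coords, alpha, p, fun, spacing = 0.15,
                                pad = 4) {
  lo <- apply(coords, 2, min) - pad
  hi <- apply(coords, 2, max) + pad
  xs <- seq(lo[1], hi[1], by = spacing)
  ys <- seq(lo[2], hi[2], by = spacing)
  zs <- seq(lo[3], hi[3], by = spacing)
  n <- nrow(coords)
  total <- 0
  for (z in zs) {
    g <- expand.grid(x = xs, y = ys)
    rho_i <- lapply(seq_len(n), function(i) {
      d2 <- (g$x - coords[i, 1])^2 + (g$y - coords[i, 2])^2 +
        (z - coords[i, 3])^2
      p * exp(-alpha[i] * d2)
    })
    dens <- Reduce(`+`, rho_i)
    if (n > 1) for (i in 1:(n - 1)) for (j in (i + 1):n)
      dens <- dens - rho_i[[i]] * rho_i[[j]]
    total <- total + sum(dens * fun(g$x, g$y, z))
  }
  total * spacing^3
}

# connected components by hand-rolled union-find
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (NROW(edges)) for (k in seq_len(nrow(edges))) {
    ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# brute-force pairwise superposed heavy-atom RMSD matrix via base svd
brute_rmsd_matrix <- function(conformers) {
  n <- length(conformers)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    a <- conformers[[i]]$coords[conformers[[i]]$heavy_idx, , drop = FALSE]
    b <- conformers[[j]]$coords[conformers[[j]]$heavy_idx, , drop = FALSE]
    a0 <- sweep(a, 2, colMeans(a)); b0 <- sweep(b, 2, colMeans(b))
    s <- svd(crossprod(b0, a0))
    d <- sign(det(s$v %*% t(s$u)))
    r <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
    m[i, j] <- m[j, i] <- sqrt(mean(rowSums((b0 %*% r - a0)^2)))
  }
  m
}

# step-by-step simulation of the greedy diverse-ordering rule
oracle_diverse_order <- function(combo, energies, lids) {
  k <- nrow(combo)
  first <- order(energies, lids)[1]
  assigned <- first
  un <- setdiff(seq_len(k), first)
  while (length(un)) {
    s <- sapply(un, function(i) sum(combo[i, assigned]))
    cand <- un[abs(s - min(s)) < 1e-12]
    if (length(cand) > 1) {
      s2 <- sapply(cand, function(i) sum(combo[i, setdiff(un, i)]))
      cand <- cand[abs(s2 - max(s2)) < 1e-12]
      if (length(cand) > 1) cand <- cand[order(lids[cand])]
    }
    assigned <- c(assigned, cand[1])
    un <- setdiff(un, cand[1])
  }
  assigned
}

random_proper_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
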