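#' Gaussian shape model parameters
#'
#' Parameters of the Grant-Pickup Gaussian description of molecular shape.
#' Each heavy atom contributes a spherical Gaussian of height `p` whose
#' exponent is chosen so that the isolated-atom Gaussian volume equals the
#' hard-sphere volume 4/3*pi*R^3 for the element's radius. Molecular volume
#' is the inclusion-exclusion sum over atom subsets, truncated at
#' `inclusion_exclusion_order` (pairwise by default).
#'
#' @param p Gaussian height (dimensionless, > 1).
#' @param radius_table named numeric vector of per-element radii in
#'   Angstrom; elements absent from the table fall back to the carbon
#'   radius.
#' @param inclusion_exclusion_order truncation order, >= 2.
#' @param carbon_radius_mode treat every heavy atom as carbon.
#' @param color_radius radius of the fictitious feature ("color") atom
#'   Gaussians, Angstrom.
#' @return a list of class `shape_params`.
#' @export
shape_params <- function(p = 2.7,
                         radius_table = c(C = 1.70, N = 1.55, O = 1.52,
                                          F = 1.47, Si = 2.10, P = 1.80,
                                          S = 1.80, Cl = 1.75, Br = 1.85,
                                          I = 1.98, H = 1.20),
                         inclusion_exclusion_order = 2L,
                         carbon_radius_mode = FALSE,
                         color_radius = 1.0) {
  if (p <= 1) abort("gaussian height p must be > 1")
  if (any(radius_table <= 0)) abort("radii must be > 0")
  if (inclusion_exclusion_order < 2L) abort("inclusion_exclusion_order must be >= 2")
  structure(list(p = p, radius_table = radius_table,
                 inclusion_exclusion_order = as.integer(inclusion_exclusion_order),
                 carbon_radius_mode = isTRUE(carbon_radius_mode),
                 color_radius = color_radius),
            class = "shape_params")
}

# exponent making an isolated atom's Gaussian volume equal 4/3 pi R^3
gauss_alpha <- function(radius, p) pi * (3 * p / (4 * pi * radius^3))^(2 / 3)

heavy_radii <- function(conf, mol = NULL, params = shape_params()) {
  n <- length(conf$heavy_idx)
  if (params$carbon_radius_mode || is.null(mol))
    return(rep(params$radius_table[["C"]], n))
  el <- mol$atoms$element[conf$heavy_idx]
  r <- unname(params$radius_table[el])
  r[is.na(r)] <- params$radius_table[["C"]]
  r
}

# inclusion-exclusion Gaussian volume of one atom set.
# coords: n x 3; alpha: exponents; p: height; order: truncation order.
gauss_union_volume <- function(coords, alpha, p, order = 2L) {
  n <- nrow(coords)
  v1 <- p * (pi / alpha)^1.5
  total <- sum(v1)
  if (n < 2L || order < 2L) return(total)
  d2 <- as.matrix(stats::dist(coords))^2
  asum <- outer(alpha, alpha, "+")
  pairv <- p^2 * (pi / asum)^1.5 * exp(-outer(alpha, alpha) / asum * d2)
  total <- total - sum(pairv[upper.tri(pairv)])
  if (order >= 3L && n >= 3L) {
    maxord <- min(order, n)
    for (k in 3:maxord) {
      sets <- utils::combn(n, k)
      sgn <- (-1)^(k + 1)
      for (s in seq_len(ncol(sets))) {
        idx <- sets[, s]
        term <- gauss_subset_term(coords[idx, , drop = FALSE], alpha[idx], p)
        total <- total + sgn * term$v
      }
    }
  }
  total
}

# product of k Gaussians collapses to one Gaussian: volume, center, exponent
gauss_subset_term <- function(coords, alpha, p) {
  a <- sum(alpha)
  ctr <- colSums(coords * alpha) / a
  dev <- sweep(coords, 2, ctr)
  kq <- sum(alpha * rowSums(dev^2))
  v <- p^length(alpha) * exp(-kq) * (pi / a)^1.5
  list(v = v, center = ctr, a = a)
}

#' Analytic Gaussian volume of a conformer
#'
#' Inclusion-exclusion Gaussian volume over heavy atoms (the "conformer
#' volume" property). An isolated atom contributes exactly its hard-sphere
#' volume by the Gaussian parameterization.
#'
#' @param conf a [conformer()] with at least one heavy atom.
#' @param params a [shape_params()].
#' @param mol optional parent [molecule()] supplying element radii; without
#'   it every heavy atom uses the carbon radius.
#' @return volume in Angstrom^3.
#' @examples
#' a <- conformer(matrix(0, 1, 3))
#' self_volume(a)  # 4/3 * pi * 1.7^3
#' @export
self_volume <- function(conf, params = shape_params(), mol = NULL) {
  hc <- heavy_coords(conf)
  if (nrow(hc) == 0L) abort("conformer has no heavy atoms")
  r <- heavy_radii(conf, mol, params)
  gauss_union_volume(hc, gauss_alpha(r, params$p), params$p,
                     params$inclusion_exclusion_order)
}

# pairwise Gaussian-product overlap sum between two atom sets (the order-2
# cross term of the union-difference overlap volume)
gauss_cross_overlap <- function(ca, aa, cb, ab, p) {
  asum <- outer(aa, ab, "+")
  d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * tcrossprod(ca, cb)
  d2[d2 < 0] <- 0
  sum(p^2 * (pi / asum)^1.5 * exp(-outer(aa, ab) / asum * d2))
}

#' Overlap volume between two conformers
#'
#' The common Gaussian volume `V_AB = V_A + V_B - V_(A union B)` with every
#' term computed by the same inclusion-exclusion truncation. At the default
#' pairwise order this reduces exactly to the Grant-Pickup cross-term sum
#' over atom pairs of the two conformers. Coordinates are taken as given
#' (common frame); no superposition is performed.
#'
#' @param a,b [conformer()]s with heavy atoms.
#' @param params a [shape_params()].
#' @param mol_a,mol_b optional parent molecules supplying element radii.
#' @return overlap volume in Angstrom^3 (symmetric, non-negative).
#' @export
overlap_volume <- function(a, b, params = shape_params(),
                           mol_a = NULL, mol_b = NULL) {
  ca <- heavy_coords(a); cb <- heavy_coords(b)
  if (nrow(ca) == 0L || nrow(cb) == 0L) abort("conformer has no heavy atoms")
  aa <- gauss_alpha(heavy_radii(a, mol_a, params), params$p)
  ab <- gauss_alpha(heavy_radii(b, mol_b, params), params$p)
  ord <- params$inclusion_exclusion_order
  if (ord == 2L) return(gauss_cross_overlap(ca, aa, cb, ab, params$p))
  va <- gauss_union_volume(ca, aa, params$p, ord)
  vb <- gauss_union_volume(cb, ab, params$p, ord)
  vu <- gauss_union_volume(rbind(ca, cb), c(aa, ab), params$p, ord)
  max(0, va + vb - vu)
}

#' Shape self-overlap volume
#'
#' `overlap_volume(conf, conf)`: the quantity appearing in the shape
#' Tanimoto denominator. It differs from [self_volume()] because the
#' Gaussian density overlapped with itself is not the union density; both
#' are stored as separate conformer properties.
#'
#' @inheritParams self_volume
#' @return self-overlap volume in Angstrom^3.
#' @export
self_overlap_volume <- function(conf, params = shape_params(), mol = NULL) {
  hc <- heavy_coords(conf)
  if (nrow(hc) == 0L) abort("conformer has no heavy atoms")
  al <- gauss_alpha(heavy_radii(conf, mol, params), params$p)
  gauss_cross_overlap(hc, al, hc, al, params$p)
}

#' Shape Tanimoto at a fixed pose
#'
#' `ST = V_AB / (V_AA + V_BB - V_AB)` with self-overlap volumes in the
#' denominator, so `ST(A, A)` at the identity pose is exactly 1. The
#' optional rigid transform is applied to `b` before scoring.
#'
#' @param a,b [conformer()]s.
#' @param transform optional list with `rotation` (3 x 3) and `translation`
#'   (length 3) applied to `b`, in that order.
#' @param params a [shape_params()].
#' @param mol_a,mol_b optional parent molecules.
#' @return ST in [0, 1].
#' @export
shape_tanimoto <- function(a, b, transform = NULL, params = shape_params(),
                           mol_a = NULL, mol_b = NULL) {
  if (!is.null(transform)) b <- transform_conformer(b, transform)
  vab <- overlap_volume(a, b, params, mol_a, mol_b)
  vaa <- self_overlap_volume(a, params, mol_a)
  vbb <- self_overlap_volume(b, params, mol_b)
  den <- vaa + vbb - vab
  stopifnot(den > 0)
  min(1, max(0, vab / den))
}

#' Apply a rigid transform to a conformer
#'
#' Rotates then translates all coordinates: `x' = R x + t`.
#'
#' @param conf a [conformer()].
#' @param transform list with `rotation` and `translation`.
#' @return transformed conformer.
#' @export
transform_conformer <- function(conf, transform) {
  r <- transform$rotation; t <- transform$translation
  conf$coords <- sweep(conf$coords %*% t(r), 2, -t)
  conf
}

compose_transform <- function(outer, inner) {
  # x -> outer(inner(x))
  list(rotation = outer$rotation %*% inner$rotation,
       translation = as.numeric(outer$rotation %*% inner$translation) +
         outer$translation)
}

identity_transform <- function() {
  list(rotation = diag(3), translation = numeric(3))
}

# --- principal steric axes --------------------------------------------------

#' Canonicalize a conformer to its principal steric axes
#'
#' Translates the heavy-atom centroid to the origin and rotates the
#' conformer so the unit-weight (non-mass-weighted) principal moments of
#' inertia of the heavy atoms are axis-aligned, with x the longest extent,
#' y the next, z the shortest. Axis signs are fixed by making the
#' heavy-atom third moment along each axis non-negative; if that leaves an
#' improper frame, the axis with the smallest third-moment magnitude is
#' flipped back. Idempotent up to numerical tolerance.
#'
#' @param conf a [conformer()] with at least one heavy atom.
#' @return the canonicalized conformer; attribute `canonical_transform`
#'   holds the rigid transform mapping input to output coordinates.
#' @export
canonicalize_principal_axes <- function(conf) {
  hc <- heavy_coords(conf)
  if (nrow(hc) == 0L) abort("conformer has no heavy atoms")
  ctr <- colMeans(hc)
  x0 <- sweep(hc, 2, ctr)
  cv <- crossprod(x0)                       # unit-weight second moments
  # already axis-aligned with descending moments (e.g. a prior pass over a
  # degenerate symmetric top): keep the frame so canonicalization is an
  # exact fixpoint instead of rotating freely in the degenerate subspace
  tol <- 1e-8 * (1 + max(diag(cv)))
  if (max(abs(cv[upper.tri(cv)])) <= tol && all(diff(diag(cv)) <= tol)) {
    axes <- diag(3)
  } else {
    ev <- eigen(cv, symmetric = TRUE)       # descending: x = longest extent
    axes <- ev$vectors
  }
  proj <- x0 %*% axes
  skew <- colSums(proj^3)
  flips <- ifelse(skew < -1e-9, -1, 1)
  axes <- sweep(axes, 2, flips, "*")
  if (det(axes) < 0) {
    k <- which.min(abs(skew))
    axes[, k] <- -axes[, k]
  }
  rot <- t(axes)                            # x' = rot %*% (x - ctr)
  tr <- list(rotation = rot, translation = as.numeric(-rot %*% ctr))
  out <- transform_conformer(conf, tr)
  attr(out, "canonical_transform") <- tr
  out
}

# --- steric moments ---------------------------------------------------------

#' Steric multipole moments of a conformer's Gaussian shape density
#'
#' Monopole (the analytic volume), the three diagonal second moments
#' (quadrupoles, ordered `Qx >= Qy >= Qz`; length, width, height), and the
#' ten third moments (octopoles) of the inclusion-exclusion Gaussian
#' density, taken about the heavy-atom steric center in the principal
#' steric frame. A non-canonical conformer is canonicalized first.
#'
#' @param conf a [conformer()].
#' @param params a [shape_params()].
#' @param mol optional parent molecule for element radii.
#' @return a list of class `steric_moments`: `volume` (A^3), `quadrupole`
#'   (named length-3, A^5), `octopole` (named length-10, A^6).
#' @export
steric_moments <- function(conf, params = shape_params(), mol = NULL) {
  cc <- canonicalize_principal_axes(conf)
  hc <- heavy_coords(cc)
  alpha <- gauss_alpha(heavy_radii(cc, mol, params), params$p)
  ord <- min(params$inclusion_exclusion_order, nrow(hc))

  m0 <- 0
  q <- c(x = 0, y = 0, z = 0)
  oct <- setNames(numeric(10),
                  c("xxx", "yyy", "zzz", "xxy", "xxz", "yyx", "yyz",
                    "zzx", "zzy", "xyz"))
  add_term <- function(v, ctr, a, sgn) {
    s <- 1 / (2 * a)
    m0 <<- m0 + sgn * v
    q <<- q + sgn * v * (ctr^2 + s)
    oct["xxx"] <<- oct["xxx"] + sgn * v * (ctr[1]^3 + 3 * ctr[1] * s)
    oct["yyy"] <<- oct["yyy"] + sgn * v * (ctr[2]^3 + 3 * ctr[2] * s)
    oct["zzz"] <<- oct["zzz"] + sgn * v * (ctr[3]^3 + 3 * ctr[3] * s)
    oct["xxy"] <<- oct["xxy"] + sgn * v * (ctr[1]^2 * ctr[2] + ctr[2] * s)
    oct["xxz"] <<- oct["xxz"] + sgn * v * (ctr[1]^2 * ctr[3] + ctr[3] * s)
    oct["yyx"] <<- oct["yyx"] + sgn * v * (ctr[2]^2 * ctr[1] + ctr[1] * s)
    oct["yyz"] <<- oct["yyz"] + sgn * v * (ctr[2]^2 * ctr[3] + ctr[3] * s)
    oct["zzx"] <<- oct["zzx"] + sgn * v * (ctr[3]^2 * ctr[1] + ctr[1] * s)
    oct["zzy"] <<- oct["zzy"] + sgn * v * (ctr[3]^2 * ctr[2] + ctr[2] * s)
    oct["xyz"] <<- oct["xyz"] + sgn * v * prod(ctr)
  }
  n <- nrow(hc)
  for (k in seq_len(ord)) {
    sgn <- (-1)^(k + 1)
    sets <- utils::combn(n, k)
    for (s in seq_len(ncol(sets))) {
      term <- gauss_subset_term(hc[sets[, s], , drop = FALSE],
                                alpha[sets[, s]], params$p)
      add_term(term$v, term$center, term$a, sgn)
    }
  }
  # enforce Qx >= Qy >= Qz by axis relabeling (degenerate frames only)
  perm <- order(q, decreasing = TRUE)
  if (!identical(perm, 1:3)) {
    q <- q[perm]
    oct <- relabel_octopole(oct, perm)
  }
  names(q) <- c("x", "y", "z")
  structure(list(volume = m0, quadrupole = q, octopole = oct),
            class = "steric_moments")
}

relabel_octopole <- function(oct, perm) {
  lab <- c("x", "y", "z")
  old_of_new <- lab[perm]
  comp <- function(new_triplet) {
    key <- paste(sort(old_of_new[match(strsplit(new_triplet, "")[[1]], lab)]),
                 collapse = "")
    canon <- c(xxx = "xxx", yyy = "yyy", zzz = "zzz", xxy = "xxy",
               xxz = "xxz", xyy = "yyx", yyz = "yyz", xzz = "zzx",
               yzz = "zzy", xyz = "xyz")
    oct[[canon[[key]]]]
  }
  out <- oct
  for (nm in names(oct)) out[[nm]] <- comp(nm)
  out
}
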