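single_atom <- function(x = c(0, 0, 0)) conformer(matrix(x, 1, 3))

test_that("isolated-atom Gaussian volume equals the hard-sphere volume", {
  expect_equal(self_volume(single_atom()), 4 / 3 * pi * 1.7^3,
               tolerance = 1e-10)
  # far-separated atoms are additive
  pair <- conformer(rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(self_volume(pair), 2 * 4 / 3 * pi * 1.7^3, tolerance = 1e-9)
  expect_error(self_volume(conformer(matrix(0, 1, 3), heavy_idx = integer())),
               "heavy")
})

test_that("analytic volumes match grid integration on small toys", {
  params <- shape_params()
  tri <- conformer(rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.75, 1.3, 0)))
  full <- shape_params(inclusion_exclusion_order = 3L)
  alpha <- rep(pubshape3d:::gauss_alpha(1.7, params$p), 3)
  oracle <- grid_union_volume(pubshape3d:::heavy_coords(tri), alpha, params$p)
  expect_equal(self_volume(tri, full), oracle, tolerance = 0.02)
  # pairwise truncation under-counts dense triple overlaps by design;
  # it must stay within the documented truncation bias on small toys
  expect_equal(self_volume(tri, params), oracle, tolerance = 0.15)
})

test_that("overlap volume identities hold", {
  a <- single_atom()
  b <- single_atom(c(100, 0, 0))
  expect_lt(overlap_volume(a, b), 1e-9)

  # coincident equal atoms: closed-form two-Gaussian product integral
  p <- 2.7
  alpha <- pubshape3d:::gauss_alpha(1.7, p)
  closed <- p^2 * (pi / (2 * alpha))^1.5
  expect_equal(overlap_volume(a, single_atom()), closed, tolerance = 1e-10)

  # symmetry and self-overlap identity
  tri <- conformer(rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.75, 1.3, 0)))
  bu <- conformer(toy_butane()$conformer$coords)
  expect_equal(overlap_volume(tri, bu), overlap_volume(bu, tri),
               tolerance = 1e-10)
  expect_equal(overlap_volume(tri, tri), self_overlap_volume(tri),
               tolerance = 1e-10)
  # in the weak-overlap regime the self-overlap tracks the union volume
  expect_equal(overlap_volume(a, a), self_volume(a), tolerance = 0.05)
})

test_that("shape Tanimoto follows its defining ratio", {
  tri <- conformer(rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.75, 1.3, 0)))
  expect_equal(shape_tanimoto(tri, tri), 1)
  far <- conformer(sweep(tri$coords, 2, c(200, 0, 0), "+"))
  expect_lt(shape_tanimoto(tri, far), 1e-9)

  bu <- conformer(toy_butane()$conformer$coords)
  vab <- overlap_volume(tri, bu)
  st_manual <- vab / (self_overlap_volume(tri) + self_overlap_volume(bu) - vab)
  expect_equal(shape_tanimoto(tri, bu), st_manual, tolerance = 1e-12)
})

test_that("ST is invariant under a common rigid motion", {
  set.seed(7)
  a <- conformer(toy_butane()$conformer$coords)
  b <- conformer(toy_benzene()$conformer$coords)
  st0 <- shape_tanimoto(a, b)
  for (k in 1:5) {
    r <- random_proper_rotation(); t <- rnorm(3, sd = 5)
    am <- conformer(sweep(a$coords %*% t(r), 2, t, "+"))
    bm <- conformer(sweep(b$coords %*% t(r), 2, t, "+"))
    expect_equal(shape_tanimoto(am, bm), st0, tolerance = 1e-8)
  }
})

test_that("pose optimization recovers rotated copies and beats its starts", {
  set.seed(3)
  bu <- toy_butane()
  moved <- conformer(sweep(bu$conformer$coords %*%
                             t(random_proper_rotation()), 2, c(3, -1, 2), "+"),
                     molecule = bu$molecule)
  r <- optimize_overlap(bu$conformer, moved)
  expect_gte(r$st, 0.99)
  # the returned transform reproduces the reported score
  expect_equal(shape_tanimoto(bu$conformer, moved,
                              transform = list(rotation = r$rotation,
                                               translation = r$translation)),
               r$st, tolerance = 1e-6)

  # optimum at least as good as every canonical starting pose
  a <- canonicalize_principal_axes(bu$conformer)
  b <- canonicalize_principal_axes(toy_ethanol()$conformer)
  res <- optimize_overlap(a, b)
  for (flip in pubshape3d:::proper_flips()) {
    bf <- b; bf$coords <- bf$coords %*% t(flip)
    expect_gte(res$st + 1e-9, shape_tanimoto(a, bf))
  }
})

test_that("optimizer lands within ST 0.02 of a rotation-grid oracle", {
  a <- canonicalize_principal_axes(conformer(toy_butane()$conformer$coords))
  b <- canonicalize_principal_axes(conformer(toy_ethanol()$conformer$coords))
  res <- optimize_overlap(a, b)
  # exhaustive coarse rotation grid (Euler angles), translation at centroids
  best <- 0
  step <- pi / 12
  for (az in seq(0, 2 * pi - step, by = step))
    for (el in seq(0, pi, by = step))
      for (tw in seq(0, 2 * pi - step, by = step)) {
        rz <- matrix(c(cos(az), -sin(az), 0, sin(az), cos(az), 0, 0, 0, 1),
                     3, 3, byrow = TRUE)
        ry <- matrix(c(cos(el), 0, sin(el), 0, 1, 0, -sin(el), 0, cos(el)),
                     3, 3, byrow = TRUE)
        rz2 <- matrix(c(cos(tw), -sin(tw), 0, sin(tw), cos(tw), 0, 0, 0, 1),
                      3, 3, byrow = TRUE)
        st <- shape_tanimoto(a, b, transform = list(rotation = rz %*% ry %*% rz2,
                                                    translation = numeric(3)))
        if (st > best) best <- st
      }
  expect_gte(res$st, best - 0.02)
})

test_that("steric moments reflect molecular anisotropy and match the grid", {
  mono <- steric_moments(single_atom(c(5, 5, 5)))
  expect_equal(unname(mono$quadrupole[1]), unname(mono$quadrupole[2]))
  expect_equal(unname(mono$quadrupole[2]), unname(mono$quadrupole[3]))
  expect_equal(mono$volume, 4 / 3 * pi * 1.7^3, tolerance = 1e-9)

  chain <- conformer(cbind(seq(0, 6.16, by = 1.54), 0, 0))
  sm <- steric_moments(chain)
  expect_gt(sm$quadrupole[["x"]], sm$quadrupole[["y"]])
  expect_equal(sm$quadrupole[["y"]], sm$quadrupole[["z"]], tolerance = 1e-6)
  expect_true(all(diff(sm$quadrupole) <= 1e-9))

  # grid oracle for the order-2 density moments of a bent triatomic
  tri <- canonicalize_principal_axes(
    conformer(rbind(c(0, 0, 0), c(1.5, 0, 0), c(0.75, 1.3, 0))))
  sm <- steric_moments(tri)
  alpha <- rep(pubshape3d:::gauss_alpha(1.7, 2.7), 3)
  hc <- pubshape3d:::heavy_coords(tri)
  gx2 <- grid_density_moment(hc, alpha, 2.7, function(x, y, z) x^2,
                             spacing = 0.12)
  gy2 <- grid_density_moment(hc, alpha, 2.7, function(x, y, z) y^2,
                             spacing = 0.12)
  expect_equal(sm$quadrupole[["x"]], gx2, tolerance = 0.02)
  expect_equal(sm$quadrupole[["y"]], gy2, tolerance = 0.02)
})

test_that("principal-axes canonicalization is idempotent and stable", {
  bu <- conformer(toy_butane()$conformer$coords)
  c1 <- canonicalize_principal_axes(bu)
  c2 <- canonicalize_principal_axes(c1)
  expect_lt(max(abs(c1$coords - c2$coords)), 1e-9)

  # single atom moves to the origin
  expect_equal(unname(canonicalize_principal_axes(single_atom(c(5, 5, 5)))$coords),
               matrix(0, 1, 3))

  # rotated copies agree with the original canonical form up to the four
  # proper sign flips
  set.seed(19)
  dp <- toy_dopamine()
  base <- canonicalize_principal_axes(dp$conformer)
  for (k in 1:4) {
    moved <- dp$conformer
    moved$coords <- sweep(moved$coords %*% t(random_proper_rotation()), 2,
                          rnorm(3, sd = 4), "+")
    cc <- canonicalize_principal_axes(moved)
    errs <- vapply(pubshape3d:::proper_flips(), function(f)
      max(abs(cc$coords %*% t(f) - base$coords)), numeric(1))
    expect_lt(min(errs), 1e-6)
  }
})
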