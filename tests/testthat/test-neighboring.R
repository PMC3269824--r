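test_that("the neighbor predicate uses strict inequalities per case", {
  expect_true(is_neighbor(0.796, 0.496, TRUE, TRUE))
  expect_false(is_neighbor(0.80, 0.23, TRUE, TRUE))   # the probe-pair scores
  expect_true(is_neighbor(0.93, 0, FALSE, FALSE))
  expect_false(is_neighbor(0.95, 0, TRUE, FALSE))     # mixed case
  expect_false(is_neighbor(0.95, 0, FALSE, TRUE))

  # exact threshold equality is not a neighbor
  expect_false(is_neighbor(0.795, 0.6, TRUE, TRUE))
  expect_false(is_neighbor(0.9, 0.495, TRUE, TRUE))
  expect_false(is_neighbor(0.925, 0, FALSE, FALSE))
  # just above passes
  expect_true(is_neighbor(0.7951, 0.4951, TRUE, TRUE))
  expect_true(is_neighbor(0.9251, 0, FALSE, FALSE))
})

make_corpus <- function() {
  # featureless point-cloud compounds with distinct record ids
  lapply(1:6, function(i) {
    ens <- synthetic_ensemble(n_atoms = 7,
                              n_groups = if (i <= 2) 1 else i,
                              n_per_group = if (i <= 2) 3 else 1,
                              jitter = 0.2, seed = 100 + (i + 1) %/% 2)
    mol <- ens$molecule
    mol$record_id <- i
    conformer_model(mol, ens$conformers, sampling_rmsd = 0.4)
  })
}

test_that("neighbor search finds self-matches and is shard-invariant", {
  corpus <- make_corpus()
  q <- corpus[[1]]
  nb <- neighbor_search(q, corpus)
  self_gid <- conformer_gid(q$molecule,
                            q$conformers[[q$diverse_order[1]]])
  self_rows <- nb[nb$gid_a == self_gid & nb$gid_b == self_gid, ]
  expect_gte(nrow(self_rows), 1L)
  expect_gte(self_rows$st[1], 0.999)

  # compounds 1 and 2 share base shapes (same ensemble seed): must match
  expect_true(any(decode_gid(nb$gid_b)$structure_id == 2))

  for (s in c(2L, 4L)) {
    nb_s <- neighbor_search(q, corpus, shards = s)
    expect_equal(nb_s, nb)
  }
})

test_that("the fingerprint prefilter does not change accepted records", {
  corpus <- make_corpus()
  q <- corpus[[1]]
  # reference leaders at a threshold below the neighbor threshold, built
  # over every conformer the search will touch, so accepted pairs share bits
  pool <- unlist(lapply(corpus, function(m)
    m$conformers[m$diverse_order[seq_len(min(3, length(m$conformers)))]]),
    recursive = FALSE)
  refs <- build_reference_set(pool, st_threshold = 0.8)
  nb_plain <- neighbor_search(q, corpus)
  nb_pref <- neighbor_search(q, corpus, refs = refs)
  expect_equal(nb_pref, nb_plain)
})

test_that("neighbor records carry the pose that reproduces their scores", {
  corpus <- make_corpus()
  nb <- neighbor_search(corpus[[2]], corpus[1:2])
  nb <- nb[nb$gid_a != nb$gid_b, ]
  expect_gte(nrow(nb), 1L)
  lookup <- function(gid) {
    d <- decode_gid(gid)
    mdl <- corpus[[d$structure_id]]
    lids <- vapply(mdl$conformers, function(cf) cf$local_id, integer(1))
    mdl$conformers[[match(d$local_id, lids)]]
  }
  for (i in seq_len(min(3, nrow(nb)))) {
    r <- nb[i, ]
    a <- lookup(r$gid_a); b <- lookup(r$gid_b)
    tr <- list(rotation = matrix(c(r$r11, r$r12, r$r13, r$r21, r$r22, r$r23,
                                   r$r31, r$r32, r$r33), 3, 3, byrow = TRUE),
               translation = c(r$t1, r$t2, r$t3))
    expect_equal(shape_tanimoto(a, b, transform = tr), r$st,
                 tolerance = 1e-6)
  }
})

test_that("score matrices are symmetric and match per-pair recomputation", {
  pan <- toy_panel()
  models <- lapply(pan[c("benzene", "cyclohexane", "butane", "ethanol")],
                   function(rec) conformer_model(rec$molecule,
                                                 list(rec$conformer),
                                                 sampling_rmsd = 0.4))
  sm <- score_matrix(models, per_compound = 1)
  expect_true(isSymmetric(sm$st, tol = 1e-12))
  expect_equal(unname(diag(sm$st)), rep(1, 4))
  expect_equal(sm$combo, sm$st + sm$ct, tolerance = 1e-12)

  # element-wise recomputation oracle
  for (i in 1:3) for (j in (i + 1):4) {
    r <- optimize_overlap(models[[i]]$conformers[[1]],
                          models[[j]]$conformers[[1]],
                          mol_a = models[[i]]$molecule,
                          mol_b = models[[j]]$molecule)
    expect_equal(sm$combo[i, j], r$combo, tolerance = 1e-9)
  }

  # far-separated rigid toys score ~ 0 without optimization in the way
  far_a <- conformer_model(molecule(rep("C", 2),
                                    data.frame(a1 = 1, a2 = 2, order = 1),
                                    record_id = 50),
                           list(conformer(rbind(c(0, 0, 0), c(1.5, 0, 0)))),
                           sampling_rmsd = 0.4)
  expect_error(score_matrix(list(far_a), per_compound = 1), "two")
  expect_error(score_matrix(models, per_compound = 1, max_pairs = 2),
               "budget")
})

test_that("single-linkage clusters equal union-find components", {
  set.seed(33)
  n <- 10
  m <- matrix(runif(n * n), n, n)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  diag(m) <- 1
  for (thr in c(0, 0.5, 0.9)) {
    got <- single_linkage_cluster(m, thr)
    edges <- which(m > thr & upper.tri(m), arr.ind = TRUE)
    want <- uf_components(n, edges)
    # same partition up to label renaming
    expect_equal(length(unique(got)), length(unique(want)))
    expect_true(all(tapply(want, got, function(x) length(unique(x))) == 1))
  }
  expect_equal(length(unique(single_linkage_cluster(m, 1))), n)
  expect_equal(length(unique(single_linkage_cluster(m, 0))), 1L)
  expect_error(single_linkage_cluster(m[, -1, drop = FALSE], 0.5))
})

test_that("random-similarity statistics are reproducible and well-formed", {
  ens1 <- synthetic_ensemble(n_atoms = 6, n_groups = 1, n_per_group = 1,
                             seed = 3)
  same <- list(list(conformer = ens1$conformers[[1]]))
  rs <- random_similarity_study(same, n_pairs = 3, seed = 1)
  expect_equal(rs$mean[rs$score == "st"], 1, tolerance = 1e-6)
  expect_equal(rs$sd[rs$score == "st"], 0, tolerance = 1e-6)

  pool <- lapply(1:8, function(i) {
    e <- synthetic_ensemble(n_atoms = 7, n_groups = 1, n_per_group = 1,
                            seed = 200 + i)
    list(conformer = e$conformers[[1]])
  })
  r1 <- random_similarity_study(pool, n_pairs = 10, seed = 7)
  r2 <- random_similarity_study(pool, n_pairs = 10, seed = 7)
  expect_equal(r1, r2)
  expect_equal(r1$threshold, r1$mean + 2 * r1$sd)
  expect_error(random_similarity_study(pool, n_pairs = 1), "n_pairs")
})
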