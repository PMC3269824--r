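test_that("sampling RMSD prediction rounds to 0.2 and applies the floor", {
  expect_equal(predict_sampling_rmsd(5, 0), 0.4)    # 0.2685 -> 0.2 -> floor
  expect_equal(predict_sampling_rmsd(20, 3), 0.6)   # 0.537
  expect_equal(predict_sampling_rmsd(50, 15), 1.4)  # 1.314
  expect_error(predict_sampling_rmsd(0, 0), "nha")
  expect_error(predict_sampling_rmsd(5, -1), "er")

  # midway values round up (coarser sampling): pred = 0.9 -> 1.0
  # 0.219 + 0.0099*nha + 0.04*er = 0.9 at nha = 30, er = 9.6
  expect_equal(predict_sampling_rmsd(30, 9.6), 1.0)
})

test_that("heavy-atom RMSD removes rigid motion and symmetry relabeling", {
  bu <- toy_butane()
  expect_equal(heavy_atom_rmsd(bu$conformer, bu$conformer,
                               mol = bu$molecule), 0)

  shifted <- bu$conformer
  shifted$coords <- sweep(shifted$coords, 2, c(-1, 0, 0))
  expect_lt(heavy_atom_rmsd(bu$conformer, shifted, mol = bu$molecule), 1e-9)

  set.seed(11)
  rot <- bu$conformer
  rot$coords <- rot$coords %*% t(random_proper_rotation()) + 2
  expect_lt(heavy_atom_rmsd(bu$conformer, rot, mol = bu$molecule), 1e-9)

  # ring rotation relabeling: zero only when automorphisms are searched
  bz <- toy_benzene()
  relab <- conformer(bz$conformer$coords[c(2:6, 1), ],
                     molecule = bz$molecule)
  expect_lt(heavy_atom_rmsd(bz$conformer, relab, mol = bz$molecule,
                            overlay = FALSE), 1e-9)
  expect_gt(heavy_atom_rmsd(bz$conformer, relab, automorph = FALSE,
                            overlay = FALSE), 0.1)

  expect_error(heavy_atom_rmsd(bu$conformer, toy_benzene()$conformer,
                               automorph = FALSE), "mismatched")
})

test_that("ensemble sampling guarantees coverage and separation", {
  # degenerate inputs
  ens1 <- synthetic_ensemble(n_atoms = 6, n_groups = 1, n_per_group = 1,
                             seed = 1)
  expect_equal(sample_ensemble(ens1$conformers, 0.4, mol = ens1$molecule), 1L)

  dup <- ens1$conformers[[1]]
  dup2 <- dup; dup2$local_id <- 1L
  expect_length(sample_ensemble(list(dup, dup2), 0.4, mol = ens1$molecule), 1L)
  expect_error(sample_ensemble(list(dup), 0), "rmsd")

  # 50 synthetic conformers vs exhaustive pairwise oracle
  ens <- synthetic_ensemble(n_atoms = 8, n_groups = 5, n_per_group = 10,
                            jitter = 0.15, seed = 23)
  r <- 0.6
  keep <- sample_ensemble(ens$conformers, r, mol = ens$molecule)
  m <- brute_rmsd_matrix(ens$conformers)
  # separation: retained pairs >= r apart
  expect_true(all(m[keep, keep][upper.tri(diag(length(keep)))] >= r - 1e-9))
  # coverage: everyone within r of a retained conformer
  expect_true(all(apply(m[, keep, drop = FALSE], 1, min) < r + 1e-9))
  # lowest-energy conformer always retained
  expect_true(1L %in% keep)
})

test_that("sampling is idempotent and collapses duplicate groups", {
  ens <- synthetic_ensemble(n_atoms = 8, n_groups = 5, n_per_group = 10,
                            jitter = 0.05, seed = 5)
  keep <- sample_ensemble(ens$conformers, 0.5, mol = ens$molecule)
  expect_equal(length(keep), 5L)           # one representative per group
  again <- sample_ensemble(ens$conformers[keep], 0.5, mol = ens$molecule)
  expect_length(again, length(keep))
})

test_that("model building caps the ensemble and stores the final RMSD", {
  ens1 <- synthetic_ensemble(n_atoms = 6, n_groups = 1, n_per_group = 1,
                             seed = 9)
  mdl <- build_conformer_model(ens1$molecule, ens1$conformers)
  expect_length(mdl$conformers, 1L)
  d <- count_descriptors(ens1$molecule)
  expect_equal(mdl$sampling_rmsd,
               predict_sampling_rmsd(d$nha, effective_rotor_count(d$rb, d$nara)))

  # a widely spread duplicate-free set is fully retained
  ens <- synthetic_ensemble(n_atoms = 8, n_groups = 12, n_per_group = 1,
                            jitter = 0, spread = 4, seed = 31)
  mdl <- build_conformer_model(ens$molecule, ens$conformers)
  expect_length(mdl$conformers, 12L)

  # cap forces re-clustering at coarser RMSD
  cfg <- sampling_config(max_conformers = 3L)
  ens2 <- synthetic_ensemble(n_atoms = 8, n_groups = 8, n_per_group = 2,
                             jitter = 0.05, seed = 13)
  mdl2 <- build_conformer_model(ens2$molecule, ens2$conformers, cfg)
  expect_lte(length(mdl2$conformers), 3L)
  d2 <- count_descriptors(ens2$molecule)
  expect_gte(mdl2$sampling_rmsd,
             predict_sampling_rmsd(d2$nha,
                                   effective_rotor_count(d2$rb, d2$nara)))
  # local ids sequential in energy order, conformers canonicalized
  lids <- vapply(mdl2$conformers, function(cf) cf$local_id, integer(1))
  expect_equal(lids, seq_along(lids) - 1L)
})
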