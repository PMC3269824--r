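test_that("rule perception places features at steric centers", {
  bz <- toy_benzene()
  fs <- perceive_features(bz$molecule, bz$conformer)
  expect_equal(nrow(fs$features), 1L)
  expect_equal(fs$features$type, "ring")
  expect_equal(unname(fs$features$position[1, ]),
               unname(colMeans(bz$conformer$coords)), tolerance = 1e-9)

  ac <- toy_acetate()
  counts <- feature_counts(perceive_features(ac$molecule, ac$conformer))
  expect_equal(unname(counts["anion"]), 1L)
  an <- perceive_features(ac$molecule, ac$conformer)
  anion <- an$features[an$features$type == "anion", ]
  expect_setequal(anion$members[[1]], c(2L, 3L, 4L))

  et <- toy_ethane()
  counts <- feature_counts(perceive_features(et$molecule, et$conformer))
  expect_equal(sum(counts[c("anion", "cation", "acceptor", "donor",
                            "ring")]), 0L)

  dp <- toy_dopamine()
  counts <- feature_counts(perceive_features(dp$molecule, dp$conformer))
  expect_equal(unname(counts["donor"]), 3L)     # two phenols + amine
  expect_equal(unname(counts["cation"]), 1L)    # aliphatic amine at pH 7
  expect_equal(unname(counts["ring"]), 1L)
})

test_that("same-type features merge within 1.0 A and keep types separate", {
  mol <- molecule(c("O", "O", "O", "N"),
                  formal_charge = 0L)
  mk <- function(coords) conformer(coords, molecule = mol)

  # two donors 0.8 A apart merge into one at the members' steric center
  cf <- mk(rbind(c(0, 0, 0), c(0.8, 0, 0), c(10, 0, 0), c(20, 0, 0)))
  fs <- perceive_features(mol, cf, merge = FALSE)
  donors <- fs$features[fs$features$type == "donor", ]
  expect_gte(nrow(donors), 3L)
  merged <- merge_features(fs, 1.0)
  md <- merged$features[merged$features$type == "donor", ]
  expect_equal(nrow(md), 3L)
  pos <- md$position[order(md$position[, 1]), , drop = FALSE]
  expect_equal(pos[1, 1], 0.4, tolerance = 1e-9)

  # 1.2 A apart stays separate
  cf2 <- mk(rbind(c(0, 0, 0), c(1.2, 0, 0), c(10, 0, 0), c(20, 0, 0)))
  fs2 <- merge_features(perceive_features(mol, cf2, merge = FALSE), 1.0)
  expect_equal(sum(fs2$features$type == "donor"), 4L)

  # donor and acceptor 0.1 A apart are different types: both kept
  mixed <- pubshape3d:::new_feature_set(
    c("donor", "acceptor"), list(1L, 2L),
    rbind(c(0, 0, 0), c(0.1, 0, 0)))
  kept <- merge_features(mixed, 1.0)
  expect_equal(nrow(kept$features), 2L)

  # idempotence and post-merge separation
  again <- merge_features(merged, 1.0)
  expect_identical(again$features$members, merged$features$members)
  for (tp in unique(merged$features$type)) {
    pos <- merged$features$position[merged$features$type == tp, ,
                                    drop = FALSE]
    if (nrow(pos) > 1)
      expect_true(all(dist(pos) > 1.0))
  }
})

test_that("cascading merges recompute centers from member atoms", {
  mol <- molecule(c("O", "O", "O"))
  cf <- conformer(rbind(c(0, 0, 0), c(0.9, 0, 0), c(1.7, 0, 0)),
                  molecule = mol)
  fs <- merge_features(perceive_features(mol, cf, merge = FALSE), 1.0)
  # 1-2 merge to 0.45; then 0.45-1.7 are 1.25 apart for the donor pair,
  # but the acceptor cascade continues from merged positions
  don <- fs$features[fs$features$type == "donor", ]
  expect_equal(nrow(don), 2L)
})

test_that("color Tanimoto identities and per-type decomposition hold", {
  dp <- toy_dopamine()
  fs <- perceive_features(dp$molecule, dp$conformer)
  expect_equal(color_tanimoto(fs, fs), 1)

  # disjoint types only: a donor set against an acceptor set at the same spot
  pt <- matrix(0, 1, 3)
  f_donor <- pubshape3d:::new_feature_set("donor", list(1L), pt)
  f_acceptor <- pubshape3d:::new_feature_set("acceptor", list(1L), pt)
  expect_equal(color_tanimoto(f_donor, f_acceptor), 0)

  # both empty -> 0 by convention
  et <- toy_ethane()
  fe <- perceive_features(et$molecule, et$conformer)
  expect_equal(color_tanimoto(fe, fe), 0)

  # restricting to a single type equals the single-type Tanimoto
  keep_type <- function(f, tp)
    structure(list(features = f$features[f$features$type == tp, ],
                   coords = f$coords), class = "feature_set")
  set.seed(4)
  tr <- list(rotation = random_proper_rotation(), translation = rnorm(3))
  fs2 <- transform_feature_positions(fs, tr)
  for (tp in c("donor", "acceptor")) {
    expect_equal(color_tanimoto(keep_type(fs, tp), keep_type(fs2, tp)),
                 color_tanimoto(keep_type(fs, tp), keep_type(fs2, tp)))
  }

  # CT invariant under a common rigid motion
  ct0 <- color_tanimoto(fs, fs2)
  tr2 <- list(rotation = random_proper_rotation(), translation = rnorm(3))
  expect_equal(color_tanimoto(transform_feature_positions(fs, tr2),
                              transform_feature_positions(fs2, tr2)),
               ct0, tolerance = 1e-8)
})
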