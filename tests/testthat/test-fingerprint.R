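test_that("the 64-bit transform codec round-trips with small error", {
  set.seed(12)
  for (k in 1:20) {
    tr <- list(rotation = random_proper_rotation(),
               translation = runif(3, -7, 7))
    hex <- pack_transform(tr)
    expect_true(grepl("^[0-9A-F]{16}$", hex))
    back <- unpack_transform(hex)
    expect_lt(max(abs(back$rotation - tr$rotation)), 5e-4)
    expect_lt(max(abs(back$translation - tr$translation)), 0.125 + 1e-9)
    expect_lt(max(abs(crossprod(back$rotation) - diag(3))), 1e-9)
  }
})

test_that("reference sets are mutually dissimilar by construction", {
  ens1 <- synthetic_ensemble(n_atoms = 6, n_groups = 1, n_per_group = 1,
                             seed = 2)
  refs <- build_reference_set(ens1$conformers)
  expect_length(refs$conformers, 1L)

  # duplicates of one conformer collapse to a single reference
  dup <- rep(ens1$conformers, 4)
  expect_length(build_reference_set(dup)$conformers, 1L)

  # 20 synthetic shapes: verify the invariant by exhaustive pairwise check
  ens <- synthetic_ensemble(n_atoms = 7, n_groups = 20, n_per_group = 1,
                            spread = 2, seed = 41)
  refs <- build_reference_set(ens$conformers, st_threshold = 0.75)
  k <- length(refs$conformers)
  expect_gte(k, 2L)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- optimize_overlap(refs$conformers[[i]], refs$conformers[[j]])
    expect_lte(r$st, 0.75 + 0.02)  # small optimizer slack on recheck
  }
})

test_that("fingerprint bits match an all-pairs ST oracle", {
  ens <- synthetic_ensemble(n_atoms = 7, n_groups = 8, n_per_group = 1,
                            spread = 2, seed = 43)
  refs <- build_reference_set(ens$conformers[1:5], st_threshold = 0.75)
  thr <- 0.7
  for (i in 6:8) {
    fp <- fingerprint_conformer(ens$conformers[[i]], refs, st_threshold = thr)
    oracle_bits <- character()
    for (j in seq_along(refs$conformers)) {
      r <- optimize_overlap(refs$conformers[[j]], ens$conformers[[i]])
      if (r$st > thr) oracle_bits <- c(oracle_bits, refs$ids$gid[j])
    }
    expect_setequal(fp$bits$ref_gid, oracle_bits)
  }

  # a conformer that is itself a reference: bit with ST ~ 1
  fp <- fingerprint_conformer(refs$conformers[[1]], refs)
  expect_true(refs$ids$gid[1] %in% fp$bits$ref_gid)
  expect_gte(max(fp$bits$st), 0.999)
})

test_that("alignment recycling skips disjoint pairs and replays well", {
  ens <- synthetic_ensemble(n_atoms = 7, n_groups = 6, n_per_group = 2,
                            jitter = 0.1, spread = 2.5, seed = 47)
  refs <- build_reference_set(ens$conformers[seq(1, 12, by = 2)],
                              st_threshold = 0.85)
  fps <- lapply(ens$conformers, fingerprint_conformer, refs = refs,
                st_threshold = 0.8)

  # same group members share a reference; replay close to full optimization
  a <- ens$conformers[[1]]; b <- ens$conformers[[2]]
  expect_gt(length(intersect(fps[[1]]$bits$ref_gid, fps[[2]]$bits$ref_gid)), 0)
  rec <- recycle_alignment(a, b, fps[[1]], fps[[2]])
  expect_false(is_skip(rec))
  full <- optimize_overlap(a, b)
  expect_lte(rec$st, full$st + 1e-6)
  expect_gte(rec$st, full$st - 0.05)

  # identical conformers sharing a reference replay to ST ~ 1
  rec_same <- recycle_alignment(a, a, fps[[1]], fps[[1]])
  expect_gte(rec_same$st, 0.98)

  # disjoint fingerprints: skip signal
  far <- lapply(1:12, function(i) {
    if (!nrow(fps[[i]]$bits)) i else NA_integer_
  })
  empty_fp <- fps[[1]]; empty_fp$bits <- empty_fp$bits[0, ]
  expect_true(is_skip(recycle_alignment(a, b, empty_fp, fps[[2]])))

  # mismatched reference sets error
  other <- build_reference_set(ens$conformers[1:2], st_threshold = 0.85)
  fp_other <- fingerprint_conformer(a, other)
  expect_error(recycle_alignment(a, b, fp_other, fps[[2]]), "reference")
})
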