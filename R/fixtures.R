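# Deterministic toy molecules and synthetic conformer ensembles.
# These are first-class generators used by the test oracles and examples:
# every structure is built in code (no data files) and every random
# ensemble is reproducible from its seed.

toy_record <- function(elements, bonds, coords, formal_charge = 0L,
                       record_id = 0L, name = NULL, energy = NA_real_) {
  mol <- molecule(elements, bonds, formal_charge = formal_charge,
                  record_id = record_id, name = name)
  list(molecule = mol,
       conformer = conformer(as.matrix(coords), molecule = mol,
                             energy = energy))
}

#' Toy molecule builders
#'
#' Small hand-built molecules with fixed 3-D coordinates, used as
#' deterministic fixtures: methane, ethane, n-butane (anti), benzene
#' (Kekule hexagon), cyclohexane (chair), ethanol, acetate (charged
#' carboxylate), and a dopamine-like catecholamine with explicit
#' hydrogens. Each returns a list with `molecule` and `conformer`.
#'
#' @return list with elements `molecule` ([molecule()]) and `conformer`
#'   ([conformer()]).
#' @name toy_molecules
NULL

#' @rdname toy_molecules
#' @export
toy_methane <- function() {
  h <- 0.629
  toy_record(
    c("C", "H", "H", "H", "H"),
    data.frame(a1 = 1, a2 = 2:5, order = 1),
    rbind(c(0, 0, 0), c(h, h, h), c(-h, -h, h), c(-h, h, -h), c(h, -h, -h)),
    record_id = 297, name = "methane")
}

#' @rdname toy_molecules
#' @export
toy_ethane <- function() {
  toy_record(c("C", "C"),
             data.frame(a1 = 1, a2 = 2, order = 1),
             rbind(c(0, 0, 0), c(1.54, 0, 0)),
             record_id = 6324, name = "ethane")
}

#' @rdname toy_molecules
#' @export
toy_butane <- function() {
  dx <- 1.54 * sin(55.25 * pi / 180); dy <- 1.54 * cos(55.25 * pi / 180)
  toy_record(c("C", "C", "C", "C"),
             data.frame(a1 = 1:3, a2 = 2:4, order = 1),
             rbind(c(0, 0, 0), c(dx, dy, 0), c(2 * dx, 0, 0),
                   c(3 * dx, dy, 0)),
             record_id = 7843, name = "butane")
}

#' @rdname toy_molecules
#' @export
toy_benzene <- function() {
  ang <- seq(0, by = pi / 3, length.out = 6)
  toy_record(rep("C", 6),
             data.frame(a1 = 1:6, a2 = c(2:6, 1),
                        order = c(2, 1, 2, 1, 2, 1)),
             cbind(1.39 * cos(ang), 1.39 * sin(ang), 0),
             record_id = 241, name = "benzene")
}

#' @rdname toy_molecules
#' @export
toy_cyclohexane <- function() {
  ang <- seq(0, by = pi / 3, length.out = 6)
  toy_record(rep("C", 6),
             data.frame(a1 = 1:6, a2 = c(2:6, 1), order = 1),
             cbind(1.46 * cos(ang), 1.46 * sin(ang),
                   0.25 * rep(c(1, -1), 3)),
             record_id = 8078, name = "cyclohexane")
}

#' @rdname toy_molecules
#' @export
toy_ethanol <- function() {
  toy_record(c("C", "C", "O"),
             data.frame(a1 = 1:2, a2 = 2:3, order = 1),
             rbind(c(0, 0, 0), c(1.54, 0, 0), c(2.05, 1.33, 0)),
             record_id = 702, name = "ethanol")
}

#' @rdname toy_molecules
#' @export
toy_acetate <- function() {
  toy_record(c("C", "C", "O", "O"),
             data.frame(a1 = c(1, 2, 2), a2 = c(2, 3, 4),
                        order = c(1, 2, 1)),
             rbind(c(0, 0, 0), c(1.52, 0, 0), c(2.12, 1.06, 0),
                   c(2.12, -1.06, 0)),
             formal_charge = c(0L, 0L, 0L, -1L),
             record_id = 175, name = "acetate")
}

#' @rdname toy_molecules
#' @export
toy_dopamine <- function() {
  coords <- matrix(c(
    -1.8936,  0.7100,  0.0133,  -0.6860,  1.4161,  0.0278,
     0.5101,  0.7102,  0.0291,   0.5041, -0.6827,  0.0214,
    -0.6909, -1.3910,  0.0066,  -1.9089, -0.6967, -0.0081,
    -3.2229, -1.4424, -0.0568,  -3.7868, -1.7514,  1.3345,
    -5.0733, -2.4435,  1.2380,   1.6881, -1.3653,  0.0225,
     1.7234,  1.3434,  0.0331,  -2.8295,  1.2655,  0.0048,
    -0.7035,  2.5010,  0.0327,  -0.6664, -2.4776, -0.0077,
    -3.0888, -2.3726, -0.6243,  -3.9461, -0.8464, -0.6295,
    -3.9218, -0.8280,  1.9093,  -3.0882, -2.3838,  1.8936,
    -5.7618, -1.8329,  0.7988,  -5.4234, -2.6380,  2.1757,
     2.3724, -0.6664,  0.0222,   1.5627,  2.3020,  0.0157),
    ncol = 3, byrow = TRUE)
  elements <- c(rep("C", 8), "N", "O", "O", rep("H", 11))
  bonds <- data.frame(
    a1 = c(1, 1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 7, 7, 7, 8, 8, 8, 9, 9, 10, 11),
    a2 = c(2, 6, 12, 3, 13, 4, 11, 5, 10, 6, 14, 7, 8, 15, 16, 9, 17, 18,
           19, 20, 21, 22),
    order = c(2, 1, 1, 1, 1, 2, 1, 1, 1, 2, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1,
              1, 1))
  toy_record(elements, bonds, coords, record_id = 681, name = "dopamine")
}

#' The toy molecule panel
#'
#' All deterministic toy molecules as a named list, the fixture analogue of
#' a small-drug SMILES panel.
#'
#' @return named list of `list(molecule, conformer)` records.
#' @export
toy_panel <- function() {
  list(methane = toy_methane(), ethane = toy_ethane(),
       butane = toy_butane(), benzene = toy_benzene(),
       cyclohexane = toy_cyclohexane(), ethanol = toy_ethanol(),
       acetate = toy_acetate(), dopamine = toy_dopamine())
}

# random rotation via QR of a normal matrix, made proper
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Synthetic point-cloud conformer ensembles
#'
#' Generates a carbon-chain "molecule" of `n_atoms` and a conformer
#' ensemble with known group structure: `n_groups` well-separated base
#' shapes, each copied `n_per_group` times with isotropic coordinate
#' jitter of standard deviation `jitter` and a random rigid motion (which
#' superposed RMSD removes). Energies increase with draw order so the
#' first member of group 1 is the lowest-energy conformer. Deterministic
#' given `seed`.
#'
#' @param n_atoms atoms per conformer.
#' @param n_groups number of duplicate groups.
#' @param n_per_group jittered copies per group.
#' @param jitter per-coordinate Gaussian jitter, Angstrom.
#' @param spread scale of the base shapes, Angstrom.
#' @param seed RNG seed.
#' @return list with `molecule`, `conformers` (list), and `group`
#'   (integer vector of ground-truth group labels).
#' @export
synthetic_ensemble <- function(n_atoms = 8L, n_groups = 5L,
                               n_per_group = 10L, jitter = 0.05,
                               spread = 2.5, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  mol <- molecule(rep("C", n_atoms),
                  data.frame(a1 = seq_len(n_atoms - 1),
                             a2 = 2:n_atoms, order = 1),
                  record_id = 9000 + n_atoms, name = "point_cloud_chain")
  bases <- lapply(seq_len(n_groups), function(g)
    matrix(stats::rnorm(n_atoms * 3, sd = spread), n_atoms, 3))
  confs <- list(); group <- integer()
  k <- 0L
  for (g in seq_len(n_groups)) {
    for (m in seq_len(n_per_group)) {
      x <- bases[[g]] + matrix(stats::rnorm(n_atoms * 3, sd = jitter),
                               n_atoms, 3)
      x <- sweep(x %*% random_rotation(), 2, stats::rnorm(3, sd = 3), "+")
      k <- k + 1L
      confs[[k]] <- conformer(x, molecule = mol, energy = k * 0.1,
                              local_id = k - 1L)
      group[k] <- g
    }
  }
  list(molecule = mol, conformers = confs, group = group)
}

#' Write fixture SDF files
#'
#' Deterministic fixture emitter: materializes a named fixture family as
#' SDF under `dir`. Families: `"toy_panel"` (the hand-built molecules),
#' `"duplicate_groups"` (a synthetic ensemble with known group structure),
#' `"degenerate"` (single atom, linear chain, symmetric ring).
#'
#' @param spec fixture family name.
#' @param seed RNG seed used by the random families.
#' @param dir output directory (created if missing).
#' @param ... passed on to [synthetic_ensemble()] for the random families.
#' @return invisible character vector of the files written.
#' @export
fixture_generator <- function(spec = c("toy_panel", "duplicate_groups",
                                       "degenerate"),
                              seed = 1L, dir = tempdir(), ...) {
  spec <- match.arg(spec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(spec, ".sdf"))
  models <- switch(spec,
    toy_panel = lapply(toy_panel(), function(rec)
      conformer_model(rec$molecule, list(rec$conformer),
                      sampling_rmsd = 0.4)),
    duplicate_groups = {
      ens <- synthetic_ensemble(seed = seed, ...)
      list(conformer_model(ens$molecule, ens$conformers,
                           sampling_rmsd = 0.4))
    },
    degenerate = {
      single <- toy_record("C", NULL, matrix(c(5, 5, 5), 1, 3),
                           record_id = 1, name = "single_atom")
      chain <- toy_record(rep("C", 5),
                          data.frame(a1 = 1:4, a2 = 2:5, order = 1),
                          cbind(seq(0, 6.16, by = 1.54), 0, 0),
                          record_id = 2, name = "linear_chain")
      ring <- toy_benzene()
      lapply(list(single, chain, ring), function(rec)
        conformer_model(rec$molecule, list(rec$conformer),
                        sampling_rmsd = 0.4))
    })
  write_model(models, path)
  invisible(path)
}
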