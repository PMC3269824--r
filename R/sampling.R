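#' Sampling configuration
#'
#' Parameters of the conformer-ensemble RMSD sampling stage.
#'
#' @param rmsd_increment rounding/iteration increment in Angstrom.
#' @param rmsd_floor smallest sampling RMSD ever used, Angstrom.
#' @param max_conformers retained-count cap of a finalized model.
#' @param use_automorphism minimize RMSD over heavy-atom graph
#'   automorphisms (symmetry-equivalent relabelings).
#' @param use_overlay minimize RMSD over rigid superposition.
#' @param automorph_budget cap on enumerated automorphisms before falling
#'   back to the identity mapping.
#' @return a list of class `sampling_config`.
#' @export
sampling_config <- function(rmsd_increment = 0.2, rmsd_floor = 0.4,
                            max_conformers = 500L, use_automorphism = TRUE,
                            use_overlay = TRUE, automorph_budget = 2000L) {
  if (rmsd_increment <= 0) abort("rmsd_increment must be > 0")
  if (rmsd_floor < rmsd_increment) abort("rmsd_floor must be >= rmsd_increment")
  if (max_conformers < 1L) abort("max_conformers must be >= 1")
  structure(list(rmsd_increment = rmsd_increment, rmsd_floor = rmsd_floor,
                 max_conformers = as.integer(max_conformers),
                 use_automorphism = isTRUE(use_automorphism),
                 use_overlay = isTRUE(use_overlay),
                 automorph_budget = as.integer(automorph_budget)),
            class = "sampling_config")
}

#' Conformer-generator backend contract
#'
#' The package does not generate conformers from scratch; torsion-driving
#' generation is a pluggable backend. This record carries the contract
#' parameters a backend must honor: a strain-energy window of 25 kcal/mol
#' and at most 100,000 conformers per stereoisomer, with undefined
#' stereocenters enumerated.
#'
#' @param energy_window kcal/mol strain window.
#' @param max_conformers_per_stereoisomer raw-ensemble cap.
#' @param enumerate_undefined_stereo enumerate unassigned stereocenters.
#' @return a list of class `generator_config`.
#' @export
generator_config <- function(energy_window = 25,
                             max_conformers_per_stereoisomer = 100000L,
                             enumerate_undefined_stereo = TRUE) {
  if (energy_window <= 0) abort("energy_window must be > 0")
  if (max_conformers_per_stereoisomer < 1L) abort("cap must be >= 1")
  structure(list(energy_window = energy_window,
                 max_conformers_per_stereoisomer =
                   as.integer(max_conformers_per_stereoisomer),
                 enumerate_undefined_stereo = isTRUE(enumerate_undefined_stereo)),
            class = "generator_config")
}

#' Predict the sampling RMSD from size and flexibility
#'
#' Evaluates the regression `0.219 + 0.0099 * nha + 0.040 * er`, rounds to
#' the nearest increment (ties round up), and applies the floor. The result
#' is the minimum heavy-atom RMSD guaranteed between retained conformers.
#'
#' @param nha non-hydrogen atom count (>= 1).
#' @param er effective rotor count (>= 0), see [effective_rotor_count()].
#' @param config a [sampling_config()].
#' @return sampling RMSD in Angstrom, a positive multiple of the increment.
#' @examples
#' predict_sampling_rmsd(5, 0)    # 0.4 (floor engaged)
#' predict_sampling_rmsd(20, 3)   # 0.6
#' @export
predict_sampling_rmsd <- function(nha, er, config = sampling_config()) {
  if (any(nha < 1)) abort("nha must be >= 1")
  if (any(er < 0)) abort("er must be >= 0")
  pred <- 0.219 + 0.0099 * nha + 0.040 * er
  inc <- config$rmsd_increment
  k <- pred / inc
  # round half up so midway values take the coarser sampling
  rounded <- ifelse(abs(k - floor(k) - 0.5) < 1e-12, ceiling(k), round(k)) * inc
  pmax(config$rmsd_floor, rounded)
}

# --- rigid superposition ----------------------------------------------------

# Kabsch: optimal proper rotation mapping centered B onto centered A.
kabsch_rotation <- function(a, b) {
  h <- crossprod(b, a)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  s$v %*% diag(c(1, 1, d)) %*% t(s$u)
}

rmsd_raw <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

rmsd_superposed <- function(a, b) {
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  r <- kabsch_rotation(a0, b0)
  sqrt(max(0, mean(rowSums((tcrossprod(b0, r) - a0)^2))))
}

# --- automorphisms ----------------------------------------------------------

# Expand the automorphism group of the heavy-atom subgraph (vertices colored
# by element) from igraph generators, by BFS with a budget. Returns a matrix
# with one permutation per row; falls back to the identity row when the
# group is larger than the budget.
heavy_automorphisms <- function(mol, budget = 2000L) {
  heavy <- which(!mol$atoms$is_hydrogen)
  n <- length(heavy)
  idmap <- seq_len(n)
  if (n == 0L) return(matrix(integer(), nrow = 0))
  b <- mol$bonds
  keep <- b$a1 %in% heavy & b$a2 %in% heavy
  b <- b[keep, , drop = FALSE]
  pos <- match(seq_len(nrow(mol$atoms)), heavy)
  g <- igraph::graph_from_data_frame(
    data.frame(from = pos[b$a1], to = pos[b$a2]),
    directed = FALSE, vertices = data.frame(name = idmap))
  colors <- as.integer(factor(mol$atoms$element[heavy]))
  gens <- tryCatch(igraph::automorphism_group(g, colors = colors),
                   error = function(e) list())
  gens <- lapply(gens, as.integer)
  gens <- gens[!vapply(gens, function(p) identical(p, idmap), logical(1))]
  if (!length(gens)) return(matrix(idmap, nrow = 1))
  seen <- new.env(parent = emptyenv())
  key <- function(p) paste(p, collapse = ",")
  assign(key(idmap), TRUE, envir = seen)
  queue <- list(idmap)
  out <- list(idmap)
  overflow <- FALSE
  while (length(queue)) {
    p <- queue[[1]]; queue <- queue[-1]
    for (gperm in gens) {
      q <- gperm[p]
      k <- key(q)
      if (!exists(k, envir = seen, inherits = FALSE)) {
        if (length(out) >= budget) { overflow <- TRUE; break }
        assign(k, TRUE, envir = seen)
        out[[length(out) + 1L]] <- q
        queue[[length(queue) + 1L]] <- q
      }
    }
    if (overflow) break
  }
  if (overflow) return(matrix(idmap, nrow = 1))
  do.call(rbind, out)
}

#' Symmetry-aware heavy-atom RMSD between two conformers
#'
#' RMSD over non-hydrogen atoms, optionally minimized over rigid
#' superposition (Kabsch) and over graph automorphisms of the heavy-atom
#' subgraph so that symmetry-equivalent poses (e.g. a flipped phenyl ring)
#' score zero.
#'
#' @param a,b [conformer()] objects of the same parent molecule.
#' @param mol the parent [molecule()]; required when `automorph = TRUE`.
#' @param automorph minimize over heavy-atom automorphisms.
#' @param overlay minimize over rotation + translation.
#' @param automorphisms optional precomputed permutation matrix from
#'   `heavy_automorphisms()` (one permutation per row), to amortize the
#'   group expansion over many pairs.
#' @return RMSD in Angstrom (non-negative, symmetric in a and b).
#' @export
heavy_atom_rmsd <- function(a, b, mol = NULL, automorph = !is.null(mol),
                            overlay = TRUE, automorphisms = NULL) {
  ha <- heavy_coords(a); hb <- heavy_coords(b)
  if (nrow(ha) != nrow(hb)) abort("conformers have mismatched heavy atom counts")
  if (nrow(ha) == 0L) abort("conformers have no heavy atoms")
  perms <- if (automorph) {
    automorphisms %||% {
      if (is.null(mol)) abort("automorph = TRUE requires mol or automorphisms")
      heavy_automorphisms(mol)
    }
  } else matrix(seq_len(nrow(ha)), nrow = 1)
  fn <- if (overlay) rmsd_superposed else rmsd_raw
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    v <- fn(ha, hb[perms[r, ], , drop = FALSE])
    if (v < best) best <- v
    if (best < 1e-12) break
  }
  best
}

# --- ensemble sampling ------------------------------------------------------

#' Reduce a conformer ensemble to RMSD-separated representatives
#'
#' Two-stage exclusion-region clustering at radius `rmsd`: a partition pass
#' over an exclusion-region hierarchy of decreasing radius (4r, 2r, r),
#' followed by a quadratic pass over the stage-one representatives, and a
#' final coverage sweep. Conformers are visited in ascending energy (ties by
#' input order), so the lowest-energy conformer is always retained. The
#' result satisfies both guarantees: every input conformer lies within
#' `rmsd` of a retained one (coverage), and retained conformers are pairwise
#' `>= rmsd` apart (separation).
#'
#' @param conformers list of [conformer()]s sharing one parent molecule.
#' @param rmsd exclusion radius in Angstrom (> 0).
#' @param config a [sampling_config()].
#' @param mol parent [molecule()] enabling automorphism-aware RMSD.
#' @return integer vector of retained indices into `conformers`, in
#'   ascending energy order.
#' @export
sample_ensemble <- function(conformers, rmsd, config = sampling_config(),
                            mol = NULL) {
  if (rmsd <= 0) abort("rmsd must be > 0")
  if (!length(conformers)) abort("need at least one conformer")
  n <- length(conformers)
  perms <- if (config$use_automorphism && !is.null(mol))
    heavy_automorphisms(mol, config$automorph_budget) else NULL
  dist_fn <- function(i, j)
    heavy_atom_rmsd(conformers[[i]], conformers[[j]],
                    automorph = !is.null(perms), overlay = config$use_overlay,
                    automorphisms = perms)
  ord <- energy_order(conformers)

  # stage 1: hierarchical partition, radii 4r -> 2r -> r
  radii <- rmsd * c(4, 2, 1)
  # each level: list of leader indices; children tracked per leader chain
  reps <- integer()         # bottom-level representatives
  tree <- list()            # per top leader: nested leaders
  top <- integer(); mid <- list(); bot <- list()
  for (i in ord) {
    # find (or create) top-level leader
    ti <- 0L
    for (k in seq_along(top)) if (dist_fn(i, top[k]) <= radii[1]) { ti <- k; break }
    if (ti == 0L) { top <- c(top, i); mid[[length(top)]] <- integer(); bot[[length(top)]] <- list(); ti <- length(top) }
    mi <- 0L
    for (k in seq_along(mid[[ti]])) if (dist_fn(i, mid[[ti]][k]) <= radii[2]) { mi <- k; break }
    if (mi == 0L) { mid[[ti]] <- c(mid[[ti]], i); bot[[ti]][[length(mid[[ti]])]] <- integer(); mi <- length(mid[[ti]]) }
    bi <- 0L
    for (k in seq_along(bot[[ti]][[mi]])) if (dist_fn(i, bot[[ti]][[mi]][k]) < rmsd) { bi <- k; break }
    if (bi == 0L) bot[[ti]][[mi]] <- c(bot[[ti]][[mi]], i)
  }
  reps <- unlist(bot, use.names = FALSE)
  reps <- reps[order(match(reps, ord))]

  # stage 2: quadratic exclusion over representatives (removes edge effects)
  kept <- integer()
  for (i in reps) {
    ok <- TRUE
    for (j in kept) if (dist_fn(i, j) < rmsd) { ok <- FALSE; break }
    if (ok) kept <- c(kept, i)
  }

  # coverage sweep: promote anything left uncovered by the kept set
  for (i in ord) {
    if (i %in% kept) next
    covered <- FALSE
    for (j in kept) if (dist_fn(i, j) < rmsd) { covered <- TRUE; break }
    if (!covered) kept <- c(kept, i)
  }
  kept[order(match(kept, ord))]
}

#' Build a finalized conformer model
#'
#' Starts from the predicted sampling RMSD for the molecule's size and
#' flexibility, samples the raw ensemble, and while more than
#' `config$max_conformers` conformers remain, increments the RMSD by one
#' increment and re-samples. Retained conformers are canonicalized to their
#' principal steric axes and assigned sequential local ids in energy order.
#'
#' @param mol an eligible [molecule()].
#' @param raw nonempty list of raw [conformer()]s.
#' @param config a [sampling_config()].
#' @param canonicalize rotate/translate retained conformers to principal
#'   steric axes (default TRUE).
#' @return a [conformer_model()].
#' @export
build_conformer_model <- function(mol, raw, config = sampling_config(),
                                  canonicalize = TRUE) {
  if (!length(raw)) abort("raw ensemble is empty")
  d <- count_descriptors(mol)
  er <- effective_rotor_count(d$rb, d$nara)
  rmsd <- predict_sampling_rmsd(d$nha, er, config)
  repeat {
    keep <- sample_ensemble(raw, rmsd, config, mol = mol)
    if (length(keep) <= config$max_conformers) break
    rmsd <- rmsd + config$rmsd_increment
  }
  confs <- raw[keep]
  confs <- lapply(seq_along(confs), function(i) {
    cf <- confs[[i]]
    cf$local_id <- i - 1L
    if (canonicalize) cf <- canonicalize_principal_axes(cf)
    cf
  })
  conformer_model(mol, confs, sampling_rmsd = rmsd)
}
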