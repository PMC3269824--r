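FEATURE_TYPES <- c("anion", "cation", "acceptor", "donor", "hydrophobe", "ring")

#' Feature perception rule set
#'
#' Explicit, documented substructure rules for the six pharmacophore
#' feature types, evaluated at an assumed pH-7 protonation state:
#' carboxylate/sulfonate/phosphate groups and negatively charged O/S/N are
#' anions; positively charged nitrogens, non-amide sp3 amines and
#' amidine/guanidine carbons are cations; oxygens and lone-pair nitrogens
#' are acceptors; O-H and N-H (explicit or implicit hydrogen) are donors;
#' connected groups of at least `min_hydrophobe_size` apolar carbons and
#' halogens are hydrophobes; every ring of the minimum cycle basis is a
#' ring feature. The rules are this package's own inspectable content; no
#' parity with any proprietary rule set is claimed.
#'
#' @param merge_radius same-type features closer than this are merged, A.
#' @param min_hydrophobe_size minimum atom count of a hydrophobe group.
#' @return a list of class `feature_rules`.
#' @export
feature_rules <- function(merge_radius = 1.0, min_hydrophobe_size = 3L) {
  structure(list(merge_radius = merge_radius,
                 min_hydrophobe_size = as.integer(min_hydrophobe_size)),
            class = "feature_rules")
}

new_feature_set <- function(type, members, coords) {
  position <- if (length(members)) {
    do.call(rbind, lapply(members, function(m)
      colMeans(coords[m, , drop = FALSE])))
  } else matrix(numeric(), 0, 3)
  fs <- tibble(type = type, members = members)
  fs$position <- position
  structure(list(features = fs, coords = coords), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set>", nrow(x$features), "feature(s)\n")
  if (nrow(x$features)) print(table(x$features$type))
  invisible(x)
}

#' Number of features per type
#' @param fs a feature set.
#' @return named integer vector over the six feature types.
#' @export
feature_counts <- function(fs) {
  out <- setNames(integer(length(FEATURE_TYPES)), FEATURE_TYPES)
  tb <- table(fs$features$type)
  out[names(tb)] <- as.integer(tb)
  out
}

#' Does a conformer have any pharmacophore features?
#' @param fs a feature set (or NULL).
#' @return logical.
#' @export
has_features <- function(fs) !is.null(fs) && nrow(fs$features) > 0L

neighbors_of <- function(mol, i) {
  b <- mol$bonds
  c(b$a2[b$a1 == i], b$a1[b$a2 == i])
}

bond_order_between <- function(mol, i, j) {
  b <- mol$bonds
  hit <- (b$a1 == i & b$a2 == j) | (b$a1 == j & b$a2 == i)
  if (any(hit)) b$order[which(hit)[1]] else 0L
}

#' Perceive pharmacophore features of a conformer
#'
#' Applies the documented rule set (see [feature_rules()]) to the molecule
#' graph and places one fictitious "color" atom per matched group at the
#' steric center (unweighted coordinate mean) of its member heavy atoms.
#' Same-type features within the merge radius are then iteratively merged
#' unless `merge = FALSE`.
#'
#' @param mol a [molecule()].
#' @param conf a [conformer()] of that molecule.
#' @param rules a [feature_rules()].
#' @param merge merge nearby same-type features (default TRUE).
#' @return a `feature_set`.
#' @export
perceive_features <- function(mol, conf, rules = feature_rules(),
                              merge = TRUE) {
  stopifnot(inherits(mol, "mol_record"), inherits(conf, "conformer"))
  if (nrow(conf$coords) != nrow(mol$atoms))
    abort("conformer does not belong to molecule")
  at <- mol$atoms
  el <- at$element
  n <- nrow(at)
  types <- character(); members <- list()
  add <- function(tp, m) {
    types[[length(types) + 1L]] <<- tp
    members[[length(members) + 1L]] <<- sort(unique(as.integer(m)))
  }
  hdeg <- function(i) sum(!at$is_hydrogen[neighbors_of(mol, i)])
  terminal_o <- function(o) el[o] == "O" && hdeg(o) == 1L
  has_h <- function(i) at$implicit_h[i] > 0L ||
    any(at$is_hydrogen[neighbors_of(mol, i)])

  in_anion_group <- rep(FALSE, n)
  # anion: carboxylate / sulfonate / phosphate heads
  for (i in which(el %in% c("C", "S", "P"))) {
    nb <- neighbors_of(mol, i)
    term_o <- nb[vapply(nb, terminal_o, logical(1))]
    need <- switch(el[i], C = 2L, S = 2L, P = 2L)
    dbl_o <- any(vapply(term_o, function(o)
      bond_order_between(mol, i, o) == 2L, logical(1)))
    chg_o <- any(at$formal_charge[term_o] < 0L)
    if (length(term_o) >= need && (dbl_o || chg_o)) {
      grp <- c(i, term_o)
      add("anion", grp)
      in_anion_group[grp] <- TRUE
    }
  }
  # anion: bare negatively charged O/S/N
  for (i in which(el %in% c("O", "S", "N") & at$formal_charge < 0L))
    if (!in_anion_group[i]) add("anion", i)

  # cation
  is_amide_n <- function(i) any(vapply(neighbors_of(mol, i), function(c)
    el[c] == "C" && any(vapply(neighbors_of(mol, c), function(o)
      el[o] == "O" && bond_order_between(mol, c, o) == 2L, logical(1))),
    logical(1)))
  guanidine_c <- rep(FALSE, n)
  for (i in which(el == "C" & !at$aromatic)) {
    nb <- neighbors_of(mol, i)
    nnb <- nb[el[nb] == "N" & !at$aromatic[nb]]
    dbl_n <- any(vapply(nnb, function(j)
      bond_order_between(mol, i, j) == 2L, logical(1)))
    if (length(nnb) >= 2L && dbl_n) {
      add("cation", c(i, nnb))
      guanidine_c[c(i, nnb)] <- TRUE
    }
  }
  for (i in which(el == "N")) {
    if (guanidine_c[i]) next
    if (at$formal_charge[i] > 0L) { add("cation", i); next }
    if (at$aromatic[i] || at$is_sp2[i]) next
    if (is_amide_n(i)) next
    nb <- neighbors_of(mol, i)
    if (all(el[nb] %in% c("C", "H")) && at$formal_charge[i] == 0L)
      add("cation", i)
  }

  # acceptor: oxygens and lone-pair nitrogens
  for (i in which(el == "O" & at$formal_charge <= 0L)) add("acceptor", i)
  for (i in which(el == "N" & at$formal_charge <= 0L)) {
    arom_pyridine <- at$aromatic[i] && hdeg(i) == 2L && !has_h(i)
    multiple <- any(vapply(neighbors_of(mol, i), function(j)
      bond_order_between(mol, i, j) >= 2L, logical(1)))
    if (arom_pyridine || multiple) add("acceptor", i)
  }

  # donor: O-H / N-H
  for (i in which(el %in% c("O", "N") & at$formal_charge >= 0L))
    if (has_h(i)) add("donor", i)

  # hydrophobe: connected apolar carbon/halogen groups
  apolar <- (el == "C" & !at$aromatic &
               !vapply(seq_len(n), function(i)
                 any(el[neighbors_of(mol, i)] %in% c("N", "O", "S", "P")),
                 logical(1))) |
    el %in% c("F", "Cl", "Br", "I")
  if (any(apolar)) {
    b <- mol$bonds
    keep <- b$a1 %in% which(apolar) & b$a2 %in% which(apolar)
    g <- igraph::graph_from_data_frame(
      data.frame(from = b$a1[keep], to = b$a2[keep]), directed = FALSE,
      vertices = data.frame(name = which(apolar)))
    cm <- igraph::components(g)$membership
    for (grp in split(as.integer(names(cm)), cm))
      if (length(grp) >= rules$min_hydrophobe_size) add("hydrophobe", grp)
  }

  # ring: one feature per minimum-cycle-basis ring
  for (cy in mol$rings) add("ring", cy)

  fs <- new_feature_set(types, members, conf$coords)
  if (merge) fs <- merge_features(fs, rules$merge_radius) else fs
}

#' Merge nearby same-type features
#'
#' Iteratively merges the closest same-type feature pair within `radius`
#' until none remain. The merged feature's member set is the union and its
#' position is recomputed as the steric center of the union. Equidistant
#' candidates are broken deterministically by (type, smallest member atom
#' index). Idempotent.
#'
#' @param fs a `feature_set`.
#' @param radius merge distance in Angstrom.
#' @return a `feature_set` in which same-type features are pairwise farther
#'   than `radius` apart.
#' @export
merge_features <- function(fs, radius = 1.0) {
  f <- fs$features
  repeat {
    if (nrow(f) < 2L) break
    cand <- NULL
    for (tp in unique(f$type)) {
      idx <- which(f$type == tp)
      if (length(idx) < 2L) next
      pos <- f$position[idx, , drop = FALSE]
      d <- as.matrix(stats::dist(pos))
      for (i in seq_along(idx)) for (j in seq_along(idx)) {
        if (j <= i) next
        if (d[i, j] <= radius + 1e-12) {
          key <- c(d[i, j], match(tp, FEATURE_TYPES),
                   min(f$members[[idx[i]]], f$members[[idx[j]]]))
          if (is.null(cand) || lex_less(key, cand$key))
            cand <- list(key = key, i = idx[i], j = idx[j])
        }
      }
    }
    if (is.null(cand)) break
    mem <- sort(unique(c(f$members[[cand$i]], f$members[[cand$j]])))
    f$members[[cand$i]] <- mem
    f$position[cand$i, ] <- colMeans(fs$coords[mem, , drop = FALSE])
    f <- f[-cand$j, ]
  }
  out <- fs
  out$features <- f
  out
}

lex_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k] - 1e-12) return(TRUE)
    if (a[k] > b[k] + 1e-12) return(FALSE)
  }
  FALSE
}

transform_feature_positions <- function(fs, transform) {
  if (!nrow(fs$features)) return(fs)
  fs$features$position <-
    sweep(fs$features$position %*% t(transform$rotation), 2,
          -transform$translation)
  fs$coords <- sweep(fs$coords %*% t(transform$rotation), 2,
                     -transform$translation)
  fs
}

#' Color (feature) Tanimoto at a fixed pose
#'
#' `CT = sum_f V_AB^f / (sum_f V_AA^f + sum_f V_BB^f - sum_f V_AB^f)` where
#' `f` runs over the six feature types and overlaps are Gaussian
#' product-overlap sums between same-type color atoms of fixed radius.
#' When both sets are empty the convention is `CT = 0` (the featureless
#' case is handled by a separate shape-only neighboring threshold).
#'
#' @param a,b `feature_set`s.
#' @param transform optional rigid transform applied to `b`'s positions.
#' @param params a [shape_params()] (supplies color radius and height).
#' @return CT in [0, 1].
#' @export
color_tanimoto <- function(a, b, transform = NULL, params = shape_params()) {
  if (!has_features(a) || !has_features(b)) return(0)
  if (!is.null(transform)) b <- transform_feature_positions(b, transform)
  alpha <- gauss_alpha(params$color_radius, params$p)
  fa <- a$features; fb <- b$features
  vab <- 0
  for (tp in intersect(unique(fa$type), unique(fb$type))) {
    pa <- fa$position[fa$type == tp, , drop = FALSE]
    pb <- fb$position[fb$type == tp, , drop = FALSE]
    vab <- vab + gauss_cross_overlap(pa, rep(alpha, nrow(pa)),
                                     pb, rep(alpha, nrow(pb)), params$p)
  }
  vaa <- color_self_overlap(fa, alpha, params$p)
  vbb <- color_self_overlap(fb, alpha, params$p)
  den <- vaa + vbb - vab
  if (den <= 0) return(0)
  min(1, max(0, vab / den))
}
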