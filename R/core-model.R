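#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
#' @import dplyr
NULL

PERIODIC_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn"
)

# default valences used for implicit-hydrogen accounting (neutral atoms)
DEFAULT_VALENCE <- c(H = 1, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
                     S = 2, Cl = 1, Br = 1, I = 1, B = 3)

#' Construct a molecule record
#'
#' A molecule record holds the chemical graph (atoms, bonds), perceived atom
#' environment flags used by the eligibility descriptors and feature
#' perception, and bookkeeping identifiers. Perception (ring membership,
#' aromaticity, sp2 character, bridgeheads, covalent units) is run at
#' construction time from the bond graph, so the flags are always consistent
#' with the bonds supplied.
#'
#' @param elements character vector of element symbols, one per atom.
#' @param bonds data frame (or matrix) with columns `a1`, `a2`, `order`
#'   (1, 2, 3, or 4 for an input-flagged aromatic bond) and optionally
#'   `aromatic`.  One row per bond; indices are 1-based atom positions.
#' @param formal_charge integer vector of per-atom formal charges (recycled).
#' @param record_id non-negative integer structure identifier (CID or SID).
#' @param record_id_kind `"compound"` or `"substance"`.
#' @param undefined_stereo_count count of unassigned stereocenters (atom plus
#'   bond centers) as declared by the producing toolkit; this package does
#'   not perceive stereogenicity itself.
#' @param name optional molecule title carried through SDF round trips.
#' @return an object of class `mol_record`.
#' @examples
#' m <- molecule(c("C", "C", "O"),
#'               data.frame(a1 = c(1, 2), a2 = c(2, 3), order = 1))
#' m$covalent_unit_count
#' @export
molecule <- function(elements, bonds = NULL, formal_charge = 0L,
                     record_id = 0L, record_id_kind = c("compound", "substance"),
                     undefined_stereo_count = 0L, name = NULL) {
  record_id_kind <- match.arg(record_id_kind)
  elements <- as.character(elements)
  n <- length(elements)
  if (n == 0L) abort("molecule must contain at least one atom")
  bad <- setdiff(unique(elements), PERIODIC_SYMBOLS)
  if (length(bad)) abort(paste0("unknown element symbol(s): ", paste(bad, collapse = ", ")))
  if (is.null(bonds) || NROW(bonds) == 0L) {
    bonds <- tibble(a1 = integer(), a2 = integer(), order = integer(),
                    aromatic = logical())
  } else {
    bonds <- as_tibble(as.data.frame(bonds))
    if (!all(c("a1", "a2") %in% names(bonds)))
      abort("bonds must have columns a1 and a2")
    if (!"order" %in% names(bonds)) bonds$order <- 1L
    if (!"aromatic" %in% names(bonds)) bonds$aromatic <- bonds$order == 4L
    bonds <- tibble(a1 = as.integer(bonds$a1), a2 = as.integer(bonds$a2),
                    order = as.integer(bonds$order),
                    aromatic = as.logical(bonds$aromatic))
    idx <- c(bonds$a1, bonds$a2)
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > n))
      abort("bond atom index out of range")
    if (any(bonds$a1 == bonds$a2)) abort("self-bond not allowed")
    if (!all(bonds$order %in% 1:4)) abort("bond order must be 1, 2, 3 or 4")
  }
  formal_charge <- as.integer(rep_len(formal_charge, n))
  if (undefined_stereo_count < 0L) abort("undefined_stereo_count must be >= 0")

  per <- perceive_atom_environment(elements, bonds)
  atoms <- tibble(
    element = elements,
    is_hydrogen = elements == "H",
    formal_charge = formal_charge,
    aromatic = per$aromatic,
    in_ring_nonaromatic = per$in_ring & !per$aromatic,
    is_bridgehead = per$bridgehead,
    is_sp2 = per$sp2,
    implicit_h = implicit_h_count(elements, formal_charge, bonds)
  )
  if (any(atoms$is_hydrogen & atoms$aromatic))
    abort("inconsistent perception: aromatic hydrogen")
  bonds$aromatic <- bonds$aromatic | per$bond_aromatic
  structure(
    list(atoms = atoms, bonds = bonds, rings = per$rings,
         covalent_unit_count = per$n_components,
         undefined_stereo_count = as.integer(undefined_stereo_count),
         record_id = as.numeric(record_id), record_id_kind = record_id_kind,
         name = name %||% paste0(record_id_kind, "_", record_id)),
    class = "mol_record"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a raw parsed structure into a molecule record
#'
#' Thin wrapper used by the SDF reader and fixture builders: takes a bare
#' list with `elements`, `bonds`, and optional charge/identifier fields and
#' returns a validated [molecule()].  Signals a parse error on malformed
#' valence tables or dangling bond indices.
#'
#' @param raw list with at least `elements` and `bonds`.
#' @return a `mol_record`.
#' @export
validate_record <- function(raw) {
  if (!is.list(raw) || is.null(raw$elements))
    abort("raw structure must be a list with an 'elements' field")
  molecule(raw$elements, raw$bonds,
           formal_charge = raw$formal_charge %||% 0L,
           record_id = raw$record_id %||% 0L,
           record_id_kind = raw$record_id_kind %||% "compound",
           undefined_stereo_count = raw$undefined_stereo_count %||% 0L,
           name = raw$name)
}

#' @export
print.mol_record <- function(x, ...) {
  cat(sprintf("<mol_record> %s: %d atoms (%d heavy), %d bonds, %d covalent unit(s)\n",
              x$name, nrow(x$atoms), sum(!x$atoms$is_hydrogen),
              nrow(x$bonds), x$covalent_unit_count))
  invisible(x)
}

bond_graph <- function(elements, bonds) {
  igraph::graph_from_data_frame(
    data.frame(from = bonds$a1, to = bonds$a2),
    directed = FALSE,
    vertices = data.frame(name = seq_along(elements))
  )
}

# Ring perception: smallest cycle through every ring (non-bridge) bond,
# reduced to a GF(2)-independent basis. Adequate for small molecules.
find_rings <- function(g, n_atoms, bonds) {
  if (nrow(bonds) == 0L) return(list())
  br <- igraph::bridges(g)
  ring_edge <- rep(TRUE, nrow(bonds))
  if (length(br)) ring_edge[as.integer(br)] <- FALSE
  cycles <- list()
  for (e in which(ring_edge)) {
    u <- bonds$a1[e]; v <- bonds$a2[e]
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = u, to = v)$vpath[[1]])
    if (length(sp) == 0L) next
    cycles[[length(cycles) + 1L]] <- as.integer(sp)
  }
  if (!length(cycles)) return(list())
  # order by size, keep a GF(2)-independent set over edge incidence vectors
  cycles <- cycles[order(lengths(cycles))]
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  all_keys <- ekey(bonds$a1, bonds$a2)
  basis <- matrix(0L, nrow = 0L, ncol = nrow(bonds))
  kept <- list()
  for (cy in cycles) {
    nxt <- c(cy[-1], cy[1])
    vec <- as.integer(all_keys %in% ekey(cy, nxt))
    red <- vec
    if (nrow(basis)) {
      for (r in seq_len(nrow(basis))) {
        piv <- which(basis[r, ] == 1L)[1]
        if (red[piv] == 1L) red <- (red + basis[r, ]) %% 2L
      }
    }
    if (any(red == 1L)) {
      basis <- rbind(basis, red)
      kept[[length(kept) + 1L]] <- cy
    }
  }
  kept
}

# Perceive ring membership, aromaticity, sp2 character and bridgeheads from
# the bond graph. Aromaticity: input-flagged (order 4) bonds, plus rings of
# even size whose atoms are all C/N/O/S and whose bond orders alternate 1/2
# around the cycle (Kekule alternation).
perceive_atom_environment <- function(elements, bonds) {
  n <- length(elements)
  g <- bond_graph(elements, bonds)
  comp <- igraph::components(g)
  rings <- find_rings(g, n, bonds)

  in_ring <- rep(FALSE, n)
  ring_bond_count <- rep(0L, n)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  bond_key <- if (nrow(bonds)) ekey(bonds$a1, bonds$a2) else character()
  bond_aromatic <- if (nrow(bonds)) bonds$order == 4L else logical()
  atom_aromatic <- rep(FALSE, n)

  ring_edges_seen <- character()
  for (cy in rings) {
    in_ring[cy] <- TRUE
    nxt <- c(cy[-1], cy[1])
    keys <- ekey(cy, nxt)
    ring_edges_seen <- c(ring_edges_seen, keys)
    ord <- bonds$order[match(keys, bond_key)]
    all_ok <- all(elements[cy] %in% c("C", "N", "O", "S"))
    flagged <- all(ord == 4L)
    alternating <- length(cy) %% 2L == 0L &&
      all(ord %in% c(1L, 2L)) &&
      all(abs(diff(c(ord, ord[1]))) == 1L)
    if (all_ok && (flagged || alternating)) {
      atom_aromatic[cy] <- TRUE
      bond_aromatic[match(keys, bond_key)] <- TRUE
    }
  }
  for (k in unique(ring_edges_seen)) {
    i <- match(k, bond_key)
    ring_bond_count[bonds$a1[i]] <- ring_bond_count[bonds$a1[i]] + 1L
    ring_bond_count[bonds$a2[i]] <- ring_bond_count[bonds$a2[i]] + 1L
  }
  # atoms on ring bonds not covered by a basis cycle (rare) still count as in-ring
  if (nrow(bonds)) {
    br <- igraph::bridges(g)
    nb <- setdiff(seq_len(nrow(bonds)), as.integer(br))
    in_ring[c(bonds$a1[nb], bonds$a2[nb])] <- TRUE
  }

  sp2 <- rep(FALSE, n)
  if (nrow(bonds)) {
    dbl <- bonds$order == 2L | bond_aromatic
    sp2[c(bonds$a1[dbl], bonds$a2[dbl])] <- TRUE
  }
  sp2 <- sp2 | atom_aromatic

  list(n_components = comp$no, rings = rings, in_ring = in_ring,
       aromatic = atom_aromatic, bond_aromatic = bond_aromatic,
       sp2 = sp2, bridgehead = ring_bond_count >= 3L)
}

# Implicit hydrogen count from default valences; negative charge removes an H
# site (e.g. carboxylate O-), positive charge on N adds one.
implicit_h_count <- function(elements, formal_charge, bonds) {
  n <- length(elements)
  deg <- rep(0, n)
  if (nrow(bonds)) {
    ord <- ifelse(bonds$order == 4L, 1.5, bonds$order)
    for (i in seq_len(nrow(bonds))) {
      deg[bonds$a1[i]] <- deg[bonds$a1[i]] + ord[i]
      deg[bonds$a2[i]] <- deg[bonds$a2[i]] + ord[i]
    }
  }
  val <- DEFAULT_VALENCE[elements]
  val[is.na(val)] <- 0
  adj <- ifelse(elements %in% c("N", "P"), formal_charge,
                ifelse(elements %in% c("O", "S"), pmin(formal_charge, 0), 0))
  out <- pmax(0, round(val + adj - deg))
  as.integer(ifelse(elements == "H", 0L, out))
}

#' Construct a conformer
#'
#' One 3-D realization of a molecule's atoms. Coordinates include hydrogens
#' when the molecule has them; all RMSD/shape computations use the heavy-atom
#' subset selected by `heavy_idx`.
#'
#' @param coords numeric N x 3 matrix of coordinates in Angstrom.
#' @param molecule optional parent [molecule()]; when given, `heavy_idx`
#'   defaults to its non-hydrogen atoms and N must match its atom count.
#' @param heavy_idx indices of non-hydrogen atoms within `coords`.
#' @param energy force-field strain energy in kcal/mol (coulombic terms
#'   removed), `NA` when unknown.
#' @param local_id non-negative integer conformer identifier within the
#'   parent ensemble (LID).
#' @return an object of class `conformer`.
#' @export
conformer <- function(coords, molecule = NULL, heavy_idx = NULL,
                      energy = NA_real_, local_id = 0L) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) abort("coords must be an N x 3 matrix")
  storage.mode(coords) <- "double"
  if (!all(is.finite(coords))) abort("coordinates must be finite")
  if (!is.null(molecule)) {
    if (nrow(coords) != nrow(molecule$atoms))
      abort("coords row count does not match molecule atom count")
    if (is.null(heavy_idx)) heavy_idx <- which(!molecule$atoms$is_hydrogen)
  }
  if (is.null(heavy_idx)) heavy_idx <- seq_len(nrow(coords))
  heavy_idx <- as.integer(heavy_idx)
  if (length(heavy_idx) && (min(heavy_idx) < 1L || max(heavy_idx) > nrow(coords)))
    abort("heavy_idx out of range")
  structure(
    list(coords = coords, heavy_idx = heavy_idx,
         energy = as.numeric(energy), local_id = as.integer(local_id),
         tags = list()),
    class = "conformer"
  )
}

heavy_coords <- function(conf) conf$coords[conf$heavy_idx, , drop = FALSE]

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer> LID %d: %d atoms (%d heavy), energy %s\n",
              x$local_id, nrow(x$coords), length(x$heavy_idx),
              ifelse(is.na(x$energy), "NA", sprintf("%.3f", x$energy))))
  invisible(x)
}

#' Construct a conformer model
#'
#' A bounded, RMSD-sampled set of conformers for one molecule, together with
#' the sampling RMSD that guarantees the minimum pairwise dissimilarity of
#' the retained conformers and a conformer ordering (energy order until
#' [diverse_order()] is applied).
#'
#' @param molecule a [molecule()].
#' @param conformers list of [conformer()] objects.
#' @param sampling_rmsd sampling RMSD in Angstrom; must be at least 0.4 and a
#'   multiple of 0.2.
#' @param diverse_order permutation of `seq_along(conformers)`; defaults to
#'   ascending energy (ties by local id).
#' @return an object of class `conformer_model`.
#' @export
conformer_model <- function(molecule, conformers, sampling_rmsd,
                            diverse_order = NULL) {
  if (!inherits(molecule, "mol_record")) abort("molecule must be a mol_record")
  if (!length(conformers)) abort("conformer model needs at least one conformer")
  k <- length(conformers)
  if (k > 500L) warn("conformer model holds more than 500 conformers")
  if (sampling_rmsd < 0.4 - 1e-9 ||
      abs(sampling_rmsd / 0.2 - round(sampling_rmsd / 0.2)) > 1e-9)
    abort("sampling_rmsd must be >= 0.4 and a multiple of 0.2")
  if (is.null(diverse_order)) diverse_order <- energy_order(conformers)
  diverse_order <- as.integer(diverse_order)
  if (!identical(sort(diverse_order), seq_len(k)))
    abort("diverse_order must be a permutation of the conformer indices")
  structure(
    list(molecule = molecule, conformers = conformers,
         sampling_rmsd = sampling_rmsd, diverse_order = diverse_order),
    class = "conformer_model"
  )
}

energy_order <- function(conformers) {
  e <- vapply(conformers, function(cf) cf$energy, numeric(1))
  lid <- vapply(conformers, function(cf) cf$local_id, integer(1))
  e[is.na(e)] <- Inf
  order(e, lid)
}

#' @export
print.conformer_model <- function(x, ...) {
  cat(sprintf("<conformer_model> %s: %d conformer(s), sampling RMSD %.1f A\n",
              x$molecule$name, length(x$conformers), x$sampling_rmsd))
  invisible(x)
}
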