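#' Eligibility configuration
#'
#' Thresholds for the six coverage rules deciding whether a molecule
#' receives a conformer model. Defaults are the production values: at most
#' 50 non-hydrogen atoms, at most 15 rotatable bonds, supported elements
#' H/C/N/O/F/Si/P/S/Cl/Br/I, a single covalent unit, force-field-typeable
#' atoms, and fewer than six undefined stereocenters.
#'
#' @param max_nha maximum non-hydrogen atom count.
#' @param max_rb maximum rotatable-bond count.
#' @param max_undefined_stereo maximum allowed undefined stereocenters
#'   (rule reads "fewer than six", hence 5).
#' @param element_whitelist allowed element symbols.
#' @param exclude_amide_rb should amide C-N bonds be excluded from the
#'   rotatable-bond count (the common convention, switchable).
#' @return a list of class `eligibility_config`.
#' @export
eligibility_config <- function(max_nha = 50L, max_rb = 15L,
                               max_undefined_stereo = 5L,
                               element_whitelist = c("H", "C", "N", "O", "F",
                                                     "Si", "P", "S", "Cl",
                                                     "Br", "I"),
                               exclude_amide_rb = TRUE) {
  structure(list(max_nha = as.integer(max_nha), max_rb = as.integer(max_rb),
                 max_undefined_stereo = as.integer(max_undefined_stereo),
                 element_whitelist = element_whitelist,
                 exclude_amide_rb = isTRUE(exclude_amide_rb)),
            class = "eligibility_config")
}

# atoms recognized by our force-field typing approximation: supported element
# with a chemically plausible connection count
MAX_CONNECTIONS <- c(H = 1, C = 4, N = 4, O = 3, F = 1, Si = 6, P = 6,
                     S = 6, Cl = 1, Br = 1, I = 1)

#' Count the size/flexibility descriptors of a molecule
#'
#' Computes the three descriptors feeding the effective-rotor model:
#' `nha`, the non-hydrogen atom count; `rb`, the rotatable-bond count
#' (single, non-ring, non-terminal bonds between heavy atoms, excluding
#' amide C-N bonds under the default convention); and `nara`, the count of
#' atoms in non-aromatic rings excluding bridgehead and sp2-hybridized
#' atoms.
#'
#' @param mol a [molecule()].
#' @param config an [eligibility_config()].
#' @return named list with integer `nha`, `rb`, `nara`.
#' @examples
#' bu <- toy_butane()
#' count_descriptors(bu$molecule)   # nha 4, rb 1, nara 0
#' @export
count_descriptors <- function(mol, config = eligibility_config()) {
  stopifnot(inherits(mol, "mol_record"))
  atoms <- mol$atoms
  bonds <- mol$bonds
  nha <- sum(!atoms$is_hydrogen)

  rb <- 0L
  if (nrow(bonds)) {
    heavy <- !atoms$is_hydrogen
    # heavy-atom degree (heavy neighbors only)
    hdeg <- rep(0L, nrow(atoms))
    hb <- bonds[heavy[bonds$a1] & heavy[bonds$a2], , drop = FALSE]
    for (i in seq_len(nrow(hb))) {
      hdeg[hb$a1[i]] <- hdeg[hb$a1[i]] + 1L
      hdeg[hb$a2[i]] <- hdeg[hb$a2[i]] + 1L
    }
    ring_bond <- bond_in_ring(mol)
    for (i in seq_len(nrow(bonds))) {
      a <- bonds$a1[i]; b <- bonds$a2[i]
      if (!(heavy[a] && heavy[b])) next
      if (bonds$order[i] != 1L || bonds$aromatic[i]) next
      if (ring_bond[i]) next
      if (hdeg[a] < 2L || hdeg[b] < 2L) next           # terminal
      if (config$exclude_amide_rb && is_amide_cn(mol, a, b)) next
      rb <- rb + 1L
    }
  }

  nara <- sum(atoms$in_ring_nonaromatic & !atoms$is_bridgehead &
                !atoms$is_sp2 & !atoms$is_hydrogen)
  list(nha = as.integer(nha), rb = as.integer(rb), nara = as.integer(nara))
}

bond_in_ring <- function(mol) {
  bonds <- mol$bonds
  if (!nrow(bonds)) return(logical())
  g <- bond_graph(mol$atoms$element, bonds)
  out <- rep(TRUE, nrow(bonds))
  br <- igraph::bridges(g)
  if (length(br)) out[as.integer(br)] <- FALSE
  out
}

# amide C-N: C double-bonded to O on one end, N on the other
is_amide_cn <- function(mol, a, b) {
  el <- mol$atoms$element
  cn <- NULL
  if (el[a] == "C" && el[b] == "N") cn <- c(a, b)
  if (el[a] == "N" && el[b] == "C") cn <- c(b, a)
  if (is.null(cn)) return(FALSE)
  bonds <- mol$bonds
  nb <- bonds[bonds$a1 == cn[1] | bonds$a2 == cn[1], , drop = FALSE]
  any(nb$order == 2L & el[ifelse(nb$a1 == cn[1], nb$a2, nb$a1)] == "O")
}

#' Effective rotor count
#'
#' The flexibility proxy `er = rb + nara / 5`: rotatable bonds plus one
#' fifth of the eligible non-aromatic ring atoms.
#'
#' @param rb rotatable-bond count (non-negative integer).
#' @param nara non-aromatic ring atom count (non-negative integer).
#' @return `rb + nara / 5`, unrounded.
#' @examples
#' effective_rotor_count(2, 5)  # 3
#' @export
effective_rotor_count <- function(rb, nara) {
  if (any(rb < 0) || any(nara < 0)) abort("rb and nara must be non-negative")
  rb + nara / 5
}

#' Decide whether a molecule receives a conformer model
#'
#' Evaluates the six coverage rules: size (`nha`), flexibility (`rb`),
#' supported elements, single covalent unit, force-field-typeable atoms, and
#' undefined stereocenters. All violated rules are reported, not only the
#' first.
#'
#' @param mol a [molecule()] or a list of them.
#' @param config an [eligibility_config()].
#' @return a tibble with one row per molecule: `record_id`, `eligible`,
#'   `failed_rules` (list column of rule names), `nha`, `rb`, `nara`, `er`.
#' @examples
#' check_eligibility(toy_methane()$molecule)
#' @export
check_eligibility <- function(mol, config = eligibility_config()) {
  if (inherits(mol, "mol_record")) mol <- list(mol)
  rows <- lapply(mol, check_eligibility_one, config = config)
  dplyr::bind_rows(rows)
}

check_eligibility_one <- function(mol, config) {
  d <- count_descriptors(mol, config)
  failed <- character()
  if (d$nha > config$max_nha) failed <- c(failed, "too_large")
  if (d$rb > config$max_rb) failed <- c(failed, "too_flexible")
  if (!all(mol$atoms$element %in% config$element_whitelist))
    failed <- c(failed, "unsupported_element")
  if (mol$covalent_unit_count > 1L) failed <- c(failed, "multi_component")
  if (!all(atoms_typeable(mol))) failed <- c(failed, "unsupported_atom_type")
  if (mol$undefined_stereo_count > config$max_undefined_stereo)
    failed <- c(failed, "excess_undefined_stereo")
  tibble(
    record_id = mol$record_id,
    eligible = length(failed) == 0L,
    failed_rules = list(failed),
    nha = d$nha, rb = d$rb, nara = d$nara,
    er = effective_rotor_count(d$rb, d$nara)
  )
}

# force-field typing approximation: supported element whose explicit
# connection count does not exceed its maximum coordination
atoms_typeable <- function(mol) {
  el <- mol$atoms$element
  deg <- rep(0L, length(el))
  b <- mol$bonds
  for (i in seq_len(nrow(b))) {
    deg[b$a1[i]] <- deg[b$a1[i]] + 1L
    deg[b$a2[i]] <- deg[b$a2[i]] + 1L
  }
  maxc <- MAX_CONNECTIONS[el]
  is.na(maxc) | deg <= maxc
}
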