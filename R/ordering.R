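#' Pairwise ComboT matrix of a conformer model
#'
#' Symmetric matrix of shape-optimized ComboT scores (ST-optimized overlay,
#' single-point CT) between all conformer pairs of a model.
#'
#' @param model a [conformer_model()].
#' @param params a [shape_params()].
#' @return K x K symmetric numeric matrix with diagonal 2 (ST = CT = 1 for
#'   a featured conformer against itself; 1 when featureless).
#' @export
pairwise_combo_matrix <- function(model, params = shape_params()) {
  k <- length(model$conformers)
  mol <- model$molecule
  fsets <- lapply(model$conformers, function(cf) perceive_features(mol, cf))
  m <- matrix(0, k, k)
  for (i in seq_len(k)) {
    fi <- if (has_features(fsets[[i]])) 1 else 0
    m[i, i] <- 1 + fi
    if (i == k) next
    for (j in (i + 1):k) {
      r <- optimize_overlap(model$conformers[[i]], model$conformers[[j]],
                            mode = "shape", params = params,
                            mol_a = mol, mol_b = mol,
                            features_a = fsets[[i]], features_b = fsets[[j]])
      m[i, j] <- m[j, i] <- r$combo
    }
  }
  m
}

#' Diverse conformer ordering
#'
#' Greedy maximal-dissimilarity ordering of a conformer ensemble. The
#' lowest-energy conformer is the initial default conformer; each
#' subsequent pick is the unassigned conformer with the smallest sum of
#' ComboT to all already-assigned conformers; ties are broken by the
#' largest ComboT sum to the remaining unassigned conformers, then by the
#' smallest local id.
#'
#' @param model a [conformer_model()].
#' @param params a [shape_params()].
#' @param combo_matrix optional precomputed symmetric ComboT matrix
#'   (`pairwise_combo_matrix()`); useful for testing and reuse.
#' @return a list of class `diverse_ordering`: `order` (permutation of
#'   conformer indices) and `combo_matrix`.
#' @export
diverse_order <- function(model, params = shape_params(),
                          combo_matrix = NULL) {
  k <- length(model$conformers)
  if (is.null(combo_matrix)) combo_matrix <- pairwise_combo_matrix(model, params)
  stopifnot(nrow(combo_matrix) == k, ncol(combo_matrix) == k)
  lid <- vapply(model$conformers, function(cf) cf$local_id, integer(1))
  first <- energy_order(model$conformers)[1]
  assigned <- first
  unassigned <- setdiff(seq_len(k), first)
  while (length(unassigned)) {
    s_assigned <- vapply(unassigned, function(i)
      sum(combo_matrix[i, assigned]), numeric(1))
    best <- min(s_assigned)
    tie <- unassigned[s_assigned <= best + 1e-12]
    if (length(tie) > 1L) {
      s_un <- vapply(tie, function(i)
        sum(combo_matrix[i, setdiff(unassigned, i)]), numeric(1))
      mx <- max(s_un)
      tie <- tie[s_un >= mx - 1e-12]
      if (length(tie) > 1L) tie <- tie[order(lid[tie])]
    }
    pick <- tie[1]
    assigned <- c(assigned, pick)
    unassigned <- setdiff(unassigned, pick)
  }
  structure(list(order = as.integer(assigned), combo_matrix = combo_matrix),
            class = "diverse_ordering")
}

#' Apply a diverse ordering to a conformer model
#'
#' Stores the ordering in the model's `diverse_order` field (used by
#' neighboring and download subsets, which take the first N diverse
#' conformers).
#'
#' @param model a [conformer_model()].
#' @param ordering a `diverse_ordering` (computed when omitted).
#' @param params a [shape_params()].
#' @return the model with its `diverse_order` replaced.
#' @export
apply_diverse_order <- function(model, ordering = NULL,
                                params = shape_params()) {
  if (is.null(ordering)) ordering <- diverse_order(model, params)
  model$diverse_order <- ordering$order
  model
}
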