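#' Neighboring thresholds
#'
#' Score thresholds of the "similar conformers" relationship: a featured
#' pair neighbors when `ST > 0.795` and `CT > 0.495`; a featureless pair
#' when `ST > 0.925`. Inequalities are strict; mixed featured/featureless
#' pairs never neighbor. Three diverse conformers per compound are
#' considered by default (at most ten).
#'
#' @param st_featured,ct_featured thresholds for pairs where both
#'   conformers have pharmacophore features.
#' @param st_featureless ST threshold for pairs where neither has features.
#' @param conformers_per_compound diverse conformers searched per compound.
#' @return a list of class `neighbor_thresholds`.
#' @export
neighbor_thresholds <- function(st_featured = 0.795, ct_featured = 0.495,
                                st_featureless = 0.925,
                                conformers_per_compound = 3L) {
  vals <- c(st_featured, ct_featured, st_featureless)
  if (any(vals <= 0 | vals >= 1)) abort("thresholds must lie in (0, 1)")
  if (conformers_per_compound < 1L || conformers_per_compound > 10L)
    abort("conformers_per_compound must be in 1..10")
  structure(list(st_featured = st_featured, ct_featured = ct_featured,
                 st_featureless = st_featureless,
                 conformers_per_compound = as.integer(conformers_per_compound)),
            class = "neighbor_thresholds")
}

#' Neighbor predicate
#'
#' Decides whether a scored conformer pair qualifies as "similar
#' conformers". Threshold equality does NOT qualify (strict inequalities).
#'
#' @param st,ct scores from a shape-optimized overlay.
#' @param a_has_features,b_has_features do the conformers have any
#'   pharmacophore features?
#' @param t a [neighbor_thresholds()].
#' @return logical.
#' @examples
#' is_neighbor(0.796, 0.496, TRUE, TRUE)    # TRUE
#' is_neighbor(0.80, 0.23, TRUE, TRUE)      # FALSE (CT too low)
#' is_neighbor(0.93, 0, FALSE, FALSE)       # TRUE
#' @export
is_neighbor <- function(st, ct, a_has_features, b_has_features,
                        t = neighbor_thresholds()) {
  both_feat <- a_has_features & b_has_features
  both_bare <- !a_has_features & !b_has_features
  (both_feat & st > t$st_featured & ct > t$ct_featured) |
    (both_bare & st > t$st_featureless)
}

model_search_confs <- function(model, n) {
  idx <- model$diverse_order[seq_len(min(n, length(model$conformers)))]
  model$conformers[idx]
}

#' Search a corpus for similar conformers
#'
#' Scores the first `t$conformers_per_compound` diverse conformers of the
#' query model against the same subset of every corpus model
#' (shape-optimized overlay, single-point CT) and returns every conformer
#' pair passing [is_neighbor()]. The corpus may be split into any number of
#' evenly-sized shards processed independently; the result set is
#' identical for every shard count. When fingerprints are supplied, pairs
#' without common bits are skipped without optimization.
#'
#' @param query a [conformer_model()].
#' @param corpus list of [conformer_model()]s.
#' @param t a [neighbor_thresholds()].
#' @param shards shard count for the divide-and-conquer contract.
#' @param params a [shape_params()].
#' @param refs optional [build_reference_set()]; enables the fingerprint
#'   prefilter.
#' @return tibble of neighbor records: `gid_a`, `gid_b`, `st`, `ct`, the
#'   nine rotation elements `r11..r33` and translation `t1..t3` mapping
#'   conformer b onto conformer a. Each unordered pair appears once with
#'   `gid_a < gid_b`.
#' @export
neighbor_search <- function(query, corpus, t = neighbor_thresholds(),
                            shards = 1L, params = shape_params(),
                            refs = NULL) {
  stopifnot(shards >= 1L)
  qconfs <- model_search_confs(query, t$conformers_per_compound)
  qmol <- query$molecule
  qfeats <- lapply(qconfs, function(cf) perceive_features(qmol, cf))
  qfps <- if (!is.null(refs))
    lapply(qconfs, fingerprint_conformer, refs = refs, params = params)
  shard_of <- rep(seq_len(shards), length.out = length(corpus))
  rows <- list()
  for (s in seq_len(shards)) {
    for (ci in which(shard_of == s)) {
      model <- corpus[[ci]]
      confs <- model_search_confs(model, t$conformers_per_compound)
      feats <- lapply(confs, function(cf)
        perceive_features(model$molecule, cf))
      fps <- if (!is.null(refs))
        lapply(confs, fingerprint_conformer, refs = refs, params = params)
      for (qi in seq_along(qconfs)) {
        for (ki in seq_along(confs)) {
          ga <- conformer_gid(qmol, qconfs[[qi]])
          gb <- conformer_gid(model$molecule, confs[[ki]])
          if (!is.null(refs) &&
              !length(intersect(qfps[[qi]]$bits$ref_gid,
                                fps[[ki]]$bits$ref_gid))) next
          r <- optimize_overlap(qconfs[[qi]], confs[[ki]], mode = "shape",
                                params = params, mol_a = qmol,
                                mol_b = model$molecule,
                                features_a = qfeats[[qi]],
                                features_b = feats[[ki]])
          if (!is_neighbor(r$st, r$ct, has_features(qfeats[[qi]]),
                           has_features(feats[[ki]]), t)) next
          rec <- neighbor_record_row(ga, gb, r)
          rows[[length(rows) + 1L]] <- rec
        }
      }
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else empty_neighbor_tbl()
  dplyr::distinct(out, .data$gid_a, .data$gid_b, .keep_all = TRUE) |>
    dplyr::arrange(.data$gid_a, .data$gid_b)
}

neighbor_record_row <- function(ga, gb, r) {
  rot <- r$rotation; tr <- r$translation
  if (ga > gb) {
    # emit unordered pair once with gid_a < gid_b; invert the pose
    rot <- t(r$rotation)
    tr <- as.numeric(-rot %*% r$translation)
    tmp <- ga; ga <- gb; gb <- tmp
  }
  tibble(gid_a = ga, gid_b = gb, st = r$st, ct = r$ct,
         r11 = rot[1, 1], r12 = rot[1, 2], r13 = rot[1, 3],
         r21 = rot[2, 1], r22 = rot[2, 2], r23 = rot[2, 3],
         r31 = rot[3, 1], r32 = rot[3, 2], r33 = rot[3, 3],
         t1 = tr[1], t2 = tr[2], t3 = tr[3])
}

empty_neighbor_tbl <- function() {
  tibble(gid_a = character(), gid_b = character(), st = numeric(),
         ct = numeric(), r11 = numeric(), r12 = numeric(), r13 = numeric(),
         r21 = numeric(), r22 = numeric(), r23 = numeric(),
         r31 = numeric(), r32 = numeric(), r33 = numeric(),
         t1 = numeric(), t2 = numeric(), t3 = numeric())
}

#' Pairwise 3-D similarity matrix of a compound panel
#'
#' Scores every compound pair using up to `per_compound` diverse conformers
#' per compound with the selected superposition optimization. The default
#' `best_pair` metric keeps, per compound pair, the single conformer pair
#' with the largest ComboT; `all_pairs` returns the full conformer-pair
#' score table instead.
#'
#' @param compounds list of [conformer_model()]s (>= 2).
#' @param mode `"shape"` or `"feature"` superposition optimization.
#' @param per_compound conformers per compound, at most 10.
#' @param metric `"best_pair"` or `"all_pairs"`.
#' @param params a [shape_params()].
#' @param max_pairs conformer-pair budget (request cap).
#' @return for `best_pair`, an object of class `score_matrix` holding
#'   symmetric `st`, `ct` and `combo` matrices (Tanimoto diagonals 1, combo
#'   diagonal 2); for `all_pairs`, a tibble of per-conformer-pair scores.
#' @export
score_matrix <- function(compounds, mode = c("shape", "feature"),
                         per_compound = 10L,
                         metric = c("best_pair", "all_pairs"),
                         params = shape_params(), max_pairs = 1e6) {
  mode <- match.arg(mode); metric <- match.arg(metric)
  n <- length(compounds)
  if (n < 2L) abort("need at least two compounds")
  if (per_compound < 1L || per_compound > 10L)
    abort("per_compound must be in 1..10")
  confs <- lapply(compounds, model_search_confs, n = per_compound)
  kc <- lengths(confs)
  total_pairs <- sum(tcrossprod(kc)[upper.tri(diag(n))])
  if (total_pairs > max_pairs)
    abort(sprintf("request of %d conformer pairs exceeds the %d pair budget",
                  total_pairs, max_pairs))
  feats <- lapply(seq_len(n), function(i)
    lapply(confs[[i]], function(cf)
      perceive_features(compounds[[i]]$molecule, cf)))
  st <- ct <- combo <- diag(1, n)
  rows <- list()
  for (i in seq_len(n)) {
    combo[i, i] <- 1 + as.numeric(has_features(feats[[i]][[1]]))
    if (i == n) break
    for (j in (i + 1):n) {
      best <- NULL
      for (a in seq_along(confs[[i]])) for (b in seq_along(confs[[j]])) {
        r <- optimize_overlap(confs[[i]][[a]], confs[[j]][[b]], mode = mode,
                              params = params,
                              mol_a = compounds[[i]]$molecule,
                              mol_b = compounds[[j]]$molecule,
                              features_a = feats[[i]][[a]],
                              features_b = feats[[j]][[b]])
        if (metric == "all_pairs")
          rows[[length(rows) + 1L]] <- tibble(
            i = i, j = j,
            lid_a = confs[[i]][[a]]$local_id, lid_b = confs[[j]][[b]]$local_id,
            st = r$st, ct = r$ct, combo = r$combo)
        if (is.null(best) || r$combo > best$combo) best <- r
      }
      st[i, j] <- st[j, i] <- best$st
      ct[i, j] <- ct[j, i] <- best$ct
      combo[i, j] <- combo[j, i] <- best$combo
    }
  }
  if (metric == "all_pairs") return(dplyr::bind_rows(rows))
  structure(list(st = st, ct = ct, combo = combo, mode = mode,
                 per_compound = as.integer(per_compound)),
            class = "score_matrix")
}

#' Single-linkage clustering of a similarity matrix
#'
#' Connected components of the graph joining every pair with similarity
#' strictly above the threshold (single linkage).
#'
#' @param matrix symmetric similarity matrix.
#' @param threshold similarity threshold.
#' @param max_compounds request cap (the service clusters up to 4,000
#'   compounds at a time).
#' @return integer cluster assignment, one label per row.
#' @export
single_linkage_cluster <- function(matrix, threshold, max_compounds = 4000L) {
  if (inherits(matrix, "score_matrix")) matrix <- matrix$combo
  matrix <- as.matrix(matrix)
  n <- nrow(matrix)
  if (n > max_compounds)
    abort(sprintf("%d compounds exceed the %d-compound cap", n, max_compounds))
  if (!isTRUE(all.equal(matrix, t(matrix), tolerance = 1e-8)))
    abort("similarity matrix must be symmetric")
  adj <- matrix > threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::components(g)$membership)
}

#' Monte-Carlo statistics of random 3-D similarity
#'
#' Draws random conformer pairs from a corpus generator, runs the
#' shape-optimized overlay on each, and reports mean and standard deviation
#' of ST, CT and ComboT together with the mu + 2 sigma exceedance
#' thresholds and the fraction of pairs at or above them.
#'
#' @param corpus_generator function(i) returning a list with `conformer`
#'   and optionally `molecule` for draw i; or a list of such records.
#' @param n_pairs number of random pairs (>= 2).
#' @param seed RNG seed for reproducibility.
#' @param params a [shape_params()].
#' @return a tibble of class `random_similarity_stats` with one row per
#'   score (`st`, `ct`, `combo`): `mean`, `sd`, `threshold`
#'   (mean + 2 sd), `p_exceed`.
#' @export
random_similarity_study <- function(corpus_generator, n_pairs, seed = 1L,
                                    params = shape_params()) {
  if (n_pairs < 2) abort("n_pairs must be >= 2")
  draw <- if (is.function(corpus_generator)) corpus_generator
  else {
    pool <- corpus_generator
    function(i) pool[[sample.int(length(pool), 1L)]]
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  st <- ct <- numeric(n_pairs)
  for (k in seq_len(n_pairs)) {
    a <- draw(2 * k - 1); b <- draw(2 * k)
    r <- optimize_overlap(a$conformer, b$conformer, mode = "shape",
                          params = params,
                          mol_a = a$molecule, mol_b = b$molecule)
    st[k] <- r$st; ct[k] <- r$ct
  }
  combo <- st + ct
  stat_row <- function(name, x) {
    thr <- mean(x) + 2 * stats::sd(x)
    tibble(score = name, mean = mean(x), sd = stats::sd(x),
           threshold = thr, p_exceed = mean(x >= thr))
  }
  out <- dplyr::bind_rows(stat_row("st", st), stat_row("ct", ct),
                          stat_row("combo", combo))
  class(out) <- c("random_similarity_stats", class(out))
  attr(out, "n_pairs") <- n_pairs
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
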