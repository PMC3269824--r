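# --- 64-bit packed rigid-transform codec ------------------------------------
# Layout (MSB first): 2-bit index of the dropped (largest) quaternion
# component; 3 x 14-bit remaining components scaled by sqrt(2) into [-1, 1];
# 2 spare bits; 3 x 6-bit translation components on a 0.25 A grid over
# [-8, 7.75].

bits_to_hex <- function(bits) {
  stopifnot(length(bits) == 64L)
  nib <- vapply(seq(1, 64, by = 4), function(i)
    sum(bits[i:(i + 3)] * c(8, 4, 2, 1)), numeric(1))
  paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
          "A", "B", "C", "D", "E", "F")[nib + 1], collapse = "")
}

hex_to_bits <- function(hex) {
  hex <- toupper(sub("^0X", "", toupper(hex)))
  stopifnot(grepl("^[0-9A-F]{16}$", hex))
  nib <- strtoi(strsplit(hex, "")[[1]], 16L)
  as.integer(unlist(lapply(nib, function(v)
    c(v %/% 8, v %/% 4 %% 2, v %/% 2 %% 2, v %% 2))))
}

int_to_bits <- function(x, width) {
  out <- integer(width)
  for (i in width:1) { out[i] <- x %% 2; x <- x %/% 2 }
  out
}

bits_to_int <- function(bits) sum(bits * 2^(rev(seq_along(bits)) - 1))

#' Pack a rigid transform into a 64-bit code
#'
#' Quantizes the rotation as a smallest-three quaternion (3 x 14 bits) and
#' the translation on a 0.25 Angstrom grid spanning +/- 8 A (3 x 6 bits),
#' and returns the 64-bit code as a 16-digit hex string. Lossy but
#' accurate enough for alignment replay.
#'
#' @param transform list with `rotation` and `translation`.
#' @return 16-character hex string.
#' @export
pack_transform <- function(transform) {
  q <- rotation_to_quaternion(transform$rotation)
  if (q[1] < 0) q <- -q                      # canonical hemisphere
  drop <- which.max(abs(q))
  if (q[drop] < 0) q <- -q
  rest <- q[-drop] * sqrt(2)
  rest <- pmin(1, pmax(-1, rest))
  qbits <- unlist(lapply(rest, function(x)
    int_to_bits(round((x + 1) / 2 * 16383), 14L)))
  t <- pmin(7.75, pmax(-8, transform$translation))
  tbits <- unlist(lapply(t, function(x)
    int_to_bits(round((x + 8) / 0.25), 6L)))
  bits <- c(int_to_bits(drop - 1L, 2L), qbits, integer(2), tbits)
  bits_to_hex(bits)
}

#' Unpack a 64-bit transform code
#' @param hex 16-character hex string from [pack_transform()].
#' @return list with `rotation` and `translation`.
#' @export
unpack_transform <- function(hex) {
  bits <- hex_to_bits(hex)
  drop <- bits_to_int(bits[1:2]) + 1L
  rest <- vapply(0:2, function(k)
    bits_to_int(bits[(3 + 14 * k):(16 + 14 * k)]) / 16383 * 2 - 1,
    numeric(1)) / sqrt(2)
  t <- vapply(0:2, function(k)
    bits_to_int(bits[(47 + 6 * k):(52 + 6 * k)]) * 0.25 - 8, numeric(1))
  q <- numeric(4)
  q[-drop] <- rest
  q[drop] <- sqrt(max(0, 1 - sum(rest^2)))
  list(rotation = quaternion_to_rotation(q), translation = t)
}

# --- reference shape set ----------------------------------------------------

# Cauchy-Schwarz bound on ST from self-overlap volumes; used to skip pose
# optimizations that cannot reach the threshold.
st_upper_bound <- function(saa, sbb) {
  s <- sqrt(saa * sbb)
  s / (saa + sbb - s)
}

#' Build a reference shape set by greedy leader clustering
#'
#' Scans the conformers in order and admits one as a new reference iff its
#' ST-optimized similarity to every existing reference is at most
#' `st_threshold`, so the set spans the input's shape diversity: no two
#' references exceed the construction threshold to each other. References
#' are stored canonicalized, binned by analytic volume.
#'
#' @param conformers list of [conformer()]s.
#' @param st_threshold construction ST threshold.
#' @param params a [shape_params()].
#' @param ids optional tibble with `structure_id` and `local_id` per input
#'   conformer (defaults to sequence / local ids).
#' @param volume_bin width of the analytic-volume bins, Angstrom^3.
#' @return object of class `reference_shape_set`.
#' @export
build_reference_set <- function(conformers, st_threshold = 0.8,
                                params = shape_params(), ids = NULL,
                                volume_bin = 50) {
  if (!length(conformers)) abort("need at least one conformer")
  if (is.null(ids))
    ids <- tibble(structure_id = seq_along(conformers),
                  local_id = vapply(conformers, function(cf) cf$local_id,
                                    integer(1)))
  refs <- list(); ref_rows <- integer(); saa <- numeric()
  for (i in seq_along(conformers)) {
    cc <- canonicalize_principal_axes(conformers[[i]])
    si <- self_overlap_volume(cc, params)
    admit <- TRUE
    for (j in seq_along(refs)) {
      if (st_upper_bound(si, saa[j]) <= st_threshold) next
      r <- optimize_overlap(cc, refs[[j]], mode = "shape", params = params)
      if (r$st > st_threshold) { admit <- FALSE; break }
    }
    if (admit) {
      refs[[length(refs) + 1L]] <- cc
      ref_rows <- c(ref_rows, i)
      saa <- c(saa, si)
    }
  }
  id_tbl <- ids[ref_rows, , drop = FALSE]
  id_tbl$gid <- encode_gid(id_tbl$structure_id, 0, id_tbl$local_id)
  vol <- vapply(refs, function(cf) self_volume(cf, params), numeric(1))
  structure(list(conformers = refs, ids = id_tbl,
                 st_threshold = st_threshold,
                 volume = vol, volume_bin = volume_bin,
                 bin = as.integer(floor(vol / volume_bin)),
                 self_overlap = saa),
            class = "reference_shape_set")
}

#' @export
print.reference_shape_set <- function(x, ...) {
  cat(sprintf("<reference_shape_set> %d reference(s), ST threshold %.3f\n",
              length(x$conformers), x$st_threshold))
  invisible(x)
}

#' Shape-fingerprint a conformer against a reference set
#'
#' ST-optimizes the conformer to each reference; every reference exceeding
#' the threshold contributes one fingerprint bit holding the reference GID
#' and the packed rigid transform that maps the conformer onto that
#' reference. At pipeline level fingerprints are computed for the first ten
#' diverse conformers of a model.
#'
#' @param conf a [conformer()].
#' @param refs a [build_reference_set()] result.
#' @param st_threshold bit threshold (defaults to the set's construction
#'   threshold).
#' @param params a [shape_params()].
#' @return object of class `shape_fingerprint`: tibble `bits` with columns
#'   `ref_gid`, `st`, `packed`.
#' @export
fingerprint_conformer <- function(conf, refs, st_threshold = NULL,
                                  params = shape_params()) {
  st_threshold <- st_threshold %||% refs$st_threshold
  s_conf <- self_overlap_volume(conf, params)
  rows <- list()
  for (j in seq_along(refs$conformers)) {
    if (st_upper_bound(s_conf, refs$self_overlap[j]) <= st_threshold) next
    # transform maps conf onto the reference frame
    r <- optimize_overlap(refs$conformers[[j]], conf, mode = "shape",
                          params = params)
    if (r$st > st_threshold)
      rows[[length(rows) + 1L]] <- tibble(
        ref_gid = refs$ids$gid[j], st = r$st,
        packed = pack_transform(list(rotation = r$rotation,
                                     translation = r$translation)))
  }
  bits <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(ref_gid = character(), st = numeric(), packed = character())
  structure(list(bits = bits, st_threshold = st_threshold,
                 ref_signature = paste(refs$ids$gid, collapse = "|")),
            class = "shape_fingerprint")
}

#' @export
print.shape_fingerprint <- function(x, ...) {
  cat(sprintf("<shape_fingerprint> %d bit(s) at ST threshold %.3f\n",
              nrow(x$bits), x$st_threshold))
  invisible(x)
}

#' Replay fingerprint alignments instead of optimizing a pair
#'
#' If the two fingerprints share no reference bit the pair is declared
#' dissimilar and a skip signal is returned (no pose optimization). When
#' common references exist, the stored alignments of both conformers to
#' each common reference are composed into a direct b-to-a pose, evaluated
#' single-point, and the best replayed pose is returned. The replayed ST
#' can never meaningfully exceed the fully optimized ST and is typically
#' very close to it.
#'
#' @param a,b [conformer()]s.
#' @param fp_a,fp_b their [fingerprint_conformer()] fingerprints against a
#'   common reference set.
#' @param params a [shape_params()].
#' @param refine run a short local refinement from the best replayed pose.
#' @return a [similarity_result()] (with attribute `replayed = TRUE`), or
#'   an object of class `recycle_skip` when the bit intersection is empty.
#' @export
recycle_alignment <- function(a, b, fp_a, fp_b, params = shape_params(),
                              refine = FALSE) {
  if (!identical(fp_a$ref_signature, fp_b$ref_signature))
    abort("fingerprints were computed against different reference sets")
  common <- intersect(fp_a$bits$ref_gid, fp_b$bits$ref_gid)
  if (!length(common))
    return(structure(list(reason = "no common fingerprint bits"),
                     class = "recycle_skip"))
  best <- NULL; best_st <- -Inf
  for (g in common) {
    ta <- unpack_transform(fp_a$bits$packed[match(g, fp_a$bits$ref_gid)])
    tb <- unpack_transform(fp_b$bits$packed[match(g, fp_b$bits$ref_gid)])
    inv_ta <- list(rotation = t(ta$rotation),
                   translation = as.numeric(-t(ta$rotation) %*% ta$translation))
    tr <- compose_transform(inv_ta, tb)     # b -> ref -> a
    st <- shape_tanimoto(a, b, transform = tr, params = params)
    if (st > best_st) { best_st <- st; best <- tr }
  }
  if (refine) {
    bt <- transform_conformer(b, best)
    r <- optimize_overlap(a, bt, mode = "shape", params = params)
    out <- similarity_result(r$st, r$ct,
                             compose_transform(list(rotation = r$rotation,
                                                    translation = r$translation),
                                               best))
  } else {
    out <- similarity_result(best_st, 0, best)
  }
  attr(out, "replayed") <- TRUE
  out
}

#' Test for a recycling skip signal
#' @param x object returned by [recycle_alignment()].
#' @return TRUE when the pair was declared dissimilar without optimization.
#' @export
is_skip <- function(x) inherits(x, "recycle_skip")
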