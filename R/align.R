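# Rodrigues rotation vector -> 3x3 rotation matrix
rotvec_to_matrix <- function(v) {
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) return(diag(3))
  k <- v / theta
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * kx + (1 - cos(theta)) * (kx %*% kx)
}

rotation_to_quaternion <- function(r) {
  tr <- sum(diag(r))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (r[3, 2] - r[2, 3]) / s, (r[1, 3] - r[3, 1]) / s,
           (r[2, 1] - r[1, 2]) / s)
  } else {
    i <- which.max(diag(r))
    if (i == 1) {
      s <- sqrt(1 + r[1, 1] - r[2, 2] - r[3, 3]) * 2
      q <- c((r[3, 2] - r[2, 3]) / s, 0.25 * s,
             (r[1, 2] + r[2, 1]) / s, (r[1, 3] + r[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + r[2, 2] - r[1, 1] - r[3, 3]) * 2
      q <- c((r[1, 3] - r[3, 1]) / s, (r[1, 2] + r[2, 1]) / s,
             0.25 * s, (r[2, 3] + r[3, 2]) / s)
    } else {
      s <- sqrt(1 + r[3, 3] - r[1, 1] - r[2, 2]) * 2
      q <- c((r[2, 1] - r[1, 2]) / s, (r[1, 3] + r[3, 1]) / s,
             (r[2, 3] + r[3, 2]) / s, 0.25 * s)
    }
  }
  q / sqrt(sum(q^2))
}

quaternion_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

# the four proper sign-flip poses of a principal-axes frame
proper_flips <- function() {
  list(diag(c(1, 1, 1)), diag(c(1, -1, -1)), diag(c(-1, 1, -1)),
       diag(c(-1, -1, 1)))
}

#' Similarity scores of a conformer pair
#'
#' Container for the shape Tanimoto `ST`, color Tanimoto `CT`, their sum
#' `ComboT = ST + CT`, and the rigid transform (rotation then translation,
#' applied to conformer b's input coordinates) realizing the scored pose.
#'
#' @param st,ct shape and color Tanimoto in [0, 1].
#' @param transform list with `rotation` (3 x 3 proper orthonormal) and
#'   `translation` (length 3, Angstrom).
#' @return object of class `similarity_result` with fields `st`, `ct`,
#'   `combo`, `rotation`, `translation`.
#' @export
similarity_result <- function(st, ct, transform = identity_transform()) {
  if (st < -1e-9 || st > 1 + 1e-9) abort("ST out of [0, 1]")
  if (ct < -1e-9 || ct > 1 + 1e-9) abort("CT out of [0, 1]")
  r <- transform$rotation
  if (max(abs(crossprod(r) - diag(3))) > 1e-6 || det(r) < 0)
    abort("rotation must be proper orthonormal")
  structure(list(st = min(1, max(0, st)), ct = min(1, max(0, ct)),
                 combo = min(1, max(0, st)) + min(1, max(0, ct)),
                 rotation = r,
                 translation = as.numeric(transform$translation)),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat(sprintf("<similarity_result> ST %.4f  CT %.4f  ComboT %.4f\n",
              x$st, x$ct, x$combo))
  invisible(x)
}

# fast pose objective machinery: precomputed Gaussian constants
cross_overlap_fun <- function(ca, aa, cb, ab, p) {
  asum <- outer(aa, ab, "+")
  pref <- p^2 * (pi / asum)^1.5
  kfac <- outer(aa, ab) / asum
  na2 <- rowSums(ca^2)
  function(cbt) {
    d2 <- outer(na2, rowSums(cbt^2), "+") - 2 * tcrossprod(ca, cbt)
    d2[d2 < 0] <- 0
    sum(pref * exp(-kfac * d2))
  }
}

# same-type color overlap objective over feature positions
color_overlap_fun <- function(fa, fb, alpha, p) {
  types <- intersect(unique(fa$type), unique(fb$type))
  if (!length(types)) return(function(pos_b) 0)
  blocks <- lapply(types, function(tp) {
    ia <- which(fa$type == tp); ib <- which(fb$type == tp)
    pa <- fa$position[ia, , drop = FALSE]
    list(ib = ib, fn = cross_overlap_fun(pa, rep(alpha, length(ia)),
                                         matrix(0, length(ib), 3),
                                         rep(alpha, length(ib)), p))
  })
  function(pos_b) {
    s <- 0
    for (bl in blocks) s <- s + bl$fn(pos_b[bl$ib, , drop = FALSE])
    s
  }
}

#' Optimize the rigid superposition of two conformers
#'
#' Rigid-body (6 degrees of freedom) local optimization of the overlap
#' between conformers `a` and `b`. Both are first canonicalized to their
#' principal steric axes; optimization is started from the four proper
#' sign-flip poses of the canonical frame and the best local optimum is
#' kept. In `"shape"` mode the objective is the Gaussian overlap volume
#' `V_AB`; in `"feature"` mode it is the total same-type color-atom
#' overlap. The color Tanimoto is always reported as a single-point
#' evaluation at the final pose.
#'
#' @param a,b [conformer()]s.
#' @param mode `"shape"` or `"feature"`.
#' @param params a [shape_params()].
#' @param mol_a,mol_b optional parent molecules (element radii and feature
#'   perception).
#' @param features_a,features_b optional precomputed [feature_set]s in the
#'   conformers' input frames; perceived from the molecules when omitted.
#' @param maxit optimizer iteration cap per start.
#' @return a [similarity_result()]; its transform maps `b`'s input
#'   coordinates onto `a`'s input frame.
#' @export
optimize_overlap <- function(a, b, mode = c("shape", "feature"),
                             params = shape_params(),
                             mol_a = NULL, mol_b = NULL,
                             features_a = NULL, features_b = NULL,
                             maxit = 300L) {
  mode <- match.arg(mode)
  ca_full <- canonicalize_principal_axes(a)
  cb_full <- canonicalize_principal_axes(b)
  tra <- attr(ca_full, "canonical_transform")
  trb <- attr(cb_full, "canonical_transform")
  ca <- heavy_coords(ca_full); cb <- heavy_coords(cb_full)
  aa <- gauss_alpha(heavy_radii(a, mol_a, params), params$p)
  ab <- gauss_alpha(heavy_radii(b, mol_b, params), params$p)
  shape_obj <- cross_overlap_fun(ca, aa, cb, ab, params$p)

  if (is.null(features_a) && !is.null(mol_a))
    features_a <- perceive_features(mol_a, a)
  if (is.null(features_b) && !is.null(mol_b))
    features_b <- perceive_features(mol_b, b)
  fa <- fb <- NULL
  if (!is.null(features_a) && nrow(features_a$features))
    fa <- transform_feature_positions(features_a, tra)
  if (!is.null(features_b) && nrow(features_b$features))
    fb <- transform_feature_positions(features_b, trb)
  alpha_col <- gauss_alpha(params$color_radius, params$p)
  col_obj <- if (!is.null(fa) && !is.null(fb))
    color_overlap_fun(fa$features, fb$features, alpha_col, params$p)
  else function(pos) 0

  objective <- if (mode == "shape") {
    function(rot, tvec) shape_obj(sweep(cb %*% t(rot), 2, -tvec))
  } else {
    if (is.null(fb)) function(rot, tvec) 0
    else function(rot, tvec)
      col_obj(sweep(fb$features$position %*% t(rot), 2, -tvec))
  }

  best <- NULL; best_val <- -Inf
  for (flip in proper_flips()) {
    par0 <- numeric(6)
    fn <- function(par) {
      rot <- rotvec_to_matrix(par[1:3]) %*% flip
      -objective(rot, par[4:6])
    }
    opt <- stats::optim(par0, fn, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-8))
    start_val <- -fn(numeric(6))
    val <- max(-opt$value, start_val)
    if (val > best_val) {
      best_val <- val
      use_start <- start_val >= -opt$value
      rot <- if (use_start) flip else rotvec_to_matrix(opt$par[1:3]) %*% flip
      tvec <- if (use_start) numeric(3) else opt$par[4:6]
      best <- list(rotation = rot, translation = tvec)
    }
  }

  # score at the optimal canonical-frame pose
  cbt <- sweep(cb %*% t(best$rotation), 2, -best$translation)
  vab <- shape_obj(cbt)
  vaa <- gauss_cross_overlap(ca, aa, ca, aa, params$p)
  vbb <- gauss_cross_overlap(cb, ab, cb, ab, params$p)
  st <- min(1, max(0, vab / (vaa + vbb - vab)))

  ct <- 0
  if (!is.null(fa) && !is.null(fb)) {
    posb <- sweep(fb$features$position %*% t(best$rotation), 2,
                  -best$translation)
    cab <- col_obj(posb)
    caa <- color_self_overlap(fa$features, alpha_col, params$p)
    cbb <- color_self_overlap(fb$features, alpha_col, params$p)
    den <- caa + cbb - cab
    ct <- if (den > 0) min(1, max(0, cab / den)) else 0
  }

  # compose: b-input -> canonical-b -> optimal pose -> a-input frame
  inv_tra <- list(rotation = t(tra$rotation),
                  translation = as.numeric(-t(tra$rotation) %*% tra$translation))
  full <- compose_transform(inv_tra, compose_transform(best, trb))
  similarity_result(st, ct, full)
}

color_self_overlap <- function(fdf, alpha, p) {
  if (!nrow(fdf)) return(0)
  s <- 0
  for (tp in unique(fdf$type)) {
    pos <- fdf$position[fdf$type == tp, , drop = FALSE]
    al <- rep(alpha, nrow(pos))
    s <- s + gauss_cross_overlap(pos, al, pos, al, p)
  }
  s
}
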