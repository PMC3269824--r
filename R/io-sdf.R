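# SDF property-tag dialect. Compound-level tags are repeated on every
# conformer record of a compound; conformer-level tags are per record.
SDF_TAGS <- c("PUBCHEM_CONFORMER_ID", "PUBCHEM_CONFORMER_RMSD",
              "PUBCHEM_EFFECTIVE_ROTOR_COUNT", "PUBCHEM_MMFF94_ENERGY",
              "PUBCHEM_SHAPE_VOLUME", "PUBCHEM_SHAPE_MULTIPOLES",
              "PUBCHEM_SHAPE_SELFOVERLAP", "PUBCHEM_FEATURE_SELFOVERLAP",
              "PUBCHEM_PHARMACOPHORE_FEATURES",
              "PUBCHEM_CONFORMER_DIVERSEORDERING",
              "PUBCHEM_SHAPE_FINGERPRINT")

#' Write conformer models to a multi-record V2000 SDF
#'
#' One SDF record per conformer, grouped by compound, carrying the
#' property-tag dialect: conformer identifier (hex GID), sampling RMSD,
#' effective rotor count, energy, analytic shape volume, steric multipoles
#' (14 values: volume, 3 quadrupoles, 10 octopoles), shape and feature
#' self-overlap volumes, pharmacophore feature definitions, and the
#' diverse conformer ordering. Unknown tags attached to a conformer are
#' preserved verbatim. Coordinates are written at 4 decimal places.
#'
#' @param models a [conformer_model()] or list of them.
#' @param path output file.
#' @param params a [shape_params()] for the computed properties.
#' @param compute_properties write the shape/feature property tags
#'   (volume, multipoles, self-overlaps, features).
#' @return invisible `path`.
#' @export
write_model <- function(models, path, params = shape_params(),
                        compute_properties = TRUE) {
  if (inherits(models, "conformer_model")) models <- list(models)
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (model in models) {
    mol <- model$molecule
    d <- count_descriptors(mol)
    er <- effective_rotor_count(d$rb, d$nara)
    lids <- vapply(model$conformers, function(cf) cf$local_id, integer(1))
    div_lids <- lids[model$diverse_order]
    for (conf in model$conformers) {
      writeLines(format_sdf_record(mol, conf, model, er, div_lids,
                                   params, compute_properties), con)
    }
  }
  invisible(path)
}

format_sdf_record <- function(mol, conf, model, er, div_lids, params,
                              compute_properties) {
  at <- mol$atoms
  n <- nrow(at); nb <- nrow(mol$bonds)
  out <- c(mol$name, "  pubshape3d", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  for (i in seq_len(n)) {
    out <- c(out, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                          conf$coords[i, 1], conf$coords[i, 2],
                          conf$coords[i, 3], at$element[i]))
  }
  b <- mol$bonds
  for (i in seq_len(nb)) {
    out <- c(out, sprintf("%3d%3d%3d  0", b$a1[i], b$a2[i], b$order[i]))
  }
  chg <- which(at$formal_charge != 0L)
  while (length(chg)) {
    take <- utils::head(chg, 8L); chg <- chg[-seq_along(take)]
    out <- c(out, paste0(sprintf("M  CHG%3d", length(take)),
                         paste0(sprintf("%4d%4d", take,
                                        at$formal_charge[take]),
                                collapse = "")))
  }
  out <- c(out, "M  END")

  tag <- function(name, value) c(paste0("> <", name, ">"), value, "")
  out <- c(out, tag("PUBCHEM_CONFORMER_ID", conformer_gid(mol, conf)))
  out <- c(out, tag("PUBCHEM_CONFORMER_RMSD",
                    sprintf("%.6g", model$sampling_rmsd)))
  out <- c(out, tag("PUBCHEM_EFFECTIVE_ROTOR_COUNT", sprintf("%.6g", er)))
  if (!is.na(conf$energy))
    out <- c(out, tag("PUBCHEM_MMFF94_ENERGY", sprintf("%.4f", conf$energy)))
  out <- c(out, tag("PUBCHEM_CONFORMER_DIVERSEORDERING",
                    paste(div_lids, collapse = " ")))
  if (compute_properties) {
    sm <- steric_moments(conf, params, mol)
    fs <- perceive_features(mol, conf)
    alpha_col <- gauss_alpha(params$color_radius, params$p)
    out <- c(out,
      tag("PUBCHEM_SHAPE_VOLUME", sprintf("%.3f", sm$volume)),
      tag("PUBCHEM_SHAPE_MULTIPOLES",
          sprintf("%.3f", c(sm$volume, sm$quadrupole, sm$octopole))),
      tag("PUBCHEM_SHAPE_SELFOVERLAP",
          sprintf("%.3f", self_overlap_volume(conf, params, mol))),
      tag("PUBCHEM_FEATURE_SELFOVERLAP",
          sprintf("%.3f", color_self_overlap(fs$features, alpha_col,
                                             params$p))),
      tag("PUBCHEM_PHARMACOPHORE_FEATURES", format_feature_lines(fs)))
  }
  known <- SDF_TAGS
  for (nm in setdiff(names(conf$tags), known))
    out <- c(out, tag(nm, conf$tags[[nm]]))
  if (!is.null(conf$tags$PUBCHEM_SHAPE_FINGERPRINT))
    out <- c(out, tag("PUBCHEM_SHAPE_FINGERPRINT",
                      conf$tags$PUBCHEM_SHAPE_FINGERPRINT))
  c(out, "$$$$")
}

# first line: feature count; then "k idx1 ... idxk type" per feature
format_feature_lines <- function(fs) {
  f <- fs$features
  c(as.character(nrow(f)),
    vapply(seq_len(nrow(f)), function(i)
      paste(c(length(f$members[[i]]), f$members[[i]], f$type[i]),
            collapse = " "), character(1)))
}

parse_feature_lines <- function(lines) {
  toks <- strsplit(paste(lines, collapse = " "), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  n <- as.integer(toks[1]); p <- 2L
  out <- vector("list", n); types <- character(n)
  for (i in seq_len(n)) {
    k <- as.integer(toks[p]); p <- p + 1L
    out[[i]] <- as.integer(toks[p:(p + k - 1L)]); p <- p + k
    types[i] <- toks[p]; p <- p + 1L
  }
  list(members = out, types = types)
}

#' Read conformer models from a multi-record V2000 SDF
#'
#' Parses every record (ChemmineR performs the block parsing; formal
#' charges are recovered from the raw `M  CHG` lines, which ChemmineR does
#' not expose), groups consecutive records sharing a structure identifier
#' into one conformer model, and interprets the property-tag dialect of
#' [write_model()]. Unknown tags are kept verbatim on each conformer.
#' Records whose coordinates are all zero in z are accepted with a warning
#' (treated as the provided pose). Missing conformer identifiers get
#' sequential local ids from 0.
#'
#' @param path SDF file.
#' @return list of [conformer_model()]s.
#' @export
read_model <- function(path) {
  sdfstr <- ChemmineR::read.SDFstr(path)
  recs <- as(sdfstr, "list")
  sdfset <- tryCatch(suppressWarnings(as(sdfstr, "SDFset")),
                     error = function(e) abort(paste0("malformed SDF: ", path,
                                                     ": ", conditionMessage(e))))
  blocks <- lapply(seq_along(recs), function(i) {
    blk <- tryCatch(chemminer_blocks(sdfset[[i]]), error = function(e) NULL)
    # ChemmineR cannot parse bond-free records; fall back to fixed-width
    if (is.null(blk)) blk <- tryCatch(parse_v2000_blocks(recs[[i]]),
                                      error = function(e) NULL)
    blk
  })
  bad <- which(vapply(blocks, is.null, logical(1)))
  if (length(bad))
    abort(sprintf("malformed SDF record(s) at position(s) %s in %s",
                  paste(bad, collapse = ", "), path))
  parsed <- lapply(seq_along(recs), function(i)
    parse_sdf_record(blocks[[i]], recs[[i]], i))

  # group consecutive records by structure key
  keys <- vapply(parsed, function(p) p$group_key, character(1))
  grp <- cumsum(c(TRUE, keys[-1] != keys[-length(keys)]))
  lapply(split(parsed, grp), build_model_from_records)
}

chemminer_blocks <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
  if (nrow(coords) < 1L || anyNA(coords) ||
      !all(elements %in% PERIODIC_SYMBOLS))
    stop("unparseable atom block")
  bonds <- if (is.null(bb) || NROW(bb) == 0L) NULL else
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  list(elements = elements, coords = coords, bonds = bonds)
}

# minimal fixed-width V2000 block parser (fallback path)
parse_v2000_blocks <- function(lines) {
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || na < 1L || is.na(nb)) stop("bad counts line")
  atoms <- lines[4 + seq_len(na)]
  coords <- cbind(as.numeric(substr(atoms, 1, 10)),
                  as.numeric(substr(atoms, 11, 20)),
                  as.numeric(substr(atoms, 21, 30)))
  elements <- trimws(substr(atoms, 32, 34))
  if (anyNA(coords) || !all(elements %in% PERIODIC_SYMBOLS))
    stop("bad atom block")
  bonds <- NULL
  if (nb > 0L) {
    bl <- lines[4 + na + seq_len(nb)]
    bonds <- data.frame(a1 = as.integer(substr(bl, 1, 3)),
                        a2 = as.integer(substr(bl, 4, 6)),
                        order = as.integer(substr(bl, 7, 9)))
    if (anyNA(bonds)) stop("bad bond block")
  }
  list(elements = elements, coords = coords, bonds = bonds)
}

parse_sdf_record <- function(blk, lines, pos) {
  elements <- blk$elements
  coords <- blk$coords
  bonds <- blk$bonds
  if (all(abs(coords[, 3]) < 1e-12))
    warn(sprintf("SDF record %d has no z variation; treating as provided pose",
                 pos))
  charges <- rep(0L, length(elements))
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    k <- as.integer(substr(ln, 7, 9))
    for (j in seq_len(k)) {
      off <- 10 + (j - 1) * 8
      idx <- as.integer(substr(ln, off, off + 3))
      charges[idx] <- as.integer(substr(ln, off + 4, off + 7))
    }
  }
  tags <- parse_sdf_tags(lines)
  gid <- tags[["PUBCHEM_CONFORMER_ID"]]
  if (!is.null(gid)) {
    dg <- decode_gid(trimws(gid[1]))
    record_id <- dg$structure_id
    kind <- if (dg$is_substance) "substance" else "compound"
    local_id <- dg$local_id
    group_key <- paste0(kind, ":", record_id)
  } else {
    record_id <- NA_real_
    kind <- "compound"
    local_id <- NA_integer_
    group_key <- paste0("title:", lines[1])
  }
  energy <- if (!is.null(tags[["PUBCHEM_MMFF94_ENERGY"]]))
    as.numeric(tags[["PUBCHEM_MMFF94_ENERGY"]][1]) else NA_real_
  list(elements = elements, coords = coords, bonds = bonds,
       charges = charges, tags = tags, name = lines[1],
       record_id = record_id, kind = kind, local_id = local_id,
       energy = energy, group_key = group_key, pos = pos)
}

parse_sdf_tags <- function(lines) {
  starts <- grep("^> *<.*>", lines)
  tags <- list()
  for (s in starts) {
    nm <- sub("^> *<([^>]*)>.*$", "\\1", lines[s])
    e <- s
    while (e < length(lines) && nzchar(lines[e + 1]) &&
           !startsWith(lines[e + 1], "$$$$")) e <- e + 1L
    tags[[nm]] <- if (e > s) lines[(s + 1):e] else character()
  }
  tags
}

build_model_from_records <- function(precs) {
  first <- precs[[1]]
  rid <- if (is.na(first$record_id)) 0 else first$record_id
  mol <- molecule(first$elements, first$bonds,
                  formal_charge = first$charges, record_id = rid,
                  record_id_kind = first$kind, name = first$name)
  confs <- lapply(seq_along(precs), function(i) {
    p <- precs[[i]]
    lid <- if (is.na(p$local_id)) i - 1L else p$local_id
    cf <- conformer(p$coords, molecule = mol, energy = p$energy,
                    local_id = as.integer(lid))
    cf$tags <- p$tags[setdiff(names(p$tags), SDF_TAGS_COMPOUND_DERIVED)]
    cf
  })
  tags <- first$tags
  rmsd <- if (!is.null(tags[["PUBCHEM_CONFORMER_RMSD"]]))
    as.numeric(tags[["PUBCHEM_CONFORMER_RMSD"]][1]) else 0.4
  div <- NULL
  if (!is.null(tags[["PUBCHEM_CONFORMER_DIVERSEORDERING"]])) {
    lids <- as.integer(strsplit(trimws(
      paste(tags[["PUBCHEM_CONFORMER_DIVERSEORDERING"]], collapse = " ")),
      "\\s+")[[1]])
    conf_lids <- vapply(confs, function(cf) cf$local_id, integer(1))
    div <- match(lids, conf_lids)
    if (anyNA(div) || length(div) != length(confs)) div <- NULL
  }
  conformer_model(mol, confs, sampling_rmsd = rmsd, diverse_order = div)
}

# tags recomputed at write time (not carried as unknown extras)
SDF_TAGS_COMPOUND_DERIVED <- setdiff(SDF_TAGS, "PUBCHEM_SHAPE_FINGERPRINT")

#' Write neighbor records to a flat pair file
#'
#' One pair per line, tab-separated: `gid_a gid_b ST CT r11..r33 t1..t3`,
#' scores at 4 decimals, transform elements at 6.
#'
#' @param records tibble from [neighbor_search()].
#' @param path output file.
#' @return invisible `path`.
#' @export
write_neighbor_pairs <- function(records, path) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    paste(c(r$gid_a, r$gid_b, sprintf("%.4f", c(r$st, r$ct)),
            sprintf("%.6f", c(r$r11, r$r12, r$r13, r$r21, r$r22, r$r23,
                              r$r31, r$r32, r$r33, r$t1, r$t2, r$t3))),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a neighbor pair file written by [write_neighbor_pairs()]
#' @param path pair file.
#' @return tibble with the neighbor-record columns.
#' @export
read_neighbor_pairs <- function(path) {
  if (file.size(path) == 0) return(empty_neighbor_tbl())
  m <- utils::read.table(path, sep = "\t", colClasses = c("character",
                         "character", rep("numeric", 14)))
  names(m) <- names(empty_neighbor_tbl())
  as_tibble(m)
}
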