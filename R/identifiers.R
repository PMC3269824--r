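#' Encode a global conformer identifier (GID)
#'
#' Packs `{structure id, version, local id}` into a 64-bit unsigned value
#' `gid = (structure_id << 32) | (version << 16) | local_id`, rendered as a
#' zero-padded 16-digit hexadecimal string (R has no native 64-bit unsigned
#' integer). A version of 0 marks a compound conformer (structure id is a
#' CID); a nonzero version marks a deposited substance conformer (SID).
#'
#' @param structure_id CID or SID, 0..2^32-1.
#' @param version substance version, 0..65535.
#' @param local_id conformer LID within its ensemble, 0..65535.
#' @return 16-character uppercase hex string.
#' @examples
#' encode_gid(681, 0, 0)  # "000002A900000000"
#' @export
encode_gid <- function(structure_id, version = 0, local_id = 0) {
  structure_id <- as.numeric(structure_id)
  version <- as.numeric(version)
  local_id <- as.numeric(local_id)
  if (any(structure_id < 0 | structure_id > 2^32 - 1) ||
      any(structure_id != floor(structure_id)))
    abort("structure_id out of 32-bit unsigned range")
  if (any(version < 0 | version > 65535) || any(version != floor(version)))
    abort("version out of 16-bit unsigned range")
  if (any(local_id < 0 | local_id > 65535) || any(local_id != floor(local_id)))
    abort("local_id out of 16-bit unsigned range")
  # structure_id may exceed the signed 32-bit range sprintf("%x") accepts
  toupper(sprintf("%04x%04x%04x%04x", structure_id %/% 65536,
                  structure_id %% 65536, version, local_id))
}

#' Decode a global conformer identifier
#'
#' Accepts a 16-digit hex string (case-insensitive, optional `0x` prefix)
#' or a non-negative number below 2^53, and unpacks the three bit fields.
#'
#' @param gid hex string(s) or number(s).
#' @return tibble with `structure_id`, `version`, `local_id`,
#'   `is_substance` (version != 0), and the normalized `gid` hex string.
#' @examples
#' decode_gid("0000000100010002")
#' @export
decode_gid <- function(gid) {
  if (is.numeric(gid)) {
    if (any(gid < 0 | gid >= 2^53 | gid != floor(gid)))
      abort("numeric gid must be an integer in [0, 2^53)")
    hex <- vapply(gid, function(g) {
      hi <- floor(g / 2^32)
      lo <- g - hi * 2^32
      toupper(sprintf("%08x%08x", hi, lo))
    }, character(1))
  } else {
    hex <- toupper(sub("^0X", "", toupper(as.character(gid))))
    if (any(!grepl("^[0-9A-F]{1,16}$", hex)))
      abort("gid must be a hex string of up to 16 digits")
    hex <- sprintf("%016s", hex)
    hex <- gsub(" ", "0", hex, fixed = TRUE)
  }
  # strtoi overflows signed 32-bit for values >= 2^31; go via two halves
  structure_id <- strtoi(substr(hex, 1, 4), 16L) * 65536 +
    strtoi(substr(hex, 5, 8), 16L)
  version <- strtoi(substr(hex, 9, 12), 16L)
  local_id <- strtoi(substr(hex, 13, 16), 16L)
  tibble(structure_id = structure_id, version = version,
         local_id = local_id, is_substance = version != 0, gid = hex)
}

#' GID of one conformer of a molecule
#' @param mol a [molecule()].
#' @param conf a [conformer()].
#' @return 16-character hex GID.
#' @export
conformer_gid <- function(mol, conf) {
  encode_gid(mol$record_id,
             version = if (mol$record_id_kind == "substance") 1 else 0,
             local_id = conf$local_id)
}
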