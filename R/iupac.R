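# Internal IUPAC machinery shared by all modules.
#
# The IUPAC code -> base-set map comes from Biostrings; everything else
# (compatibility / disjointness lookups, tie -> code resolution) is derived
# from it once and cached in the package environment.

.pkg_env <- new.env(parent = emptyenv())

.iupac_map <- function() {
  if (is.null(.pkg_env$iupac_map)) {
    m <- Biostrings::IUPAC_CODE_MAP
    .pkg_env$iupac_map <- m
  }
  .pkg_env$iupac_map
}

.iupac_chars <- function() names(.iupac_map())

# logical matrix: do the concrete base sets of two codes intersect?
# '-' (gap) intersects nothing, including itself.
.compat_matrix <- function() {
  if (is.null(.pkg_env$compat)) {
    map <- .iupac_map()
    codes <- names(map)
    all <- c(codes, "-")
    mat <- matrix(FALSE, length(all), length(all), dimnames = list(all, all))
    sets <- lapply(map, function(s) strsplit(s, "", fixed = TRUE)[[1]])
    for (a in codes) {
      for (b in codes) {
        mat[a, b] <- length(intersect(sets[[a]], sets[[b]])) > 0L
      }
    }
    .pkg_env$compat <- mat
  }
  .pkg_env$compat
}

# IUPAC code for a set of concrete bases (chr vector drawn from A,C,G,T)
.code_for_set <- function(bases) {
  map <- .iupac_map()
  key <- paste(sort(unique(bases)), collapse = "")
  hit <- names(map)[map == key]
  if (length(hit) != 1L) {
    stop("no IUPAC code for base set: ", key)
  }
  hit
}

.IUPAC_FROM <- "ACGTRYSWKMBDHVN"
.IUPAC_TO   <- "TGCAYRSWMKVHDBN"

.valid_residue_chars <- function(allow_gap = TRUE) {
  ch <- strsplit(.IUPAC_FROM, "", fixed = TRUE)[[1]]
  if (allow_gap) c(ch, "-") else ch
}

# validate one residue string; err_label names the offending record in errors
.check_residues <- function(x, allow_gap = TRUE, err_label = "sequence") {
  if (is.na(x) || !nzchar(x)) {
    stop(sprintf("record '%s': residues must be non-empty", err_label))
  }
  ok <- .valid_residue_chars(allow_gap)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% ok)
  if (length(bad)) {
    stop(sprintf(
      "record '%s': illegal character '%s' at position %d (IUPAC DNA%s expected)",
      err_label, chars[bad[1]], bad[1], if (allow_gap) " or '-'" else ""
    ))
  }
  invisible(TRUE)
}
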