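# Per-species consensus profiles, intraspecific polymorphic-column masks, and
# counts of discriminative nucleotide positions between species.

.BASES <- c("A", "C", "G", "T")

# expand an alignment into a character matrix (rows = members, cols = columns)
.char_matrix <- function(seqs) {
  do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

#' Build a species consensus profile
#'
#' The consensus is the per-column majority base over non-gap residues; an
#' ambiguity code in a member contributes one count to each base of its set.
#' Ties are resolved to the IUPAC code of the tied base set, so within-species
#' variation is preserved rather than collapsed to an arbitrary base. Columns
#' containing only gaps become `N`. A column is polymorphic when at least two
#' distinct concrete bases occur among the members.
#'
#' @param species Species label.
#' @param members Either a character vector of equal-length residue strings or
#'   a sequence table / alignment subset (data frame with `residues`).
#' @return A `species_profile`: list with `species`, `n_members`, `length`,
#'   `consensus` (string), `degenerate_consensus` (per-column IUPAC union of
#'   every observed base, used for worst-case specificity screening),
#'   `polymorphic_columns` (sorted 1-based integer vector), `column_counts`
#'   (4 x length base-count matrix) and `members` (the residue strings, kept
#'   for worst-case discrimination counting).
#' @export
build_profile <- function(species, members) {
  if (is.data.frame(members)) members <- members$residues
  if (inherits(members, "dna_alignment")) members <- members$seqs
  if (length(members) < 1L) stop("build_profile: empty member list")
  len <- nchar(members)
  if (length(unique(len)) != 1L) {
    stop("build_profile: members have unequal lengths")
  }
  mat <- .char_matrix(members)
  L <- ncol(mat)
  counts <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(.BASES, NULL))
  map <- .iupac_map()
  for (code in names(map)) {
    hits <- mat == code
    if (!any(hits)) next
    n_per_col <- colSums(hits)
    for (b in strsplit(map[[code]], "", fixed = TRUE)[[1]]) {
      counts[b, ] <- counts[b, ] + n_per_col
    }
  }
  n_distinct <- colSums(counts > 0L)
  consensus <- character(L)
  degenerate <- character(L)
  for (j in seq_len(L)) {
    cj <- counts[, j]
    if (all(cj == 0L)) {           # only gaps
      consensus[j] <- "N"
      degenerate[j] <- "-"
    } else {
      top <- .BASES[cj == max(cj)]
      consensus[j] <- if (length(top) == 1L) top else .code_for_set(top)
      degenerate[j] <- .code_for_set(.BASES[cj > 0L])
    }
  }
  structure(
    list(species = species, n_members = length(members), length = L,
         consensus = paste(consensus, collapse = ""),
         # IUPAC union of every base observed at each column: the
         # "any individual" view used for worst-case specificity screening
         degenerate_consensus = paste(degenerate, collapse = ""),
         polymorphic_columns = which(n_distinct >= 2L),
         column_counts = counts,
         members = members),
    class = "species_profile"
  )
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("Species profile '%s': %d members, %d columns, %d polymorphic\n",
              x$species, x$n_members, x$length,
              length(x$polymorphic_columns)))
  invisible(x)
}

# disjointness indicator over paired character vectors; gap/N columns never
# count as discriminative
.disjoint_columns <- function(a_chars, b_chars) {
  compat <- .compat_matrix()
  idx <- cbind(match(a_chars, rownames(compat)),
               match(b_chars, colnames(compat)))
  disjoint <- !compat[idx]
  disjoint & a_chars != "-" & b_chars != "-" & a_chars != "N" & b_chars != "N"
}

#' Count discriminative nucleotide positions in a region
#'
#' A column counts as discriminative when the two species' consensus bases are
#' disjoint as IUPAC sets, i.e. share no concrete base. An ambiguous consensus
#' that overlaps the other species' base is not counted, and gap or `N`
#' columns never count. With `mode = "worst_case"` the count is instead the
#' minimum over the other profile's individual member sequences, i.e. the
#' discrimination guaranteed against every non-target individual.
#'
#' @param region Integer vector `c(start, end)`, 1-based inclusive columns on
#'   the shared master alignment.
#' @param target,other `species_profile` objects built on the same master
#'   alignment (equal lengths are enforced).
#' @param mode `"consensus"` (default) or `"worst_case"`.
#' @return Integer count, between 0 and the region length.
#' @export
count_discriminative_positions <- function(region, target, other,
                                           mode = c("consensus", "worst_case")) {
  mode <- match.arg(mode)
  stopifnot(inherits(target, "species_profile"),
            inherits(other, "species_profile"))
  if (target$length != other$length) {
    stop("profiles are not on a shared master alignment (lengths differ)")
  }
  s <- as.integer(region[1]); e <- as.integer(region[2])
  if (is.na(s) || is.na(e) || s < 1L || e > target$length || s > e) {
    stop(sprintf("region [%s, %s] out of bounds for alignment of length %d",
                 region[1], region[2], target$length))
  }
  tgt <- strsplit(substr(target$consensus, s, e), "", fixed = TRUE)[[1]]
  if (mode == "consensus") {
    oth <- strsplit(substr(other$consensus, s, e), "", fixed = TRUE)[[1]]
    return(sum(.disjoint_columns(tgt, oth)))
  }
  counts <- vapply(other$members, function(m) {
    oth <- strsplit(substr(m, s, e), "", fixed = TRUE)[[1]]
    sum(.disjoint_columns(tgt, oth))
  }, integer(1))
  min(counts)
}

#' Discrimination table over named primer regions
#'
#' The full matrix of discriminative-position counts for every
#' (region, target species, other species) combination, excluding
#' self-comparisons. Regions are named column intervals on the shared master
#' alignment, typically the annealing regions of candidate or published
#' primers.
#'
#' @param regions Named list of `c(start, end)` intervals. Each region is
#'   counted for the target species named in `region_targets` (or for every
#'   profile when `region_targets` is `NULL`).
#' @param profiles Named list of `species_profile` objects (>= 2) on one
#'   master alignment.
#' @param region_targets Optional character vector, parallel to `regions`,
#'   giving the target species of each region.
#' @inheritParams count_discriminative_positions
#' @return A data frame (class `discrimination_table`) with columns `region`,
#'   `target_species`, `other_species`, `count`.
#' @export
discrimination_table <- function(regions, profiles, region_targets = NULL,
                                 mode = c("consensus", "worst_case")) {
  mode <- match.arg(mode)
  if (is.null(names(regions)) || any(!nzchar(names(regions)))) {
    stop("regions must be named")
  }
  if (anyDuplicated(names(regions))) {
    stop("duplicate region names: ",
         names(regions)[duplicated(names(regions))][1])
  }
  if (length(profiles) < 2L) stop("need >= 2 profiles")
  sp <- vapply(profiles, function(p) p$species, character(1))
  names(profiles) <- sp
  if (!is.null(region_targets)) {
    stopifnot(length(region_targets) == length(regions),
              all(region_targets %in% sp))
  }
  rows <- list()
  for (i in seq_along(regions)) {
    targets <- if (is.null(region_targets)) sp else region_targets[i]
    for (t in targets) {
      for (o in setdiff(sp, t)) {
        rows[[length(rows) + 1L]] <- data.frame(
          region = names(regions)[i], target_species = t, other_species = o,
          count = count_discriminative_positions(regions[[i]], profiles[[t]],
                                                 profiles[[o]], mode = mode),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("discrimination_table", "data.frame")
  out
}

#' Write a discrimination table as a wide TSV
#'
#' Rows are region x target species, columns are the other species.
#'
#' @param tab A `discrimination_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_discrimination_table <- function(tab, path) {
  others <- sort(unique(tab$other_species))
  key <- unique(tab[, c("region", "target_species")])
  wide <- key
  for (o in others) {
    m <- tab[tab$other_species == o, ]
    wide[[o]] <- m$count[match(paste(key$region, key$target_species),
                               paste(m$region, m$target_species))]
  }
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Check that profiles share one master alignment
#'
#' @param profiles List of `species_profile` objects.
#' @return `TRUE` invisibly; errors naming the offending profile otherwise.
#' @export
validate_shared_alignment <- function(profiles) {
  lens <- vapply(profiles, function(p) p$length, integer(1))
  if (length(unique(lens)) > 1L) {
    bad <- which(lens != lens[1])[1]
    stop(sprintf("profile '%s' has length %d, expected %d: profiles must be built on one master alignment",
                 profiles[[bad]]$species, lens[bad], lens[1]))
  }
  invisible(TRUE)
}
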