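# Readers/writers and core sequence types: FASTA sequence tables, gapped
# alignments, primer-panel tables and gel band-pattern tables.

#' Read a FASTA file into a sequence table
#'
#' Records are returned as a data frame with one row per sequence. Residues
#' are uppercased on ingest; `U` is accepted and converted to `T` with a
#' warning. A `species=<label>` token in the description line (the label runs
#' to the end of the line, so it may contain spaces) populates the `species`
#' column.
#'
#' @param path Path to a FASTA file. Line wrapping is ignored.
#' @return A data frame with columns `id`, `residues`, `species` (`NA` when no
#'   `species=` token is present).
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 species=demo", "acgtacgt"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), residues = character(),
                      species = character(), stringsAsFactors = FALSE))
  }
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1]
  if (is.na(first)) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), residues = character(),
                      species = character(), stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[first]), ">")) {
    stop(sprintf("malformed FASTA at line %d: expected '>' header, got '%s'",
                 first, substr(trimws(lines[first]), 1, 30)))
  }
  ss <- Biostrings::readBStringSet(path)
  desc <- names(ss)
  id <- sub("\\s.*$", "", desc)
  if (any(!nzchar(id))) {
    stop("malformed FASTA: record with empty identifier in ", path)
  }
  if (anyDuplicated(id)) {
    stop("duplicate sequence id in ", path, ": ",
         id[duplicated(id)][1])
  }
  species <- ifelse(grepl("species=", desc, fixed = TRUE),
                    sub("^.*species=", "", desc), NA_character_)
  res <- toupper(as.character(ss))
  names(res) <- NULL
  if (any(grepl("U", res, fixed = TRUE))) {
    warning("'U' residues converted to 'T' in ", path)
    res <- gsub("U", "T", res, fixed = TRUE)
  }
  for (i in seq_along(res)) .check_residues(res[i], allow_gap = TRUE, err_label = id[i])
  data.frame(id = id, residues = res, species = species,
             stringsAsFactors = FALSE)
}

#' Write a sequence table to FASTA
#'
#' Inverse of [read_fasta()]: `species` (when not `NA`) is written back as a
#' `species=<label>` description token. Sequences are wrapped at 70 columns.
#'
#' @param seqs Data frame with columns `id`, `residues` and optionally
#'   `species`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.data.frame(seqs), all(c("id", "residues") %in% names(seqs)))
  hdr <- seqs$id
  if ("species" %in% names(seqs)) {
    has <- !is.na(seqs$species) & nzchar(seqs$species)
    hdr[has] <- paste0(seqs$id[has], " species=", seqs$species[has])
  }
  ss <- Biostrings::BStringSet(seqs$residues)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read a gapped FASTA alignment
#'
#' All records must have identical length; the first offending record is named
#' otherwise.
#'
#' @inheritParams read_fasta
#' @return A `dna_alignment` object (see [as_alignment()]).
#' @export
read_alignment <- function(path) {
  as_alignment(read_fasta(path))
}

#' Build an alignment object from a sequence table
#'
#' @param seqs Data frame as returned by [read_fasta()], with equal-length
#'   (gapped) residues.
#' @return An object of class `dna_alignment`: a list with `ids`, `seqs`,
#'   `species` and `length` (number of columns). Column coordinates reported
#'   by downstream functions are 1-based and inclusive.
#' @export
as_alignment <- function(seqs) {
  stopifnot(is.data.frame(seqs), nrow(seqs) >= 1L)
  len <- nchar(seqs$residues)
  if (length(unique(len)) != 1L) {
    bad <- which(len != len[1])[1]
    stop(sprintf("alignment record '%s' has length %d, expected %d",
                 seqs$id[bad], len[bad], len[1]))
  }
  structure(
    list(ids = seqs$id, seqs = seqs$residues,
         species = if ("species" %in% names(seqs)) seqs$species else rep(NA_character_, nrow(seqs)),
         length = len[1]),
    class = "dna_alignment"
  )
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("DNA alignment: %d sequences x %d columns\n",
              length(x$ids), x$length))
  invisible(x)
}

#' Reverse complement of an IUPAC DNA string
#'
#' The complement is extended over all IUPAC ambiguity codes (R<->Y, S<->S,
#' W<->W, K<->M, B<->V, D<->H, N<->N). Gaps are rejected.
#'
#' @param x Character vector of DNA strings (no gaps).
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("AAGG")  # "CCTT"
#' @export
reverse_complement <- function(x) {
  vapply(x, function(s) {
    .check_residues(s, allow_gap = FALSE, err_label = s)
    comp <- chartr(.IUPAC_FROM, .IUPAC_TO, s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

.orientations <- c("forward", "reverse")

#' Read a primer-panel table
#'
#' The file is a TSV with header
#' `name  target_species  orientation  sequence  expected_product_bp`.
#' Each `name` must occur exactly twice, once per orientation; primer
#' sequences are written 5'->3' and may not contain gaps.
#'
#' @param path Path to the TSV file.
#' @return A data frame of validated primer records (class `primer_table`).
#' @seealso [as_multiplex_panel()] to pair the records into a panel.
#' @export
read_primer_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("name", "target_species", "orientation", "sequence",
            "expected_product_bp")
  if (!identical(names(df)[seq_along(need)], need)) {
    stop("primer table must have header: ", paste(need, collapse = "\t"))
  }
  bad_or <- which(!df$orientation %in% .orientations)
  if (length(bad_or)) {
    stop(sprintf("row %d: orientation '%s' invalid; allowed values: %s",
                 bad_or[1], df$orientation[bad_or[1]],
                 paste(.orientations, collapse = ", ")))
  }
  df$sequence <- toupper(df$sequence)
  for (i in seq_len(nrow(df))) {
    .check_residues(df$sequence[i], allow_gap = FALSE, err_label = df$name[i])
  }
  key <- paste(df$name, df$orientation)
  if (anyDuplicated(key)) {
    stop("duplicate primer record: ", key[duplicated(key)][1])
  }
  prod <- suppressWarnings(as.integer(df$expected_product_bp))
  if (any(!is.na(prod) & prod <= 0L)) {
    stop("expected_product_bp must be a positive integer")
  }
  df$expected_product_bp <- prod
  # every name stem must have both mates
  tab <- table(df$name)
  lone <- names(tab)[tab != 2L]
  if (length(lone)) {
    stop("primer '", lone[1], "' is missing its mate (need one forward and one reverse record)")
  }
  class(df) <- c("primer_table", "data.frame")
  df
}

#' Write a primer table
#' @param primers A `primer_table` data frame (long format, one row per oligo).
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_primer_table <- function(primers, path) {
  out <- as.data.frame(primers)
  out$expected_product_bp[is.na(out$expected_product_bp)] <- ""
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pair primer records into a multiplex panel
#'
#' @param primers A `primer_table` from [read_primer_table()].
#' @param annealing_temp_c Optional annealing temperature recorded as panel
#'   metadata (the empirical reaction condition; not modelled).
#' @return A `multiplex_panel`: a list with `pairs` (one row per primer pair:
#'   `name`, `target_species`, `forward`, `reverse`, `expected_product_bp`),
#'   `annealing_temp_c`, and slots for `spacing_report` / `specificity_report`.
#' @export
as_multiplex_panel <- function(primers, annealing_temp_c = NA_real_) {
  stopifnot(is.data.frame(primers))
  fwd <- primers[primers$orientation == "forward", ]
  rev <- primers[primers$orientation == "reverse", ]
  rev <- rev[match(fwd$name, rev$name), ]
  if (any(is.na(rev$name))) stop("unpaired primer records")
  pairs <- data.frame(
    name = fwd$name,
    target_species = fwd$target_species,
    forward = fwd$sequence,
    reverse = rev$sequence,
    expected_product_bp = fwd$expected_product_bp,
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$target_species, pairs$name), ]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, annealing_temp_c = annealing_temp_c,
                 spacing_report = NULL, specificity_report = NULL),
            class = "multiplex_panel")
}

#' @export
print.multiplex_panel <- function(x, ...) {
  cat(sprintf("Multiplex panel: %d primer pairs\n", nrow(x$pairs)))
  print(x$pairs, row.names = FALSE)
  if (!is.na(x$annealing_temp_c)) {
    cat(sprintf("annealing temperature: %.1f C (empirical metadata)\n",
                x$annealing_temp_c))
  }
  invisible(x)
}

#' Pairwise product-size spacing of a panel
#'
#' @param panel A `multiplex_panel` whose pairs carry `expected_product_bp`.
#' @return A data frame of all unordered pair combinations with columns
#'   `name_a`, `name_b`, `delta_bp`, sorted by `delta_bp`.
#' @export
panel_spacing <- function(panel) {
  p <- panel$pairs
  if (any(is.na(p$expected_product_bp))) {
    stop("all panel pairs need expected_product_bp for a spacing report")
  }
  if (nrow(p) < 2L) {
    return(data.frame(name_a = character(), name_b = character(),
                      delta_bp = integer()))
  }
  cmb <- utils::combn(nrow(p), 2L)
  out <- data.frame(
    name_a = p$name[cmb[1, ]],
    name_b = p$name[cmb[2, ]],
    delta_bp = abs(p$expected_product_bp[cmb[1, ]] -
                   p$expected_product_bp[cmb[2, ]]),
    stringsAsFactors = FALSE
  )
  out[order(out$delta_bp, out$name_a, out$name_b), , drop = FALSE]
}

#' Read a band-pattern table
#'
#' One row per sample; the `bands` column holds comma-separated integer band
#' sizes in base pairs. An empty cell means the sample did not amplify.
#'
#' @param path Path to a TSV with header `sample_id  bands`.
#' @return A data frame with `sample_id` and a list-column `bands` of sorted
#'   integer vectors (possibly length 0).
#' @export
read_band_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("sample_id", "bands") %in% names(df))) {
    stop("band table must have header: sample_id\tbands")
  }
  bands <- lapply(df$bands, function(cell) {
    cell <- trimws(cell)
    if (is.na(cell) || !nzchar(cell)) return(integer())
    v <- suppressWarnings(as.integer(strsplit(cell, ",", fixed = TRUE)[[1]]))
    if (any(is.na(v)) || any(v <= 0L)) {
      stop("band sizes must be positive integers, got: ", cell)
    }
    sort(v)
  })
  data.frame(sample_id = df$sample_id, bands = I(bands),
             stringsAsFactors = FALSE)
}

#' Write a band-pattern table
#' @param obs Data frame with `sample_id` and list-column `bands`.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_band_table <- function(obs, path) {
  cells <- vapply(obs$bands, function(v) paste(sort(v), collapse = ","),
                  character(1))
  utils::write.table(
    data.frame(sample_id = obs$sample_id, bands = cells),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
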