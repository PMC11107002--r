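# Mismatch-tolerant in-silico PCR: binding-site search, amplicon prediction,
# multiplex band simulation, rule-based species calling, gel rendering.

#' Primer-annealing mismatch model
#'
#' A primer is considered to anneal when its total mismatch count against the
#' template does not exceed `max_total` and the mismatches falling inside the
#' 3'-terminal window do not exceed `max_three_prime`. Matching is IUPAC-aware
#' (a position matches when the two base sets intersect). The defaults are
#' deliberately conservative; real specificity is also annealing-temperature
#' dependent, which this model does not capture, so positive predictions
#' should be verified empirically.
#'
#' @param max_total Maximum mismatches over the whole primer (default 2).
#' @param three_prime_window Length of the 3'-terminal window (default 4).
#' @param max_three_prime Maximum mismatches allowed inside that window
#'   (default 0).
#' @return A `mismatch_model` list.
#' @export
mismatch_model <- function(max_total = 2L, three_prime_window = 4L,
                           max_three_prime = 0L) {
  stopifnot(max_total >= 0L, three_prime_window >= 1L, max_three_prime >= 0L)
  structure(list(max_total = as.integer(max_total),
                 three_prime_window = as.integer(three_prime_window),
                 max_three_prime = as.integer(max_three_prime)),
            class = "mismatch_model")
}

# per-code mismatch lookup rows: mmrows[[code]][template_code_index] is TRUE
# when the two IUPAC sets are disjoint
.mm_rows <- function() {
  if (is.null(.pkg_env$mm_rows)) {
    compat <- .compat_matrix()
    .pkg_env$mm_rows <- lapply(stats::setNames(rownames(compat),
                                               rownames(compat)),
                               function(code) !compat[code, ])
  }
  .pkg_env$mm_rows
}

# mismatch counts of a primer char vector against every window of a template
# (given as integer indices into the compat alphabet); returns
# list(total, three_prime) of length n - L + 1. three-prime mismatches are
# counted over the primer positions in tp_idx.
.scan_mismatches <- function(p_chars, t_i, tp_idx) {
  n <- length(t_i); L <- length(p_chars)
  mmrows <- .mm_rows()
  n_win <- n - L + 1L
  total <- integer(n_win); three <- integer(n_win)
  offs <- seq_len(n_win) - 1L
  for (j in seq_len(L)) {
    mm <- mmrows[[p_chars[j]]][t_i[offs + j]]
    total <- total + mm
    if (j %in% tp_idx) three <- three + mm
  }
  list(total = total, three_prime = three)
}

#' Find primer binding sites on a template
#'
#' Brute-force scan of both strands of an ungapped template for sites where
#' the primer anneals under the mismatch model. Positions are 1-based starts
#' of the primer footprint on the plus strand. On the minus strand the
#' primer's 3' terminus corresponds to the low-coordinate end of the
#' footprint.
#'
#' @param primer Primer sequence, 5'->3' (IUPAC, no gaps).
#' @param template A residue string, or a one-row sequence table.
#' @param model A [mismatch_model()].
#' @param template_id Identifier used in the output (taken from the sequence
#'   table when one is supplied).
#' @param strands Strands to scan (default both).
#' @return Data frame with columns `template_id`, `position`, `strand`
#'   (`"plus"`/`"minus"`), `mismatch_total`, `mismatch_3prime`, sorted by
#'   position. Empty when the template is shorter than the primer.
#' @export
find_binding_sites <- function(primer, template, model = mismatch_model(),
                               template_id = "template",
                               strands = c("plus", "minus")) {
  if (is.data.frame(template)) {
    template_id <- template$id[1]
    template <- template$residues[1]
  }
  empty <- data.frame(template_id = character(), position = integer(),
                      strand = character(), mismatch_total = integer(),
                      mismatch_3prime = integer(), stringsAsFactors = FALSE)
  if (!nzchar(template) || nchar(template) < nchar(primer)) return(empty)
  .check_residues(primer, allow_gap = FALSE, err_label = "primer")
  .check_residues(template, allow_gap = FALSE, err_label = template_id)
  p <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  t_chars <- strsplit(toupper(template), "", fixed = TRUE)[[1]]
  t_i <- match(t_chars, names(.mm_rows()))
  L <- length(p)
  w <- min(model$three_prime_window, L)
  keep_plus <- integer(0); keep_minus <- integer(0)
  plus <- minus <- NULL
  if ("plus" %in% strands) {
    # plus strand: primer 3' end is the high-coordinate end of the footprint
    plus <- .scan_mismatches(p, t_i, tp_idx = (L - w + 1L):L)
    keep_plus <- which(plus$total <= model$max_total &
                       plus$three_prime <= model$max_three_prime)
  }
  if ("minus" %in% strands) {
    # minus strand: compare the reverse complement; after
    # reverse-complementing, the primer's 3'-terminal bases sit at the start
    # of the footprint
    q <- strsplit(reverse_complement(paste(p, collapse = "")), "",
                  fixed = TRUE)[[1]]
    minus <- .scan_mismatches(q, t_i, tp_idx = 1L:w)
    keep_minus <- which(minus$total <= model$max_total &
                        minus$three_prime <= model$max_three_prime)
  }
  out <- rbind(
    if (length(keep_plus)) data.frame(
      template_id = template_id, position = keep_plus, strand = "plus",
      mismatch_total = plus$total[keep_plus],
      mismatch_3prime = plus$three_prime[keep_plus],
      stringsAsFactors = FALSE) else empty,
    if (length(keep_minus)) data.frame(
      template_id = template_id, position = keep_minus, strand = "minus",
      mismatch_total = minus$total[keep_minus],
      mismatch_3prime = minus$three_prime[keep_minus],
      stringsAsFactors = FALSE) else empty
  )
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Predict PCR amplicons of a primer pair on a template
#'
#' Every combination of a plus-strand forward site and a minus-strand reverse
#' site in convergent orientation whose product length falls inside the
#' allowed range yields one amplicon. The product spans from the forward
#' footprint start to the reverse footprint end, inclusive of both primer
#' footprints.
#'
#' @param forward,reverse Primer sequences, 5'->3'.
#' @param template Residue string or one-row sequence table.
#' @inheritParams find_binding_sites
#' @param product_min,product_max Allowed product length range in bp.
#' @param pair_name Label copied to the output.
#' @return Data frame with columns `pair_name`, `template_id`, `start`, `end`,
#'   `length_bp`, sorted by `start`, `end`.
#' @export
predict_amplicons <- function(forward, reverse, template,
                              model = mismatch_model(),
                              product_min = 50L, product_max = 2000L,
                              pair_name = "pair", template_id = "template") {
  if (is.data.frame(template)) {
    template_id <- template$id[1]
    template <- template$residues[1]
  }
  empty <- data.frame(pair_name = character(), template_id = character(),
                      start = integer(), end = integer(),
                      length_bp = integer(), stringsAsFactors = FALSE)
  if (!nzchar(template)) return(empty)
  f_sites <- find_binding_sites(forward, template, model, template_id,
                                strands = "plus")
  if (!nrow(f_sites)) return(empty)
  r_sites <- find_binding_sites(reverse, template, model, template_id,
                                strands = "minus")
  if (!nrow(r_sites)) return(empty)
  rev_len <- nchar(reverse)
  combos <- expand.grid(f = f_sites$position, r = r_sites$position)
  combos$end <- combos$r + rev_len - 1L
  combos$len <- combos$end - combos$f + 1L
  combos <- combos[combos$r >= combos$f & combos$len >= product_min &
                   combos$len <= product_max, , drop = FALSE]
  if (!nrow(combos)) return(empty)
  out <- data.frame(pair_name = pair_name, template_id = template_id,
                    start = combos$f, end = combos$end,
                    length_bp = combos$len, stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a multiplex PCR over templates
#'
#' Runs every primer pair of the panel against every template and reports, per
#' template, the union of predicted amplicon lengths - the band sizes a gel
#' lane would show. Presence/absence only; no intensity model. Templates with
#' empty residues (failed extractions) yield empty band lists.
#'
#' @param panel A `multiplex_panel`.
#' @param templates Sequence table (data frame with `id`, `residues`).
#' @inheritParams predict_amplicons
#' @return Band-observation data frame: `sample_id` plus list-column `bands`
#'   of sorted unique integer band sizes.
#' @export
simulate_multiplex <- function(panel, templates, model = mismatch_model(),
                               product_min = 50L, product_max = 2000L) {
  stopifnot(inherits(panel, "multiplex_panel"))
  bands <- lapply(seq_len(nrow(templates)), function(i) {
    tpl <- templates$residues[i]
    if (is.na(tpl) || !nzchar(tpl)) return(integer())
    sizes <- integer()
    for (k in seq_len(nrow(panel$pairs))) {
      amp <- predict_amplicons(panel$pairs$forward[k], panel$pairs$reverse[k],
                               tpl, model, product_min, product_max,
                               pair_name = panel$pairs$name[k],
                               template_id = templates$id[i])
      sizes <- c(sizes, amp$length_bp)
    }
    sort(unique(sizes))
  })
  data.frame(sample_id = templates$id, bands = I(bands),
             stringsAsFactors = FALSE)
}

#' Default band-interpretation priority rules
#'
#' Rules are data, not code: an ordered table of band patterns (sets of
#' matched target species) and the call each resolves to. The shipped default
#' encodes the interpretation that a lane showing both the lineage B and
#' lineage G product sizes is lineage G, because the lineage B primers can
#' cross-amplify lineage G DNA at multiplex annealing temperatures while the
#' reverse does not occur.
#'
#' @return Data frame with columns `pattern` (species labels joined by
#'   `" + "`) and `call`, in priority order.
#' @export
default_priority_rules <- function() {
  path <- system.file("extdata", "default_rules.tsv", package = "ampliplex")
  if (nzchar(path)) return(read_priority_rules(path))
  data.frame(pattern = "lineage B + lineage G", call = "lineage G",
             stringsAsFactors = FALSE)
}

#' Read a priority-rules table
#' @param path TSV with header `pattern  call`; `pattern` lists target species
#'   joined by `" + "`.
#' @return Data frame of rules in file order (highest priority first).
#' @export
read_priority_rules <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("pattern", "call") %in% names(df))) {
    stop("rules table must have header: pattern\tcall")
  }
  df
}

.pattern_key <- function(species) paste(sort(unique(species)), collapse = " + ")

#' Call a species from an observed band pattern
#'
#' Bands are matched to the panel's expected product sizes within a size
#' tolerance. Bands larger than the panel's largest expected size plus the
#' tolerance are ignored as non-specific amplification (they cannot collide
#' with any diagnostic product). No matched band gives `unidentified`; one
#' matched species gives that species; several matched species are resolved by
#' the priority rules, and `ambiguous` when no rule applies. Every band set
#' maps to exactly one call.
#'
#' @param bands Integer vector of observed band sizes in bp (may be empty).
#' @param panel A `multiplex_panel` whose pairs carry `expected_product_bp`.
#' @param tolerance_bp Band-size matching tolerance in bp (default 10,
#'   reflecting agarose sizing precision).
#' @param rules Priority-rules data frame (see [default_priority_rules()]).
#' @param sample_id Label copied to the output row.
#' @return One-row data frame: `sample_id`, `call`, `matched_bands`
#'   (`size=species`, `;`-joined), `ignored_bands`, `rationale`.
#' @export
call_species <- function(bands, panel, tolerance_bp = 10L,
                         rules = default_priority_rules(),
                         sample_id = "sample") {
  stopifnot(inherits(panel, "multiplex_panel"))
  if (is.na(tolerance_bp) || tolerance_bp < 0) {
    stop("tolerance_bp must be >= 0")
  }
  expected <- panel$pairs$expected_product_bp
  if (any(is.na(expected))) {
    stop("all panel pairs need expected_product_bp for species calling")
  }
  species <- panel$pairs$target_species
  bands <- sort(unique(as.integer(bands)))
  max_expected <- max(expected)
  ignored <- bands[bands > max_expected + tolerance_bp]
  usable <- setdiff(bands, ignored)
  matched <- character(0)
  matched_txt <- character(0)
  unexplained <- integer(0)
  for (b in usable) {
    hit <- which(abs(expected - b) <= tolerance_bp)
    if (length(hit)) {
      matched <- c(matched, species[hit])
      matched_txt <- c(matched_txt, paste0(b, "=", species[hit]))
    } else {
      unexplained <- c(unexplained, b)
    }
  }
  matched <- unique(matched)
  note <- character(0)
  if (length(ignored)) {
    note <- c(note, sprintf("band(s) %s above panel maximum %d + %d bp ignored as non-specific",
                            paste(ignored, collapse = ","), max_expected,
                            as.integer(tolerance_bp)))
  }
  if (length(unexplained)) {
    note <- c(note, sprintf("unexplained band(s) %s within the diagnostic size range",
                            paste(unexplained, collapse = ",")))
  }
  if (length(matched) == 0L) {
    call <- "unidentified"
    rationale <- "no band matched an expected product size"
  } else if (length(matched) == 1L) {
    call <- matched
    rationale <- sprintf("single expected-size match: %s",
                         paste(matched_txt, collapse = ";"))
  } else {
    key <- .pattern_key(matched)
    rule_keys <- vapply(strsplit(rules$pattern, "+", fixed = TRUE),
                        function(p) .pattern_key(trimws(p)), character(1))
    hit <- which(rule_keys == key)
    if (length(hit)) {
      call <- rules$call[hit[1]]
      rationale <- sprintf("multiple matches (%s) resolved by priority rule '%s' -> %s",
                           key, rules$pattern[hit[1]], call)
    } else {
      call <- "ambiguous"
      rationale <- sprintf("multiple expected-size matches with no priority rule: %s",
                           key)
    }
  }
  if (length(note)) rationale <- paste(c(rationale, note), collapse = "; ")
  data.frame(sample_id = sample_id, call = call,
             matched_bands = paste(matched_txt, collapse = ";"),
             ignored_bands = paste(ignored, collapse = ","),
             rationale = rationale, stringsAsFactors = FALSE)
}

#' Call species for a whole band table
#'
#' @param obs Band-observation data frame (`sample_id`, list-column `bands`).
#' @inheritParams call_species
#' @return Data frame with one call row per sample.
#' @export
call_cohort <- function(obs, panel, tolerance_bp = 10L,
                        rules = default_priority_rules()) {
  out <- lapply(seq_len(nrow(obs)), function(i) {
    call_species(obs$bands[[i]], panel, tolerance_bp, rules,
                 sample_id = obs$sample_id[i])
  })
  do.call(rbind, out)
}

#' Render band observations as a text gel
#'
#' A deterministic lane diagram: rows are band sizes ascending, the first lane
#' is the size ladder. Bands within one lane closer than
#' `merge_below_bp` are drawn merged and annotated as unresolvable, mirroring
#' the readability limit that motivates minimum product-size spacing.
#'
#' @param obs Band-observation data frame.
#' @param ladder Ladder mark sizes in bp (default 100 bp ladder to 1000).
#' @param merge_below_bp Bands closer than this merge into one row.
#' @return Character vector of lines (class `gel_render`).
#' @export
render_lanes <- function(obs, ladder = seq(100L, 1000L, by = 100L),
                         merge_below_bp = 55L) {
  ladder <- sort(unique(as.integer(ladder)))
  lanes <- obs$sample_id
  # cluster each lane's bands: adjacent sizes closer than merge_below_bp merge
  clusters <- lapply(obs$bands, function(b) {
    b <- sort(unique(as.integer(b)))
    if (!length(b)) return(list())
    grp <- cumsum(c(1L, diff(b) >= merge_below_bp))
    lapply(split(b, grp), function(v) {
      list(size = as.integer(round(mean(v))), members = v,
           merged = length(v) > 1L)
    })
  })
  row_sizes <- sort(unique(c(ladder,
                             unlist(lapply(clusters, function(cl)
                               vapply(cl, `[[`, integer(1), "size"))))))
  wlab <- max(nchar(as.character(row_sizes)), 4L)
  wlane <- max(nchar(lanes), 6L, 0L)
  header <- sprintf(paste0("%", wlab, "s bp  %-6s"), "size", "ladder")
  for (ln in lanes) header <- paste0(header, sprintf(" %-*s", wlane, ln))
  lines <- header
  notes <- character(0)
  for (s in row_sizes) {
    row <- sprintf(paste0("%", wlab, "d bp  %-6s"), s,
                   if (s %in% ladder) "====" else "")
    for (i in seq_along(lanes)) {
      cl <- clusters[[i]]
      hit <- ""
      for (c0 in cl) {
        if (c0$size == s) {
          hit <- if (c0$merged) "####*" else "####"
          if (c0$merged) {
            notes <- c(notes, sprintf(
              "* lane %s: bands %s closer than %d bp drawn merged (unresolvable)",
              lanes[i], paste(c0$members, collapse = ","),
              as.integer(merge_below_bp)))
          }
        }
      }
      row <- paste0(row, sprintf(" %-*s", wlane, hit))
    }
    lines <- c(lines, row)
  }
  structure(c(lines, unique(notes)), class = "gel_render")
}

#' @export
print.gel_render <- function(x, ...) {
  cat(unclass(x), sep = "\n")
  invisible(x)
}
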