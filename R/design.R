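# Discriminative primer design: candidate enumeration under Primer3-style
# constraints, cross-amplification screening, and multiplex panel search
# under product-size spacing constraints.

#' Primer design parameters
#'
#' Defaults follow the constraint set commonly used for species-diagnostic
#' barcode primers: 20 bp optimum length (18-23), 59 degC optimum annealing
#' temperature (57-62), 50 % optimum GC (30-70), and a minimum difference of
#' 55 bp between the product sizes of panel members so neighbouring bands stay
#' readable on an agarose gel.
#'
#' @param length_min,length_opt,length_max Primer length bounds (bp).
#' @param tm_min,tm_opt,tm_max Melting-temperature bounds (degC).
#' @param gc_min,gc_opt,gc_max GC-content bounds (percent).
#' @param min_product_spacing_bp Minimum pairwise product-size difference
#'   within a panel (bp).
#' @param product_min_bp,product_max_bp Allowed product-size range (bp).
#' @param max_plex Maximum number of primer pairs in one multiplex reaction.
#' @param max_total_mismatches,three_prime_window,max_three_prime_mismatches
#'   Annealing mismatch model (see [mismatch_model()]).
#' @param tm_window_c Maximum Tm spread among all primers of a panel (degC).
#' @param min_discrimination Minimum discriminative positions each primer must
#'   have against every non-target species; at least one of them must fall in
#'   the 3'-terminal window.
#' @param na_mM,mg_mM,dntp_mM,oligo_nM Tm chemistry (see
#'   [melting_temperature()]).
#' @param max_candidates_per_strand,max_pairs_per_species Search-size caps;
#'   candidates/pairs are kept in score order, pairs additionally spread over
#'   distinct product sizes.
#' @return A `design_params` list.
#' @export
design_params <- function(length_min = 18L, length_opt = 20L, length_max = 23L,
                          tm_min = 57, tm_opt = 59, tm_max = 62,
                          gc_min = 30, gc_opt = 50, gc_max = 70,
                          min_product_spacing_bp = 55L,
                          product_min_bp = 100L, product_max_bp = 600L,
                          max_plex = 4L,
                          max_total_mismatches = 2L,
                          three_prime_window = 4L,
                          max_three_prime_mismatches = 0L,
                          tm_window_c = 5,
                          min_discrimination = 1L,
                          na_mM = 50, mg_mM = 1.5, dntp_mM = 0.6,
                          oligo_nM = 50,
                          max_candidates_per_strand = 60L,
                          max_pairs_per_species = 60L) {
  p <- list(length_min = as.integer(length_min),
            length_opt = as.integer(length_opt),
            length_max = as.integer(length_max),
            tm_min = tm_min, tm_opt = tm_opt, tm_max = tm_max,
            gc_min = gc_min, gc_opt = gc_opt, gc_max = gc_max,
            min_product_spacing_bp = as.integer(min_product_spacing_bp),
            product_min_bp = as.integer(product_min_bp),
            product_max_bp = as.integer(product_max_bp),
            max_plex = as.integer(max_plex),
            model = mismatch_model(max_total_mismatches, three_prime_window,
                                   max_three_prime_mismatches),
            tm_window_c = tm_window_c,
            min_discrimination = as.integer(min_discrimination),
            na_mM = na_mM, mg_mM = mg_mM, dntp_mM = dntp_mM,
            oligo_nM = oligo_nM,
            max_candidates_per_strand = as.integer(max_candidates_per_strand),
            max_pairs_per_species = as.integer(max_pairs_per_species))
  for (triple in list(c("length_min", "length_opt", "length_max"),
                      c("tm_min", "tm_opt", "tm_max"),
                      c("gc_min", "gc_opt", "gc_max"))) {
    v <- unlist(p[triple])
    if (!(v[1] <= v[2] && v[2] <= v[3])) {
      stop("design_params: need ", triple[1], " <= ", triple[2], " <= ",
           triple[3])
    }
  }
  if (p$min_product_spacing_bp <= 0L) stop("min_product_spacing_bp must be > 0")
  structure(p, class = "design_params")
}

#' GC content of a sequence, in percent
#' @param sequence Character vector of DNA strings.
#' @return Numeric vector of GC percentages.
#' @export
gc_content <- function(sequence) {
  vapply(sequence, function(s) {
    ch <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    100 * sum(ch %in% c("G", "C")) / length(ch)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Enumerate admissible primer candidates for one species
#'
#' Every window of admissible length on the species consensus, on both
#' strands, that contains no gap, no ambiguity code and no intraspecific
#' polymorphic column (so all conspecific individuals amplify) and whose
#' length, Tm and GC fall inside the parameter bounds. Each candidate is
#' annotated with its discriminative-position counts against every other
#' profile, both over the whole window and inside the 3'-terminal window.
#' Candidates are sorted by a score that weighs closeness to the length/Tm/GC
#' optima and the minimum discrimination equally.
#'
#' @param profile Target `species_profile`.
#' @param all_profiles List of all `species_profile` objects on the same
#'   master alignment (the target may be included; it is skipped).
#' @param params A [design_params()].
#' @return Data frame (class `primer_candidates`): `species`, `strand`,
#'   `start`, `end`, `length`, `sequence` (5'->3'), `tm_c`, `gc_pct`,
#'   `polymorphic_overlap` (always 0 by construction), `disc_min`,
#'   `disc3_min`, `score`, plus list-columns `disc` and `disc3` of per-species
#'   counts. Empty (zero rows) when no window qualifies.
#' @export
enumerate_candidates <- function(profile, all_profiles, params = design_params()) {
  stopifnot(inherits(profile, "species_profile"))
  others <- Filter(function(p) p$species != profile$species, all_profiles)
  if (!length(others)) {
    stop("enumerate_candidates: need at least one non-target profile to score discrimination")
  }
  validate_shared_alignment(c(list(profile), others))
  chars <- strsplit(profile$consensus, "", fixed = TRUE)[[1]]
  L <- length(chars)
  bad <- !(chars %in% .BASES)
  bad[profile$polymorphic_columns] <- TRUE
  cum_bad <- c(0L, cumsum(bad))
  cum_gc <- c(0L, cumsum(chars %in% c("G", "C")))
  other_names <- vapply(others, function(p) p$species, character(1))
  cum_dj <- lapply(others, function(o) {
    oc <- strsplit(o$consensus, "", fixed = TRUE)[[1]]
    c(0L, cumsum(.disjoint_columns(chars, oc)))
  })
  # strict variant against the degenerate consensus: a column only counts
  # when the target base is disjoint from every base observed in the other
  # species, so a mismatch there blocks annealing for all its individuals
  cum_djs <- lapply(others, function(o) {
    oc <- strsplit(o$degenerate_consensus, "", fixed = TRUE)[[1]]
    c(0L, cumsum(.disjoint_columns(chars, oc)))
  })
  rows <- list()
  for (Lw in params$length_min:params$length_max) {
    if (L < Lw) next
    tm_all <- .tm_windows(chars, Lw, na_mM = params$na_mM,
                          mg_mM = params$mg_mM, dntp_mM = params$dntp_mM,
                          oligo_nM = params$oligo_nM)
    starts <- seq_len(L - Lw + 1L)
    keep <- (cum_bad[starts + Lw] - cum_bad[starts]) == 0L
    starts <- starts[keep]
    if (!length(starts)) next
    ends <- starts + Lw - 1L
    gc <- 100 * (cum_gc[ends + 1L] - cum_gc[starts]) / Lw
    tm <- tm_all[starts]
    ok <- gc >= params$gc_min & gc <= params$gc_max &
      !is.na(tm) & tm >= params$tm_min & tm <= params$tm_max
    starts <- starts[ok]; ends <- ends[ok]; gc <- gc[ok]; tm <- tm[ok]
    if (!length(starts)) next
    w3 <- min(params$model$three_prime_window, Lw)
    disc_tot <- sapply(cum_dj, function(cd) cd[ends + 1L] - cd[starts])
    disc_tot <- matrix(disc_tot, nrow = length(starts))
    # 3' window: high-coordinate end for plus-strand, low end for minus
    disc3_plus <- sapply(cum_dj, function(cd) cd[ends + 1L] - cd[ends - w3 + 1L])
    disc3_minus <- sapply(cum_dj, function(cd) cd[starts + w3] - cd[starts])
    disc3_plus <- matrix(disc3_plus, nrow = length(starts))
    disc3_minus <- matrix(disc3_minus, nrow = length(starts))
    disc3s_plus <- sapply(cum_djs, function(cd) cd[ends + 1L] - cd[ends - w3 + 1L])
    disc3s_minus <- sapply(cum_djs, function(cd) cd[starts + w3] - cd[starts])
    disc3s_plus <- matrix(disc3s_plus, nrow = length(starts))
    disc3s_minus <- matrix(disc3s_minus, nrow = length(starts))
    seq_plus <- substring(profile$consensus, starts, ends)
    for (strand in c("plus", "minus")) {
      d3 <- if (strand == "plus") disc3_plus else disc3_minus
      d3s <- if (strand == "plus") disc3s_plus else disc3s_minus
      seqs <- if (strand == "plus") seq_plus else reverse_complement(seq_plus)
      rows[[length(rows) + 1L]] <- data.frame(
        species = profile$species, strand = strand,
        start = starts, end = ends, length = Lw,
        sequence = seqs, tm_c = tm, gc_pct = gc,
        polymorphic_overlap = 0L,
        disc_min = apply(disc_tot, 1L, min),
        disc3_min = apply(d3, 1L, min),
        disc = I(lapply(seq_along(starts), function(i)
          stats::setNames(disc_tot[i, ], other_names))),
        disc3 = I(lapply(seq_along(starts), function(i)
          stats::setNames(d3[i, ], other_names))),
        disc3_strict = I(lapply(seq_along(starts), function(i)
          stats::setNames(d3s[i, ], other_names))),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    out <- data.frame(species = character(), strand = character(),
                      start = integer(), end = integer(), length = integer(),
                      sequence = character(), tm_c = numeric(),
                      gc_pct = numeric(), polymorphic_overlap = integer(),
                      disc_min = integer(), disc3_min = integer(),
                      score = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("primer_candidates", "data.frame")
    return(out)
  }
  out <- do.call(rbind, rows)
  out$score <- out$disc_min -
    (abs(out$tm_c - params$tm_opt) +
       abs(out$gc_pct - params$gc_opt) / 10 +
       abs(out$length - params$length_opt))
  out <- out[order(-out$score, out$start, out$length,
                   match(out$strand, c("plus", "minus"))), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("primer_candidates", "data.frame")
  out
}

#' Pair forward and reverse candidates into candidate pairs
#'
#' Combines plus-strand (forward) and downstream minus-strand (reverse)
#' candidates of one species. The product size is measured on the gap-stripped
#' target consensus from the forward footprint start to the reverse footprint
#' end, inclusive of both primer footprints - the length the gel band would
#' run at. Each primer must have at least `min_discrimination` discriminative
#' positions against every other species, and for every other species at
#' least one of the two primers must carry a discriminative position inside
#' its 3'-terminal window - exactly the condition under which the default
#' mismatch model forbids annealing to that species. Pairs are kept in score
#' order, at most one per 10 bp product-size bin, capped at
#' `max_pairs_per_species`.
#'
#' @param candidates Output of [enumerate_candidates()] for the species.
#' @param profile The species' `species_profile`.
#' @param params A [design_params()].
#' @return Data frame (class `candidate_pairs`): `species`, forward/reverse
#'   coordinates and sequences, `tm_f`, `tm_r`, `product_bp`, `disc_min`,
#'   `score`.
#' @export
enumerate_pairs <- function(candidates, profile, params = design_params()) {
  empty <- data.frame(species = character(), fwd_start = integer(),
                      fwd_end = integer(), fwd_seq = character(),
                      tm_f = numeric(), rev_start = integer(),
                      rev_end = integer(), rev_seq = character(),
                      tm_r = numeric(), product_bp = integer(),
                      disc_min = integer(), score = numeric(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("candidate_pairs", "data.frame")
  if (!nrow(candidates)) return(empty)
  adm <- candidates[candidates$disc_min >= params$min_discrimination, ,
                    drop = FALSE]
  fwd <- adm[adm$strand == "plus", , drop = FALSE]
  rev <- adm[adm$strand == "minus", , drop = FALSE]
  k <- params$max_candidates_per_strand
  if (nrow(fwd) > k) fwd <- fwd[seq_len(k), ]
  if (nrow(rev) > k) rev <- rev[seq_len(k), ]
  if (!nrow(fwd) || !nrow(rev)) return(empty)
  chars <- strsplit(profile$consensus, "", fixed = TRUE)[[1]]
  cum_ng <- c(0L, cumsum(chars != "-"))
  combos <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
  fs <- fwd$start[combos$f]; fe <- fwd$end[combos$f]
  rs <- rev$start[combos$r]; re <- rev$end[combos$r]
  product <- cum_ng[re + 1L] - cum_ng[fs]
  ok <- rs > fe & product >= params$product_min_bp &
    product <= params$product_max_bp
  # per non-target species, at least one primer of the pair must carry a
  # strict 3'-window discriminative position (disjoint from every base
  # observed in that species), which blocks annealing under the model for
  # every non-target individual, not just the consensus
  if (params$min_discrimination > 0L && nrow(fwd) &&
      length(fwd$disc3_strict[[1]])) {
    f3 <- do.call(rbind, fwd$disc3_strict)
    r3 <- do.call(rbind, rev$disc3_strict)
    pair3_ok <- rowSums((f3[combos$f, , drop = FALSE] >= 1L) |
                        (r3[combos$r, , drop = FALSE] >= 1L)) == ncol(f3)
    ok <- ok & pair3_ok
  }
  combos <- combos[ok, , drop = FALSE]
  product <- product[ok]
  if (!nrow(combos)) return(empty)
  out <- data.frame(
    species = profile$species,
    fwd_start = fwd$start[combos$f], fwd_end = fwd$end[combos$f],
    fwd_seq = fwd$sequence[combos$f], tm_f = fwd$tm_c[combos$f],
    rev_start = rev$start[combos$r], rev_end = rev$end[combos$r],
    rev_seq = rev$sequence[combos$r], tm_r = rev$tm_c[combos$r],
    product_bp = as.integer(product),
    disc_min = pmin(fwd$disc_min[combos$f], rev$disc_min[combos$r]),
    score = fwd$score[combos$f] + rev$score[combos$r],
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$score, out$fwd_start, out$rev_start), , drop = FALSE]
  bin <- out$product_bp %/% 10L
  out <- out[!duplicated(bin), , drop = FALSE]
  if (nrow(out) > params$max_pairs_per_species) {
    out <- out[seq_len(params$max_pairs_per_species), ]
  }
  rownames(out) <- NULL
  class(out) <- c("candidate_pairs", "data.frame")
  out
}

#' Predict cross-amplification of a primer pair on a non-target species
#'
#' TRUE when both primers anneal to the other species' gap-stripped consensus
#' under the mismatch model in convergent orientation with a product inside
#' the allowed size range. With `template = "degenerate"` the scan runs
#' against the per-column IUPAC union of every base observed in the other
#' species, so amplification of any (even rare) non-target haplotype is
#' flagged - mirroring specificity testing against individual non-target
#' specimens rather than a single reference. The model is sequence-based
#' only; annealing temperature effects are not captured, so a positive
#' prediction carries a "verify empirically" note.
#'
#' @param pair One-row `candidate_pairs` data frame, or any list with
#'   `fwd_seq` and `rev_seq`.
#' @param other Non-target `species_profile`.
#' @param model A [mismatch_model()].
#' @param product_min,product_max Product-size bounds in bp.
#' @param template Scan against the `"consensus"` (default) or the
#'   `"degenerate"` any-individual consensus.
#' @param detail When `TRUE`, also report each primer's best (fewest-mismatch)
#'   binding site on the non-target consensus regardless of the model.
#' @return List with `amplifies` (logical), `amplicons` (data frame),
#'   `detail` (best per-primer mismatch counts, or `NULL`) and `note`.
#' @export
predict_cross_amplification <- function(pair, other, model = mismatch_model(),
                                        product_min = 100L,
                                        product_max = 600L,
                                        template = c("consensus", "degenerate"),
                                        detail = TRUE) {
  stopifnot(inherits(other, "species_profile"))
  template <- match.arg(template)
  template <- gsub("-", "", if (template == "degenerate")
    other$degenerate_consensus else other$consensus, fixed = TRUE)
  amp <- predict_amplicons(pair$fwd_seq, pair$rev_seq, template, model,
                           product_min, product_max,
                           pair_name = paste0(pair$species %||% "pair"),
                           template_id = other$species)
  det <- if (!detail) NULL else
    lapply(c(forward = pair$fwd_seq, reverse = pair$rev_seq), function(p) {
      sites <- find_binding_sites(p, template, mismatch_model(
        max_total = nchar(p), three_prime_window = model$three_prime_window,
        max_three_prime = nchar(p)), template_id = other$species)
      if (!nrow(sites)) return(NULL)
      sites[which.min(sites$mismatch_total), , drop = FALSE]
    })
  list(amplifies = nrow(amp) > 0L, amplicons = amp, detail = det,
       note = if (nrow(amp) > 0L)
         "predicted cross-amplification: verify empirically (annealing-temperature effects are not modelled)"
       else "no predicted cross-amplification under the mismatch model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# cross-amplification sets for every pair of every species vs the profiles
# of the given species set
.cross_amp_sets <- function(pairs_by_species, profiles, params) {
  prof_names <- vapply(profiles, function(p) p$species, character(1))
  names(profiles) <- prof_names
  lapply(pairs_by_species, function(pr) {
    lapply(seq_len(nrow(pr)), function(i) {
      hits <- character(0)
      for (o in setdiff(prof_names, pr$species[i])) {
        res <- predict_cross_amplification(pr[i, ], profiles[[o]],
                                           params$model,
                                           params$product_min_bp,
                                           params$product_max_bp,
                                           template = "degenerate",
                                           detail = FALSE)
        if (res$amplifies) hits <- c(hits, o)
      }
      hits
    })
  })
}

# depth-first search for the best feasible assignment of one pair per species
# in `spp`; deterministic, with a node cap. Returns NULL or a list of row
# indices into pairs_by_species.
.search_assignment <- function(spp, pairs_by_species, cross, params,
                               node_cap = 200000L) {
  spp <- sort(spp)
  n_sp <- length(spp)
  prods <- lapply(spp, function(s) as.numeric(pairs_by_species[[s]]$product_bp))
  discs <- lapply(spp, function(s) as.numeric(pairs_by_species[[s]]$disc_min))
  tmfs <- lapply(spp, function(s) as.numeric(pairs_by_species[[s]]$tm_f))
  tmrs <- lapply(spp, function(s) as.numeric(pairs_by_species[[s]]$tm_r))
  # TRUE when pair i of species s cross-amplifies some species of the subset
  blocked <- lapply(seq_len(n_sp), function(si) {
    if (is.null(cross)) return(rep(FALSE, length(prods[[si]])))
    vapply(cross[[spp[si]]], function(h) length(intersect(h, spp)) > 0L,
           logical(1))
  })
  min_sp_req <- params$min_product_spacing_bp
  tm_win <- params$tm_window_c
  best <- NULL
  best_key <- c(-Inf, -Inf)
  nodes <- 0L
  chosen <- integer(n_sp)
  chosen_prod <- numeric(n_sp)
  recurse <- function(level, cur_sp, cur_disc, tmin, tmax) {
    if (nodes > node_cap) return()
    if (level > n_sp) {
      if (cur_sp > best_key[1] ||
          (cur_sp == best_key[1] && cur_disc > best_key[2])) {
        best_key <<- c(cur_sp, cur_disc)
        best <<- chosen[seq_len(n_sp)]
      }
      return()
    }
    pv <- prods[[level]]
    for (i in seq_along(pv)) {
      nodes <<- nodes + 1L
      if (nodes > node_cap) return()
      if (blocked[[level]][i]) next
      nsp <- cur_sp
      if (level > 1L) {
        gap <- min(abs(chosen_prod[seq_len(level - 1L)] - pv[i]))
        if (gap < min_sp_req) next
        nsp <- min(cur_sp, gap)
        # bound: min spacing only decreases along a branch
        if (nsp < best_key[1]) next
      }
      ntmin <- min(tmin, tmfs[[level]][i], tmrs[[level]][i], na.rm = TRUE)
      ntmax <- max(tmax, tmfs[[level]][i], tmrs[[level]][i], na.rm = TRUE)
      if (is.finite(ntmin) && is.finite(ntmax) && (ntmax - ntmin) > tm_win)
        next
      chosen[level] <<- i
      chosen_prod[level] <<- pv[i]
      recurse(level + 1L, nsp, min(cur_disc, discs[[level]][i]), ntmin, ntmax)
    }
  }
  recurse(1L, Inf, Inf, Inf, -Inf)
  if (is.null(best)) NULL else stats::setNames(best, spp)
}

.panel_from_assignment <- function(assignment, pairs_by_species, params,
                                   cross = NULL) {
  spp <- names(assignment)
  rows <- lapply(spp, function(s) pairs_by_species[[s]][assignment[[s]], ])
  sel <- do.call(rbind, rows)
  pairs <- data.frame(
    name = paste0(gsub("[^A-Za-z0-9]+", "_", sel$species), "_pair"),
    target_species = sel$species,
    forward = sel$fwd_seq, reverse = sel$rev_seq,
    expected_product_bp = sel$product_bp,
    tm_f = sel$tm_f, tm_r = sel$tm_r, disc_min = sel$disc_min,
    stringsAsFactors = FALSE
  )
  pairs <- pairs[order(pairs$target_species), ]
  rownames(pairs) <- NULL
  panel <- structure(list(pairs = pairs, annealing_temp_c = NA_real_,
                          spacing_report = NULL, specificity_report = NULL),
                     class = "multiplex_panel")
  panel$spacing_report <- panel_spacing(panel)
  spec_rows <- list()
  for (i in seq_along(spp)) {
    for (o in setdiff(spp, spp[i])) {
      amp <- if (is.null(cross)) NA else
        o %in% cross[[spp[i]]][[assignment[[spp[i]]]]]
      spec_rows[[length(spec_rows) + 1L]] <- data.frame(
        pair_species = spp[i], other_species = o,
        predicted_amplification = amp, stringsAsFactors = FALSE)
    }
  }
  panel$specificity_report <- do.call(rbind, spec_rows)
  panel
}

#' Search for a feasible multiplex panel
#'
#' Deterministic branch-and-bound over one candidate pair per species. A
#' feasible panel satisfies: pairwise product-size differences of at least
#' `min_product_spacing_bp`, no predicted cross-amplification among the
#' panel's species (when `profiles` are supplied), Tm spread of all primers
#' within `tm_window_c`, and at most `max_plex` pairs. Among feasible panels
#' the search maximises the minimum pairwise spacing, then the minimum
#' discrimination, with a deterministic lexicographic tie-break. When the full
#' species set is infeasible (or exceeds `max_plex`), all maximal feasible
#' subsets are reported instead - an infeasible full panel is a structured
#' result, not an error, since split assays are a legitimate outcome.
#'
#' @param pairs_by_species Named list (one element per species) of
#'   `candidate_pairs` data frames. Minimal columns: `species`, `product_bp`;
#'   `tm_f`/`tm_r` and `disc_min` are honoured when present.
#' @param params A [design_params()].
#' @param profiles Optional list of `species_profile` objects used to screen
#'   within-panel cross-amplification.
#' @return A `panel_search` object: list with `feasible` (any panel found),
#'   `full_feasible` (single panel covering all species), `panels` (list of
#'   `multiplex_panel`), `subsets` (character vector per panel) and `note`.
#' @export
select_panel <- function(pairs_by_species, params = design_params(),
                         profiles = NULL) {
  stopifnot(is.list(pairs_by_species), length(pairs_by_species) >= 2L)
  if (is.null(names(pairs_by_species)) || any(!nzchar(names(pairs_by_species)))) {
    names(pairs_by_species) <- vapply(pairs_by_species, function(d)
      d$species[1], character(1))
  }
  pairs_by_species <- pairs_by_species[order(names(pairs_by_species))]
  # normalise minimal inputs
  pairs_by_species <- lapply(pairs_by_species, function(d) {
    d <- as.data.frame(d)
    if (is.null(d$tm_f)) d$tm_f <- NA_real_
    if (is.null(d$tm_r)) d$tm_r <- NA_real_
    if (is.null(d$disc_min)) d$disc_min <- 0L
    d
  })
  n_pairs <- vapply(pairs_by_species, nrow, integer(1))
  spp_all <- names(pairs_by_species)[n_pairs > 0L]
  if (length(spp_all) < 2L) {
    return(structure(list(feasible = FALSE, full_feasible = FALSE,
                          panels = list(), subsets = list(),
                          note = "fewer than two species have admissible candidate pairs"),
                     class = "panel_search"))
  }
  cross <- if (!is.null(profiles))
    .cross_amp_sets(pairs_by_species[spp_all], profiles, params) else NULL
  k_max <- min(length(spp_all), params$max_plex)
  found <- list()
  full_feasible <- FALSE
  if (length(spp_all) <= params$max_plex) {
    a <- .search_assignment(spp_all, pairs_by_species, cross, params)
    if (!is.null(a)) {
      found[[1L]] <- a
      full_feasible <- TRUE
    }
  }
  if (!full_feasible) {
    for (k in seq(k_max, 2L)) {
      subs <- utils::combn(spp_all, k, simplify = FALSE)
      for (s in subs) {
        covered <- any(vapply(found, function(a) all(s %in% names(a)),
                              logical(1)))
        if (covered) next
        a <- .search_assignment(s, pairs_by_species, cross, params)
        if (!is.null(a)) found[[length(found) + 1L]] <- a
      }
    }
  }
  panels <- lapply(found, .panel_from_assignment,
                   pairs_by_species = pairs_by_species, params = params,
                   cross = cross)
  note <- if (!length(panels)) {
    "no feasible panel for any pair of species under the spacing/specificity/Tm constraints"
  } else if (full_feasible) {
    sprintf("single panel covering all %d species", length(spp_all))
  } else {
    sprintf("full %d-species panel infeasible; %d maximal feasible subset panel(s) reported",
            length(spp_all), length(panels))
  }
  structure(list(feasible = length(panels) > 0L,
                 full_feasible = full_feasible, panels = panels,
                 subsets = lapply(found, names), note = note),
            class = "panel_search")
}

#' @export
print.panel_search <- function(x, ...) {
  cat("Panel search:", x$note, "\n")
  for (i in seq_along(x$panels)) {
    cat(sprintf("-- panel %d: %s\n", i,
                paste(x$subsets[[i]], collapse = ", ")))
    print(x$panels[[i]])
  }
  invisible(x)
}

#' Deterministic text report of a panel search
#'
#' Identical inputs and parameters yield byte-identical report lines.
#'
#' @param search A `panel_search` object.
#' @return Character vector of report lines.
#' @export
format_panel_report <- function(search) {
  lines <- c(paste0("panel_search: ", search$note))
  for (i in seq_along(search$panels)) {
    p <- search$panels[[i]]
    lines <- c(lines, sprintf("panel %d: %s", i,
                              paste(search$subsets[[i]], collapse = ",")))
    for (j in seq_len(nrow(p$pairs))) {
      lines <- c(lines, sprintf(
        "  %s\t%s\t%s\t%s\t%d",
        p$pairs$name[j], p$pairs$target_species[j], p$pairs$forward[j],
        p$pairs$reverse[j], p$pairs$expected_product_bp[j]))
    }
    sp <- p$spacing_report
    for (j in seq_len(nrow(sp))) {
      lines <- c(lines, sprintf("  spacing %s vs %s: %d bp",
                                sp$name_a[j], sp$name_b[j], sp$delta_bp[j]))
    }
  }
  lines
}

#' Advisory 3'-end cross-dimer screen
#'
#' Flags primer pairs whose 3'-terminal bases can anneal to the other primer:
#' the reverse complement of one primer's 3'-terminal k-mer (k >=
#' `max_3prime_complement`) occurs in the other primer. Extendable 3' dimers
#' of this kind are a plausible cause of multiplex failure. Advisory only -
#' the screen never blocks a panel.
#'
#' @param primers Named character vector of primer sequences, or a
#'   `multiplex_panel` (all forward and reverse primers are screened).
#' @param max_3prime_complement Minimum 3'-anchored complementary overlap to
#'   flag (default 5).
#' @return Data frame of flagged pairs: `primer_a`, `primer_b`, `overlap_len`.
#' @export
cross_dimer_screen <- function(primers, max_3prime_complement = 5L) {
  if (inherits(primers, "multiplex_panel")) {
    p <- primers$pairs
    primers <- stats::setNames(c(p$forward, p$reverse),
                               c(paste0(p$name, "_F"), paste0(p$name, "_R")))
  }
  if (is.null(names(primers))) names(primers) <- paste0("primer", seq_along(primers))
  nm <- names(primers)
  three_prime_overlap <- function(a, b) {
    # longest k such that revcomp(3'-terminal k-mer of a) occurs in b
    best <- 0L
    k_hi <- min(nchar(a), nchar(b))
    if (k_hi < max_3prime_complement) return(0L)
    for (k in seq(k_hi, max_3prime_complement, by = -1L)) {
      tail_k <- substr(a, nchar(a) - k + 1L, nchar(a))
      if (grepl(reverse_complement(tail_k), b, fixed = TRUE)) {
        best <- k
        break  # descending k: first hit is the longest
      }
    }
    best
  }
  flags <- list()
  for (i in seq_along(primers)) {
    for (j in i:length(primers)) {
      ov <- max(three_prime_overlap(primers[i], primers[j]),
                three_prime_overlap(primers[j], primers[i]))
      if (ov >= max_3prime_complement) {
        flags[[length(flags) + 1L]] <- data.frame(
          primer_a = nm[i], primer_b = nm[j], overlap_len = ov,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(flags)) {
    return(data.frame(primer_a = character(), primer_b = character(),
                      overlap_len = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, flags)
}

#' Design a multiplex panel from a labelled master alignment
#'
#' Convenience wrapper chaining profile building, candidate enumeration,
#' pairing and the panel search.
#'
#' @param alignment A `dna_alignment` whose members carry `species` labels.
#' @param params A [design_params()].
#' @return List with `profiles`, `candidates`, `pairs` (per species) and
#'   `search` (a `panel_search`).
#' @export
design_panel <- function(alignment, params = design_params()) {
  stopifnot(inherits(alignment, "dna_alignment"))
  if (any(is.na(alignment$species))) {
    stop("design_panel: every alignment member needs a species label")
  }
  spp <- sort(unique(alignment$species))
  profiles <- lapply(spp, function(s)
    build_profile(s, alignment$seqs[alignment$species == s]))
  names(profiles) <- spp
  candidates <- lapply(profiles, enumerate_candidates,
                       all_profiles = profiles, params = params)
  pairs <- lapply(spp, function(s)
    enumerate_pairs(candidates[[s]], profiles[[s]], params))
  names(pairs) <- spp
  search <- select_panel(pairs, params, profiles = profiles)
  list(profiles = profiles, candidates = candidates, pairs = pairs,
       search = search)
}
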