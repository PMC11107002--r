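# Synthetic barcode clades and sample cohorts with the statistical structure
# the design and calling pipeline assumes: a star phylogeny with controllable
# interspecific divergence and intraspecific polymorphism.

#' Specification of a synthetic barcode clade
#'
#' The defaults emulate the design substrate the pipeline targets: a clade of
#' five morphologically confusable congeners with ~600 bp barcode sequences
#' (publicly available COI records for such groups are typically under
#' 600 bp) and 20 sequenced individuals per species - the per-species sample
#' size commonly used to confirm primer functionality.
#'
#' @param n_species Number of species (>= 2; default 5).
#' @param seq_length_bp Barcode length in bp (>= 100; default 600).
#' @param interspecific_divergence Per-site substitution probability on each
#'   species branch of the star phylogeny (default 0.05).
#' @param intraspecific_polymorphism Per-site per-individual substitution
#'   probability from the species consensus (default 0.003).
#' @param n_individuals_per_species Individuals sampled per species
#'   (default 20).
#' @param indel_rate Per-site probability that a species deletes a column
#'   (gap in all its individuals; default 0, so the generated matrix is
#'   already the master alignment).
#' @param seed Integer RNG seed; all outputs are pure functions of it.
#' @return A `clade_spec` list.
#' @export
clade_spec <- function(n_species = 5L, seq_length_bp = 600L,
                       interspecific_divergence = 0.05,
                       intraspecific_polymorphism = 0.003,
                       n_individuals_per_species = 20L,
                       indel_rate = 0, seed = 1L) {
  stopifnot(n_species >= 2L, seq_length_bp >= 100L,
            interspecific_divergence >= 0, interspecific_divergence <= 1,
            intraspecific_polymorphism >= 0, intraspecific_polymorphism <= 1,
            indel_rate >= 0, indel_rate <= 1,
            n_individuals_per_species >= 1L)
  structure(list(n_species = as.integer(n_species),
                 seq_length_bp = as.integer(seq_length_bp),
                 interspecific_divergence = interspecific_divergence,
                 intraspecific_polymorphism = intraspecific_polymorphism,
                 n_individuals_per_species = as.integer(n_individuals_per_species),
                 indel_rate = indel_rate, seed = as.integer(seed)),
            class = "clade_spec")
}

#' Specification of a synthetic sample cohort
#'
#' @param proportions Named numeric vector of species proportions (must sum
#'   to 1).
#' @param n_samples Number of samples to draw.
#' @param dropout_rate Fraction of samples that yield no template (failed
#'   extraction / inhibitors; default 0.1).
#' @param seed Integer RNG seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(proportions, n_samples = 50L, dropout_rate = 0.1,
                        seed = 1L) {
  stopifnot(is.numeric(proportions), !is.null(names(proportions)),
            n_samples >= 1L, dropout_rate >= 0, dropout_rate <= 1)
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("cohort proportions must sum to 1 (got ", sum(proportions), ")")
  }
  structure(list(proportions = proportions, n_samples = as.integer(n_samples),
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "cohort_spec")
}

# substitute to a uniformly chosen different base
.mutate_sites <- function(chars, sites) {
  for (i in sites) {
    chars[i] <- sample(setdiff(.BASES, chars[i]), 1L)
  }
  chars
}

#' Generate a synthetic barcode clade
#'
#' One random ancestral sequence; each species consensus is derived from it
#' by independent per-site substitutions at the interspecific rate (star
#' phylogeny); each individual is derived from its species consensus at the
#' polymorphism rate. Substitutions are uniform over the three alternative
#' bases. The truth record lists every mutated column, so every consensus
#' difference is explained by a logged mutation.
#'
#' @param spec A [clade_spec()].
#' @return List with `alignment` (a `dna_alignment` of all individuals, with
#'   species labels), `species` (character vector of labels),
#'   `species_consensus` (named character vector of true consensus strings),
#'   `ancestor` (string), `truth` (data frame of mutations: `level`,
#'   `species`, `individual`, `column`, `from`, `to`) and `spec`.
#' @export
generate_clade <- function(spec = clade_spec()) {
  stopifnot(inherits(spec, "clade_spec"))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  L <- spec$seq_length_bp
  anc <- sample(.BASES, L, replace = TRUE)
  species <- paste0("species_", LETTERS[seq_len(spec$n_species)])
  truth <- list()
  cons <- list()
  seqs <- character(0); ids <- character(0); labels <- character(0)
  for (s in species) {
    sites <- which(stats::runif(L) < spec$interspecific_divergence)
    sc <- .mutate_sites(anc, sites)
    if (length(sites)) {
      truth[[length(truth) + 1L]] <- data.frame(
        level = "interspecific", species = s, individual = NA_character_,
        column = sites, from = anc[sites], to = sc[sites],
        stringsAsFactors = FALSE)
    }
    gap_sites <- if (spec$indel_rate > 0)
      which(stats::runif(L) < spec$indel_rate) else integer(0)
    if (length(gap_sites)) {
      truth[[length(truth) + 1L]] <- data.frame(
        level = "deletion", species = s, individual = NA_character_,
        column = gap_sites, from = sc[gap_sites], to = "-",
        stringsAsFactors = FALSE)
      sc[gap_sites] <- "-"
    }
    cons[[s]] <- paste(sc, collapse = "")
    for (k in seq_len(spec$n_individuals_per_species)) {
      id <- sprintf("%s_%02d", s, k)
      mutable <- which(sc != "-")
      ind_sites <- mutable[stats::runif(length(mutable)) <
                             spec$intraspecific_polymorphism]
      ind <- .mutate_sites(sc, ind_sites)
      if (length(ind_sites)) {
        truth[[length(truth) + 1L]] <- data.frame(
          level = "intraspecific", species = s, individual = id,
          column = ind_sites, from = sc[ind_sites], to = ind[ind_sites],
          stringsAsFactors = FALSE)
      }
      seqs <- c(seqs, paste(ind, collapse = ""))
      ids <- c(ids, id)
      labels <- c(labels, s)
    }
  }
  aln <- as_alignment(data.frame(id = ids, residues = seqs, species = labels,
                                 stringsAsFactors = FALSE))
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(level = character(), species = character(),
               individual = character(), column = integer(),
               from = character(), to = character(), stringsAsFactors = FALSE)
  list(alignment = aln, species = species,
       species_consensus = unlist(cons), ancestor = paste(anc, collapse = ""),
       truth = truth, spec = spec)
}

#' Draw a synthetic sample cohort from a clade
#'
#' Species are assigned by a multinomial draw of the cohort proportions; each
#' sample's template is the (ungapped) sequence of a uniformly chosen
#' individual of its species. Dropout samples carry an empty template string,
#' emulating failed amplification.
#'
#' @param clade Output of [generate_clade()].
#' @param spec A [cohort_spec()]; its `proportions` names must be clade
#'   species.
#' @return Data frame with `sample_id`, `species` (truth label), `template`
#'   (residue string, `""` for dropouts) and `dropout` (logical).
#' @export
generate_cohort <- function(clade, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!all(names(spec$proportions) %in% clade$species)) {
    stop("cohort proportions reference unknown species: ",
         paste(setdiff(names(spec$proportions), clade$species), collapse = ", "))
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  n <- spec$n_samples
  labels <- sample(names(spec$proportions), n, replace = TRUE,
                   prob = spec$proportions)
  dropout <- stats::runif(n) < spec$dropout_rate
  aln <- clade$alignment
  template <- vapply(seq_len(n), function(i) {
    if (dropout[i]) return("")
    members <- which(aln$species == labels[i])
    pick <- members[sample.int(length(members), 1L)]
    gsub("-", "", aln$seqs[pick], fixed = TRUE)
  }, character(1))
  data.frame(sample_id = sprintf("sample_%03d", seq_len(n)),
             species = labels, template = template, dropout = dropout,
             stringsAsFactors = FALSE)
}

#' End-to-end benchmark: generate, design, amplify in silico, call
#'
#' Runs the whole pipeline on one synthetic clade and cohort: profile
#' building, panel design, multiplex simulation and band-pattern calling,
#' then scores the calls against the cohort truth. When the full species set
#' exceeds one reaction, the reported subset panels are applied sequentially
#' (largest first): samples left unidentified by one assay are re-run with
#' the next, mirroring how split assays are used in practice.
#'
#' @param clade_specification A [clade_spec()].
#' @param cohort_specification A [cohort_spec()]; when `NULL`, a uniform
#'   cohort over all clade species with 10% dropout and the clade's seed is
#'   used.
#' @param params A [design_params()].
#' @return List with `feasible`, `full_feasible`, `panel` (the primary,
#'   largest panel), `panels_used` (all panels applied, in order), `calls`,
#'   `confusion` (table truth x call), `accuracy` (correct-call fraction
#'   among non-dropout samples of species covered by some panel),
#'   `n_unidentified`, `n_dropout`, `search`, `cohort`.
#' @export
end_to_end_benchmark <- function(clade_specification = clade_spec(),
                                 cohort_specification = NULL,
                                 params = design_params()) {
  clade <- tryCatch(generate_clade(clade_specification),
                    error = function(e) stop("synthclade stage: ",
                                             conditionMessage(e)))
  if (is.null(cohort_specification)) {
    props <- stats::setNames(rep(1 / length(clade$species),
                                 length(clade$species)), clade$species)
    cohort_specification <- cohort_spec(props, n_samples = 50L,
                                        dropout_rate = 0.1,
                                        seed = clade_specification$seed)
  }
  design <- tryCatch(design_panel(clade$alignment, params),
                     error = function(e) stop("design stage: ",
                                              conditionMessage(e)))
  search <- design$search
  if (!search$feasible) {
    return(list(feasible = FALSE, full_feasible = FALSE, panel = NULL,
                panels_used = list(), calls = NULL, confusion = NULL,
                accuracy = NA_real_, n_unidentified = NA_integer_,
                n_dropout = NA_integer_, search = search, cohort = NULL))
  }
  sizes <- vapply(search$subsets, length, integer(1))
  panels <- search$panels[order(-sizes)]
  panel <- panels[[1L]]
  cohort <- tryCatch(generate_cohort(clade, cohort_specification),
                     error = function(e) stop("cohort stage: ",
                                              conditionMessage(e)))
  templates <- data.frame(id = cohort$sample_id, residues = cohort$template,
                          stringsAsFactors = FALSE)
  # apply the assays sequentially: samples a panel leaves unidentified are
  # re-run with the next panel
  calls <- NULL
  pending <- rep(TRUE, nrow(templates))
  for (pnl in panels) {
    if (!any(pending)) break
    obs <- tryCatch(
      simulate_multiplex(pnl, templates[pending, , drop = FALSE],
                         params$model,
                         product_min = params$product_min_bp,
                         product_max = params$product_max_bp),
      error = function(e) stop("ispcr stage: ", conditionMessage(e)))
    new_calls <- tryCatch(call_cohort(obs, pnl),
                          error = function(e) stop("call stage: ",
                                                   conditionMessage(e)))
    calls <- if (is.null(calls)) new_calls else
      rbind(calls[calls$sample_id %in%
                    setdiff(calls$sample_id, new_calls$sample_id), ],
            new_calls)
    done <- new_calls$sample_id[new_calls$call != "unidentified"]
    pending <- pending & !(templates$id %in% done)
  }
  calls <- calls[match(templates$id, calls$sample_id), ]
  rownames(calls) <- NULL
  covered <- unique(unlist(lapply(panels, function(p) p$pairs$target_species)))
  eval_idx <- !cohort$dropout & cohort$species %in% covered
  accuracy <- if (any(eval_idx))
    mean(calls$call[eval_idx] == cohort$species[eval_idx]) else NA_real_
  list(feasible = TRUE, full_feasible = search$full_feasible, panel = panel,
       panels_used = panels, calls = calls,
       confusion = table(truth = cohort$species, call = calls$call),
       accuracy = accuracy,
       n_unidentified = sum(calls$call == "unidentified"),
       n_dropout = sum(cohort$dropout),
       search = search, cohort = cohort)
}
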