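# Frozen reference Tm values computed with an independent nearest-neighbor
# implementation (Biopython MeltingTemp.Tm_NN, DNA_NN3 table, Na=50 mM,
# Mg=1.5 mM, dNTPs=0.6 mM, 25+25 nM strands, entropy salt correction).
TM_REFERENCE <- c(
  ACGTACGTACGTACGTACGT = 58.67,
  AAAAAAAAAATTTTTTTTTT = 41.22,
  GCGCGCGCGCGCGCGCGCGC = 82.52,
  ATGCATTAGGCCTAGGATCA = 55.74,
  TTACGGATCCGAGTCAAGTC = 56.78,
  CCGGTTAACGGTTAACCGGT = 60.32
)

test_that("nearest-neighbor Tm matches an independent thermodynamic oracle", {
  for (s in names(TM_REFERENCE)) {
    expect_equal(melting_temperature(s), TM_REFERENCE[[s]], tolerance = 0.011)
  }
  expect_error(melting_temperature("ACGTACG"), "at least 8")
  expect_error(melting_temperature("ACGTACGTRT"), "ambiguous")
})

test_that("Tm rises with GC content and is invariant under reverse complement", {
  withr::local_seed(7)
  for (i in 1:20) {
    s <- strsplit(rand_dna(20), "", fixed = TRUE)[[1]]
    a_pos <- which(s == "A")
    if (!length(a_pos)) next
    s2 <- s
    s2[sample(a_pos, 1)] <- "G"
    expect_gt(melting_temperature(paste(s2, collapse = "")),
              melting_temperature(paste(s, collapse = "")))
    seq1 <- paste(s, collapse = "")
    expect_equal(melting_temperature(reverse_complement(seq1)),
                 melting_temperature(seq1))
  }
})

test_that("design parameter triples are validated", {
  expect_error(design_params(length_min = 25), "length_min")
  expect_error(design_params(tm_opt = 70), "tm_min")
  expect_error(design_params(min_product_spacing_bp = 0), "spacing")
  p <- design_params()
  expect_equal(c(p$length_min, p$length_opt, p$length_max), c(18L, 20L, 23L))
  expect_equal(c(p$tm_min, p$tm_opt, p$tm_max), c(57, 59, 62))
  expect_equal(c(p$gc_min, p$gc_opt, p$gc_max), c(30, 50, 70))
  expect_equal(p$min_product_spacing_bp, 55L)
})

test_that("an all-N consensus yields no candidates", {
  a <- build_profile("a", paste(rep("N", 200), collapse = ""))
  b <- build_profile("b", rand_dna(200))
  expect_equal(nrow(enumerate_candidates(a, list(a, b))), 0L)
})

test_that("a constructed unique window is found and every candidate re-validates", {
  withr::local_seed(61)
  clade <- generate_clade(clade_spec(n_species = 3L, seq_length_bp = 400L,
                                     n_individuals_per_species = 6L,
                                     seed = 61L))
  aln <- clade$alignment
  spp <- sort(unique(aln$species))
  profs <- lapply(spp, function(s) build_profile(s, aln$seqs[aln$species == s]))
  names(profs) <- spp
  params <- design_params()
  cand <- enumerate_candidates(profs[[1]], profs, params)
  expect_gt(nrow(cand), 0L)
  others <- profs[-1]
  # brute-force re-validation of a sample of candidates
  idx <- unique(round(seq(1, nrow(cand), length.out = 25)))
  for (i in idx) {
    expect_length(oracle_check_candidate(cand[i, ], profs[[1]], others, params), 0L)
  }
  # a window planted as the species consensus appears among plus candidates
  planted <- cand[cand$strand == "plus", ][1, ]
  expect_equal(planted$sequence,
               substr(profs[[1]]$consensus, planted$start, planted$end))
})

test_that("pair products measure the gap-stripped span inclusive of footprints", {
  # gap-free case: product = rev_end - fwd_start + 1
  withr::local_seed(62)
  cons <- rand_dna(300)
  a <- build_profile("a", cons)
  b <- build_profile("b", rand_dna(300))
  params <- design_params(tm_min = 0, tm_max = 100, gc_min = 0, gc_max = 100,
                          min_discrimination = 0L, product_min_bp = 50L)
  cand <- enumerate_candidates(a, list(a, b), params)
  pairs <- enumerate_pairs(cand, a, params)
  expect_gt(nrow(pairs), 0L)
  expect_equal(pairs$product_bp, pairs$rev_end - pairs$fwd_start + 1L)
  # gapped consensus: gap columns inside the span are not counted
  gcons <- paste0(substr(cons, 1, 150),
                  paste(rep("-", 30), collapse = ""),
                  substr(cons, 151, 300))
  ga <- build_profile("a", gcons)
  gb <- build_profile("b", paste0(substr(cons, 1, 150),
                                  paste(rep("-", 30), collapse = ""),
                                  rand_dna(150)))
  gcand <- enumerate_candidates(ga, list(ga, gb), params)
  gpairs <- enumerate_pairs(gcand, ga, params)
  spanning <- gpairs[gpairs$fwd_end <= 150 & gpairs$rev_start > 180, ]
  if (nrow(spanning)) {
    expect_equal(spanning$product_bp,
                 spanning$rev_end - spanning$fwd_start + 1L - 30L)
  }
})

test_that("panel spacing feasibility follows the 55 bp rule", {
  mk <- function(species, product) {
    data.frame(species = species, product_bp = product,
               fwd_seq = rand_dna(20), rev_seq = rand_dna(20),
               fwd_start = 1L, fwd_end = 20L,
               rev_start = product - 19L, rev_end = product,
               tm_f = 59, tm_r = 59, disc_min = 1L, score = 0,
               stringsAsFactors = FALSE)
  }
  withr::local_seed(70)
  ok <- select_panel(list(A = mk("A", 100L), B = mk("B", 160L),
                          C = mk("C", 220L), D = mk("D", 280L)))
  expect_true(ok$feasible)
  expect_true(ok$full_feasible)
  expect_true(all(ok$panels[[1]]$spacing_report$delta_bp >= 55L))

  bad <- select_panel(list(A = mk("A", 100L), B = mk("B", 140L)))
  expect_false(bad$feasible)
  expect_s3_class(bad, "panel_search")   # infeasibility is a result, not an error
  expect_match(bad$note, "no feasible panel")

  # full set infeasible: maximal feasible subsets are reported and cover
  # every species that can be paired
  part <- select_panel(list(A = mk("A", 100L), B = mk("B", 140L),
                            C = mk("C", 210L)))
  expect_true(part$feasible)
  expect_false(part$full_feasible)
  subs <- lapply(part$subsets, sort)
  expect_true(any(vapply(subs, identical, logical(1), y = c("A", "C"))))
  expect_true(any(vapply(subs, identical, logical(1), y = c("B", "C"))))
  expect_equal(sort(unique(unlist(subs))), c("A", "B", "C"))
})

test_that("panel search is deterministic and respects its own constraints", {
  clade <- generate_clade(clade_spec(n_species = 4L, seq_length_bp = 500L,
                                     n_individuals_per_species = 8L,
                                     seed = 77L))
  params <- design_params()
  d1 <- design_panel(clade$alignment, params)
  d2 <- design_panel(clade$alignment, params)
  expect_identical(format_panel_report(d1$search), format_panel_report(d2$search))
  if (d1$search$feasible) {
    for (panel in d1$search$panels) {
      expect_length(oracle_check_panel(panel, d1$profiles, params), 0L)
    }
  }
})

test_that("cross-amplification prediction follows the 3'-mismatch model", {
  withr::local_seed(80)
  cons <- rand_dna(400)
  other <- build_profile("other", cons)
  fwd <- substr(cons, 51, 70)
  rev <- reverse_complement(substr(cons, 281, 300))
  pair <- list(species = "t", fwd_seq = fwd, rev_seq = rev)
  # both primers identical to the other consensus -> amplifies
  res <- predict_cross_amplification(pair, other)
  expect_true(res$amplifies)
  expect_equal(res$amplicons$length_bp, 250L)
  expect_equal(res$detail$forward$mismatch_total, 0L)
  # a disjoint base at the forward 3' terminus blocks annealing
  fwd3 <- fwd
  last <- substr(fwd3, 20, 20)
  substr(fwd3, 20, 20) <- setdiff(c("A", "C", "G", "T"),
                                  c(last, ORACLE_COMP[[last]]))[1]
  res2 <- predict_cross_amplification(list(species = "t", fwd_seq = fwd3,
                                           rev_seq = rev), other)
  expect_false(res2$amplifies)
})

test_that("3'-dimer screen agrees with a brute-force scan and never blocks", {
  flagged <- cross_dimer_screen(c(a = "AAAAAAGGGG", b = "CCCCTTTTTT"),
                                max_3prime_complement = 5L)
  expect_equal(nrow(flagged), 1L)
  expect_gte(flagged$overlap_len, 5L)
  # A/G-only primers cannot complement each other (complements are T/C)
  clean <- cross_dimer_screen(c(a = "AAAAAAAAGAGAGAG", b = "AAAAAAAAGGAAGGA"),
                              max_3prime_complement = 5L)
  expect_equal(nrow(clean), 0L)
  withr::local_seed(90)
  for (i in 1:15) {
    p <- c(a = rand_dna(sample(15:25, 1)), b = rand_dna(sample(15:25, 1)))
    got <- cross_dimer_screen(p, max_3prime_complement = 4L)
    want <- oracle_dimer(p[["a"]], p[["b"]], 4)
    self_a <- oracle_dimer(p[["a"]], p[["a"]], 4)
    self_b <- oracle_dimer(p[["b"]], p[["b"]], 4)
    expect_equal(nrow(got) > 0, want >= 4 || self_a >= 4 || self_b >= 4)
  }
})
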