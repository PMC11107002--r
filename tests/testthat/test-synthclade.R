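test_that("clade generation is a pure function of its seed", {
  s <- clade_spec(n_species = 3L, seq_length_bp = 200L,
                  n_individuals_per_species = 4L, seed = 42L)
  c1 <- generate_clade(s)
  c2 <- generate_clade(s)
  expect_identical(c1, c2)
  c3 <- generate_clade(clade_spec(n_species = 3L, seq_length_bp = 200L,
                                  n_individuals_per_species = 4L, seed = 43L))
  expect_false(identical(c1$ancestor, c3$ancestor))
})

test_that("zero divergence collapses all species to the ancestor", {
  c0 <- generate_clade(clade_spec(n_species = 4L, seq_length_bp = 150L,
                                  interspecific_divergence = 0,
                                  intraspecific_polymorphism = 0,
                                  n_individuals_per_species = 2L, seed = 9L))
  expect_true(all(c0$species_consensus == c0$ancestor))
  expect_equal(nrow(c0$truth), 0L)
})

test_that("the truth record explains every consensus difference", {
  cl <- generate_clade(clade_spec(n_species = 3L, seq_length_bp = 300L,
                                  n_individuals_per_species = 3L, seed = 14L))
  for (s in cl$species) {
    anc <- strsplit(cl$ancestor, "", fixed = TRUE)[[1]]
    mut <- cl$truth[cl$truth$level == "interspecific" & cl$truth$species == s, ]
    anc[mut$column] <- mut$to
    expect_equal(paste(anc, collapse = ""), unname(cl$species_consensus[s]))
    # and every individual is its species consensus plus its logged mutations
    aln <- cl$alignment
    for (id in aln$ids[aln$species == s]) {
      sc <- strsplit(cl$species_consensus[[s]], "", fixed = TRUE)[[1]]
      im <- cl$truth[cl$truth$level == "intraspecific" &
                     !is.na(cl$truth$individual) & cl$truth$individual == id, ]
      sc[im$column] <- im$to
      expect_equal(paste(sc, collapse = ""), aln$seqs[aln$ids == id])
    }
  }
})

test_that("pairwise consensus divergence matches its closed form", {
  # two independent branches at per-site rate d differ with probability
  # 2 d (1 - d) + (2/3) d^2 (both mutate to different targets w.p. 2/3)
  d <- 0.05
  L <- 600L
  diffs <- c()
  for (seed in 1:30) {
    cl <- generate_clade(clade_spec(n_species = 2L, seq_length_bp = L,
                                    interspecific_divergence = d,
                                    intraspecific_polymorphism = 0,
                                    n_individuals_per_species = 1L,
                                    seed = seed))
    a <- strsplit(cl$species_consensus[[1]], "", fixed = TRUE)[[1]]
    b <- strsplit(cl$species_consensus[[2]], "", fixed = TRUE)[[1]]
    diffs <- c(diffs, mean(a != b))
  }
  p <- 2 * d * (1 - d) + (2 / 3) * d^2
  se <- sqrt(p * (1 - p) / (30 * L))
  expect_lt(abs(mean(diffs) - p), 3 * se)
})

test_that("indel columns appear as species-wide gaps without length change", {
  cl <- generate_clade(clade_spec(n_species = 2L, seq_length_bp = 200L,
                                  indel_rate = 0.02,
                                  n_individuals_per_species = 3L, seed = 31L))
  expect_equal(cl$alignment$length, 200L)
  del <- cl$truth[cl$truth$level == "deletion", ]
  expect_gt(nrow(del), 0L)
  for (r in seq_len(nrow(del))) {
    members <- cl$alignment$seqs[cl$alignment$species == del$species[r]]
    expect_true(all(substr(members, del$column[r], del$column[r]) == "-"))
  }
})

test_that("cohort draws follow proportions, dropout and determinism", {
  cl <- generate_clade(clade_spec(n_species = 3L, seq_length_bp = 150L,
                                  n_individuals_per_species = 4L, seed = 3L))
  co <- generate_cohort(cl, cohort_spec(c(species_A = 1.0), n_samples = 10L,
                                        dropout_rate = 0, seed = 8L))
  expect_true(all(co$species == "species_A"))
  expect_true(all(nchar(co$template) == 150L))

  co2 <- generate_cohort(cl, cohort_spec(c(species_A = 0.5, species_B = 0.5),
                                         n_samples = 20L, dropout_rate = 1,
                                         seed = 8L))
  expect_true(all(co2$template == ""))
  expect_true(all(co2$dropout))

  expect_error(cohort_spec(c(species_A = 0.6, species_B = 0.5)), "sum to 1")
  expect_error(generate_cohort(cl, cohort_spec(c(nope = 1.0), seed = 1L)),
               "unknown species")

  expect_identical(
    generate_cohort(cl, cohort_spec(c(species_A = 0.5, species_B = 0.5),
                                    n_samples = 30L, seed = 4L)),
    generate_cohort(cl, cohort_spec(c(species_A = 0.5, species_B = 0.5),
                                    n_samples = 30L, seed = 4L)))

  # species frequencies across seeds stay inside binomial 99% bounds
  props <- c(species_A = 0.3, species_B = 0.7)
  n_tot <- 0L; n_a <- 0L
  for (seed in 1:30) {
    co3 <- generate_cohort(cl, cohort_spec(props, n_samples = 40L,
                                           dropout_rate = 0, seed = seed))
    n_tot <- n_tot + nrow(co3)
    n_a <- n_a + sum(co3$species == "species_A")
  }
  bound <- qnorm(0.995) * sqrt(0.3 * 0.7 / n_tot)
  expect_lt(abs(n_a / n_tot - 0.3), bound + 1e-12)
})

test_that("panel feasibility rises with interspecific divergence", {
  rates <- vapply(c(0.01, 0.03, 0.05, 0.08), function(d) {
    feas <- vapply(1:15, function(seed) {
      cl <- generate_clade(clade_spec(n_species = 4L, seq_length_bp = 500L,
                                      interspecific_divergence = d,
                                      n_individuals_per_species = 8L,
                                      seed = seed))
      design_panel(cl$alignment)$search$feasible
    }, logical(1))
    mean(feas)
  }, numeric(1))
  # non-decreasing along the grid, allowing one seed of sampling noise
  expect_true(all(diff(rates) >= -1 / 15))
  expect_gt(rates[4], rates[1] - 1e-9)
})

test_that("the end-to-end benchmark wires all stages together", {
  # sufficient divergence: full pipeline, perfect calls, dropouts unidentified
  b <- end_to_end_benchmark(clade_spec(n_species = 3L, seq_length_bp = 500L,
                                       n_individuals_per_species = 8L,
                                       seed = 5L),
                            cohort_spec(c(species_A = 0.4, species_B = 0.3,
                                          species_C = 0.3),
                                        n_samples = 30L, dropout_rate = 0.1,
                                        seed = 5L))
  expect_true(b$feasible)
  expect_equal(b$accuracy, 1.0)
  expect_equal(b$n_unidentified, b$n_dropout)
  expect_s3_class(b$calls, "data.frame")
  # the confusion matrix margins add up to the cohort size
  expect_equal(sum(b$confusion), 30L)
  # zero divergence: no discriminative windows, design reports infeasibility
  b0 <- end_to_end_benchmark(clade_spec(n_species = 3L, seq_length_bp = 300L,
                                        interspecific_divergence = 0,
                                        n_individuals_per_species = 4L,
                                        seed = 6L))
  expect_false(b0$feasible)
  expect_null(b0$panel)
})
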