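test_that("binding sites are found on both strands with exact arithmetic", {
  withr::local_seed(101)
  tpl <- rand_dna(300)
  primer <- substr(tpl, 101, 120)
  sites <- find_binding_sites(primer, tpl)
  plus <- sites[sites$strand == "plus", ]
  expect_true(any(plus$position == 101 & plus$mismatch_total == 0))
  # reverse complement of a substring binds the minus strand at that footprint
  rprimer <- reverse_complement(substr(tpl, 201, 220))
  sites <- find_binding_sites(rprimer, tpl)
  minus <- sites[sites$strand == "minus", ]
  expect_true(any(minus$position == 201 & minus$mismatch_total == 0))
  # template shorter than primer: empty result, no error
  expect_equal(nrow(find_binding_sites(primer, "ACGT")), 0L)
})

test_that("binding-site scanner agrees with the quadratic oracle", {
  withr::local_seed(102)
  for (i in 1:30) {
    tpl <- rand_iupac(sample(60:200, 1), p_ambig = 0.03)
    primer <- if (runif(1) < 0.5) {
      rand_dna(sample(12:22, 1))
    } else {
      # seed a near-match so non-trivial hits occur
      start <- sample(1:(nchar(tpl) - 25), 1)
      win <- substr(tpl, start, start + 19)
      win <- gsub("[^ACGT]", "A", win)
      ch <- strsplit(win, "", fixed = TRUE)[[1]]
      pos <- sample(20, sample(0:3, 1))
      ch[pos] <- sample(c("A", "C", "G", "T"), length(pos), replace = TRUE)
      s <- paste(ch, collapse = "")
      if (runif(1) < 0.5) s else reverse_complement(s)
    }
    got <- find_binding_sites(primer, tpl)
    want <- oracle_scan(primer, tpl)
    expect_equal(got[, c("position", "strand", "mismatch_total",
                         "mismatch_3prime")],
                 want, ignore_attr = TRUE)
  }
})

test_that("amplicon prediction reproduces constructed product arithmetic", {
  withr::local_seed(103)
  tpl <- rand_dna(500)
  fwd <- substr(tpl, 61, 80)
  rev <- reverse_complement(substr(tpl, 421, 440))
  amp <- predict_amplicons(fwd, rev, tpl)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$length_bp, 380L)
  expect_equal(c(amp$start, amp$end), c(61L, 440L))
  # absent primers: no amplicons
  expect_equal(nrow(predict_amplicons(rand_dna(20), rand_dna(20), tpl)), 0L)
  # divergent orientation (reverse site upstream of forward) does not amplify
  amp2 <- predict_amplicons(reverse_complement(substr(tpl, 21, 40)),
                            substr(tpl, 301, 320), tpl)
  expect_equal(nrow(amp2), 0L)
})

test_that("multiplex simulation reports one band per matching pair", {
  panel <- as_multiplex_panel(read_primer_table(
    fixture_path("saccostrea_panel_synthetic.tsv")))
  origins <- read_fasta(fixture_path("saccostrea_origins_synthetic.fasta"))
  obs <- simulate_multiplex(panel, origins)
  sizes <- panel$pairs$expected_product_bp[
    match(origins$species, panel$pairs$target_species)]
  expect_equal(unname(lapply(obs$bands, as.integer)), as.list(sizes))
  # a template with no binding sites yields an empty lane, as does a failed
  # extraction (empty template)
  withr::local_seed(104)
  blank <- data.frame(id = c("none", "dropout"),
                      residues = c(rand_dna(400), ""))
  obs2 <- simulate_multiplex(panel, blank)
  expect_equal(obs2$bands[[1]], integer(0))
  expect_equal(obs2$bands[[2]], integer(0))
})

test_that("band-pattern calling follows the panel rules", {
  panel <- as_multiplex_panel(read_primer_table(
    fixture_path("saccostrea_panel_synthetic.tsv")))
  rules <- default_priority_rules()
  # double band at the lineage B and lineage G sizes is called lineage G
  expect_equal(call_species(c(244, 380), panel, rules = rules)$call,
               "lineage G")
  # a large non-specific band is ignored; the 185 bp product still calls
  res <- call_species(c(185, 600), panel, rules = rules)
  expect_equal(res$call, "S. glomerata")
  expect_equal(res$ignored_bands, "600")
  # no bands: unidentified
  expect_equal(call_species(integer(0), panel, rules = rules)$call,
               "unidentified")
  # two matches without a covering rule: ambiguous, matches listed
  res2 <- call_species(c(185, 244), panel, rules = rules)
  expect_equal(res2$call, "ambiguous")
  expect_match(res2$rationale, "lineage G")
  expect_match(res2$rationale, "S. glomerata")
  # size tolerance: 250 is within 10 bp of 244
  expect_equal(call_species(250, panel, rules = rules)$call, "lineage G")
  expect_equal(call_species(260, panel, rules = rules)$call, "unidentified")
  expect_error(call_species(100, panel, tolerance_bp = -1), "tolerance")
})

test_that("calls are total, deterministic and robust to oversized bands", {
  panel <- as_multiplex_panel(read_primer_table(
    fixture_path("saccostrea_panel_synthetic.tsv")))
  withr::local_seed(105)
  max_exp <- max(panel$pairs$expected_product_bp)
  for (i in 1:40) {
    bands <- sample(50:900, sample(0:4, 1))
    r1 <- call_species(bands, panel)
    r2 <- call_species(bands, panel)
    expect_identical(r1, r2)
    expect_true(nzchar(r1$rationale))
    expect_true(r1$call %in% c(panel$pairs$target_species, "unidentified",
                               "ambiguous"))
    # adding any band above max expected + tolerance never changes the call
    extra <- sample((max_exp + 11):2000, 1)
    r3 <- call_species(c(bands, extra), panel)
    expect_equal(r3$call, r1$call)
  }
})

test_that("text gel rendering places bands and merges unresolvable ones", {
  obs <- data.frame(sample_id = c("s1", "s2"),
                    bands = I(list(380L, c(240L, 250L))))
  g <- render_lanes(obs)
  lines <- unclass(g)
  row_of <- function(pat) grep(pat, lines)[1]
  # ladder marks ascending; a 380 bp band sits between the 300 and 400 marks
  mark_rows <- vapply(c(100, 300, 380, 400, 1000), function(s)
    row_of(sprintf("^\\s*%d bp", s)), numeric(1))
  expect_true(all(diff(mark_rows) > 0))
  expect_match(lines[row_of("^\\s*380 bp")], "####")
  # 240/250 merge below the 55 bp readability limit, with an annotation
  expect_match(paste(lines, collapse = "\n"), "unresolvable")
  expect_true(any(grepl("245 bp", lines)))  # merged cluster at the mean size
})
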