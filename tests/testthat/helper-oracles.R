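# Independent oracles used to cross-check the implementation. These are
# deliberately written from first principles (own IUPAC tables, quadratic
# scans, brute-force constraint re-application) and share no code with R/.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A")

oracle_revcomp <- function(s) {
  chars <- rev(strsplit(s, "", fixed = TRUE)[[1]])
  out <- vapply(chars, function(ch) {
    set <- ORACLE_SETS[[ch]]
    comp <- sort(unname(ORACLE_COMP[set]))
    hit <- names(ORACLE_SETS)[vapply(ORACLE_SETS, function(v)
      identical(sort(v), comp), logical(1))]
    hit[1]
  }, character(1))
  paste(out, collapse = "")
}

# do two IUPAC codes share a concrete base? gaps never match anything
oracle_match <- function(a, b) {
  if (a == "-" || b == "-") return(FALSE)
  length(intersect(ORACLE_SETS[[a]], ORACLE_SETS[[b]])) > 0
}

# brute-force polymorphic columns: >= 2 distinct concrete bases (ambiguity
# codes contribute their whole set) among members at a column
oracle_polymorphic_columns <- function(members) {
  mat <- do.call(rbind, strsplit(members, "", fixed = TRUE))
  which(apply(mat, 2, function(col) {
    bases <- unique(unlist(ORACLE_SETS[col[col != "-"]]))
    length(bases) >= 2
  }))
}

# brute-force discriminative-position count between two consensus strings
oracle_disjoint_count <- function(a, b, s, e) {
  ac <- strsplit(a, "", fixed = TRUE)[[1]][s:e]
  bc <- strsplit(b, "", fixed = TRUE)[[1]][s:e]
  sum(vapply(seq_along(ac), function(i) {
    if (ac[i] %in% c("-", "N") || bc[i] %in% c("-", "N")) return(FALSE)
    !oracle_match(ac[i], bc[i])
  }, logical(1)))
}

# pairwise code-compatibility tables derived from the oracle's own sets:
# direct (plus strand) and complemented (minus strand: does the primer base
# pair with the complement of the template base?)
ORACLE_CODES <- c(names(ORACLE_SETS), "-")
ORACLE_DIRECT <- outer(ORACLE_CODES, ORACLE_CODES,
                       Vectorize(function(a, b) oracle_match(a, b)))
dimnames(ORACLE_DIRECT) <- list(ORACLE_CODES, ORACLE_CODES)
ORACLE_PAIRS <- outer(ORACLE_CODES, ORACLE_CODES,
                      Vectorize(function(a, b) {
                        if (a == "-" || b == "-") return(FALSE)
                        comp_set <- unname(ORACLE_COMP[ORACLE_SETS[[b]]])
                        length(intersect(ORACLE_SETS[[a]], comp_set)) > 0
                      }))
dimnames(ORACLE_PAIRS) <- list(ORACLE_CODES, ORACLE_CODES)

# quadratic binding-site scan, from the duplex definition: primer position k
# (5'->3') pairs with the template base directly (plus strand) or with the
# complement of the template base read 3'->5' (minus strand); vectorized over
# footprint offsets for each primer position k
oracle_scan <- function(primer, template, max_total = 2, window = 4,
                        max_3p = 0) {
  empty <- data.frame(position = integer(), strand = character(),
                      mismatch_total = integer(), mismatch_3prime = integer(),
                      stringsAsFactors = FALSE)
  p <- strsplit(primer, "", fixed = TRUE)[[1]]
  tc <- strsplit(template, "", fixed = TRUE)[[1]]
  L <- length(p); n <- length(tc)
  if (n < L) return(empty)
  w <- min(window, L)
  offs <- 0:(n - L)
  mm_p <- mm3_p <- mm_m <- mm3_m <- integer(n - L + 1)
  for (k in seq_len(L)) {
    bad_plus <- !ORACLE_DIRECT[p[k], tc[offs + k]]
    bad_minus <- !ORACLE_PAIRS[p[k], tc[offs + L - k + 1]]
    mm_p <- mm_p + bad_plus
    mm_m <- mm_m + bad_minus
    if (k > L - w) {
      mm3_p <- mm3_p + bad_plus
      mm3_m <- mm3_m + bad_minus
    }
  }
  rows <- rbind(
    data.frame(position = offs + 1, strand = "plus", mismatch_total = mm_p,
               mismatch_3prime = mm3_p, stringsAsFactors = FALSE),
    data.frame(position = offs + 1, strand = "minus", mismatch_total = mm_m,
               mismatch_3prime = mm3_m, stringsAsFactors = FALSE))
  rows <- rows[rows$mismatch_total <= max_total &
               rows$mismatch_3prime <= max_3p, , drop = FALSE]
  if (!nrow(rows)) return(empty)
  rows[order(rows$position, rows$strand), , drop = FALSE]
}

# independent re-validation of one enumerated candidate against the profile
# and parameters (constraint re-application from scratch)
oracle_check_candidate <- function(cand, profile, others, params) {
  s <- cand$start; e <- cand$end
  win <- substr(profile$consensus, s, e)
  chars <- strsplit(win, "", fixed = TRUE)[[1]]
  probs <- character(0)
  if (cand$length < params$length_min || cand$length > params$length_max)
    probs <- c(probs, "length")
  if (any(!chars %in% c("A", "C", "G", "T")))
    probs <- c(probs, "ambiguity/gap in window")
  if (any(seq(s, e) %in% profile$polymorphic_columns))
    probs <- c(probs, "polymorphic overlap")
  gc <- 100 * sum(chars %in% c("G", "C")) / length(chars)
  if (gc < params$gc_min - 1e-9 || gc > params$gc_max + 1e-9)
    probs <- c(probs, "gc")
  tm <- melting_temperature(win, na_mM = params$na_mM, mg_mM = params$mg_mM,
                            dntp_mM = params$dntp_mM,
                            oligo_nM = params$oligo_nM)
  if (tm < params$tm_min - 1e-9 || tm > params$tm_max + 1e-9)
    probs <- c(probs, "tm")
  expect_seq <- if (cand$strand == "plus") win else oracle_revcomp(win)
  if (cand$sequence != expect_seq) probs <- c(probs, "sequence")
  for (o in others) {
    if (cand$disc[[1]][[o$species]] !=
        oracle_disjoint_count(profile$consensus, o$consensus, s, e))
      probs <- c(probs, paste("disc vs", o$species))
  }
  probs
}

# independent multiplex-panel constraint checker
oracle_check_panel <- function(panel, profiles, params) {
  p <- panel$pairs
  probs <- character(0)
  if (nrow(p) > params$max_plex) probs <- c(probs, "panel too large")
  if (nrow(p) >= 2) {
    for (i in seq_len(nrow(p) - 1)) {
      for (j in seq(i + 1, nrow(p))) {
        if (abs(p$expected_product_bp[i] - p$expected_product_bp[j]) <
            params$min_product_spacing_bp)
          probs <- c(probs, sprintf("spacing %s/%s", p$name[i], p$name[j]))
      }
    }
  }
  tms <- c(p$tm_f, p$tm_r)
  if (all(is.finite(tms)) && diff(range(tms)) > params$tm_window_c + 1e-9)
    probs <- c(probs, "tm window")
  # cross-amplification within the panel species set, via the quadratic scan
  for (i in seq_len(nrow(p))) {
    for (o in setdiff(p$target_species, p$target_species[i])) {
      tpl <- gsub("-", "", profiles[[o]]$consensus, fixed = TRUE)
      f <- oracle_scan(p$forward[i], tpl, params$model$max_total,
                       params$model$three_prime_window,
                       params$model$max_three_prime)
      f <- f[f$strand == "plus", , drop = FALSE]
      r <- oracle_scan(p$reverse[i], tpl, params$model$max_total,
                       params$model$three_prime_window,
                       params$model$max_three_prime)
      r <- r[r$strand == "minus", , drop = FALSE]
      if (nrow(f) && nrow(r)) {
        for (fp in f$position) {
          for (rp in r$position) {
            len <- rp + nchar(p$reverse[i]) - 1 - fp + 1
            if (rp >= fp && len >= params$product_min_bp &&
                len <= params$product_max_bp)
              probs <- c(probs, sprintf("cross-amp %s on %s", p$name[i], o))
          }
        }
      }
    }
  }
  unique(probs)
}

# brute-force 3'-dimer scan: revcomp of a 3'-terminal k-mer of one primer
# occurring anywhere in the other
oracle_dimer <- function(a, b, kmin) {
  found <- 0
  for (k in seq(kmin, min(nchar(a), nchar(b)))) {
    ta <- substr(a, nchar(a) - k + 1, nchar(a))
    tb <- substr(b, nchar(b) - k + 1, nchar(b))
    if (grepl(oracle_revcomp(ta), b, fixed = TRUE)) found <- max(found, k)
    if (grepl(oracle_revcomp(tb), a, fixed = TRUE)) found <- max(found, k)
  }
  found
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")
rand_iupac <- function(n, p_ambig = 0.05) {
  base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  amb <- runif(n) < p_ambig
  base[amb] <- sample(c("R", "Y", "S", "W", "K", "M", "N"), sum(amb),
                      replace = TRUE)
  paste(base, collapse = "")
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "ampliplex", mustWork = TRUE)
}
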