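# Nearest-neighbor duplex melting temperature.
#
# Unified nearest-neighbor parameters (SantaLucia-style dH/dS stacks with
# terminal A.T / G.C initiation corrections) and the entropy-based salt
# correction dS + 0.368 * (N-1) * ln[Mon+], where divalent cations enter as
# a monovalent equivalent Mon = Na + 120 * sqrt(Mg - dNTP) (all mM).
# Chemistry defaults (50 mM monovalent, 1.5 mM Mg2+, 0.6 mM dNTP, 50 nM
# total oligo, Ct/4 for non-self-complementary duplexes) follow the Primer3
# defaults so the usual 57-62 degC design window applies.

# dH in kcal/mol, dS in cal/(mol K); keys are the top-strand dinucleotide.
.NN_DH <- c(
  AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
  CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
  CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
  CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0
)
.NN_DS <- c(
  AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
  CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
  CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
  CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9
)
# initiation with a terminal A.T or G.C pair, per end
.TERM_DH <- c(A = 2.3, T = 2.3, G = 0.1, C = 0.1)
.TERM_DS <- c(A = 4.1, T = 4.1, G = -2.8, C = -2.8)
.GAS_R <- 1.9872      # cal/(mol K)

#' Nearest-neighbor melting temperature
#'
#' Duplex Tm of an unambiguous DNA oligo against its perfect complement under
#' the unified nearest-neighbor model, with an entropy salt correction of
#' `0.368 * (N - 1) * ln[Na+]` and `Tm = 1000 dH / (dS + R ln(Ct/4)) - 273.15`.
#' Results are reported to 0.01 degC.
#'
#' @param sequence Character vector of DNA strings (A/C/G/T only, length >= 8;
#'   ambiguity codes are rejected - candidates containing them are screened
#'   out before Tm is ever computed).
#' @param na_mM Monovalent cation concentration in mM (default 50).
#' @param mg_mM Divalent (Mg2+) concentration in mM (default 1.5); entered as
#'   a monovalent equivalent of `120 * sqrt(mg_mM - dntp_mM)`.
#' @param dntp_mM dNTP concentration in mM (default 0.6); chelates Mg2+.
#' @param oligo_nM Total oligo strand concentration in nM (default 50); the
#'   non-self-complementary factor Ct/4 is applied.
#' @return Numeric vector of melting temperatures in degC.
#' @examples
#' melting_temperature("ATGCATTAGGCCTAGGATCA")
#' @export
melting_temperature <- function(sequence, na_mM = 50, mg_mM = 1.5,
                                dntp_mM = 0.6, oligo_nM = 50) {
  mon_mM <- na_mM + 120 * sqrt(max(mg_mM - dntp_mM, 0))
  vapply(sequence, function(s) {
    if (is.na(s) || nchar(s) < 8L) {
      stop("melting_temperature: sequence must be at least 8 bases")
    }
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
    if (any(!chars %in% .BASES)) {
      stop("melting_temperature: ambiguous or illegal base '",
           chars[which(!chars %in% .BASES)[1]],
           "' (only A/C/G/T supported)")
    }
    n <- length(chars)
    dinuc <- paste0(chars[-n], chars[-1])
    dH <- sum(.NN_DH[dinuc]) + .TERM_DH[[chars[1]]] + .TERM_DH[[chars[n]]]
    dS <- sum(.NN_DS[dinuc]) + .TERM_DS[[chars[1]]] + .TERM_DS[[chars[n]]]
    dS <- dS + 0.368 * (n - 1) * log(mon_mM / 1000)
    tm <- 1000 * dH / (dS + .GAS_R * log(oligo_nM * 1e-9 / 4)) - 273.15
    round(tm, 2)
  }, numeric(1), USE.NAMES = FALSE)
}

# Vectorized Tm for all windows of length L over a character vector.
# Returns NA where a window contains a non-ACGT character; callers filter
# such windows out beforehand.
.tm_windows <- function(chars, L, na_mM = 50, mg_mM = 1.5, dntp_mM = 0.6,
                        oligo_nM = 50) {
  mon_mM <- na_mM + 120 * sqrt(max(mg_mM - dntp_mM, 0))
  n <- length(chars)
  if (n < L) return(numeric(0))
  ok <- chars %in% .BASES
  dinuc <- paste0(chars[-n], chars[-1])
  dh_step <- unname(.NN_DH[dinuc]); dh_step[is.na(dh_step)] <- 0
  ds_step <- unname(.NN_DS[dinuc]); ds_step[is.na(ds_step)] <- 0
  cum_dh <- c(0, cumsum(dh_step))
  cum_ds <- c(0, cumsum(ds_step))
  starts <- seq_len(n - L + 1L)
  dH <- cum_dh[starts + L - 1L] - cum_dh[starts]
  dS <- cum_ds[starts + L - 1L] - cum_ds[starts]
  first <- chars[starts]; last <- chars[starts + L - 1L]
  dH <- dH + .TERM_DH[first] + .TERM_DH[last]
  dS <- dS + .TERM_DS[first] + .TERM_DS[last]
  dS <- dS + 0.368 * (L - 1) * log(mon_mM / 1000)
  tm <- 1000 * dH / (dS + .GAS_R * log(oligo_nM * 1e-9 / 4)) - 273.15
  bad_in_window <- (c(0, cumsum(!ok))[starts + L] - c(0, cumsum(!ok))[starts]) > 0
  tm[bad_in_window] <- NA_real_
  unname(round(tm, 2))
}
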