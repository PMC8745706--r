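# Shared fixtures and independent oracles.

amp1 <- builtin_assay("AR-Amp-1/T877A")
amp2 <- builtin_assay("AR-Amp-2")

# Control-derived gates reused across tests (clean simulated controls).
gates_amp1 <- derive_gates(control_well(amp1, seed = 101), amp1)
gates_amp2 <- derive_gates(control_well(amp2, seed = 102), amp2)

# Independent Fisher oracle: margin enumeration with choose(), no dhyper.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + cc + d
  r1 <- a + b; c1 <- a + cc
  x <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- choose(r1, x) * choose(n - r1, c1 - x) / choose(n, c1)
  obs <- probs[x == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Independent Mann-Whitney oracle: full enumeration of rank assignments.
oracle_mw_p <- function(a, b) {
  pooled <- c(a, b)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  na <- length(a)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(length(pooled), na)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# Printed cell-line table for the mutation assay (copies/uL inputs and the
# published ratio / CN columns).
table2 <- data.frame(
  sample = c("PBMC-M", "PBMC-F", "MFM-223", "VCaP", "LNCaP",
             "LNCaP+PBMC-M", "LNCaP+MFM-223", "LNCaP+VCaP"),
  mt = c(0, 0, 0, 0, 114, 30.1, 29, 20.4),
  wt = c(45.4, 81, 198, 721, 0, 16.2, 60.7, 191),
  rpp30 = c(90, 77, 51.5, 52.5, 228, 89.3, 68.7, 61.7),
  ratio = c(0.51, 1.05, 3.84, 13.73, 0.50, 0.52, 1.31, 3.43),
  mixture = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
  cn_display = c(1, 2, 8, 28, 1, 1.0, 2.6, 6.9))

# Printed two-amplicon table (MYM* column as published; PBMC-F is female
# so its MYM* equals the raw reading).
table3 <- data.frame(
  sample = c("PBMC-M", "PBMC-F", "MFM-223", "VCaP", "LNCaP"),
  x1 = c(45.9, 73, 173, 696, 97),
  x2 = c(42, 72.6, 176, 709, 100),
  tbp = c(87, 73.1, 46.3, 54, 189),
  mym_star = c(84.6, 75, 51.8, 69, 194),
  sex = c("male", "female", "male", "male", "male"),
  cn_display = c(1, 2, 7, 23, 1))

# Published treatment-association tables (rows high/normal AR CN).
table4 <- list(
  chemo = rbind(c(5, 4), c(7, 14)),
  enz_abi = rbind(c(4, 5), c(10, 11)),
  chemo_and_enz_abi = rbind(c(2, 7), c(2, 19)))
table4_printed_p <- c(chemo = 0.42, enz_abi = 0.99, chemo_and_enz_abi = 0.56)

# 30-patient cohort whose joint treatment distribution reproduces the
# published marginals for all three groupings.
make_treatment_cohort <- function() {
  mk <- function(n, amplified, chemo, enz) {
    cn <- if (amplified) 6 else 1
    do.call(rbind, lapply(seq_len(n), function(i)
      cohort_record(paste0("P", chemo, enz, amplified, i), "male", "CRPC",
                    cn, cn, chemo = chemo, enz_abi = enz)))
  }
  rbind(mk(2, TRUE, TRUE, TRUE), mk(3, TRUE, TRUE, FALSE),
        mk(2, TRUE, FALSE, TRUE), mk(2, TRUE, FALSE, FALSE),
        mk(2, FALSE, TRUE, TRUE), mk(5, FALSE, TRUE, FALSE),
        mk(8, FALSE, FALSE, TRUE), mk(6, FALSE, FALSE, FALSE))
}
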