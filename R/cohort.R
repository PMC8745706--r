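#' Summarise healthy-control copy numbers and suggest a threshold
#'
#' Healthy cfDNA defines the normal CN band; the suggested amplification
#' threshold is conservative: never below 2, and never below the healthy
#' maximum (rounded up to one decimal). SEM uses the sample SD
#' (n - 1 denominator).
#'
#' @param healthy_cns Numeric vector of healthy-control CN values
#'   (length >= 2).
#' @return List: `min`, `max`, `mean`, `sem`, `n`, `suggested_threshold`.
#' @export
healthy_threshold_summary <- function(healthy_cns) {
  if (length(healthy_cns) < 2)
    stop("need at least 2 healthy-control CN values")
  list(min = min(healthy_cns), max = max(healthy_cns),
       mean = mean(healthy_cns),
       sem = stats::sd(healthy_cns) / sqrt(length(healthy_cns)),
       n = length(healthy_cns),
       suggested_threshold = max(2, ceiling(max(healthy_cns) * 10) / 10))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by the sum-of-small-probabilities convention: with margins
#' fixed, p is the sum of hypergeometric point probabilities not exceeding
#' that of the observed table (with the customary 1e-7 relative tie
#' tolerance). The odds ratio is the sample cross-product `(a d)/(b c)`
#' (`Inf` when only `b c` is zero, `NaN` when both products vanish), not a
#' conditional MLE.
#'
#' @param tab A 2x2 matrix of non-negative counts `rbind(c(a, b), c(c, d))`
#'   with positive grand total.
#' @return List: `p_two_sided`, `odds_ratio`.
#' @examples
#' fisher_exact_2x2(rbind(c(5, 4), c(7, 14)))  # p ~ 0.42
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + cc + d
  if (n == 0) stop("all-zero contingency table")
  r1 <- a + b; c1 <- a + cc
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, r1, n - r1, c1)
  obs <- stats::dhyper(a, r1, n - r1, c1)
  p <- min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
  or <- if (b * cc == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * cc)
  list(p_two_sided = p, odds_ratio = or)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Reports the U statistic for the first group and the two-sided p-value:
#' exact when `min(n_a, n_b) <= 8` and the pooled data are tie-free,
#' otherwise the normal approximation with continuity correction.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List: `U`, `p_two_sided`, `exact` (logical).
#' @examples
#' mann_whitney(c(1, 2, 3), c(10, 11, 12))  # U = 0, exact p = 0.1
#' @export
mann_whitney <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- min(length(group_a), length(group_b)) <= 8 && !ties
  r <- rank(c(group_a, group_b))
  na <- length(group_a)
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, exact = exact, correct = TRUE))
  list(U = U, p_two_sided = wt$p.value, exact = exact)
}

#' Pearson correlation with t-distributed p-value
#'
#' @param x,y Equal-length numeric vectors (length >= 3), each with
#'   nonzero variance.
#' @return List: `r`, `p_two_sided`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need equal-length vectors of length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_two_sided = ct$p.value, n = length(x))
}

#' Assemble a cohort record
#'
#' One analysed patient or control: per-assay CN, mutation status, Chr X
#' CN, and optional treatment history. Healthy records carry no treatment
#' flags.
#'
#' @param sample_id Identifier.
#' @param sex `"male"` or `"female"`.
#' @param disease_state `"HSPC"`, `"CRPC"` or `"healthy"`.
#' @param cn_assay1,cn_assay2 Copy numbers from the two assays.
#' @param t877a_detected Logical.
#' @param chrx_cn Chromosome X CN (NA if not measured).
#' @param chemo,enz_abi Logical treatment flags (prior chemotherapy;
#'   prior enzalutamide/abiraterone); NA when unknown or healthy.
#' @return One-row data frame.
#' @export
cohort_record <- function(sample_id, sex, disease_state, cn_assay1,
                          cn_assay2, t877a_detected = FALSE, chrx_cn = NA,
                          chemo = NA, enz_abi = NA) {
  disease_state <- match.arg(disease_state, c("HSPC", "CRPC", "healthy"))
  if (disease_state == "healthy" && (isTRUE(chemo) || isTRUE(enz_abi)))
    stop("healthy records cannot carry treatment flags")
  stopifnot(cn_assay1 >= 0, cn_assay2 >= 0)
  data.frame(sample_id = sample_id, sex = sex,
             disease_state = disease_state, cn_assay1 = cn_assay1,
             cn_assay2 = cn_assay2, t877a_detected = t877a_detected,
             chrx_cn = chrx_cn, chemo = chemo, enz_abi = enz_abi,
             stringsAsFactors = FALSE)
}

#' Build a treatment-association contingency table
#'
#' Rows are amplified ("high AR CN") vs normal, using the assay-1 call with
#' assay-2 concordance required; discordant samples are excluded and
#' reported, not silently resolved. Columns split the cohort by prior
#' treatment: chemotherapy, second-generation ADT (enzalutamide or
#' abiraterone), or both-vs-others. Records missing a needed flag are
#' excluded with a warning.
#'
#' @param cohort Data frame of [cohort_record()] rows (patients).
#' @param grouping `"chemo"`, `"enz_abi"` or `"chemo_and_enz_abi"`.
#' @param threshold Amplification threshold (default 2).
#' @return 2x2 integer matrix (rows `high`/`normal`, columns
#'   `treated`/`untreated`) with attributes `n_excluded_missing` and
#'   `n_discordant`.
#' @export
build_table4 <- function(cohort,
                         grouping = c("chemo", "enz_abi",
                                      "chemo_and_enz_abi"),
                         threshold = 2) {
  grouping <- match.arg(grouping)
  if (!nrow(cohort)) stop("empty cohort")
  treated <- switch(grouping,
    chemo = cohort$chemo,
    enz_abi = cohort$enz_abi,
    chemo_and_enz_abi = cohort$chemo & cohort$enz_abi)
  missing_flag <- is.na(treated)
  if (any(missing_flag))
    warning(sum(missing_flag),
            " record(s) excluded: missing treatment information")
  amp1 <- classify_amplification(cohort$cn_assay1, threshold)
  amp2 <- classify_amplification(cohort$cn_assay2, threshold)
  discordant <- amp1 != amp2
  if (any(discordant & !missing_flag))
    warning(sum(discordant & !missing_flag),
            " record(s) excluded: assay-1/assay-2 amplification calls ",
            "discordant (flagged for review)")
  keep <- !missing_flag & !discordant
  tab <- matrix(c(sum(amp1[keep] & treated[keep]),
                  sum(amp1[keep] & !treated[keep]),
                  sum(!amp1[keep] & treated[keep]),
                  sum(!amp1[keep] & !treated[keep])),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("high", "normal"),
                                c("treated", "untreated")))
  attr(tab, "n_excluded_missing") <- sum(missing_flag)
  attr(tab, "n_discordant") <- sum(discordant & !missing_flag)
  tab
}

#' Simulate a paired-assay cohort through the full pipeline
#'
#' For each sample a true AR copy number is realised as a male genome
#' profile (AR amplicons at `true_cn` copies per cell; references at
#' normal ploidy), both assays are simulated, gated against their own
#' simulated control wells, quantified, and CN-called. This is the
#' synthetic stand-in for patient cohorts used to exercise the
#' cohort-level statistics.
#'
#' @param true_cn Numeric vector of true per-sample AR copy numbers.
#' @param genome_equivalents_per_uL Genome concentration per sample
#'   (recycled).
#' @param n_droplets Droplets per well.
#' @param seed Integer seed for the whole cohort.
#' @param disease_state Per-sample state label (recycled).
#' @param model An [amplitude_model()].
#' @return Data frame of cohort records plus columns `true_cn`.
#' @export
simulate_cohort <- function(true_cn, genome_equivalents_per_uL = 45,
                            n_droplets = 20000, seed = 1,
                            disease_state = "CRPC",
                            model = amplitude_model()) {
  a1 <- builtin_assay("AR-Amp-1/T877A")
  a2 <- builtin_assay("AR-Amp-2")
  ge <- rep_len(genome_equivalents_per_uL, length(true_cn))
  disease_state <- rep_len(disease_state, length(true_cn))
  gates1 <- derive_gates(control_well(a1, seed = seed, model = model), a1)
  gates2 <- derive_gates(control_well(a2, seed = seed + 1, model = model), a2)
  rows <- lapply(seq_along(true_cn), function(i) {
    cn <- true_cn[i]
    ds1 <- simulate_sample(a1, c(MT = 0, WT = cn, RPP30 = 2), ge[i],
                           n_droplets = n_droplets, seed = seed + 100 + 2 * i,
                           sample_id = paste0("S", i), model = model)
    ds2 <- simulate_sample(a2, c("AR-X1" = cn, "AR-X2" = cn, MYM = 1,
                                 TBP = 2), ge[i],
                           n_droplets = n_droplets, seed = seed + 101 + 2 * i,
                           sample_id = paste0("S", i), model = model)
    r1 <- analyze_sample(ds1, gates1, a1, sex = "male")
    r2 <- analyze_sample(ds2, gates2, a2, sex = "male")
    rec <- cohort_record(paste0("S", i), "male", disease_state[i],
                         r1$cn$cn, r2$cn$cn,
                         t877a_detected = r1$t877a$detected,
                         chrx_cn = r2$chrx$chrx_cn)
    rec$true_cn <- cn
    rec
  })
  do.call(rbind, rows)
}

#' Simulate a control well containing every assay population
#'
#' All targets at a moderate concentration, so the negative and every
#' single-positive population are well populated — the simulated analogue
#' of running positive/negative control wells to set thresholds.
#'
#' @param assay A `ddpcr_assay`.
#' @param copies_per_uL Concentration for every target (default 60).
#' @param n_droplets,seed,model As in [simulate_well()].
#' @return A `droplet_set` with ground truth.
#' @export
control_well <- function(assay, copies_per_uL = 60, n_droplets = 20000,
                         seed = NULL, model = amplitude_model()) {
  conc <- setNames(rep(copies_per_uL, length(assay$targets)),
                   target_names(assay))
  simulate_well(assay, well_spec(conc, n_droplets = n_droplets, seed = seed,
                                 well_id = "CTRL", sample_id = "control"),
                model = model)
}
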