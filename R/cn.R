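#' Round half away from zero (display convention for reported CN)
#' @param x Numeric.
#' @param digits Decimal places (default 0).
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

cn_display_value <- function(cn, mixture = FALSE) {
  if (mixture && cn < 10) round_half_up(cn, 1) else round_half_up(cn, 0)
}

#' Classify amplification against a copy-number threshold
#'
#' The threshold (default 2) is set conservatively above the healthy-control
#' CN range; the boundary is inclusive, so a CN exactly at the threshold is
#' called amplified.
#'
#' @param cn Non-negative copy number.
#' @param threshold Amplification threshold (default 2).
#' @return Logical.
#' @export
classify_amplification <- function(cn, threshold = 2) {
  stopifnot(all(cn >= 0))
  cn >= threshold
}

new_cn_result <- function(assay_id, ratio, cn, threshold, sex_used = NA,
                          mixture = FALSE) {
  structure(
    list(assay_id = assay_id, ar_ref_ratio = ratio, cn = cn,
         cn_display = cn_display_value(cn, mixture),
         amplified = classify_amplification(cn, threshold),
         threshold = threshold, sex_used = sex_used),
    class = "cn_result")
}

#' @export
print.cn_result <- function(x, ...) {
  cat(sprintf(
    "<cn_result> %s: ratio %.2f:1, CN %.2f (display %s), %samplified (threshold %g)\n",
    x$assay_id, x$ar_ref_ratio, x$cn, format(x$cn_display),
    if (x$amplified) "" else "not ", x$threshold))
  invisible(x)
}

#' AR copy number from the mutation assay (AR-Amp-1/T877A)
#'
#' `AR CN = (WT + MT) / RPP30 x 2`: total AR signal (wild-type plus mutant
#' probe) over the diploid chromosome-10 reference, scaled to a diploid
#' genome.
#'
#' @param mt,wt Mutant- and wild-type-probe concentrations, copies/uL.
#' @param rpp30 RPP30 reference concentration, copies/uL (> 0).
#' @param threshold Amplification threshold (default 2).
#' @param mixture Logical; use the one-decimal display convention for
#'   sub-10 CN (mixture reports).
#' @return A `cn_result`.
#' @examples
#' ar_cn_amp1(0, 198, 51.5)   # CN 7.69, displays 8
#' ar_cn_amp1(114, 0, 228)    # CN 1.0
#' @export
ar_cn_amp1 <- function(mt, wt, rpp30, threshold = 2, mixture = FALSE) {
  stopifnot(mt >= 0, wt >= 0)
  if (rpp30 <= 0)
    stop("no reference signal: RPP30 concentration must be > 0")
  ratio <- (wt + mt) / rpp30
  new_cn_result("AR-Amp-1/T877A", ratio, 2 * ratio, threshold,
                mixture = mixture)
}

#' AR copy number from the two-amplicon assay (AR-Amp-2)
#'
#' `AR CN = (AR-X1 + AR-X2) / (MYM* + TBP) x 2`, where `MYM*` doubles the
#' raw X-chromosomal MYM reading for male samples to correct for
#' hemizygosity (one X per normal male cell); female samples use the raw
#' reading.
#'
#' @param x1,x2 AR exon 1 / exon 2 concentrations, copies/uL.
#' @param mym MYM reference concentration, copies/uL. Raw instrument
#'   reading unless `mym_is_star = TRUE`, in which case it is taken as the
#'   already hemizygosity-corrected MYM*.
#' @param tbp TBP reference concentration, copies/uL.
#' @param sex `"male"` or `"female"`.
#' @param threshold Amplification threshold (default 2).
#' @param mym_is_star Set when `mym` is already the corrected MYM* value.
#' @param mixture See [ar_cn_amp1()].
#' @return A `cn_result`.
#' @examples
#' ar_cn_amp2(696, 709, 69, 54, sex = "male", mym_is_star = TRUE)  # CN 23
#' @export
ar_cn_amp2 <- function(x1, x2, mym, tbp, sex = c("male", "female"),
                       threshold = 2, mym_is_star = FALSE, mixture = FALSE) {
  sex <- match.arg(sex)
  stopifnot(x1 >= 0, x2 >= 0, mym >= 0, tbp >= 0)
  mym_star <- if (mym_is_star || sex == "female") mym else 2 * mym
  if (mym_star + tbp <= 0)
    stop("no reference signal: MYM* + TBP must be > 0")
  ratio <- (x1 + x2) / (mym_star + tbp)
  new_cn_result("AR-Amp-2", ratio, 2 * ratio, threshold, sex_used = sex,
                mixture = mixture)
}

#' Chromosome X copy number
#'
#' `Chr X CN = 2 x MYM / TBP`, using the raw (undoubled) MYM reading: a
#' normal male genome then reads ~1 and whole-X doubling reads ~2, the
#' amplification threshold. The formula is defined for the male cohort it
#' was designed for; female inputs are accepted with a warning.
#'
#' @param mym Raw MYM concentration, copies/uL.
#' @param tbp TBP concentration, copies/uL (> 0).
#' @param sex `"male"` or `"female"`.
#' @param threshold Amplification threshold (default 2).
#' @return An object of class `chrx_result`: `chrx_cn`, `amplified`,
#'   `threshold`, `sex_used`.
#' @examples
#' chrx_cn(42.3, 87)  # ~0.97, normal male
#' @export
chrx_cn <- function(mym, tbp, sex = c("male", "female"), threshold = 2) {
  sex <- match.arg(sex)
  stopifnot(mym >= 0)
  if (tbp <= 0) stop("no reference signal: TBP concentration must be > 0")
  if (sex == "female")
    warning("Chr X CN is defined against a male (hemizygous) expectation; ",
            "interpret female samples with care")
  cnx <- 2 * mym / tbp
  structure(list(chrx_cn = cnx,
                 amplified = classify_amplification(cnx, threshold),
                 threshold = threshold, sex_used = sex),
            class = "chrx_result")
}

#' Call the T877A mutation from mutant/wild-type concentrations
#'
#' A mutation is reported when at least `min_positive_droplets`
#' mutant-probe-positive droplets are seen (a simple false-positive floor;
#' default 3). The mutant fraction is `MT / (MT + WT)` and is undefined
#' (NA) when no AR template is detected at all.
#'
#' @param mt,wt `target_concentration` objects for the mutant and wild-type
#'   probes (numeric copies/uL also accepted, in which case droplet-count
#'   gating of `detected` falls back to `mt > 0`).
#' @param min_positive_droplets Detection floor in droplets (default 3).
#' @return An object of class `mutation_call`: `mutant_copies_per_uL`,
#'   `wildtype_copies_per_uL`, `mutant_fraction`, `detected`,
#'   `min_positive_droplets`.
#' @examples
#' t877a_call(30.1, 16.2)  # mutant fraction 0.65
#' @export
t877a_call <- function(mt, wt, min_positive_droplets = 3L) {
  mt_c <- if (inherits(mt, "target_concentration")) mt$copies_per_uL else mt
  wt_c <- if (inherits(wt, "target_concentration")) wt$copies_per_uL else wt
  stopifnot(mt_c >= 0, wt_c >= 0)
  detected <- if (inherits(mt, "target_concentration"))
    mt$n_positive >= min_positive_droplets
  else mt_c > 0
  frac <- if (mt_c + wt_c > 0) mt_c / (mt_c + wt_c) else NA_real_
  structure(list(mutant_copies_per_uL = mt_c, wildtype_copies_per_uL = wt_c,
                 mutant_fraction = frac, detected = detected,
                 min_positive_droplets = as.integer(min_positive_droplets)),
            class = "mutation_call")
}

#' Cross-validate the two assays' copy-number calls for one sample
#'
#' The two assays interrogate disjoint AR amplicons with independent
#' references, so concordant calls are the basis of a confident
#' amplification report; discordant calls are surfaced for review, never
#' silently resolved.
#'
#' @param cn1,cn2 `cn_result` objects for the same sample.
#' @return A list: `cn_assay1`, `cn_assay2`, `both_amplified`,
#'   `concordant`, `status` (`"concordant-amplified"`,
#'   `"concordant-normal"` or `"discordant"`), `relative_difference`
#'   (`|cn1 - cn2| / mean`).
#' @examples
#' cross_validate(ar_cn_amp1(0, 721, 52.5),
#'                ar_cn_amp2(696, 709, 69, 54, "male", mym_is_star = TRUE))
#' @export
cross_validate <- function(cn1, cn2) {
  concordant <- cn1$amplified == cn2$amplified
  m <- mean(c(cn1$cn, cn2$cn))
  list(cn_assay1 = cn1$cn, cn_assay2 = cn2$cn,
       both_amplified = cn1$amplified && cn2$amplified,
       concordant = concordant,
       status = if (!concordant) "discordant"
                else if (cn1$amplified) "concordant-amplified"
                else "concordant-normal",
       relative_difference = if (m > 0) abs(cn1$cn - cn2$cn) / m else 0)
}

#' Run the full per-sample analysis for one assay well
#'
#' Gating, quantification and the assay-appropriate biomarker calls in one
#' step: AR CN (and T877A for the mutation assay; Chr X CN for the
#' two-amplicon assay).
#'
#' @param ds A `droplet_set`.
#' @param gates A `gate_set`.
#' @param assay A `ddpcr_assay` (one of the built-ins, or any assay whose
#'   target roles identify mutant/wild-type/reference channels).
#' @param sex `"male"` or `"female"`.
#' @param droplet_volume_uL Droplet volume.
#' @param threshold Amplification threshold (default 2).
#' @param min_positive_droplets Mutation detection floor.
#' @return A list: `concentrations` (named `target_concentration` list),
#'   `cn` (`cn_result`), and `t877a` (`mutation_call`) or `chrx`
#'   (`chrx_result`) depending on the assay.
#' @export
analyze_sample <- function(ds, gates, assay, sex = c("male", "female"),
                           droplet_volume_uL = 0.00085, threshold = 2,
                           min_positive_droplets = 3L) {
  sex <- match.arg(sex)
  q <- quantify_assay(ds, gates, assay, droplet_volume_uL)
  if (assay$assay_id == "AR-Amp-1/T877A" ||
      all(c("MT", "WT", "RPP30") %in% names(q))) {
    cn <- ar_cn_amp1(q$MT$copies_per_uL, q$WT$copies_per_uL,
                     q$RPP30$copies_per_uL, threshold = threshold)
    list(concentrations = q, cn = cn,
         t877a = t877a_call(q$MT, q$WT, min_positive_droplets))
  } else if (assay$assay_id == "AR-Amp-2" ||
             all(c("AR-X1", "AR-X2", "MYM", "TBP") %in% names(q))) {
    cn <- ar_cn_amp2(q[["AR-X1"]]$copies_per_uL, q[["AR-X2"]]$copies_per_uL,
                     q$MYM$copies_per_uL, q$TBP$copies_per_uL, sex = sex,
                     threshold = threshold)
    list(concentrations = q, cn = cn,
         chrx = chrx_cn(q$MYM$copies_per_uL, q$TBP$copies_per_uL, sex = sex,
                        threshold = threshold))
  } else {
    stop("analyze_sample knows the built-in assays only; got '",
         assay$assay_id, "'")
  }
}
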