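#' Gate set: per-channel amplitude bands and their population labels
#'
#' A gate set makes the manual, control-guided thresholding of instrument
#' software reproducible. Each channel carries strictly increasing cut
#' points that split its amplitude axis into bands (negative, single
#' levels, additive combination levels); every band maps to the subset of
#' same-channel targets whose expected additive amplitude falls in it. A
#' droplet's label is the union of its two per-channel subsets.
#'
#' @param assay A `ddpcr_assay`.
#' @param baseline Named numeric `c(ch1 = , ch2 = )`, fitted negative mean.
#' @param levels Named numeric, fitted amplitude level per target.
#' @param noise_sd Named numeric `c(ch1 = , ch2 = )`, fitted within-band SD.
#' @param provenance `"derived-from-controls"` or `"manual"`.
#' @param min_separation_sd Adjacent expected band centres closer than this
#'   many noise-SDs are rejected as inseparable (default 4).
#' @return An object of class `gate_set` with elements `cuts` (per-channel
#'   cut points), `band_targets` (per-channel list of target subsets),
#'   `band_centers`, `baseline`, `levels`, `noise_sd`, `provenance`.
#' @seealso [derive_gates()], [call_populations()]
#' @export
gate_set <- function(assay, baseline, levels, noise_sd,
                     provenance = c("derived-from-controls", "manual"),
                     min_separation_sd = 4) {
  provenance <- match.arg(provenance)
  ch <- channel_of(assay)
  tn <- target_names(assay)
  cuts <- band_targets <- band_centers <- list(ch1 = NULL, ch2 = NULL)
  for (ci in 1:2) {
    chname <- c("ch1", "ch2")[ci]
    tch <- tn[ch == c("CH1_FAM", "CH2_HEX")[ci]]
    subsets <- subset_list(tch)
    centers <- baseline[[chname]] +
      vapply(subsets, function(s) sum(levels[s]), numeric(1))
    o <- order(centers)
    subsets <- subsets[o]
    centers <- centers[o]
    gaps <- diff(centers)
    if (any(gaps < min_separation_sd * noise_sd[[chname]]))
      stop(sprintf(
        "inseparable bands in %s: centre gap %.1f < %g noise-SDs (SD %.1f)",
        chname, min(gaps), min_separation_sd, noise_sd[[chname]]))
    cuts[[chname]] <- centers[-length(centers)] + gaps / 2
    band_targets[[chname]] <- subsets
    band_centers[[chname]] <- centers
  }
  structure(list(assay_id = assay$assay_id, cuts = cuts,
                 band_targets = band_targets, band_centers = band_centers,
                 baseline = baseline, levels = levels, noise_sd = noise_sd,
                 provenance = provenance),
            class = "gate_set")
}

# All subsets (incl. empty) of a character vector, as a list.
subset_list <- function(x) {
  k <- length(x)
  lapply(0:(2^k - 1), function(m)
    x[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
}

#' @export
print.gate_set <- function(x, ...) {
  cat(sprintf("<gate_set> assay %s (%s)\n", x$assay_id, x$provenance))
  for (chname in c("ch1", "ch2"))
    cat(sprintf("  %s cuts: %s\n", chname,
                paste(round(x$cuts[[chname]], 1), collapse = ", ")))
  invisible(x)
}

#' Derive gates from control droplets
#'
#' Mirrors the paper-workflow of setting thresholds against the positive and
#' negative controls of each run, reproducibly. Band centres are estimated
#' either from ground-truth labels (simulated controls: negative mean and
#' single-positive means) or, for unlabelled instrument controls, by 1-D
#' k-means per channel with one cluster per expected single level plus the
#' negative. Cut points are placed at midpoints between adjacent expected
#' band centres, with combination bands at additive expected amplitudes.
#'
#' @param controls A `droplet_set` containing the negative population and
#'   every single-positive population (or ground-truth labels).
#' @param assay A `ddpcr_assay`.
#' @param min_cluster Minimum droplets per fitted population (default 10).
#' @param min_separation_sd Passed to [gate_set()].
#' @return A `gate_set` with provenance `"derived-from-controls"`.
#' @export
derive_gates <- function(controls, assay, min_cluster = 10,
                         min_separation_sd = 4) {
  tn <- target_names(assay)
  ch <- channel_of(assay)
  amp <- controls$amplitudes
  if (!is.null(controls$truth)) {
    neg <- controls$truth == ""
    if (sum(neg) < min_cluster)
      stop("controls lack a negative population")
    baseline <- c(ch1 = mean(amp$ch1[neg]), ch2 = mean(amp$ch2[neg]))
    noise_sd <- c(ch1 = stats::sd(amp$ch1[neg]),
                  ch2 = stats::sd(amp$ch2[neg]))
    levels <- setNames(numeric(length(tn)), tn)
    for (t in tn) {
      single <- controls$truth == t
      if (sum(single) < min_cluster)
        stop("controls lack a single-positive population for target ", t)
      chname <- if (ch[[t]] == "CH1_FAM") "ch1" else "ch2"
      levels[t] <- mean(amp[[chname]][single]) - baseline[[chname]]
    }
  } else {
    baseline <- noise_sd <- c(ch1 = NA_real_, ch2 = NA_real_)
    levels <- setNames(numeric(length(tn)), tn)
    for (ci in 1:2) {
      chname <- c("ch1", "ch2")[ci]
      tch <- tn[ch == c("CH1_FAM", "CH2_HEX")[ci]]
      x <- amp[[chname]]
      if (!length(tch)) {
        baseline[[chname]] <- mean(x)
        noise_sd[[chname]] <- stats::sd(x)
        next
      }
      nb <- 2^length(tch)  # one cluster per expected additive band
      km <- tryCatch(
        stats::kmeans(x, centers = matrix(seq(min(x), max(x),
                                              length.out = nb)),
                      iter.max = 50),
        error = function(e)
          stop("channel ", chname, ": could not fit ", nb,
               " bands (insufficient controls): ", conditionMessage(e)))
      if (any(km$size < min_cluster))
        stop("channel ", chname, ": controls do not populate all ", nb,
             " expected bands (insufficient controls)")
      centers <- sort(km$centers[, 1])
      baseline[[chname]] <- centers[1]
      noise_sd[[chname]] <- sqrt(km$tot.withinss / (length(x) - nb))
      # match sorted fitted centers to subsets positionally, in the order
      # of their nominal additive amplitudes
      subsets <- subset_list(tch)
      nominal <- vapply(subsets, function(s)
        sum(amplitude_levels(assay)[s]), numeric(1))
      pos <- order(order(nominal))  # band rank of each subset
      for (j in seq_along(tch)) {
        single_idx <- 2^(j - 1) + 1L  # subset {tch[j]} in subset_list order
        levels[tch[j]] <- centers[pos[single_idx]] - baseline[[chname]]
      }
      if (any(levels[tch] < min_separation_sd * noise_sd[[chname]]))
        stop("channel ", chname, ": fitted bands collapse into noise ",
             "(insufficient controls)")
    }
  }
  gate_set(assay, baseline, levels, noise_sd,
           provenance = "derived-from-controls",
           min_separation_sd = min_separation_sd)
}

#' Manual gates from nominal assay amplitudes
#'
#' Builds a `gate_set` from the assay's declared amplitude levels and a
#' stated baseline/noise (config-driven override path, for parity with
#' hand-set instrument thresholds).
#'
#' @inheritParams gate_set
#' @return A `gate_set` with provenance `"manual"`.
#' @export
manual_gates <- function(assay, baseline = c(ch1 = 1000, ch2 = 1000),
                         noise_sd = c(ch1 = 120, ch2 = 120),
                         levels = amplitude_levels(assay)) {
  gate_set(assay, baseline, levels, noise_sd, provenance = "manual")
}

#' Assign droplets to population labels
#'
#' Each droplet falls in one band per channel (by its amplitude relative to
#' the cut points); its label is the union of the two bands' target
#' subsets. Droplets far from their assigned band centre (beyond
#' `flag_sd` noise-SDs in either channel, e.g. rain) are flagged as
#' ambiguous but still counted — dropping them would bias the Poisson
#' negative fraction.
#'
#' @param ds A `droplet_set`.
#' @param gates A `gate_set` for the same assay.
#' @param assay The `ddpcr_assay`.
#' @param flag_sd Distance (in noise-SDs) from the assigned band centre
#'   beyond which a droplet is flagged (default 4).
#' @return A list of class `population_calls`: `labels` (per droplet),
#'   `flagged` (logical per droplet), `counts` (a `population_counts`:
#'   named label counts summing to `n_total`).
#' @export
call_populations <- function(ds, gates, assay, flag_sd = 4) {
  amp <- ds$amplitudes
  lab1 <- band_index(amp$ch1, gates$cuts$ch1)
  lab2 <- band_index(amp$ch2, gates$cuts$ch2)
  labels <- character(nrow(amp))
  # vectorised over the (band1, band2) grid
  grid <- unique(data.frame(b1 = lab1, b2 = lab2))
  for (i in seq_len(nrow(grid))) {
    members <- c(gates$band_targets$ch1[[grid$b1[i]]],
                 gates$band_targets$ch2[[grid$b2[i]]])
    sel <- lab1 == grid$b1[i] & lab2 == grid$b2[i]
    labels[sel] <- population_label(members, assay)
  }
  flagged <-
    abs(amp$ch1 - gates$band_centers$ch1[lab1]) >
      flag_sd * gates$noise_sd[["ch1"]] |
    abs(amp$ch2 - gates$band_centers$ch2[lab2]) >
      flag_sd * gates$noise_sd[["ch2"]]
  tab <- table(labels)
  counts <- structure(
    list(counts = setNames(as.integer(tab), names(tab)),
         n_total = nrow(amp)),
    class = "population_counts")
  structure(list(labels = labels, flagged = flagged, counts = counts),
            class = "population_calls")
}

band_index <- function(x, cuts) findInterval(x, cuts) + 1L

#' Per-target positive droplet counts
#'
#' A combination droplet counts once toward every member target, so
#' `n_positive(T)` is the sum of counts over all labels containing `T`.
#'
#' @param pc A `population_counts` (from [call_populations()]`$counts`).
#' @param assay A `ddpcr_assay`.
#' @return A data frame with columns `target`, `n_positive`, `n_total`.
#' @examples
#' pc <- structure(list(counts = setNames(c(100L, 50L, 10L, 40L),
#'                                        c("", "WT", "WT+RPP30", "RPP30")),
#'                      n_total = 200L),
#'                 class = "population_counts")
#' positive_counts(pc, builtin_assay("AR-Amp-1/T877A"))
#' @export
positive_counts <- function(pc, assay) {
  tn <- target_names(assay)
  labels <- names(pc$counts)
  membership <- lapply(labels, label_members)
  npos <- vapply(tn, function(t)
    sum(pc$counts[vapply(membership, function(m) t %in% m, logical(1))]),
    numeric(1))
  data.frame(target = tn, n_positive = as.integer(npos),
             n_total = pc$n_total, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write / read a gate file
#'
#' Audit format: per-channel cut points, fitted baseline/levels/noise and
#' provenance, as YAML. Round-trips to an equal gate set when re-read with
#' the same assay.
#'
#' @param gates A `gate_set`.
#' @param path File path.
#' @param assay The `ddpcr_assay` the gates belong to.
#' @return `write_gates` returns `path` invisibly; `read_gates` a
#'   `gate_set`.
#' @export
write_gates <- function(gates, path) {
  yaml::write_yaml(list(
    assay_id = gates$assay_id,
    provenance = gates$provenance,
    baseline = as.list(gates$baseline),
    noise_sd = as.list(gates$noise_sd),
    levels = as.list(gates$levels)), path)
  invisible(path)
}

#' @rdname write_gates
#' @export
read_gates <- function(path, assay) {
  obj <- yaml::read_yaml(path)
  if (!identical(obj$assay_id, assay$assay_id))
    stop("gate file is for assay '", obj$assay_id, "', not '",
         assay$assay_id, "'")
  gate_set(assay,
           baseline = unlist(obj$baseline),
           levels = unlist(obj$levels),
           noise_sd = unlist(obj$noise_sd),
           provenance = obj$provenance)
}
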