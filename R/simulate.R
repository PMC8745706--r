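#' Amplitude model for the droplet simulator
#'
#' Describes the two-channel fluorescence geometry of a well: negative
#' (empty-droplet) baseline per channel, Gaussian read noise, an optional
#' fraction of "rain" droplets whose amplitude falls uniformly between
#' baseline and their cluster level, and an optional detector saturation
#' cap. Combination droplets are additive per channel before noise, which
#' reproduces the stacked/diagonal combination clusters of multiplexed
#' two-channel plots.
#'
#' @param baseline Named numeric `c(ch1 = , ch2 = )`, negative-droplet mean.
#' @param noise_sd Named numeric `c(ch1 = , ch2 = )`, per-channel read-noise
#'   SD (> 0).
#' @param rain_fraction Fraction in `[0, 1]` of positive droplets rained
#'   down; default 0 (clean clusters).
#' @param saturation_cap Optional named numeric `c(ch1 = , ch2 = )` upper
#'   clip applied to the noiseless signal.
#' @return An object of class `amplitude_model`.
#' @export
amplitude_model <- function(baseline = c(ch1 = 1000, ch2 = 1000),
                            noise_sd = c(ch1 = 120, ch2 = 120),
                            rain_fraction = 0,
                            saturation_cap = NULL) {
  stopifnot(all(noise_sd > 0), rain_fraction >= 0, rain_fraction <= 1)
  structure(list(baseline = baseline[c("ch1", "ch2")],
                 noise_sd = noise_sd[c("ch1", "ch2")],
                 rain_fraction = rain_fraction,
                 saturation_cap = saturation_cap),
            class = "amplitude_model")
}

#' Specification of one simulated well
#'
#' @param concentrations Named numeric vector, copies/uL of reaction per
#'   target; names must be targets of the assay being simulated.
#' @param n_droplets Droplets generated per well; default 20000 (QX200
#'   nominal).
#' @param droplet_volume_uL Droplet volume in uL; default 0.00085 (0.85 nL,
#'   QX200 nominal).
#' @param seed Optional integer seed; identical seeds give bit-identical
#'   wells without disturbing the global RNG stream.
#' @param well_id,sample_id Labels carried into the output.
#' @return An object of class `well_spec`.
#' @export
well_spec <- function(concentrations, n_droplets = 20000,
                      droplet_volume_uL = 0.00085, seed = NULL,
                      well_id = "A01", sample_id = "sample") {
  stopifnot(n_droplets >= 1, droplet_volume_uL > 0)
  structure(list(concentrations = concentrations,
                 n_droplets = as.integer(n_droplets),
                 droplet_volume_uL = droplet_volume_uL, seed = seed,
                 well_id = well_id, sample_id = sample_id),
            class = "well_spec")
}

#' Construct a droplet set
#'
#' One well's droplet-level data: paired channel-1/channel-2 amplitudes and,
#' for simulated wells, the ground-truth population label of every droplet
#' (member target names joined by `"+"`, `""` for empty droplets).
#'
#' @param well_id,sample_id Labels.
#' @param ch1,ch2 Numeric amplitude vectors of equal, positive length.
#' @param truth Optional character vector of ground-truth labels, same
#'   length as the amplitudes.
#' @param assay_id Optional assay identifier annotation.
#' @return An object of class `droplet_set`.
#' @export
droplet_set <- function(well_id, sample_id, ch1, ch2, truth = NULL,
                        assay_id = NULL) {
  stopifnot(length(ch1) >= 1L, length(ch1) == length(ch2),
            is.null(truth) || length(truth) == length(ch1))
  structure(list(well_id = well_id, sample_id = sample_id,
                 amplitudes = data.frame(ch1 = as.numeric(ch1),
                                         ch2 = as.numeric(ch2)),
                 truth = truth, assay_id = assay_id),
            class = "droplet_set")
}

#' @export
print.droplet_set <- function(x, ...) {
  cat(sprintf("<droplet_set> well %s sample %s: %d droplets%s\n",
              x$well_id, x$sample_id, nrow(x$amplitudes),
              if (is.null(x$truth)) "" else " (with ground truth)"))
  invisible(x)
}

n_droplets <- function(ds) nrow(ds$amplitudes)

#' Concatenate droplet sets (e.g. pooled control wells) into one set.
#' Ground truth is kept only if present in every input.
#' @param ... `droplet_set` objects, or a single list of them.
#' @return A `droplet_set`.
#' @export
bind_droplets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1]], "droplet_set"))
    sets <- sets[[1]]
  stopifnot(length(sets) >= 1L)
  truth <- if (all(!vapply(sets, function(s) is.null(s$truth), logical(1))))
    unlist(lapply(sets, `[[`, "truth"), use.names = FALSE)
  droplet_set(sets[[1]]$well_id, sets[[1]]$sample_id,
              unlist(lapply(sets, function(s) s$amplitudes$ch1)),
              unlist(lapply(sets, function(s) s$amplitudes$ch2)),
              truth = truth, assay_id = sets[[1]]$assay_id)
}

# Run `expr` under `seed` (if non-NULL) without disturbing the caller's RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Simulate one ddPCR well
#'
#' Template molecules partition into droplets independently per target with
#' Poisson counts of mean `lambda_T = concentration_T x droplet volume`. A
#' droplet's ground-truth label is the set of targets with count >= 1. Each
#' channel's amplitude is baseline + the sum of the amplitude levels of the
#' labelled targets on that channel (capped at the saturation cap if set)
#' plus Gaussian noise; a `rain_fraction` of channel-positive droplets is
#' instead placed uniformly between baseline and its cluster level.
#'
#' @param assay A `ddpcr_assay`.
#' @param spec A [well_spec()]; its concentration names must all be assay
#'   targets and values non-negative.
#' @param model An [amplitude_model()].
#' @return A `droplet_set` with ground-truth labels.
#' @examples
#' a <- builtin_assay("AR-Amp-1/T877A")
#' ds <- simulate_well(a, well_spec(c(WT = 40, RPP30 = 90), seed = 1))
#' table(ds$truth)[1:3]
#' @export
simulate_well <- function(assay, spec, model = amplitude_model()) {
  conc <- spec$concentrations
  tn <- target_names(assay)
  unknown <- setdiff(names(conc), tn)
  if (length(unknown))
    stop("concentrations name targets not in assay '", assay$assay_id,
         "': ", paste(unknown, collapse = ", "))
  if (any(conc < 0))
    stop("negative concentration for target(s): ",
         paste(names(conc)[conc < 0], collapse = ", "))
  lam <- setNames(numeric(length(tn)), tn)
  lam[names(conc)] <- conc * spec$droplet_volume_uL
  n <- spec$n_droplets
  ch <- channel_of(assay)
  lv <- amplitude_levels(assay)

  with_seed(spec$seed, {
    pos <- vapply(tn, function(t) stats::rpois(n, lam[t]) >= 1L,
                  logical(n))
    pos <- matrix(pos, nrow = n, dimnames = list(NULL, tn))
    # labels via subset code -> precomputed lookup (assay-order canonical)
    code <- as.integer(pos %*% 2^(seq_along(tn) - 1))
    lookup <- vapply(0:(2^length(tn) - 1), function(k) {
      members <- tn[bitwAnd(k, 2^(seq_along(tn) - 1)) > 0]
      paste(members, collapse = "+")
    }, character(1))
    truth <- lookup[code + 1L]

    amp <- matrix(NA_real_, n, 2)
    for (ci in 1:2) {
      chname <- c("ch1", "ch2")[ci]
      in_ch <- ch == c("CH1_FAM", "CH2_HEX")[ci]
      base <- model$baseline[[chname]]
      signal <- base +
        if (any(in_ch)) as.numeric(pos[, in_ch, drop = FALSE] %*% lv[in_ch])
        else 0
      if (model$rain_fraction > 0) {
        hot <- which(signal > base)
        if (length(hot)) {
          rained <- hot[stats::runif(length(hot)) < model$rain_fraction]
          signal[rained] <- base +
            stats::runif(length(rained)) * (signal[rained] - base)
        }
      }
      if (!is.null(model$saturation_cap))
        signal <- pmin(signal, model$saturation_cap[[chname]])
      amp[, ci] <- signal + stats::rnorm(n, 0, model$noise_sd[[chname]])
    }
    droplet_set(spec$well_id, spec$sample_id, amp[, 1], amp[, 2],
                truth = truth, assay_id = assay$assay_id)
  })
}

#' Copies-per-cell profile of a normal genome for an assay
#'
#' Reference and wild-type targets take their normal-cell allele count for
#' the given sex; mutant-probe targets are 0 (a normal genome carries no
#' mutant allele).
#'
#' @param assay A `ddpcr_assay`.
#' @param sex `"male"` or `"female"`.
#' @return Named numeric vector of copies per cell.
#' @export
normal_profile <- function(assay, sex = c("male", "female")) {
  sex <- match.arg(sex)
  p <- vapply(assay$targets, function(t)
    if (t$role == "mutant") 0 else as.numeric(t$alleles_per_normal_cell[[sex]]),
    numeric(1))
  setNames(p, target_names(assay))
}

#' Simulate a well from a per-cell genome profile
#'
#' Converts copies-per-cell (e.g. male normal: WT = 1, RPP30 = 2) and a
#' genome concentration into per-target copies/uL and delegates to
#' [simulate_well()]. Two profiles can be mixed at a stated mass ratio,
#' emulating spike-in experiments such as a 2:1 mutant:high-CN gDNA mix.
#'
#' @param assay A `ddpcr_assay`.
#' @param profile Named copies-per-cell vector (targets of `assay`).
#' @param genome_equivalents_per_uL Haploid-genome concentration of the
#'   (first) DNA in the reaction, copies/uL. Default 45, giving a diploid
#'   reference gene ~90 copies/uL as seen for a few ng of gDNA per well.
#' @param profile2 Optional second profile to mix in.
#' @param mass_ratio Length-2 mass ratio of `profile`:`profile2`
#'   (default `c(2, 1)`).
#' @param ... Passed to [well_spec()] (`n_droplets`, `seed`, `well_id`, ...).
#' @param model An [amplitude_model()].
#' @return A `droplet_set`.
#' @export
simulate_sample <- function(assay, profile, genome_equivalents_per_uL = 45,
                            profile2 = NULL, mass_ratio = c(2, 1), ...,
                            model = amplitude_model()) {
  stopifnot(all(profile >= 0), is.null(profile2) || all(profile2 >= 0))
  tn <- target_names(assay)
  full <- function(p) {
    out <- setNames(numeric(length(tn)), tn)
    out[names(p)] <- p
    out
  }
  conc <- full(profile) * genome_equivalents_per_uL
  if (!is.null(profile2)) {
    w <- mass_ratio / sum(mass_ratio)
    conc <- genome_equivalents_per_uL *
      (w[1] * full(profile) + w[2] * full(profile2))
  }
  simulate_well(assay, well_spec(conc, ...), model = model)
}

#' Write / read a ground-truth sidecar table
#'
#' One row per droplet: well id, 1-based droplet index, and the true
#' population label (`""` for empty droplets). Round-trips exactly.
#'
#' @param ds A simulated `droplet_set` with truth labels.
#' @param path File path (CSV).
#' @return `write_ground_truth` returns `path` invisibly;
#'   `read_ground_truth` the label character vector.
#' @export
write_ground_truth <- function(ds, path) {
  if (is.null(ds$truth))
    stop("droplet set has no ground-truth labels (instrument data?)")
  utils::write.csv(
    data.frame(well = ds$well_id, droplet = seq_along(ds$truth),
               label = ds$truth, stringsAsFactors = FALSE),
    path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(label = "character"))
  df$label[is.na(df$label)] <- ""
  df$label
}
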