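#' Define a single ddPCR target
#'
#' A target is one primer/probe set read on one fluorescence channel. In an
#' amplitude-multiplexed assay several targets share a channel and are
#' distinguished by the intensity band their single-positive droplets occupy.
#'
#' @param name Target identifier, unique within an assay (e.g. `"RPP30"`).
#' @param channel Detection channel, `"CH1_FAM"` or `"CH2_HEX"`.
#' @param amplitude_level Expected amplitude of the single-positive cluster
#'   above baseline, in arbitrary fluorescence units. Must be positive.
#' @param role One of `"mutant"`, `"wildtype"`, `"gene_target"`,
#'   `"reference"`. Reference targets normalise copy number.
#' @param chromosome Chromosome label, e.g. `"X"`, `"10"`.
#' @param alleles_per_normal_cell Named integer vector
#'   `c(male = , female = )` giving the locus copy number in a normal cell
#'   (1 or 2). X-chromosomal loci have one allele per normal male cell.
#' @return An object of class `ddpcr_target`.
#' @export
target_def <- function(name, channel, amplitude_level, role, chromosome,
                       alleles_per_normal_cell) {
  channel <- match.arg(channel, c("CH1_FAM", "CH2_HEX"))
  role <- match.arg(role, c("mutant", "wildtype", "gene_target", "reference"))
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  apc <- as.integer(alleles_per_normal_cell[c("male", "female")])
  names(apc) <- c("male", "female")
  structure(
    list(name = name, channel = channel,
         amplitude_level = as.numeric(amplitude_level), role = role,
         chromosome = as.character(chromosome),
         alleles_per_normal_cell = apc),
    class = "ddpcr_target")
}

#' Assemble an assay design
#'
#' An assay design declares the multiplexed targets, their channels and
#' amplitude bands, and the reference-gene ploidy, so that gating,
#' quantification and copy-number calling are generic over assays.
#'
#' @param assay_id Assay identifier.
#' @param targets List of [target_def()] objects.
#' @param probe_metadata Optional free-form per-target annotation (primer and
#'   probe sequences, working concentrations). Carried, never computed on.
#' @return An object of class `ddpcr_assay`.
#' @seealso [builtin_assay()], [validate_assay()]
#' @export
assay_design <- function(assay_id, targets, probe_metadata = NULL) {
  stopifnot(is.character(assay_id), length(assay_id) == 1L,
            is.list(targets), length(targets) >= 1L,
            all(vapply(targets, inherits, logical(1), "ddpcr_target")))
  names(targets) <- vapply(targets, `[[`, character(1), "name")
  structure(
    list(assay_id = assay_id, targets = targets,
         probe_metadata = probe_metadata),
    class = "ddpcr_assay")
}

#' @export
print.ddpcr_assay <- function(x, ...) {
  cat(sprintf("<ddpcr_assay> %s\n", x$assay_id))
  for (t in x$targets)
    cat(sprintf("  %-8s %s level %g  role %-10s chr %s (M:%d F:%d)\n",
                t$name, t$channel, t$amplitude_level, t$role, t$chromosome,
                t$alleles_per_normal_cell[["male"]],
                t$alleles_per_normal_cell[["female"]]))
  invisible(x)
}

target_names <- function(assay) names(assay$targets)

channel_of <- function(assay) {
  vapply(assay$targets, `[[`, character(1), "channel")
}

amplitude_levels <- function(assay) {
  vapply(assay$targets, `[[`, numeric(1), "amplitude_level")
}

#' Canonical droplet label for a set of targets
#'
#' Labels are the member target names in assay order joined by `"+"`; the
#' empty set is `""` (an empty droplet).
#' @param members Character vector of target names (any order).
#' @param assay The `ddpcr_assay` the names belong to.
#' @return A length-1 character label.
#' @export
population_label <- function(members, assay) {
  paste(intersect(target_names(assay), members), collapse = "+")
}

label_members <- function(label) {
  if (!nzchar(label)) character(0) else strsplit(label, "+", fixed = TRUE)[[1]]
}

# Table-1-derived primer/probe annotation for the built-in assays.
builtin_probe_metadata <- function(assay_id) {
  if (assay_id == "AR-Amp-1/T877A") {
    data.frame(
      target = c("MT", "WT", "RPP30"),
      forward_primer = c(rep("CCCTACAGATTGCGAGAGAGC", 2),
                         "GATTTGGACCTGCGAGCG"),
      reverse_primer = c(rep("GAAAGTCCACGCTCACCATGT", 2),
                         "GCGGCTGTCTCCACAAGT"),
      primer_nM = c(500, 500, 500),
      probe = c("[6FAM]ATCAGTTCGCTTTTGACCTG[BHQ1]",
                "[HEX]ATCAGTTCACTTTTGACCTG[BHQ1]",
                "[HEX]TCTGACCTGAAGGCTCTG[BHQ1]"),
      probe_nM = c(250, 250, 250),
      stringsAsFactors = FALSE)
  } else {
    data.frame(
      target = c("AR-X1", "AR-X2", "MYM", "TBP"),
      forward_primer = c("CCTATGCAAATGCCTGCCTG", "TTTCCACCCCAGAAGACCTG",
                         "ACAGGGAACAGAACAAGCTGGTCTT",
                         "ACAGAAGTTGGGTTTTCCAGC"),
      reverse_primer = c("GCACTCTGCATTCGTTTCCC", "AAGACCTTGCAGCTTCCACA",
                         "GCAAGACCCTGTGTAAGAACTTTGA",
                         "TCACATCACAGCTCCCCAC"),
      primer_nM = c(500, 500, 1000, 500),
      probe = c("[6FAM]AAGTCCGGTACAAAGCCAG[BHQ1]",
                "[6FAM]CACCCAGAAGCTTCATCTC[BHQ1]",
                "[HEX]CATTACGATCCACATGTGATAG[BHQ]",
                "[HEX]TCTTGGACTTCAAGATTCAG[BHQ1]"),
      probe_nM = c(125, 250, 250, 500),
      stringsAsFactors = FALSE)
  }
}

#' Built-in assay designs
#'
#' Two amplitude-multiplexed AR assays are shipped:
#' \describe{
#'   \item{`"AR-Amp-1/T877A"`}{Mutation + copy number. T877A mutant probe
#'     (MT) on FAM, wild-type probe (WT) and the chromosome-10 reference
#'     RPP30 on HEX at distinct bands. AR CN = (WT + MT)/RPP30 x 2.}
#'   \item{`"AR-Amp-2"`}{Copy number cross-validation. Two AR amplicons
#'     (exon 1 AR-X1, exon 2 AR-X2) on FAM; references MYM (X-chromosomal,
#'     hemizygous in males) and TBP (chromosome 6) on HEX.
#'     AR CN = (AR-X1 + AR-X2)/(MYM* + TBP) x 2 with MYM* = 2 x MYM for
#'     male samples.}
#' }
#' Amplitude levels are simulator defaults chosen for clean band separation;
#' instrument data are gated against run controls, not these nominals.
#'
#' @param assay_id One of the identifiers above.
#' @return A `ddpcr_assay`.
#' @examples
#' builtin_assay("AR-Amp-2")
#' @export
builtin_assay <- function(assay_id) {
  known <- c("AR-Amp-1/T877A", "AR-Amp-2")
  if (!assay_id %in% known)
    stop("unknown assay_id '", assay_id, "'; built-ins are: ",
         paste(known, collapse = ", "))
  if (assay_id == "AR-Amp-1/T877A") {
    targets <- list(
      target_def("MT", "CH1_FAM", 5000, "mutant", "X",
                 c(male = 1L, female = 2L)),
      target_def("WT", "CH2_HEX", 3000, "wildtype", "X",
                 c(male = 1L, female = 2L)),
      target_def("RPP30", "CH2_HEX", 6000, "reference", "10",
                 c(male = 2L, female = 2L)))
  } else {
    targets <- list(
      target_def("AR-X1", "CH1_FAM", 3000, "gene_target", "X",
                 c(male = 1L, female = 2L)),
      target_def("AR-X2", "CH1_FAM", 6000, "gene_target", "X",
                 c(male = 1L, female = 2L)),
      target_def("MYM", "CH2_HEX", 3000, "reference", "X",
                 c(male = 1L, female = 2L)),
      target_def("TBP", "CH2_HEX", 6000, "reference", "6",
                 c(male = 2L, female = 2L)))
  }
  assay_design(assay_id, targets, builtin_probe_metadata(assay_id))
}

#' Validate an assay design
#'
#' Checks the structural invariants amplitude multiplexing relies on.
#' Violations are returned, not raised, so designs can be inspected.
#'
#' @param assay A `ddpcr_assay`.
#' @return Character vector of violation messages; empty if valid.
#' @export
validate_assay <- function(assay) {
  v <- character(0)
  tn <- target_names(assay)
  if (anyDuplicated(tn))
    v <- c(v, sprintf("duplicate target names: %s",
                      paste(unique(tn[duplicated(tn)]), collapse = ", ")))
  roles <- vapply(assay$targets, `[[`, character(1), "role")
  if (!any(roles == "reference"))
    v <- c(v, "assay has no reference target")
  for (t in assay$targets) {
    if (!is.finite(t$amplitude_level) || t$amplitude_level <= 0)
      v <- c(v, sprintf("target %s: amplitude_level must be > 0", t$name))
    apc <- t$alleles_per_normal_cell
    if (!all(apc %in% 1:2))
      v <- c(v, sprintf("target %s: alleles per normal cell must be 1 or 2",
                        t$name))
    if (identical(t$chromosome, "X") &&
        !(apc[["male"]] == 1L && apc[["female"]] == 2L))
      v <- c(v, sprintf(
        "target %s: X-chromosomal targets need male=1, female=2 alleles",
        t$name))
  }
  ch <- channel_of(assay)
  lv <- amplitude_levels(assay)
  for (channel in unique(ch)) {
    l <- lv[ch == channel]
    if (anyDuplicated(l))
      v <- c(v, sprintf(
        "channel %s: amplitude levels not strictly distinct (%s)",
        channel, paste(l, collapse = ", ")))
  }
  v
}

#' Write / read an assay design as a YAML config
#'
#' The config schema mirrors the `ddpcr_assay` structure: `assay_id`, a
#' `targets` list (name, channel, amplitude_level, role, chromosome,
#' alleles_per_normal_cell) and optional `probe_metadata` rows. Round-trips
#' to an equal design. The two built-in designs ship as packaged configs
#' under `extdata/assays/`.
#'
#' @param assay A `ddpcr_assay`.
#' @param path File path.
#' @return `write_assay_config` returns `path` invisibly;
#'   `read_assay_config` returns a `ddpcr_assay`.
#' @export
write_assay_config <- function(assay, path) {
  tgt <- lapply(unname(assay$targets), function(t)
    list(name = t$name, channel = t$channel,
         amplitude_level = t$amplitude_level, role = t$role,
         chromosome = t$chromosome,
         alleles_per_normal_cell = as.list(t$alleles_per_normal_cell)))
  obj <- list(assay_id = assay$assay_id, targets = tgt)
  if (!is.null(assay$probe_metadata))
    obj$probe_metadata <- lapply(seq_len(nrow(assay$probe_metadata)),
                                 function(i) as.list(assay$probe_metadata[i, ]))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_assay_config
#' @export
read_assay_config <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$assay_id) || is.null(obj$targets))
    stop("assay config must contain 'assay_id' and 'targets': ", path)
  targets <- lapply(obj$targets, function(t)
    target_def(t$name, t$channel, t$amplitude_level, t$role, t$chromosome,
               c(male = t$alleles_per_normal_cell$male,
                 female = t$alleles_per_normal_cell$female)))
  pm <- NULL
  if (!is.null(obj$probe_metadata))
    pm <- do.call(rbind,
                  lapply(obj$probe_metadata, as.data.frame,
                         stringsAsFactors = FALSE))
  assay_design(obj$assay_id, targets, pm)
}
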