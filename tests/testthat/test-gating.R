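test_that("control-derived gates recover the simulated band geometry", {
  ctrl <- control_well(amp1, seed = 21)
  g <- derive_gates(ctrl, amp1)
  m <- amplitude_model()
  # CH1 carries one target (MT): 2 bands, 1 cut; CH2 carries WT and RPP30:
  # 4 bands (neg, WT, RPP30, WT+RPP30 additive), 3 cuts
  expect_length(g$cuts$ch1, 1)
  expect_length(g$cuts$ch2, 3)
  expect_true(all(diff(g$cuts$ch2) > 0))
  # fitted centres close to the simulator's truth-label cluster means
  expect_lt(abs(g$baseline[["ch1"]] - m$baseline[["ch1"]]), 20)
  expect_lt(abs(g$levels[["WT"]] - amp1$targets$WT$amplitude_level), 30)
  expect_lt(abs(g$levels[["RPP30"]] - amp1$targets$RPP30$amplitude_level), 30)

  # the four-plex enumerates all 16 combination labels
  g2 <- gates_amp2
  expect_length(g2$band_targets$ch1, 4)
  expect_length(g2$band_targets$ch2, 4)
  all_labels <- outer(seq_len(4), seq_len(4), Vectorize(function(i, j)
    population_label(c(g2$band_targets$ch1[[i]], g2$band_targets$ch2[[j]]),
                     amp2)))
  expect_length(unique(as.vector(all_labels)), 16)
})

test_that("gates can be fit without truth labels via per-channel k-means", {
  ctrl <- control_well(amp1, copies_per_uL = 150, seed = 22)
  ctrl$truth <- NULL
  g <- derive_gates(ctrl, amp1)
  expect_lt(abs(g$levels[["WT"]] - amp1$targets$WT$amplitude_level), 60)
  expect_lt(abs(g$levels[["RPP30"]] - amp1$targets$RPP30$amplitude_level), 60)
  ds <- simulate_well(amp1, well_spec(c(MT = 30, WT = 60, RPP30 = 120),
                                      seed = 23))
  calls <- call_populations(ds, g, amp1)
  expect_gt(mean(calls$labels == ds$truth), 0.995)
})

test_that("insufficient controls and inseparable bands are rejected", {
  # single-population input: no WT or RPP30 singles to fit
  only_neg <- simulate_well(amp1, well_spec(c(WT = 0), n_droplets = 5000,
                                            seed = 2))
  expect_error(derive_gates(only_neg, amp1), "single-positive")
  only_neg$truth <- NULL
  expect_error(derive_gates(only_neg, amp1), "insufficient controls")

  # bands closer than 4 pooled noise-SDs cannot be separated
  cramped <- assay_design("cramped", list(
    target_def("A", "CH2_HEX", 300, "gene_target", "1", c(male = 2, female = 2)),
    target_def("B", "CH2_HEX", 600, "reference", "1", c(male = 2, female = 2))))
  ctrl <- control_well(cramped, seed = 4)
  expect_error(derive_gates(ctrl, cramped), "inseparable")
})

test_that("clean wells are labelled to >=99.5% agreement with ground truth", {
  for (seed in c(31, 32, 33)) {
    ds <- simulate_well(amp2,
                        well_spec(c("AR-X1" = 300, "AR-X2" = 350, MYM = 100,
                                    TBP = 200), seed = seed))
    calls <- call_populations(ds, gates_amp2, amp2)
    expect_gt(mean(calls$labels == ds$truth), 0.995)
    # conservation: population counts always sum to the droplet total
    expect_identical(sum(calls$counts$counts), calls$counts$n_total)
  }
})

test_that("empty and single-target wells produce the expected labels", {
  empty <- simulate_well(amp1, well_spec(c(WT = 0), n_droplets = 2000,
                                         seed = 6))
  calls <- call_populations(empty, gates_amp1, amp1)
  expect_true(all(calls$labels == ""))

  rp_only <- simulate_well(amp1, well_spec(c(RPP30 = 400), seed = 7))
  calls <- call_populations(rp_only, gates_amp1, amp1)
  hit <- unique(calls$labels[calls$labels != ""])
  expect_true(all(vapply(hit, function(l)
    "RPP30" %in% strsplit(l, "+", fixed = TRUE)[[1]], logical(1))))
})

test_that("rain droplets are flagged as ambiguous but still counted", {
  rainy <- simulate_well(amp1, well_spec(c(WT = 200, RPP30 = 200), seed = 8),
                         model = amplitude_model(rain_fraction = 0.2))
  calls <- call_populations(rainy, gates_amp1, amp1)
  expect_gt(sum(calls$flagged), 0)
  expect_identical(sum(calls$counts$counts), nrow(rainy$amplitudes))
  clean <- simulate_well(amp1, well_spec(c(WT = 200, RPP30 = 200), seed = 8))
  expect_lt(mean(call_populations(clean, gates_amp1, amp1)$flagged), 0.01)
})

test_that("positive counts sum combination droplets once per member target", {
  pc <- structure(list(counts = setNames(c(100L, 50L, 10L, 40L),
                                         c("", "WT", "WT+RPP30", "RPP30")),
                       n_total = 200L),
                  class = "population_counts")
  out <- positive_counts(pc, amp1)
  expect_identical(out$n_positive[out$target == "WT"], 60L)
  expect_identical(out$n_positive[out$target == "RPP30"], 50L)
  expect_identical(out$n_positive[out$target == "MT"], 0L)
  expect_true(all(out$n_total == 200L))

  # monotonicity: adding a droplet with WT never decreases WT positives
  pc2 <- pc
  pc2$counts[["WT"]] <- pc2$counts[["WT"]] + 1
  pc2$n_total <- pc2$n_total + 1L
  out2 <- positive_counts(pc2, amp1)
  expect_gte(out2$n_positive[out2$target == "WT"],
             out$n_positive[out$target == "WT"])
})

test_that("gate files round-trip and refuse the wrong assay", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_gates(gates_amp2, path)
  back <- read_gates(path, amp2)
  expect_equal(back$cuts, gates_amp2$cuts, tolerance = 1e-9)
  expect_identical(back$band_targets, gates_amp2$band_targets)
  expect_error(read_gates(path, amp1), "is for assay")
})
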