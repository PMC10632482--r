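stress_trace <- function(ocr, ecar = ocr / 4, k = 3, well = "A1") {
  nt <- 4 * k
  SeahorseTrace(well, time = seq_len(nt) * 30,
                ocr = rep(ocr, each = k), ecar = rep(ecar, each = k),
                injections = data.frame(
                  label = c("oligomycin", "FCCP", "rotenone/antimycinA"),
                  time = (c(1, 2, 3) * k + 0.5) * 30))
}

test_that("segmentation partitions every measurement exactly once", {
  segs <- segmentTrace(stress_trace(c(100, 30, 160, 10)))
  expect_named(segs, c("pre_oligo", "post_oligomycin", "post_FCCP",
                       "post_RA"))
  expect_equal(vapply(segs, function(s) length(s$ocr), integer(1)),
               c(pre_oligo = 3L, post_oligomycin = 3L, post_FCCP = 3L,
                 post_RA = 3L))
  set.seed(41)
  for (k in c(2, 3, 5)) {
    tr <- stress_trace(runif(4, 10, 200), k = k)
    segs <- segmentTrace(tr)
    expect_equal(sum(vapply(segs, function(s) length(s$time), integer(1))),
                 4 * k)
  }
})

test_that("injections outside the span or empty segments are rejected", {
  expect_error(
    SeahorseTrace("A1", time = 1:4, ocr = 1:4, ecar = 1:4,
                  injections = data.frame(label = "oligomycin", time = 10)),
    "span")
  expect_error(
    SeahorseTrace("A1", time = 1:12, ocr = 1:12, ecar = 1:12,
                  injections = data.frame(
                    label = c("oligomycin", "FCCP"), time = c(3.2, 3.7))),
    NA)  # construction fine, but FCCP segment between 3.2 and 3.7 is empty
  tr <- SeahorseTrace("A1", time = 1:12, ocr = 1:12, ecar = 1:12,
                      injections = data.frame(
                        label = c("oligomycin", "FCCP"), time = c(3.2, 3.7)))
  expect_error(segmentTrace(tr), "empty segment")
})

test_that("index formulas recover the plateau arithmetic", {
  idx <- computeSeahorseIndices(stress_trace(c(100, 30, 160, 10),
                                             ecar = c(20, 35, 30, 5)))
  expect_equal(idx$basal_respiration, 90)
  expect_equal(idx$maximal_oxygen_consumption, 150)
  expect_equal(idx$spare_respiratory_capacity, 60)
  expect_equal(idx$proton_leak, 20)
  expect_equal(idx$atp_linked_respiration, 70)
  expect_equal(idx$basal_glycolysis, 15)
  expect_equal(idx$glycolytic_capacity, 30)
})

test_that("constant traces give zero OCR indices; identical paired trace
           gives zero exogenous FAO", {
  tr <- stress_trace(c(50, 50, 50, 50))
  idx <- computeSeahorseIndices(tr)
  expect_equal(idx$basal_respiration, 0)
  expect_equal(idx$maximal_oxygen_consumption, 0)
  expect_equal(idx$proton_leak, 0)
  idx2 <- computeSeahorseIndices(stress_trace(c(100, 30, 160, 10)),
                                 paired = stress_trace(c(100, 30, 160, 10)))
  expect_equal(idx2$exogenous_fao_max, 0)
})

test_that("algebraic identities and shift invariance hold on noisy traces", {
  set.seed(42)
  for (i in 1:20) {
    ocr <- runif(4, 5, 200)
    k <- sample(2:5, 1)
    noise <- rnorm(4 * k, 0, 3)
    tr <- stress_trace(ocr, k = k)
    tr@ocr <- tr@ocr + noise
    idx <- suppressWarnings(computeSeahorseIndices(tr))
    expect_equal(idx$spare_respiratory_capacity,
                 idx$maximal_oxygen_consumption - idx$basal_respiration,
                 tolerance = 1e-12)
    expect_equal(idx$atp_linked_respiration,
                 idx$basal_respiration - idx$proton_leak,
                 tolerance = 1e-12)
    shifted <- tr
    shifted@ocr <- tr@ocr + 37.5
    idx_s <- suppressWarnings(computeSeahorseIndices(shifted))
    ocr_idx <- c("basal_respiration", "maximal_oxygen_consumption",
                 "spare_respiratory_capacity", "proton_leak",
                 "atp_linked_respiration")
    expect_equal(unlist(idx_s[ocr_idx]), unlist(idx[ocr_idx]),
                 tolerance = 1e-9)
  }
})

test_that("negative indices are reported with a warning, not clipped", {
  expect_warning(idx <- computeSeahorseIndices(
    stress_trace(c(10, 30, 5, 20))), "negative")
  expect_lt(idx$basal_respiration, 0)
})

test_that("with linear aggregators, indices of the mean trace equal the
           mean of per-well indices", {
  set.seed(43)
  agg <- seahorseAggregators(
    ocr = list(post_oligomycin = "mean", post_FCCP = "mean",
               post_RA = "mean"),
    ecar = list(post_oligomycin = "mean", post_RA = "mean"))
  wells <- lapply(1:3, function(i) {
    tr <- stress_trace(c(100, 30, 160, 10))
    tr@ocr <- tr@ocr + rnorm(12, 0, 4)
    tr@ecar <- tr@ecar + rnorm(12, 0, 2)
    tr
  })
  per_well <- do.call(rbind, lapply(wells, computeSeahorseIndices,
                                    aggregators = agg))
  mean_trace <- wells[[1]]
  mean_trace@ocr <- rowMeans(vapply(wells, slot, numeric(12), "ocr"))
  mean_trace@ecar <- rowMeans(vapply(wells, slot, numeric(12), "ecar"))
  expect_equal(unlist(averageReplicateIndices(per_well)),
               unlist(computeSeahorseIndices(mean_trace,
                                             aggregators = agg)[-1]),
               tolerance = 1e-9)
})

test_that("scaling conventions and round trip", {
  df <- data.frame(a = c(1, 2, 3), b = c(2, 4, 6))
  z <- scaleIndices(df, "zscore")
  expect_equal(mean(z$a), 0)
  expect_equal(sd(z$a), 1)
  expect_equal(z$a, c(-1, 0, 1))
  mm <- scaleIndices(df, "minmax")
  expect_equal(mm$b, c(0, 0.5, 1))
  cs <- attr(z, "center_scale")$a
  expect_equal(z$a * cs[["scale"]] + cs[["center"]], df$a)
  expect_warning(scaleIndices(data.frame(a = c(1, 1, 1), b = 1:3)),
                 "zero-variance")
  expect_error(scaleIndices(df[1, , drop = FALSE]), ">= 2")
})

test_that("noiseless generated traces return the configured indices
           exactly", {
  cfg <- small_config(seed = 88)
  tr <- generateSeahorseTrace(cfg, "good", noise_sd = 0)
  idx <- computeSeahorseIndices(tr$control, tr$palmitate_etomoxir)
  expect_equal(idx$basal_respiration, 100 - 10)
  expect_equal(idx$maximal_oxygen_consumption, 160 - 10)
  expect_equal(idx$proton_leak, 30 - 10)
  expect_equal(idx$glycolytic_capacity, 35 - 5)
  expect_equal(idx$exogenous_fao_max, 40)
})

test_that("noisy basal respiration is recovered without bias under linear
           aggregators", {
  agg <- seahorseAggregators(
    ocr = list(post_oligomycin = "mean", post_FCCP = "mean",
               post_RA = "mean"),
    ecar = list(post_oligomycin = "mean", post_RA = "mean"))
  cfg6 <- small_config(seed = 89,
                       seahorse = list(good = list(
                         segments = list(
                           ocr = c(pre_oligo = 100, post_oligomycin = 30,
                                   post_FCCP = 160, post_RA = 10),
                           ecar = c(pre_oligo = 20, post_oligomycin = 35,
                                    post_FCCP = 30, post_RA = 5)),
                         noise_sd = 5, n_per_segment = 6, fao_drop = 40)))
  basal <- vapply(1:50, function(i) {
    tr <- generateSeahorseTrace(cfg6, "good", seed = 10000 + i)
    computeSeahorseIndices(tr$control, aggregators = agg)$basal_respiration
  }, numeric(1))
  expect_lt(abs(mean(basal) - 90), 2)
})
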