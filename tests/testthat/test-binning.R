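make_o_events <- function(puro, sample_id = "s1") {
  EventTable(data.frame(sample_id = sample_id, condition = "O",
                        population = "mDC", viability_pass = TRUE,
                        puromycin = puro),
             puromycinChannel = "puromycin")
}

# bin_oracle(): shared sort-based binning oracle in helper-synthetic.R

test_that("eight ordered cells split into exact quartile pairs", {
  asg <- assignOligomycinQuantiles(make_o_events(1:8))
  expect_equal(asg$bin, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
})

test_that("fewer than 8 oligomycin cells is an error", {
  expect_error(assignOligomycinQuantiles(make_o_events(1:7)), ">= 8")
})

test_that("degenerate all-identical intensities collapse to bin 1 with a
           warning", {
  expect_warning(asg <- assignOligomycinQuantiles(make_o_events(rep(5, 20))),
                 "degenerate")
  expect_true(all(asg$bin == 1L))
})

test_that("binning agrees with the sort-based brute-force oracle", {
  set.seed(91)
  x <- rlnorm(10000, log(200), 0.6)
  asg <- assignOligomycinQuantiles(make_o_events(x))
  expect_equal(asg$bin, bin_oracle(x))
  expect_true(all(abs(table(asg$bin) - 2500) <= 1))
})

test_that("binning only uses rank information (monotone-transform
           invariant) and ignores non-O conditions", {
  set.seed(92)
  x <- rlnorm(500, log(100), 0.5)
  b1 <- assignOligomycinQuantiles(make_o_events(x))$bin
  b2 <- assignOligomycinQuantiles(make_o_events(log(x)))$bin
  b3 <- assignOligomycinQuantiles(make_o_events(x^3))$bin
  expect_equal(b1, b2)
  expect_equal(b1, b3)

  df <- rbind(eventData(make_o_events(x)),
              data.frame(sample_id = "s1", condition = "C",
                         population = "mDC", viability_pass = TRUE,
                         puromycin = rep(1e6, 50)))
  withC <- assignOligomycinQuantiles(
    EventTable(df, puromycinChannel = "puromycin"))
  expect_equal(withC$bin, b1)
})

test_that("cohort-scope boundaries do not depend on sample order", {
  set.seed(93)
  df <- data.frame(sample_id = rep(c("a", "b", "c"), each = 200),
                   condition = "O", population = "mDC",
                   viability_pass = TRUE,
                   puromycin = rlnorm(600, log(150), c(0.4, 0.6, 0.5)))
  ev1 <- EventTable(df, puromycinChannel = "puromycin")
  perm <- order(rev(seq_len(nrow(df))))
  ev2 <- EventTable(df[rev(seq_len(nrow(df))), ],
                    puromycinChannel = "puromycin")
  a1 <- assignOligomycinQuantiles(ev1)
  a2 <- assignOligomycinQuantiles(ev2)
  expect_equal(attr(a1, "boundaries"), attr(a2, "boundaries"))
  m1 <- a1$bin[order(a1$puromycin)]
  m2 <- a2$bin[order(a2$puromycin)]
  expect_equal(m1, m2)
})

test_that("bin proportions sum to one and respect group symmetry", {
  set.seed(94)
  x <- rlnorm(400, log(100), 0.5)
  asg <- assignOligomycinQuantiles(make_o_events(x))
  p1 <- binProportionsByGroup(asg, c(s1 = "g1"))
  expect_equal(sum(p1$proportion), 1, tolerance = 1e-9)
  expect_equal(p1$proportion, rep(0.25, 4))

  # two groups built from identical cell sets -> identical vectors
  df <- rbind(eventData(make_o_events(x, "sA")),
              eventData(make_o_events(x, "sB")))
  asg2 <- assignOligomycinQuantiles(
    EventTable(df, puromycinChannel = "puromycin"))
  p2 <- binProportionsByGroup(asg2, c(sA = "g1", sB = "g2"))
  expect_equal(p2$proportion[p2$group == "g1"],
               p2$proportion[p2$group == "g2"])

  expect_error(binProportionsByGroup(asg2, c(sA = "g1")), "sB")
})

test_that("generator's glycolytic enrichment lands in bin 4 of the bad
           group", {
  cfg <- small_config(seed = 555, cells = 800)
  ch <- generateCohort(cfg)
  asg <- assignOligomycinQuantiles(ch$events)
  props <- binProportionsByGroup(asg, ch$groups)
  bad4 <- props$proportion[props$group == "bad" & props$bin == 4]
  expect_gt(bad4, max(props$proportion[props$group != "bad" &
                                         props$bin == 4]))
})

test_that("marker coupled to the latent glycolytic state rises
           monotonically across bins", {
  cfg <- small_config(seed = 777, cells = 1500)
  ev <- generateCellEvents(cfg, "good", "sA")
  asg <- assignOligomycinQuantiles(ev)
  df <- eventData(ev)
  df <- df[df$condition == "O", ]
  meds <- vapply(1:4, function(b) median(df$ILT3[asg$bin == b]), numeric(1))
  expect_true(all(diff(meds) > 0))
  anti <- vapply(1:4, function(b) median(df$CD86[asg$bin == b]), numeric(1))
  expect_true(all(diff(anti) < 0))
})

test_that("per-bin marker tests: null, spiked and degenerate paths", {
  set.seed(95)
  base <- data.frame(sample_id = "hd1", condition = "O", population = "mDC",
                     viability_pass = TRUE,
                     puromycin = rlnorm(400, log(100), 0.5),
                     mk = rnorm(400, 50, 5), flat = 1)
  dup <- base
  dup$sample_id <- "pt1"
  groups <- c(hd1 = "HD", pt1 = "good")
  ev <- EventTable(rbind(base, dup), puromycinChannel = "puromycin")
  asg <- assignOligomycinQuantiles(ev)

  # identical groups: every computable contrast has adjusted p = 1
  cmp <- perBinMarkerComparison(ev, asg, markers = "mk", groups = groups,
                                reference_group = "HD")
  expect_true(all(cmp$p_holm[!is.na(cmp$p_holm)] > 0.999))

  # constant marker everywhere: flagged, never silently dropped
  cmp0 <- perBinMarkerComparison(ev, asg, markers = "flat", groups = groups,
                                 reference_group = "HD")
  expect_true(all(grepl("not_computable", cmp0$flag)))
  expect_equal(nrow(cmp0), 4)

  # marker shifted +2 SD only in bin 4 of the patient group
  spiked <- rbind(base, dup)
  sel <- spiked$sample_id == "pt1"
  bin4 <- asg$bin == 4 & asg$sample_id == "pt1"
  spiked$mk[sel][asg$bin[asg$sample_id == "pt1"] == 4] <-
    spiked$mk[sel][asg$bin[asg$sample_id == "pt1"] == 4] + 10
  ev2 <- EventTable(spiked, puromycinChannel = "puromycin")
  cmp2 <- perBinMarkerComparison(ev2, asg, markers = "mk", groups = groups,
                                 reference_group = "HD")
  expect_equal(cmp2$bin[which.min(cmp2$p_holm)], 4)
})
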