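test_that("the behavioral generator respects the study layout", {
  design <- synth_design()
  beh <- generate_behavior(design, seed = 41)
  tr <- beh$trials
  expect_equal(nrow(tr), 2 * 2 * 160)
  expect_equal(unname(table(tr$condition)), rep(160L, 4),
               ignore_attr = TRUE)
  ok <- tr[!tr$excluded, ]
  # deadlines are enforced per urgency condition
  expect_true(all(ok$rt[ok$urgency == "speed"] <= 1))
  expect_true(all(ok$rt[ok$urgency == "accuracy"] <= 1.6))
  # qualitative speed-accuracy pattern: slower under accuracy instructions,
  # and better accuracy for high than low sensory evidence
  expect_gt(mean(ok$rt[ok$urgency == "accuracy"]),
            mean(ok$rt[ok$urgency == "speed"]))
  expect_gt(mean(ok$correct[ok$condition %in% c(2, 4)]),
            mean(ok$correct[ok$condition %in% c(1, 3)]))
  # hands follow the category mapping for correct responses
  corr_face <- ok$condition %in% c(1, 2) & ok$correct
  expect_true(all(ok$hand[corr_face] == "left"))
  # seeded reproducibility
  beh2 <- generate_behavior(design, seed = 41)
  expect_identical(beh$trials$rt, beh2$trials$rt)
})

test_that("synthetic epochs carry planted components with matched metadata", {
  design <- synth_design(trials_per_block = 32L, blocks_per_urgency = 1L)
  beh <- generate_behavior(design, seed = 43)
  synth <- generate_eeg(design, beh, seed = 44)
  ep <- synth$epochs
  expect_equal(dim(ep$data)[1], nrow(ep$metadata))
  expect_equal(dim(ep$data)[2], 64L)
  expect_equal(sum(!beh$trials$excluded), dim(ep$data)[1])
  # planted topographies are unit-norm and zero-mean (average-reference safe)
  expect_equal(sum(synth$truth$evidence_topo^2), 1)
  expect_lt(abs(mean(synth$truth$motor_topo$left)), 1e-12)
  # matched-filter readout against noiseless truth
  rec <- project_signal(ep, synth$truth$evidence_topo, zscore = FALSE)
  expect_gt(cor(as.numeric(rec), as.numeric(synth$truth$evidence_signal)),
            0.6)
  # zero signal gain means chance-level decoding
  d0 <- synth_design(trials_per_block = 32L, blocks_per_urgency = 1L,
                     evidence_gain = 0, motor_gain = 0)
  s0 <- generate_eeg(d0, generate_behavior(d0, seed = 43), seed = 44)
  coh <- ifelse(s0$epochs$metadata$condition %in% c(2, 4), "high", "low")
  disc <- sliding_discrimination(s0$epochs, coh, step = 0.2)
  expect_lt(abs(mean(disc$az) - 0.5), 0.08)
})

test_that("blink calibration is dominated by the planted blink component", {
  design <- synth_design()
  cal <- generate_blink_calibration(design, duration = 20, seed = 45)
  cc <- cal$data - rowMeans(cal$data)
  u1 <- svd(cc, nu = 1, nv = 0)$u[, 1]
  expect_gt(abs(cor(u1, cal$blink_topo)), 0.95)
  # a blink-free recording has no such dominant transient direction
  cal0 <- generate_blink_calibration(design, duration = 20, seed = 45,
                                     blinks = FALSE)
  c0 <- cal0$data - rowMeans(cal0$data)
  u0 <- svd(c0, nu = 1, nv = 0)$u[, 1]
  expect_lt(abs(cor(u0, cal$blink_topo)), 0.8)
  cal2 <- generate_blink_calibration(design, duration = 20, seed = 45)
  expect_identical(cal$data, cal2$data)
})

test_that("combined-family generator honors per-urgency parameters", {
  design <- synth_design(trials_per_block = 40L, blocks_per_urgency = 1L)
  tr <- generate_combined_behavior(design, seed = 46)
  expect_true(all(c("speed", "accuracy") %in% tr$urgency))
  ok <- tr[!tr$excluded, ]
  expect_gt(mean(ok$rt[ok$urgency == "accuracy"]),
            mean(ok$rt[ok$urgency == "speed"]))
})
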