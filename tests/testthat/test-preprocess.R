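full_montage <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                  "A1", "T3", "C3", "Cz", "C4", "T4", "A2",
                  "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

test_that("systematic channel exclusion leaves the 17 analysis channels", {
  set.seed(1)
  rec <- continuous_recording(matrix(rnorm(21 * 64), 21, 64), 32, full_montage)
  kept <- exclude_channels(rec, c("A1", "A2", "Fp1", "Fp2"))
  expect_equal(length(kept$channel_labels), 17)
  expect_equal(kept$channel_labels, setdiff(full_montage, c("A1", "A2", "Fp1", "Fp2")))
  # dropping nothing is the identity; unknown labels warn; dropping all errors
  expect_identical(exclude_channels(rec, character(0)), rec)
  expect_warning(exclude_channels(rec, c("A1", "XX")), "unknown")
  expect_error(exclude_channels(rec, full_montage), "every channel")
})

test_that("average reference zeroes the per-timepoint channel mean and is idempotent", {
  rec <- quick_subject(seed = 2, nch = 5)
  ref <- average_reference(rec)
  for (e in ref$epochs) expect_lt(max(abs(colMeans(e))), 1e-12)
  ref2 <- average_reference(ref)
  expect_equal(ref$epochs, ref2$epochs, tolerance = 1e-12)
  # two channels: hand-derived result
  a <- sin(seq(0, 2 * pi, length.out = 64)); b <- cos(seq(0, 2 * pi, length.out = 64))
  rec2 <- epoched_recording(list(rbind(a, b)), c("x", "y"), 32)
  out <- average_reference(rec2)$epochs[[1]]
  expect_equal(out[1, ], (a - b) / 2, ignore_attr = TRUE)
  expect_equal(out[2, ], (b - a) / 2, ignore_attr = TRUE)
  single <- epoched_recording(list(matrix(a, 1)), "x", 32)
  expect_error(average_reference(single), ">= 2 channels")
})

test_that("epoch selection honours count, order, seed and clean-epoch bookkeeping", {
  fs <- 32; n_ep <- 14
  cont <- continuous_recording(matrix(rnorm(2 * fs * 8 * n_ep), 2), fs, c("a", "b"))
  pol <- epoch_policy(10, epoch_len = 8, selection = "random_among_clean", seed = 4)
  sel1 <- select_epochs(cont, pol)
  sel2 <- select_epochs(cont, pol)
  expect_equal(n_epochs(sel1), 10)
  expect_identical(sel1$epochs, sel2$epochs)  # reproducible under the seed
  # first_clean takes the leading epochs in temporal order
  pol_f <- epoch_policy(4, epoch_len = 8, selection = "first_clean")
  self <- select_epochs(cont, pol_f)
  expect_identical(self$epochs[[2]], cont$samples[, (fs * 8 + 1):(2 * fs * 8)])
  # insufficient clean epochs reports the available count
  short <- continuous_recording(matrix(rnorm(2 * fs * 8 * 3), 2), fs, c("a", "b"))
  expect_error(select_epochs(short, pol_f), "3 available")
})

test_that("artifact and eyes-state annotations gate epoch selection", {
  fs <- 32
  ann <- data.frame(start_s = c(8.5, 0), end_s = c(9.5, 48),
                    label = c("artifact", "eyes-closed"), stringsAsFactors = FALSE)
  cont <- continuous_recording(matrix(rnorm(2 * fs * 8 * 6), 2), fs, c("a", "b"),
                               annotations = ann)
  # windows: 0-8 ok, 8-16 artifact, 16-24/24-32/32-40/40-48 ok -> 5 clean
  sel <- select_epochs(cont, epoch_policy(5, 8, "first_clean"))
  expect_equal(n_epochs(sel), 5)
  expect_identical(sel$epochs[[2]], cont$samples[, (2 * fs * 8 + 1):(3 * fs * 8)])
  expect_error(select_epochs(cont, epoch_policy(6, 8, "first_clean")), "insufficient")
})

test_that("random epoch selection gives every clean epoch equal probability", {
  fs <- 16
  cont <- continuous_recording(matrix(rnorm(1 * fs * 8 * 5), 1), fs, "a")
  counts <- integer(5)
  n_draws <- 600
  for (s in seq_len(n_draws)) {
    sel <- select_epochs(cont, epoch_policy(2, 8, "random_among_clean", seed = s))
    for (i in 1:5) {
      hit <- any(vapply(sel$epochs, function(e) {
        identical(e, cont$samples[, ((i - 1) * fs * 8 + 1):(i * fs * 8), drop = FALSE])
      }, logical(1)))
      if (hit) counts[i] <- counts[i] + 1L
    }
  }
  expect_equal(sum(counts), n_draws * 2)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("the amplitude screen flags exactly the spiked window", {
  fs <- 32
  x <- matrix(rnorm(2 * fs * 8 * 4), 2)
  cont <- continuous_recording(x, fs, c("a", "b"))
  expect_equal(nrow(amplitude_artifact_screen(cont, threshold = 100)), 0)
  expect_equal(nrow(amplitude_artifact_screen(cont, threshold = Inf)), 0)
  x2 <- x; x2[1, fs * 8 * 2 + 5] <- 10 * max(abs(x))  # spike in third window
  cont2 <- continuous_recording(x2, fs, c("a", "b"))
  flags <- amplitude_artifact_screen(cont2, threshold = 5 * max(abs(x)))
  expect_equal(nrow(flags), 1)
  expect_equal(flags$start_s, 16)
  expect_equal(flags$label, "artifact")
  # screen annotations feed straight back into epoch selection
  cont3 <- continuous_recording(x2, fs, c("a", "b"), annotations = flags)
  sel <- select_epochs(cont3, epoch_policy(3, 8, "first_clean"))
  expect_equal(n_epochs(sel), 3)
})

test_that("the preprocessing order exclude -> select -> reference composes", {
  fs <- 32
  cont <- continuous_recording(matrix(rnorm(21 * fs * 8 * 4), 21), fs, full_montage)
  rec <- exclude_channels(cont, c("A1", "A2", "Fp1", "Fp2"))
  rec <- select_epochs(rec, epoch_policy(3, 8, "random_among_clean", seed = 1))
  rec <- average_reference(rec)
  expect_equal(length(rec$channel_labels), 17)
  expect_equal(n_epochs(rec), 3)
  # the reference is over the retained channel set only
  for (e in rec$epochs) expect_lt(max(abs(colMeans(e))), 1e-12)
})
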