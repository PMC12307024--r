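sine_epochs <- function(freq, amp, n_trials = 2, n = 2000, channels = 31) {
  t <- (seq_len(n) - 1) / 1000            # window-internal time (used twice)
  x <- amp * sin(2 * pi * freq * t)
  data <- array(rep(x, each = n_trials * channels),
                dim = c(n_trials, channels, n))
  make_epochs(data)
}

test_that("an on-grid tone has bin power amplitude^2/4 and no leakage", {
  ep <- sine_epochs(54, amp = 2)
  sp <- windowed_power(ep, "tagging")
  expect_equal(dim(sp$power), c(1, 2, 31, 80))
  expect_equal(unname(sp$power[1, "related", 1, "54"]), 1.0, tolerance = 1e-10)
  expect_lt(max(sp$power[1, "related", 1, -54]), 1e-12)
  # baseline window of the same pure tone carries the same power
  expect_equal(unname(windowed_power(ep, "baseline")$power[1, , 1, "54"]),
               c(related = 1, unrelated = 1), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("the default analysis grid spans 1-80 Hz in 1 Hz steps", {
  sp <- windowed_power(sine_epochs(10, 1), "tagging")
  expect_equal(sp$freqs, 1:80)
  expect_length(sp$freqs, 80)
})

test_that("all-zero epochs give an all-zero spectrum", {
  sp <- windowed_power(sine_epochs(10, 0), "tagging")
  expect_true(all(sp$power == 0))
})

test_that("grid and window requests are validated", {
  ep <- sine_epochs(10, 1)
  expect_error(windowed_power(ep, "tagging", 1, 80, 3), "does not divide")
  expect_error(windowed_power(ep, "tagging", 1, 600, 1), "Nyquist")
  pos <- make_epochs(array(0, dim = c(2, 31, 1000)), t0 = 0)
  expect_error(windowed_power(pos, "baseline"), "outside the epoch")
})

test_that("percent change implements ((tagging - baseline)/baseline) * 100", {
  m <- default_montage()
  base <- windowed_power(sine_epochs(20, 2), "baseline")
  tagg <- windowed_power(sine_epochs(20, 2), "tagging")
  # identical windows -> 0 %
  pc0 <- percent_change(tagg, base)
  expect_equal(max(abs(pc0$pc[, , , "20"])), 0, tolerance = 1e-8)
  # doubling amplitude quadruples power -> +300 %
  tag4 <- windowed_power(sine_epochs(20, 4), "tagging")
  pc <- percent_change(tag4, base)
  expect_equal(unname(pc$pc[1, "related", 5, "20"]), 300, tolerance = 1e-6)
  # plain arithmetic on hand-built spectra: 1.5 vs 2 -> -25 %
  mk <- function(val) {
    arr <- array(val, dim = c(1, 2, 31, 1))
    dimnames(arr) <- list("P01", c("related", "unrelated"), m$channels, "14")
    structure(list(power = arr, freqs = 14, window = "tagging",
                   n_trials = matrix(1, 1, 2), montage = m),
              class = "rift_spectra")
  }
  expect_equal(unname(percent_change(mk(1.5), mk(2))$pc[1, 1, 1, 1]), -25)
  expect_error(percent_change(mk(1), mk(0)), "zero baseline power")
  bad <- windowed_power(sine_epochs(20, 2), "baseline", 1, 40, 1)
  expect_error(percent_change(tagg, bad), "grid")
})

test_that("scaling epochs by c scales power by c^2 and leaves percent change invariant", {
  ds <- simulate_dataset(quick_cfg(n_participants = 1, n_trials_per_condition = 3))
  scaled <- ds
  scaled[[1]]$data <- ds[[1]]$data * 3
  for (win in c("tagging", "baseline")) {
    expect_equal(windowed_power(scaled, win)$power,
                 9 * windowed_power(ds, win)$power, tolerance = 1e-10)
  }
  pc1 <- percent_change(windowed_power(ds, "tagging"),
                        windowed_power(ds, "baseline"))
  pc3 <- percent_change(windowed_power(scaled, "tagging"),
                        windowed_power(scaled, "baseline"))
  expect_equal(pc1$pc, pc3$pc, tolerance = 1e-8)
})

test_that("intermodulation frequencies are the difference and sum of the tags", {
  expect_equal(intermodulation_freqs(54, 68), list(difference = 14, sum = 122))
  expect_equal(intermodulation_freqs(10, 20), list(difference = 10, sum = 30))
  expect_equal(intermodulation_freqs(10, 11), list(difference = 1, sum = 21))
  expect_error(intermodulation_freqs(68, 54), "f2 > f1")
  expect_error(intermodulation_freqs(0, 5), "f2 > f1")
})

test_that("group-mean percent change reflects the configured topographies", {
  cfg <- sim_config(n_participants = 6, n_trials_per_condition = 20,
                    participant_jitter_sdlog = 0, seed = 11)
  ds <- simulate_dataset(cfg)
  pc <- percent_change(windowed_power(ds, "tagging"),
                       windowed_power(ds, "baseline"))
  gm <- apply(pc$pc, c(3, 4), mean)           # channel x frequency group mean
  expect_gt(cor(gm[, "68"], cfg$topo_visual, method = "spearman"), 0.8)
  # the visual response is occipitally dominated, the auditory one broad
  occ <- match(c("O1", "Oz", "O2"), cfg$montage$channels)
  expect_gt(mean(gm[occ, "68"]), 2 * mean(gm[-occ, "68"]))
  expect_lt(mean(gm[occ, "54"]), 2 * mean(gm[-occ, "54"]))
})

test_that("spectra and percent-change maps export as long-format TSV", {
  ds <- simulate_dataset(quick_cfg(n_participants = 1, n_trials_per_condition = 2))
  sp <- windowed_power(ds, "tagging", 10, 12, 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_spectra_tsv(sp, path)
  tab <- utils::read.delim(path)
  expect_equal(nrow(tab), 1 * 2 * 31 * 3)
  expect_named(tab, c("participant", "condition", "window", "channel",
                      "frequency_hz", "power_uv2"))
  expect_equal(tab$power_uv2[tab$channel == "Oz" & tab$frequency_hz == 11 &
                               tab$condition == "related"],
               unname(sp$power[1, "related", "Oz", "11"]))
})
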