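test_that("top-k selection picks the largest condition-averaged percent change", {
  m <- default_montage()
  arr <- array(0, dim = c(1, 2, 31, 1))
  winners <- c("F3", "Fz", "F4", "FC1", "FC2", "Cz")
  arr[1, , match(winners, m$channels), 1] <- 100
  pc <- make_pc(arr, 14, m)
  expect_setequal(top_k_electrodes(pc, "P01", 14, 6), winners)
  expect_setequal(top_k_electrodes(pc, 1, 14, 31), m$channels)
  expect_error(top_k_electrodes(pc, 1, 15, 6), "not on the analysis grid")
  expect_error(top_k_electrodes(pc, 1, 14, 32), "channel count")
  # ties broken by montage order
  tied <- make_pc(array(1, dim = c(1, 2, 31, 1)), 14, m)
  expect_equal(top_k_electrodes(tied, 1, 14, 3), m$channels[1:3])
  # condition averaging: a channel strong in one condition only can win
  arr2 <- array(0, dim = c(1, 2, 31, 1))
  arr2[1, 1, 1, 1] <- 300   # related-only response at Fp1
  arr2[1, , 2, 1] <- 100    # both conditions at Fp2
  pc2 <- make_pc(arr2, 14, m)
  expect_equal(top_k_electrodes(pc2, 1, 14, 2), c("Fp1", "Fp2"))
})

test_that("largest neighboring cluster follows the adjacency structure", {
  m <- toy_montage6()
  # all six mutually reachable -> the whole set
  expect_setequal(largest_neighbor_cluster(LETTERS[1:6], m), LETTERS[1:6])
  # components {A,B,C} vs {E} on the cycle-with-chord graph
  expect_setequal(largest_neighbor_cluster(c("A", "B", "C", "E"), m),
                  c("A", "B", "C", "E"))  # E neighbors B via the chord
  expect_setequal(largest_neighbor_cluster(c("A", "B", "D"), m), c("A", "B"))
  # singleton selections are legal here (unlike permutation-test clusters)
  expect_equal(largest_neighbor_cluster("C", m), "C")
  # size tie broken toward the component holding the largest value
  path <- rift_montage(LETTERS[1:6],
                       rbind(c("A", "B"), c("B", "C"), c("C", "D"),
                             c("D", "E"), c("E", "F")))
  vals <- c(A = 1, B = 1, C = 0, D = 10, E = 10, F = 0)
  expect_setequal(largest_neighbor_cluster(c("A", "B", "D", "E"), path, vals),
                  c("D", "E"))
  # and by montage order when no values are supplied
  expect_setequal(largest_neighbor_cluster(c("A", "B", "D", "E"), path),
                  c("A", "B"))
  expect_error(largest_neighbor_cluster(character(0), m), "empty")
  expect_error(largest_neighbor_cluster("Z", m), "unknown")
})

test_that("selection agrees with a brute-force component oracle over all subsets", {
  m <- toy_montage6()
  for (bits in 1:63) {
    sel <- m$channels[as.logical(bitwAnd(bits, 2^(0:5)))]
    got <- largest_neighbor_cluster(sel, m)
    comps <- igraph_components(m, match(sel, m$channels))
    best <- max(lengths(comps))
    expect_equal(length(got), best)
    expect_true(any(vapply(comps, function(c_) setequal(c_, got), TRUE)))
  }
})

test_that("the group selection contrast matches a longhand paired t and Cohen's d", {
  m <- default_montage()
  # four participants with known cluster means: load two adjacent channels
  rel <- c(10, 12, 8, 11)
  unrel <- c(14, 18, 13, 15)
  arr <- array(0, dim = c(4, 2, 31, 1))
  idx <- match(c("F3", "Fz"), m$channels)
  # four mutually non-adjacent decoys complete the top-6 without joining the
  # F3-Fz cluster
  decoys <- match(c("T7", "T8", "PO9", "PO10"), m$channels)
  for (p in 1:4) {
    arr[p, 1, idx, 1] <- rel[p]
    arr[p, 2, idx, 1] <- unrel[p]
    arr[p, , decoys, 1] <- 5
  }
  pc <- make_pc(arr, 14, m)
  sel <- selection_contrast(pc, m, 14, k = 6)
  tt <- stats::t.test(rel, unrel, paired = TRUE)
  expect_equal(sel$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(sel$p, tt$p.value, tolerance = 1e-12)
  expect_equal(sel$df, 3)
  d <- rel - unrel
  expect_equal(sel$cohens_d, mean(d) / sd(d), tolerance = 1e-12)
  expect_true(all(vapply(strsplit(sel$per_participant$cluster, ","),
                         function(x) setequal(x, c("F3", "Fz")), TRUE)))
  # equal conditions -> t = 0, d = 0
  arr0 <- arr; arr0[, 2, , ] <- arr0[, 1, , ]
  sel0 <- selection_contrast(make_pc(arr0, 14, m), m, 14, k = 6)
  expect_equal(sel0$t, 0)
  expect_equal(sel0$cohens_d, 0)
})

test_that("on simulated data the selection contrast recovers the gain asymmetry sign", {
  cfg <- sim_config(n_participants = 20, n_trials_per_condition = 15, seed = 19)
  ds <- simulate_dataset(cfg)
  pc <- percent_change(windowed_power(ds, "tagging", 14, 14, 1),
                       windowed_power(ds, "baseline", 14, 14, 1))
  sel <- selection_contrast(pc, cfg$montage, 14, k = 6)
  expect_lt(sel$t, 0)        # related < unrelated by construction
  expect_lt(sel$cohens_d, 0)
})

test_that("high-SNR selection recovers the interaction topography support", {
  m <- default_montage()
  topo <- numeric(31)
  support <- match(c("F3", "FC5", "FC1", "F7", "C3", "Fz"), m$channels)
  topo[support] <- c(1, 0.9, 0.8, 0.7, 0.6, 0.5)
  cfg <- sim_config(n_participants = 2, n_trials_per_condition = 10,
                    topo_im = topo, noise_sd = 0.05, alpha_amp = 0,
                    participant_jitter_sdlog = 0, seed = 23)
  ds <- simulate_dataset(cfg)
  pc <- percent_change(windowed_power(ds, "tagging", 14, 14, 1),
                       windowed_power(ds, "baseline", 14, 14, 1))
  for (p in c("P01", "P02")) {
    expect_setequal(top_k_electrodes(pc, p, 14, 6), m$channels[support])
  }
})

test_that("neighbor-frequency validation finds the intermodulation peak at 14 Hz", {
  cfg <- sim_config(n_participants = 6, n_trials_per_condition = 15, seed = 29)
  ds <- simulate_dataset(cfg)
  pc <- percent_change(windowed_power(ds, "tagging", 12, 16, 1),
                       windowed_power(ds, "baseline", 12, 16, 1))
  nv <- neighbor_frequency_validation(pc, cfg$montage, k = 6)
  expect_equal(nv$peak_frequency, 14)
  expect_equal(nv$table$frequency_hz, 12:16)
  expect_error(neighbor_frequency_validation(
    percent_change(windowed_power(ds, "tagging", 12, 15, 1),
                   windowed_power(ds, "baseline", 12, 15, 1)),
    cfg$montage), "missing 16")
})

test_that("without any interaction no neighbor frequency dominates", {
  cfg <- sim_config(n_participants = 6, n_trials_per_condition = 15,
                    g_related = 0, g_unrelated = 0, seed = 31)
  ds <- simulate_dataset(cfg)
  pc <- percent_change(windowed_power(ds, "tagging", 12, 16, 1),
                       windowed_power(ds, "baseline", 12, 16, 1))
  nv <- neighbor_frequency_validation(pc, cfg$montage, k = 6)
  expect_lt(max(nv$table$mean_percent_change),
            2 * stats::median(nv$table$mean_percent_change))
})

test_that("base-frequency selection lands on the configured source topographies", {
  m <- default_montage()
  topo_v <- numeric(31)
  occ <- match(c("O1", "Oz", "O2", "PO9", "PO10", "Pz"), m$channels)
  topo_v[occ] <- c(1, 0.95, 0.9, 0.8, 0.75, 0.7)
  cfg <- sim_config(n_participants = 3, n_trials_per_condition = 10,
                    topo_visual = topo_v, noise_sd = 0.05, alpha_amp = 0,
                    participant_jitter_sdlog = 0, seed = 37)
  ds <- simulate_dataset(cfg)
  pc <- percent_change(windowed_power(ds, "tagging"),
                       windowed_power(ds, "baseline"))
  bv <- base_frequency_validation(pc, m, k = 6)
  chosen68 <- bv[["68"]]$electrode[bv[["68"]]$count > 0]
  expect_true(all(chosen68 %in% m$channels[occ]))
  # identical topographies make the 54 and 68 Hz selections coincide
  cfg2 <- sim_config(n_participants = 2, n_trials_per_condition = 8,
                     topo_visual = topo_v, topo_audio = topo_v,
                     noise_sd = 0.05,
                     alpha_amp = 0, participant_jitter_sdlog = 0, seed = 41)
  ds2 <- simulate_dataset(cfg2)
  pc2 <- percent_change(windowed_power(ds2, "tagging"),
                        windowed_power(ds2, "baseline"))
  bv2 <- base_frequency_validation(pc2, m, k = 6)
  expect_equal(bv2[["54"]], bv2[["68"]])
})
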