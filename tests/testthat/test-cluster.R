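test_that("the paired t map matches t.test electrode by electrode", {
  set.seed(31)
  a <- matrix(rnorm(8), 4, 2)
  b <- matrix(rnorm(8), 4, 2)
  tm <- dependent_t_map(a, b)
  oracle <- vapply(1:2, function(e) {
    unname(stats::t.test(a[, e], b[, e], paired = TRUE)$statistic)
  }, 0)
  expect_equal(unname(tm), oracle, tolerance = 1e-12)
  expect_equal(unname(dependent_t_map(b, a)), -oracle, tolerance = 1e-12)
  expect_equal(unname(dependent_t_map(a, a)), c(0, 0))
})

test_that("zero-variance differences give signed infinite t with a warning", {
  a <- matrix(1:4, 4, 2)
  b <- a
  b[, 1] <- b[, 1] - 1          # constant positive difference
  expect_warning(tm <- dependent_t_map(a, b), "zero variance")
  expect_equal(unname(tm), c(Inf, 0))
})

test_that("clusters need two or more adjacent electrodes of the same sign", {
  m <- toy_montage6()
  tm <- c(A = 5, B = 5, C = 0, D = 0, E = 0, F = 0)
  cl <- form_clusters(tm, m, df = 9)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$electrodes, c("A", "B"))
  expect_equal(cl[[1]]$mass, 10)
  expect_equal(cl[[1]]$sign, 1)
  # isolated significant electrode: no cluster
  expect_length(form_clusters(c(A = 5, B = 0, C = 0, D = 0, E = 0, F = 0),
                              m, df = 9), 0)
  # opposite signs never join even when adjacent
  expect_length(form_clusters(c(A = 5, B = -5, C = 0, D = 0, E = 0, F = 0),
                              m, df = 9), 0)
  expect_error(form_clusters(tm, m, df = 9, alpha_form = 1.5), "alpha_form")
})

test_that("cluster formation agrees with a brute-force component oracle on all patterns", {
  m <- toy_montage6()
  tcrit <- qt(0.975, 9)
  for (bits in 0:63) {
    sig <- as.logical(bitwAnd(bits, 2^(0:5)))
    tm <- ifelse(sig, 5, 0)
    names(tm) <- m$channels
    got <- form_clusters(tm, m, df = 9)
    comps <- if (any(sig)) igraph_components(m, which(sig)) else list()
    comps <- Filter(function(x) length(x) >= 2, comps)
    expect_equal(length(got), length(comps))
    got_sets <- lapply(got, `[[`, "electrodes")
    want_sets <- lapply(comps, function(x) sort(unname(x)))
    expect_setequal(lapply(got_sets, sort), want_sets)
    for (cl in got) expect_equal(cl$mass, 5 * length(cl$electrodes))
  }
})

test_that("a null contrast yields a null distribution of zeros and no clusters", {
  m <- toy_montage6()
  a <- matrix(rnorm(24), 4, 6)
  null <- permutation_null(a, a, m, n_perm = 50)
  expect_equal(null, rep(0, 50))
  ct <- cluster_test(a, a, m, n_perm = 50, seed = 1)
  expect_length(ct$clusters, 0)
  expect_false(any_significant(ct))
})

test_that("label flips negate the t map (paired exchangeability)", {
  set.seed(5)
  a <- matrix(rnorm(30), 5, 6)
  b <- matrix(rnorm(30), 5, 6)
  expect_equal(dependent_t_map(b, a), -dependent_t_map(a, b))
})

test_that("exhaustive enumeration p equals a from-scratch enumeration oracle", {
  m <- rift_montage(c("A", "B", "C", "D"),
                    rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  set.seed(17)
  n <- 6
  a <- matrix(rnorm(n * 4, mean = 0.8), n, 4)
  b <- matrix(rnorm(n * 4), n, 4)
  ct <- cluster_test(a, b, m, exhaustive = TRUE, alpha_form = 0.05)
  expect_length(ct$null, 2^n)
  # independent oracle: direct enumeration with t.test + igraph components
  d <- a - b
  tcrit <- qt(0.975, n - 1)
  max_mass <- function(dd) {
    tv <- vapply(1:4, function(e) {
      s <- sd(dd[, e])
      if (s == 0) return(0)
      mean(dd[, e]) / (s / sqrt(n))
    }, 0)
    best <- 0
    for (sgn in c(1, -1)) {
      keep <- which(abs(tv) > tcrit & sign(tv) == sgn)
      if (length(keep) >= 2) {
        for (comp in igraph_components(m, keep)) {
          if (length(comp) >= 2) {
            best <- max(best, abs(sum(tv[match(comp, m$channels)])))
          }
        }
      }
    }
    best
  }
  null <- numeric(2^n)
  for (i in 0:(2^n - 1)) {
    flips <- ifelse(as.logical(bitwAnd(i, 2^(0:(n - 1)))), -1, 1)
    null[i + 1] <- max_mass(d * flips)
  }
  obs <- max_mass(d)
  expect_gt(length(ct$clusters), 0)
  expect_equal(max(vapply(ct$clusters, function(cl) abs(cl$mass), 0)), obs,
               tolerance = 1e-12)
  p_pkg <- min(vapply(ct$clusters, `[[`, 0, "p"))
  expect_equal(p_pkg, mean(null >= obs), tolerance = 1e-12)
})

test_that("permutation machinery is seeded and validates its inputs", {
  m <- toy_montage6()
  set.seed(3)
  a <- matrix(rnorm(36, 1), 6, 6)
  b <- matrix(rnorm(36), 6, 6)
  ct1 <- cluster_test(a, b, m, n_perm = 200, seed = 9)
  ct2 <- cluster_test(a, b, m, n_perm = 200, seed = 9)
  expect_identical(ct1$null, ct2$null)
  expect_identical(vapply(ct1$clusters, `[[`, 0, "p"),
                   vapply(ct2$clusters, `[[`, 0, "p"))
  expect_error(permutation_null(a, b, m, n_perm = 0), "n_perm")
  expect_error(permutation_null(a[1, , drop = FALSE], b[1, , drop = FALSE], m),
               "at least 2")
  expect_error(permutation_null(a[, 1:3], b[, 1:3], m), "montage")
  # Monte Carlo p uses the +1 correction: never zero, never above 1
  p <- vapply(ct1$clusters, `[[`, 0, "p")
  expect_true(all(p > 0 & p <= 1))
})
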