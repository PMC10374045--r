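sim_from_values <- function(vals_fn, ids) {
  n <- length(ids)
  m <- diag(1, n)
  m[upper.tri(m)] <- vals_fn(sum(upper.tri(m)))
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  similarity_matrix(m, call_ids = ids)
}

test_that("partitions count within/among pairs correctly and honor constraints", {
  ids <- c("x1", "x2", "y1")
  md <- tibble::tibble(call_id = ids,
                       individual_id = c("X", "X", "Y"),
                       site_id = c("s1", "s1", "s2"),
                       region_id = "r1")
  m <- sim_from_values(function(n) seq(0.1, 0.9, length.out = n), ids)
  part <- suppressWarnings(partition_similarities(m, md, "individual"))
  expect_equal(nrow(part$within), 1)
  expect_equal(nrow(part$among), 2)

  # 4 individuals at 2 sites, same-site among-pairs excluded:
  # among pairs = 2 * 2 cross-site pairs * 1 call each = 4 (by enumeration)
  ids2 <- paste0("c", 1:4)
  md2 <- tibble::tibble(call_id = ids2,
                        individual_id = c("A", "B", "C", "D"),
                        site_id = c("s1", "s1", "s2", "s2"),
                        region_id = "r1")
  m2 <- sim_from_values(function(n) rep(0.5, n) + seq_len(n) / 100, ids2)
  expect_warning(
    p2 <- partition_similarities(m2, md2, "individual",
                                 exclude_same_site = TRUE),
    "no within-category"
  )
  expect_equal(nrow(p2$among), 4)
  expect_equal(nrow(p2$within), 0)
})

test_that("histogram EMD matches the exact Wasserstein oracle and its closed forms", {
  # extreme separation with 16 bins: all mass 15 bins apart -> 15/16
  w <- rep(0.97, 40)
  a <- rep(0.01, 25)
  expect_equal(histogram_emd(w, a, n_bins = 16), 15 / 16)
  # identical sets and order-invariance
  set.seed(1)
  v <- runif(50)
  expect_equal(histogram_emd(v, v), 0)
  expect_equal(histogram_emd(v, rev(v)), 0)
  # equality with the independent stepfun-integration oracle
  for (i in 1:25) {
    w <- runif(sample(5:200, 1))
    a <- rbeta(sample(5:200, 1), 2, 5)
    got <- histogram_emd(w, a, n_bins = 16)
    bw <- bin_atoms(w, 16)
    ba <- bin_atoms(a, 16)
    want <- wasserstein_oracle(bw$atoms, bw$mass, ba$atoms, ba$mass)
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(got, histogram_emd(a, w, n_bins = 16), tolerance = 1e-15)
  }
  expect_error(histogram_emd(numeric(0), a), "non-empty")
  expect_error(histogram_emd(c(0.5, 1.2), a), "domain")
})

test_that("resampled EMD separates planted signatures and is seed-stable", {
  pop <- small_pop()
  sm <- small_spcc()
  e1 <- emd_convergence(sm, pop, "individual", n_iter = 50,
                        n_categories = 4, n_per_class = 20, seed = 9)
  e2 <- emd_convergence(sm, pop, "individual", n_iter = 50,
                        n_categories = 4, n_per_class = 20, seed = 9)
  expect_identical(e1$values, e2$values)
  expect_gt(e1$mean, 0.1)
  expect_true(e1$ci_low <= e1$mean && e1$mean <= e1$ci_high)
  expect_true(all(e1$values >= 0 & e1$values <= 1))

  # unsatisfiable subsample sizes error cleanly
  expect_error(
    emd_convergence(sm, pop, "individual", n_per_class = 10000),
    "unsatisfiable"
  )
  expect_error(
    emd_convergence(sm, pop, "individual", n_categories = 50),
    "need n_categories"
  )
})

test_that("EMD under a true null sits near the finite-sample floor", {
  # within and among drawn from the same distribution
  set.seed(5)
  ids <- paste0("c", 1:60)
  md <- tibble::tibble(call_id = ids,
                       individual_id = rep(paste0("I", 1:6), each = 10),
                       site_id = "s1", region_id = "r1")
  m <- sim_from_values(function(n) runif(n, 0.2, 0.8), ids)
  e <- emd_convergence(m, md, "individual", n_iter = 100, n_categories = 4,
                       n_per_class = 100, seed = 2)
  expect_lt(e$mean, 0.05)
})

test_that("bin sensitivity reports the grid with 16 bins as headline", {
  pop <- small_pop()
  sm <- small_spcc()
  bs <- bin_sensitivity(sm, pop, "individual", n_iter = 20,
                        n_categories = 4, n_per_class = 20, seed = 4)
  expect_equal(nrow(bs), 6)
  expect_equal(bs$n_bins[bs$headline], 16)
  # single-element grid reproduces emd_convergence exactly
  one <- bin_sensitivity(sm, pop, "individual", bin_grid = 16, n_iter = 20,
                         n_categories = 4, n_per_class = 20, seed = 4)
  ref <- emd_convergence(sm, pop, "individual", n_iter = 20,
                         n_categories = 4, n_per_class = 20, n_bins = 16,
                         seed = 4)
  expect_equal(one$mean, ref$mean)
})

test_that("bootstrap ratios honor the 5 x 200 = 1000 contract and forced values", {
  r <- bootstrap_similarity_ratio(rep(0.9, 30), rep(0.3, 30), seed = 1)
  expect_equal(length(r$ratios), 1000)
  expect_equal(unique(r$ratios), 3)
  expect_equal(r$mean_ratio, 3)
  expect_error(bootstrap_similarity_ratio(numeric(0), 1), "non-empty")
  expect_error(bootstrap_similarity_ratio(c(0.5), c(0, 0)), "zero")
  # zero denominators are redrawn, not propagated
  set.seed(2)
  rz <- bootstrap_similarity_ratio(runif(20, 0.4, 0.8),
                                   c(0, runif(19, 0.2, 0.6)), seed = 3)
  expect_true(all(is.finite(rz$ratios)))
  expect_gte(rz$n_redraws, 0)
})

test_that("null bootstrap ratios have a simulation band covering 1", {
  means <- vapply(1:10, function(seed) {
    set.seed(seed * 13)
    pool <- runif(200, 0.2, 0.8)
    w <- sample(pool, 80)
    a <- sample(pool, 80)
    bootstrap_similarity_ratio(w, a, seed = seed)$mean_ratio
  }, numeric(1))
  expect_gt(max(means), 1)
  expect_lt(min(means), max(means))
  expect_lt(abs(mean(means) - 1), 0.25)
})

test_that("Mantel exact enumeration matches sampled p and finds perfect correlation", {
  ids <- paste0("c", 1:5)
  md <- tibble::tibble(call_id = ids,
                       individual_id = c("A", "A", "B", "B", "C"),
                       site_id = "s", region_id = "r")
  memb <- membership_matrix(md, "individual", ids)
  set.seed(8)
  base <- 0.2 + 0.6 * memb[upper.tri(memb)] + runif(10, 0, 0.1)
  m <- diag(1, 5)
  m[upper.tri(m)] <- base
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m <- similarity_matrix(m, call_ids = ids)

  ex <- mantel_test(m, memb, exact = TRUE)
  sa <- mantel_test(m, memb, n_perm = 9999, seed = 1, exact = FALSE)
  expect_equal(ex$r, sa$r)
  expect_lt(abs(ex$p - sa$p), 3 * sqrt(ex$p * (1 - ex$p) / 9999) + 1e-4)
  # the observed labelling is the best attainable: only the 8 permutations
  # preserving the partition {A,B}/{C} reproduce r_obs, so p = 8/120
  expect_equal(ex$p, 8 / 120)
  expect_gt(ex$r, 0.9)
})

test_that("Mantel agrees with the vegan implementation on r", {
  pop <- small_pop()
  sm <- small_spcc()
  memb <- membership_matrix(pop, "individual", rownames(sm))
  ours <- mantel_test(sm, memb, n_perm = 199, seed = 2, exact = FALSE)
  veg <- vegan::mantel(1 - unclass(sm), 1 - memb, permutations = 99)
  expect_equal(ours$r, unname(veg$statistic), tolerance = 1e-10)
  expect_lt(ours$p, 0.05)
})

test_that("Mantel p-values are calibrated under the null", {
  set.seed(33)
  ps <- replicate(100, {
    n <- 10
    ids <- paste0("c", 1:n)
    md <- tibble::tibble(call_id = ids,
                         individual_id = sample(rep(c("A", "B"), n / 2)),
                         site_id = "s", region_id = "r")
    m <- diag(1, n)
    v <- runif(n * (n - 1) / 2, 0.2, 0.8)
    m[upper.tri(m)] <- v
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m <- similarity_matrix(m, call_ids = ids)
    mantel_test(m, membership_matrix(md, "individual", ids),
                n_perm = 99, seed = sample.int(1e6, 1), exact = FALSE)$p
  })
  # roughly uniform: mean near 0.5, no pile-up below 0.05
  expect_lt(abs(mean(ps) - 0.5), 0.12)
  expect_lt(mean(ps <= 0.05), 0.15)
})

test_that("constant matrices are rejected by the Mantel test", {
  ids <- paste0("c", 1:4)
  m <- matrix(0.5, 4, 4)
  diag(m) <- 1
  m <- similarity_matrix(m, call_ids = ids)
  md <- tibble::tibble(call_id = ids, individual_id = c("A", "A", "B", "B"),
                       site_id = "s", region_id = "r")
  expect_error(mantel_test(m, membership_matrix(md, "individual", ids)),
               "undefined")
})
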