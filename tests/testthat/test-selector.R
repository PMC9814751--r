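test_that("marginal score counts uncovered gain minus NMOL-scaled penalty", {
  sp <- path_space()
  st <- selection_state(sp)
  # first pick: score = neighbor count including self (penalty term zero)
  expect_equal(sfmmol_score(sp, st, 2), 3)   # {1, 2, 3}
  expect_equal(sfmmol_score(sp, st, 1), 2)   # {1, 2}
  # isolated candidate whose only neighbor is itself
  D <- matrix(0.9, 3, 3)
  diag(D) <- 0
  iso <- molspace_from_distances(D, d_th = 0.3)
  expect_equal(sfmmol_score(iso, selection_state(iso), 1), 1)

  # candidate with 1 evaluated neighbor and 3 uncovered neighbors, NMOL = 100
  D <- matrix(0.9, 100, 100)
  diag(D) <- 0
  D[1, 2:5] <- D[2:5, 1] <- 0.1   # candidate 1 near molecules 2..5
  spc <- molspace_from_distances(D, d_th = 0.3)
  st <- selection_state(spc, evaluated = 2L)
  # covered = nb(2) = {1, 2}; uncovered neighbors of 1 = {3, 4, 5}
  expect_equal(sfmmol_score(spc, st, 1), 3 - 100 * 1)
})

test_that("greedy ranking picks the hub first and matches the exhaustive oracle", {
  # star: molecule 1 adjacent to 2..6, molecules 7..10 isolated
  D <- matrix(0.9, 10, 10)
  diag(D) <- 0
  D[1, 2:6] <- D[2:6, 1] <- 0.1
  sp <- molspace_from_distances(D, d_th = 0.3)
  rk <- rank_sfmmol(sp, n_select = 10)
  expect_equal(rk$order[1], 1L)
  expect_equal(rk$scores[1], 6)
  expect_equal(rk$order, oracle_greedy(D, 0.3, 10))

  # random clustered spaces: every pick equals the exhaustive argmax
  for (seed in 1:10) {
    spr <- synth_space(24, 4, nbits = 64, flip = 0.08, seed = seed)
    rkr <- rank_sfmmol(spr, n_select = 24)
    expect_equal(rkr$order, oracle_greedy(spr$dist, spr$d_th, 24),
                 info = paste("seed", seed))
  }
})

test_that("maximal penalty makes evaluated-adjacent candidates always lose", {
  for (seed in 1:6) {
    sp <- synth_space(30, 5, nbits = 64, flip = 0.08, seed = seed)
    st <- selection_state(sp, evaluated = rank_sfmmol(sp, 3)$order)
    evl <- st$evaluated
    scores <- vapply(setdiff(seq_len(sp$nmol), evl),
                     function(i) sfmmol_score(sp, st, i), numeric(1))
    cand <- setdiff(seq_len(sp$nmol), evl)
    near_eval <- vapply(cand, function(i)
      any(sp$dist[i, evl] < sp$d_th), logical(1))
    has_gain <- vapply(cand, function(i)
      sum(sp$dist[i, ] < sp$d_th & !st$covered) > 0, logical(1))
    if (any(near_eval) && any(!near_eval & has_gain)) {
      expect_lt(max(scores[near_eval]), min(scores[!near_eval & has_gain]))
    }
  }
})

test_that("random ranking is a reproducible uniform permutation", {
  sp <- synth_space(10, 2, nbits = 64, seed = 5)
  r1 <- rank_random(sp, 10, seed = 11)
  r2 <- rank_random(sp, 10, seed = 11)
  expect_identical(r1$order, r2$order)
  expect_setequal(r1$order, 1:10)            # full permutation
  expect_false(identical(r1$order, rank_random(sp, 10, seed = 12)$order))
  # each molecule lands first ~100 times over 1000 seeds (binomial, 4 sigma)
  firsts <- vapply(1:1000, function(s) rank_random(sp, 1, seed = s)$order[1],
                   integer(1))
  counts <- tabulate(firsts, nbins = 10)
  expect_true(all(counts > 100 - 4 * sqrt(1000 * 0.1 * 0.9)))
  expect_true(all(counts < 100 + 4 * sqrt(1000 * 0.1 * 0.9)))
})

test_that("GP posterior variance matches the closed form and drives UNC", {
  sp <- path_space()
  K <- 1 - sp$dist
  ev <- c(1L, 4L)
  v <- gp_posterior_variance(sp, ev, jitter = 1e-8)
  for (i in setdiff(1:6, ev)) {
    kk <- K[ev, i]
    expect_equal(unname(v[sp$ids[i]]),
                 max(0, 1 - drop(t(kk) %*% solve(K[ev, ev] +
                                                   diag(1e-8, 2), kk))),
                 tolerance = 1e-4)
  }

  # a candidate identical to an evaluated molecule has ~zero variance and is
  # picked last
  fp <- rbind(diag(8)[rep(1, 2), ], diag(8)[3:6, ])
  dup <- molspace(fp, d_th = 0.3)
  rk <- rank_unc(dup, dup$nmol)
  # once either twin is evaluated the other has ~zero posterior variance and
  # is never picked while informative candidates remain
  expect_equal(rk$order[6], setdiff(1:2, rk$order[1:5]))
  expect_lt(rk$scores[6], 1e-4)
  expect_true(all(rk$scores[2:5] > 0.5))

  # two clusters, one fully evaluated: variance is maximal in the other
  sp2 <- synth_space(12, 2, nbits = 64, flip = 0, seed = 3)
  cl <- attr(sp2, "true_clusters")
  v2 <- gp_posterior_variance(sp2, which(cl == 1), seq_len(sp2$nmol))
  expect_true(all(v2[which(cl == 2)] > max(v2[which(cl == 1)])))

  # degenerate kernel: all-identical fingerprints abort
  same <- molspace(matrix(rep(c(1L, 0L), each = 4), 4, 2, byrow = FALSE),
                   d_th = 0.3)
  same$dist[] <- 0
  expect_error(rank_unc(same, 2), "degenerate")
})

test_that("coverage curves start at zero, end at one, and match brute force", {
  sp <- path_space()
  rk <- rank_sfmmol(sp, 6)
  for (ord in 1:2) {
    cc <- coverage_curve(sp, rk, order = ord)
    expect_equal(cc$coverage[1], 0)
    expect_equal(cc$coverage[nrow(cc)], 1)
    expect_true(all(diff(cc$coverage) >= -1e-12))
    for (k in 1:6) {
      expect_equal(cc$coverage[k + 1],
                   oracle_coverage(sp$dist, rk$order[1:k], 0.3, ord))
    }
  }
  # plain index vector input: picks 1 and 4 on the path
  cc2 <- coverage_curve(sp, c(1L, 4L), order = 1)
  expect_equal(cc2$coverage, c(0, 2 / 6, 5 / 6))
})

test_that("selection ranked by coverage gain beats random on clustered spaces", {
  covs_sfm <- covs_rnd <- numeric(0)
  for (seed in 1:3) {
    sp <- synth_space(120, 8, nbits = 64, flip = 0.05, seed = seed)
    covs_sfm <- c(covs_sfm,
                  coverage_curve(sp, rank_sfmmol(sp, 5), 2)$coverage[6])
    covs_rnd <- c(covs_rnd, vapply(1:20, function(s)
      coverage_curve(sp, rank_random(sp, 5, seed = s), 2)$coverage[6],
      numeric(1)))
  }
  expect_gt(mean(covs_sfm), mean(covs_rnd))
})
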