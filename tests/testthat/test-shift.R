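# Shift analysis: pairwise diffs, the 2x(Q3 - median) threshold,
# permutation p-values, discretization, and tree parsimony.

test_that("pairwise_diffs subtracts per family and drops incomplete ones", {
  piset <- toy_piset(
    family = c("f1", "f1", "f2", "f2", "f3"),
    species = c("human", "mouse", "human", "mouse", "human"),
    pi = c(5.0, 7.5, 6.0, 6.1, 9.0))
  d <- pairwise_diffs(piset, "human", "mouse")
  expect_equal(d, c(f1 = 2.5, f2 = 0.1)) # f3 lacks mouse
  expect_error(pairwise_diffs(piset, "human", "dog"), "unknown species")
})

test_that("shift_threshold follows the stated quantile convention", {
  expect_equal(shift_threshold(c(0.0, 0.1, 0.2, 0.3, 1.0)), 0.2)
  expect_equal(shift_threshold(c(0.3, 0.3, 0.3, 0.3)), 0)
  expect_error(shift_threshold(c(0.1, 0.2, 0.3)), "at least 4")
})

test_that("shift_threshold is order-invariant and scale-equivariant", {
  set.seed(5)
  for (i in 1:20) {
    x <- abs(rnorm(sample(4:200, 1)))
    expect_equal(shift_threshold(sample(x)), shift_threshold(x))
    c0 <- runif(1, 0.1, 10)
    expect_equal(shift_threshold(c0 * x), c0 * shift_threshold(x))
    expect_gte(shift_threshold(x), 0)
  }
})

test_that("flag_shifters uses strict inequality", {
  d <- c(a = 0.0, b = 0.20, c = 0.21)
  res <- flag_shifters(d, threshold = 0.2)
  expect_equal(res$flagged, "c")
  expect_equal(flag_shifters(c(a = 0), threshold = 0.5)$flagged, character(0))
})

test_that("permutation p-value matches exhaustive enumeration on toy sets", {
  piset <- toy_piset(
    family = rep(c("f1", "f2", "f3"), each = 2),
    species = rep(c("human", "mouse"), 3),
    pi = c(5.0, 8.1, 6.0, 6.2, 7.0, 7.1))
  # oracle: enumerate all 3! pairings of mouse values by hand
  a <- c(5.0, 6.0, 7.0); b <- c(8.1, 6.2, 7.1)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2),
                c(3, 2, 1))
  obs <- abs(a[1] - b[1])
  enum <- mean(vapply(perms, function(p) abs(a[1] - b[p][1]) >= obs,
                      logical(1)))
  expect_equal(
    permutation_pvalue(piset, "human", "mouse", "f1", n_perm = 1000),
    enum)
  # and for a middling family, under both modes
  obs2 <- abs(a[2] - b[2])
  enum2 <- mean(vapply(perms, function(p) abs(a[2] - b[p][2]) >= obs2,
                       logical(1)))
  expect_equal(
    permutation_pvalue(piset, "human", "mouse", "f2", n_perm = 1000),
    enum2)
  # threshold mode needs >= 4 families for the permuted threshold itself
  piset4 <- toy_piset(
    family = rep(c("f1", "f2", "f3", "f4"), each = 2),
    species = rep(c("human", "mouse"), 4),
    pi = c(5.0, 8.1, 6.0, 6.2, 7.0, 7.1, 6.5, 6.4))
  a4 <- c(5.0, 6.0, 7.0, 6.5); b4 <- c(8.1, 6.2, 7.1, 6.4)
  perms4 <- asplit(pishift:::all_permutations(4), 1)
  thr_stat <- function(p) {
    d <- abs(a4 - b4[p]); d[1] - shift_threshold(d)
  }
  enum_thr <- mean(vapply(perms4, function(p) thr_stat(p) >= thr_stat(1:4),
                          logical(1)))
  expect_equal(
    permutation_pvalue(piset4, "human", "mouse", "f1", n_perm = 1000,
                       mode = "threshold"),
    enum_thr)
})

test_that("Monte Carlo permutation p-values are bounded and reproducible", {
  set.seed(99)
  n_fam <- 40
  piset <- toy_piset(
    family = rep(sprintf("f%02d", 1:n_fam), each = 2),
    species = rep(c("A", "B"), n_fam),
    pi = runif(2 * n_fam, 4, 10))
  p1 <- permutation_pvalue(piset, "A", "B", "f01", n_perm = 99, seed = 7)
  p2 <- permutation_pvalue(piset, "A", "B", "f01", n_perm = 99, seed = 7)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 100)
  expect_lte(p1, 1)
  # add-one floor: even an extreme shift can never drop below 1/(n+1),
  # because the estimator counts the observed arrangement once
  piset2 <- toy_piset(
    family = rep(sprintf("g%02d", 1:30), each = 2),
    species = rep(c("A", "B"), 30),
    pi = c(rbind(rep(7, 30), c(14, rep(7, 29)))))
  p_extreme <- permutation_pvalue(piset2, "A", "B", "g01", n_perm = 99,
                                  seed = 1)
  expect_gte(p_extreme, 1 / 100)
  expect_lte(p_extreme, 0.2) # only re-drawing the 14 reaches the observed
  # exhaustive mode: with 3 families each B value reaches the tested slot
  # in 2 of the 6 permutations, so a uniquely maximal pairing has p = 1/3
  piset3 <- toy_piset(
    family = rep(c("f1", "f2", "f3"), each = 2),
    species = rep(c("A", "B"), 3),
    pi = c(0, 9, 5, 5.5, 6, 6.5))
  expect_equal(
    permutation_pvalue(piset3, "A", "B", "f1", n_perm = 1000), 1 / 3)
  expect_error(
    permutation_pvalue(piset, "A", "B", "nope", n_perm = 10), "lacks a pI")
})

test_that("discretize_pi respects its bounds, inclusively neutral", {
  expect_equal(discretize_pi(c(4.75, 8.59, 7.0)),
               c("acidic", "basic", "neutral"))
  expect_equal(discretize_pi(6.8), "neutral") # boundary convention
  expect_equal(discretize_pi(7.2), "neutral")
  expect_equal(discretize_pi(5.9, bounds = c(6, 8)), "acidic")
  expect_error(discretize_pi(7, bounds = c(8, 6)))
})

test_that("fitch_shift_count handles the documented base cases", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(fitch_shift_count(tr, c(A = "acidic", B = "acidic",
                                       C = "acidic", D = "acidic")), 0)
  expect_equal(fitch_shift_count(tr, c(A = "acidic", B = "acidic",
                                       C = "basic", D = "basic")), 1)
  expect_equal(fitch_shift_count("(A,B,C,D);",
                                 c(A = "acidic", B = "basic",
                                   C = "neutral", D = "basic")), 2)
  expect_error(fitch_shift_count(tr, c(A = "acidic", B = "acidic",
                                       C = "basic")), "D")
})

test_that("fitch_shift_count equals brute force on random small trees", {
  set.seed(17)
  cats <- c("acidic", "neutral", "basic")
  for (i in 1:40) {
    n <- sample(3:6, 1)
    tr <- random_leaf_tree(n)
    states <- setNames(sample(cats, n, replace = TRUE), tr$tip.label)
    expect_equal(fitch_shift_count(tr, states),
                 brute_force_parsimony(tr, states),
                 info = paste("tree", i))
  }
})
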