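# Generators: reproducibility, documented contracts, and ground truth.

test_that("random_protein draws from the stated residue classes", {
  s <- random_protein(300, charged_fraction = 0, seed = 1)
  expect_equal(nchar(s), 300)
  expect_true(all(strsplit(s, "")[[1]] %in%
                  c("G", "A", "S", "T", "L", "V", "P", "N", "Q")))
  # charge-free sequence: pI is exactly the termini midpoint
  expect_equal(isoelectric_point(build_groups(s)), 5.55, tolerance = 0.005)

  s_basic <- random_protein(200, charged_fraction = 0.3, basic_bias = 1,
                            seed = 2)
  expect_gt(isoelectric_point(build_groups(s_basic)), 9)
  expect_identical(random_protein(50, seed = 9), random_protein(50, seed = 9))
  expect_false(random_protein(50, seed = 9) == random_protein(50, seed = 10))
})

test_that("mutate_to_target_pi reaches reachable targets, length fixed", {
  for (target in c(4.5, 7.0, 9.5)) {
    out <- mutate_to_target_pi("GGGGGGGGGG", target, tolerance = 0.05,
                               seed = 3)
    expect_equal(nchar(out), 10)
    expect_lte(abs(isoelectric_point(build_groups(out)) - target), 0.05)
  }
  # identity when already on target
  s <- random_protein(60, seed = 4)
  cur <- isoelectric_point(build_groups(s))
  expect_identical(mutate_to_target_pi(s, cur, tolerance = 0.05, seed = 5), s)
  # impossible target within one step errors, carrying the best pI
  err <- tryCatch(
    mutate_to_target_pi("GGGGGGGGGG", 13.9, max_steps = 1L, seed = 6),
    pishift_target_unreachable = function(e) e)
  expect_s3_class(err, "pishift_target_unreachable")
  expect_true(is.numeric(err$best_pi))
  expect_error(mutate_to_target_pi("GGGG", 7, tolerance = 0.001),
               "tolerance")
})

test_that("mutate_to_target_pi only touches charged/neutral classes", {
  s <- random_protein(80, charged_fraction = 0.3, seed = 11)
  out <- mutate_to_target_pi(s, 9.0, tolerance = 0.05, seed = 12)
  a <- strsplit(s, "")[[1]]; b <- strsplit(out, "")[[1]]
  changed <- which(a != b)
  allowed <- c("G", "A", "S", "T", "L", "V", "P", "N", "Q",
               "R", "K", "H", "D", "E", "C", "Y")
  expect_true(all(a[changed] %in% allowed))
  expect_true(all(b[changed] %in% allowed))
})

test_that("simulate_proteome honors its spec and is seed-reproducible", {
  spec <- synthetic_proteome_spec(n_families = 50, background_sigma = 0.1,
                                  outliers = data.frame(family = "fam0007",
                                                        shift = 3),
                                  seed = 21)
  sim1 <- simulate_proteome(spec)
  sim2 <- simulate_proteome(spec)
  expect_identical(sim1$pi_set$pi, sim2$pi_set$pi)
  expect_equal(sim1$outlier_families, "fam0007")
  d <- pairwise_diffs(sim1$pi_set, "human", "mouse")
  expect_equal(unname(d["fam0007"]), 3, tolerance = 0.011)

  # sigma 0, no outliers: all diffs zero, threshold zero, nothing flagged
  flat <- simulate_proteome(synthetic_proteome_spec(
    n_families = 20, background_sigma = 0,
    outliers = data.frame(family = character(0), shift = numeric(0)),
    seed = 1))
  d0 <- pairwise_diffs(flat$pi_set, "human", "mouse")
  expect_true(all(d0 == 0))
  res <- flag_shifters(d0)
  expect_equal(res$threshold, 0)
  expect_length(res$flagged, 0)

  expect_error(synthetic_proteome_spec(outliers = data.frame(
    family = c("fam0001", "fam0001"), shift = 2)), "duplicate")
  expect_error(synthetic_proteome_spec(n_families = 3), "n_families")
})

test_that("planted outliers are always flagged; background behaves as the
           threshold statistic dictates", {
  # The 2x(Q3 - median) threshold sits at ~0.95 sigma for a half-normal
  # background, above which ~34% of its mass lies. So planted outliers are
  # recovered with certainty, together with a ~34% background exceedance --
  # the statistic flags a fixed *quantile*, not a fixed effect size.
  hits <- numeric(10); bg_rate <- numeric(10)
  for (r in 1:10) {
    sim <- simulate_proteome(synthetic_proteome_spec(
      n_families = 400, background_sigma = 0.2, seed = 300 + r))
    d <- pairwise_diffs(sim$pi_set, "human", "mouse")
    res <- flag_shifters(d)
    hits[r] <- all(sim$outlier_families %in% res$flagged)
    bg <- setdiff(names(d), sim$outlier_families)
    bg_rate[r] <- mean(bg %in% res$flagged)
  }
  expect_true(all(hits == 1))
  analytic <- 2 * (1 - pnorm(2 * (qnorm(0.875) - qnorm(0.75)))) # 0.3412
  expect_lt(abs(mean(bg_rate) - analytic), 0.04)
})

test_that("plant_selection_sites respects rates, odds, and consistency", {
  sim <- plant_selection_sites(synthetic_selection_spec(
    n_sites = 2000, charged_fraction = 0.3, base_selected_rate = 0.05,
    odds_ratio = 4, seed = 13))
  expect_length(sim$charge_classes, 2000)
  tab <- sim$sites
  # omega > 1 and p <= alpha exactly for the planted selected sites
  expect_equal(call_selected_sites(tab, alpha = 0.05), sim$selected_sites)
  # empirical rates near their targets
  chg <- sim$charge_classes == "charged"
  sel <- seq_len(2000) %in% sim$selected_sites
  expect_lt(abs(mean(chg) - 0.3), 0.05)
  expect_lt(abs(mean(sel[!chg]) - 0.05), 0.02)
  p_charged <- 4 * 0.05 / 0.95 / (1 + 4 * 0.05 / 0.95)
  expect_lt(abs(mean(sel[chg]) - p_charged), 0.05)

  # degenerate: no base selection and no enrichment -> nothing selected
  none <- plant_selection_sites(synthetic_selection_spec(
    n_sites = 100, base_selected_rate = 0, odds_ratio = 1, seed = 14))
  expect_length(none$selected_sites, 0)
  expect_equal(
    enrichment_test(none$selected_sites, none$charge_classes)$p_value, 1)
  # reproducibility
  again <- plant_selection_sites(synthetic_selection_spec(
    n_sites = 100, base_selected_rate = 0, odds_ratio = 1, seed = 14))
  expect_identical(none, again)
})

test_that("simulate_family plants sequence-level pI targets", {
  recs <- simulate_family(c("human", "mouse"), length = 150,
                          target_pi = c(mouse = 4.8), seed = 8)
  expect_equal(vapply(recs, function(r) r$species, character(1)),
               c("human", "mouse"))
  expect_equal(nchar(recs[[2]]$sequence), 150)
  expect_equal(protein_pi(recs[[2]]), 4.8, tolerance = 0.06)
  # same seed, same family
  again <- simulate_family(c("human", "mouse"), length = 150,
                           target_pi = c(mouse = 4.8), seed = 8)
  expect_identical(recs, again)
})
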