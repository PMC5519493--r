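test_that("cell extraction yields one z per session, seed, and target", {
  sessions <- lapply(1:12, function(i)
    manual_session(matrix(rnorm(6 * 80), 6, 80), run_id = 2 * i))
  cells <- extract_cell_values(sessions, 1, 2, 3, 4)
  expect_equal(nrow(cells), 12 * 4)
  expect_equal(unname(table(cells$seed, cells$target)),
               matrix(12L, 2, 2))
  expect_error(extract_cell_values(sessions, 1, 2, 1, 4), "distinct")
})

test_that("cell extraction reports zero-variance region vertices by session", {
  data <- matrix(rnorm(5 * 60), 5, 60)
  data[3, ] <- 4
  sessions <- list(manual_session(data, run_id = 2, subject_id = 9))
  expect_error(extract_cell_values(sessions, 1, 2, 3, 5),
               "subject 9 run 2")
})

test_that("2x2 ANOVA agrees with the explicit sums-of-squares oracle", {
  for (i in 1:20) {
    cells <- with_seed(i, data.frame(
      seed = rep(c("a", "b"), each = 24),
      target = rep(rep(c("a", "b"), each = 12), 2),
      z = rnorm(48, mean = rep(c(0.5, 0.2, 0.1, 0.45), each = 12))))
    res <- anova_2x2(cells)
    ora <- anova_ss_oracle(cells)
    expect_lt(abs(res$F_interaction - ora$F_interaction), 1e-8)
    expect_lt(abs(res$F_seed - ora$F_seed), 1e-8)
    expect_lt(abs(res$F_target - ora$F_target), 1e-8)
    expect_lt(abs(res$p_interaction - ora$p_interaction), 1e-8)
  }
})

test_that("ANOVA df are (1, 4(n-1)) and degenerate input gives F=0, p=1", {
  cells <- data.frame(seed = rep(c("a", "b"), each = 24),
                      target = rep(rep(c("a", "b"), each = 12), 2),
                      z = rnorm(48))
  res <- anova_2x2(cells)
  expect_equal(res$df, c(1L, 44L))
  expect_equal(res$n_per_cell, 12L)
  const <- transform(cells, z = 0.3)
  res0 <- anova_2x2(const)
  expect_equal(res0$F_interaction, 0)
  expect_equal(res0$p_interaction, 1)
  expect_error(anova_2x2(cells[-1, ]), "unbalanced")
})

test_that("ANOVA interaction is invariant to constant shifts and label swaps", {
  cells <- with_seed(5, data.frame(
    seed = rep(c("a", "b"), each = 12),
    target = rep(rep(c("a", "b"), each = 6), 2),
    z = rnorm(24)))
  base <- anova_2x2(cells)
  shifted <- transform(cells, z = z + 3.21)
  expect_equal(anova_2x2(shifted)$F_interaction, base$F_interaction,
               tolerance = 1e-9)
  swapped <- transform(cells, seed = ifelse(seed == "a", "b", "a"),
                       target = ifelse(target == "a", "b", "a"))
  expect_equal(anova_2x2(swapped)$F_interaction, base$F_interaction,
               tolerance = 1e-9)
})

test_that("crossover classification follows the two-inequality rule", {
  mk <- function(aa, ab, ba, bb)
    matrix(c(aa, ba, ab, bb), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  expect_equal(classify_crossover(mk(0.6, 0.1, 0.1, 0.6)), "crossover")
  # positive interaction contrast but one direction fails
  expect_equal(classify_crossover(mk(0.6, 0.4, 0.55, 0.5)), "ordinal")
  expect_equal(classify_crossover(mk(0.3, 0.3, 0.3, 0.3)), "none")
  expect_equal(classify_crossover(mk(0.1, 0.6, 0.6, 0.1)), "none")
})

test_that("the battery enforces the discovery/replication firewall", {
  rep_report <- null_battery(1, n_subjects = 1, n_zones = 2,
                             n_sessions = 4)
  expect_s3_class(rep_report, "dissociation_report")
  # forging replication-derived regions must be refused
  p <- tiny_params(n_sessions = 4, frames_per_run = 100)
  study <- simulate_study(p)
  regions <- structure(
    list(subject_id = 1L, seed_a = 1L, seed_b = 2L,
         target_zones = 1:2,
         targets = matrix(3:6, 2, dimnames = list(c("a", "b"), NULL)),
         lone = NULL, provenance = "replication"),
    class = "region_set")
  expect_error(run_battery(study, list(regions)), "firewall")
})

test_that("battery shape: subjects x zones tests with summary counts", {
  report <- null_battery(3, n_subjects = 2, n_zones = 3, n_sessions = 6)
  expect_equal(report$n_tests, 2 * 3)
  expect_equal(nrow(report$results), 6)
  expect_equal(report$expected_null_significant, 0.06)
  expect_true(all(report$results$df1 == 1))
  expect_true(all(report$results$df2 == 4 * (3 - 1)))
})

test_that("a strongly planted study turns every battery test significant", {
  cfg_p <- tiny_params(n_subjects = 2, n_sessions = 12,
                       frames_per_run = 200)
  study <- preprocess_study(simulate_study(cfg_p),
                            preproc_params(n_discard = 4))
  regions <- lapply(seq_along(study$subjects), function(s) {
    tpl <- study$subjects[[s]]$template
    z <- mean_z_matrix(study_sessions(study, s, "discovery"), "discovery")
    pair <- find_seed_pair(z, 1, tpl$zones, seed_criteria(), study$mesh)
    select_regions(z, pair, tpl$zones, target_zones = 2:6, subject_id = s)
  })
  report <- run_battery(study, regions)
  expect_equal(report$n_tests, 2 * 5)
  expect_equal(report$n_significant, report$n_tests)
  expect_gt(report$n_crossover, 0)
})

test_that("the lone-region pairing adds one extra test per subject", {
  p <- tiny_params(n_sessions = 6, frames_per_run = 150)
  study <- preprocess_study(simulate_study(p), preproc_params(n_discard = 4))
  tpl <- study$subjects[[1]]$template
  z <- mean_z_matrix(study_sessions(study, 1, "discovery"), "discovery")
  pair <- find_seed_pair(z, 1, tpl$zones, seed_criteria(), study$mesh)
  regions <- select_regions(z, pair, tpl$zones, target_zones = 2:5,
                            lone_zone = 6, lone_partner = 5)
  report <- run_battery(study, list(regions))
  expect_equal(report$n_tests, 5)   # 4 zones + 1 lone pairing
  expect_true(any(grepl("lone", report$results$zone)))
})
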