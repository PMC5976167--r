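# expected allowed sets of the seven default blockmodels (zero/nonzero
# census pattern of the ideal networks)
expected_allowed <- list(
  cohesive = c("003", "102", "300"),
  core_periphery_symmetric = c("003", "201", "300"),
  core_periphery_asymmetric = c("003", "021U", "120D", "300"),
  hierarchical_null_diag = c("003", "021D", "021U", "021C"),
  hierarchical_complete_diag = c("102", "021C", "120D", "120U", "300"),
  transitivity_null_diag = c("003", "021D", "021U", "030T"),
  transitivity_complete_diag = c("030T", "120D", "120U", "300"))

test_that("allowed/forbidden classification matches each blockmodel's pattern", {
  for (tp in blockmodel_types) {
    cls <- classify_triads(blockmodel_spec(tp))
    expect_setequal(cls$allowed, expected_allowed[[tp]])
    expect_setequal(cls$forbidden, setdiff(triad_labels, expected_allowed[[tp]]))
  }
})

test_that("six triad types are forbidden in all seven blockmodels", {
  universal <- c("012", "111D", "111U", "030C", "120C", "210")
  for (tp in blockmodel_types) {
    cls <- classify_triads(blockmodel_spec(tp))
    expect_true(all(universal %in% cls$forbidden))
  }
})

test_that("selected allowed sets drop the two documented exceptions", {
  s <- selected_sets("hierarchical_null_diag", quiet = TRUE)
  expect_setequal(s$selected_allowed, c("003", "021U", "021D"))
  s <- selected_sets("transitivity_complete_diag", quiet = TRUE)
  expect_setequal(s$selected_allowed, c("120D", "120U", "030T"))
  s <- selected_sets("cohesive", quiet = TRUE)
  expect_setequal(s$selected_allowed, expected_allowed$cohesive)
  expect_message(selected_sets("cohesive"), "full forbidden set")
  expect_error(selected_sets("cohesive", selected_forbidden = "300"),
               "subset of the forbidden")
  s <- selected_sets("cohesive", selected_forbidden = c("012", "210"))
  expect_setequal(s$selected_forbidden, c("012", "210"))
})

test_that("A-measure is zero for forbidden types and one under an identity reference", {
  set.seed(3)
  s <- blockmodel_spec("cohesive")
  a <- a_measure(s, reps = 50)
  expect_true(all(a[setdiff(triad_labels, expected_allowed$cohesive)] == 0))
  a_id <- a_measure(s, reps = 3, reference = function(net) net)
  expect_true(all(a_id[expected_allowed$cohesive] == 1))
  expect_true(all(a_id[setdiff(triad_labels, expected_allowed$cohesive)] == 0))
})

test_that("A-measure of the complete triad matches the hypergeometric closed form", {
  set.seed(19)
  s <- blockmodel_spec("cohesive")
  reps <- 400
  draws <- replicate(reps, triad_census(randomize_network(build_ideal(s)))["300"])
  a <- a_measure(s, reps = reps, seed = 19)
  closed <- 168 / hypergeom_triad_mean(24, 168, q = 6)
  # Monte-Carlo error of the ratio, via the delta method on the mean count
  se_mean <- stats::sd(draws) / sqrt(reps)
  se_a <- closed * se_mean / mean(draws)
  expect_lt(abs(a["300"] - closed), 4 * se_a)
})

test_that("A-measure approaches 1 as the reference nears the ideal network", {
  # the reference at low level-of-errors is close to the ideal, so the
  # ideal-to-reference ratio shrinks toward 1; at LE = 1 it is largest
  set.seed(31)
  s <- blockmodel_spec("cohesive")
  les <- c(0.2, 0.4, 0.6, 0.8, 1)
  a300 <- vapply(les, function(le) a_measure(s, reps = 200, le = le)["300"],
                 numeric(1))
  expect_gt(stats::cor(les, a300, method = "spearman"), 0)
  expect_lt(a300[1], a300[5])
  expect_gt(min(a300), 1)
})

test_that("target vectors hold exact ideal counts for the chosen statistic set", {
  s <- blockmodel_spec("cohesive")
  tv <- target_vector(s, "all")
  expect_length(tv, 16)
  expect_equal(sum(tv), choose(24, 3))
  expect_equal(unname(tv["300"]), 168)
  tvf <- target_vector(s, "forbidden")
  expect_length(tvf, 13)
  expect_true(all(tvf == 0))
  sh <- blockmodel_spec("hierarchical_null_diag")
  tvh <- target_vector(sh, "selected_allowed", extra_stats = "three_paths")
  expect_false("021C" %in% names(tvh))
  expect_equal(unname(tvh["three_paths"]), 0)  # ideal hierarchy has no 3-trail
  expect_error(target_vector(s, extra_stats = "degree"), "unknown statistic")
})

test_that("classification is deterministic and agrees with a positive A-measure", {
  s <- blockmodel_spec("transitivity_null_diag")
  cls1 <- classify_triads(s)
  cls2 <- classify_triads(build_ideal(s))
  expect_identical(cls1$allowed, cls2$allowed)
  a <- a_measure(s, reps = 5, seed = 99)
  expect_setequal(names(a)[a > 0], cls1$allowed)
})
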