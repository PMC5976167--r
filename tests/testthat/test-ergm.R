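test_that("acceptance probability follows the change-statistic exponential", {
  s <- blockmodel_spec("cohesive", sizes = c(3, 3, 3))
  mdl <- blockmodel_ergm_model(s, "all")
  net <- build_ideal(s)
  expect_equal(acceptance_probability(mdl, net, net), 1)
  # one added arc between clusters turns three 003 triads (theta +2) into
  # 012 triads (theta -2): log-ratio is predictable from the census delta
  prop <- net
  prop[1, 4] <- 1L
  d <- census_delta(net, data.frame(i = 1, j = 4, op = "add"))
  lp <- sum(mdl$theta[names(d)] * d)
  expect_equal(acceptance_probability(mdl, net, prop), min(1, exp(lp)))
  # antisymmetry: swapping current and proposal flips the exponent's sign
  expect_equal(acceptance_probability(mdl, prop, net), min(1, exp(-lp)))
})

test_that("a unit increase of one forbidden statistic is accepted with exp(-2)", {
  mdl <- ergm_model("030C", -2)
  cyc <- empty_network(3)
  cyc[1, 2] <- cyc[2, 3] <- cyc[3, 1] <- 1L
  almost <- cyc
  almost[3, 1] <- 0L
  expect_equal(acceptance_probability(mdl, almost, cyc), exp(-2),
               tolerance = 1e-12)
  expect_equal(acceptance_probability(mdl, cyc, almost), 1)
})

test_that("fixed-density sampling conserves the arc count", {
  s <- blockmodel_spec("cohesive")
  mdl <- blockmodel_ergm_model(s, "all")
  for (seed in 1:3) {
    net <- sample_ergm(mdl, s, iterations = 10000, mode = "fixed",
                       seed = seed)
    expect_equal(sum(net), 168)
  }
})

test_that("a zero-coefficient fixed-density chain matches uniform randomization", {
  set.seed(44)
  s <- blockmodel_spec("cohesive", sizes = c(5, 5, 5))
  mdl <- ergm_model(triad_labels, rep(0, 16))
  m <- sum(build_ideal(s))
  chain <- replicate(200, triad_census(
    sample_ergm(mdl, s, iterations = 300, mode = "fixed"))["300"])
  unif <- replicate(200, triad_census(
    randomize_network(build_ideal(s)))["300"])
  se <- sqrt(stats::var(chain) / 200 + stats::var(unif) / 200)
  expect_lt(abs(mean(chain) - mean(unif)), 4 * se)
})

test_that("an edges-only model at coefficient zero has long-run density one half", {
  set.seed(9)
  mdl <- ergm_model("edges", 0)
  d <- replicate(60, {
    net <- sample_ergm(mdl, initial = empty_network(10),
                       iterations = 2000, mode = "free")
    sum(net) / 90
  })
  expect_lt(abs(mean(d) - 0.5), 0.03)
})

test_that("the free-density chain has the exact model distribution as its stationary law", {
  # n = 3: all 64 digraph states enumerated; the chain's empirical state
  # distribution is compared to exp(theta . g) / kappa by chi-squared
  set.seed(123)
  stats_used <- c("edges", "030T")
  theta <- c(0.2, 0.8)
  mdl <- ergm_model(stats_used, theta)
  res <- sample_ergm(mdl, initial = empty_network(3), iterations = 400000,
                     mode = "free", thin = 20)
  # state encoding used by the sampler: bits over ordered pairs, row-major
  decode_state <- function(code) {
    a <- matrix(0L, 3, 3)
    bit <- 0
    for (i in 1:3) for (j in 1:3) {
      if (i == j) next
      if (bitwAnd(code, bitwShiftL(1L, bit)) != 0) a[i, j] <- 1L
      bit <- bit + 1
    }
    a
  }
  logw <- vapply(0:63, function(code) {
    g <- network_stats(decode_state(code), stats_used)
    sum(theta * g)
  }, numeric(1))
  probs <- exp(logw - max(logw))
  probs <- probs / sum(probs)
  obs <- tabulate(res$states + 1L, nbins = 64)
  chi <- suppressWarnings(stats::chisq.test(obs, p = probs))
  expect_gt(chi$p.value, 0.001)
})

test_that("edges tuning recovers a near-zero coefficient at half density", {
  set.seed(77)
  s <- blockmodel_spec("cohesive", sizes = c(12, 12))  # ideal density 0.478
  mdl <- ergm_model("300", 0)  # no active structure term
  tuned <- tune_edges(mdl, s, window = 0.05, reps = 10, iterations = 2000)
  expect_lt(abs(tuned$edges), 1)
  expect_lt(abs(tuned$mean_density - tuned$ideal_density), 0.05)
  # postcondition re-test on a fresh sample
  fresh <- mean(replicate(10, sum(sample_ergm(tuned$model, s,
    iterations = 2000, mode = "free")) / (24 * 23)))
  expect_lt(abs(fresh - tuned$ideal_density), 0.1)
  expect_error(tune_edges(tuned$model, s), "edges term")
})

test_that("the hierarchical fix model is assembled as documented", {
  mdl <- hierarchical_fix_model()
  expect_equal(unname(mdl$theta["three_paths"]), -2)
  expect_equal(unname(mdl$theta["021C"]), 4)
  expect_true(all(mdl$theta[c("003", "021U", "021D")] == 2))
  mdl2 <- hierarchical_fix_model(boost = 2)
  expect_equal(unname(mdl2$theta["021C"]), 2)  # ordinary allowed weight
  mdl3 <- hierarchical_fix_model(boost_label = "021D")
  expect_equal(unname(mdl3$theta["021D"]), 4)
  expect_false("021C" %in% mdl3$statistics)
})

test_that("the fix model suppresses mutual dyads and three-paths", {
  set.seed(55)
  s <- blockmodel_spec("hierarchical_null_diag")
  fix <- hierarchical_fix_model()
  tuned <- tune_edges(fix, s, reps = 10, iterations = 5000)
  fix_nets <- lapply(1:6, function(i)
    sample_ergm(tuned$model, s, iterations = 10000, mode = "free"))
  base <- blockmodel_ergm_model(s, "selected", quiet = TRUE)
  tuned_base <- tune_edges(base, s, reps = 10, iterations = 5000)
  base_nets <- lapply(1:6, function(i)
    sample_ergm(tuned_base$model, s, iterations = 10000, mode = "free"))
  mutuals <- vapply(fix_nets, function(a) sum(a * t(a)) / 2, numeric(1))
  expect_true(all(mutuals == 0))
  tp_fix <- vapply(fix_nets, count_three_paths, numeric(1))
  tp_base <- vapply(base_nets, count_three_paths, numeric(1))
  expect_lte(stats::median(tp_fix), 0.05 * stats::median(tp_base))
})
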