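test_that("triad classification matches igraph for all 64 dyad configurations", {
  states <- c("null", "mutual", "asym_ij", "asym_ji")
  to_adj <- function(d_ab, d_ac, d_bc) {
    a <- matrix(0L, 3, 3)
    put <- function(state, i, j) {
      if (state == "mutual") { a[i, j] <<- 1L; a[j, i] <<- 1L }
      else if (state == "asym_ij") a[i, j] <<- 1L
      else if (state == "asym_ji") a[j, i] <<- 1L
    }
    put(d_ab, 1, 2); put(d_ac, 1, 3); put(d_bc, 2, 3)
    a
  }
  for (d_ab in states) for (d_ac in states) for (d_bc in states) {
    adj <- to_adj(d_ab, d_ac, d_bc)
    expected <- triad_labels[which(igraph_census(adj) == 1)]
    expect_identical(classify_triad(d_ab, d_ac, d_bc), expected)
  }
})

test_that("triad classification is invariant under unit relabeling", {
  set.seed(1)
  perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (code in 0:63) {
    adj <- matrix(0L, 3, 3)
    bits <- as.integer(intToBits(code))[1:6]
    adj[1, 2] <- bits[1]; adj[2, 1] <- bits[2]
    adj[1, 3] <- bits[3]; adj[3, 1] <- bits[4]
    adj[2, 3] <- bits[5]; adj[3, 2] <- bits[6]
    base <- triad_census(adj)
    for (p in perms) expect_identical(triad_census(adj[p, p]), base)
  }
})

test_that("census equals the igraph oracle on random digraphs and sums to choose(n,3)", {
  set.seed(42)
  for (r in 1:200) {
    n <- sample(3:12, 1)
    a <- random_digraph(n, sample(0:(n * (n - 1)), 1))
    cens <- triad_census(a)
    expect_equal(sum(cens), choose(n, 3))
    expect_equal(unname(cens), unname(igraph_census(a)))
  }
})

test_that("arc reversal swaps the up/down triad orientations and fixes the rest", {
  dual <- c("003" = "003", "012" = "012", "102" = "102",
            "021D" = "021U", "021U" = "021D", "021C" = "021C",
            "111D" = "111U", "111U" = "111D", "030T" = "030T",
            "030C" = "030C", "201" = "201", "120D" = "120U",
            "120U" = "120D", "120C" = "120C", "210" = "210", "300" = "300")
  set.seed(7)
  for (r in 1:50) {
    n <- sample(4:10, 1)
    a <- random_digraph(n, sample(1:(n * (n - 1)), 1))
    cens <- triad_census(a)
    rev_cens <- triad_census(t(a))
    expect_identical(unname(rev_cens[dual]), unname(cens))
  }
})

test_that("degenerate census inputs are handled", {
  expect_warning(cens <- triad_census(empty_network(2)), "fewer than 3")
  expect_true(all(cens == 0))
  expect_error(as_network(matrix(1L, 3, 3)), "loops")
  expect_error(as_network(matrix(2L, 3, 3)), "0 or 1")
})

test_that("census_delta matches a full recount for random toggles", {
  set.seed(11)
  for (r in 1:200) {
    n <- sample(4:10, 1)
    a <- random_digraph(n, sample(2:(n * (n - 1) - 2), 1))
    ntog <- sample(1:2, 1)
    togs <- NULL
    b <- a
    for (t in seq_len(ntog)) {
      if (runif(1) < 0.5 && sum(b) > 0) {
        pos <- which(b == 1L, arr.ind = TRUE)
        pick <- pos[sample.int(nrow(pos), 1), ]
        togs <- rbind(togs, data.frame(i = pick[1], j = pick[2], op = "remove"))
        b[pick[1], pick[2]] <- 0L
      } else {
        pos <- which(b == 0L & row(b) != col(b), arr.ind = TRUE)
        pick <- pos[sample.int(nrow(pos), 1), ]
        togs <- rbind(togs, data.frame(i = pick[1], j = pick[2], op = "add"))
        b[pick[1], pick[2]] <- 1L
      }
    }
    expect_identical(triad_census(a) + census_delta(a, togs),
                     suppressWarnings(triad_census(b)))
  }
})

test_that("census_delta of add-then-remove is zero and bad toggles error", {
  a <- empty_network(5)
  d <- census_delta(a, data.frame(i = c(1, 1), j = c(2, 2),
                                  op = c("add", "remove")))
  expect_true(all(d == 0))
  d2 <- census_delta(a, data.frame(i = 1, j = 2, op = "add"))
  expect_equal(unname(d2["012"]), 3)
  expect_equal(unname(d2["003"]), -3)
  expect_error(census_delta(a, data.frame(i = 1, j = 2, op = "remove")),
               "not applicable")
  expect_error(census_delta(a, data.frame(i = 1, j = 1, op = "add")),
               "invalid dyad")
})

test_that("three-path counts match the trail definition", {
  chain <- empty_network(4)
  chain[1, 2] <- chain[2, 3] <- chain[3, 4] <- 1L
  expect_equal(count_three_paths(chain), 1)
  cyc <- empty_network(3)
  cyc[1, 2] <- cyc[2, 3] <- cyc[3, 1] <- 1L
  expect_equal(count_three_paths(cyc), 3)
  expect_equal(count_three_paths(empty_network(6)), 0)
  mut <- empty_network(3)
  mut[1, 2] <- mut[2, 1] <- 1L  # a->b->a->b repeats an arc: not a trail
  expect_equal(count_three_paths(mut), 0)
})

test_that("three-path counts match brute-force enumeration over arc triples", {
  set.seed(23)
  for (r in 1:40) {
    n <- sample(4:7, 1)
    a <- random_digraph(n, sample(2:min(14, n * (n - 1)), 1))
    expect_equal(count_three_paths(a), brute_three_trails(a))
    expect_equal(count_three_paths(a, distinct_units = TRUE),
                 brute_three_trails(a, distinct_units = TRUE))
  }
})
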