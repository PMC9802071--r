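make_clean <- function(df) {
  df$order <- ave(seq_len(nrow(df)), df$participant, df$condition, df$target,
                  FUN = seq_along)
  df
}

test_that("count matrix cells count distinct participants", {
  raw <- make_clean(data.frame(
    participant = c("p1", "p2", "p3", "p1", "p1"),
    condition = "OR",
    target = c("gatto", "gatto", "gatto", "gatto", "cane"),
    response = c("latte", "latte", "latte", "pelo", "osso")))
  M <- build_count_matrix(raw, "OR")
  expect_equal(M["latte", "gatto"], 3L)
  expect_equal(M["pelo", "gatto"], 1L)
  expect_equal(M["osso", "gatto"], 0L)
  expect_error(build_count_matrix(raw, "CR"), "absent")
})

test_that("count matrix column sums match a brute-force recount", {
  w <- small_world()
  M <- build_count_matrix(w$clean, "OR")
  sub <- unique(w$clean[w$clean$condition == "OR",
                        c("participant", "target", "response")])
  recount <- table(sub$target)
  expect_equal(colSums(M)[names(recount)], as.vector(recount),
               ignore_attr = TRUE)
  expect_equal(rownames(M), sort(rownames(M)))
})

test_that("cosine weights match hand computations", {
  M <- cbind(a = c(2, 1, 0), b = c(1, 2, 0), c = c(2, 1, 0), d = c(0, 0, 3))
  rownames(M) <- c("r1", "r2", "r3")
  net <- cosine_network(M)
  expect_equal(net$weights["a", "b"], 0.8)          # 4 / (sqrt(5) sqrt(5))
  expect_equal(net$weights["a", "c"], 1)            # identical columns
  expect_equal(net$weights["a", "d"], 0)            # disjoint response sets
  expect_equal(net$weights, t(net$weights))
  expect_equal(unname(diag(net$weights)), rep(0, 4))
})

test_that("cosine similarity ignores positive rescaling of a count column", {
  set.seed(5)
  M <- matrix(rpois(60, 2), 10, 6, dimnames = list(paste0("r", 1:10), paste0("t", 1:6)))
  net1 <- cosine_network(M)
  M2 <- M; M2[, 3] <- M2[, 3] * 7L
  net2 <- cosine_network(M2)
  expect_equal(net1$weights, net2$weights, tolerance = 1e-12)
})

test_that("all-zero columns yield zero similarity with a warning", {
  M <- cbind(a = c(1, 0), b = c(0, 0), c = c(1, 1))
  rownames(M) <- c("r1", "r2")
  expect_warning(net <- cosine_network(M), "all-zero")
  expect_equal(unname(net$weights["b", ]), c(0, 0, 0))
})

test_that("TMFG keeps all 6 edges of a 4-node network", {
  net <- tmfg_filter(toy_network(random_weights(4, 1)))
  expect_equal(sum(net$weights[upper.tri(net$weights)] > 0), 6L)
  expect_true(is_planar_triangulation(net))
})

test_that("TMFG emits 3n - 6 edges and a planarity certificate (property)", {
  for (n in c(5, 8, 12, 40)) {
    net <- tmfg_filter(toy_network(random_weights(n, n)))
    expect_equal(nrow(attr(net, "edges")), 3L * n - 6L)
    expect_true(is_planar_triangulation(net))
  }
  expect_error(tmfg_filter(toy_network(random_weights(3, 1))), "at least 4")
})

test_that("5-node TMFG matches the exhaustive maximal-planar oracle", {
  # every maximal planar graph on 5 nodes is K5 minus one edge, so the oracle
  # enumerates the 10 candidates and keeps the heaviest
  W <- matrix(c(0, .05, .60, .70, .80,
                .05, 0, .55, .65, .75,
                .60, .55, 0, .85, .90,
                .70, .65, .85, 0, .95,
                .80, .75, .90, .95, 0), 5, 5)
  pairs <- t(combn(5, 2))
  totals <- sum(W[pairs]) - W[pairs]
  oracle_drop <- pairs[which.max(totals), ]
  net <- tmfg_filter(toy_network(W))
  kept <- attr(net, "edges")
  kept <- paste(pmin(kept[, 1], kept[, 2]), pmax(kept[, 1], kept[, 2]))
  missing <- setdiff(paste(pairs[, 1], pairs[, 2]), kept)
  expect_equal(missing, paste(oracle_drop[1], oracle_drop[2]))
})

test_that("TMFG edge selection is invariant to a constant weight shift", {
  W <- random_weights(9, 17)
  e1 <- attr(tmfg_filter(toy_network(W)), "edges")
  e2 <- attr(tmfg_filter(toy_network(W + 0.37)), "edges")
  expect_identical(e1, e2)
})

test_that("topology quantifiers match hand counts on toy graphs", {
  triangle <- toy_network(matrix(1, 3, 3))
  rep <- topology(triangle, n_random = 5, seed = 1)
  expect_equal(rep$cc, 1)
  expect_equal(rep$aspl, 1)

  k4_minus <- matrix(1, 4, 4); k4_minus[1, 4] <- k4_minus[4, 1] <- 0
  rep <- topology(toy_network(k4_minus), n_random = 5, seed = 1)
  expect_equal(rep$cc, 0.75)  # 6 closed / 8 connected triples

  # two disconnected K5s, partition = components: Q = 2 (1/2 - 1/4) = 0.5
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 1; W[6:10, 6:10] <- 1; diag(W) <- 0
  two_k5 <- toy_network(W)
  expect_equal(network_modularity(two_k5, membership = rep(1:2, each = 5)), 0.5)
  expect_error(topology(two_k5), "disconnected")
})

test_that("LONO drops one node per report and is symmetric on a cycle", {
  n <- 10
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- i %% n + 1
    W[i, j] <- W[j, i] <- 1
  }
  cyc <- toy_network(W)
  cyc$filtered <- TRUE
  reps <- lono_topology(cyc, n_random = 5, seed = 3)
  expect_equal(nrow(reps), n)
  # vertex-transitive graph: every leave-one-node-out report is identical
  expect_equal(length(unique(reps$cc)), 1L)
  expect_equal(length(unique(reps$aspl)), 1L)
})

test_that("LOSO produces one rebuilt-pipeline report per participant", {
  w <- small_world(small_config(n_participants = 5L))
  reps <- loso_topology(w$clean, "CR", n_random = 5, seed = 2)
  expect_equal(nrow(reps), 5L)
  expect_true(all(is.finite(reps$s)))
})

test_that("topology reports stay within their defined ranges", {
  w <- small_world()
  net <- tmfg_filter(cosine_network(build_count_matrix(w$clean, "OR"), "OR"))
  rep <- topology(net, n_random = 20, seed = 11)
  expect_true(rep$cc >= 0 && rep$cc <= 1)
  expect_gte(rep$aspl, 1)
  expect_true(rep$q >= -0.5 && rep$q <= 1)
  expect_gt(rep$s, 0)
})
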