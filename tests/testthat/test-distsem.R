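test_that("word2vec text round-trips through write and read", {
  set.seed(3)
  emb <- matrix(rnorm(20), 5, 4,
                dimnames = list(c("cane", "gatto", "sole", "luna", "mare"), NULL))
  path <- withr::local_tempfile(fileext = ".vec")
  write_word2vec(emb, path)
  first <- readLines(path, n = 1)
  expect_equal(first, "5 4")
  back <- read_word2vec(path)
  expect_equal(back, emb, tolerance = 1e-9)
  sub <- read_word2vec(path, vocab = c("cane", "luna"))
  expect_equal(rownames(sub), c("cane", "luna"))
})

test_that("averaging uses exactly the models that contain each word", {
  a <- matrix(1, 2, 3, dimnames = list(c("x", "y"), NULL))
  b <- matrix(3, 2, 3, dimnames = list(c("x", "z"), NULL))
  c3 <- matrix(5, 1, 3, dimnames = list("x", NULL))
  out <- average_embeddings(list(a, b, c3))
  expect_equal(unname(out["x", ]), rep(3, 3))   # mean of 1, 3, 5
  expect_equal(unname(out["y", ]), rep(1, 3))   # only model a
  expect_equal(unname(out["z", ]), rep(3, 3))   # only model b
  cov <- attr(out, "coverage")
  expect_equal(unname(cov[c("x", "y", "z")]), c(3L, 1L, 1L))
  # idempotence: averaging identical tables returns the table
  expect_equal(average_embeddings(list(a, a, a)), a, ignore_attr = TRUE)
})

test_that("words in no model are excluded and reported", {
  a <- matrix(1, 1, 2, dimnames = list("x", NULL))
  expect_warning(out <- average_embeddings(list(a), vocab = c("x", "ghost")),
                 "absent from all models")
  expect_equal(attr(out, "excluded"), "ghost")
  expect_false("ghost" %in% rownames(out))
  expect_error(average_embeddings(list(a), vocab = "ghost"), "no requested word")
  b <- matrix(1, 1, 5, dimnames = list("x", NULL))
  expect_error(average_embeddings(list(a, b)), "dimension mismatch")
})

test_that("semantic distance hits its closed-form endpoints", {
  x <- c(1, 2, 3)
  expect_equal(semantic_distance(x, x), 0)
  expect_equal(semantic_distance(x, -x), 2)
  expect_equal(semantic_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(semantic_distance(x, 10 * x), 0)            # scale invariance
  expect_equal(semantic_distance(2 * x, c(3, 2, 1)),
               semantic_distance(x, c(3, 2, 1)))
  expect_error(semantic_distance(x, c(0, 0, 0)), "zero vector")
  expect_error(semantic_distance(x, c(1, 2)), "length")
})

test_that("category assignment matches the brute-force argmin", {
  set.seed(8)
  K <- matrix(rnorm(100), 10, 10)
  for (i in 1:20) {
    x <- rnorm(10)
    oracle <- which.min(apply(K, 1, function(k) semantic_distance(x, k)))
    expect_equal(assign_category(x, K), oracle)
  }
  expect_equal(assign_category(K[3, ], K), 3L)   # zero distance to itself
  expect_error(assign_category(x, K[0, , drop = FALSE]), "empty category")
})

test_that("category ties go to the lowest index with a warning", {
  K <- rbind(c(1, 0), c(1, 0), c(0, 1))
  expect_warning(idx <- assign_category(c(2, 0), K), "tie")
  expect_equal(idx, 1L)
})

test_that("category switching is 1 minus the Kronecker delta", {
  expect_equal(category_switch(2L, 2L), 0L)
  expect_equal(category_switch(2L, 7L), 1L)
  ct <- c(1, 1, 2, 3, 5)
  cr <- c(1, 2, 2, 1, 5)
  expect_equal(sum(category_switch(ct, cr)), 2L)   # hand count of switches
})

test_that("distance records and summaries aggregate correctly", {
  # 2-d embedding with known angles: response at 90 deg -> sd 1, at 0 -> 0
  emb <- rbind(t1 = c(1, 0), r1 = c(0, 1), r2 = c(1, 0),
               k1 = c(1, 0.2), k2 = c(-1, 0.5))
  clean <- data.frame(participant = "p1", condition = "OR", target = "t1",
                      response = c("r1", "r2"), order = 1:2)
  rec <- distance_records(clean, emb, c("k1", "k2"))
  expect_equal(rec$sd, c(1, 0), tolerance = 1e-9)
  expect_true(all(rec$sd >= 0 & rec$sd <= 2))
  expect_equal(rec$cs, c(1L, 0L))
  expect_equal(rec$cs, as.integer(rec$target_category != rec$response_category))
  summ <- participant_summaries(rec)
  expect_equal(summ$mean_sd, 0.5, tolerance = 1e-9)
  expect_equal(summ$mean_cs, 0.5)
})

test_that("unembedded responses are dropped with a count", {
  emb <- rbind(t1 = c(1, 0), r1 = c(0, 1), k1 = c(1, 1))
  clean <- data.frame(participant = "p1", condition = "OR", target = "t1",
                      response = c("r1", "ghost"), order = 1:2)
  expect_message(rec <- distance_records(clean, emb, "k1"), "dropped")
  expect_equal(nrow(rec), 1L)
  expect_equal(attr(rec, "n_unembedded"), 1L)
})

test_that("synthetic group ordering of distance is OR < CR < RA", {
  w <- small_world()
  consensus <- average_embeddings(w$spaces)
  cats <- grep("^category", rownames(consensus), value = TRUE)
  rec <- distance_records(w$clean, consensus, cats)
  summ <- participant_summaries(rec)
  m <- tapply(summ$mean_sd, summ$condition, mean)
  expect_true(m[["OR"]] < m[["CR"]] && m[["CR"]] < m[["RA"]])
  cs <- tapply(summ$mean_cs, summ$condition, mean)
  expect_true(all(cs >= 0 & cs <= 1))
  expect_true(cs[["RA"]] > cs[["OR"]])
})

test_that("model-space correlations detect shared and independent structure", {
  a <- matrix(rnorm(200), 20, 10, dimnames = list(paste0("w", 1:20), NULL))
  expect_equal(unname(model_space_correlation(list(a, a), paste0("w", 1:5),
                                              paste0("w", 6:20))[1, 2]), 1)
  set.seed(4)
  # independent random spaces over many pairs decorrelate
  n <- 110
  words <- paste0("w", seq_len(n))
  b1 <- matrix(rnorm(n * 50), n, 50, dimnames = list(words, NULL))
  b2 <- matrix(rnorm(n * 50), n, 50, dimnames = list(words, NULL))
  r <- model_space_correlation(list(b1, b2), words[1:100], words[101:110])
  expect_lt(abs(r[1, 2]), 0.1)
})
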