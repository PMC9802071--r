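# tiny embedding with exact angles: distances to "t" are 0.5 and 1
angle_embedding <- function() {
  rbind(t = c(1, 0),
        half = c(0.5, sqrt(3) / 2),   # cos 60deg = 0.5 -> sd = 0.5
        orth = c(0, 1))               # sd = 1
}

# a well-conditioned random value matrix plus i.i.d. policy draws
simulated_cell <- function(beta, n_resp, nt = 40, k = 100, seed = 1) {
  set.seed(seed)
  V <- matrix(runif(nt * k, 0.5, 3), nt, k,
              dimnames = list(paste0("t", seq_len(nt)), paste0("w", seq_len(k))))
  class(V) <- c("value_matrix", class(V))
  tg <- sample(rownames(V), n_resp, replace = TRUE)
  resp <- vapply(tg, function(t)
    sample(colnames(V), 1, prob = semexp_policy(V[t, ], beta)), character(1))
  list(V = V, responses = data.frame(target = tg, response = resp))
}

test_that("value transforms follow their closed forms", {
  emb <- angle_embedding()
  V <- build_value_matrix(emb, "t", c("half", "orth"))
  expect_equal(unname(V["t", "orth"]), 1)       # sd 1 -> 1/1
  expect_equal(unname(V["t", "half"]), 2)       # sd 0.5 -> 1/0.5
  V2 <- build_value_matrix(emb, "t", c("half", "orth"), transform = "linear")
  expect_equal(unname(V2["t", c("half", "orth")]), c(1.5, 1))
  expect_error(build_value_matrix(emb, "t", "ghost"), "ghost")
})

test_that("value matrices are nonnegative for random embeddings (property)", {
  for (seed in 1:3) {
    set.seed(seed)
    emb <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(paste0("w", 1:30), NULL))
    V <- build_value_matrix(emb, paste0("w", 1:5), paste0("w", 6:30))
    expect_true(all(V >= 0) && all(is.finite(V)))
    V2 <- build_value_matrix(emb, paste0("w", 1:5), paste0("w", 6:30),
                             transform = "linear")
    expect_true(all(V2 >= 0))
  }
})

test_that("the softmax policy matches closed forms and sums to one", {
  expect_equal(semexp_policy(c(1, 0), 1),
               c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
  expect_equal(semexp_policy(runif(7), 0), rep(1 / 7, 7))
  p <- semexp_policy(c(0.2, 0.9, 0.5), 1e6)
  expect_equal(p[2], 1)
  set.seed(2)
  for (i in 1:20) {
    p <- semexp_policy(rnorm(50), runif(1, 0, 10))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
  expect_error(semexp_policy(numeric(0), 1), "empty")
})

test_that("the NLL matches hand-summed cross-entropies", {
  expect_equal(semexp_nll(matrix(0.25, 1, 4), 1L), log(4))
  perfect <- matrix(c(1, 0, 0), 1)
  expect_no_warning(expect_equal(semexp_nll(perfect, 1L), 0))
  two <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(semexp_nll(two, c(1L, 1L)), -log(0.5) - log(0.25))
  expect_warning(semexp_nll(matrix(c(0, 1), 1), 1L), "clamped")
})

test_that("stacked NLL agrees with the per-response definition", {
  cell <- simulated_cell(1.3, 40, nt = 6, k = 12, seed = 5)
  beta <- 0.8
  pred <- t(vapply(cell$responses$target,
                   function(t) semexp_policy(cell$V[t, ], beta), numeric(12)))
  chosen <- match(cell$responses$response, colnames(cell$V))
  expect_equal(semexp_nll_at(cell$V, cell$responses, beta),
               semexp_nll(pred, chosen), tolerance = 1e-10)
})

test_that("analytic beta-gradient matches centered finite differences", {
  for (seed in 1:5) {
    cell <- simulated_cell(runif(1, 0.3, 3), 60, nt = 8, k = 30, seed = seed)
    beta <- runif(1, 0.1, 4)
    st <- semexplore:::stack_responses(cell$V, cell$responses)
    g <- semexplore:::nll_grad_beta(st, beta)[["grad"]]
    h <- 1e-5
    fd <- (semexp_nll_at(cell$V, cell$responses, beta + h) -
             semexp_nll_at(cell$V, cell$responses, beta - h)) / (2 * h)
    expect_lt(abs(g - fd) / max(abs(fd), 1e-8), 1e-5)
  }
})

test_that("fit_beta recovers a known beta and zeroes the gradient", {
  cell <- simulated_cell(2.0, 500, seed = 7)
  fit <- fit_beta(cell$V, cell$responses, seed = 3)
  expect_lt(abs(fit$beta - 2.0), 0.15)
  expect_lt(abs(fit$gradient), 1e-4)
  expect_true(any(fit$restarts$converged))
  expect_equal(fit$nll, min(fit$restarts$nll))
  expect_error(fit_beta(cell$V, cell$responses[0, ]), "no responses")
})

test_that("balanced responses over the vocabulary drive beta to zero", {
  set.seed(11)
  V <- matrix(runif(5 * 20, 0.5, 3), 5, 20,
              dimnames = list(paste0("t", 1:5), paste0("w", 1:20)))
  responses <- expand.grid(target = rownames(V), response = colnames(V),
                           stringsAsFactors = FALSE)
  fit <- fit_beta(V, responses, seed = 2)
  expect_lt(abs(fit$beta), 0.1)
})

test_that("the grid landscape is finite, convex, and brackets the optimum", {
  cell <- simulated_cell(1.5, 200, seed = 9)
  land <- grid_landscape(cell$V, cell$responses)
  expect_equal(nrow(land), 50L)
  expect_true(all(is.finite(land$nll)))
  expect_true(all(diff(diff(land$nll)) >= -1e-6))   # numerical convexity
  fit <- fit_beta(cell$V, cell$responses, seed = 4)
  step <- diff(land$beta[1:2])
  expect_lt(abs(land$beta[which.min(land$nll)] - fit$beta), step + 1e-9)
  # the fitted NLL never exceeds any grid evaluation
  expect_true(all(fit$nll <= land$nll + 1e-8))
})

test_that("model selection orders SemExp <= WordEmb <= null on model data", {
  cell <- simulated_cell(1.8, 150, seed = 13)
  clean <- cbind(participant = "p1", condition = "CR", cell$responses)
  sel <- model_selection(cell$V, clean, seed = 5)
  expect_equal(sel$nll_null, 150 * log(ncol(cell$V)))
  expect_lte(sel$nll_semexp, sel$nll_wordemb + 1e-6)
  expect_lte(sel$nll_wordemb, sel$nll_null + 1e-6)
})

test_that("group-mean fitted betas preserve the OR > CR > RA ordering", {
  # full vocabulary and dimensionality: a small response pool depletes under
  # without-replacement sampling and would blur the 0.13 OR-CR contrast
  cfg <- synth_config(n_participants = 12L, seed = 42L)
  spaces <- make_embedding_spaces(cfg)
  resp <- simulate_responses(spaces, cfg)
  clean <- clean_responses(resp, stopwords = synth_stopwords())
  consensus <- average_embeddings(spaces)
  targets <- sort(unique(clean$target))
  vocab <- sort(unique(clean$response[clean$response %in% rownames(consensus)]))
  V <- build_value_matrix(consensus, targets, vocab)
  sel <- model_selection(V, clean, control = semexp_control(n_restarts = 3L),
                         seed = 5)
  m <- tapply(sel$beta, sel$condition, mean)
  expect_true(m[["OR"]] > m[["CR"]] && m[["CR"]] > m[["RA"]])
})

test_that("shuffled recovery destroys the true-fitted correlation", {
  set.seed(17)
  true <- runif(30, 0.1, 4)
  fitted <- true + rnorm(30, 0, 0.1)
  r_real <- pearson_r(true, fitted)$r
  r_null <- mean(replicate(200, pearson_r(true, sample(fitted))$r))
  expect_gt(r_real, 0.97)
  expect_lt(abs(r_null), 0.1)
})
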