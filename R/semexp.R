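#' Build the SemExp value matrix from consensus embeddings
#'
#' The first component of the Semantic Explorer model: a targets x vocabulary
#' matrix of nonnegative similarity values derived from the consensus
#' embedding. The default transform is the reciprocal of the semantic
#' distance, `1 / max(sd, eps)`; the alternative `"linear"` transform uses
#' `2 - sd`. Both are positive and decreasing in distance.
#'
#' @param emb Consensus embedding matrix covering all targets and vocabulary
#'   words (missing words raise an error naming them).
#' @param targets Character vector of target words (rows).
#' @param vocab Character vector of response words (columns); typically all
#'   unique responses given by the sample.
#' @param transform `"reciprocal"` (default) or `"linear"`.
#' @param eps Floor applied to the distance before taking the reciprocal.
#' @return Numeric matrix of class `value_matrix` (rows targets, columns
#'   vocabulary) with a `transform` attribute.
#' @export
build_value_matrix <- function(emb, targets, vocab,
                               transform = c("reciprocal", "linear"),
                               eps = 1e-6) {
  transform <- match.arg(transform)
  D <- semantic_distance_matrix(emb, targets, vocab)
  V <- if (transform == "reciprocal") 1 / pmax(D, eps) else 2 - D
  if (any(!is.finite(V)) || any(V < 0))
    stop("value matrix has nonfinite or negative entries")
  structure(V, transform = transform, class = c("value_matrix", class(V)))
}

#' SemExp softmax action-selection policy
#'
#' Probability of each response word given a target's value row:
#' `softmax(beta * x)`, computed with max-subtraction for numerical
#' stability. `beta = 0` gives the uniform distribution; large `beta`
#' concentrates all mass on the highest-value word.
#'
#' @param values_row Numeric vector of similarity values for one target.
#' @param beta Inverse temperature.
#' @return Probability vector summing to 1.
#' @export
semexp_policy <- function(values_row, beta) {
  if (length(values_row) == 0L) stop("empty value row")
  if (any(!is.finite(values_row))) stop("value row must be finite")
  z <- beta * values_row
  e <- exp(z - max(z))
  e / sum(e)
}

#' Negative log-likelihood of observed choices under predicted probabilities
#'
#' Cross-entropy loss: the sum over responses of minus the log predicted
#' probability of the chosen word. Predicted probabilities of observed
#' choices are clamped at `1e-12` (with a warning) to keep the loss finite.
#'
#' @param pred Matrix of predicted probability vectors, one row per response.
#' @param chosen Integer vector of chosen column indices (the one-hot
#'   positions), one per row of `pred`.
#' @return The summed negative log-likelihood.
#' @export
semexp_nll <- function(pred, chosen) {
  if (is.null(dim(pred))) pred <- matrix(pred, nrow = 1L)
  if (nrow(pred) != length(chosen)) stop("one chosen index per prediction row")
  p <- pred[cbind(seq_along(chosen), chosen)]
  if (any(p <= 1e-12)) {
    warning("predicted probability of an observed choice clamped at 1e-12")
    p <- pmax(p, 1e-12)
  }
  -sum(log(p))
}

#' Optimiser settings for SemExp fitting
#'
#' @param lr Gradient-descent learning rate.
#' @param tol Convergence tolerance on the change in NLL.
#' @param patience Number of consecutive sub-tolerance iterations required to
#'   declare convergence.
#' @param max_iter Iteration cap per restart.
#' @param n_restarts Number of random restarts.
#' @param init_range Range of the uniform initialisation of beta.
#' @return List of class `semexp_control`.
#' @export
semexp_control <- function(lr = 0.01, tol = 1e-7, patience = 20L,
                           max_iter = 10000L, n_restarts = 10L,
                           init_range = c(0.5, 5)) {
  structure(list(lr = lr, tol = tol, patience = as.integer(patience),
                 max_iter = as.integer(max_iter),
                 n_restarts = as.integer(n_restarts), init_range = init_range),
            class = "semexp_control")
}

## Stack one participant-condition's responses against the value matrix:
## per-target counts, the summed chosen values, and row extrema for the
## stable log-sum-exp.
stack_responses <- function(values, responses) {
  ti <- match(responses$target, rownames(values))
  ri <- match(responses$response, colnames(values))
  if (anyNA(ti))
    stop("target(s) missing from the value matrix: ",
         paste(unique(responses$target[is.na(ti)]), collapse = ", "))
  if (anyNA(ri))
    stop("response word(s) missing from the value matrix: ",
         paste(utils::head(unique(responses$response[is.na(ri)]), 5L), collapse = ", "))
  rows <- sort(unique(ti))
  list(V = values[rows, , drop = FALSE],
       cnt = tabulate(match(ti, rows), length(rows)),
       sum_chosen = sum(values[cbind(ti, ri)]),
       rmax = apply(values[rows, , drop = FALSE], 1L, max),
       rmin = apply(values[rows, , drop = FALSE], 1L, min),
       n = length(ti), chosen_rows = ti, chosen_cols = ri)
}

## NLL and its analytic beta-gradient on stacked data.
## NLL(beta) = sum_t cnt_t * logsumexp(beta * V_t) - beta * sum_chosen
## dNLL/dbeta = sum_t cnt_t * E_softmax[V_t] - sum_chosen
nll_grad_beta <- function(st, beta) {
  m <- if (beta >= 0) beta * st$rmax else beta * st$rmin
  E <- exp(beta * st$V - m)
  S0 <- rowSums(E)
  S1 <- rowSums(E * st$V)
  c(nll = sum(st$cnt * (log(S0) + m)) - beta * st$sum_chosen,
    grad = sum(st$cnt * (S1 / S0)) - st$sum_chosen)
}

#' NLL of a response set at a fixed inverse temperature
#'
#' @param values A [build_value_matrix()] result.
#' @param responses Data frame with `target` and `response` columns (one
#'   participant-condition cell).
#' @param beta Inverse temperature.
#' @return The negative log-likelihood.
#' @export
semexp_nll_at <- function(values, responses, beta) {
  st <- stack_responses(values, responses)
  unname(nll_grad_beta(st, beta)["nll"])
}

#' Fit the SemExp inverse temperature by gradient descent
#'
#' Minimises the stacked negative log-likelihood of one participant-condition
#' cell over beta using plain gradient descent with the analytic gradient
#' (the model is fully differentiable and convex in beta). The optimiser runs
#' `n_restarts` times from uniform random initialisations; a restart stops
#' when the NLL change stays below `tol` for `patience` consecutive
#' iterations, or at `max_iter`. The restart with the lowest final NLL is
#' reported. Beta is unconstrained during descent: values below 1 indicate
#' exploratory behaviour and are meaningful.
#'
#' @param values A [build_value_matrix()] result.
#' @param responses Data frame with `target` and `response` columns; at least
#'   one row.
#' @param control A [semexp_control()].
#' @param seed Optional seed for the restart initialisations.
#' @return Object of class `semexp_fit`: list with `beta`, `nll`, `gradient`
#'   (at the optimum), `restarts` (per-restart data frame: `init`, `beta`,
#'   `nll`, `iterations`, `converged`), and `control`.
#' @export
fit_beta <- function(values, responses, control = semexp_control(), seed = NULL) {
  if (is.null(responses) || nrow(responses) == 0L) stop("no responses to fit")
  st <- stack_responses(values, responses)
  if (!is.null(seed)) set.seed(seed)
  inits <- stats::runif(control$n_restarts, control$init_range[1], control$init_range[2])
  restarts <- data.frame(init = inits, beta = NA_real_, nll = NA_real_,
                         iterations = NA_integer_, converged = NA)
  for (r in seq_len(control$n_restarts)) {
    beta <- inits[r]
    prev <- Inf; pat <- 0L; it <- 0L; nll <- NA_real_
    repeat {
      it <- it + 1L
      ng <- nll_grad_beta(st, beta)
      nll <- ng[["nll"]]
      beta <- beta - control$lr * ng[["grad"]]
      pat <- if (abs(prev - nll) < control$tol) pat + 1L else 0L
      prev <- nll
      if (pat >= control$patience || it >= control$max_iter) break
    }
    restarts$beta[r] <- beta
    restarts$nll[r] <- nll_grad_beta(st, beta)[["nll"]]
    restarts$iterations[r] <- it
    restarts$converged[r] <- pat >= control$patience
  }
  best <- which.min(restarts$nll)
  structure(list(beta = restarts$beta[best], nll = restarts$nll[best],
                 gradient = unname(nll_grad_beta(st, restarts$beta[best])["grad"]),
                 restarts = restarts, control = control, n = st$n),
            class = "semexp_fit")
}

#' @export
print.semexp_fit <- function(x, ...) {
  cat(sprintf("SemExp fit: beta = %.4f, NLL = %.4f (%d responses, %d/%d restarts converged)\n",
              x$beta, x$nll, x$n, sum(x$restarts$converged), nrow(x$restarts)))
  invisible(x)
}

#' NLL loss landscape over a beta grid
#'
#' Evaluates the stacked NLL on a linear grid of beta values (0.1 to 5 in 50
#' steps by default), for visual inspection of the loss landscape.
#'
#' @inheritParams semexp_nll_at
#' @param grid Numeric vector of beta values.
#' @return Data frame `beta`, `nll`.
#' @export
grid_landscape <- function(values, responses, grid = seq(0.1, 5, length.out = 50L)) {
  st <- stack_responses(values, responses)
  data.frame(beta = grid,
             nll = vapply(grid, function(b) nll_grad_beta(st, b)[["nll"]], numeric(1)))
}

#' Compare the null, WordEmb, and SemExp models per participant-condition
#'
#' Three nested accounts of response generation: a null model assigning
#' uniform probability `1/k` to every vocabulary word (NLL = `n log k`); the
#' parameter-free WordEmb model using each row of the value matrix, normalised
#' to sum to one, as the choice distribution; and the fitted SemExp model.
#'
#' @param values A [build_value_matrix()] result.
#' @param clean Cleaned response table covering one or more
#'   participant-condition cells.
#' @param control A [semexp_control()] for the SemExp fits.
#' @param seed Optional seed (per-cell fit seeds are derived from it).
#' @return Data frame `participant`, `condition`, `n`, `nll_null`,
#'   `nll_wordemb`, `nll_semexp`, `beta`.
#' @export
model_selection <- function(values, clean, control = semexp_control(), seed = NULL) {
  k <- ncol(values)
  Vnorm <- values / rowSums(values)
  cells <- unique(clean[, c("participant", "condition")])
  cells <- cells[order(cells$condition, cells$participant), ]
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- clean[clean$participant == cells$participant[i] &
                   clean$condition == cells$condition[i], ]
    st <- stack_responses(values, sub)
    nll_we <- -sum(log(pmax(Vnorm[cbind(st$chosen_rows, st$chosen_cols)], 1e-12)))
    fit <- fit_beta(values, sub, control = control,
                    seed = if (is.null(seed)) NULL else seed + i)
    out[[i]] <- data.frame(participant = cells$participant[i],
                           condition = cells$condition[i], n = st$n,
                           nll_null = st$n * log(k), nll_wordemb = nll_we,
                           nll_semexp = fit$nll, beta = fit$beta)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Parameter recovery of the SemExp inverse temperature
#'
#' Simulates artificial response data from the SemExp policy itself — for
#' each participant x condition cell, a true beta drawn uniformly from
#' `beta_range` and per-target response counts drawn as in the synthetic
#' study (Poisson with the condition's mean fluency split over targets) —
#' then refits every cell and correlates fitted against true betas. High
#' correlation shows the study's sample sizes identify the parameter.
#'
#' @param values A [build_value_matrix()] result (e.g. from synthetic
#'   embedding spaces).
#' @param config A [synth_config()] supplying sample sizes and fluencies.
#' @param control A [semexp_control()].
#' @param seed Seed for simulation and fitting.
#' @param beta_range Range of the uniform true-beta draw.
#' @return List with `cells` (data frame `participant`, `condition`,
#'   `true_beta`, `fitted_beta`, `n`), `r` (Pearson correlation), and `p`.
#' @export
parameter_recovery <- function(values, config, control = semexp_control(),
                               seed = 1L, beta_range = c(0.1, 4)) {
  set.seed(seed)
  conds <- wat_conditions()
  participants <- sprintf("p%02d", seq_len(config$n_participants))
  cells <- expand.grid(participant = participants, condition = conds,
                       stringsAsFactors = FALSE)
  cells$true_beta <- stats::runif(nrow(cells), beta_range[1], beta_range[2])
  cells$fitted_beta <- NA_real_
  cells$n <- NA_integer_
  nt <- nrow(values)
  for (i in seq_len(nrow(cells))) {
    lambda <- config$fluency_mean_by_condition[[cells$condition[i]]] / nt
    counts <- stats::rpois(nt, lambda)
    if (sum(counts) == 0L) counts[sample.int(nt, 1L)] <- 1L
    sim <- sample_semexp_cell(values, cells$true_beta[i], counts, replace = TRUE)
    fit <- fit_beta(values, sim, control = control, seed = seed + i)
    cells$fitted_beta[i] <- fit$beta
    cells$n[i] <- nrow(sim)
  }
  ct <- stats::cor.test(cells$true_beta, cells$fitted_beta)
  list(cells = cells, r = unname(ct$estimate), p = ct$p.value)
}
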