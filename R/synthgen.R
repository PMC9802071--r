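#' Conditions of the word association task
#'
#' The three instruction conditions: ordinary (`OR`, appropriateness-driven),
#' creative (`CR`, balanced), and random (`RA`, novelty-driven).
#'
#' @return Character vector of condition labels.
#' @export
wat_conditions <- function() c("OR", "CR", "RA")

#' Configuration for the synthetic word-association study
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate the study conditions the pipeline is designed for: 56 participants,
#' 40 target words drawn evenly from 10 semantic categories, 300-dimensional
#' embeddings from 3 correlated model spaces, condition-specific softmax
#' inverse temperatures (OR 2.47, CR 2.34, RA 0.76), condition mean fluencies
#' (OR 130.96, CR 78.45, RA 172.52 responses per participant), and 8 raters.
#'
#' @param n_participants Number of participants.
#' @param n_targets Number of target words; must be divisible by
#'   `n_categories`.
#' @param n_categories Number of semantic categories.
#' @param embed_dim Embedding dimensionality (>= 2).
#' @param n_models Number of word-embedding model spaces to emulate.
#' @param vocab_size Size of the response-word pool (disjoint from targets).
#' @param beta_by_condition Named positive vector of softmax inverse
#'   temperatures used to generate responses, one per condition.
#' @param fluency_mean_by_condition Named positive vector of mean response
#'   counts per participant and condition.
#' @param cross_model_noise Standard deviation of the additive Gaussian noise
#'   applied independently to each model space after rotation. `0` makes all
#'   model spaces geometrically identical up to rotation.
#' @param within_category_sd Spread of word vectors around their category
#'   centroid in the latent space.
#' @param n_raters Number of simulated raters.
#' @param rater_noise Named vector of rater noise standard deviations for the
#'   novelty, appropriateness, and creativity scales.
#' @param dirty_fraction Fraction of additional "dirty" rows (uppercase,
#'   punctuation, target-containing, stop-word, nonword responses) injected
#'   into the simulated response table to exercise preprocessing.
#' @param seed Integer seed; every generator output is deterministic given it.
#'
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_participants = 56L,
                         n_targets = 40L,
                         n_categories = 10L,
                         embed_dim = 300L,
                         n_models = 3L,
                         vocab_size = 3300L,
                         beta_by_condition = c(OR = 2.47, CR = 2.34, RA = 0.76),
                         fluency_mean_by_condition = c(OR = 130.96, CR = 78.45, RA = 172.52),
                         cross_model_noise = 0.35,
                         within_category_sd = 0.7,
                         n_raters = 8L,
                         rater_noise = c(novelty = 0.35, appropriateness = 0.25, creativity = 2.5),
                         dirty_fraction = 0.02,
                         seed = 1L) {
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_targets = as.integer(n_targets),
    n_categories = as.integer(n_categories),
    embed_dim = as.integer(embed_dim),
    n_models = as.integer(n_models),
    vocab_size = as.integer(vocab_size),
    beta_by_condition = beta_by_condition,
    fluency_mean_by_condition = fluency_mean_by_condition,
    cross_model_noise = cross_model_noise,
    within_category_sd = within_category_sd,
    n_raters = as.integer(n_raters),
    rater_noise = rater_noise,
    dirty_fraction = dirty_fraction,
    seed = as.integer(seed)
  )
  if (cfg$n_targets %% cfg$n_categories != 0L)
    stop("n_targets must be divisible by n_categories")
  if (cfg$embed_dim < 2L) stop("embed_dim must be >= 2")
  if (cfg$vocab_size < cfg$n_targets) stop("vocab_size must be >= n_targets")
  conds <- wat_conditions()
  if (!all(conds %in% names(cfg$beta_by_condition)))
    stop("beta_by_condition must name all conditions: ", paste(conds, collapse = ", "))
  if (any(cfg$beta_by_condition <= 0)) stop("all betas must be > 0")
  if (!all(conds %in% names(cfg$fluency_mean_by_condition)))
    stop("fluency_mean_by_condition must name all conditions")
  if (any(cfg$fluency_mean_by_condition <= 0)) stop("all fluency means must be > 0")
  if (any(cfg$cross_model_noise < 0)) stop("cross_model_noise must be >= 0")
  if (!all(c("novelty", "appropriateness", "creativity") %in% names(cfg$rater_noise)))
    stop("rater_noise must name the novelty, appropriateness and creativity scales")
  if (cfg$dirty_fraction < 0 || cfg$dirty_fraction >= 1)
    stop("dirty_fraction must be in [0, 1)")
  class(cfg) <- "synth_config"
  cfg
}

## letter-only token suffixes, so synthetic words survive the alphabetic
## cleaning rule
letter_code <- function(i, width = 3L) {
  out <- character(length(i))
  i <- i - 1L
  for (w in seq_len(width)) {
    out <- paste0(letters[i %% 26L + 1L], out)
    i <- i %/% 26L
  }
  out
}

#' Token sets of the synthetic study
#'
#' Deterministic letter-only tokens for the target words, category words, and
#' response-word pool of a synthetic configuration.
#'
#' @param config A [synth_config()].
#' @return Character vector of tokens.
#' @export
synth_target_words <- function(config)
  paste0("target", letter_code(seq_len(config$n_targets), 2L))

#' @rdname synth_target_words
#' @export
synth_category_words <- function(config)
  paste0("category", letter_code(seq_len(config$n_categories), 2L))

#' @rdname synth_target_words
#' @export
synth_response_words <- function(config)
  paste0("word", letter_code(seq_len(config$vocab_size), 3L))

#' Stop-word tokens used by the synthetic generator
#'
#' Dirty rows injected by [simulate_responses()] draw stop-word responses from
#' this list; pass it to [clean_responses()] to have them removed.
#'
#' @return Character vector of synthetic stop-word tokens.
#' @export
synth_stopwords <- function() paste0("stopword", letters[1:8])

#' Generate correlated synthetic word-embedding spaces
#'
#' Builds `n_models` embedding tables over a shared vocabulary (target words,
#' category words, and a response-word pool). Words live in one latent space
#' in which each category has a Gaussian centroid and members scatter around
#' it; each model space is an independent random rotation of the latent space
#' plus additive Gaussian noise, so pairwise semantic distances correlate
#' strongly across models (tunable via `cross_model_noise`; `0` gives
#' identical distance structure). Category words sit essentially on their
#' centroids.
#'
#' @param config A [synth_config()].
#' @return A list of `n_models` embedding matrices (rows = words, rownames =
#'   tokens), each carrying a `categories` attribute (named integer vector
#'   giving every word's generating category) and a `kind` attribute
#'   (`"target"`, `"category"`, or `"response"` per word).
#' @export
make_embedding_spaces <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  if (config$embed_dim < 2L) stop("embed_dim must be >= 2")
  if (config$vocab_size < config$n_targets) stop("vocab_size must be >= n_targets")
  set.seed(config$seed)
  d <- config$embed_dim
  targets <- synth_target_words(config)
  cats <- synth_category_words(config)
  resp <- synth_response_words(config)
  words <- c(targets, cats, resp)
  kind <- rep(c("target", "category", "response"),
              c(length(targets), length(cats), length(resp)))

  centroids <- matrix(stats::rnorm(config$n_categories * d), config$n_categories, d)
  cat_of <- c(
    rep(seq_len(config$n_categories), each = config$n_targets / config$n_categories),
    seq_len(config$n_categories),
    rep_len(seq_len(config$n_categories), config$vocab_size)
  )
  names(cat_of) <- words
  scatter <- ifelse(kind == "category", 0.05, config$within_category_sd)
  latent <- centroids[cat_of, , drop = FALSE] +
    matrix(stats::rnorm(length(words) * d), length(words), d) * scatter
  rownames(latent) <- words

  spaces <- vector("list", config$n_models)
  for (m in seq_len(config$n_models)) {
    rot <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
    emb <- latent %*% rot +
      matrix(stats::rnorm(length(words) * d), length(words), d) * config$cross_model_noise
    rownames(emb) <- words
    attr(emb, "categories") <- cat_of
    attr(emb, "kind") <- stats::setNames(kind, words)
    spaces[[m]] <- emb
  }
  names(spaces) <- sprintf("model%d", seq_len(config$n_models))
  spaces
}

## Sample one participant-condition cell from the SemExp policy.
## counts: per-target response counts; V: value matrix (targets x vocab).
sample_semexp_cell <- function(V, beta, counts, replace = FALSE) {
  vocab <- colnames(V)
  out_target <- character(0); out_resp <- character(0); out_order <- integer(0)
  for (t in which(counts > 0L)) {
    n <- counts[t]
    if (!replace) n <- min(n, ncol(V))
    p <- semexp_policy(V[t, ], beta)
    if (!replace && sum(p > 0) < n) {
      ## extreme beta underflows all but the top probabilities; draw
      ## sequentially, renormalising the softmax over the remaining words
      remaining <- seq_along(vocab)
      picks <- character(n)
      for (j in seq_len(n)) {
        pr <- semexp_policy(V[t, remaining], beta)
        pick <- sample.int(length(remaining), 1L, prob = pr)
        picks[j] <- vocab[remaining[pick]]
        remaining <- remaining[-pick]
      }
    } else {
      picks <- sample(vocab, n, replace = replace, prob = p)
    }
    out_target <- c(out_target, rep(rownames(V)[t], n))
    out_resp <- c(out_resp, picks)
    out_order <- c(out_order, seq_len(n))
  }
  data.frame(target = out_target, response = out_resp, order = out_order,
             stringsAsFactors = FALSE)
}

#' Simulate word-association responses from the SemExp policy
#'
#' For each participant x condition x target, draws a response count from a
#' Poisson distribution with mean `fluency_mean / n_targets`, then samples
#' that many responses from the SemExp softmax policy over the value row of
#' the target (values built from the consensus of the supplied embedding
#' spaces) at the condition's inverse temperature. Within a participant-target
#' pair responses are drawn without replacement by default, emulating that
#' participants do not repeat themselves.
#'
#' @param spaces List of embedding matrices from [make_embedding_spaces()].
#' @param config A [synth_config()].
#' @param betas Optional data frame (`participant`, `condition`, `beta`)
#'   overriding the per-cell generating inverse temperature; defaults to the
#'   condition values in `config`.
#' @param replace Sample responses with replacement within a target (i.e.
#'   i.i.d. draws from the policy, as in model-faithful simulations).
#' @param transform Value-matrix transform passed to [build_value_matrix()].
#' @return A response table (`participant`, `condition`, `target`, `response`,
#'   `order`) with attributes `true_beta` (the generating per-cell betas),
#'   `value_matrix`, and `n_dirty` (number of injected dirty rows).
#' @export
simulate_responses <- function(spaces, config, betas = NULL, replace = FALSE,
                               transform = "reciprocal") {
  stopifnot(inherits(config, "synth_config"))
  if (length(spaces) == 0L) stop("spaces must be a nonempty list of embedding matrices")
  set.seed(config$seed + 1L)
  targets <- synth_target_words(config)
  vocab <- synth_response_words(config)
  if (length(vocab) == 0L) stop("empty vocabulary")
  consensus <- average_embeddings(spaces)
  V <- build_value_matrix(consensus, targets, vocab, transform = transform)

  conds <- wat_conditions()
  participants <- sprintf("p%02d", seq_len(config$n_participants))
  if (is.null(betas)) {
    betas <- expand.grid(participant = participants, condition = conds,
                         stringsAsFactors = FALSE)
    betas$beta <- config$beta_by_condition[betas$condition]
  }
  if (any(betas$beta <= 0)) stop("all betas must be > 0")

  rows <- vector("list", nrow(betas))
  for (i in seq_len(nrow(betas))) {
    cond <- betas$condition[i]
    lambda <- config$fluency_mean_by_condition[[cond]] / config$n_targets
    counts <- stats::rpois(config$n_targets, lambda)
    cell <- sample_semexp_cell(V, betas$beta[i], counts, replace = replace)
    if (nrow(cell)) {
      cell$participant <- betas$participant[i]
      cell$condition <- cond
    }
    rows[[i]] <- cell
  }
  tab <- do.call(rbind, rows[vapply(rows, nrow, 1L) > 0])
  tab <- tab[, c("participant", "condition", "target", "response", "order")]

  n_dirty <- 0L
  if (config$dirty_fraction > 0) {
    n_dirty <- ceiling(config$dirty_fraction * nrow(tab))
    src <- tab[sample.int(nrow(tab), n_dirty, replace = TRUE), ]
    type <- rep_len(c("upper", "punct", "target", "stopword", "nonword"), n_dirty)
    src$response <- ifelse(type == "upper", toupper(src$response),
                    ifelse(type == "punct", paste0(src$response, "!"),
                    ifelse(type == "target", paste0(src$target, "ish"),
                    ifelse(type == "stopword",
                           sample(synth_stopwords(), n_dirty, replace = TRUE),
                           "0000"))))
    src$order <- src$order + config$fluency_mean_by_condition[src$condition]
    tab <- rbind(tab, src)
  }
  tab <- tab[order(tab$participant, tab$condition, tab$target, tab$order), ]
  tab$order <- stats::ave(seq_len(nrow(tab)), tab$participant, tab$condition,
                          tab$target, FUN = seq_along)
  rownames(tab) <- NULL
  attr(tab, "true_beta") <- betas
  attr(tab, "value_matrix") <- V
  attr(tab, "n_dirty") <- n_dirty
  tab
}

#' Retrieve the generating inverse temperatures of a simulated table
#'
#' @param responses A table produced by [simulate_responses()].
#' @return Data frame with `participant`, `condition`, and the true `beta`.
#' @export
true_betas <- function(responses) {
  gt <- attr(responses, "true_beta")
  if (is.null(gt)) stop("responses carry no ground-truth betas")
  gt
}

#' Simulate Likert ratings of target-response pairs
#'
#' Emulates a human rating study: for one target per category, every unique
#' target-response pair receives scores from `n_raters` raters on three
#' 5-point scales. The latent score is a deterministic transform of the
#' consensus semantic distance `sd` between target and response — novelty
#' increases with distance (`1 + 2 sd`), appropriateness decreases
#' (`5 - 2 sd`), creativity peaks at intermediate distance (`5 - 4|sd - 1|`) —
#' to which a rater-specific bias and per-rating Gaussian noise (sd from
#' `config$rater_noise`) are added before discretising to 1..5. The noise
#' level controls the achievable inter-rater ICC.
#'
#' @param responses Response table from [simulate_responses()].
#' @param spaces Embedding spaces used to compute semantic distances.
#' @param config A [synth_config()].
#' @return Long data frame (`rater`, `target`, `response`, `scale`, `score`)
#'   with a `latent` attribute holding the noiseless per-pair scores.
#' @export
simulate_ratings <- function(responses, spaces, config) {
  stopifnot(inherits(config, "synth_config"))
  if (nrow(responses) == 0L) stop("responses is empty")
  set.seed(config$seed + 2L)
  consensus <- average_embeddings(spaces)
  cat_of <- attr(spaces[[1]], "categories")
  targets <- synth_target_words(config)
  rated_targets <- targets[!duplicated(cat_of[targets])]

  sub <- responses[responses$target %in% rated_targets &
                     responses$response %in% rownames(consensus), ]
  pairs <- unique(sub[, c("target", "response")])
  if (nrow(pairs) == 0L) stop("no ratable target-response pairs")
  sdist <- vapply(seq_len(nrow(pairs)), function(i)
    semantic_distance(consensus[pairs$target[i], ], consensus[pairs$response[i], ]),
    numeric(1))
  latent <- data.frame(
    pairs,
    novelty = 1 + 2 * sdist,
    appropriateness = 5 - 2 * sdist,
    creativity = 5 - 4 * abs(sdist - 1)
  )

  scales <- c("novelty", "appropriateness", "creativity")
  raters <- sprintf("rater%d", seq_len(config$n_raters))
  out <- vector("list", length(scales))
  for (s in seq_along(scales)) {
    sc <- scales[s]
    ## rater-specific leniency scales with the noise level, so noiseless
    ## raters are exactly interchangeable
    bias <- stats::rnorm(config$n_raters, 0, 0.5 * config$rater_noise[[sc]])
    score <- outer(latent[[sc]], bias, "+") +
      matrix(stats::rnorm(nrow(pairs) * config$n_raters, 0, config$rater_noise[[sc]]),
             nrow(pairs), config$n_raters)
    score <- pmin(pmax(round(score), 1), 5)
    out[[s]] <- data.frame(
      rater = rep(raters, each = nrow(pairs)),
      target = rep(pairs$target, config$n_raters),
      response = rep(pairs$response, config$n_raters),
      scale = sc,
      score = as.vector(score),
      stringsAsFactors = FALSE
    )
  }
  ratings <- do.call(rbind, out)
  rownames(ratings) <- NULL
  attr(ratings, "latent") <- latent
  ratings
}
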