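# Small study configurations and hand-built fixtures shared across tests.

# a scaled-down study: 8 participants, 50-d embeddings, 300-word vocabulary
small_config <- function(...) {
  args <- list(n_participants = 8L, embed_dim = 50L, vocab_size = 300L,
               seed = 42L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(synth_config, args)
}

small_world <- function(cfg = small_config()) {
  spaces <- make_embedding_spaces(cfg)
  responses <- simulate_responses(spaces, cfg)
  list(cfg = cfg, spaces = spaces, responses = responses,
       clean = clean_responses(responses, stopwords = synth_stopwords()))
}

# symmetric weight matrix wrapped as an unfiltered semantic network
toy_network <- function(W, nodes = NULL, condition = NULL) {
  if (is.null(nodes)) nodes <- paste0("n", seq_len(nrow(W)))
  dimnames(W) <- list(nodes, nodes)
  diag(W) <- 0
  structure(list(weights = W, nodes = nodes, condition = condition,
                 filtered = FALSE),
            class = "semantic_network")
}

# dense symmetric random weights in (0, 1)
random_weights <- function(n, seed) {
  set.seed(seed)
  W <- matrix(stats::runif(n * n), n, n)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  W
}

# a raw response table with known cleaning violations
dirty_fixture <- function() {
  data.frame(
    participant = rep(c("p1", "p2"), each = 5),
    condition = "OR",
    target = "sole",
    response = c("luna", "Mare!", "sole splendente", "stopwordz", "cielo",
                 "luna", "12 34", "girasole", "cielo", "stella cadente"),
    order = rep(1:5, 2),
    stringsAsFactors = FALSE
  )
}
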