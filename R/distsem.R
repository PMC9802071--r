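#' Read word embeddings in word2vec text format
#'
#' Parses the plain-text word2vec format: a header line `<n_words> <dim>`
#' followed by one `word v1 ... v_dim` line per word.
#'
#' @param path File path.
#' @param vocab Optional character vector; only these words are returned.
#' @return Numeric matrix with one row per word (rownames = tokens).
#' @export
read_word2vec <- function(path, vocab = NULL) {
  header <- scan(path, what = integer(), n = 2L, quiet = TRUE)
  tab <- utils::read.table(path, skip = 1L, header = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  if (ncol(tab) != header[2] + 1L)
    stop("embedding dimension mismatch: header says ", header[2],
         ", rows have ", ncol(tab) - 1L)
  words <- tab[[1]]
  if (anyDuplicated(words)) stop("duplicate tokens in ", path)
  emb <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(emb) <- list(words, NULL)
  if (!all(is.finite(emb))) stop("non-finite embedding values in ", path)
  if (!is.null(vocab)) emb <- emb[rownames(emb) %in% vocab, , drop = FALSE]
  emb
}

#' Write word embeddings in word2vec text format
#'
#' @param emb Numeric matrix with token rownames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_word2vec <- function(emb, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(nrow(emb), ncol(emb)), con)
  lines <- paste(rownames(emb),
                 apply(emb, 1L, function(v)
                   paste(formatC(v, digits = 12, format = "g"), collapse = " ")))
  writeLines(lines, con)
  invisible(path)
}

#' Average several embedding model spaces into a consensus space
#'
#' Element-wise mean of each word's vectors across the model tables that
#' contain it; words present in no model are excluded and reported. Averaging
#' across models reduces the influence of any single model.
#'
#' @param spaces List of embedding matrices (token rownames), all with the
#'   same dimensionality.
#' @param vocab Optional character vector restricting (and ordering) the
#'   output rows; defaults to the union of all model vocabularies.
#' @return Consensus embedding matrix with attributes `coverage` (number of
#'   contributing models per word) and `excluded` (words found in no model).
#' @export
average_embeddings <- function(spaces, vocab = NULL) {
  if (length(spaces) == 0L) stop("need at least one embedding table")
  dims <- vapply(spaces, ncol, 1L)
  if (length(unique(dims)) != 1L)
    stop("embedding dimension mismatch across models: ",
         paste(dims, collapse = ", "))
  if (is.null(vocab))
    vocab <- Reduce(union, lapply(spaces, rownames))
  excluded <- vocab[!vocab %in% unlist(lapply(spaces, rownames))]
  keep <- setdiff(vocab, excluded)
  if (length(keep) == 0L) stop("no requested word is present in any model")
  if (length(excluded))
    warning(length(excluded), " word(s) absent from all models, excluded")
  acc <- matrix(0, length(keep), dims[1], dimnames = list(keep, NULL))
  cov <- stats::setNames(integer(length(keep)), keep)
  for (sp in spaces) {
    hit <- keep[keep %in% rownames(sp)]
    acc[hit, ] <- acc[hit, , drop = FALSE] + sp[hit, , drop = FALSE]
    cov[hit] <- cov[hit] + 1L
  }
  out <- acc / cov
  attr(out, "coverage") <- cov
  attr(out, "excluded") <- excluded
  out
}

#' Load word2vec files and average them
#'
#' Convenience wrapper: reads each file with [read_word2vec()] and combines
#' with [average_embeddings()].
#'
#' @param paths Character vector of word2vec text files.
#' @param vocab Optional vocabulary restriction.
#' @return Consensus embedding matrix (see [average_embeddings()]).
#' @export
load_and_average <- function(paths, vocab = NULL) {
  if (length(paths) == 0L) stop("need at least one embedding file")
  average_embeddings(lapply(paths, read_word2vec, vocab = vocab), vocab = vocab)
}

#' Semantic distance between two word vectors
#'
#' One minus the cosine similarity; ranges over \[0, 2\] (0 identical
#' direction, 1 orthogonal, 2 opposite).
#'
#' @param x,y Numeric vectors of equal length, both nonzero.
#' @return The semantic distance.
#' @export
semantic_distance <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("semantic distance undefined for a zero vector")
  1 - sum(x * y) / (nx * ny)
}

## rows x cols matrix of semantic distances between two sets of embeddings
semantic_distance_matrix <- function(emb, rows, cols) {
  miss <- setdiff(c(rows, cols), rownames(emb))
  if (length(miss))
    stop("word(s) missing from the embedding: ",
         paste(utils::head(miss, 5L), collapse = ", "),
         if (length(miss) > 5L) ", ..." else "")
  A <- emb[rows, , drop = FALSE]
  B <- emb[cols, , drop = FALSE]
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  if (any(na == 0) || any(nb == 0))
    stop("semantic distance undefined for a zero vector")
  1 - (A %*% t(B)) / outer(na, nb)
}

#' Assign a word to its nearest semantic category
#'
#' Computes the semantic distance between `x` and every category vector and
#' returns the index of the minimum. Ties are broken by the lowest index, with
#' a warning.
#'
#' @param x A word vector.
#' @param category_vectors Matrix of category word vectors (one per row).
#' @return Integer category index.
#' @export
assign_category <- function(x, category_vectors) {
  if (is.null(dim(category_vectors)) || nrow(category_vectors) == 0L)
    stop("empty category set")
  z <- apply(category_vectors, 1L, semantic_distance, y = x)
  hits <- which(z == min(z))
  if (length(hits) > 1L)
    warning("tie between categories ", paste(hits, collapse = ", "),
            "; lowest index returned")
  hits[1]
}

#' Category switching indicator
#'
#' 1 minus the Kronecker delta of the two category indices: 0 when target and
#' response map to the same category, 1 otherwise.
#'
#' @param c_t,c_r Integer category indices (vectorised).
#' @return Integer vector of 0/1 switch indicators.
#' @export
category_switch <- function(c_t, c_r) as.integer(c_t != c_r)

#' Per-response semantic distance and category switching records
#'
#' For every response row, computes the consensus-embedding semantic distance
#' between target and response, assigns both words to their nearest category,
#' and derives the switch indicator. Responses without a consensus embedding
#' are dropped with a message (their count is recorded in the
#' `n_unembedded` attribute).
#'
#' @param clean Cleaned response table.
#' @param emb Consensus embedding matrix covering targets, responses, and
#'   category words.
#' @param categories Character vector of category word tokens (rows of `emb`).
#' @return Data frame `participant`, `condition`, `target`, `response`,
#'   `order`, `sd`, `target_category`, `response_category`, `cs`.
#' @export
distance_records <- function(clean, emb, categories) {
  if (!all(categories %in% rownames(emb)))
    stop("category word(s) missing from the embedding")
  embedded <- clean$response %in% rownames(emb) & clean$target %in% rownames(emb)
  n_out <- sum(!embedded)
  if (n_out) message(n_out, " response row(s) without consensus embedding dropped")
  x <- clean[embedded, ]
  targets <- sort(unique(x$target))
  resps <- sort(unique(x$response))
  D <- semantic_distance_matrix(emb, targets, resps)
  K <- semantic_distance_matrix(emb, c(targets, resps), categories)
  nearest <- apply(K, 1L, which.min)
  x$sd <- D[cbind(match(x$target, targets), match(x$response, resps))]
  x$target_category <- unname(nearest[x$target])
  x$response_category <- unname(nearest[x$response])
  x$cs <- category_switch(x$target_category, x$response_category)
  rownames(x) <- NULL
  attr(x, "n_unembedded") <- n_out
  x
}

#' Participant-level summaries of distance and switching
#'
#' Averages semantic distance and category switching over all of a
#' participant's responses in each condition; optionally restricted to the
#' first two responses per target.
#'
#' @param records Output of [distance_records()].
#' @param first_two Restrict to the first-two-responses subset.
#' @return Data frame `participant`, `condition`, `mean_sd`, `mean_cs`, `n`.
#'   Cells with no responses are absent (and noted in a message).
#' @export
participant_summaries <- function(records, first_two = FALSE) {
  if (nrow(records) == 0L) stop("no distance records")
  x <- if (first_two) first_two_subset(records) else records
  key <- interaction(x$participant, x$condition, drop = TRUE)
  out <- data.frame(
    participant = tapply(x$participant, key, `[`, 1L),
    condition = tapply(x$condition, key, `[`, 1L),
    mean_sd = as.numeric(tapply(x$sd, key, mean)),
    mean_cs = as.numeric(tapply(x$cs, key, mean)),
    n = as.integer(tapply(x$sd, key, length))
  )
  full <- nlevels(factor(records$participant)) * length(unique(records$condition))
  if (nrow(out) < full)
    message(full - nrow(out), " participant-condition cell(s) have no responses")
  rownames(out) <- NULL
  out[order(out$condition, out$participant), ]
}

#' Pairwise consistency of the per-model distance structures
#'
#' Pearson correlations between the vectorised target-response semantic
#' distance matrices computed separately in each model space, over the
#' target-response word pairs covered by both models of a pair. High
#' correlations justify averaging the models into a consensus space.
#'
#' @param spaces List of >= 2 embedding matrices.
#' @param targets,vocab Word sets defining the distance matrices.
#' @return Symmetric matrix of pairwise Pearson r (diagonal 1).
#' @export
model_space_correlation <- function(spaces, targets, vocab) {
  if (length(spaces) < 2L) stop("need at least two model spaces")
  mats <- lapply(spaces, function(sp) {
    tg <- intersect(targets, rownames(sp))
    vc <- intersect(vocab, rownames(sp))
    D <- matrix(NA_real_, length(targets), length(vocab),
                dimnames = list(targets, vocab))
    D[tg, vc] <- semantic_distance_matrix(sp, tg, vc)
    D
  })
  k <- length(mats)
  R <- diag(1, k)
  dimnames(R) <- list(names(spaces), names(spaces))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    a <- as.vector(mats[[i]]); b <- as.vector(mats[[j]])
    ok <- is.finite(a) & is.finite(b)
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0)
      stop("constant distance vector; correlation undefined")
    R[i, j] <- R[j, i] <- stats::cor(a[ok], b[ok])
  }
  R
}
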