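#' Clean raw word-association responses
#'
#' Applies the standard cleaning rules for word association data: responses
#' are lowercased and trimmed; characters other than letters, hyphens, and
#' internal spaces are stripped; multi-word answers are joined into hyphenated
#' compounds; empty responses, stop-words, and responses equal to or
#' containing their target word are dropped. A user-supplied map handles
#' singularisation/spelling corrections (identity by default). Optionally,
#' idiosyncratic responses — strings produced by exactly one participant
#' within a condition — are removed. Surviving rows are re-ranked so that
#' `order` stays a dense 1-based rank within participant x condition x target.
#'
#' @param raw Data frame with columns `participant`, `condition`, `target`,
#'   `response`, `order`.
#' @param stopwords Character vector of stop-word tokens to drop.
#' @param lemma_map Named character vector mapping response forms to
#'   replacement forms (e.g. plural to singular); applied after lowercasing.
#' @param drop_idiosyncratic Remove responses given by exactly one participant
#'   within a condition. The group network analyses use `TRUE` (idiosyncratic
#'   answers carry no overlap signal); the distributional and SemExp analyses
#'   use `FALSE` so that the vocabulary covers all unique sample responses.
#' @return Cleaned response table; attribute `cleaning_log` counts the rows
#'   removed by each rule.
#' @export
clean_responses <- function(raw, stopwords = character(), lemma_map = NULL,
                            drop_idiosyncratic = FALSE) {
  required <- c("participant", "condition", "target", "response", "order")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  bad <- setdiff(unique(raw$condition), wat_conditions())
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))

  x <- raw
  log <- c(input = nrow(x), empty = 0L, stopword = 0L,
           target_match = 0L, idiosyncratic = 0L)
  x$target <- tolower(trimws(as.character(x$target)))
  resp <- tolower(trimws(as.character(x$response)))
  resp <- gsub("[^[:alpha:] -]", "", resp)
  resp <- gsub("[ ]+", " ", trimws(resp))
  resp <- gsub(" ", "-", resp)
  x$response <- resp

  keep <- nzchar(x$response)
  log["empty"] <- sum(!keep)
  x <- x[keep, ]

  if (length(stopwords)) {
    keep <- !(x$response %in% tolower(stopwords))
    log["stopword"] <- sum(!keep)
    x <- x[keep, ]
  }
  if (!is.null(lemma_map)) {
    hit <- x$response %in% names(lemma_map)
    x$response[hit] <- unname(lemma_map[x$response[hit]])
  }
  ## substring match on the lowercased forms
  if (nrow(x)) {
    keep <- !mapply(grepl, x$target, x$response, MoreArgs = list(fixed = TRUE))
    log["target_match"] <- sum(!keep)
    x <- x[keep, ]
  }

  if (drop_idiosyncratic && nrow(x)) {
    key <- paste(x$condition, x$response, sep = "\r")
    n_part <- tapply(x$participant, key, function(p) length(unique(p)))
    keep <- n_part[key] > 1L
    log["idiosyncratic"] <- sum(!keep)
    x <- x[keep, ]
  }

  if (nrow(x)) {
    x <- x[order(x$participant, x$condition, x$target, x$order), ]
    x$order <- stats::ave(seq_len(nrow(x)), x$participant, x$condition,
                          x$target, FUN = seq_along)
  }
  rownames(x) <- NULL
  attr(x, "cleaning_log") <- log
  x
}

#' Fluency statistics of a cleaned response table
#'
#' Counts responses per participant x condition and summarises each condition
#' with its total, mean, and standard deviation across participants.
#'
#' @param clean Cleaned response table.
#' @return List of class `fluency_table` with elements `per_participant`
#'   (`participant`, `condition`, `n`) and `summary` (`condition`, `total`,
#'   `mean`, `sd`).
#' @export
fluency <- function(clean) {
  conds <- wat_conditions()
  if (nrow(clean) == 0L) {
    per <- data.frame(participant = character(0), condition = character(0),
                      n = integer(0))
    summ <- data.frame(condition = conds, total = 0L, mean = 0, sd = NA_real_)
  } else {
    participants <- sort(unique(clean$participant))
    per <- expand.grid(participant = participants, condition = conds,
                       stringsAsFactors = FALSE)
    key <- paste(clean$participant, clean$condition)
    cnt <- table(key)
    per$n <- as.integer(cnt[paste(per$participant, per$condition)])
    per$n[is.na(per$n)] <- 0L
    summ <- do.call(rbind, lapply(conds, function(cd) {
      n <- per$n[per$condition == cd]
      data.frame(condition = cd, total = sum(n), mean = mean(n), sd = stats::sd(n))
    }))
  }
  structure(list(per_participant = per, summary = summ), class = "fluency_table")
}

#' @export
print.fluency_table <- function(x, ...) {
  cat("Fluency by condition:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' First-two-responses control subset
#'
#' Keeps, for every participant x condition x target cell, only the first two
#' responses (by rank). Used to control the fluency confound: conditions that
#' elicit more responses would otherwise contribute more association overlap.
#'
#' @param clean Cleaned response table with `order` ranks.
#' @return The subset table, re-ranked.
#' @export
first_two_subset <- function(clean) {
  if (nrow(clean) == 0L) return(clean)
  x <- clean[order(clean$participant, clean$condition, clean$target, clean$order), ]
  rank <- stats::ave(seq_len(nrow(x)), x$participant, x$condition, x$target,
                     FUN = seq_along)
  x <- x[rank <= 2L, ]
  x$order <- stats::ave(seq_len(nrow(x)), x$participant, x$condition, x$target,
                        FUN = seq_along)
  rownames(x) <- NULL
  x
}
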