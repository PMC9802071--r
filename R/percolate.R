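#' Normalise network weights by relative fluency
#'
#' Conditions that elicit more responses inflate association overlap and hence
#' link weights. Taking the lowest-fluency condition (CR by default) as
#' reference, every other condition's weights are divided by the ratio of its
#' mean fluency to the reference mean. With the study's printed means
#' (172.52 RA, 130.96 OR, 78.45 CR) the factors are 2.20 for RA and 1.67 for
#' OR to two decimals.
#'
#' @param nets Named list of unfiltered weighted `semantic_network`s, one per
#'   condition.
#' @param fluency_table A [fluency()] result for the same data.
#' @param reference Reference condition (factor 1).
#' @return The list of networks with rescaled weights; each carries a
#'   `fluency_factor` attribute.
#' @export
normalize_fluency <- function(nets, fluency_table, reference = "CR") {
  summ <- fluency_table$summary
  ref_mean <- summ$mean[summ$condition == reference]
  if (length(ref_mean) != 1L || is.na(ref_mean) || ref_mean == 0)
    stop("reference condition '", reference, "' has zero or missing mean fluency")
  for (cond in names(nets)) {
    f <- summ$mean[summ$condition == cond] / ref_mean
    nets[[cond]]$weights <- nets[[cond]]$weights / f
    attr(nets[[cond]], "fluency_factor") <- f
  }
  nets
}

## union-find with path halving; returns LCCS for each descending threshold
lccs_trace <- function(edges, weights, n, thresholds_desc) {
  parent <- seq_len(n)
  size <- rep(1L, n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(weights, decreasing = TRUE)
  edges <- edges[ord, , drop = FALSE]
  weights <- weights[ord]
  lccs <- integer(length(thresholds_desc))
  biggest <- 1L
  e <- 1L
  for (k in seq_along(thresholds_desc)) {
    th <- thresholds_desc[k]
    while (e <= length(weights) && weights[e] >= th) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a != b) {
        if (size[a] < size[b]) { tmp <- a; a <- b; b <- tmp }
        parent[b] <- a
        size[a] <- size[a] + size[b]
        if (size[a] > biggest) biggest <- size[a]
      }
      e <- e + 1L
    }
    lccs[k] <- biggest
  }
  lccs
}

#' Edge-threshold percolation curve and robustness integral
#'
#' Attacks a weighted network by removing, at each percolation step, all edges
#' whose weight falls below the current threshold (edges equal to the
#' threshold survive). The threshold grid is the ascending set of unique edge
#' weights — the largest connected component size (LCCS) can only change
#' there, so the grid is exact — starting at the minimum weight. The curve
#' stops at the first threshold where the LCCS drops below `min_lccs` (3 by
#' default). The percolation integral `phi` is the area under the LCCS curve,
#' a left Riemann sum `sum_i LCCS(th_i) * (th_{i+1} - th_i)` over the steps
#' before termination; `method = "weighted"` instead returns the sum of LCCS
#' values weighted by their threshold.
#'
#' @param net A weighted `semantic_network` with at least 3 nodes.
#' @param min_lccs Component size at which the percolation process ends.
#' @return Object of class `percolation_curve`: data frame
#'   (`threshold`, `lccs`) with attribute `phi`.
#' @export
percolation_curve <- function(net, min_lccs = 3L) {
  W <- net$weights
  n <- nrow(W)
  if (n < 3L) stop("percolation needs at least 3 nodes")
  ut <- upper.tri(W)
  pos <- which(ut & W > 0, arr.ind = TRUE)
  weights <- W[pos]
  thresholds <- sort(unique(weights))
  if (length(thresholds) == 1L)
    message("all edge weights equal; percolation curve has a single step")
  lccs <- rev(lccs_trace(pos, weights, n, rev(thresholds)))
  stop_at <- which(lccs < min_lccs)
  keep <- if (length(stop_at)) seq_len(stop_at[1]) else seq_along(thresholds)
  curve <- data.frame(threshold = thresholds[keep], lccs = lccs[keep])
  structure(curve, class = c("percolation_curve", "data.frame"),
            phi = percolation_integral(curve, min_lccs = min_lccs))
}

## area under the LCCS curve (left Riemann sum on the step grid)
percolation_integral <- function(curve, method = c("auc", "weighted"),
                                 min_lccs = 3L) {
  method <- match.arg(method)
  alive <- curve$lccs >= min_lccs
  if (method == "weighted") return(sum(curve$lccs[alive] * curve$threshold[alive]))
  if (sum(alive) < 2L && all(alive)) return(0)
  dx <- diff(curve$threshold)
  sum(curve$lccs[-nrow(curve)][alive[-nrow(curve)]] * dx[alive[-nrow(curve)]])
}

#' Percolation integral of a network
#'
#' @param net A weighted `semantic_network`, or a `percolation_curve`.
#' @param method `"auc"` (area under the LCCS curve, default) or `"weighted"`
#'   (sum of LCCS values weighted by their threshold).
#' @param min_lccs Component size at which percolation ends.
#' @return The integral `phi`.
#' @export
phi <- function(net, method = c("auc", "weighted"), min_lccs = 3L) {
  method <- match.arg(method)
  curve <- if (inherits(net, "percolation_curve")) net else
    percolation_curve(net, min_lccs = min_lccs)
  if (method == "auc") attr(curve, "phi") else
    percolation_integral(curve, method = method, min_lccs = min_lccs)
}

#' Resampling and perturbation distributions of the percolation integral
#'
#' Four procedures probe the stability of `phi`:
#' * `LONO` — drop each node, recompute `phi` (one sample per node);
#' * `LOSO` — rebuild the condition network per left-out participant
#'   (requires `responses`) and recompute `phi`;
#' * `LS` — link shuffling: per iteration, repeatedly pick two random edges
#'   and swap their weights, `passes` times per link (10 passes over a
#'   114-edge TMFG graph is ~1,140 swaps), then recompute `phi`; the edge
#'   weight multiset is preserved;
#' * `NOISE` — per iteration add Gaussian noise (mean 0, sd drawn uniformly
#'   from `sigma_range`) to every weight, clip at 0, recompute `phi`.
#'
#' @param net Weighted `semantic_network` (ignored for `LOSO`).
#' @param mode One of `"LONO"`, `"LOSO"`, `"LS"`, `"NOISE"`.
#' @param n_iter Iterations for `LS` and `NOISE`.
#' @param seed Seed for the random procedures.
#' @param responses Cleaned response table (for `LOSO`).
#' @param condition Condition label (for `LOSO`).
#' @param targets Optional fixed target set (for `LOSO`).
#' @param fluency_table Optional [fluency()] result; if supplied, `LOSO`
#'   networks are fluency-normalised with factors recomputed on the reduced
#'   sample.
#' @param reference Reference condition for `LOSO` normalisation.
#' @param passes Link-shuffling passes over the edge set per iteration.
#' @param sigma_range Noise sd range for `NOISE`.
#' @param min_lccs Passed to [percolation_curve()].
#' @return Numeric vector of `phi` samples (named for LONO/LOSO).
#' @export
percolation_significance <- function(net = NULL,
                                     mode = c("LONO", "LOSO", "LS", "NOISE"),
                                     n_iter = 500L, seed = NULL,
                                     responses = NULL, condition = NULL,
                                     targets = NULL, fluency_table = NULL,
                                     reference = "CR",
                                     passes = 10L,
                                     sigma_range = c(1e-4, 1e-3),
                                     min_lccs = 3L) {
  if (!is.character(mode) || !all(mode %in% c("LONO", "LOSO", "LS", "NOISE")))
    stop("unknown mode; use LONO, LOSO, LS or NOISE")
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)

  if (mode == "LONO") {
    nodes <- net$nodes
    out <- vapply(seq_along(nodes), function(i) {
      sub <- net
      sub$weights <- net$weights[-i, -i, drop = FALSE]
      sub$nodes <- nodes[-i]
      phi(sub, min_lccs = min_lccs)
    }, numeric(1))
    names(out) <- nodes
    return(out)
  }

  if (mode == "LOSO") {
    if (is.null(responses) || is.null(condition))
      stop("LOSO requires `responses` and `condition`")
    participants <- sort(unique(responses$participant))
    out <- vapply(participants, function(p) {
      sub <- responses[responses$participant != p, ]
      nets <- list(cosine_network(
        build_count_matrix(sub, condition, targets = targets), condition))
      names(nets) <- condition
      if (!is.null(fluency_table))
        nets <- normalize_fluency(nets, fluency(sub), reference = reference)
      phi(nets[[condition]], min_lccs = min_lccs)
    }, numeric(1))
    names(out) <- participants
    return(out)
  }

  W <- net$weights
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  w0 <- W[ut]
  out <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    sub <- net
    if (mode == "LS") {
      w <- w0
      n_swap <- passes * length(w)
      a <- sample.int(length(w), n_swap, replace = TRUE)
      b <- sample.int(length(w), n_swap, replace = TRUE)
      for (s in seq_len(n_swap)) {
        tmp <- w[a[s]]; w[a[s]] <- w[b[s]]; w[b[s]] <- tmp
      }
    } else {
      sigma <- stats::runif(1, sigma_range[1], sigma_range[2])
      w <- pmax(w0 + stats::rnorm(length(w0), 0, sigma), 0)
    }
    Wp <- W * 0
    Wp[ut] <- w
    Wp[ut[, 2:1]] <- w
    sub$weights <- Wp
    out[it] <- phi(sub, min_lccs = min_lccs)
  }
  out
}
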