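#' Configuration of a full pipeline run
#'
#' Collects every knob of [run_all()]. With `synth = TRUE` (default) all
#' inputs are generated by the synthetic module; otherwise supply `responses`
#' (a raw response table), `spaces` (a list of embedding matrices), and
#' `category_words`.
#'
#' @param synth Generate inputs with the synthetic module.
#' @param synth_cfg A [synth_config()].
#' @param responses,spaces,category_words User-supplied inputs when
#'   `synth = FALSE`.
#' @param stopwords Stop-word list for cleaning.
#' @param first_two Also compute the first-two-responses control analyses.
#' @param n_random Erdos-Renyi replicates for small-worldness.
#' @param run_lono,run_loso Run the leave-one-out resampling analyses
#'   (topology and percolation).
#' @param perc_modes Perturbation modes for percolation significance
#'   (subset of `"LS"`, `"NOISE"`).
#' @param perc_n_iter Iterations for the LS and NOISE procedures.
#' @param stat_n_iter Permutation iterations for the paired tests.
#' @param semexp_ctrl A [semexp_control()].
#' @param value_transform Transform for [build_value_matrix()].
#' @param ratings Simulate and analyse rater scores (synthetic mode).
#' @param seed Master seed; all stage seeds derive from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(synth = TRUE, synth_cfg = synth_config(),
                       responses = NULL, spaces = NULL, category_words = NULL,
                       stopwords = synth_stopwords(), first_two = FALSE,
                       n_random = 100L, run_lono = FALSE, run_loso = FALSE,
                       perc_modes = c("LS", "NOISE"), perc_n_iter = 100L,
                       stat_n_iter = 10000L, semexp_ctrl = semexp_control(),
                       value_transform = "reciprocal", ratings = TRUE,
                       seed = 1L) {
  structure(list(synth = synth, synth_cfg = synth_cfg, responses = responses,
                 spaces = spaces, category_words = category_words,
                 stopwords = stopwords, first_two = first_two,
                 n_random = as.integer(n_random), run_lono = run_lono,
                 run_loso = run_loso, perc_modes = perc_modes,
                 perc_n_iter = as.integer(perc_n_iter),
                 stat_n_iter = as.integer(stat_n_iter),
                 semexp_ctrl = semexp_ctrl, value_transform = value_transform,
                 ratings = ratings, seed = as.integer(seed)),
            class = "run_config")
}

## all three pairwise condition contrasts on a per-participant summary column
pairwise_condition_tests <- function(df, col, n_iter, seed) {
  pairs <- list(c("CR", "OR"), c("OR", "RA"), c("CR", "RA"))
  out <- vector("list", length(pairs))
  for (i in seq_along(pairs)) {
    p1 <- pairs[[i]][1]; p2 <- pairs[[i]][2]
    a <- df[df$condition == p1, ]
    b <- df[df$condition == p2, ]
    common <- intersect(a$participant, b$participant)
    tt <- paired_perm_ttest(a[[col]][match(common, a$participant)],
                            b[[col]][match(common, b$participant)],
                            n_iter = n_iter, seed = seed + i)
    out[[i]] <- data.frame(comparison = paste(p1, "vs", p2), t = tt$t, p = tt$p,
                           d = tt$d, d_lo = tt$d_ci[1], d_hi = tt$d_ci[2],
                           alpha_corrected = tt$alpha_corrected)
  }
  do.call(rbind, out)
}

#' Run the complete word-association analysis pipeline
#'
#' Executes, on synthetic or user data: preprocessing and fluency statistics;
#' per-condition semantic networks (count matrix, cosine similarity, TMFG)
#' with topological quantifiers and optional LONO/LOSO resampling;
#' fluency-normalised percolation with robustness integrals and optional
#' perturbation analyses; distributional semantic distance and category
#' switching with participant summaries; SemExp model fitting with model
#' selection; rater-agreement ICCs; and paired permutation tests on every
#' participant-level summary. All randomness derives from `config$seed`, so
#' identical configurations give identical reports.
#'
#' @param config A [run_config()].
#' @return List of class `wat_run` with blocks `inputs`, `fluency`,
#'   `networks`, `percolation`, `distsem`, `semexp`, `ratings`, and
#'   `manifest`.
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  scfg <- config$synth_cfg
  if (config$synth) {
    spaces <- make_embedding_spaces(scfg)
    raw <- simulate_responses(spaces, scfg)
    category_words <- synth_category_words(scfg)
    ratings <- if (config$ratings) simulate_ratings(raw, spaces, scfg) else NULL
  } else {
    if (is.null(config$responses) || is.null(config$spaces) ||
        is.null(config$category_words))
      stop("non-synthetic runs need responses, spaces, and category_words")
    spaces <- config$spaces
    raw <- config$responses
    category_words <- config$category_words
    ratings <- NULL
  }

  ## networks drop idiosyncratic responses; the distributional and SemExp
  ## vocabulary keeps all unique sample responses
  net_clean <- clean_responses(raw, stopwords = config$stopwords,
                               drop_idiosyncratic = TRUE)
  ds_clean <- clean_responses(raw, stopwords = config$stopwords,
                              drop_idiosyncratic = FALSE)
  if (nrow(net_clean) == 0L) stop("preprocess left no usable responses")
  flu <- fluency(ds_clean)
  flu_tests <- pairwise_condition_tests(
    stats::setNames(flu$per_participant, c("participant", "condition", "value")),
    "value", config$stat_n_iter, config$seed + 100L)

  conds <- intersect(wat_conditions(), unique(net_clean$condition))
  targets <- sort(unique(net_clean$target))
  networks <- list()
  topo <- list(); lono <- list(); loso <- list()
  unfiltered <- list()
  for (cd in conds) {
    un <- cosine_network(build_count_matrix(net_clean, cd, targets = targets), cd)
    fl <- tmfg_filter(un)
    unfiltered[[cd]] <- un
    networks[[cd]] <- fl
    topo[[cd]] <- topology(fl, n_random = config$n_random, seed = config$seed + 200L)
    if (config$run_lono)
      lono[[cd]] <- lono_topology(fl, n_random = config$n_random,
                                  seed = config$seed + 201L)
    if (config$run_loso)
      loso[[cd]] <- loso_topology(net_clean, cd, targets = targets,
                                  n_random = config$n_random,
                                  seed = config$seed + 202L)
  }
  topo_tab <- do.call(rbind, topo)
  topo_tab <- cbind(condition = conds, topo_tab)

  norm_nets <- normalize_fluency(unfiltered, flu, reference = "CR")
  curves <- lapply(norm_nets, percolation_curve)
  phis <- vapply(curves, function(cv) attr(cv, "phi"), numeric(1))
  perc_sig <- list()
  for (md in config$perc_modes)
    perc_sig[[md]] <- lapply(norm_nets, percolation_significance,
                             mode = md, n_iter = config$perc_n_iter,
                             seed = config$seed + 300L)
  if (config$run_lono)
    perc_sig[["LONO"]] <- lapply(norm_nets, percolation_significance, mode = "LONO")
  if (config$run_loso)
    perc_sig[["LOSO"]] <- stats::setNames(lapply(conds, function(cd)
      percolation_significance(mode = "LOSO", responses = net_clean,
                               condition = cd, targets = targets,
                               fluency_table = flu)), conds)

  consensus <- average_embeddings(spaces)
  records <- distance_records(ds_clean, consensus, category_words)
  summaries <- participant_summaries(records)
  sd_tests <- pairwise_condition_tests(summaries, "mean_sd",
                                       config$stat_n_iter, config$seed + 400L)
  cs_tests <- pairwise_condition_tests(summaries, "mean_cs",
                                       config$stat_n_iter, config$seed + 401L)
  model_r <- model_space_correlation(spaces, targets,
                                     sort(unique(records$response)))
  first_two <- NULL
  if (config$first_two)
    first_two <- participant_summaries(records, first_two = TRUE)

  vocab <- sort(unique(ds_clean$response[ds_clean$response %in% rownames(consensus)]))
  values <- build_value_matrix(consensus, targets, vocab,
                               transform = config$value_transform)
  selection <- model_selection(values, records, control = config$semexp_ctrl,
                               seed = config$seed + 500L)
  beta_tests <- pairwise_condition_tests(
    stats::setNames(selection[, c("participant", "condition", "beta")],
                    c("participant", "condition", "value")),
    "value", config$stat_n_iter, config$seed + 501L)

  rating_block <- NULL
  if (!is.null(ratings)) {
    icc <- icc_two_way_fixed(ratings)
    joined <- merge(ratings, unique(ds_clean[, c("condition", "target", "response")]))
    by_cond <- stats::aggregate(score ~ scale + condition, joined, mean)
    rating_block <- list(icc = icc, mean_by_condition = by_cond, table = ratings)
  }

  structure(list(
    inputs = list(raw = raw, net_clean = net_clean, ds_clean = ds_clean,
                  spaces = spaces, category_words = category_words),
    fluency = list(table = flu, tests = flu_tests),
    networks = list(filtered = networks, topology = topo_tab,
                    lono = lono, loso = loso),
    percolation = list(networks = norm_nets, curves = curves, phi = phis,
                       significance = perc_sig),
    distsem = list(records = records, summaries = summaries,
                   sd_tests = sd_tests, cs_tests = cs_tests,
                   model_correlation = model_r, first_two = first_two),
    semexp = list(values = values, selection = selection, beta_tests = beta_tests),
    ratings = rating_block,
    manifest = list(seed = config$seed, config = config,
                    package_version = as.character(utils::packageVersion("semexplore")))
  ), class = "wat_run")
}

#' @export
print.wat_run <- function(x, ...) {
  cat("Word association pipeline run\n")
  cat("  responses:", nrow(x$inputs$ds_clean), "cleaned rows,",
      length(unique(x$inputs$ds_clean$participant)), "participants\n")
  cat("  fluency means:",
      paste(sprintf("%s %.1f", x$fluency$table$summary$condition,
                    x$fluency$table$summary$mean), collapse = ", "), "\n")
  cat("  topology:\n")
  print(x$networks$topology, row.names = FALSE)
  cat("  percolation phi:",
      paste(sprintf("%s %.3f", names(x$percolation$phi), x$percolation$phi),
            collapse = ", "), "\n")
  betas <- tapply(x$semexp$selection$beta, x$semexp$selection$condition, mean)
  cat("  mean fitted beta:",
      paste(sprintf("%s %.2f", names(betas), betas), collapse = ", "), "\n")
  if (!is.null(x$ratings))
    cat("  rater ICC:",
        paste(sprintf("%s %.2f", names(x$ratings$icc), x$ratings$icc),
              collapse = ", "), "\n")
  invisible(x)
}

#' Write a pipeline run to disk
#'
#' Serialises the main tables of a [run_all()] report as CSV files, networks
#' as GraphML, and a manifest (seed, version, fluency factors) as JSON.
#'
#' @param run A `wat_run` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(run$fluency$table$summary, "fluency_summary.csv")
  wr(run$fluency$tests, "fluency_tests.csv")
  wr(run$networks$topology, "topology.csv")
  for (cd in names(run$networks$filtered))
    write_network(run$networks$filtered[[cd]],
                  file.path(dir, paste0("network_", cd, ".graphml")))
  for (cd in names(run$percolation$curves))
    wr(as.data.frame(run$percolation$curves[[cd]]),
       paste0("percolation_curve_", cd, ".csv"))
  wr(data.frame(condition = names(run$percolation$phi),
                phi = unname(run$percolation$phi)), "percolation_phi.csv")
  wr(run$distsem$summaries, "distsem_summaries.csv")
  wr(run$distsem$sd_tests, "sd_tests.csv")
  wr(run$distsem$cs_tests, "cs_tests.csv")
  wr(run$semexp$selection, "semexp_selection.csv")
  wr(run$semexp$beta_tests, "beta_tests.csv")
  if (!is.null(run$ratings)) {
    wr(data.frame(scale = names(run$ratings$icc), icc = unname(run$ratings$icc)),
       "rating_icc.csv")
    wr(run$ratings$mean_by_condition, "rating_means.csv")
  }
  manifest <- list(seed = run$manifest$seed,
                   package_version = run$manifest$package_version,
                   fluency_factors = lapply(run$percolation$networks,
                                            function(nt) attr(nt, "fluency_factor")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
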