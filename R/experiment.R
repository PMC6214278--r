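#' Run the full sampling-evaluation experiment
#'
#' Executes the four-step procedure that scores a sampling algorithm as
#' an influential-spreader identifier:
#'
#' 1. **Ground-truth ranking** — simulate the epidemic model on the
#'    original graph and rank nodes by spreading efficiency (SIR) or
#'    persistence (SIS).
#' 2. **Samples ranking** — draw `n_samples` samples with the chosen
#'    sampler, compute each centrality in the sample subgraph structure
#'    and rank the discovered nodes.
#' 3. **Graph ranking** — the full-information baseline: the same
#'    centralities computed on the original graph.
#' 4. **Evaluation** — imprecision (SIR) or persistence-distance (SIS),
#'    OSim and top-k Kendall tau for every top-k fraction, for both the
#'    sample-based and the full-information rankings; sample statistics
#'    are averaged over the samples.
#'
#' Top-k sizes are always relative to the original graph's |N|. A sample
#' that discovered fewer than k nodes yields missing statistics for that
#' (sample, top-k) cell; missing cells are excluded from the means and
#' counted in the summary.
#'
#' @param graph An undirected igraph graph.
#' @param sampler Sampling algorithm: `"maxrd"`, `"ff"`, `"mhrw"` or
#'   `"mh"`.
#' @param sampler_config A [sampler_config()]; its `rng_seed` seeds
#'   sample 1, subsequent samples use derived seeds.
#' @param ground_truth A precomputed `ground_truth` object (reusable
#'   across samplers), or `NULL` to compute one from `epidemic_config`.
#' @param epidemic_config An [sir_config()] or [sis_config()]; required
#'   when `ground_truth` is `NULL`.
#' @param measures Centralities to evaluate: subset of `"degree"`,
#'   `"kcore"`, `"betweenness"`.
#' @param top_k_fractions Top-k grid (reference setup: 1%...10%).
#' @param n_samples Number of samples (reference setup: 100).
#' @param rng_seed Seed for ranking tie-breaks.
#' @return An object of class `evaluation_report`: list with `cells`
#'   (long data frame: sample, source, measure, top_k, statistic,
#'   value), `summary` (mean, sd and missing count per source x measure
#'   x top_k x statistic) and `meta`.
#' @export
run_experiment <- function(graph,
                           sampler = c("maxrd", "ff", "mhrw", "mh"),
                           sampler_config = maxrd::sampler_config(),
                           ground_truth = NULL,
                           epidemic_config = NULL,
                           measures = c("degree", "kcore"),
                           top_k_fractions = seq(0.01, 0.10, by = 0.01),
                           n_samples = 100L,
                           rng_seed = 1L) {
  sampler <- match.arg(sampler)
  graph <- as_maxrd_graph(graph)
  n <- igraph::vcount(graph)
  if (is.null(ground_truth)) {
    if (is.null(epidemic_config)) {
      stop("give either a precomputed 'ground_truth' or an ",
           "'epidemic_config'", call. = FALSE)
    }
    ground_truth <- if (inherits(epidemic_config, "sir_config")) {
      sir_ground_truth(graph, epidemic_config)
    } else {
      sis_ground_truth(graph, epidemic_config)
    }
  }
  dist_stat <- if (ground_truth$kind == "sir_efficiency") "imprecision"
               else "persistence_distance"
  dist_fun <- if (dist_stat == "imprecision") imprecision
              else persistence_distance
  gt_sorted <- sort(ground_truth$values, decreasing = TRUE)

  sample_fun <- sampler_function(sampler)
  rankings <- list()   # [[source]][[measure]] -> ranked_list
  for (si in seq_len(n_samples)) {
    cfg <- sampler_config
    cfg$rng_seed <- if (si == 1L) sampler_config$rng_seed
                    else mix_seed(sampler_config$rng_seed, si)
    sub <- sample_subgraph(sample_fun(graph, cfg))
    rankings[[paste0("sample", si)]] <- lapply(
      stats::setNames(measures, measures),
      function(m) rank_nodes(centrality_function(m)(sub),
                             rng_seed = mix_seed(rng_seed, si, match(m, measures)))
    )
  }
  rankings[["graph"]] <- lapply(
    stats::setNames(measures, measures),
    function(m) rank_nodes(centrality_function(m)(graph),
                           rng_seed = mix_seed(rng_seed, 0L, match(m, measures)))
  )

  rows <- list()
  for (src in names(rankings)) {
    source_kind <- if (src == "graph") "graph" else "sample"
    for (m in measures) {
      rl <- rankings[[src]][[m]]
      for (f in top_k_fractions) {
        k <- top_k_size(f, n)
        if (length(rl$ordered_nodes) < k) {
          vals <- c(NA_real_, NA_real_, NA_real_, NA_real_)
        } else {
          cand_k <- top_k_nodes(rl, k)
          gt_k <- top_k_nodes(ground_truth$ranking, k)
          vals <- c(dist_fun(ground_truth, rl, f, n),
                    osim(gt_k, cand_k, k),
                    kendall_top_k(ground_truth, rl, f, n),
                    tie_fraction(rl$scores[cand_k]))
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample = src, source = source_kind, measure = m, top_k = f,
          statistic = c(dist_stat, "osim", "kendall", "tie_fraction"),
          value = vals, stringsAsFactors = FALSE)
      }
    }
  }
  cells <- do.call(rbind, rows)

  agg_mean <- stats::aggregate(value ~ source + measure + top_k + statistic,
                               data = cells, FUN = mean, na.rm = TRUE,
                               na.action = stats::na.pass)
  agg_sd <- stats::aggregate(value ~ source + measure + top_k + statistic,
                             data = cells,
                             FUN = function(v) if (sum(!is.na(v)) > 1)
                               stats::sd(v, na.rm = TRUE) else NA_real_,
                             na.action = stats::na.pass)
  agg_na <- stats::aggregate(value ~ source + measure + top_k + statistic,
                             data = cells, FUN = function(v) sum(is.na(v)),
                             na.action = stats::na.pass)
  summary_df <- agg_mean
  names(summary_df)[names(summary_df) == "value"] <- "mean"
  summary_df$sd <- agg_sd$value
  summary_df$n_missing <- agg_na$value

  structure(list(cells = cells,
                 summary = summary_df,
                 meta = list(sampler = sampler,
                             ground_truth_kind = ground_truth$kind,
                             n_samples = n_samples,
                             population_size = n,
                             rng_seed = rng_seed)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> sampler %s vs %s ground truth (%d samples, |N| = %d)\n",
              x$meta$sampler, x$meta$ground_truth_kind, x$meta$n_samples,
              x$meta$population_size))
  s <- x$summary[x$summary$statistic != "tie_fraction", ]
  print(utils::head(s[order(s$statistic, s$source, s$measure, s$top_k), ],
                    20L), row.names = FALSE)
  if (nrow(s) > 20L) cat("  ...", nrow(s) - 20L, "more rows\n")
  invisible(x)
}

#' Summary table of an evaluation report
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return The summary data frame (mean, sd, missing count per source x
#'   measure x top-k x statistic).
#' @export
summary.evaluation_report <- function(object, ...) {
  object$summary
}
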