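#' Imprecision of a candidate top-k (SIR)
#'
#' The imprecision of a centrality-based ranking at a given top-k is
#' `1 - mean_C / mean_eff`, where `mean_C` is the average ground-truth
#' spreading efficiency of the candidate's top-k nodes and `mean_eff`
#' the average efficiency of the ground-truth ranking's own top-k. It is
#' 0 when the candidate identifies a set of spreaders as efficient as
#' the true one, and approaches 1 as the identified nodes become
#' irrelevant. Because the ground-truth top-k maximizes the k-mean, the
#' value is always in \[0, 1).
#'
#' @param ground_truth A `ground_truth` of kind `"sir_efficiency"`.
#' @param candidate A `ranked_list` whose nodes all appear in the ground
#'   truth.
#' @param fraction Top-k fraction in (0, 1].
#' @param population_size Number of nodes defining k; defaults to the
#'   ground truth's population (the original graph's |N|), which is the
#'   right reference when the candidate comes from a sample.
#' @return A single number in \[0, 1\].
#' @seealso [persistence_distance()], [osim()], [kendall_top_k()]
#' @export
imprecision <- function(ground_truth, candidate, fraction,
                        population_size = length(ground_truth$values)) {
  if (ground_truth$kind != "sir_efficiency") {
    stop("imprecision expects an SIR (spreading efficiency) ground truth; ",
         "use persistence_distance() for SIS", call. = FALSE)
  }
  top_k_ratio_complement(ground_truth, candidate, fraction, population_size)
}

#' Persistence-distance of a candidate top-k (SIS)
#'
#' The SIS analogue of [imprecision()]: `1 - mean_C / mean_eff` with
#' node persistence values in place of spreading efficiencies.
#'
#' @inheritParams imprecision
#' @param ground_truth A `ground_truth` of kind `"sis_persistence"`.
#' @return A single number in \[0, 1\].
#' @export
persistence_distance <- function(ground_truth, candidate, fraction,
                                 population_size = length(ground_truth$values)) {
  if (ground_truth$kind != "sis_persistence") {
    stop("persistence_distance expects an SIS (persistence) ground truth; ",
         "use imprecision() for SIR", call. = FALSE)
  }
  top_k_ratio_complement(ground_truth, candidate, fraction, population_size)
}

top_k_ratio_complement <- function(ground_truth, candidate, fraction,
                                   population_size) {
  stopifnot(inherits(candidate, "ranked_list"))
  k <- top_k_size(fraction, population_size)
  cand <- top_k_nodes(candidate, k)
  vals <- ground_truth$values[cand]
  if (anyNA(vals)) {
    stop("candidate top-k contains nodes without a ground-truth value",
         call. = FALSE)
  }
  best <- mean(sort(ground_truth$values, decreasing = TRUE)[seq_len(k)])
  if (best <= 0) {
    stop("ground-truth top-k mean is zero; the statistic is undefined",
         call. = FALSE)
  }
  1 - mean(vals) / best
}

#' OSim: overlap similarity of two top-k node sets
#'
#' The fraction of nodes shared by two top-k sets, ignoring order:
#' `|A intersect B| / k`. Symmetric in its arguments.
#'
#' @param a,b Character vectors of node ids, each of length `k`.
#' @param k The top-k size.
#' @return A single number in \[0, 1\].
#' @examples
#' osim(c("a", "b", "c"), c("b", "c", "d"), 3) # 2/3
#' @export
osim <- function(a, b, k) {
  if (length(unique(a)) != k || length(unique(b)) != k) {
    stop("both top-k sets must contain exactly k = ", k, " distinct nodes",
         call. = FALSE)
  }
  length(intersect(a, b)) / k
}

#' Top-k Kendall rank correlation against the ground truth
#'
#' List A is the candidate ranking's top-k nodes in candidate order;
#' list B is the same k nodes ordered by their ground-truth values,
#' regardless of where those nodes sit in the full ground-truth ranking
#' (some of the sample's top-k may not be in the ground truth's top-k).
#' The statistic is the Kendall rank correlation between the two
#' orderings of this common node set: +1 when the candidate orders the
#' nodes exactly as the ground truth does, -1 when it exactly reverses
#' them.
#'
#' The default `"tau_b"` variant adjusts for ties in the ground-truth
#' values (heavy for k-core scores); `"tau_a"` divides the concordant
#' minus discordant pair count by k(k-1)/2 without tie correction. With
#' all ground-truth values tied, tau-b is undefined and `NA` is
#' returned.
#'
#' @inheritParams imprecision
#' @param ground_truth A `ground_truth` of either kind.
#' @param variant `"tau_b"` (tie-adjusted, default) or `"tau_a"`.
#' @return A single number in \[-1, 1\] (or `NA`).
#' @export
kendall_top_k <- function(ground_truth, candidate, fraction,
                          population_size = length(ground_truth$values),
                          variant = c("tau_b", "tau_a")) {
  variant <- match.arg(variant)
  k <- top_k_size(fraction, population_size)
  cand <- top_k_nodes(candidate, k)
  vals <- as.numeric(ground_truth$values[cand])
  if (anyNA(vals)) {
    stop("candidate top-k contains nodes without a ground-truth value",
         call. = FALSE)
  }
  if (k < 2L) return(NA_real_)
  pos <- seq_len(k)                 # candidate order, best first
  if (variant == "tau_b") {
    if (stats::sd(vals) == 0) return(NA_real_)
    # positions rank best-first, values rank best-highest: flip the sign
    -stats::cor(pos, vals, method = "kendall")
  } else {
    conc <- 0L
    disc <- 0L
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        s <- sign(vals[i] - vals[j])   # pos[i] < pos[j] always
        if (s > 0) conc <- conc + 1L else if (s < 0) disc <- disc + 1L
      }
    }
    (conc - disc) / (k * (k - 1L) / 2)
  }
}

# Fraction of tied pairs among a score vector; reported alongside
# Kendall because heavily tied measures (k-core) make tau fragile.
tie_fraction <- function(scores) {
  k <- length(scores)
  if (k < 2L) return(0)
  tab <- table(scores)
  sum(tab * (tab - 1) / 2) / (k * (k - 1) / 2)
}
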