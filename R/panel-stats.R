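#' Listener-panel rating matrix
#'
#' Ratings from a blinded listening panel: each rater hears a number of
#' question sets and either agrees (1) or disagrees (0) with the
#' fingerprint-based similar/dissimilar classification in each set.
#'
#' @param x Binary matrix (or data frame), raters in rows, question sets in
#'   columns; entries 0/1. Row and column names default to `rater_i` /
#'   `set_j`.
#' @return An object of class `"panel_ratings"` (a binary integer matrix).
#' @export
panel_ratings <- function(x) {
  m <- as.matrix(x)
  if (length(m) == 0L || !is.numeric(m) || anyNA(m) || !all(m %in% c(0, 1)))
    stop_("ratings must be a non-empty binary (0/1) matrix",
          class = "validation_error")
  storage.mode(m) <- "integer"
  if (is.null(rownames(m))) rownames(m) <- paste0("rater_", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("set_", seq_len(ncol(m)))
  structure(m, class = c("panel_ratings", "matrix", "array"))
}

#' Read listener-panel ratings from a long-format CSV
#'
#' @param path CSV with columns `rater_id`, `set_id`, `agrees` (0/1); every
#'   rater must rate every set exactly once.
#' @return A [panel_ratings()] matrix.
#' @export
read_ratings <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("rater_id", "set_id", "agrees")
  if (!all(need %in% names(d)))
    stop_("ratings CSV needs columns %s", paste(need, collapse = ", "),
          class = "format_error")
  tab <- table(d$rater_id, d$set_id)
  if (any(tab != 1L))
    stop_("each rater must rate each set exactly once", class = "format_error")
  m <- stats::xtabs(agrees ~ rater_id + set_id, data = d)
  panel_ratings(matrix(as.integer(m), nrow = nrow(m),
                       dimnames = dimnames(m)))
}

#' Per-rater agreement scores
#'
#' @param ratings A [panel_ratings()] matrix.
#' @return Named integer vector of row sums: each rater's number of sets in
#'   agreement with the fingerprint classification (0 to the number of sets).
#' @export
rater_scores <- function(ratings) {
  stopifnot(inherits(ratings, "panel_ratings"))
  rowSums(unclass(ratings))
}

#' Panel agreement summary
#'
#' @param ratings A [panel_ratings()] matrix.
#' @return List: `mean_score` (mean per-rater score), `total_agreements`
#'   (grand sum), `total_classifications` (raters x sets), and
#'   `percent_agreement` (100 x grand sum / total, rounded half-up to the
#'   nearest integer percent).
#' @export
agreement_summary <- function(ratings) {
  stopifnot(inherits(ratings, "panel_ratings"))
  scores <- rater_scores(ratings)
  total <- length(ratings)
  agreements <- as.integer(sum(scores))
  list(mean_score = mean(scores),
       total_agreements = agreements,
       total_classifications = as.integer(total),
       percent_agreement = floor(100 * agreements / total + 0.5))
}

#' One-sample t-test of panel scores against chance
#'
#' With binary questions, an unbiased guesser agrees on half the sets, so
#' for 5 sets the chance-level mean score is 2.5. Tests (two-sided) whether
#' the observed mean per-rater score differs from that hypothesized mean.
#'
#' @param scores Numeric vector of per-rater scores (see [rater_scores()]).
#' @param mu0 Hypothesized mean under random guessing (default 2.5).
#' @return List: `n`, `mean`, `sd` (sample, n-1), `mu0`, `t`, `df` (n-1),
#'   `p` (two-sided).
#' @export
one_sample_ttest <- function(scores, mu0 = 2.5) {
  if (length(scores) < 2L)
    stop_("need at least 2 scores", class = "validation_error")
  s <- stats::sd(scores)
  if (s == 0)
    stop_("all scores identical; t statistic undefined",
          class = "degenerate_sample")
  ht <- stats::t.test(scores, mu = mu0, alternative = "two.sided")
  list(n = length(scores), mean = mean(scores), sd = s, mu0 = mu0,
       t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Fleiss' kappa for multi-rater categorical agreement
#'
#' Chance-corrected agreement for `n` raters assigning each item to one of
#' `n_categories` categories. Per-item agreement is
#' `P_i = (sum_j n_ij^2 - n) / (n (n - 1))`; expected agreement is the sum
#' of squared overall category proportions; kappa is
#' `(P_bar - P_e) / (1 - P_e)`.
#'
#' @param ratings A [panel_ratings()] matrix (items are the columns, each
#'   rated by all raters) or an items x categories count matrix.
#' @param n_categories Number of categories (default 2; for a binary
#'   [panel_ratings()] matrix the categories are disagree/agree).
#' @return List: `kappa`, `p_bar` (mean observed agreement), `p_e`
#'   (expected agreement), `n_items`, `n_raters`, `n_categories`.
#' @export
fleiss_kappa <- function(ratings, n_categories = 2L) {
  n_categories <- check_count(n_categories, "n_categories", lower = 2L)
  if (inherits(ratings, "panel_ratings")) {
    m <- unclass(ratings)
    # items = question sets; count raters per category (0/1) per item
    counts <- t(apply(m, 2, function(col)
      tabulate(col + 1L, nbins = n_categories)))
  } else {
    counts <- as.matrix(ratings)
  }
  n_raters <- unique(rowSums(counts))
  if (length(n_raters) != 1L || n_raters < 2L)
    stop_("every item must be rated by the same number (>= 2) of raters",
          class = "validation_error")
  n <- n_raters
  p_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_j <- colSums(counts) / sum(counts)
  p_e <- sum(p_j^2)
  if (p_e >= 1)
    stop_("a single category was used everywhere; kappa undefined",
          class = "degenerate_marginals")
  list(kappa = (p_bar - p_e) / (1 - p_e), p_bar = p_bar, p_e = p_e,
       n_items = nrow(counts), n_raters = n, n_categories = n_categories)
}

#' Synthetic panel ratings with a given per-rater score distribution
#'
#' Builds a binary raters x sets matrix whose row sums follow the given
#' score distribution, with the disagreeing sets placed uniformly at random.
#' The default distribution is 11 raters scoring 5/5, 12 scoring 4/5 and one
#' scoring 3/5 over 5 sets (mean 4.42, 106/120 agreements).
#'
#' @param score_counts Named integer vector: names are scores, values the
#'   number of raters attaining each score.
#' @param n_sets Number of question sets.
#' @param seed Seed for placing the disagreements.
#' @return A [panel_ratings()] matrix.
#' @export
synthetic_panel_ratings <- function(score_counts = c("5" = 11, "4" = 12, "3" = 1),
                                    n_sets = 5L, seed = 1L) {
  n_sets <- check_count(n_sets, "n_sets")
  scores <- rep(as.integer(names(score_counts)), times = score_counts)
  if (any(scores < 0 | scores > n_sets))
    stop_("scores must lie in 0..n_sets", class = "validation_error")
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  m <- t(vapply(scores, function(s) {
    row <- rep(1L, n_sets)
    if (s < n_sets) row[sample.int(n_sets, n_sets - s)] <- 0L
    row
  }, integer(n_sets)))
  panel_ratings(m)
}
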