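#' One-way analysis of variance
#'
#' Classical between/within sum-of-squares decomposition with the p-value
#' from the F distribution on (k - 1, N - k) degrees of freedom. Degenerate
#' inputs follow the usual conventions: zero between-group variance gives
#' F = 0 (p = 1); zero within-group variance with unequal means gives
#' F = Inf with p = 0 and a \code{degenerate} flag.
#'
#' @param groups list of numeric vectors, >= 2 groups of >= 2 values.
#' @return list with \code{F}, \code{p}, \code{df} (length 2),
#'   \code{ss_between}, \code{ss_within}, \code{degenerate}.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs at least 2 values")
  k <- length(groups)
  n <- vapply(groups, length, integer(1))
  N <- sum(n)
  means <- vapply(groups, mean, numeric(1))
  grand <- sum(unlist(groups)) / N
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df <- c(k - 1, N - k)
  if (ssw == 0) {
    if (ssb == 0)
      return(list(F = 0, p = 1, df = df, ss_between = 0, ss_within = 0,
                  degenerate = TRUE))
    return(list(F = Inf, p = 0, df = df, ss_between = ssb, ss_within = 0,
                degenerate = TRUE))
  }
  f <- (ssb / df[1]) / (ssw / df[2])
  list(F = f, p = stats::pf(f, df[1], df[2], lower.tail = FALSE), df = df,
       ss_between = ssb, ss_within = ssw, degenerate = FALSE)
}

#' Point-biserial correlation
#'
#' Equals the Pearson correlation between the 0/1 group coding and the
#' values; the two-sided p-value uses the t transform with n - 2 degrees of
#' freedom.
#'
#' @param binary_group vector of 0/1 group codes, both levels present.
#' @param values numeric vector of the same length, non-constant.
#' @return list with \code{r_pb}, \code{p}, \code{df}.
#' @export
point_biserial <- function(binary_group, values) {
  g <- as.numeric(binary_group)
  v <- as.numeric(values)
  if (length(g) != length(v)) stop("length mismatch")
  if (!all(g %in% c(0, 1))) stop("'binary_group' must be 0/1")
  n0 <- sum(g == 0); n1 <- sum(g == 1); n <- n0 + n1
  if (n0 == 0 || n1 == 0) stop("both binary levels must be present")
  if (stats::sd(v) == 0) stop("'values' are constant")
  m0 <- mean(v[g == 0]); m1 <- mean(v[g == 1])
  s_n <- sqrt(sum((v - mean(v))^2) / n)   # population SD
  r <- (m1 - m0) / s_n * sqrt(n0 * n1 / n^2)
  r <- max(-1, min(1, r))
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  list(r_pb = r, p = 2 * stats::pt(-abs(tt), n - 2), df = n - 2)
}

#' Dichotomize expert utility scores for correlation analysis
#'
#' Scores 1 and 2 (useful, no or minor edits) become group 0; score 3
#' (major edits, not useful) becomes group 1.
#'
#' @param scores integer vector with values in {1, 2, 3}.
#' @return 0/1 vector.
#' @export
dichotomize_scores <- function(scores) {
  check_scores(scores)
  as.numeric(scores == 3)
}

check_scores <- function(scores) {
  if (length(scores) == 0) stop("no scores supplied")
  if (!all(scores %in% c(1, 2, 3)))
    stop("scores must be exactly 1, 2 or 3")
  invisible(scores)
}

#' Summarize expert utility scores
#'
#' Tallies the 1/2/3 scores (1 = no edits needed, 2 = minor edits but
#' useful, 3 = major edits, not useful), the proportion considered useful
#' (score <= 2) and the proportion requiring major edits (score 3).
#' Percentages are also reported rounded to the nearest integer.
#'
#' @param scores integer vector of scores in {1, 2, 3}, or a data.frame
#'   with a \code{score} column.
#' @return list with \code{counts} (named, scores 1..3), \code{n_total},
#'   \code{proportion_useful}, \code{percent_useful},
#'   \code{proportion_major}, \code{percent_major}.
#' @export
score_summary <- function(scores) {
  if (is.data.frame(scores)) scores <- scores$score
  check_scores(scores)
  counts <- vapply(1:3, function(s) sum(scores == s), numeric(1))
  names(counts) <- c("1", "2", "3")
  n <- length(scores)
  pu <- (counts[["1"]] + counts[["2"]]) / n
  pm <- counts[["3"]] / n
  list(counts = counts, n_total = n,
       proportion_useful = pu, percent_useful = round(100 * pu),
       proportion_major = pm, percent_major = round(100 * pm))
}

#' Read an expert-score table from CSV
#'
#' Expected columns: patient, roi_label, algorithm, score (1/2/3).
#'
#' @param path CSV file path.
#' @return validated data.frame.
#' @export
read_scores_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "roi_label", "algorithm", "score")
  if (!all(need %in% names(df)))
    stop("score CSV must have columns: ", paste(need, collapse = ", "))
  check_scores(df$score)
  df
}
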