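# Cohort construction: GDS-30 scoring, exclusion screening, 1:1 frequency
# matching, sample-size arithmetic, and baseline (Table-1 style) statistics.

# The 20 positively keyed GDS-30 items (a "yes" scores 1) and the 10
# reverse-keyed items (a "no" scores 1).
gds_positive_items <- function() c(2:4, 6, 8, 10:14, 16:18, 20, 22:26, 28)
gds_negative_items <- function() c(1, 5, 7, 9, 15, 19, 21, 27, 29, 30)

#' Score the 30-item Geriatric Depression Scale
#'
#' One point for "yes" on the 20 positively keyed items (2-4, 6, 8, 10-14,
#' 16-18, 20, 22-26, 28) and one point for "no" on the 10 reverse-keyed items
#' (1, 5, 7, 9, 15, 19, 21, 27, 29, 30). A total score strictly greater than
#' 10 flags clinically significant depression.
#'
#' @param responses length-30 vector of answers; accepts logical, 0/1
#'   integers, or "yes"/"no" strings. `NA` is an error.
#' @return List with `score` (0-30) and `depressed` (logical, score > 10).
#' @examples
#' score_gds(rep("yes", 30))  # score 20
#' score_gds(rep("no", 30))   # score 10, not depressed
#' @export
score_gds <- function(responses) {
  if (length(responses) != 30L)
    stop("exactly 30 GDS responses required, got ", length(responses))
  yes <- parse_yes_no(responses)
  if (anyNA(yes))
    stop("missing GDS response at item(s) ",
         paste(which(is.na(yes)), collapse = ", "))
  score <- sum(yes[gds_positive_items()]) + sum(!yes[gds_negative_items()])
  list(score = as.integer(score), depressed = score > 10)
}

parse_yes_no <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1, NA))) stop("numeric responses must be 0/1")
    return(x == 1)
  }
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("yes", "y", "1", "true")] <- TRUE
  out[x %in% c("no", "n", "0", "false")] <- FALSE
  out
}

#' Apply the study exclusion criteria to a participant roster
#'
#' Criteria are applied in a fixed order -- incomplete questionnaire, then
#' antidepressant use, then missing blood sample -- and a participant failing
#' several criteria is counted once, under the first failed criterion.
#'
#' @param roster data.frame with logical columns `questionnaire_complete`,
#'   `on_antidepressant`, `has_blood_sample` (and any identifier/covariate
#'   columns, preserved in the output).
#' @return List with `eligible` (order-preserving subset of `roster`) and
#'   `excluded` (named integer counts per criterion).
#' @export
apply_exclusions <- function(roster) {
  needed <- c("questionnaire_complete", "on_antidepressant", "has_blood_sample")
  missing_cols <- setdiff(needed, names(roster))
  if (length(missing_cols))
    stop("roster lacks columns: ", paste(missing_cols, collapse = ", "))
  fail_q <- !roster$questionnaire_complete
  fail_a <- roster$on_antidepressant & !fail_q
  fail_b <- !roster$has_blood_sample & !fail_q & !fail_a
  counts <- c(questionnaire = sum(fail_q), antidepressant = sum(fail_a),
              blood_sample = sum(fail_b))
  list(eligible = roster[!(fail_q | fail_a | fail_b), , drop = FALSE],
       excluded = counts)
}

#' 1:1 frequency matching of cases to controls by sex and age
#'
#' Each case is paired with exactly one unused control of the same sex whose
#' age differs by at most `age_tol_years`. Admissible case-control pairs are
#' taken greedily in order of increasing absolute age difference, ties broken
#' by a seeded shuffle, so the closest-age pairs are fixed first.
#'
#' @param cases,control_pool data.frames with columns `id`, `age`, `sex`;
#'   the pools must be disjoint on `id`.
#' @param age_tol_years maximum allowed absolute age difference (years).
#' @param seed integer seed for tie shuffling.
#' @return data.frame of pairs: `case_id`, `control_id`, `case_age`,
#'   `control_age`, `sex`, `age_diff`.
#' @export
match_controls <- function(cases, control_pool, age_tol_years = 3, seed = 1L) {
  for (d in list(cases, control_pool))
    if (!all(c("id", "age", "sex") %in% names(d)))
      stop("cases and control_pool need columns id, age, sex")
  if (length(intersect(cases$id, control_pool$id)))
    stop("control_pool must be disjoint from cases")
  cand <- do.call(rbind, lapply(seq_len(nrow(cases)), function(i) {
    ok <- control_pool$sex == cases$sex[i] &
      abs(control_pool$age - cases$age[i]) <= age_tol_years
    if (!any(ok)) return(NULL)
    data.frame(case_idx = i, control_idx = which(ok),
               age_diff = abs(control_pool$age[ok] - cases$age[i]))
  }))
  set.seed(derive_seed(seed, "matching"))
  if (!is.null(cand)) {
    cand <- cand[sample.int(nrow(cand)), , drop = FALSE]  # seeded tie order
    cand <- cand[order(cand$age_diff), , drop = FALSE]
  }
  used_case <- logical(nrow(cases)); used_ctl <- logical(nrow(control_pool))
  pairs <- vector("list", nrow(cases)); k <- 0L
  for (j in seq_len(NROW(cand))) {
    ci <- cand$case_idx[j]; oi <- cand$control_idx[j]
    if (used_case[ci] || used_ctl[oi]) next
    used_case[ci] <- TRUE; used_ctl[oi] <- TRUE; k <- k + 1L
    pairs[[k]] <- data.frame(
      case_id = cases$id[ci], control_id = control_pool$id[oi],
      case_age = cases$age[ci], control_age = control_pool$age[oi],
      sex = cases$sex[ci], age_diff = cand$age_diff[j],
      stringsAsFactors = FALSE)
  }
  if (!all(used_case))
    stop("no admissible control for case(s): ",
         paste(cases$id[!used_case], collapse = ", "))
  out <- do.call(rbind, pairs[seq_len(k)])
  out[order(match(out$case_id, cases$id)), , drop = FALSE]
}

#' Per-group sample size for a two-sample comparison (normal approximation)
#'
#' `n = ceiling(2 * (z_{1-alpha/tails} + z_{power})^2 / d^2)`, floored at 2
#' per group. This is the large-sample approximation to the noncentral-t
#' power calculation; for d = 0.5, alpha = 0.05, power = 0.80 it gives 50
#' (one-tailed) or 63 (two-tailed).
#'
#' @param d standardized effect size (Cohen's d), positive.
#' @param alpha significance level in (0, 1).
#' @param power target power in (alpha, 1).
#' @param tail `"one"` or `"two"`.
#' @return Integer sample size per group.
#' @export
required_n_per_group <- function(d, alpha = 0.05, power = 0.80,
                                 tail = c("two", "one")) {
  tail <- match.arg(tail)
  if (d <= 0) stop("effect size d must be positive")
  stopifnot(alpha > 0, alpha < 1, power > alpha, power < 1)
  tails <- if (tail == "two") 2 else 1
  z <- stats::qnorm(1 - alpha / tails) + stats::qnorm(power)
  max(2L, as.integer(ceiling(2 * z^2 / d^2)))
}

#' Baseline comparison table (two-group)
#'
#' Numeric variables are compared by a two-sided independent t-test (pooled
#' variance by default, matching the SPSS equal-variances row; Welch via
#' `welch = TRUE`); categorical variables by Pearson chi-square without
#' continuity correction on the observed counts.
#'
#' @param metadata data.frame with a `group` column (two levels).
#' @param numeric_vars,categorical_vars character vectors of column names.
#' @param welch use Welch's t-test instead of pooled variance.
#' @return data.frame: variable, summary per group (`mean ± SD` or
#'   percentage breakdown), test, p.
#' @export
baseline_table <- function(metadata, numeric_vars = character(),
                           categorical_vars = character(), welch = FALSE) {
  groups <- unique(metadata$group)
  if (length(groups) != 2) stop("exactly two groups required")
  g1 <- metadata$group == groups[1]
  rows <- list()
  for (v in numeric_vars) {
    x <- metadata[[v]][g1]; y <- metadata[[v]][!g1]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      warning("zero variance in both groups for ", v, "; p set to 1")
      p <- 1
    } else {
      p <- stats::t.test(x, y, var.equal = !welch)$p.value
    }
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v,
      summary_g1 = sprintf("%.2f ± %.2f", mean(x), stats::sd(x)),
      summary_g2 = sprintf("%.2f ± %.2f", mean(y), stats::sd(y)),
      test = if (welch) "Welch t" else "t", p = p, stringsAsFactors = FALSE)
  }
  for (v in categorical_vars) {
    tab <- table(metadata$group, metadata[[v]])
    p <- chisq_p(tab)
    pct <- function(i) paste(sprintf("%s %.1f%%", colnames(tab),
                                     100 * tab[i, ] / sum(tab[i, ])),
                             collapse = ", ")
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, summary_g1 = pct(1), summary_g2 = pct(2),
      test = "chi-square", p = p, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Pearson chi-square p-value from a contingency table (no correction)
#'
#' @param counts matrix of counts (e.g. 2x2).
#' @return Two-sided p-value.
#' @export
chisq_p <- function(counts) {
  suppressWarnings(stats::chisq.test(counts, correct = FALSE)$p.value)
}

#' Reconstruct 2x2 counts from printed percentages and compare groups
#'
#' Rounds `percent/100 * n` to the nearest integer per group (documented as
#' lossy) and returns the Pearson chi-square p-value without continuity
#' correction -- the convention needed to reproduce published baseline
#' p-values from percentage summaries.
#'
#' @param pct_g1,pct_g2 percentage of the index category in each group.
#' @param n_g1,n_g2 group sizes.
#' @return List with `counts` (2x2 matrix) and `p`.
#' @export
chisq_from_percent <- function(pct_g1, pct_g2, n_g1, n_g2) {
  a <- round(pct_g1 / 100 * n_g1); c_ <- round(pct_g2 / 100 * n_g2)
  counts <- matrix(c(a, n_g1 - a, c_, n_g2 - c_), nrow = 2, byrow = TRUE,
                   dimnames = list(group = c("g1", "g2"),
                                   category = c("yes", "no")))
  list(counts = counts, p = chisq_p(counts))
}
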