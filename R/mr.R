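# Two-sample Mendelian randomization on GWAS summary statistics:
# instrument selection, LD clumping, harmonization, Steiger filtering,
# causal estimators (IVW, Egger, weighted median, simple mode) and
# sensitivity analyses.

#' Select candidate instruments from exposure summary statistics
#'
#' Keeps SNPs associated with the exposure below `p_thresh` whose
#' single-SNP F statistic `(beta/se)^2` exceeds `f_min`.
#'
#' @param exposure data.frame with columns `snp`, `beta`, `se`, `pval`.
#' @param p_thresh exposure association threshold (default 1e-5).
#' @param f_min minimum instrument strength (default 10, strict inequality).
#' @return The filtered data.frame with an added `F` column.
#' @export
select_instruments <- function(exposure, p_thresh = 1e-5, f_min = 10) {
  need_cols(exposure, c("snp", "beta", "se", "pval"))
  exposure$F <- (exposure$beta / exposure$se)^2
  out <- exposure[exposure$pval < p_thresh & exposure$F > f_min, , drop = FALSE]
  if (!nrow(out)) stop("no instruments pass p < ", p_thresh, " and F > ", f_min)
  out
}

need_cols <- function(d, cols) {
  miss <- setdiff(cols, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
}

#' Greedy LD clumping to near-independent instruments
#'
#' SNPs are visited in order of increasing exposure p-value (ties broken by
#' SNP ID); a SNP is kept iff its squared correlation with every already-kept
#' SNP lying within `window_kb` is below `r2_max`. Pairs outside the window
#' are treated as independent. A missing LD entry counts as r^2 = 0 with a
#' warning.
#'
#' @param candidates data.frame with `snp`, `pval`, and (optionally)
#'   `position` in base pairs.
#' @param ld_matrix SNP x SNP correlation (r) matrix with dimnames.
#' @param r2_max maximum allowed r^2 between kept SNPs (default 0.001).
#' @param window_kb window in kilobases within which LD is enforced.
#' @param positions optional named vector of base-pair positions overriding
#'   the `position` column; if neither is given every pair is in-window.
#' @return The kept subset of `candidates`, in p-value order.
#' @export
ld_clump <- function(candidates, ld_matrix, r2_max = 0.001,
                     window_kb = 10000, positions = NULL) {
  need_cols(candidates, c("snp", "pval"))
  if (is.null(positions) && "position" %in% names(candidates))
    positions <- stats::setNames(candidates$position, candidates$snp)
  ord <- order(candidates$pval, candidates$snp)
  cand <- candidates[ord, , drop = FALSE]
  missing_warned <- FALSE
  r2_of <- function(a, b) {
    if (a %in% rownames(ld_matrix) && b %in% colnames(ld_matrix))
      return(ld_matrix[a, b]^2)
    if (!missing_warned) {
      warning("LD entry missing for some SNP pairs; treated as r^2 = 0")
      missing_warned <<- TRUE
    }
    0
  }
  kept <- character()
  for (s in cand$snp) {
    ok <- TRUE
    for (k in kept) {
      in_window <- is.null(positions) ||
        abs(positions[[s]] - positions[[k]]) <= window_kb * 1000
      if (in_window && r2_of(s, k) >= r2_max) { ok <- FALSE; break }
    }
    if (ok) kept <- c(kept, s)
  }
  cand[cand$snp %in% kept, , drop = FALSE]
}

is_palindromic <- function(a1, a2) {
  paste0(a1, a2) %in% c("AT", "TA", "CG", "GC")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome effects to the exposure effect allele: rows with swapped
#' alleles get their outcome beta sign-flipped and allele frequency
#' reflected; palindromic SNPs with ambiguous frequency (EAF in the
#' `ambiguity_window`) are dropped, otherwise aligned by frequency;
#' irreconcilable allele pairs are dropped with a log entry. SNPs whose
#' outcome association is stronger than `outcome_p_thresh` are removed so
#' that instruments are not themselves outcome loci.
#'
#' @param exposure,outcome data.frames sharing `snp`, with `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pval` (and optional `n`).
#' @param outcome_p_thresh exclusion threshold for outcome-associated SNPs
#'   (default 1e-5, matching the instrument threshold).
#' @param ambiguity_window EAF interval in which a palindromic SNP is
#'   considered unresolvable (default c(0.42, 0.58)).
#' @return data.frame of class `mr_instruments`: one row per retained SNP
#'   with `beta_exp`, `se_exp`, `p_exp`, `beta_out`, `se_out`, `p_out`,
#'   `eaf`, `F`, `n_exp`, `n_out`; attribute `log` records drops.
#' @export
harmonize <- function(exposure, outcome, outcome_p_thresh = 1e-5,
                      ambiguity_window = c(0.42, 0.58)) {
  for (d in list(exposure, outcome))
    need_cols(d, c("snp", "effect_allele", "other_allele", "eaf",
                   "beta", "se", "pval"))
  m <- merge(exposure, outcome, by = "snp", suffixes = c("_exp", "_out"))
  log <- character()
  rows <- lapply(seq_len(nrow(m)), function(i) {
    r <- m[i, ]
    same <- r$effect_allele_exp == r$effect_allele_out &&
      r$other_allele_exp == r$other_allele_out
    swapped <- r$effect_allele_exp == r$other_allele_out &&
      r$other_allele_exp == r$effect_allele_out
    if (!same && !swapped) {
      log <<- c(log, paste0(r$snp, ": irreconcilable alleles"))
      return(NULL)
    }
    beta_out <- r$beta_out; eaf_out <- r$eaf_out
    if (swapped) { beta_out <- -beta_out; eaf_out <- 1 - eaf_out }
    if (is_palindromic(r$effect_allele_exp, r$other_allele_exp)) {
      if (r$eaf_exp > ambiguity_window[1] && r$eaf_exp < ambiguity_window[2]) {
        log <<- c(log, paste0(r$snp, ": palindromic with ambiguous EAF"))
        return(NULL)
      }
      # align strands by frequency: flip if the frequencies disagree
      if ((r$eaf_exp < 0.5) != (eaf_out < 0.5)) {
        beta_out <- -beta_out; eaf_out <- 1 - eaf_out
      }
    }
    data.frame(snp = r$snp,
               effect_allele = r$effect_allele_exp,
               other_allele = r$other_allele_exp,
               eaf = r$eaf_exp,
               beta_exp = r$beta_exp, se_exp = r$se_exp, p_exp = r$pval_exp,
               beta_out = beta_out, se_out = r$se_out, p_out = r$pval_out,
               eaf_out = eaf_out,
               n_exp = if ("n_exp" %in% names(r)) r$n_exp else NA_real_,
               n_out = if ("n_out" %in% names(r)) r$n_out else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- empty_instruments()
  drop_out <- out$p_out < outcome_p_thresh
  if (any(drop_out))
    log <- c(log, paste0(out$snp[drop_out], ": outcome-associated, excluded"))
  out <- out[!drop_out, , drop = FALSE]
  out$F <- (out$beta_exp / out$se_exp)^2
  attr(out, "log") <- log
  class(out) <- c("mr_instruments", class(out))
  out
}

empty_instruments <- function() data.frame(
  snp = character(), effect_allele = character(), other_allele = character(),
  eaf = numeric(), beta_exp = numeric(), se_exp = numeric(), p_exp = numeric(),
  beta_out = numeric(), se_out = numeric(), p_out = numeric(),
  eaf_out = numeric(), n_exp = numeric(), n_out = numeric(),
  stringsAsFactors = FALSE)

#' Steiger filtering of instrument direction
#'
#' Per SNP, the variance explained in each trait is approximated from the F
#' statistic, `r2 = F / (F + n - 2)`; a SNP is kept when it explains
#' strictly more variance in the exposure than in the outcome. When sample
#' sizes are missing the filter is skipped with a warning.
#'
#' @param rows harmonized instrument rows (see [harmonize()]).
#' @return List: `rows` (with a `steiger_ok` column), `kept` (the filtered
#'   subset).
#' @export
steiger_filter <- function(rows) {
  if (anyNA(rows$n_exp) || anyNA(rows$n_out)) {
    warning("sample sizes missing; Steiger filter skipped")
    rows$steiger_ok <- TRUE
    return(list(rows = rows, kept = rows))
  }
  f_exp <- (rows$beta_exp / rows$se_exp)^2
  f_out <- (rows$beta_out / rows$se_out)^2
  r2_exp <- f_exp / (f_exp + rows$n_exp - 2)
  r2_out <- f_out / (f_out + rows$n_out - 2)
  rows$steiger_ok <- r2_exp > r2_out
  list(rows = rows, kept = rows[rows$steiger_ok, , drop = FALSE])
}

mr_estimate <- function(method, beta, se, p, ...) {
  out <- data.frame(method = method, beta = beta, se = se, p = p,
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted meta-analysis of per-SNP Wald ratios, equivalent to weighted
#' least squares of the outcome betas on the exposure betas through the
#' origin with weights `1/se_out^2`. The multiplicative random-effects
#' model (default) inflates the fixed-effect standard error by
#' `sqrt(max(1, Q/(k-1)))`.
#'
#' @param rows harmonized instruments (>= 2 rows).
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return One-row data.frame: method, beta, se, p, cochran_Q, Q_df, Q_p.
#' @export
mr_ivw <- function(rows, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  k <- nrow(rows)
  if (k < 2) stop("IVW needs at least 2 instruments; use a Wald ratio")
  w <- rows$beta_exp^2 / rows$se_out^2
  beta <- sum(rows$beta_exp * rows$beta_out / rows$se_out^2) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  ratio <- rows$beta_out / rows$beta_exp
  Q <- sum(w * (ratio - beta)^2)
  se <- if (model == "fixed") se_fixed else se_fixed * sqrt(max(1, Q / (k - 1)))
  mr_estimate("IVW", beta, se, 2 * stats::pnorm(-abs(beta / se)),
              cochran_Q = Q, Q_df = k - 1,
              Q_p = stats::pchisq(Q, k - 1, lower.tail = FALSE))
}

#' MR-Egger regression with pleiotropy intercept test
#'
#' Weighted linear regression of outcome betas on exposure betas with an
#' intercept (weights `1/se_out^2`), after orienting every exposure beta
#' positive. The slope estimates the causal effect; a non-zero intercept
#' indicates directional pleiotropy.
#'
#' @param rows harmonized instruments (>= 3 rows).
#' @return One-row data.frame: method, beta, se, p, egger_intercept,
#'   egger_intercept_se, egger_intercept_p.
#' @export
mr_egger <- function(rows) {
  if (nrow(rows) < 3) stop("MR-Egger needs at least 3 instruments")
  flip <- sign(rows$beta_exp)
  bx <- rows$beta_exp * flip
  by <- rows$beta_out * flip
  fit <- stats::lm(by ~ bx, weights = 1 / rows$se_out^2)
  s <- summary(fit)$coefficients
  df <- nrow(rows) - 2
  mr_estimate("Egger", s["bx", 1], s["bx", 2],
              2 * stats::pt(-abs(s["bx", 3]), df),
              egger_intercept = s["(Intercept)", 1],
              egger_intercept_se = s["(Intercept)", 2],
              egger_intercept_p = 2 * stats::pt(-abs(s["(Intercept)", 3]), df))
}

# Weighted median of `x` with weights `w`: cumulative-weight interpolation
# at probability one half.
weighted_median_value <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cum <- (cumsum(w) - w / 2) / sum(w)
  if (cum[1] >= 0.5) return(x[1])
  if (cum[length(cum)] <= 0.5) return(x[length(x)])
  below <- max(which(cum < 0.5))
  x[below] + (x[below + 1] - x[below]) *
    (0.5 - cum[below]) / (cum[below + 1] - cum[below])
}

#' Weighted-median causal estimate
#'
#' Median of the per-SNP Wald ratios under inverse-variance weights
#' (`1 / var(ratio)` by the delta method), consistent when at least half the
#' weight comes from valid instruments. The standard error comes from a
#' seeded parametric bootstrap.
#'
#' @param rows harmonized instruments (>= 3 rows).
#' @param n_boot bootstrap replicates for the standard error.
#' @param seed integer seed.
#' @return One-row data.frame: method, beta, se, p.
#' @export
mr_weighted_median <- function(rows, n_boot = 1000L, seed = 1L) {
  if (nrow(rows) < 3) stop("weighted median needs at least 3 instruments")
  ratio <- rows$beta_out / rows$beta_exp
  w <- rows$beta_exp^2 / rows$se_out^2      # 1 / var(ratio), delta method
  beta <- weighted_median_value(ratio, w)
  set.seed(derive_seed(seed, "bootstrap"))
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(nrow(rows), rows$beta_exp, rows$se_exp)
    by <- stats::rnorm(nrow(rows), rows$beta_out, rows$se_out)
    weighted_median_value(by / bx, bx^2 / rows$se_out^2)
  }, numeric(1))
  se <- stats::sd(boots)
  mr_estimate("weighted_median", beta, se, 2 * stats::pnorm(-abs(beta / se)))
}

#' Simple-mode causal estimate
#'
#' The mode of a Gaussian kernel density over the per-SNP Wald ratios
#' (bandwidth `phi` times the default normal-reference rule); the standard
#' error comes from a seeded parametric bootstrap.
#'
#' @param rows harmonized instruments (>= 3 rows).
#' @param phi bandwidth multiplier (default 1).
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return One-row data.frame: method, beta, se, p.
#' @export
mr_simple_mode <- function(rows, phi = 1, n_boot = 200L, seed = 1L) {
  if (nrow(rows) < 3) stop("simple mode needs at least 3 instruments")
  mode_of <- function(ratio) {
    d <- stats::density(ratio, bw = stats::bw.nrd0(ratio) * phi)
    d$x[which.max(d$y)]
  }
  ratio <- rows$beta_out / rows$beta_exp
  beta <- mode_of(ratio)
  set.seed(derive_seed(seed, "bootstrap"))
  boots <- vapply(seq_len(n_boot), function(b) {
    bx <- stats::rnorm(nrow(rows), rows$beta_exp, rows$se_exp)
    by <- stats::rnorm(nrow(rows), rows$beta_out, rows$se_out)
    mode_of(by / bx)
  }, numeric(1))
  se <- stats::sd(boots)
  mr_estimate("simple_mode", beta, se, 2 * stats::pnorm(-abs(beta / se)))
}

#' Sensitivity suite: heterogeneity, leave-one-out, global outlier test
#'
#' Computes Cochran's Q over the Wald ratios against the IVW estimate,
#' re-estimates IVW leaving each SNP out, runs a seeded global outlier test
#' (observed weighted residual sum of squares against `n_sim` simulations
#' under the no-outlier model, in the spirit of MR-PRESSO's global test),
#' and the simple-mode estimate.
#'
#' @param rows harmonized instruments (>= 3 rows).
#' @param n_sim simulations for the global outlier test.
#' @param seed integer seed.
#' @return List: `cochran_Q` (Q, df, p), `loo` (data.frame snp, beta, se, p
#'   of IVW without that SNP), `presso_global_p`, `simple_mode` (estimate
#'   row).
#' @export
mr_sensitivity <- function(rows, n_sim = 1000L, seed = 1L) {
  if (nrow(rows) < 3) stop("sensitivity suite needs at least 3 instruments")
  ivw <- mr_ivw(rows)
  loo <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    e <- mr_ivw(rows[-i, , drop = FALSE])
    data.frame(snp = rows$snp[i], beta = e$beta, se = e$se, p = e$p,
               stringsAsFactors = FALSE)
  }))
  set.seed(derive_seed(seed, "presso"))
  rss_obs <- sum((rows$beta_out - ivw$beta * rows$beta_exp)^2 / rows$se_out^2)
  rss_sim <- vapply(seq_len(n_sim), function(s) {
    by <- stats::rnorm(nrow(rows), ivw$beta * rows$beta_exp, rows$se_out)
    b <- sum(rows$beta_exp * by / rows$se_out^2) /
      sum(rows$beta_exp^2 / rows$se_out^2)
    sum((by - b * rows$beta_exp)^2 / rows$se_out^2)
  }, numeric(1))
  list(cochran_Q = list(Q = ivw$cochran_Q, df = ivw$Q_df, p = ivw$Q_p),
       loo = loo,
       presso_global_p = (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1),
       simple_mode = mr_simple_mode(rows, seed = seed))
}

#' Run the full MR analysis for one exposure
#'
#' Instrument selection, LD clumping, harmonization, Steiger filtering, then
#' IVW, Egger, weighted median and the sensitivity suite.
#'
#' @param exposure,outcome GWAS summary data.frames (synthetic-data schema).
#' @param ld_matrix SNP x SNP r matrix.
#' @param p_thresh,f_min instrument selection parameters.
#' @param r2_max,window_kb clumping parameters.
#' @param seed integer seed.
#' @return List: `instruments` (final rows), `estimates` (data.frame of all
#'   methods), `sensitivity`, `log` (counts at each filtering step).
#' @export
mr_analysis <- function(exposure, outcome, ld_matrix = NULL,
                        p_thresh = 1e-5, f_min = 10,
                        r2_max = 0.001, window_kb = 10000, seed = 1L) {
  sel <- select_instruments(exposure, p_thresh, f_min)
  clumped <- if (!is.null(ld_matrix))
    ld_clump(sel, ld_matrix, r2_max, window_kb) else sel
  harm <- harmonize(clumped, outcome, outcome_p_thresh = p_thresh)
  st <- steiger_filter(harm)
  rows <- st$kept
  if (nrow(rows) < 3)
    stop("fewer than 3 instruments survive filtering (", nrow(rows), ")")
  est <- rbind(
    mr_ivw(rows)[, c("method", "beta", "se", "p")],
    mr_egger(rows)[, c("method", "beta", "se", "p")],
    mr_weighted_median(rows, seed = seed)[, c("method", "beta", "se", "p")])
  sens <- mr_sensitivity(rows, seed = seed)
  est <- rbind(est, sens$simple_mode[, c("method", "beta", "se", "p")])
  list(instruments = rows, estimates = est, sensitivity = sens,
       log = c(selected = nrow(sel), clumped = nrow(clumped),
               harmonized = nrow(harm), steiger = nrow(rows)))
}
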