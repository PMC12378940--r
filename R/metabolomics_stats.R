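# Normalization, OPLS-DA with permutation validation, VIP scoring, and
# univariate differential-metabolite screening.

#' Internal-standard normalization with RSD-based filtering
#'
#' Each sample's intensities are divided by that sample's internal-standard
#' level (the mean over retained IS features). Internal standards whose
#' cross-sample relative standard deviation exceeds `rsd_cutoff` are excluded
#' from the normalizer. Optionally, features whose RSD across QC samples
#' exceeds `qc_rsd_cutoff` are removed after normalization.
#'
#' @param x feature x sample intensity matrix (rownames = feature IDs).
#' @param internal_standard_ids feature IDs of the internal standards; they
#'   are removed from the returned matrix.
#' @param qc_sample_ids optional sample IDs (colnames) of QC injections used
#'   for the feature-level RSD filter.
#' @param rsd_cutoff maximum cross-sample RSD for an IS to be used.
#' @param qc_rsd_cutoff maximum QC RSD for a feature to be kept.
#' @return List: `normalized` (matrix without IS rows), `is_used`,
#'   `is_dropped`, `features_dropped` (QC filter casualties).
#' @export
normalize_intensities <- function(x, internal_standard_ids,
                                  qc_sample_ids = NULL,
                                  rsd_cutoff = 0.3, qc_rsd_cutoff = 0.3) {
  if (!all(internal_standard_ids %in% rownames(x)))
    stop("internal standards absent from matrix: ",
         paste(setdiff(internal_standard_ids, rownames(x)), collapse = ", "))
  is_mat <- x[internal_standard_ids, , drop = FALSE]
  rsd <- apply(is_mat, 1, function(v) stats::sd(v) / mean(v))
  keep_is <- internal_standard_ids[rsd <= rsd_cutoff]
  if (!length(keep_is))
    stop("all internal standards exceed the RSD cutoff (", rsd_cutoff, ")")
  normalizer <- colMeans(x[keep_is, , drop = FALSE])
  out <- sweep(x[setdiff(rownames(x), internal_standard_ids), , drop = FALSE],
               2, normalizer, "/")
  dropped_feat <- character()
  if (!is.null(qc_sample_ids)) {
    if (!all(qc_sample_ids %in% colnames(out)))
      stop("unknown QC sample IDs")
    qc_rsd <- apply(out[, qc_sample_ids, drop = FALSE], 1,
                    function(v) stats::sd(v) / mean(v))
    dropped_feat <- rownames(out)[qc_rsd > qc_rsd_cutoff]
    out <- out[!rownames(out) %in% dropped_feat, , drop = FALSE]
  }
  list(normalized = out, is_used = keep_is,
       is_dropped = setdiff(internal_standard_ids, keep_is),
       features_dropped = dropped_feat)
}

# Autoscale columns; returns scaled matrix plus the centering/scaling
# parameters so held-out samples can be projected identically.
autoscale <- function(X, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) scale <- apply(X, 2, stats::sd)
  list(X = sweep(sweep(X, 2, center, "-"), 2, scale, "/"),
       center = center, scale = scale)
}

# Core OPLS fit on an already-scaled matrix and centered y. One predictive
# component; n_ortho orthogonal components removed first (Trygg-Wold NIPALS
# for a single response).
opls_core <- function(Xs, yc, n_ortho) {
  W_o <- P_o <- NULL
  Xd <- Xs
  for (a in seq_len(n_ortho)) {
    w <- drop(crossprod(Xd, yc)); w <- w / sqrt(sum(w^2))
    t_ <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t_)) / sum(t_^2)
    w_o <- p - sum(w * p) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break   # no orthogonal variation left
    w_o <- w_o / nw
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o)
  }
  w <- drop(crossprod(Xd, yc)); w <- w / sqrt(sum(w^2))
  t_ <- drop(Xd %*% w)
  p <- drop(crossprod(Xd, t_)) / sum(t_^2)
  c_ <- sum(yc * t_) / sum(t_^2)
  list(w = w, t = t_, p = p, c = c_, W_ortho = W_o, P_ortho = P_o,
       t_ortho = if (is.null(W_o)) NULL else Xs %*% W_o)
}

# Project new (already-scaled) rows through the fitted orthogonal filter and
# return predicted y on the centered scale.
opls_predict_core <- function(fit, Xs) {
  if (!is.null(fit$W_ortho)) {
    for (a in seq_len(ncol(fit$W_ortho))) {
      t_o <- drop(Xs %*% fit$W_ortho[, a])
      Xs <- Xs - tcrossprod(t_o, fit$P_ortho[, a])
    }
  }
  drop(Xs %*% fit$w) * fit$c
}

#' Fit an OPLS-DA model (one predictive component)
#'
#' Features are centered and unit-variance scaled internally; the class is
#' encoded 0/1 and centered. Orthogonal (class-unrelated) variation is
#' deflated before the single predictive component is extracted. R2Y is the
#' fraction of class variance explained; Q2 its cross-validated counterpart
#' from stratified k-fold prediction residuals (PRESS).
#'
#' @param X sample x feature numeric matrix.
#' @param y binary class vector (factor, 0/1, or two-level character).
#' @param n_ortho number of orthogonal components (default 1).
#' @param cv_folds folds for Q2 (stratified by class).
#' @param seed seed for the fold assignment.
#' @return An `opls_model`: scores/weights/loadings, `R2Y`, `Q2`, `vip`,
#'   and the preprocessing parameters.
#' @export
fit_oplsda <- function(X, y, n_ortho = 1L, cv_folds = 7L, seed = 1L) {
  X <- as.matrix(X)
  y01 <- encode_binary(y)
  if (min(table(y01)) < 2) stop("need at least 2 samples per class")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " constant feature(s)")
    X <- X[, sds > 0, drop = FALSE]
  }
  if (n_ortho >= qr(scale(X))$rank)
    stop("n_ortho must be below the rank of the scaled matrix")
  sc <- autoscale(X)
  yc <- y01 - mean(y01)
  fit <- opls_core(sc$X, yc, n_ortho)
  ss_y <- sum(yc^2)
  R2Y <- 1 - sum((yc - fit$t * fit$c)^2) / ss_y

  # stratified CV for Q2
  folds <- stratified_folds(y01, cv_folds, seed = derive_seed(seed, "cv"))
  press <- 0
  for (k in sort(unique(folds))) {
    tr <- folds != k; te <- !tr
    sck <- autoscale(X[tr, , drop = FALSE])
    yk <- y01[tr] - mean(y01[tr])
    fk <- opls_core(sck$X, yk, n_ortho)
    Xte <- autoscale(X[te, , drop = FALSE], sck$center, sck$scale)$X
    pred <- opls_predict_core(fk, Xte) + mean(y01[tr])
    press <- press + sum((y01[te] - pred)^2)
  }
  Q2 <- 1 - press / ss_y

  model <- structure(list(
    scores = fit$t, weights = fit$w, loadings = fit$p, c = fit$c,
    ortho_scores = fit$t_ortho, ortho_weights = fit$W_ortho,
    ortho_loadings = fit$P_ortho,
    R2Y = R2Y, Q2 = Q2, n_ortho = n_ortho,
    preprocessing = list(center = sc$center, scale = sc$scale),
    features = colnames(X), y = y01), class = "opls_model")
  model$vip <- vip_scores(model)
  model
}

encode_binary <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  u <- sort(unique(y))
  if (length(u) != 2) stop("y must have exactly two levels")
  as.numeric(y == u[2])   # second level (alphabetical) coded 1
}

stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("OPLS-DA model: 1 predictive + %d orthogonal component(s)\n",
              x$n_ortho))
  cat(sprintf("  %d features, %d samples\n", length(x$weights),
              length(x$scores)))
  cat(sprintf("  R2Y = %.3f, Q2 = %.3f\n", x$R2Y, x$Q2))
  invisible(x)
}

#' VIP scores of a fitted OPLS-DA model
#'
#' Variable importance in projection over the predictive component(s):
#' `VIP_j = sqrt(p * sum_a(w_ja^2 * SSY_a) / sum_a SSY_a)` with normalized
#' weights, so the mean squared VIP over features is exactly 1.
#'
#' @param model an `opls_model`.
#' @return Named numeric vector of VIP values (one per feature).
#' @export
vip_scores <- function(model) {
  w <- model$weights
  p <- length(w)
  # single predictive component: the SSY weighting cancels
  vip <- sqrt(p * w^2 / sum(w^2))
  names(vip) <- model$features
  vip
}

#' Permutation validation of an OPLS-DA model
#'
#' The class labels are permuted `n_perm` times and the model refit each
#' time; the p-value for a statistic is `(1 + #{perm >= observed}) /
#' (n_perm + 1)`.
#'
#' @param model the fitted `opls_model` (supplies observed R2Y/Q2 and
#'   the component count).
#' @param X,y the data the model was fit to.
#' @param n_perm number of permutations (>= 1; < 10 draws a warning).
#' @param seed integer seed.
#' @return List: `p_R2Y`, `p_Q2`, and `perm_stats` (data.frame with the
#'   permuted R2Y and Q2 values).
#' @export
permutation_test <- function(model, X, y, n_perm = 200L, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  if (n_perm < 10) warning("n_perm < 10 gives a very coarse p-value")
  set.seed(derive_seed(seed, "permutation"))
  y01 <- encode_binary(y)
  stats_perm <- matrix(NA_real_, n_perm, 2,
                       dimnames = list(NULL, c("R2Y", "Q2")))
  for (b in seq_len(n_perm)) {
    yp <- sample(y01)
    m <- fit_oplsda(X, yp, n_ortho = model$n_ortho, seed = b)
    stats_perm[b, ] <- c(m$R2Y, m$Q2)
  }
  list(p_R2Y = (1 + sum(stats_perm[, "R2Y"] >= model$R2Y)) / (n_perm + 1),
       p_Q2 = (1 + sum(stats_perm[, "Q2"] >= model$Q2)) / (n_perm + 1),
       perm_stats = as.data.frame(stats_perm))
}

#' Screen differential metabolites by VIP and univariate t-test
#'
#' A feature passes when `VIP > vip_threshold` and its two-sided t-test p is
#' below `p_threshold`. Fold change is case mean over control mean on the
#' normalized intensities; zero intensities are imputed as half the smallest
#' non-zero value of the feature before the ratio is formed.
#'
#' @param x feature x sample normalized intensity matrix.
#' @param y class vector over samples; the `case_level` group is the fold-
#'   change numerator.
#' @param vip named VIP vector covering the features of `x`.
#' @param vip_threshold,p_threshold screening thresholds (positive). The
#'   conventional screen uses VIP > 1.0; `preset = "strict"` raises it
#'   to 1.5.
#' @param case_level value of `y` treated as the case group (default "DD").
#' @param welch use Welch instead of pooled-variance t-test.
#' @param preset `"default"` (VIP > 1.0) or `"strict"` (VIP > 1.5);
#'   an explicit `vip_threshold` wins.
#' @return data.frame: feature, mean_case, mean_control, fc, log2fc, p, vip,
#'   direction ("up"/"down"), passes_screen.
#' @export
screen_differentials <- function(x, y, vip, vip_threshold = NULL,
                                 p_threshold = 0.05, case_level = "DD",
                                 welch = FALSE,
                                 preset = c("default", "strict")) {
  preset <- match.arg(preset)
  if (is.null(vip_threshold))
    vip_threshold <- if (preset == "strict") 1.5 else 1.0
  if (vip_threshold <= 0 || p_threshold < 0)
    stop("vip_threshold must be positive and p_threshold non-negative")
  if (!all(rownames(x) %in% names(vip)))
    stop("vip must cover every feature of x")
  case <- y == case_level
  if (!any(case) || all(case)) stop("case_level must split the samples")
  res <- lapply(rownames(x), function(f) {
    v <- x[f, ]
    if (any(v == 0)) {
      nz <- min(v[v > 0])
      v[v == 0] <- nz / 2
    }
    a <- v[case]; b <- v[!case]
    p <- if (stats::sd(a) == 0 && stats::sd(b) == 0) 1 else
      stats::t.test(a, b, var.equal = !welch)$p.value
    fc <- mean(a) / mean(b)
    data.frame(feature = f, mean_case = mean(a), mean_control = mean(b),
               fc = fc, log2fc = log2(fc), p = p, vip = unname(vip[f]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  out$passes_screen <- out$vip > vip_threshold & out$p < p_threshold
  out
}
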