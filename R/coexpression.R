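# Weighted metabolite co-expression analysis: variance filter, soft
# threshold by scale-free fit, topological overlap, module detection with
# eigengene merging, and MM/GS hub screening. Matrices are feature x sample
# throughout, matching the abundance tables.

#' Keep the most variable features
#'
#' @param x feature x sample matrix.
#' @param frac fraction of features to keep, ranked by variance (0 < frac <= 1).
#' @return The filtered matrix.
#' @export
filter_top_variance <- function(x, frac = 0.5) {
  stopifnot(frac > 0, frac <= 1)
  v <- apply(x, 1, stats::var)
  keep <- rank(-v, ties.method = "first") <= ceiling(frac * nrow(x))
  x[keep, , drop = FALSE]
}

# Unsigned weighted adjacency |cor|^beta with zero diagonal.
soft_adjacency <- function(x, beta, network_sign = c("unsigned", "signed")) {
  network_sign <- match.arg(network_sign)
  r <- stats::cor(t(x))
  a <- if (network_sign == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
  diag(a) <- 0
  a
}

# Signed scale-free topology fit: R^2 of log10(freq) ~ log10(k) over
# connectivity bins, negated when the slope is positive (a scale-free
# network has a negative slope).
scale_free_fit <- function(k, n_bins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 3 || diff(range(k)) < 1e-8) return(NA_real_)
  bins <- cut(k, breaks = n_bins)
  freq <- tapply(k, bins, length)
  mean_k <- tapply(k, bins, mean)
  ok <- !is.na(freq) & freq > 0
  if (sum(ok) < 3) return(NA_real_)
  fit <- stats::lm(log10(freq[ok]) ~ log10(mean_k[ok]))
  r2 <- summary(fit)$r.squared
  -sign(stats::coef(fit)[2]) * r2
}

#' Choose a soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the unsigned adjacency `|cor|^beta` is formed,
#' connectivities `k_i = sum_j a_ij` computed, and the signed scale-free fit
#' index evaluated. The smallest power reaching `target_r2` is returned; if
#' none reaches it, the power with the best fit is returned with a warning.
#'
#' @param x feature x sample matrix (already variance-filtered).
#' @param candidates integer powers to try.
#' @param target_r2 required scale-free fit index (e.g. 0.6).
#' @param network_sign `"unsigned"` (default) or `"signed"`.
#' @return List: `beta` (chosen power), `fit_table` (data.frame beta, fit,
#'   mean_k), `reached` (logical).
#' @export
pick_soft_threshold <- function(x, candidates = 1:20, target_r2 = 0.6,
                                network_sign = "unsigned") {
  if (nrow(x) < 20) stop("need at least 20 features after filtering")
  if (any(apply(x, 1, stats::sd) == 0)) stop("constant features present")
  fits <- vapply(candidates, function(b) {
    a <- soft_adjacency(x, b, network_sign)
    k <- rowSums(a)
    c(scale_free_fit(k), mean(k))
  }, numeric(2))
  tab <- data.frame(beta = candidates, fit = fits[1, ], mean_k = fits[2, ])
  ok <- which(!is.na(tab$fit) & tab$fit >= target_r2)
  if (length(ok)) {
    beta <- candidates[ok[1]]; reached <- TRUE
  } else {
    if (all(is.na(tab$fit))) {
      warning("scale-free fit degenerate for every candidate power; ",
              "falling back to the smallest candidate")
      beta <- candidates[1]
    } else {
      warning("no candidate power reaches target_r2 = ", target_r2,
              "; using the best fit")
      beta <- candidates[which.max(tab$fit)]
    }
    reached <- FALSE
  }
  list(beta = beta, fit_table = tab, reached = reached)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `TOM_ii = 1`; shared neighbours raise the similarity beyond the direct
#' adjacency.
#'
#' @param adjacency symmetric matrix with zero diagonal and entries in [0, 1].
#' @return Symmetric TOM matrix with unit diagonal, entries in [0, 1].
#' @export
tom_similarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (!isSymmetric(unname(a), tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(diag(a) != 0)) stop("adjacency diagonal must be zero")
  if (any(a < 0) || any(a > 1)) stop("adjacency entries must lie in [0, 1]")
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  tom
}

#' Detect co-expression modules from a TOM dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM` with a static cut (a
#' simplified stand-in for dynamic tree cutting): by default the tree is cut
#' in the middle of the largest gap between consecutive merge heights in the
#' upper half of the tree, the point where tight clusters stop and
#' between-cluster joins begin. Clusters below `min_size` are sent to grey
#' (unassigned). When the expression matrix is supplied, modules whose
#' eigengenes are closer than `merge_height` (on the `1 - cor` scale) are
#' merged iteratively. Modules are labelled with the conventional colour
#' names in decreasing size order.
#'
#' @param dissim square dissimilarity matrix (`1 - TOM`).
#' @param x optional feature x sample matrix for eigengene merging.
#' @param min_size minimum features per module.
#' @param merge_height eigengene-dissimilarity threshold below which two
#'   modules merge (0 disables merging).
#' @param cut `"gap"` (largest merge-height gap, default) or `"quantile"`.
#' @param cut_quantile quantile of tree heights for `cut = "quantile"`.
#' @return Named character vector: module label per feature ("grey" =
#'   unassigned).
#' @export
detect_modules <- function(dissim, x = NULL, min_size = 10L,
                           merge_height = 0.25, cut = c("gap", "quantile"),
                           cut_quantile = 0.99) {
  cut <- match.arg(cut)
  n <- nrow(dissim)
  feat <- rownames(dissim)
  if (is.null(feat)) feat <- paste0("f", seq_len(n))
  if (n < min_size) {
    warning("fewer features than min_size; all features unassigned")
    return(stats::setNames(rep("grey", n), feat))
  }
  hc <- stats::hclust(stats::as.dist(dissim), method = "average")
  hs <- sort(hc$height)
  h <- if (cut == "quantile") {
    stats::quantile(hs, cut_quantile)
  } else {
    upper <- hs[hs >= stats::median(hs)]
    if (length(upper) < 2) {
      max(hs)                     # degenerate flat tree: one cluster
    } else {
      gaps <- diff(upper)
      upper[which.max(gaps)] + max(gaps) / 2
    }
  }
  cl <- stats::cutree(hc, h = h)
  sizes <- table(cl)
  cl[cl %in% as.integer(names(sizes)[sizes < min_size])] <- 0L

  if (!is.null(x) && merge_height > 0) cl <- merge_close_modules(
    cl, x, merge_height)

  label_modules(cl, feat)
}

# Iteratively merge the closest pair of module eigengenes while their
# dissimilarity 1 - cor(ME_a, ME_b) is below the threshold.
merge_close_modules <- function(cl, x, merge_height) {
  repeat {
    mods <- setdiff(unique(cl), 0L)
    if (length(mods) < 2) break
    labels <- stats::setNames(as.character(cl), rownames(x))
    me <- module_eigengene(x, labels)
    me <- me[, colnames(me) != "0", drop = FALSE]
    d <- 1 - stats::cor(me)
    diag(d) <- Inf
    if (min(d) >= merge_height) break
    ij <- which(d == min(d), arr.ind = TRUE)[1, ]
    a <- as.integer(colnames(d)[ij[1]]); b <- as.integer(colnames(d)[ij[2]])
    cl[cl == b] <- a
  }
  cl
}

module_colours <- function() c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan", "midnightblue",
  "lightcyan", "grey60", "lightgreen", "lightyellow", "royalblue")

label_modules <- function(cl, feat) {
  out <- rep("grey", length(cl))
  mods <- setdiff(unique(cl), 0L)
  if (length(mods)) {
    sizes <- vapply(mods, function(m) sum(cl == m), integer(1))
    ord <- mods[order(-sizes)]
    pal <- module_colours()
    labs <- c(pal, paste0("module", seq_len(max(0, length(ord) - length(pal)))))
    for (i in seq_along(ord)) out[cl == ord[i]] <- labs[i]
  }
  stats::setNames(out, feat)
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal-component score across
#' samples of the module's standardized feature profiles, scaled to unit
#' variance and sign-aligned so it correlates non-negatively with the module
#' mean profile. A single-feature module returns that feature standardized.
#'
#' @param x feature x sample matrix.
#' @param labels named module label per feature ("grey" skipped).
#' @return sample x module numeric matrix of eigengenes.
#' @export
module_eigengene <- function(x, labels) {
  mods <- setdiff(unique(labels), "grey")
  if (!length(mods)) stop("no modules to summarize")
  me <- sapply(mods, function(m) {
    sub <- x[names(labels)[labels == m], , drop = FALSE]
    z <- t(scale(t(sub)))            # standardize each feature profile
    if (nrow(z) == 1) return(drop(z))
    sv <- svd(t(z), nu = 1, nv = 0)
    e <- drop(sv$u)
    e <- e / stats::sd(e)
    if (stats::cor(e, colMeans(z)) < 0) e <- -e
    e
  })
  colnames(me) <- mods
  rownames(me) <- colnames(x)
  me
}

# p-value of a Pearson correlation via the t transform, two-sided.
cor_pval <- function(r, n) {
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  t_ <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t_), df = n - 2)
}

#' Hub-metabolite screen by module membership and trait significance
#'
#' `MM` is the correlation of a feature with its own module's eigengene,
#' `GS` the absolute correlation with the trait; p-values come from the
#' t transform of `r`. A feature is a hub when `MM > mm_min`,
#' `GS > gs_min`, both p-values are below `p_max`, and its module's
#' eigengene-trait correlation is itself significant (p < 0.05).
#'
#' @param x feature x sample matrix.
#' @param me sample x module eigengene matrix from [module_eigengene()].
#' @param labels named module label per feature.
#' @param trait numeric or 0/1 trait per sample (cases coded 1).
#' @param mm_min,gs_min,p_max screen thresholds.
#' @return data.frame per feature: module, MM, p_MM, GS, p_GS,
#'   module_trait_cor, module_trait_p, hub.
#' @export
mm_gs_screen <- function(x, me, labels, trait, mm_min = 0.7, gs_min = 0.2,
                         p_max = 0.05) {
  n <- ncol(x)
  if (n <= 3) stop("need more than 3 samples for correlation p-values")
  trait <- as.numeric(trait)
  mt_cor <- stats::cor(me, trait)
  mt_p <- cor_pval(mt_cor, n)
  res <- lapply(rownames(x), function(f) {
    mod <- unname(labels[f])
    if (is.na(mod) || mod == "grey")
      return(data.frame(feature = f, module = "grey", MM = NA_real_,
                        p_MM = NA_real_, GS = NA_real_, p_GS = NA_real_,
                        module_trait_cor = NA_real_, module_trait_p = NA_real_,
                        hub = FALSE, stringsAsFactors = FALSE))
    mm <- stats::cor(x[f, ], me[, mod])
    gs_signed <- stats::cor(x[f, ], trait)
    gs <- abs(gs_signed)
    p_mm <- cor_pval(mm, n); p_gs <- cor_pval(gs_signed, n)
    data.frame(feature = f, module = mod, MM = mm, p_MM = p_mm, GS = gs,
               p_GS = p_gs, module_trait_cor = mt_cor[mod, 1],
               module_trait_p = mt_p[mod, 1],
               hub = mm > mm_min && gs > gs_min && p_mm < p_max &&
                 p_gs < p_max && mt_p[mod, 1] < 0.05,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Run the full co-expression analysis on one abundance matrix
#'
#' Convenience wrapper: variance filter, soft-threshold selection, TOM,
#' module detection with eigengene merging, and the MM/GS hub screen.
#'
#' @param x feature x sample matrix (normalized intensities; log applied
#'   internally when `log_transform`).
#' @param trait per-sample trait (cases = 1).
#' @param keep_frac variance-filter fraction.
#' @param candidates soft-threshold candidates.
#' @param target_r2 scale-free fit target.
#' @param min_size,merge_height module parameters.
#' @param log_transform log the intensities first (default TRUE).
#' @return List: `beta`, `fit_table`, `labels`, `eigengenes`, `screen`
#'   (the MM/GS table), `hubs` (hub feature IDs).
#' @export
coexpression_analysis <- function(x, trait, keep_frac = 0.5,
                                  candidates = 1:12, target_r2 = 0.6,
                                  min_size = 10L, merge_height = 0.25,
                                  log_transform = TRUE) {
  if (log_transform) x <- log(x)
  x <- filter_top_variance(x, keep_frac)
  st <- pick_soft_threshold(x, candidates, target_r2)
  adj <- soft_adjacency(x, st$beta)
  tom <- tom_similarity(adj)
  dimnames(tom) <- dimnames(adj)
  labels <- detect_modules(1 - tom, x, min_size, merge_height)
  if (all(labels == "grey"))
    return(list(beta = st$beta, fit_table = st$fit_table, labels = labels,
                eigengenes = NULL, screen = NULL, hubs = character()))
  me <- module_eigengene(x, labels)
  screen <- mm_gs_screen(x, me, labels, trait)
  list(beta = st$beta, fit_table = st$fit_table, labels = labels,
       eigengenes = me, screen = screen,
       hubs = screen$feature[screen$hub])
}
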