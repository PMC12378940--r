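#' @title Ground-truth descriptors for synthetic data
#' @description Constructors for the truth objects consumed by the synthetic
#'   generators. Truth objects carry everything needed to verify a downstream
#'   result against what was planted.
#' @name truth
NULL

#' Describe the planted structure of a synthetic metabolome
#'
#' @param diff_features character vector of feature IDs that receive a group
#'   effect (case group shifted on the log scale).
#' @param effect_size standardized mean difference (Cohen's d units) applied
#'   to `diff_features` in the case group.
#' @param module_blocks named list mapping a block label to the character
#'   vector of feature IDs forming one correlated block. Blocks must be
#'   disjoint.
#' @param block_cor target within-block Pearson correlation on the log scale,
#'   in `[0, 1)`. Achieved through a one-factor model per block:
#'   `x = sqrt(r) * factor + sqrt(1 - r) * noise`, so the population
#'   correlation of two block members is exactly `block_cor`.
#' @return An object of class `metabolome_truth`.
#' @export
metabolome_truth <- function(diff_features = character(),
                             effect_size = 0,
                             module_blocks = list(),
                             block_cor = 0) {
  stopifnot(is.numeric(effect_size), length(effect_size) == 1L)
  if (block_cor < 0 || block_cor >= 1)
    stop("block_cor must be in [0, 1)")
  if (length(module_blocks)) {
    all_members <- unlist(module_blocks, use.names = FALSE)
    if (anyDuplicated(all_members))
      stop("module_blocks must be disjoint: duplicated feature IDs ",
           paste(unique(all_members[duplicated(all_members)]), collapse = ", "))
    if (is.null(names(module_blocks)))
      names(module_blocks) <- paste0("block", seq_along(module_blocks))
  }
  structure(list(diff_features = as.character(diff_features),
                 effect_size = effect_size,
                 module_blocks = module_blocks,
                 block_cor = block_cor),
            class = "metabolome_truth")
}

#' Describe the planted structure of a synthetic GWAS pair
#'
#' @param causal_beta true exposure-to-outcome causal effect.
#' @param n_instruments number of SNPs with a real exposure effect (the
#'   remaining SNPs are null).
#' @param pleiotropy_frac fraction of instruments with a direct (horizontal)
#'   outcome effect, in `[0, 1]`.
#' @param pleiotropy_mean mean of the direct effects; non-zero values give
#'   directional pleiotropy that an Egger intercept should detect, zero gives
#'   balanced pleiotropy.
#' @param pleiotropy_sd spread of the direct effects.
#' @param ld_blocks integer vector of LD block sizes (block-diagonal AR(1)
#'   correlation); `NULL` or empty means all SNPs independent.
#' @param ld_rho AR(1) correlation parameter within each LD block.
#' @param weak_instruments if `TRUE`, instrument F statistics are drawn from
#'   roughly 2-30 instead of the default 10-200.
#' @return An object of class `gwas_truth`.
#' @export
gwas_truth <- function(causal_beta = 0,
                       n_instruments = 30L,
                       pleiotropy_frac = 0,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0.05,
                       ld_blocks = NULL,
                       ld_rho = 0.8,
                       weak_instruments = FALSE) {
  if (pleiotropy_frac < 0 || pleiotropy_frac > 1)
    stop("pleiotropy_frac must lie in [0, 1]")
  structure(list(causal_beta = causal_beta,
                 n_instruments = as.integer(n_instruments),
                 pleiotropy_frac = pleiotropy_frac,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 ld_blocks = ld_blocks,
                 ld_rho = ld_rho,
                 weak_instruments = isTRUE(weak_instruments)),
            class = "gwas_truth")
}

# Deterministic seed splitting: every generator derives its own stream from
# one master seed so that stages can be re-run independently yet
# reproducibly. Kept below 2^31 - 1.
derive_seed <- function(seed, stream) {
  offsets <- c(metabolome = 101L, metadata = 211L, gwas = 307L,
               pathways = 401L, matching = 503L, cv = 601L,
               permutation = 701L, bootstrap = 809L, presso = 907L)
  if (!stream %in% names(offsets)) stop("unknown seed stream: ", stream)
  as.integer((as.numeric(seed) * 7919 + offsets[[stream]]) %% 2147483647)
}

#' Generate a synthetic two-group metabolome with known ground truth
#'
#' Log-scale intensities are Gaussian: block members load on a shared latent
#' factor (`sqrt(block_cor)` loading), so the within-block correlation equals
#' `block_cor` in population; features listed in `truth$diff_features` are
#' shifted by `effect_size` log-scale standard deviations in the case (DD)
#' group. Values are exponentiated to positive intensities, emulating the
#' multiplicative error structure of MS peak areas.
#'
#' @param n_per_group samples per group (DD cases and ND controls).
#' @param n_features total number of features; must cover all features named
#'   in `truth`.
#' @param truth a [metabolome_truth()] object.
#' @param seed integer master seed; fixed seed gives identical output.
#' @return A list with `abundance` (feature x sample numeric matrix with
#'   feature IDs as rownames), `metadata` (data.frame: sample_id, group
#'   DD/ND, age, sex, gds_1..gds_30, gds_score), and `truth`.
#' @export
generate_metabolome <- function(n_per_group, n_features,
                                truth = metabolome_truth(), seed = 1L) {
  stopifnot(n_per_group >= 3, n_features >= 1)
  feat_ids <- sprintf("feat_%04d", seq_len(n_features))
  named <- c(truth$diff_features, unlist(truth$module_blocks, use.names = FALSE))
  if (length(named) && !all(named %in% feat_ids))
    stop("truth names features beyond n_features: ",
         paste(utils::head(setdiff(named, feat_ids), 5), collapse = ", "))

  n <- 2L * n_per_group
  group <- rep(c("DD", "ND"), each = n_per_group)
  sample_ids <- sprintf("S%03d", seq_len(n))

  set.seed(derive_seed(seed, "metabolome"))
  r <- truth$block_cor
  logx <- matrix(stats::rnorm(n_features * n), nrow = n_features,
                 dimnames = list(feat_ids, sample_ids))
  for (block in truth$module_blocks) {
    f <- stats::rnorm(n)                       # shared latent factor
    idx <- match(block, feat_ids)
    logx[idx, ] <- sqrt(r) * matrix(f, nrow = length(idx), ncol = n,
                                    byrow = TRUE) +
      sqrt(1 - r) * logx[idx, , drop = FALSE]
  }
  if (length(truth$diff_features) && truth$effect_size != 0) {
    idx <- match(truth$diff_features, feat_ids)
    logx[idx, group == "DD"] <- logx[idx, group == "DD", drop = FALSE] +
      truth$effect_size
  }
  # per-feature baseline log-abundance, then exponentiate to intensities
  base <- stats::runif(n_features, 8, 14)
  abundance <- exp(logx + base)

  metadata <- generate_metadata(group, sample_ids,
                                seed = derive_seed(seed, "metadata"))
  list(abundance = abundance, metadata = metadata, truth = truth)
}

# Sample metadata emulating a community cohort of adults >= 65 y:
# DD cases carry a GDS-30 score > 10, controls <= 10; item responses are
# drawn consistent with the score under the standard GDS keying.
generate_metadata <- function(group, sample_ids, seed = 1L) {
  set.seed(seed)
  n <- length(group)
  age <- round(ifelse(group == "DD", stats::rnorm(n, 72.1, 5.1),
                      stats::rnorm(n, 73.5, 4.5)))
  age <- pmax(65, pmin(95, age))
  sex <- sample(c("male", "female"), n, replace = TRUE, prob = c(0.35, 0.65))
  score <- ifelse(group == "DD",
                  sample(11:25, n, replace = TRUE),
                  sample(0:10, n, replace = TRUE))
  items <- t(vapply(score, gds_items_for_score, integer(30)))
  colnames(items) <- paste0("gds_", 1:30)
  out <- data.frame(sample_id = sample_ids, group = group, age = age,
                    sex = sex, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(items))
  out$gds_score <- score
  out
}

# Draw a 30-item yes(1)/no(0) response vector whose GDS score equals `score`
# under the standard keying (20 positively keyed, 10 reverse-keyed items).
gds_items_for_score <- function(score) {
  stopifnot(score >= 0, score <= 30)
  resp <- integer(30)
  resp[gds_negative_items()] <- 1L       # "yes" on reverse items scores 0
  scoring <- sample(1:30, score)
  resp[intersect(scoring, gds_positive_items())] <- 1L
  resp[intersect(scoring, gds_negative_items())] <- 0L
  resp
}

#' Generate a matched exposure/outcome GWAS summary-statistic pair
#'
#' Instrument exposure effects are drawn so the single-SNP F statistic
#' `(beta/se)^2` spans roughly 10-200 (2-30 under `weak_instruments`);
#' outcome effects follow `beta_out = causal_beta * beta_exp + alpha + e`
#' where `alpha` is a direct (pleiotropic) effect for a
#' `pleiotropy_frac` subset and `e` is sampling noise at the reported
#' standard error. LD is block-diagonal AR(1) when `truth$ld_blocks` is set.
#'
#' @param n_snps total SNPs (instruments first, then null SNPs).
#' @param truth a [gwas_truth()] object.
#' @param n_exposure,n_outcome GWAS sample sizes (positive).
#' @param seed integer master seed.
#' @return A list with `exposure` and `outcome` data.frames (snp,
#'   chromosome, position, effect_allele, other_allele, eaf, beta, se, pval,
#'   n), `ld` (SNP x SNP correlation r matrix), and `truth`.
#' @export
generate_gwas_pair <- function(n_snps, truth = gwas_truth(),
                               n_exposure = 8299L, n_outcome = 494164L,
                               seed = 1L) {
  stopifnot(n_snps >= 3)
  if (n_exposure <= 0 || n_outcome <= 0) stop("sample sizes must be positive")
  n_inst <- min(truth$n_instruments, n_snps)
  set.seed(derive_seed(seed, "gwas"))

  snp <- sprintf("rs%06d", sort(sample.int(999999, n_snps)))
  chromosome <- rep(1L, n_snps)
  position <- sort(sample.int(250e6, n_snps))
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pick <- pairs[sample.int(nrow(pairs), n_snps, replace = TRUE), , drop = FALSE]
  eaf <- stats::runif(n_snps, 0.05, 0.95)

  se_exp <- 1 / sqrt(n_exposure * 2 * eaf * (1 - eaf))
  f_target <- if (truth$weak_instruments) stats::runif(n_inst, 2, 30)
              else stats::runif(n_inst, 10, 200)
  beta_exp <- numeric(n_snps)
  beta_exp[seq_len(n_inst)] <- sqrt(f_target) * se_exp[seq_len(n_inst)] *
    sample(c(-1, 1), n_inst, replace = TRUE)
  beta_exp_hat <- beta_exp + stats::rnorm(n_snps, 0, se_exp)
  p_exp <- 2 * stats::pnorm(-abs(beta_exp_hat / se_exp))

  alpha <- numeric(n_snps)
  n_pleio <- round(truth$pleiotropy_frac * n_inst)
  if (n_pleio > 0) {
    which_pleio <- sample(seq_len(n_inst), n_pleio)
    # direct effects are directional with respect to the exposure-increasing
    # allele (the orientation Egger regression works in)
    alpha[which_pleio] <- stats::rnorm(n_pleio, truth$pleiotropy_mean,
                                       truth$pleiotropy_sd) *
      sign(beta_exp[which_pleio])
  }
  se_out <- 1 / sqrt(n_outcome * 2 * eaf * (1 - eaf))
  beta_out <- truth$causal_beta * beta_exp + alpha +
    stats::rnorm(n_snps, 0, se_out)
  p_out <- 2 * stats::pnorm(-abs(beta_out / se_out))

  ld <- diag(n_snps)
  if (length(truth$ld_blocks)) {
    stopifnot(sum(truth$ld_blocks) <= n_snps)
    at <- 1L
    for (b in truth$ld_blocks) {
      idx <- at:(at + b - 1L)
      ld[idx, idx] <- truth$ld_rho ^ abs(outer(seq_len(b), seq_len(b), "-"))
      at <- at + b
    }
  }
  dimnames(ld) <- list(snp, snp)

  mk <- function(beta, se, p, n) data.frame(
    snp = snp, chromosome = chromosome, position = position,
    effect_allele = pick[, 1], other_allele = pick[, 2], eaf = eaf,
    beta = beta, se = se, pval = p, n = n, stringsAsFactors = FALSE)
  list(exposure = mk(beta_exp_hat, se_exp, p_exp, n_exposure),
       outcome = mk(beta_out, se_out, p_out, n_outcome),
       ld = ld, truth = truth)
}

#' Generate a toy pathway database with graphs and a name-to-ID mapping
#'
#' Compound IDs follow the KEGG `C#####` pattern; every set member is a node
#' of the pathway's graph, so impact scores are well defined.
#'
#' @param n_pathways number of pathways.
#' @param size_range integer length-2 vector: min and max compounds per
#'   pathway (each >= 2).
#' @param graph_model `"path"` (linear chain), `"star"` (hub plus leaves) or
#'   `"random_tree"` (uniform random spanning tree).
#' @param seed integer master seed.
#' @return A `pathway_db` object: `sets` (named list of compound-ID vectors),
#'   `graphs` (named list of two-column edge data.frames), `mapping`
#'   (data.frame name, kegg_id), `universe` (all compound IDs).
#' @export
generate_pathway_db <- function(n_pathways, size_range = c(4L, 10L),
                                graph_model = c("path", "star", "random_tree"),
                                seed = 1L) {
  graph_model <- match.arg(graph_model)
  stopifnot(length(size_range) == 2, size_range[1] >= 2,
            size_range[2] >= size_range[1])
  set.seed(derive_seed(seed, "pathways"))
  sizes <- size_range[1] +
    sample.int(size_range[2] - size_range[1] + 1L, n_pathways,
               replace = TRUE) - 1L
  total <- sum(sizes)
  ids <- sprintf("C%05d", sample.int(99999, total))
  sets <- list(); graphs <- list(); at <- 1L
  for (i in seq_len(n_pathways)) {
    pid <- sprintf("map%05d", i)
    members <- ids[at:(at + sizes[i] - 1L)]; at <- at + sizes[i]
    sets[[pid]] <- members
    graphs[[pid]] <- toy_graph(members, graph_model)
  }
  mapping <- data.frame(name = paste0("compound_", sub("^C", "", ids)),
                        kegg_id = ids, stringsAsFactors = FALSE)
  pathway_db(sets, graphs, mapping)
}

toy_graph <- function(nodes, model) {
  m <- length(nodes)
  edges <- switch(model,
    path = cbind(nodes[-m], nodes[-1]),
    star = cbind(rep(nodes[1], m - 1L), nodes[-1]),
    random_tree = {
      # uniform attachment tree: node i attaches to a random earlier node
      parent <- vapply(2:m, function(i) sample.int(i - 1L, 1L), integer(1))
      cbind(nodes[parent], nodes[2:m])
    })
  data.frame(node1 = edges[, 1], node2 = edges[, 2], stringsAsFactors = FALSE)
}

#' Generate a synthetic participant roster for screening and matching
#'
#' Emulates a community recruitment flow: `n_total` participants with
#' exclusion flags planted in disjoint sets of the given sizes, and, among
#' the eligible, exactly `n_depressed` with a GDS-30 score above 10. Control
#' ages/sexes are drawn so that every depressed case has at least one
#' same-sex control within 3 years (matching is feasible by construction).
#'
#' @param n_total roster size before exclusions.
#' @param n_excluded named integer vector: planted counts failing the
#'   questionnaire, antidepressant and blood-sample criteria (disjoint).
#' @param n_depressed number of eligible participants with GDS score > 10.
#' @param seed integer seed.
#' @return data.frame: id, age, sex, questionnaire_complete,
#'   on_antidepressant, has_blood_sample, gds_1..gds_30, gds_score,
#'   depressed.
#' @export
generate_roster <- function(n_total = 379L,
                            n_excluded = c(questionnaire = 8L,
                                           antidepressant = 2L,
                                           blood_sample = 1L),
                            n_depressed = 49L, seed = 1L) {
  stopifnot(sum(n_excluded) + n_depressed <= n_total)
  set.seed(derive_seed(seed, "metadata"))
  n_eligible <- n_total - sum(n_excluded)
  id <- sprintf("P%04d", seq_len(n_total))
  sex <- sample(c("male", "female"), n_total, replace = TRUE,
                prob = c(0.35, 0.65))
  age <- pmax(65, pmin(95, round(stats::rnorm(n_total, 73, 5))))

  excl_idx <- sample.int(n_total, sum(n_excluded))
  q_idx <- excl_idx[seq_len(n_excluded[["questionnaire"]])]
  a_idx <- excl_idx[n_excluded[["questionnaire"]] +
                    seq_len(n_excluded[["antidepressant"]])]
  b_idx <- excl_idx[n_excluded[["questionnaire"]] +
                    n_excluded[["antidepressant"]] +
                    seq_len(n_excluded[["blood_sample"]])]
  eligible_idx <- setdiff(seq_len(n_total), excl_idx)
  dep_idx <- sample(eligible_idx, n_depressed)
  # guarantee an admissible match: each case gets a same-sex twin control
  ctl_idx <- setdiff(eligible_idx, dep_idx)
  twins <- sample(ctl_idx, n_depressed)
  sex[twins] <- sex[dep_idx]
  age[twins] <- age[dep_idx] + sample(-3:3, n_depressed, replace = TRUE)

  score <- integer(n_total)
  score[dep_idx] <- sample(11:25, n_depressed, replace = TRUE)
  score[-dep_idx] <- sample(0:10, n_total - n_depressed, replace = TRUE)
  items <- t(vapply(score, gds_items_for_score, integer(30)))
  colnames(items) <- paste0("gds_", 1:30)

  out <- data.frame(id = id, age = age, sex = sex,
                    questionnaire_complete = TRUE, on_antidepressant = FALSE,
                    has_blood_sample = TRUE, stringsAsFactors = FALSE)
  out$questionnaire_complete[q_idx] <- FALSE
  out$on_antidepressant[a_idx] <- TRUE
  out$has_blood_sample[b_idx] <- FALSE
  out <- cbind(out, as.data.frame(items))
  out$gds_score <- score
  out$depressed <- score > 10
  out
}

#' Write the synthetic inputs to plain-text files
#'
#' Emits the standard on-disk formats consumed by the pipeline readers:
#' abundance TSV (column 1 = feature ID), metadata CSV, exposure/outcome
#' GWAS TSVs, GMT, per-pathway edge-list TSVs, mapping TSV and a truth JSON.
#'
#' @param sim result of [generate_metabolome()].
#' @param gwas result of [generate_gwas_pair()] or `NULL`.
#' @param db result of [generate_pathway_db()] or `NULL`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_synthetic_inputs <- function(sim, gwas = NULL, db = NULL, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character()
  w <- function(x, f, sep) {
    path <- file.path(dir, f)
    utils::write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  ab <- data.frame(feature_id = rownames(sim$abundance), sim$abundance,
                   check.names = FALSE, stringsAsFactors = FALSE)
  w(ab, "abundance.tsv", "\t")
  w(sim$metadata, "metadata.csv", ",")
  if (!is.null(gwas)) {
    w(gwas$exposure, "exposure_gwas.tsv", "\t")
    w(gwas$outcome, "outcome_gwas.tsv", "\t")
    ld_long <- data.frame(snp_a = rep(rownames(gwas$ld), ncol(gwas$ld)),
                          snp_b = rep(colnames(gwas$ld), each = nrow(gwas$ld)),
                          r = as.vector(gwas$ld))
    ld_long <- ld_long[ld_long$snp_a < ld_long$snp_b & ld_long$r != 0, ]
    w(ld_long, "ld.tsv", "\t")
  }
  if (!is.null(db)) {
    gmt <- file.path(dir, "pathways.gmt")
    writeLines(vapply(names(db$sets), function(p)
      paste(c(p, p, db$sets[[p]]), collapse = "\t"), character(1)), gmt)
    files <- c(files, gmt)
    gdir <- file.path(dir, "graphs")
    if (!dir.exists(gdir)) dir.create(gdir)
    for (p in names(db$graphs)) {
      path <- file.path(gdir, paste0(p, ".tsv"))
      utils::write.table(db$graphs[[p]], path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      files <- c(files, path)
    }
    w(db$mapping, "kegg_mapping.tsv", "\t")
  }
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(metabolome = unclass(sim$truth),
                            gwas = if (!is.null(gwas)) unclass(gwas$truth)),
                       truth_path, auto_unbox = TRUE, null = "null")
  files <- c(files, truth_path)
  invisible(files)
}
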