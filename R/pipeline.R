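# End-to-end orchestration: configuration, input validation, staged
# execution, on-disk outputs and a reproducibility manifest.

#' Build a pipeline configuration
#'
#' All thresholds of the analysis live here, once each: the differential
#' screen (VIP and p), the co-expression screen (MM, GS, module size, merge
#' height, scale-free target), the MR instrument rules (exposure p, F,
#' clumping r^2 and window), and the tier bounds are fixed inside the
#' classifier. All stage seeds derive from the single `seed`.
#'
#' @param seed master seed (integer).
#' @param out_dir output directory for stage TSVs and the manifest.
#' @param n_per_group,n_features synthetic metabolome dimensions (defaults:
#'   the study conditions, 49 per group and 1458 features).
#' @param effect_size planted standardized group difference.
#' @param n_diff planted differential features.
#' @param block_sizes sizes of the planted correlated blocks.
#' @param block_cor within-block correlation.
#' @param causal_betas per-exposure true causal effects; one GWAS pair is
#'   generated per entry.
#' @param n_snps SNPs per GWAS pair.
#' @param n_outcome_gwas outcome GWAS sample size used for the simulated
#'   pairs; the default is desk scale so that mediated outcome associations
#'   do not trip the outcome-SNP exclusion rule for every instrument.
#' @param n_pathways,pathway_size_range,graph_model toy pathway database
#'   shape.
#' @param vip_threshold,p_threshold differential screen.
#' @param n_perm OPLS-DA permutations (0 disables the permutation test).
#' @param mm_min,gs_min hub screen.
#' @param min_module,merge_height,target_r2 network parameters.
#' @param mr_p_thresh,f_min,clump_r2,window_kb MR instrument rules.
#' @param run_mr,run_net stage toggles.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("momdep_run_"),
                            n_per_group = 49L, n_features = 1458L,
                            effect_size = 1.2, n_diff = 84L,
                            block_sizes = c(40L, 30L, 20L), block_cor = 0.7,
                            causal_betas = c(0.3, -0.3, 0),
                            n_snps = 60L, n_outcome_gwas = 20000L,
                            n_pathways = 12L,
                            pathway_size_range = c(4L, 10L),
                            graph_model = "random_tree",
                            vip_threshold = 1.0, p_threshold = 0.05,
                            n_perm = 0L,
                            mm_min = 0.7, gs_min = 0.2,
                            min_module = 10L, merge_height = 0.25,
                            target_r2 = 0.6,
                            mr_p_thresh = 1e-5, f_min = 10,
                            clump_r2 = 0.001, window_kb = 10000,
                            run_mr = TRUE, run_net = TRUE) {
  cfg <- as.list(environment())
  stopifnot(vip_threshold > 0, p_threshold > 0, mm_min > 0, gs_min > 0,
            clump_r2 > 0, window_kb > 0, seed == round(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate on-disk pipeline inputs
#'
#' Schema checks for the standard input files: duplicate feature IDs,
#' non-numeric abundance cells, unknown group or sex codes, missing GWAS
#' columns, invalid allele codes, non-positive standard errors, allele
#' frequencies outside (0, 1). Hard violations are errors; unexpected extra
#' columns only warn.
#'
#' @param paths named list/vector with any of `abundance`, `metadata`,
#'   `exposure`, `outcome`.
#' @return data.frame report (file, level, message); attribute `ok` is
#'   FALSE when any hard error was found.
#' @export
validate_inputs <- function(paths) {
  report <- data.frame(file = character(), level = character(),
                       message = character(), stringsAsFactors = FALSE)
  add <- function(file, level, message)
    report <<- rbind(report, data.frame(file = file, level = level,
                                        message = message,
                                        stringsAsFactors = FALSE))
  if (!is.null(paths$abundance)) {
    ab <- utils::read.delim(paths$abundance, check.names = FALSE)
    if (anyDuplicated(ab[[1]]))
      add("abundance", "error", "duplicate feature IDs")
    if (!all(vapply(ab[-1], is.numeric, logical(1))))
      add("abundance", "error", "non-numeric intensity column")
  }
  if (!is.null(paths$metadata)) {
    md <- utils::read.csv(paths$metadata)
    if (!all(c("sample_id", "group") %in% names(md)))
      add("metadata", "error", "missing sample_id/group column")
    else if (!all(md$group %in% c("DD", "ND")))
      add("metadata", "error", "unknown group label (expect DD/ND)")
    if ("sex" %in% names(md) && !all(md$sex %in% c("male", "female")))
      add("metadata", "error", "unknown sex code")
  }
  for (nm in c("exposure", "outcome")) {
    if (is.null(paths[[nm]])) next
    g <- utils::read.delim(paths[[nm]])
    need <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se",
              "pval")
    miss <- setdiff(need, names(g))
    if (length(miss)) {
      add(nm, "error", paste("missing columns:", paste(miss, collapse = ",")))
      next
    }
    if (!all(unlist(g[c("effect_allele", "other_allele")]) %in%
             c("A", "C", "G", "T")))
      add(nm, "error", "invalid allele code")
    if (any(g$se <= 0)) add(nm, "error", "non-positive standard error")
    if (any(g$eaf <= 0 | g$eaf >= 1)) add(nm, "error", "EAF outside (0,1)")
    extra <- setdiff(names(g), c(need, "chromosome", "position", "n"))
    if (length(extra))
      add(nm, "warning", paste("extra columns ignored:",
                               paste(extra, collapse = ",")))
  }
  attr(report, "ok") <- !any(report$level == "error")
  report
}

write_stage <- function(x, dir, name) {
  path <- file.path(dir, name)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate, cohort, differential screen, co-expression network,
#' Mendelian randomization, pathway analysis and tier integration in order,
#' writing each stage's table under `config$out_dir` and a manifest JSON
#' recording the configuration, per-stage row counts, and MD5 hashes of all
#' outputs. Identical configuration and seed give identical manifests.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with every stage result (`sim`, `roster`,
#'   `screen_counts`, `baseline`, `diff`, `net`, `mr`, `pool`, `pathways`,
#'   `tiers`, `manifest`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  log_msg <- function(...) message("[momdep] ", sprintf(...))

  ## simulate -----------------------------------------------------------
  db <- generate_pathway_db(config$n_pathways, config$pathway_size_range,
                            config$graph_model, seed = config$seed)
  feat_ids <- sprintf("feat_%04d", seq_len(config$n_features))
  blocks <- list(); at <- 1L
  for (i in seq_along(config$block_sizes)) {
    blocks[[paste0("block", i)]] <-
      feat_ids[at:(at + config$block_sizes[i] - 1L)]
    at <- at + config$block_sizes[i]
  }
  diff_feats <- feat_ids[seq_len(min(config$n_diff, config$n_features))]
  truth <- metabolome_truth(diff_features = diff_feats,
                            effect_size = config$effect_size,
                            module_blocks = blocks,
                            block_cor = config$block_cor)
  sim <- generate_metabolome(config$n_per_group, config$n_features, truth,
                             seed = config$seed)
  # feature -> compound mapping ties the streams to the toy pathway DB
  n_map <- min(length(db$universe), config$n_features)
  mapping <- data.frame(name = feat_ids[seq_len(n_map)],
                        kegg_id = db$universe[seq_len(n_map)],
                        stringsAsFactors = FALSE)
  log_msg("simulated %d features x %d samples, %d pathways",
          nrow(sim$abundance), ncol(sim$abundance), length(db$sets))

  ## cohort -------------------------------------------------------------
  roster <- generate_roster(seed = config$seed)
  scr <- apply_exclusions(roster)
  log_msg("roster %d -> eligible %d (excluded: %s)", nrow(roster),
          nrow(scr$eligible),
          paste(names(scr$excluded), scr$excluded, collapse = ", "))
  cases <- scr$eligible[scr$eligible$depressed, ]
  pool_ctl <- scr$eligible[!scr$eligible$depressed, ]
  pairs <- match_controls(cases, pool_ctl, seed = config$seed)
  log_msg("matched %d case-control pairs (%d participants)",
          nrow(pairs), 2L * nrow(pairs))
  baseline <- baseline_table(sim$metadata, numeric_vars = c("age", "gds_score"),
                             categorical_vars = "sex")
  files <- c(files, write_stage(pairs, config$out_dir, "matched_pairs.tsv"),
             write_stage(baseline, config$out_dir, "baseline.tsv"))

  ## differential screen -------------------------------------------------
  logx <- log(sim$abundance)
  X <- t(logx)
  model <- fit_oplsda(X, sim$metadata$group, seed = config$seed)
  perm <- if (config$n_perm > 0)
    permutation_test(model, X, sim$metadata$group, config$n_perm,
                     seed = config$seed)
  diff <- screen_differentials(sim$abundance, sim$metadata$group, model$vip,
                               vip_threshold = config$vip_threshold,
                               p_threshold = config$p_threshold)
  diff_ids <- diff$feature[diff$passes_screen]
  log_msg("OPLS-DA R2Y %.3f Q2 %.3f; %d/%d features pass the screen",
          model$R2Y, model$Q2, length(diff_ids), nrow(diff))
  files <- c(files, write_stage(diff, config$out_dir, "differential.tsv"))

  ## co-expression network -----------------------------------------------
  net <- NULL; hub_ids <- character()
  if (config$run_net) {
    trait <- as.numeric(sim$metadata$group == "DD")
    net <- coexpression_analysis(sim$abundance, trait,
                                 candidates = 1:12,
                                 target_r2 = config$target_r2,
                                 min_size = config$min_module,
                                 merge_height = config$merge_height)
    hub_ids <- net$hubs
    log_msg("network beta %d; %d modules; %d hub features", net$beta,
            length(setdiff(unique(net$labels), "grey")), length(hub_ids))
    files <- c(files, write_stage(net$screen, config$out_dir, "modules.tsv"))
  }

  ## Mendelian randomization ---------------------------------------------
  mr <- NULL; mr_ids <- character(); mr_dirs <- character()
  if (config$run_mr) {
    exposure_compounds <- db$universe[seq_along(config$causal_betas)]
    mr <- lapply(seq_along(config$causal_betas), function(i) {
      gw <- generate_gwas_pair(config$n_snps,
                               gwas_truth(causal_beta = config$causal_betas[i]),
                               n_outcome = config$n_outcome_gwas,
                               seed = config$seed + i)
      res <- mr_analysis(gw$exposure, gw$outcome, gw$ld,
                         p_thresh = config$mr_p_thresh, f_min = config$f_min,
                         r2_max = config$clump_r2,
                         window_kb = config$window_kb, seed = config$seed + i)
      ivw <- res$estimates[res$estimates$method == "IVW", ]
      data.frame(exposure = exposure_compounds[i], beta = ivw$beta,
                 se = ivw$se, p = ivw$p, n_instruments = nrow(res$instruments),
                 stringsAsFactors = FALSE)
    })
    mr <- do.call(rbind, mr)
    sig <- mr$p < 0.05
    mr_ids <- mr$exposure[sig]
    mr_dirs <- stats::setNames(ifelse(mr$beta > 0, "up", "down")[sig], mr_ids)
    log_msg("MR: %d/%d exposures causal at p<0.05", sum(sig), nrow(mr))
    files <- c(files, write_stage(mr, config$out_dir, "mr_estimates.tsv"))
  }

  ## evidence pool + pathways + tiers ------------------------------------
  pool <- build_pool(diff_ids, hub_ids, mr_ids, mapping)
  log_msg("evidence pool: %d compounds", pool$size)
  report <- pathway_report(pool$members$compound, db)
  hit_sets <- lapply(stats::setNames(report$pathway, report$pathway),
                     function(p) intersect(pool$members$compound,
                                           db$sets[[p]]))
  lc_dir <- stats::setNames(diff$direction[diff$passes_screen],
                            mapping$kegg_id[match(diff_ids, mapping$name)])
  lc_dir <- lc_dir[!is.na(names(lc_dir))]
  flags <- direction_flags(hit_sets, lc_dir, mr_dirs)

  per_stream_sig <- function(ids) {
    if (!length(ids)) return(stats::setNames(rep(FALSE, nrow(report)),
                                             report$pathway))
    e <- enrich(ids, db)
    stats::setNames(e$p < 0.05, e$pathway)[report$pathway]
  }
  diff_kegg <- mapping$kegg_id[match(diff_ids, mapping$name)]
  hub_kegg <- mapping$kegg_id[match(hub_ids, mapping$name)]
  tier_in <- data.frame(
    pathway = report$pathway, impact = report$impact,
    pathway_p = report$p, enrichment_p = report$p,
    sig_lcgcms = unname(per_stream_sig(diff_kegg[!is.na(diff_kegg)])),
    sig_wgcna = unname(per_stream_sig(hub_kegg[!is.na(hub_kegg)])),
    sig_mr = unname(per_stream_sig(mr_ids)),
    pool_enriched = report$p < 0.05,
    lcgcms_trend = flags$lcgcms_trend[match(report$pathway, flags$pathway)],
    mr_trend = flags$mr_trend[match(report$pathway, flags$pathway)],
    stringsAsFactors = FALSE)
  tiers <- tier_table(tier_in)
  log_msg("tiers: %s",
          paste(names(table(tiers$table$tier)), table(tiers$table$tier),
                collapse = ", ", sep = "="))
  files <- c(files, write_stage(report, config$out_dir, "pathway_report.tsv"),
             write_stage(tiers$table, config$out_dir, "tier_table.tsv"))

  ## manifest ------------------------------------------------------------
  manifest <- list(
    config = unclass(config)[setdiff(names(config), "out_dir")],
    counts = list(roster = nrow(roster), eligible = nrow(scr$eligible),
                  matched = 2L * nrow(pairs), features = nrow(sim$abundance),
                  differential = length(diff_ids), hubs = length(hub_ids),
                  mr_causal = length(mr_ids), pool = pool$size,
                  pathways_hit = nrow(report),
                  tiers = as.list(table(tiers$table$tier))),
    opls = list(R2Y = model$R2Y, Q2 = model$Q2,
                p_Q2 = if (!is.null(perm)) perm$p_Q2),
    hashes = as.list(tools::md5sum(sort(files))))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(list(sim = sim, roster = roster, screen_counts = scr$excluded,
                 baseline = baseline, diff = diff, net = net, mr = mr,
                 pool = pool, pathways = report, tiers = tiers,
                 model = model, perm = perm, manifest = manifest))
}
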