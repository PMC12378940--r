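# Cross-method evidence pool, per-stream trend flags, and the rule-based
# Class I/II/III(/III*) pathway-tier classifier.

#' Build the high-confidence metabolite evidence pool
#'
#' Union of the differential (LC/GC-MS), hub (co-expression) and causal (MR)
#' metabolite lists, de-duplicated by compound ID, with provenance flags
#' preserved. When a mapping table is supplied, each list is KEGG-matched
#' first and unmatched entries are reported, not silently dropped.
#'
#' @param diff_ids,hub_ids,mr_ids character vectors of compound IDs or names.
#' @param mapping optional data.frame `name`, `kegg_id` (see [match_kegg()]).
#' @return Object of class `evidence_pool`: data.frame `members` (compound,
#'   from_diff, from_hub, from_mr), `unmatched` list per stream, and
#'   `size`.
#' @export
build_pool <- function(diff_ids, hub_ids, mr_ids, mapping = NULL) {
  lists <- list(diff = diff_ids, hub = hub_ids, mr = mr_ids)
  if (!length(unlist(lists))) stop("all evidence lists are empty")
  unmatched <- list(diff = character(), hub = character(), mr = character())
  if (!is.null(mapping)) {
    for (nm in names(lists)) {
      if (!length(lists[[nm]])) next
      m <- match_kegg(lists[[nm]], mapping)
      unmatched[[nm]] <- m$unmatched
      lists[[nm]] <- m$matched$kegg_id
    }
  }
  members <- unique(unlist(lists, use.names = FALSE))
  tab <- data.frame(compound = members,
                    from_diff = members %in% lists$diff,
                    from_hub = members %in% lists$hub,
                    from_mr = members %in% lists$mr,
                    stringsAsFactors = FALSE)
  structure(list(members = tab, unmatched = unmatched, size = nrow(tab)),
            class = "evidence_pool")
}

#' @export
print.evidence_pool <- function(x, ...) {
  cat(sprintf("evidence_pool: %d compounds (diff %d, hub %d, mr %d)\n",
              x$size, sum(x$members$from_diff), sum(x$members$from_hub),
              sum(x$members$from_mr)))
  n_un <- sum(lengths(x$unmatched))
  if (n_un) cat(sprintf("  %d unmatched input(s) reported\n", n_un))
  invisible(x)
}

# Collapse the known directions of a pathway's hits into one stream trend.
stream_trend <- function(dirs) {
  dirs <- dirs[!is.na(dirs)]
  if (!length(dirs)) return("absent")
  if (all(dirs == "up")) return("up")
  if (all(dirs == "down")) return("down")
  "mixed"
}

#' Per-pathway trend flags for each evidence stream
#'
#' For every pathway and stream, the trend is "up" when every hit with a
#' known direction increased, "down" when every one decreased, "mixed" when
#' both occur, and "absent" when no hit has a known direction in that
#' stream.
#'
#' @param pathway_hits named list: pathway -> character vector of hit
#'   compound IDs.
#' @param lcgcms_directions named vector, compound -> "up"/"down", from the
#'   differential screen.
#' @param mr_directions named vector, compound -> "up" (risk) / "down"
#'   (protective), from the MR betas.
#' @return data.frame: pathway, lcgcms_trend, mr_trend.
#' @export
direction_flags <- function(pathway_hits, lcgcms_directions = NULL,
                            mr_directions = NULL) {
  rows <- lapply(names(pathway_hits), function(p) {
    hits <- pathway_hits[[p]]
    data.frame(
      pathway = p,
      lcgcms_trend = stream_trend(lcgcms_directions[hits]),
      mr_trend = stream_trend(mr_directions[hits]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify one pathway into the Class I/II/III(/III*) tier system
#'
#' Rules, applied in order:
#' \describe{
#'   \item{R0}{any stream trend "mixed" (internally contradictory hits)
#'     gives tier III* regardless of impact;}
#'   \item{R1}{impact >= 0.25, significant in at least two of LC/GC-MS,
#'     WGCNA and MR, enriched in the pooled analysis, and both stream
#'     trends known (non-absent): tier I;}
#'   \item{R2}{0.1 <= impact < 0.25 and significant by LC/GC-MS or MR:
#'     tier II;}
#'   \item{R3}{otherwise, any of the pathway/enrichment p-values below
#'     0.05: tier III;}
#'   \item{R4}{otherwise unclassified (`NA` tier).}
#' }
#' The Class II band is half-open at 0.25 so the tiers partition the impact
#' axis.
#'
#' @param impact pathway impact in [0, 1].
#' @param pathway_p,enrichment_p topology-analysis and enrichment p-values
#'   (either may be `NA`).
#' @param sig_methods character subset of `c("LCGCMS", "WGCNA", "MR")` in
#'   which the pathway was significant.
#' @param pool_enriched logical: significantly enriched in the pooled
#'   metabolite analysis.
#' @param lcgcms_trend,mr_trend `"up"`, `"down"`, `"mixed"` or `"absent"`.
#' @return List: `tier` ("I", "II", "III", "III*", or `NA`), `rationale`
#'   (which rule fired and why).
#' @export
classify_tier <- function(impact, pathway_p = NA, enrichment_p = NA,
                          sig_methods = character(), pool_enriched = FALSE,
                          lcgcms_trend = "absent", mr_trend = "absent") {
  if (is.na(impact) || impact < 0) stop("impact must be non-negative")
  trends <- c(lcgcms = lcgcms_trend, mr = mr_trend)
  stopifnot(all(trends %in% c("up", "down", "mixed", "absent")))
  sig_methods <- intersect(sig_methods, c("LCGCMS", "WGCNA", "MR"))
  min_p <- suppressWarnings(min(pathway_p, enrichment_p, na.rm = TRUE))

  if (any(trends == "mixed"))
    return(list(tier = "III*",
                rationale = "R0: contradictory hit trends within a stream"))
  if (impact >= 0.25 && length(sig_methods) >= 2 && isTRUE(pool_enriched) &&
      all(trends != "absent"))
    return(list(tier = "I", rationale = sprintf(
      "R1: impact %.2f >= 0.25, significant in %s, pool-enriched, consistent trends",
      impact, paste(sig_methods, collapse = "+"))))
  if (impact >= 0.1 && impact < 0.25 &&
      any(c("LCGCMS", "MR") %in% sig_methods))
    return(list(tier = "II", rationale = sprintf(
      "R2: impact %.2f in [0.1, 0.25), significant by %s",
      impact, paste(intersect(sig_methods, c("LCGCMS", "MR")),
                    collapse = "+"))))
  if (is.finite(min_p) && min_p < 0.05)
    return(list(tier = "III", rationale = sprintf(
      "R3: significant (min p = %.3g) with impact %.2f", min_p, impact)))
  list(tier = NA_character_, rationale = "R4: no rule matched; unclassified")
}

#' Classify a table of pathways
#'
#' Vectorized front end to [classify_tier()]. The input mirrors the
#' `TierInput` layout: one row per pathway with impact, p-values,
#' method-significance flags and stream trends.
#'
#' @param x data.frame with columns `pathway`, `impact`, `pathway_p`,
#'   `enrichment_p`, logical `sig_lcgcms`, `sig_wgcna`, `sig_mr`,
#'   `pool_enriched`, and `lcgcms_trend`, `mr_trend`.
#' @return `x` with added `tier` and `rationale` columns.
#' @export
classify_tiers <- function(x) {
  need_cols(x, c("pathway", "impact", "pathway_p", "enrichment_p",
                 "sig_lcgcms", "sig_wgcna", "sig_mr", "pool_enriched",
                 "lcgcms_trend", "mr_trend"))
  res <- lapply(seq_len(nrow(x)), function(i) {
    sig <- c("LCGCMS", "WGCNA", "MR")[c(x$sig_lcgcms[i], x$sig_wgcna[i],
                                        x$sig_mr[i])]
    classify_tier(x$impact[i], x$pathway_p[i], x$enrichment_p[i], sig,
                  x$pool_enriched[i], x$lcgcms_trend[i], x$mr_trend[i])
  })
  x$tier <- vapply(res, `[[`, character(1), "tier")
  x$rationale <- vapply(res, `[[`, character(1), "rationale")
  x
}

trend_arrow <- function(trend) {
  c(up = "↑", down = "↓", mixed = "↑↓",
    absent = "/")[trend]
}

#' Assemble the classified pathway tier table
#'
#' Classified rows sorted by tier (I < II < III < III*) then impact
#' descending; unclassified rows are reported separately. Trends render as
#' arrows (up/down), both arrows for mixed, and "/" for absent.
#'
#' @param x data.frame as for [classify_tiers()] (classified or not);
#'   optional extra columns (`super_class`, `hit_count`, `kegg_ids`) are
#'   carried through.
#' @return List: `table` (the sorted tier table with arrow columns),
#'   `unclassified` (rows with no tier).
#' @export
tier_table <- function(x) {
  if (!"tier" %in% names(x)) x <- classify_tiers(x)
  x$lcgcms_arrow <- trend_arrow(x$lcgcms_trend)
  x$mr_arrow <- trend_arrow(x$mr_trend)
  un <- x[is.na(x$tier), , drop = FALSE]
  cl <- x[!is.na(x$tier), , drop = FALSE]
  ord <- order(match(cl$tier, c("I", "II", "III", "III*")), -cl$impact)
  list(table = cl[ord, , drop = FALSE], unclassified = un)
}

#' Bundled reference pathway-classification example
#'
#' Twelve depression-associated metabolic pathways with published impact
#' scores, p-values, method-significance flags, per-stream trends and
#' expected tier labels, used as a worked example and regression fixture for
#' the tier classifier.
#'
#' @return data.frame with the `classify_tiers()` input columns plus
#'   `expected_tier`, `super_class`, `hit_count`, `kegg_ids`.
#' @export
load_tier_reference <- function() {
  path <- system.file("extdata", "pathway_tier_reference.tsv",
                      package = "momdep", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
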