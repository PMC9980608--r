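## Transcriptional-activity calls on complete/high-quality viral contigs,
## gene-level transcribed flags, transcription ratios and cross-dataset
## abundance correlations.

pair_key <- function(samples) paste(samples$participant, samples$site, sep = "-")

#' Call transcriptionally active (TA) viral contigs
#'
#' A complete or high-quality VC is TA in a metatranscriptome sample when its
#' NRA there reaches `ta_threshold` (default 1e-6, i.e. 0.0001%). The
#' comparison convention is `>=` by default; `strict = TRUE` switches to `>`
#' (both readings appear in the field).
#'
#' @param nra_mt A [compute_nra()] profile of the MT dataset.
#' @param contigs A [contig_set()] (for quality and viral flags).
#' @param quality Quality tiers eligible for calling (default complete/high).
#' @param ta_threshold NRA threshold as a fraction (1e-6 == 0.0001%).
#' @param strict Use strictly-greater comparison.
#' @return An object of class `activity_calls`: list with `calls` (data.frame
#'   `vc_id`, `sample_id`, `nra_MT`, `is_TA`), `vc_level` (data.frame
#'   `vc_id`, `is_TA` = TA in any MT sample), and the calling convention.
#' @export
call_ta <- function(nra_mt, contigs, quality = c("complete", "high"),
                    ta_threshold = 1e-6, strict = FALSE) {
  if (is.null(nra_mt) || ncol(nra_mt$nra) == 0) {
    warning("no MT samples: transcription calling disabled")
    return(structure(list(calls = data.frame(), vc_level = data.frame(),
                          ta_threshold = ta_threshold, strict = strict),
                     class = "activity_calls"))
  }
  stopifnot(inherits(nra_mt, "nra_profile"))
  meta <- contigs$meta
  elig <- meta$contig_id[meta$is_viral & meta$quality %in% quality]
  elig <- intersect(rownames(nra_mt$nra), elig)
  m <- nra_mt$nra[elig, , drop = FALSE]
  is_ta <- if (strict) m > ta_threshold else m >= ta_threshold
  calls <- data.frame(vc_id = rep(elig, ncol(m)),
                      sample_id = rep(colnames(m), each = length(elig)),
                      nra_MT = as.vector(m), is_TA = as.vector(is_ta),
                      stringsAsFactors = FALSE)
  vc_level <- data.frame(vc_id = elig, is_TA = rowSums(is_ta) > 0,
                         stringsAsFactors = FALSE)
  structure(list(calls = calls, vc_level = vc_level,
                 ta_threshold = ta_threshold, strict = strict),
            class = "activity_calls")
}

#' @export
print.activity_calls <- function(x, ...) {
  cat("<activity_calls> ", nrow(x$vc_level), " eligible VCs, ",
      sum(x$vc_level$is_TA), " transcriptionally active (threshold ",
      format(x$ta_threshold), if (x$strict) ", strict >" else ", >=",
      ")\n", sep = "")
  invisible(x)
}

#' Flag transcribed genes on transcriptionally active VCs
#'
#' Genes on TA VCs with at least `min_count` MT reads in a sample (the
#' ">1 counts" rule, applied per sample) are "transcribed"; other genes on TA
#' VCs are "not_transcribed"; genes on non-TA or ineligible VCs are
#' "not_evaluated" -- a distinct state, not a negative call.
#'
#' @param gene_counts Gene x MT-sample count matrix.
#' @param genes Gene table (maps `gene_id` to `contig_id`).
#' @param activity An [call_ta()] result.
#' @param min_count Minimum count to call transcribed (default 2, i.e. > 1).
#' @return data.frame `gene_id`, `contig_id`, `sample_id`, `count`, `status`.
#' @export
call_transcribed_genes <- function(gene_counts, genes, activity,
                                   min_count = 2) {
  stopifnot(inherits(activity, "activity_calls"))
  ta <- activity$calls[activity$calls$is_TA, , drop = FALSE]
  ta_key <- paste(ta$vc_id, ta$sample_id)
  cid <- genes$contig_id[match(rownames(gene_counts), genes$gene_id)]
  out <- data.frame(
    gene_id = rep(rownames(gene_counts), ncol(gene_counts)),
    contig_id = rep(cid, ncol(gene_counts)),
    sample_id = rep(colnames(gene_counts), each = nrow(gene_counts)),
    count = as.vector(gene_counts), stringsAsFactors = FALSE)
  evaluated <- paste(out$contig_id, out$sample_id) %in% ta_key
  out$status <- ifelse(!evaluated, "not_evaluated",
                       ifelse(out$count >= min_count, "transcribed",
                              "not_transcribed"))
  out
}

#' Transcription-ratio table (MT NRA / MG NRA)
#'
#' Ratios are computed per entity per (participant, site) pairing -- never
#' pooled across participants, since NRA denominators differ per sample.
#' Entities with zero MG NRA have an undefined ratio, excluded from means but
#' counted.
#'
#' @param nra_mt,nra_mg [compute_nra()] profiles sharing a row universe; the
#'   samples are paired by participant and site.
#' @param ids Optional subset of row ids (e.g. genes or VCs of interest).
#' @return list with `ratios` (long data.frame `id`, `participant`, `site`,
#'   `nra_MT`, `nra_MG`, `ratio`), `summary` (per id: mean ratio over defined
#'   pairs, `n_defined`, `n_undefined`).
#' @export
transcription_ratio_table <- function(nra_mt, nra_mg, ids = NULL) {
  stopifnot(inherits(nra_mt, "nra_profile"), inherits(nra_mg, "nra_profile"))
  common <- intersect(rownames(nra_mt$nra), rownames(nra_mg$nra))
  if (!is.null(ids)) common <- intersect(common, ids)
  kt <- pair_key(nra_mt$samples); kg <- pair_key(nra_mg$samples)
  shared <- intersect(kt, kg)
  if (!length(shared)) stop("no paired (participant, site) samples")
  rows <- lapply(shared, function(k) {
    mt_col <- nra_mt$samples$sample_id[kt == k][1]
    mg_col <- nra_mg$samples$sample_id[kg == k][1]
    mt <- nra_mt$nra[common, mt_col]
    mg <- nra_mg$nra[common, mg_col]
    data.frame(id = common,
               participant = sub("-.*$", "", k), site = sub("^.*-", "", k),
               nra_MT = mt, nra_MG = mg,
               ratio = ifelse(mg > 0, mt / mg, NA_real_),
               stringsAsFactors = FALSE)
  })
  ratios <- do.call(rbind, rows)
  rownames(ratios) <- NULL
  agg <- lapply(split(ratios, ratios$id), function(g)
    data.frame(id = g$id[1], mean_ratio = mean(g$ratio, na.rm = TRUE),
               n_defined = sum(!is.na(g$ratio)), n_undefined = sum(is.na(g$ratio)),
               stringsAsFactors = FALSE))
  summary <- do.call(rbind, agg)
  rownames(summary) <- NULL
  list(ratios = ratios, summary = summary)
}

#' Compare transcription ratios between two groups of entities
#'
#' Wilcoxon rank-sum (two-sided, normal approximation with tie correction) on
#' the defined per-site ratios of two entity groups.
#'
#' @param ratio_table Output of [transcription_ratio_table()].
#' @param group1,group2 Character vectors of entity ids.
#' @return list with the two group means and the Wilcoxon `p_value`.
#' @export
compare_transcription_ratios <- function(ratio_table, group1, group2) {
  r <- ratio_table$ratios
  x <- r$ratio[r$id %in% group1 & !is.na(r$ratio)]
  y <- r$ratio[r$id %in% group2 & !is.na(r$ratio)]
  if (!length(x) || !length(y)) stop("a group has no defined ratios")
  p <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  list(mean1 = mean(x), mean2 = mean(y), n1 = length(x), n2 = length(y),
       p_value = p)
}

#' Pairwise Pearson correlations of VC NRAs across datasets
#'
#' Observations are (VC, participant-site) cells where both datasets have a
#' paired sample and both NRAs are positive; correlation is computed on
#' log10 NRA by default.
#'
#' @param profiles Named list of [compute_nra()] profiles (e.g. MG, MV, MT).
#' @param ids Optional row subset (e.g. viral contigs only).
#' @param log10_transform Correlate log10(NRA) (default TRUE).
#' @return data.frame `pair`, `r`, `p_value`, `n`; rows with fewer than 3
#'   paired observations carry NA correlation.
#' @export
multiomic_correlations <- function(profiles, ids = NULL,
                                   log10_transform = TRUE) {
  stopifnot(length(profiles) >= 2, !is.null(names(profiles)))
  combos <- utils::combn(names(profiles), 2, simplify = FALSE)
  rows <- lapply(combos, function(pr) {
    a <- profiles[[pr[1]]]; b <- profiles[[pr[2]]]
    common <- intersect(rownames(a$nra), rownames(b$nra))
    if (!is.null(ids)) common <- intersect(common, ids)
    ka <- pair_key(a$samples); kb <- pair_key(b$samples)
    shared <- intersect(ka, kb)
    va <- vb <- numeric(0)
    for (k in shared) {
      xa <- a$nra[common, a$samples$sample_id[ka == k][1]]
      xb <- b$nra[common, b$samples$sample_id[kb == k][1]]
      ok <- xa > 0 & xb > 0
      va <- c(va, xa[ok]); vb <- c(vb, xb[ok])
    }
    if (log10_transform) { va <- log10(va); vb <- log10(vb) }
    if (length(va) < 3 || var(va) == 0 || var(vb) == 0)
      return(data.frame(pair = paste(pr, collapse = "-"), r = NA_real_,
                        p_value = NA_real_, n = length(va)))
    ct <- cor.test(va, vb, method = "pearson")
    data.frame(pair = paste(pr, collapse = "-"), r = unname(ct$estimate),
               p_value = ct$p.value, n = length(va))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
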