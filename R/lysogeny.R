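## Integrase detection, gene-family statistics in integration-capable (IC)
## versus non-integrated (NI) VCs, integration likelihood ratios, and
## transcribed-fraction contrasts.

#' Detect integrase genes by annotation-term matching
#'
#' A contig is flagged as integrase-carrying when one or more of its genes
#' carries an annotation term whose name contains `pattern`
#' (case-insensitive substring; the default aggregates variants such as
#' "Integrase" and "DDE-type integrase/transposase/recombinase"). Exact term
#' lists can be supplied instead via `terms`.
#'
#' @param genes Gene table.
#' @param pattern Substring to match in `term_name` (default "integrase").
#' @param terms Optional character vector of exact `term_id`s overriding the
#'   substring rule.
#' @return list with `by_contig` (data.frame `contig_id`, `has_integrase`,
#'   `n_integrase_genes`) and `census` (matched genes tabulated by database
#'   and term).
#' @export
detect_integrase <- function(genes, pattern = "integrase", terms = NULL) {
  hit <- if (!is.null(terms)) genes$term_id %in% terms
         else grepl(pattern, genes$term_name, ignore.case = TRUE, fixed = FALSE) &
              !is.na(genes$term_name)
  per <- tapply(hit, genes$contig_id, sum)
  by_contig <- data.frame(contig_id = names(per),
                          has_integrase = as.vector(per) > 0,
                          n_integrase_genes = as.vector(per),
                          stringsAsFactors = FALSE)
  census <- if (any(hit)) {
    tb <- as.data.frame(table(db = genes$db[hit], term_id = genes$term_id[hit],
                              term_name = genes$term_name[hit]))
    tb <- tb[tb$Freq > 0, , drop = FALSE]
    names(tb)[4] <- "n_genes"
    rownames(tb) <- NULL
    tb
  } else data.frame(db = character(), term_id = character(),
                    term_name = character(), n_genes = integer())
  list(by_contig = by_contig, census = census,
       n_integrase_genes = sum(hit),
       n_contigs_with = sum(by_contig$has_integrase))
}

#' Gene-family presence statistics for IC vs NI classification
#'
#' Core arithmetic for a single family: sensitivity `n_IC_with / n_IC_total`,
#' specificity `1 - n_NI_with / n_NI_total`, and the integration likelihood
#' ratio `sensitivity / (1 - specificity)` (infinite when the family is
#' absent from all NI VCs).
#'
#' @param n_IC_with,n_IC_total,n_NI_with,n_NI_total Presence counts.
#' @return list with `sensitivity`, `specificity`, `likelihood_ratio` and the
#'   input counts.
#' @export
gene_family_stats <- function(n_IC_with, n_IC_total, n_NI_with, n_NI_total) {
  if (n_IC_total == 0 || n_NI_total == 0)
    stop("empty IC or NI group")
  sens <- n_IC_with / n_IC_total
  spec <- 1 - n_NI_with / n_NI_total
  lr <- if (n_NI_with == 0) Inf else sens / (1 - spec)
  list(sensitivity = sens, specificity = spec, likelihood_ratio = lr,
       n_IC_with = n_IC_with, n_IC_total = n_IC_total,
       n_NI_with = n_NI_with, n_NI_total = n_NI_total)
}

#' Per-family statistics over complete/high-quality Caudovirales VCs
#'
#' Restricts to VCs of the given quality tiers and taxonomic order, keeps
#' families present in at least `min_prevalence` of them (boundary
#' inclusive), and reports per-group presence counts, sensitivity,
#' specificity, likelihood ratio and length-normalized ORF frequencies
#' (genes per kb, normalization applied to frequencies only, not to the LR).
#'
#' @param genes Gene table (family = `term_name`).
#' @param classifications The `classifications` data.frame from
#'   [classify_integration()] (or any table with `vc_id` and
#'   `integration_class`).
#' @param contigs A [contig_set()] for quality/taxonomy/length lookups; VC
#'   ids must be contig ids (cluster representatives).
#' @param quality Eligible quality tiers (default complete/high).
#' @param tax_order Eligible taxonomic order (default "Caudovirales").
#' @param min_prevalence Minimum fraction of eligible VCs carrying the family
#'   (default 0.10, `>=`).
#' @return data.frame, one row per family, with counts, `sensitivity`,
#'   `specificity`, `likelihood_ratio`, `freq_per_kb_IC`, `freq_per_kb_NI`.
#' @export
family_frequency <- function(genes, classifications, contigs,
                             quality = c("complete", "high"),
                             tax_order = "Caudovirales",
                             min_prevalence = 0.10) {
  meta <- contigs$meta
  elig <- meta$contig_id[meta$is_viral & meta$quality %in% quality &
                         meta$taxonomy_order %in% tax_order]
  cls <- classifications[classifications$vc_id %in% elig, , drop = FALSE]
  if (!nrow(cls)) stop("no eligible VCs")
  ic <- cls$vc_id[cls$integration_class == "IC"]
  ni <- cls$vc_id[cls$integration_class == "NI"]
  if (!length(ic) || !length(ni))
    stop("zero VCs in the IC or NI group; statistics undefined")
  g <- genes[genes$contig_id %in% cls$vc_id & !is.na(genes$term_name), ,
             drop = FALSE]
  kb <- setNames(meta$length_bp / 1000, meta$contig_id)
  fam_tab <- table(unique(g[c("contig_id", "term_name")])$term_name)
  keep <- names(fam_tab)[fam_tab / nrow(cls) >= min_prevalence]
  rows <- lapply(keep, function(fam) {
    gf <- g[g$term_name == fam, , drop = FALSE]
    with_ids <- unique(gf$contig_id)
    st <- gene_family_stats(sum(ic %in% with_ids), length(ic),
                            sum(ni %in% with_ids), length(ni))
    n_genes_ic <- sum(gf$contig_id %in% ic)
    n_genes_ni <- sum(gf$contig_id %in% ni)
    data.frame(term_name = fam,
               n_IC_with = st$n_IC_with, n_IC_total = st$n_IC_total,
               n_NI_with = st$n_NI_with, n_NI_total = st$n_NI_total,
               sensitivity = st$sensitivity, specificity = st$specificity,
               likelihood_ratio = st$likelihood_ratio,
               freq_per_kb_IC = n_genes_ic / sum(kb[ic]),
               freq_per_kb_NI = n_genes_ni / sum(kb[ni]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank gene families by integration likelihood ratio
#'
#' Sorted descending; infinite ratios (families absent from every NI VC) rank
#' first, resolved among themselves by sensitivity, and are flagged.
#'
#' @param stats Output of [family_frequency()].
#' @return The table sorted by `likelihood_ratio` with an `infinite` flag.
#' @export
integration_lr <- function(stats) {
  if (any(stats$n_IC_total == 0) || any(stats$n_NI_total == 0))
    stop("empty IC or NI group")
  stats$infinite <- !is.finite(stats$likelihood_ratio)
  o <- order(-stats$infinite, -ifelse(stats$infinite, stats$sensitivity, 0),
             -stats$likelihood_ratio, stats$term_name)
  out <- stats[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Transcribed-fraction contrast between IC and NI VCs per gene family
#'
#' For each family, the fraction of evaluated gene instances (gene x sample
#' on transcriptionally active VCs) called transcribed, split by the VC's
#' IC/NI class; sorted by the IC - NI difference (descending, ties by term
#' name). Families with zero evaluated instances in a group have an undefined
#' fraction and are excluded from the sorted difference.
#'
#' @param gene_status Output of [call_transcribed_genes()].
#' @param genes Gene table (provides `term_name`).
#' @param classifications Table with `vc_id`, `integration_class`.
#' @return data.frame `term_name`, `frac_IC`, `frac_NI`, `n_eval_IC`,
#'   `n_eval_NI`, `difference`.
#' @export
transcribed_fraction_contrast <- function(gene_status, genes,
                                          classifications) {
  st <- gene_status[gene_status$status != "not_evaluated", , drop = FALSE]
  st$term_name <- genes$term_name[match(st$gene_id, genes$gene_id)]
  st <- st[!is.na(st$term_name), , drop = FALSE]
  st$class <- classifications$integration_class[
    match(st$contig_id, classifications$vc_id)]
  st <- st[!is.na(st$class), , drop = FALSE]
  rows <- lapply(split(st, st$term_name), function(g) {
    f <- function(cl) {
      gg <- g[g$class == cl, , drop = FALSE]
      c(frac = if (nrow(gg)) mean(gg$status == "transcribed") else NA_real_,
        n = nrow(gg))
    }
    ic <- f("IC"); ni <- f("NI")
    data.frame(term_name = g$term_name[1],
               frac_IC = ic["frac"], frac_NI = ni["frac"],
               n_eval_IC = ic["n"], n_eval_NI = ni["n"],
               difference = ic["frac"] - ni["frac"], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  defined <- !is.na(out$difference)
  out <- rbind(out[defined, ][order(-out$difference[defined],
                                    out$term_name[defined]), ],
               out[!defined, , drop = FALSE])
  rownames(out) <- NULL
  out
}
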