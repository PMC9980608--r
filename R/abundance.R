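## Breadth-filtered, length-normalized relative abundance (NRA) and QC.

#' Apply the breadth-of-coverage detection filter
#'
#' Zeroes cells whose breadth of coverage (fraction of contig positions with
#' depth >= 1 read) is below `breadth_min`. The filter applies to metagenome
#' and metavirome tables only; a metatranscriptome matrix passes through
#' unfiltered. The input is not modified.
#'
#' @param x An [omics_matrix()].
#' @param breadth_min Minimum breadth (default 0.75); cells pass when
#'   `breadth >= breadth_min`.
#' @param datasets Datasets subject to filtering (default MG and MV).
#' @return A filtered `omics_matrix`.
#' @export
apply_breadth_filter <- function(x, breadth_min = 0.75,
                                 datasets = c("MG", "MV")) {
  stopifnot(inherits(x, "omics_matrix"))
  bad <- setdiff(datasets, DATASETS)
  if (length(bad)) stop("unknown dataset label: ", paste(bad, collapse = ", "))
  if (!x$dataset %in% datasets) return(x)
  drop <- x$breadth < breadth_min
  counts <- x$counts; breadth <- x$breadth
  counts[drop] <- 0L
  breadth[drop] <- 0
  omics_matrix(counts, breadth, x$dataset, x$samples)
}

#' Compute length-normalized relative abundance (NRA)
#'
#' For contig i in a sample, `x_i = reads_i / length_i` (reads per bp) and
#' `NRA_i = x_i / sum_j x_j`, normalized over every contig in that dataset's
#' mapping universe (viral and non-viral alike). Hosts whose prophage regions
#' were masked contribute their `effective_length` (unmasked positions) as
#' the denominator, since reads cannot map onto the N-runs.
#'
#' @param x An [omics_matrix()] (typically breadth-filtered first).
#' @param contigs A [contig_set()] providing `length_bp` and, optionally, an
#'   `effective_length` column from [mask_prophage_regions()].
#' @return An object of class `nra_profile`: list with matrices `nra` and
#'   `x` (reads per bp), `dataset` and `samples`.
#' @export
compute_nra <- function(x, contigs) {
  stopifnot(inherits(x, "omics_matrix"))
  meta <- contigs$meta
  k <- match(rownames(x$counts), meta$contig_id)
  if (anyNA(k))
    stop("contigs absent from contig set: ",
         paste(head(rownames(x$counts)[is.na(k)], 5), collapse = ", "))
  len <- if ("effective_length" %in% names(meta)) meta$effective_length[k]
         else meta$length_bp[k]
  if (any(len <= 0)) stop("non-positive contig length")
  xi <- x$counts / len
  tot <- colSums(xi)
  zero <- tot == 0
  if (any(zero)) {
    warning("all-zero sample(s): ", paste(colnames(xi)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  nra <- sweep(xi, 2, tot, "/")
  structure(list(nra = nra, x = xi, dataset = x$dataset, samples = x$samples),
            class = "nra_profile")
}

#' @export
print.nra_profile <- function(x, ...) {
  cat("<nra_profile> ", x$dataset, ": ", nrow(x$nra), " contigs x ",
      ncol(x$nra), " samples\n", sep = "")
  invisible(x)
}

#' Viral fraction of NRA per sample
#'
#' @param nra An [compute_nra()] profile.
#' @param contigs A [contig_set()] providing `is_viral`.
#' @return list with `per_sample` (named vector of viral NRA fractions) and
#'   `mean` (dataset mean).
#' @export
viral_fraction <- function(nra, contigs) {
  stopifnot(inherits(nra, "nra_profile"))
  viral <- contigs$meta$is_viral[match(rownames(nra$nra), contigs$meta$contig_id)]
  if (anyNA(viral)) stop("contigs absent from contig set")
  per <- colSums(nra$nra[viral, , drop = FALSE])
  list(per_sample = per, mean = mean(per))
}

#' Contamination QC: host-read fractions and marker fold changes
#'
#' Summarizes per-sample host-read fractions and, per (participant, site),
#' the fold change of cpn60-style housekeeping-marker read rates between the
#' metagenome and the metavirome (a purity check for VLP enrichment). A zero
#' metavirome marker rate yields an infinite fold change, flagged.
#'
#' @param samples A [sample_sheet()].
#' @param host_reads data.frame `sample_id`, `host_reads`, `total_reads`.
#' @param marker_reads data.frame `sample_id`, `marker_reads`, `total_reads`.
#' @return list with `host` (per-sample host fraction table), `marker`
#'   (per-site fold-change table with `fold_change` and `infinite` flag) and
#'   `mean_fold_change` over finite sites.
#' @export
contamination_qc <- function(samples, host_reads, marker_reads) {
  host <- merge(as.data.frame(samples), host_reads, by = "sample_id")
  host$host_fraction <- host$host_reads / host$total_reads
  if (any(host$host_fraction < 0 | host$host_fraction > 1))
    stop("host fraction outside [0, 1]")
  mk <- merge(as.data.frame(samples), marker_reads, by = "sample_id")
  mk$rate_per_million <- 1e6 * mk$marker_reads / mk$total_reads
  key <- interaction(mk$participant, mk$site, drop = TRUE)
  rows <- lapply(split(mk, key), function(g) {
    mg <- g$rate_per_million[g$dataset == "MG"]
    mv <- g$rate_per_million[g$dataset == "MV"]
    if (!length(mg) || !length(mv)) return(NULL)
    fc <- if (mv[1] == 0) Inf else mg[1] / mv[1]
    data.frame(participant = g$participant[1], site = g$site[1],
               mg_rate = mg[1], mv_rate = mv[1], fold_change = fc,
               infinite = !is.finite(fc), stringsAsFactors = FALSE)
  })
  marker <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(marker) <- NULL
  list(host = host[c("sample_id", "participant", "site", "dataset",
                     "inflammation_grade", "host_fraction")],
       marker = marker,
       mean_fold_change = mean(marker$fold_change[is.finite(marker$fold_change)]))
}
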