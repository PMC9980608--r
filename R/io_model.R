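## Core data model: contig sets, sample sheets, omics matrices, gene tables,
## host-score tables, plus readers/writers and bundle validation.

#' Construct a contig set
#'
#' A contig set couples a per-contig metadata table with (optionally) the
#' contig sequences. Metadata columns: `contig_id`, `length_bp`, `source`
#' (metavirome/metagenome/both), `is_viral`, `quality` (complete, high,
#' medium, low, not_determined), `taxonomy_order`, `taxonomy_family`, and the
#' optional prophage-provenance columns `pruned_flanks` (logical; contig was
#' pruned out of a longer assembly with flanking host sequence) and
#' `pruned_from` (id of that host contig, or NA).
#'
#' @param meta data.frame of contig metadata.
#' @param seqs Optional named [Biostrings::DNAStringSet] with names matching
#'   `meta$contig_id`.
#' @return An object of class `contig_set`.
#' @export
contig_set <- function(meta, seqs = NULL) {
  required <- c("contig_id", "length_bp", "source", "is_viral", "quality",
                "taxonomy_order", "taxonomy_family")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("contig metadata missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(meta$contig_id))
    stop("duplicate contig ids: ",
         paste(unique(meta$contig_id[duplicated(meta$contig_id)]), collapse = ", "))
  bad_q <- setdiff(unique(meta$quality), QUALITY_TIERS)
  if (length(bad_q))
    stop("unknown quality tiers: ", paste(bad_q, collapse = ", "))
  bad_s <- setdiff(unique(meta$source), SOURCES)
  if (length(bad_s))
    stop("unknown source labels: ", paste(bad_s, collapse = ", "))
  if (any(meta$length_bp <= 0)) stop("length_bp must be positive")
  if (!"pruned_flanks" %in% names(meta))
    meta$pruned_flanks <- rep(FALSE, nrow(meta))
  if (!"pruned_from" %in% names(meta))
    meta$pruned_from <- rep(NA_character_, nrow(meta))
  if (!is.null(seqs)) {
    if (is.null(names(seqs)) || !setequal(names(seqs), meta$contig_id)) {
      only_fa <- setdiff(names(seqs), meta$contig_id)
      only_tab <- setdiff(meta$contig_id, names(seqs))
      stop("sequence/metadata id mismatch; only in sequences: [",
           paste(head(only_fa, 5), collapse = ", "), "]; only in metadata: [",
           paste(head(only_tab, 5), collapse = ", "), "]")
    }
    seqs <- seqs[meta$contig_id]
    lens <- Biostrings::width(seqs)
    bad <- which(lens != meta$length_bp)
    if (length(bad))
      stop("length_bp disagrees with sequence length for: ",
           paste(meta$contig_id[bad], collapse = ", "))
  }
  structure(list(meta = meta, seqs = seqs), class = "contig_set")
}

#' @export
print.contig_set <- function(x, ...) {
  cat("<contig_set> ", nrow(x$meta), " contigs (",
      sum(x$meta$is_viral), " viral), sequences: ",
      if (is.null(x$seqs)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' Number of contigs in a contig set
#' @param x A `contig_set`.
#' @export
length.contig_set <- function(x) nrow(x$meta)

#' Subset a contig set by contig id
#' @param x A `contig_set`.
#' @param ids Character vector of contig ids to keep.
#' @return A `contig_set`.
#' @export
subset_contigs <- function(x, ids) {
  stopifnot(inherits(x, "contig_set"))
  keep <- x$meta$contig_id %in% ids
  contig_set(x$meta[keep, , drop = FALSE],
             if (is.null(x$seqs)) NULL else x$seqs[x$meta$contig_id[keep]])
}

#' Read contigs from FASTA plus a metadata table
#'
#' @param fasta_path Path to a (possibly empty) FASTA file.
#' @param metadata_path Path to a contig metadata TSV (see [contig_set()]).
#' @return A `contig_set` with sequences.
#' @export
read_contigs <- function(fasta_path, metadata_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  meta <- read_bio_tsv(metadata_path)
  if (length(seqs) == 0 && nrow(meta) == 0) {
    warning("empty FASTA: returning empty contig set")
    meta <- data.frame(contig_id = character(), length_bp = integer(),
                       source = character(), is_viral = logical(),
                       quality = character(), taxonomy_order = character(),
                       taxonomy_family = character())
    return(contig_set(meta, seqs))
  }
  if (anyDuplicated(names(seqs)))
    stop("duplicate ids in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  meta$is_viral <- as.logical(meta$is_viral)
  if ("pruned_flanks" %in% names(meta))
    meta$pruned_flanks <- as.logical(meta$pruned_flanks)
  contig_set(meta, seqs)
}

#' Write a contig set to FASTA + metadata TSV
#' @param x A `contig_set` with sequences.
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_contigs <- function(x, fasta_path, metadata_path) {
  stopifnot(inherits(x, "contig_set"), !is.null(x$seqs))
  Biostrings::writeXStringSet(x$seqs, fasta_path)
  write_bio_tsv(x$meta, metadata_path)
  invisible(c(fasta_path, metadata_path))
}

#' Construct / validate a sample sheet
#'
#' One row per sequencing library: `sample_id`, `participant`, `site`
#' (PC/DC/STL), `dataset` (MG/MV/MT), `inflammation_grade` (0-2 or NA).
#' Absent libraries (e.g. a failed MT prep for one site) are simply absent
#' rows, never zero-count columns.
#'
#' @param df data.frame of sample metadata.
#' @return The validated data.frame with class `sample_sheet`.
#' @export
sample_sheet <- function(df) {
  required <- c("sample_id", "participant", "site", "dataset")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("sample sheet missing columns: ", paste(miss, collapse = ", "))
  if (!"inflammation_grade" %in% names(df)) df$inflammation_grade <- NA_integer_
  bad <- setdiff(unique(df$site), SITES)
  if (length(bad)) stop("unknown site: ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(df$dataset), DATASETS)
  if (length(bad)) stop("unknown dataset: ", paste(bad, collapse = ", "))
  key <- paste(df$participant, df$site, df$dataset)
  if (anyDuplicated(key))
    stop("duplicate (participant, site, dataset): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id")
  g <- df$inflammation_grade
  if (any(!is.na(g) & (g < 0 | g > 2))) stop("inflammation_grade must be 0-2 or NA")
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Read a sample sheet TSV
#' @param path File path.
#' @return A `sample_sheet`.
#' @export
read_sample_sheet <- function(path) sample_sheet(read_bio_tsv(path))

#' Construct an omics matrix
#'
#' Per-(contig, sample) read counts paired with breadth of coverage (the
#' fraction of contig positions covered by at least one read) for one dataset
#' (MG, MV or MT).
#'
#' @param counts Integer matrix, rows = contigs, columns = samples.
#' @param breadth Numeric matrix in `[0, 1]`, same shape as `counts`.
#' @param dataset One of "MG", "MV", "MT".
#' @param samples Optional `sample_sheet` restricted to these columns.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(counts, breadth, dataset, samples = NULL) {
  if (!dataset %in% DATASETS) stop("unknown dataset: ", dataset)
  counts <- as.matrix(counts); breadth <- as.matrix(breadth)
  if (!identical(dim(counts), dim(breadth)))
    stop("counts and breadth must share shape")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry contig (row) and sample (column) names")
  if (any(counts < 0)) stop("negative counts")
  if (any(counts != round(counts))) stop("counts must be integers")
  if (any(breadth < 0 | breadth > 1)) stop("breadth outside [0, 1]")
  if (any((breadth == 0) != (counts == 0)))
    stop("breadth == 0 must hold exactly where counts == 0")
  dimnames(breadth) <- dimnames(counts)
  if (!is.null(samples)) {
    miss <- setdiff(colnames(counts), samples$sample_id)
    if (length(miss)) stop("samples missing from sheet: ", paste(miss, collapse = ", "))
    samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
    if (any(samples$dataset != dataset))
      stop("sample sheet dataset disagrees with matrix dataset")
  }
  structure(list(counts = counts, breadth = breadth, dataset = dataset,
                 samples = samples), class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat("<omics_matrix> ", x$dataset, ": ", nrow(x$counts), " contigs x ",
      ncol(x$counts), " samples\n", sep = "")
  invisible(x)
}

#' Read a count + breadth matrix from TSV
#'
#' Expected layout: a `contig_id` column, then per sample a pair of columns
#' `<sample_id>.count` and `<sample_id>.breadth`. Cells absent from the file
#' (contigs missing for a sample) are zero-filled.
#'
#' @param tsv_path File path.
#' @param dataset One of "MG", "MV", "MT".
#' @param samples Optional `sample_sheet`; column names must resolve to its
#'   sample ids.
#' @return An `omics_matrix`.
#' @export
read_counts <- function(tsv_path, dataset, samples = NULL) {
  df <- read_bio_tsv(tsv_path)
  if (!"contig_id" %in% names(df)) stop("counts table lacks contig_id column")
  cn <- setdiff(names(df), "contig_id")
  ids <- unique(sub("\\.(count|breadth)$", "", cn))
  need <- c(paste0(ids, ".count"), paste0(ids, ".breadth"))
  miss <- setdiff(need, cn)
  if (length(miss)) stop("unpaired count/breadth columns: ", paste(miss, collapse = ", "))
  if (!is.null(samples)) {
    unknown <- setdiff(ids, samples$sample_id)
    if (length(unknown))
      stop("column names do not resolve to sample ids: ", paste(unknown, collapse = ", "))
  }
  counts <- as.matrix(df[paste0(ids, ".count")])
  breadth <- as.matrix(df[paste0(ids, ".breadth")])
  counts[is.na(counts)] <- 0L
  breadth[is.na(breadth)] <- 0
  if (all(counts == round(counts))) storage.mode(counts) <- "integer"
  dimnames(counts) <- dimnames(breadth) <- list(df$contig_id, ids)
  omics_matrix(counts, breadth, dataset, samples)
}

#' Write an omics matrix to TSV
#' @param x An `omics_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path) {
  stopifnot(inherits(x, "omics_matrix"))
  df <- data.frame(contig_id = rownames(x$counts), check.names = FALSE)
  for (s in colnames(x$counts)) {
    df[[paste0(s, ".count")]] <- x$counts[, s]
    df[[paste0(s, ".breadth")]] <- x$breadth[, s]
  }
  write_bio_tsv(df, path, comment = paste0("dataset=", x$dataset))
}

#' Read a gene/ORF annotation table
#'
#' Columns: `gene_id`, `contig_id`, `start`, `end` (1-based inclusive),
#' `strand` (+/-), `db` (VOG, pVOG, PFAM, KEGG, TIGRFAM or none), `term_id`,
#' `term_name` (none encoded as NA).
#'
#' @param path File path.
#' @return A validated data.frame.
#' @export
read_genes <- function(path) validate_genes(read_bio_tsv(path))

#' Validate a gene table
#' @param genes data.frame of gene records.
#' @return The validated data.frame.
#' @export
validate_genes <- function(genes) {
  required <- c("gene_id", "contig_id", "start", "end", "strand", "db",
                "term_id", "term_name")
  miss <- setdiff(required, names(genes))
  if (length(miss)) stop("gene table missing columns: ", paste(miss, collapse = ", "))
  if (any(genes$start < 1) || any(genes$end < genes$start))
    stop("gene coordinates must satisfy 1 <= start <= end")
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be + or -")
  db <- ifelse(is.na(genes$db), "none", genes$db)
  no_db <- db == "none"
  if (any(no_db != is.na(genes$term_id)))
    stop("db == none must hold exactly where term_id is NA")
  genes
}

#' Read a host-score table (WIsH-style)
#'
#' Columns: `vc_id`, `host_contig_id`, `score` (log likelihood),
#' `p_adjusted`. Scores are expected to be pre-computed by an external
#' host-prediction tool; this package only filters and correlates them.
#'
#' @param path File path.
#' @param p_max Keep rows with `p_adjusted < p_max` (default `1e-5`).
#' @return A data.frame of retained virus-host pairs.
#' @export
read_host_scores <- function(path, p_max = 1e-5) {
  df <- read_bio_tsv(path)
  required <- c("vc_id", "host_contig_id", "score", "p_adjusted")
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("host-score table missing columns: ", paste(miss, collapse = ", "))
  if (any(df$p_adjusted < 0 | df$p_adjusted > 1)) stop("p_adjusted outside [0, 1]")
  if (anyDuplicated(paste(df$vc_id, df$host_contig_id)))
    stop("duplicate (vc_id, host_contig_id) pairs")
  df[df$p_adjusted < p_max, , drop = FALSE]
}

#' Validate a data bundle before analysis
#'
#' Cross-checks contigs, samples, matrices and genes and returns a report
#' rather than erroring: `fatal` findings must stop a pipeline run, warnings
#' (e.g. no MT samples, which only disables the transcription module) need
#' not.
#'
#' @param contigs A `contig_set`.
#' @param samples A `sample_sheet`.
#' @param matrices Named list of `omics_matrix` objects (names MG/MV/MT).
#' @param genes Optional gene table.
#' @return data.frame with columns `level` ("fatal"/"warning"), `code`,
#'   `message`; zero rows when the bundle is fully consistent.
#' @export
validate_bundle <- function(contigs, samples, matrices, genes = NULL) {
  findings <- list()
  add <- function(level, code, message)
    findings[[length(findings) + 1L]] <<- data.frame(level = level, code = code,
                                                     message = message)
  for (d in names(matrices)) {
    m <- matrices[[d]]
    orphan <- setdiff(rownames(m$counts), contigs$meta$contig_id)
    if (length(orphan))
      add("fatal", "matrix_orphan_contig",
          paste0(d, " matrix rows not in contig set: ",
                 paste(head(orphan, 5), collapse = ", ")))
    unknown <- setdiff(colnames(m$counts), samples$sample_id)
    if (length(unknown))
      add("fatal", "matrix_unknown_sample",
          paste0(d, " matrix columns not in sample sheet: ",
                 paste(unknown, collapse = ", ")))
  }
  covered <- unique(unlist(lapply(matrices, function(m) rownames(m$counts))))
  absent <- setdiff(contigs$meta$contig_id, covered)
  if (length(absent))
    add("warning", "contig_absent_from_matrices",
        paste0(length(absent), " contigs appear in no count matrix"))
  if (!is.null(genes)) {
    orphan <- setdiff(genes$contig_id, contigs$meta$contig_id)
    if (length(orphan))
      add("fatal", "gene_orphan_contig",
          paste0("genes on unknown contigs: ", paste(head(orphan, 5), collapse = ", ")))
    known <- genes$contig_id %in% contigs$meta$contig_id
    len <- contigs$meta$length_bp[match(genes$contig_id[known], contigs$meta$contig_id)]
    if (any(genes$end[known] > len))
      add("fatal", "gene_beyond_contig", "gene end exceeds contig length")
  }
  for (d in DATASETS) {
    if (!any(samples$dataset == d))
      add(if (d == "MT") "warning" else "fatal", "dataset_missing",
          paste0("no ", d, " samples",
                 if (d == "MT") " (transcription module disabled)" else ""))
  }
  if (length(findings)) do.call(rbind, findings)
  else data.frame(level = character(), code = character(), message = character())
}

#' Stop on fatal validation findings
#' @param report Output of [validate_bundle()].
#' @return `report`, invisibly, when no finding is fatal.
#' @export
assert_valid_bundle <- function(report) {
  fatal <- report[report$level == "fatal", , drop = FALSE]
  if (nrow(fatal))
    stop("bundle validation failed:\n",
         paste0("  [", fatal$code, "] ", fatal$message, collapse = "\n"))
  invisible(report)
}
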