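## Containment clustering of contigs across datasets and the derived
## source-of-origin / integration-capable classification.
##
## Dereplication criterion: a contig belongs to a cluster when it aligns to
## the cluster representative at >= 95% identity across >= 90% of its own
## (the smaller contig's) length. Verification uses an exact-substring fast
## path (Biostrings::matchPattern) and falls back to local alignment; a
## sampled 21-mer containment prescreen (PDict) skips hopeless pairs, which
## for unrelated sequences is essentially all of them.

KMER_K <- 21L
KMER_FRAC_MIN <- 0.10

## sampled k-mer containment prescreen: fraction of query k-mers found in
## each target; returns logical matrix [query x target]
kmer_candidate_matrix <- function(qseqs, tseqs, k = KMER_K,
                                  frac_min = KMER_FRAC_MIN) {
  nq <- length(qseqs); nt <- length(tseqs)
  out <- matrix(FALSE, nq, nt, dimnames = list(names(qseqs), names(tseqs)))
  if (nq == 0 || nt == 0) return(out)
  qlen <- Biostrings::width(qseqs)
  short <- qlen < 3L * k
  out[short, ] <- TRUE   # too short to prescreen reliably; verify directly
  idx <- which(!short)
  if (!length(idx)) return(out)
  qchar <- as.character(qseqs[idx])
  kmers <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    len <- qlen[idx[i]]
    n_samp <- min(200L, max(16L, len %/% 500L))
    pos <- unique(round(seq(1L, len - k + 1L, length.out = n_samp)))
    km <- substring(qchar[i], pos, pos + k - 1L)
    km <- km[!grepl("[^ACGT]", km)]
    kmers[[i]] <- km
  }
  n_per <- lengths(kmers)
  keep <- n_per > 0L
  if (!any(keep)) { out[idx, ] <- TRUE; return(out) }
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(unlist(kmers[keep])))
  counts <- Biostrings::vcountPDict(pd, tseqs)   # patterns x targets
  grp <- rep(seq_along(idx)[keep], n_per[keep])
  frac <- rowsum((counts > 0) + 0, grp) / n_per[keep]
  out[idx[keep], ] <- frac >= frac_min
  if (any(!keep)) out[idx[!keep], ] <- TRUE
  out
}

## verify containment of query (smaller) inside target; NULL if below
## thresholds, else a one-row data.frame ContainmentHit
verify_containment <- function(qid, tid, qseq, tseq, identity_min,
                               coverage_min) {
  hit <- function(identity, coverage, s, e)
    data.frame(query_id = qid, target_id = tid, identity = identity,
               coverage_of_smaller = coverage, target_start = s,
               target_end = e, stringsAsFactors = FALSE)
  if (length(qseq) <= 20000L) {
    m <- Biostrings::matchPattern(qseq, tseq)
    if (length(m) > 0)
      return(hit(1, 1, Biostrings::start(m)[1], Biostrings::end(m)[1]))
  } else {
    ## matchPattern caps patterns at 20 kb; plain fixed-string search instead
    pos <- regexpr(as.character(qseq), as.character(tseq), fixed = TRUE)
    if (pos > 0)
      return(hit(1, 1, as.integer(pos), as.integer(pos) + length(qseq) - 1L))
  }
  if (identity_min >= 1 || coverage_min > 1) return(NULL)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(qseq, tseq, type = "local",
                                       substitutionMatrix = sm,
                                       gapOpening = 4, gapExtension = 1)
  pat <- Biostrings::pattern(aln)
  cov <- (Biostrings::end(pat) - Biostrings::start(pat) + 1) / length(qseq)
  identity <- Biostrings::pid(aln, type = "PID1") / 100
  if (identity >= identity_min && cov >= coverage_min) {
    sub <- Biostrings::subject(aln)
    hit(identity, cov, Biostrings::start(sub), Biostrings::end(sub))
  } else NULL
}

#' Containment hits of query contigs inside target contigs
#'
#' Reports every (query, target) pair where the query aligns within the
#' target at `identity_min` identity over `coverage_min` of the query's
#' length. Queries longer than a target are never contained in it.
#'
#' @param queries,targets [contig_set()]s with sequences (may be the same
#'   object; self-pairs are skipped).
#' @param identity_min,coverage_min Containment thresholds (defaults 0.95 and
#'   0.90).
#' @return data.frame with columns `query_id`, `target_id`, `identity`,
#'   `coverage_of_smaller`, `target_start`, `target_end` (1-based inclusive
#'   aligned span on the target).
#' @export
containment_hits <- function(queries, targets, identity_min = 0.95,
                             coverage_min = 0.90) {
  stopifnot(inherits(queries, "contig_set"), inherits(targets, "contig_set"))
  if (is.null(queries$seqs) || is.null(targets$seqs))
    stop("containment requires sequences")
  cand <- kmer_candidate_matrix(queries$seqs, targets$seqs)
  qlen <- Biostrings::width(queries$seqs)
  tlen <- Biostrings::width(targets$seqs)
  hits <- list()
  for (i in seq_len(nrow(cand))) {
    for (j in which(cand[i, ])) {
      qid <- names(queries$seqs)[i]; tid <- names(targets$seqs)[j]
      if (qid == tid || qlen[i] > tlen[j]) next
      h <- verify_containment(qid, tid, queries$seqs[[i]], targets$seqs[[j]],
                              identity_min, coverage_min)
      if (!is.null(h)) hits[[length(hits) + 1L]] <- h
    }
  }
  if (length(hits)) do.call(rbind, hits)
  else data.frame(query_id = character(), target_id = character(),
                  identity = numeric(), coverage_of_smaller = numeric(),
                  target_start = integer(), target_end = integer())
}

#' Greedy containment clustering of contigs
#'
#' Contigs are sorted by length descending (ties broken by id); each contig
#' joins the first existing cluster, in founding order, whose representative
#' contains it at `identity_min` identity over `coverage_min` of its own
#' length, else founds a new cluster. Deterministic given the inputs.
#'
#' @param contigs A [contig_set()] with sequences.
#' @param identity_min,coverage_min Containment thresholds.
#' @return An object of class `cluster_result`: list with `membership`
#'   (data.frame `contig_id`, `cluster_id`, `is_representative`) and `hits`
#'   (the member-to-representative [containment_hits()] rows).
#' @export
containment_cluster <- function(contigs, identity_min = 0.95,
                                coverage_min = 0.90) {
  stopifnot(inherits(contigs, "contig_set"))
  if (is.null(contigs$seqs))
    stop("contigs without sequences: ",
         paste(head(contigs$meta$contig_id, 5), collapse = ", "))
  ids <- contigs$meta$contig_id
  lens <- contigs$meta$length_bp
  ord <- order(-lens, ids)
  seqs <- contigs$seqs[ids]
  cand <- kmer_candidate_matrix(seqs, seqs)
  reps <- integer(0)                 # indices (into ids) of representatives
  assign <- integer(length(ids))     # rep index per contig
  hits <- list()
  for (i in ord) {
    joined <- FALSE
    for (r in reps) {
      if (!cand[i, r] || lens[i] > lens[r]) next
      h <- verify_containment(ids[i], ids[r], seqs[[i]], seqs[[r]],
                              identity_min, coverage_min)
      if (!is.null(h)) {
        assign[i] <- r
        hits[[length(hits) + 1L]] <- h
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, i)
      assign[i] <- i
    }
  }
  membership <- data.frame(contig_id = ids, cluster_id = ids[assign],
                           is_representative = assign == seq_along(ids),
                           stringsAsFactors = FALSE)
  hits <- if (length(hits)) do.call(rbind, hits)
          else data.frame(query_id = character(), target_id = character(),
                          identity = numeric(), coverage_of_smaller = numeric(),
                          target_start = integer(), target_end = integer())
  structure(list(membership = membership, hits = hits,
                 identity_min = identity_min, coverage_min = coverage_min),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$membership), " contigs in ",
      sum(x$membership$is_representative), " clusters\n", sep = "")
  invisible(x)
}

#' Classify viral-contig source of origin
#'
#' A VC (cluster) is sourced "both" iff its members were assembled from both
#' the metagenome and the metavirome, else "metavirome" or "metagenome".
#'
#' @param clusters A [containment_cluster()] result over viral contigs.
#' @param contigs The clustered [contig_set()] (provides per-contig `source`).
#' @return data.frame `vc_id` (cluster representative), `n_members`,
#'   `source`; the attribute `totals` tabulates VCs per source.
#' @export
classify_source <- function(clusters, contigs) {
  mem <- clusters$membership
  src <- contigs$meta$source[match(mem$contig_id, contigs$meta$contig_id)]
  out <- do.call(rbind, lapply(split(seq_len(nrow(mem)), mem$cluster_id),
    function(ix) {
      s <- unique(src[ix])
      lab <- if (all(c("metavirome", "metagenome") %in% s) || "both" %in% s)
        "both" else s
      data.frame(vc_id = mem$cluster_id[ix[1]], n_members = length(ix),
                 source = lab, stringsAsFactors = FALSE)
    }))
  rownames(out) <- NULL
  attr(out, "totals") <- table(factor(out$source, levels = SOURCES))
  out
}

#' Published-style source accounting of a family-by-source VC table
#'
#' Sums a table with one row per viral family and counts per source column
#' (`metavirome_only`, `metagenome_only`, `both`) into the headline
#' partition arithmetic: totals per source, the grand total, and the
#' percentage of VCs found in both datasets.
#'
#' @param tab data.frame with columns `family`, `metavirome_only`,
#'   `metagenome_only`, `both`.
#' @return list with `per_source` (named totals), `total`, `pct_both`,
#'   `pct_metavirome_only`, `pct_metagenome_only`.
#' @export
vc_source_accounting <- function(tab) {
  need <- c("metavirome_only", "metagenome_only", "both")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  per <- vapply(tab[need], sum, numeric(1))
  total <- sum(per)
  list(per_source = per, total = total,
       pct_both = 100 * per[["both"]] / total,
       pct_metavirome_only = 100 * per[["metavirome_only"]] / total,
       pct_metagenome_only = 100 * per[["metagenome_only"]] / total)
}

#' Classify VCs as integration-capable (IC) or non-integrated (NI)
#'
#' A VC is IC if (a) its cluster contains a metagenome-derived member flagged
#' as pruned from a longer contig with host flanks, or (b) one of its
#' metavirome-derived members is contained within a non-viral contig at the
#' clustering thresholds. `linked_host_contigs` records every non-viral
#' contig providing evidence; a VC may link to several hosts and one host may
#' carry several VCs.
#'
#' @param clusters A [containment_cluster()] result over viral contigs.
#' @param contigs The clustered viral [contig_set()].
#' @param nonviral A [contig_set()] of non-viral contigs with sequences.
#' @param identity_min,coverage_min Containment thresholds for evidence (b).
#' @return list with `classifications` (data.frame `vc_id`, `source`,
#'   `integration_class`, `evidence`, `linked_host_contigs` comma-separated)
#'   and `host_hits` (the VC-in-non-viral [containment_hits()], used for
#'   prophage masking).
#' @export
classify_integration <- function(clusters, contigs, nonviral,
                                 identity_min = 0.95, coverage_min = 0.90) {
  src <- classify_source(clusters, contigs)
  mem <- clusters$membership
  meta <- contigs$meta
  mv_ids <- meta$contig_id[meta$source == "metavirome"]
  mv_set <- subset_contigs(contigs, mv_ids)
  host_hits <- if (length(mv_ids) && length(nonviral))
    containment_hits(mv_set, nonviral, identity_min, coverage_min)
  else data.frame(query_id = character(), target_id = character(),
                  identity = numeric(), coverage_of_smaller = numeric(),
                  target_start = integer(), target_end = integer())
  rows <- lapply(split(mem$contig_id, mem$cluster_id), function(members) {
    m <- meta[match(members, meta$contig_id), , drop = FALSE]
    pruned_hosts <- unique(m$pruned_from[m$pruned_flanks & !is.na(m$pruned_from)])
    any_pruned <- any(m$pruned_flanks)
    contained_hosts <- unique(host_hits$target_id[host_hits$query_id %in% members])
    hosts <- unique(c(pruned_hosts, contained_hosts))
    evidence <- if (any_pruned) "pruned_flanks"
      else if (length(contained_hosts)) "contained_in_nonviral" else "none"
    data.frame(vc_id = mem$cluster_id[match(members[1], mem$contig_id)],
               integration_class = if (evidence == "none") "NI" else "IC",
               evidence = evidence,
               linked_host_contigs = paste(hosts, collapse = ","),
               stringsAsFactors = FALSE)
  })
  cls <- do.call(rbind, rows)
  rownames(cls) <- NULL
  cls$source <- src$source[match(cls$vc_id, src$vc_id)]
  cls <- cls[c("vc_id", "source", "integration_class", "evidence",
               "linked_host_contigs")]
  list(classifications = cls, host_hits = host_hits)
}

#' Mask prophage regions in non-viral host contigs
#'
#' Replaces each contained-VC span with N, merging overlapping spans first so
#' no position is double-masked, and records an `effective_length` (unmasked
#' positions) used for host length normalization.
#'
#' @param nonviral A [contig_set()] of non-viral contigs with sequences.
#' @param host_hits [containment_hits()] rows of VCs inside these contigs
#'   (e.g. from [classify_integration()]).
#' @return list with `contigs` (the masked `contig_set`, its metadata gaining
#'   `effective_length`) and `mask_table` (data.frame `contig_id`, `start`,
#'   `end` of merged masked runs, 1-based inclusive).
#' @export
mask_prophage_regions <- function(nonviral, host_hits) {
  stopifnot(inherits(nonviral, "contig_set"), !is.null(nonviral$seqs))
  meta <- nonviral$meta
  seqs <- nonviral$seqs
  meta$effective_length <- meta$length_bp
  mask_rows <- list()
  for (tid in unique(host_hits$target_id)) {
    if (!tid %in% meta$contig_id) next
    h <- host_hits[host_hits$target_id == tid, , drop = FALSE]
    iv <- merge_intervals(h$target_start, h$target_end)
    w <- iv[, "end"] - iv[, "start"] + 1L
    at <- IRanges::IRanges(start = iv[, "start"], end = iv[, "end"])
    seqs[[tid]] <- Biostrings::replaceAt(seqs[[tid]], at,
                                         Biostrings::DNAStringSet(strrep("N", w)))
    k <- match(tid, meta$contig_id)
    meta$effective_length[k] <- meta$length_bp[k] - sum(w)
    mask_rows[[tid]] <- data.frame(contig_id = tid, start = iv[, "start"],
                                   end = iv[, "end"], stringsAsFactors = FALSE)
  }
  mask_table <- if (length(mask_rows)) do.call(rbind, mask_rows)
    else data.frame(contig_id = character(), start = integer(), end = integer())
  rownames(mask_table) <- NULL
  out <- nonviral
  out$meta <- meta
  out$seqs <- seqs
  list(contigs = out, mask_table = mask_table)
}
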