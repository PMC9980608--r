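# Shared fixtures and independent oracles.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# The default synthetic community (seed 42, ~500 VCs, 50 hosts), generated
# once per test run, plus its clustering and classification.
default_world <- function() memo("world", {
  spec <- community_spec()
  gen <- generate_genomes(spec)
  cnt <- simulate_counts(spec, gen)
  viral_ids <- gen$contigs$meta$contig_id[gen$contigs$meta$is_viral]
  viral <- subset_contigs(gen$contigs, viral_ids)
  nonviral <- subset_contigs(gen$contigs,
                             setdiff(gen$contigs$meta$contig_id, viral_ids))
  cl <- containment_cluster(viral)
  ic <- classify_integration(cl, viral, nonviral)
  nra <- lapply(cnt$matrices, compute_nra, contigs = gen$contigs)
  list(spec = spec, gen = gen, cnt = cnt, viral = viral, nonviral = nonviral,
       cl = cl, ic = ic, nra = nra)
})

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

mutate_seq <- function(s, rate) {
  v <- strsplit(s, "")[[1]]
  k <- which(runif(length(v)) < rate)
  for (i in k) v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1)
  paste(v, collapse = "")
}

make_contig_set <- function(seqs, is_viral = TRUE, source = "metavirome",
                            quality = "high") {
  n <- length(seqs)
  meta <- data.frame(contig_id = names(seqs), length_bp = nchar(seqs),
                     source = rep_len(source, n),
                     is_viral = rep_len(is_viral, n),
                     quality = rep_len(quality, n),
                     taxonomy_order = "Caudovirales",
                     taxonomy_family = "Siphoviridae",
                     stringsAsFactors = FALSE)
  contig_set(meta, Biostrings::DNAStringSet(seqs))
}

# A tiny omics_matrix with prescribed counts; breadth 1 where counts > 0
# unless given.
make_om <- function(counts, dataset = "MV", breadth = NULL) {
  counts <- as.matrix(counts)
  if (is.null(breadth)) breadth <- (counts > 0) * 1
  omics_matrix(counts, breadth, dataset)
}

## ---- independent oracles -------------------------------------------------

oracle_chao1 <- function(x) {
  s0 <- 0; a1 <- 0; a2 <- 0
  for (v in x) {
    if (v > 0) s0 <- s0 + 1
    if (v == 1) a1 <- a1 + 1
    if (v == 2) a2 <- a2 + 1
  }
  if (a2 > 0) s0 + a1 * a1 / (2 * a2) else s0 + a1 * (a1 - 1) / 2
}

oracle_nra <- function(counts, len) {
  out <- matrix(0, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  for (j in seq_len(ncol(counts))) {
    xi <- numeric(nrow(counts))
    for (i in seq_len(nrow(counts))) xi[i] <- counts[i, j] / len[i]
    if (sum(xi) > 0) out[, j] <- xi / sum(xi)
  }
  out
}

oracle_lr <- function(a, b, c, d) (a / b) / (c / d)   # counts, not rates

# Containment oracle: exhaustive all-pairs check using a different alignment
# route (global alignment of the query against every same-length window is
# infeasible; instead global-in-query "global-local" alignment, identity
# measured as matches over query length).
oracle_contained <- function(q, t, identity_min = 0.95, coverage_min = 0.90) {
  if (nchar(q) > nchar(t)) return(FALSE)
  if (grepl(q, t, fixed = TRUE)) return(TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q), Biostrings::DNAString(t), type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(1, -2),
    gapOpening = 4, gapExtension = 1)
  matches <- Biostrings::nmatch(aln)
  matches / nchar(q) >= identity_min * coverage_min &&
    matches / nchar(q) >= coverage_min * identity_min  # matches span the query
}

# Independent greedy containment clustering over an oracle edge matrix.
oracle_greedy_clusters <- function(ids, lens, contained) {
  ord <- order(-lens, ids)
  reps <- integer(0)
  assign <- setNames(character(length(ids)), ids)
  for (i in ord) {
    placed <- FALSE
    for (r in reps) {
      if (contained[ids[i], ids[r]]) {
        assign[ids[i]] <- ids[r]; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, i); assign[ids[i]] <- ids[i] }
  }
  assign
}
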