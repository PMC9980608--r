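## Alpha/beta diversity of the virome, rarefaction, intra- vs
## inter-individual contrasts, shared-VC site overlaps and phage-host
## abundance correlations.

#' Rarefy a count matrix
#'
#' Single seeded draw without replacement per sample, to a common depth.
#' Samples below the depth are dropped with a warning; rarefied column sums
#' equal `depth` exactly.
#'
#' @param counts Integer matrix (contigs x samples) or an [omics_matrix()].
#' @param depth Target depth; default the minimum column sum.
#' @param seed Integer seed.
#' @return Rarefied integer matrix.
#' @export
rarefy <- function(counts, depth = NULL, seed = 1) {
  if (inherits(counts, "omics_matrix")) counts <- counts$counts
  tot <- colSums(counts)
  if (is.null(depth)) depth <- min(tot)
  if (depth <= 0) stop("rarefaction depth must be positive")
  low <- tot < depth
  if (any(low)) {
    warning("dropping samples below depth: ",
            paste(colnames(counts)[low], collapse = ", "))
    counts <- counts[, !low, drop = FALSE]
  }
  set.seed(seed)
  out <- apply(counts, 2, function(x) {
    if (sum(x) == depth) return(as.integer(x))
    picked <- sample.int(sum(x), depth)
    tabulate(findInterval(picked - 1L, cumsum(x)) + 1L, nbins = length(x))
  })
  dimnames(out) <- dimnames(counts)
  out
}

#' Chao1 species-richness index
#'
#' `S_0 + a_1^2 / (2 a_2)` where `S_0` is the number of observed species,
#' `a_1` the number seen once, `a_2` the number seen twice. When `a_2 = 0`
#' the classic form is undefined and the standard bias-corrected fallback
#' `S_0 + a_1 (a_1 - 1) / 2` is used.
#'
#' @param counts Non-negative integer vector of species counts.
#' @return The Chao1 estimate (0, with a warning, for an empty vector).
#' @export
chao1 <- function(counts) {
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (!length(counts) || sum(counts) == 0) {
    warning("empty count vector")
    return(0)
  }
  s0 <- sum(counts > 0)
  a1 <- sum(counts == 1)
  a2 <- sum(counts == 2)
  if (a2 > 0) s0 + a1^2 / (2 * a2) else s0 + a1 * (a1 - 1) / 2
}

#' Shannon diversity index (natural log)
#'
#' `-sum P_i ln P_i` over species proportions; zero-count species contribute
#' nothing.
#'
#' @param counts Non-negative numeric vector (counts or abundances).
#' @return The Shannon index; NA with a warning for an all-zero vector.
#' @export
shannon <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot == 0) {
    warning("all-zero vector: Shannon undefined")
    return(NA_real_)
  }
  p <- counts[counts > 0] / tot
  -sum(p * log(p))
}

#' Population variance of a relative-abundance vector
#'
#' Variance of the NRA values over the VCs detected (NRA > 0) in a sample; an
#' evenness proxy (0 for a perfectly even community).
#'
#' @param nra Numeric vector of relative abundances for one sample.
#' @return The variance, or NA if fewer than two VCs are detected.
#' @export
population_variance <- function(nra) {
  x <- nra[nra > 0]
  if (length(x) < 2) return(NA_real_)
  var(x)
}

#' Per-sample alpha diversity table
#'
#' @param counts Rarefied count matrix (contigs x samples).
#' @return data.frame `sample_id`, `chao1`, `shannon`, `population_variance`.
#' @export
alpha_diversity <- function(counts) {
  data.frame(sample_id = colnames(counts),
             chao1 = apply(counts, 2, chao1),
             shannon = apply(counts, 2, shannon),
             population_variance = apply(counts, 2, function(x)
               population_variance(x / max(sum(x), 1))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `1 - 2 * sum(min(x_i, y_i)) / (sum x + sum y)` per sample pair.
#'
#' @param mat Abundance matrix, contigs x samples.
#' @return A symmetric dissimilarity matrix (samples x samples).
#' @export
bray_curtis <- function(mat) {
  n <- ncol(mat)
  d <- matrix(0, n, n, dimnames = list(colnames(mat), colnames(mat)))
  tot <- colSums(mat)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <-
      1 - 2 * sum(pmin(mat[, i], mat[, j])) / (tot[i] + tot[j])
  }
  d
}

#' Bray-Curtis contrasts: intra- vs inter-individual and colon vs stool
#'
#' Computes pairwise Bray-Curtis on NRA profiles, groups pairs into intra-
#' versus inter-participant comparisons (and, within participants, colonic
#' PC-DC versus colon-stool pairs), tests the groupings by two-sided
#' Wilcoxon rank-sum, and emits classical-MDS principal-coordinate positions.
#'
#' @param nra An [compute_nra()] profile (single dataset).
#' @return list with `dissimilarity` (matrix), `pairs` (long table with
#'   `type` = intra/inter and `site_contrast` = PC-DC / MLI-STL / other),
#'   `tests` (Wilcoxon p-values), `pcoa` (sample coordinates, 2 axes).
#' @export
bray_curtis_contrasts <- function(nra) {
  stopifnot(inherits(nra, "nra_profile"))
  if (ncol(nra$nra) < 2) stop("need at least 2 samples")
  d <- bray_curtis(nra$nra)
  sm <- nra$samples
  n <- ncol(d)
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    si <- sm[i, ]; sj <- sm[j, ]
    intra <- si$participant == sj$participant
    sites <- sort(c(si$site, sj$site))
    contrast <- if (identical(sites, c("DC", "PC"))) "PC-DC"
      else if ("STL" %in% sites) "MLI-STL" else "other"
    rows[[length(rows) + 1L]] <- data.frame(
      sample_1 = si$sample_id, sample_2 = sj$sample_id,
      type = if (intra) "intra" else "inter",
      site_contrast = contrast, distance = d[i, j], stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  wil <- function(x, y) if (length(x) && length(y))
    wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value else NA_real_
  tests <- data.frame(
    contrast = c("intra_vs_inter", "PCDC_vs_MLISTL_intra"),
    p_value = c(
      wil(pairs$distance[pairs$type == "intra"],
          pairs$distance[pairs$type == "inter"]),
      wil(pairs$distance[pairs$type == "intra" & pairs$site_contrast == "PC-DC"],
          pairs$distance[pairs$type == "intra" & pairs$site_contrast == "MLI-STL"])))
  pcoa <- cmdscale(stats::as.dist(d), k = min(2, n - 1))
  list(dissimilarity = d, pairs = pairs, tests = tests, pcoa = pcoa)
}

#' Shared-VC overlap partition across sampling sites
#'
#' Per participant, counts VCs in each region of the PC/DC/STL detection
#' Euler partition (breadth-filtered detection flags), plus the fractions
#' shared by all sites, unique to the colonic mucosal-luminal interface
#' (MLI), and unique to stool.
#'
#' @param detection Logical matrix, VCs x samples (e.g.
#'   `apply_breadth_filter(mv)$counts > 0`).
#' @param samples [sample_sheet()] rows matching the matrix columns.
#' @return data.frame per participant with the 7 region counts (`PC`, `DC`,
#'   `STL`, `PC.DC`, `PC.STL`, `DC.STL`, `PC.DC.STL`), `n_detected`,
#'   `frac_all_sites`, `frac_mli_only`, `frac_stl_only`, and a `reduced` flag
#'   when a site is missing.
#' @export
shared_vc_sets <- function(detection, samples) {
  rows <- lapply(split(seq_len(nrow(samples)), samples$participant),
    function(ix) {
      sm <- samples[ix, ]
      det <- list()
      for (s in SITES) {
        cols <- sm$sample_id[sm$site == s]
        if (length(cols))
          det[[s]] <- rowSums(detection[, cols, drop = FALSE]) > 0
      }
      reduced <- length(det) < 3
      m <- do.call(cbind, det)
      any_det <- rowSums(m) > 0
      key <- apply(m[any_det, , drop = FALSE], 1, function(z)
        paste(colnames(m)[z], collapse = "."))
      region_names <- c("PC", "DC", "STL", "PC.DC", "PC.STL", "DC.STL",
                        "PC.DC.STL")
      counts <- setNames(integer(length(region_names)), region_names)
      tb <- table(key)
      counts[names(tb)] <- as.integer(tb)
      total <- sum(any_det)
      mli_only <- sum(counts[c("PC", "DC", "PC.DC")])
      data.frame(participant = sm$participant[1], t(counts),
                 n_detected = total,
                 frac_all_sites = counts[["PC.DC.STL"]] / total,
                 frac_mli_only = mli_only / total,
                 frac_stl_only = counts[["STL"]] / total,
                 reduced = reduced, stringsAsFactors = FALSE)
    })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Matched vs unmatched phage-host abundance correlations
#'
#' For each matched (VC, host) pair, the Spearman correlation between the
#' VC's metavirome NRA and the host's metagenome NRA across the paired
#' (participant, site) samples; compared against a seeded null of random
#' VC-host re-pairings by two-sided Wilcoxon rank-sum.
#'
#' @param nra_mv,nra_mg [compute_nra()] profiles of the MV and MG datasets.
#' @param pairs data.frame `vc_id`, `host_contig_id` (pre-filtered, e.g. by
#'   [read_host_scores()]); an optional `pair_type` column is carried along.
#' @param n_null Number of null re-pairings (default 1000).
#' @param seed Seed for the null draw.
#' @param method Correlation method (default "spearman"; "pearson" applies
#'   the same machinery to transcriptional enrichments).
#' @return list with `matched` (per-pair rho table), `null_rho`, medians, and
#'   the Wilcoxon `p_value`.
#' @export
host_pair_correlations <- function(nra_mv, nra_mg, pairs, n_null = 1000,
                                   seed = 1, method = "spearman") {
  if (nrow(pairs) < 2) stop("need at least 2 matched pairs")
  kv <- pair_key(nra_mv$samples); kg <- pair_key(nra_mg$samples)
  shared <- intersect(kv, kg)
  if (length(shared) < 3) stop("need at least 3 paired samples")
  mv_cols <- vapply(shared, function(k) nra_mv$samples$sample_id[kv == k][1], "")
  mg_cols <- vapply(shared, function(k) nra_mg$samples$sample_id[kg == k][1], "")
  rho_of <- function(vc, host) {
    if (!vc %in% rownames(nra_mv$nra) || !host %in% rownames(nra_mg$nra))
      return(NA_real_)
    x <- nra_mv$nra[vc, mv_cols]; y <- nra_mg$nra[host, mg_cols]
    if (var(x) == 0 || var(y) == 0) return(NA_real_)
    cor(x, y, method = method)
  }
  matched <- pairs
  matched$rho <- mapply(rho_of, pairs$vc_id, pairs$host_contig_id)
  set.seed(seed)
  vcs <- unique(pairs$vc_id)
  hosts <- unique(pairs$host_contig_id)
  null_rho <- numeric(n_null)
  for (b in seq_len(n_null)) {
    vc <- sample(vcs, 1)
    host <- sample(setdiff(hosts, pairs$host_contig_id[pairs$vc_id == vc]), 1)
    null_rho[b] <- rho_of(vc, host)
  }
  m_ok <- matched$rho[!is.na(matched$rho)]
  n_ok <- null_rho[!is.na(null_rho)]
  p <- if (length(m_ok) && length(n_ok))
    wilcox.test(m_ok, n_ok, exact = FALSE, correct = TRUE)$p.value else NA_real_
  list(matched = matched, null_rho = null_rho,
       median_matched = median(m_ok), median_null = median(n_ok),
       p_value = p, method = method)
}
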