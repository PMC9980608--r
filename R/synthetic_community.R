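## Ground-truthed synthetic multiomic community generator.
##
## The generator states a world resembling a 3-participant, 3-site
## (proximal colon, distal colon, stool) paediatric IBD study sequenced with
## three technologies (whole metagenome MG, VLP-enriched metavirome MV,
## metatranscriptome MT of the two colonic sites). Free phages assemble only
## in the metavirome; prophages assemble in the metagenome as flank-pruned
## viral contigs inside non-viral host contigs; "active" prophages are
## additionally released as free particles and so also assemble in the
## metavirome. All latent states are returned as ground truth so downstream
## classification can be scored.

#' Specify a synthetic multiomic community
#'
#' Defaults state the package's reference world: ~500 viral contigs (VCs)
#' over 50 bacterial host contigs, three participants with the study-design
#' inflammation grades, one missing metatranscriptome library, dataset viral
#' NRA mass fractions of 75.1% (MV), 4.85% (MG) and 1.9% (MT), and host
#' contamination rising steeply at inflammation grade 2.
#'
#' @param n_participants Number of participants (default 3).
#' @param n_free_phages Number of free (never integrated) phages.
#' @param n_prophages Number of prophages embedded in host contigs.
#' @param n_host_contigs Number of non-viral host contigs.
#' @param fraction_temperate_active Fraction of prophages also released as
#'   free particles (detected in the metavirome).
#' @param ta_fraction Fraction of VCs that are transcriptionally active.
#' @param caudovirales_fraction Fraction of free phages drawn from the long
#'   (Caudovirales-like) length distribution; the rest are small-circular
#'   (Microviridae-like). Prophages are always Caudovirales-like.
#' @param caudo_meanlog,caudo_sdlog Log-normal genome-length parameters for
#'   Caudovirales-like phages (default median 25 kb).
#' @param micro_meanlog,micro_sdlog Log-normal length parameters for
#'   Microviridae-like phages (default median 5 kb).
#' @param sigma_global,sigma_participant,sigma_site Standard deviations of
#'   the global, per-participant and per-sample components of log abundance;
#'   defaults give intra-participant (site) correlation 0.83 versus
#'   inter-participant correlation 0.17.
#' @param p_integrase_prophage,p_integrase_free Probability that a
#'   Caudovirales-like prophage / free phage carries an integrase gene
#'   (defaults 0.696 and 0.498, the proportions observed in deeply sequenced
#'   gut viromes).
#' @param assigned_host_fraction Fraction of free phages given a
#'   probabilistic (WIsH-style) host assignment.
#' @param assigned_coupling Correlation of an assigned free phage's log
#'   abundance with its host's.
#' @param induction_sd Per-sample log-scale noise linking an active
#'   prophage's metavirome abundance to its host's abundance (flank-linked
#'   pairs are therefore tighter than assigned pairs).
#' @param mv_coupling Correlation of an active prophage's free-particle
#'   (metavirome) log abundance with its integrated (metagenome) abundance;
#'   below 1 because induction bursts decouple particle counts from host
#'   abundance, keeping the metavirome semi-independent of the metagenome.
#' @param mv_extra_sd Extra per-sample metavirome noise for free phages.
#' @param tx_noise_sd Per-sample log-scale noise linking metatranscriptome to
#'   metagenome abundance of transcriptionally active contigs.
#' @param viral_mass Named vector: target viral share of per-sample NRA mass
#'   in each dataset.
#' @param lib_size Named vector of per-sample library sizes (read pairs).
#' @param read_length Read length in bp used for the Lander-Waterman breadth
#'   model `breadth = 1 - exp(-depth_per_bp)`.
#' @param contamination_by_grade Named vector: host-read fraction of the raw
#'   metagenome library at inflammation grades "0", "1", "2".
#' @param marker_rate_per_million Named vector: cpn60-style housekeeping
#'   marker reads per million in MG and MV.
#' @param inflammation Matrix (participants x PC/DC) of inflammation grades;
#'   default mirrors the reference study design.
#' @param mt_missing Character vector of "participant-site" MT libraries that
#'   failed (default the third participant's distal colon).
#' @param flank_bp Range (min, max) of random host flank length on each side
#'   of an embedded prophage; minimum must be >= 2000.
#' @param host_max_bp Maximum allowed host contig length; exceeding it (too
#'   many/long prophages per host) is an error.
#' @param quality_probs_prophage,quality_probs_free Sampling probabilities of
#'   the five quality tiers for prophage and free VCs.
#' @param leak_prob Probability that a non-transcribed gene on a
#'   transcriptionally active VC receives a single stray MT count.
#' @param seed Integer seed; seeded runs are bit-reproducible.
#' @return A validated list of class `community_spec`.
#' @export
community_spec <- function(n_participants = 3,
                           n_free_phages = 350,
                           n_prophages = 150,
                           n_host_contigs = 50,
                           fraction_temperate_active = 0.5,
                           ta_fraction = 0.5,
                           caudovirales_fraction = 0.85,
                           caudo_meanlog = log(25000), caudo_sdlog = 0.35,
                           micro_meanlog = log(5000), micro_sdlog = 0.12,
                           sigma_global = 0.75, sigma_participant = 1.5,
                           sigma_site = 0.75,
                           p_integrase_prophage = 0.696,
                           p_integrase_free = 0.498,
                           assigned_host_fraction = 0.4,
                           assigned_coupling = 0.5,
                           induction_sd = 0.3,
                           mv_coupling = 0.7,
                           mv_extra_sd = 0.8,
                           tx_noise_sd = 0.5,
                           viral_mass = c(MG = 0.0485, MV = 0.751, MT = 0.019),
                           lib_size = c(MG = 2e6, MV = 2e6, MT = 2e7),
                           read_length = 150,
                           contamination_by_grade = c("0" = 0.02, "1" = 0.037,
                                                      "2" = 0.70),
                           marker_rate_per_million = c(MG = 172, MV = 1),
                           inflammation = NULL,
                           mt_missing = NULL,
                           flank_bp = c(2000, 4000),
                           host_max_bp = 3e5,
                           quality_probs_prophage = c(complete = 0.30, high = 0.30,
                                                      medium = 0.20, low = 0.15,
                                                      not_determined = 0.05),
                           quality_probs_free = c(complete = 0.10, high = 0.15,
                                                  medium = 0.25, low = 0.35,
                                                  not_determined = 0.15),
                           leak_prob = 0.10,
                           seed = 42) {
  participants <- paste0("P", seq_len(n_participants))
  if (is.null(inflammation)) {
    base <- rbind(c(2, 2), c(0, 1), c(0, 2))
    inflammation <- base[rep(seq_len(3), length.out = n_participants), , drop = FALSE]
    dimnames(inflammation) <- list(participants, c("PC", "DC"))
  }
  if (is.null(mt_missing))
    mt_missing <- paste0(participants[n_participants], "-DC")
  fr <- c(fraction_temperate_active, ta_fraction, caudovirales_fraction,
          p_integrase_prophage, p_integrase_free, assigned_host_fraction,
          assigned_coupling, mv_coupling, viral_mass, contamination_by_grade,
          leak_prob)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (any(c(caudo_sdlog, micro_sdlog, sigma_participant) <= 0))
    stop("scale parameters must be positive")
  if (flank_bp[1] < 2000) stop("flanks must be at least 2 kb")
  if (n_prophages > 0 && n_host_contigs == 0)
    stop("prophages require at least one host contig")
  spec <- list(n_participants = n_participants, participants = participants,
               sites = SITES,
               n_free_phages = n_free_phages, n_prophages = n_prophages,
               n_host_contigs = n_host_contigs,
               fraction_temperate_active = fraction_temperate_active,
               ta_fraction = ta_fraction,
               caudovirales_fraction = caudovirales_fraction,
               caudo_meanlog = caudo_meanlog, caudo_sdlog = caudo_sdlog,
               micro_meanlog = micro_meanlog, micro_sdlog = micro_sdlog,
               sigma_global = sigma_global, sigma_participant = sigma_participant,
               sigma_site = sigma_site,
               p_integrase_prophage = p_integrase_prophage,
               p_integrase_free = p_integrase_free,
               assigned_host_fraction = assigned_host_fraction,
               assigned_coupling = assigned_coupling,
               induction_sd = induction_sd, mv_coupling = mv_coupling,
               mv_extra_sd = mv_extra_sd,
               tx_noise_sd = tx_noise_sd,
               viral_mass = viral_mass, lib_size = lib_size,
               read_length = read_length,
               contamination_by_grade = contamination_by_grade,
               marker_rate_per_million = marker_rate_per_million,
               inflammation = inflammation, mt_missing = mt_missing,
               flank_bp = flank_bp, host_max_bp = host_max_bp,
               quality_probs_prophage = quality_probs_prophage,
               quality_probs_free = quality_probs_free,
               leak_prob = leak_prob, seed = seed)
  class(spec) <- "community_spec"
  spec
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Gene vocabulary: term, annotation database, and (for genes on
## transcriptionally active VCs) the per-gene transcription probability,
## with a bonus on packaging protein 1 for integration-capable VCs.
GENE_VOCAB <- data.frame(
  term_id   = c("VOG00035", "VOG06177", "VOG00123", "VOG00456", "VOG00789",
                "VOG01011", NA),
  term_name = c("Integrase", "repressor protein cI", "major capsid protein",
                "terminase large subunit", "packaging protein 1",
                "ParB-like nuclease domain protein", NA),
  db        = c("VOG", "VOG", "VOG", "VOG", "VOG", "VOG", "none"),
  p_place   = c(NA, 0.5, 0.7, 0.4, 0.3, 0.15, NA),
  p_tx      = c(0.84, 0.82, 0.60, 0.50, 0.50, 0.55, 0.45),
  tx_ic_bonus = c(0, 0.05, 0, -0.1, 0.25, 0.1, 0),
  stringsAsFactors = FALSE)

#' Generate synthetic genomes, gene annotations and ground truth
#'
#' Free and active phages become metavirome contigs (`MV_Vxxxx`); prophages
#' become flank-pruned metagenome viral contigs (`MG_Vxxxx`, flagged
#' `pruned_flanks` with `pruned_from` naming the host) whose sequence is also
#' embedded verbatim, with >= 2 kb random flanks, inside the non-viral host
#' contig (`Hxxx`). Gene records are placed on the contig that containment
#' clustering will elect as a cluster representative.
#'
#' @param spec A [community_spec()].
#' @param sequences Synthesize nucleotide sequences (default TRUE). With
#'   FALSE only lengths, coordinates and labels are drawn -- much faster for
#'   replicate label-recovery studies that never touch clustering. The two
#'   modes consume different random streams.
#' @return A list with elements `contigs` (a [contig_set()] with sequences,
#'   or metadata only), `genes` (gene table), `host_scores` (WIsH-style
#'   assignment table, including decoy rows above the p-value filter), and
#'   `truth` (see [truth_report()]).
#' @export
generate_genomes <- function(spec, sequences = TRUE) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(spec$seed)
  n_vc <- spec$n_free_phages + spec$n_prophages
  vc_id <- sprintf("V%04d", seq_len(n_vc))
  lifestyle <- c(rep("free", spec$n_free_phages), rep("prophage", spec$n_prophages))
  n_active <- round(spec$fraction_temperate_active * spec$n_prophages)
  active <- lifestyle == "prophage" &
    seq_len(n_vc) %in% (spec$n_free_phages + sample.int(spec$n_prophages, n_active))
  lifestyle[lifestyle == "prophage"] <- ifelse(active[lifestyle == "prophage"],
                                               "prophage_active", "prophage_inactive")

  is_caudo <- lifestyle != "free" |
    runif(n_vc) < spec$caudovirales_fraction
  len <- ifelse(is_caudo,
                round(exp(rnorm(n_vc, spec$caudo_meanlog, spec$caudo_sdlog))),
                round(exp(rnorm(n_vc, spec$micro_meanlog, spec$micro_sdlog))))
  tax_order <- ifelse(is_caudo, "Caudovirales", "unassigned")
  tax_family <- ifelse(is_caudo,
                       sample(c("Siphoviridae", "Myoviridae", "Podoviridae"),
                              n_vc, replace = TRUE, prob = c(0.6, 0.25, 0.15)),
                       "Microviridae")
  quality <- character(n_vc)
  pro <- lifestyle != "free"
  quality[pro] <- sample(QUALITY_TIERS, sum(pro), replace = TRUE,
                         prob = spec$quality_probs_prophage)
  quality[!pro] <- sample(QUALITY_TIERS, sum(!pro), replace = TRUE,
                          prob = spec$quality_probs_free)

  true_ta <- runif(n_vc) < spec$ta_fraction
  true_integrase <- is_caudo &
    runif(n_vc) < ifelse(pro, spec$p_integrase_prophage, spec$p_integrase_free)

  ## hosts: prophages dealt round-robin
  host_id <- if (spec$n_host_contigs > 0) sprintf("H%03d", seq_len(spec$n_host_contigs))
             else character()
  true_host <- rep(NA_character_, n_vc)
  if (spec$n_prophages > 0)
    true_host[pro] <- host_id[rep_len(seq_len(spec$n_host_contigs), spec$n_prophages)]

  ## sequences (or just the length/coordinate bookkeeping)
  phage_seq <- if (sequences) vapply(len, random_dna, character(1))
  host_seq <- character(spec$n_host_contigs)
  host_len <- integer(spec$n_host_contigs)
  prophage_start <- rep(NA_integer_, n_vc)
  for (h in seq_len(spec$n_host_contigs)) {
    idx <- which(!is.na(true_host) & true_host == host_id[h])
    parts <- character(0)
    pos <- 0L
    for (i in idx) {
      fl <- sample(spec$flank_bp[1]:spec$flank_bp[2], 1)
      if (sequences) parts <- c(parts, random_dna(fl), phage_seq[i])
      pos <- pos + fl
      prophage_start[i] <- pos + 1L
      pos <- pos + len[i]
    }
    fl <- sample(spec$flank_bp[1]:spec$flank_bp[2], 1)
    if (sequences) parts <- c(parts, random_dna(fl))
    pos <- pos + fl
    if (pos > spec$host_max_bp)
      stop("prophage load exceeds host contig budget (", pos, " > ",
           spec$host_max_bp, " bp) for ", host_id[h])
    if (sequences) host_seq[h] <- paste(parts, collapse = "")
    host_len[h] <- pos
  }

  ## contig records: clustering representative id per VC
  in_mv <- lifestyle %in% c("free", "prophage_active")
  in_mg <- pro
  rep_id <- ifelse(in_mg, paste0("MG_", vc_id), paste0("MV_", vc_id))

  mk_meta <- function(ids, lens, source, viral, qual, ord, fam, pruned, pruned_from)
    data.frame(contig_id = ids, length_bp = as.integer(lens), source = source,
               is_viral = viral, quality = qual, taxonomy_order = ord,
               taxonomy_family = fam, pruned_flanks = pruned,
               pruned_from = pruned_from, stringsAsFactors = FALSE)
  meta <- rbind(
    mk_meta(paste0("MV_", vc_id[in_mv]), len[in_mv], "metavirome", TRUE,
            quality[in_mv], tax_order[in_mv], tax_family[in_mv], FALSE,
            NA_character_),
    mk_meta(paste0("MG_", vc_id[in_mg]), len[in_mg], "metagenome", TRUE,
            quality[in_mg], tax_order[in_mg], tax_family[in_mg], TRUE,
            true_host[in_mg]),
    if (spec$n_host_contigs > 0)
      mk_meta(host_id, host_len, "metagenome", FALSE, "not_determined",
              sample(c("Clostridiales", "Bacteroidales"), spec$n_host_contigs,
                     replace = TRUE, prob = c(0.8, 0.2)),
              "unassigned", FALSE, NA_character_))
  seqs <- if (sequences) Biostrings::DNAStringSet(
    c(setNames(phage_seq[in_mv], paste0("MV_", vc_id[in_mv])),
      setNames(phage_seq[in_mg], paste0("MG_", vc_id[in_mg])),
      setNames(host_seq, host_id)))
  contigs <- contig_set(meta, seqs)

  ## genes on representative contigs, 1 kb slots, ~1 gene / 2 kb
  gene_rows <- vector("list", n_vc)
  for (i in seq_len(n_vc)) {
    n_slots <- max(1L, len[i] %/% 1000L)
    terms <- character(0)
    if (true_integrase[i]) terms <- "Integrase"
    if (is_caudo[i])
      for (k in which(!is.na(GENE_VOCAB$p_place)))
        if (runif(1) < GENE_VOCAB$p_place[k])
          terms <- c(terms, GENE_VOCAB$term_name[k])
    n_filler <- max(0L, min(n_slots - length(terms), round(n_slots / 2) - length(terms)))
    terms <- c(terms, rep(NA_character_, n_filler))
    if (!length(terms)) next
    terms <- terms[seq_len(min(length(terms), n_slots))]
    slots <- sort(sample.int(n_slots, length(terms)))
    vk <- match(terms, GENE_VOCAB$term_name)
    vk[is.na(terms)] <- nrow(GENE_VOCAB)
    gene_rows[[i]] <- data.frame(
      gene_id = sprintf("%s_g%02d", vc_id[i], seq_along(terms)),
      contig_id = rep_id[i],
      start = (slots - 1L) * 1000L + 1L,
      end = pmin((slots - 1L) * 1000L + 900L, len[i]),
      strand = sample(c("+", "-"), length(terms), replace = TRUE),
      db = GENE_VOCAB$db[vk], term_id = GENE_VOCAB$term_id[vk],
      term_name = GENE_VOCAB$term_name[vk],
      p_tx = GENE_VOCAB$p_tx[vk] +
        if (pro[i]) GENE_VOCAB$tx_ic_bonus[vk] else 0,
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, gene_rows)
  true_tx <- true_ta[match(sub("_g\\d+$", "", genes$gene_id), vc_id)] &
    runif(nrow(genes)) < pmin(1, genes$p_tx)
  gene_truth <- data.frame(gene_id = genes$gene_id, true_transcribed = true_tx)
  genes$p_tx <- NULL
  genes <- validate_genes(genes)

  ## WIsH-style host scores: true assignments for a fraction of free phages,
  ## plus decoy rows that the adjusted-p filter must drop
  assigned_host <- rep(NA_character_, n_vc)
  if (spec$n_host_contigs > 0) {
    cand <- which(lifestyle == "free")
    n_assign <- round(spec$assigned_host_fraction * length(cand))
    pick <- sample(cand, n_assign)
    assigned_host[pick] <- sample(host_id, n_assign, replace = TRUE)
  }
  hs_idx <- which(!is.na(assigned_host))
  host_scores <- data.frame(
    vc_id = rep_id[hs_idx], host_contig_id = assigned_host[hs_idx],
    score = rnorm(length(hs_idx), -1.2, 0.1),
    p_adjusted = 10^-runif(length(hs_idx), 6, 12), stringsAsFactors = FALSE)
  if (spec$n_host_contigs > 0 && length(hs_idx)) {
    n_decoy <- max(1L, length(hs_idx) %/% 10L)
    decoy_vc <- sample(setdiff(rep_id, host_scores$vc_id), n_decoy)
    host_scores <- rbind(host_scores, data.frame(
      vc_id = decoy_vc,
      host_contig_id = sample(host_id, n_decoy, replace = TRUE),
      score = rnorm(n_decoy, -1.6, 0.1),
      p_adjusted = runif(n_decoy, 1e-4, 0.9)))
  }

  truth <- list(
    labels = data.frame(
      vc_id = vc_id, rep_contig_id = rep_id, true_lifestyle = lifestyle,
      true_host_contig = true_host, assigned_host = assigned_host,
      true_ta = true_ta, true_integrase = true_integrase,
      taxonomy_order = tax_order, quality = quality,
      length_bp = as.integer(len), prophage_start = prophage_start,
      stringsAsFactors = FALSE),
    genes = gene_truth,
    host_ids = host_id, host_len = host_len)
  list(contigs = contigs, genes = genes, host_scores = host_scores,
       truth = truth)
}

## latent log-abundance: global + participant + per-sample components,
## rows = entities, columns = participant:site
latent_abundance <- function(n, spec) {
  ps <- expand.grid(site = spec$sites, participant = spec$participants,
                    stringsAsFactors = FALSE)[, c(2, 1)]
  cols <- paste(ps$participant, ps$site, sep = "-")
  g <- rnorm(n, 0, spec$sigma_global)
  u <- matrix(rnorm(n * spec$n_participants, 0, spec$sigma_participant),
              n, spec$n_participants, dimnames = list(NULL, spec$participants))
  e <- matrix(rnorm(n * nrow(ps), 0, spec$sigma_site), n, nrow(ps))
  z <- g + u[, ps$participant, drop = FALSE] + e
  colnames(z) <- cols
  z
}

#' Simulate tri-omic count and breadth matrices from generated genomes
#'
#' Counts per sample are multinomial over the dataset's mapping universe with
#' probabilities proportional to abundance x length, after rescaling the
#' viral/non-viral abundance split to the dataset's stated viral NRA mass
#' fraction. Breadth follows the Lander-Waterman form
#' `1 - exp(-counts * read_length / contig_length)`. Metagenome libraries
#' lose a host-contamination fraction of reads set by the sample's
#' inflammation grade; cpn60-style marker-read tallies are emitted for QC.
#'
#' @param spec A [community_spec()].
#' @param genomes Output of [generate_genomes()].
#' @param seed Seed for the counting stage (defaults to `spec$seed + 1`).
#' @param gene_level Also simulate gene-level MT counts (default TRUE; switch
#'   off to speed up replicate draws that only need contig matrices).
#' @return A list: `matrices` (named list of MG/MV/MT [omics_matrix()]
#'   objects sharing a row universe of cluster-representative contig ids plus
#'   host contigs), `gene_counts` (gene x MT-sample count matrix),
#'   `samples` (a [sample_sheet()]), `qc` (host-read and marker-read
#'   tallies), and `abundance` (the latent true abundance matrices).
#' @export
simulate_counts <- function(spec, genomes, seed = spec$seed + 1L,
                            gene_level = TRUE) {
  stopifnot(inherits(spec, "community_spec"))
  set.seed(seed)
  tr <- genomes$truth$labels
  n_vc <- nrow(tr)
  n_host <- length(genomes$truth$host_ids)
  rows <- c(tr$rep_contig_id, genomes$truth$host_ids)
  len <- c(tr$length_bp, genomes$truth$host_len)

  z_host <- if (n_host) latent_abundance(n_host, spec) else
    matrix(0, 0, spec$n_participants * length(spec$sites))
  z_own <- latent_abundance(n_vc, spec)
  base_cols <- colnames(z_own)

  ## MG-scale latent abundance of each VC
  z_mg <- z_own
  pro <- tr$true_lifestyle != "free"
  if (n_host)
    z_mg[pro, ] <- z_host[match(tr$true_host_contig[pro], genomes$truth$host_ids), ,
                          drop = FALSE]
  assigned <- !is.na(tr$assigned_host)
  if (any(assigned)) {
    rho <- spec$assigned_coupling
    zh <- z_host[match(tr$assigned_host[assigned], genomes$truth$host_ids), ,
                 drop = FALSE]
    z_mg[assigned, ] <- rho * zh + sqrt(1 - rho^2) * z_own[assigned, , drop = FALSE]
  }

  ## MV latent: particle abundance of active prophages tracks the host only
  ## partially (induction bursts), making the metavirome semi-independent of
  ## the metagenome; z_own is independent of z_host for prophages
  rho_mv <- spec$mv_coupling
  ind_offset <- rnorm(n_vc, 0, 0.3)
  z_mv <- rho_mv * z_mg + sqrt(1 - rho_mv^2) * z_own + ind_offset +
    matrix(rnorm(n_vc * ncol(z_mg), 0, spec$induction_sd), n_vc)
  free_idx <- tr$true_lifestyle == "free"
  z_mv[free_idx, ] <- z_mg[free_idx, , drop = FALSE] +
    matrix(rnorm(sum(free_idx) * ncol(z_mg), 0, spec$mv_extra_sd), sum(free_idx))

  ## MT latent: coupled to MG
  tx_offset <- rnorm(n_vc, 0, 0.5)
  z_mt <- z_mg + tx_offset +
    matrix(rnorm(n_vc * ncol(z_mg), 0, spec$tx_noise_sd), n_vc)

  in_dataset <- list(
    MG = c(pro, rep(TRUE, n_host)),
    MV = c(tr$true_lifestyle %in% c("free", "prophage_active"), rep(TRUE, n_host)),
    MT = c(tr$true_ta, rep(TRUE, n_host)))
  z_by_ds <- list(MG = z_mg, MV = z_mv, MT = z_mt)

  ## sample sheet
  grid <- expand.grid(site = spec$sites, participant = spec$participants,
                      dataset = DATASETS, stringsAsFactors = FALSE)
  grid <- grid[!(grid$dataset == "MT" &
                 (grid$site == "STL" |
                  paste(grid$participant, grid$site, sep = "-") %in% spec$mt_missing)), ]
  grade <- rep(NA_integer_, nrow(grid))
  mli <- grid$site != "STL"
  grade[mli] <- spec$inflammation[cbind(grid$participant[mli], grid$site[mli])]
  samples <- sample_sheet(data.frame(
    sample_id = paste(grid$participant, grid$site, grid$dataset, sep = "-"),
    participant = grid$participant, site = grid$site, dataset = grid$dataset,
    inflammation_grade = as.integer(grade), stringsAsFactors = FALSE))

  host_frac_of <- function(g)
    ifelse(is.na(g), spec$contamination_by_grade["1"],
           spec$contamination_by_grade[as.character(g)])

  matrices <- list()
  qc_host <- list(); qc_marker <- list()
  true_abund <- list()
  for (d in DATASETS) {
    sm <- samples[samples$dataset == d, , drop = FALSE]
    if (!nrow(sm)) next
    counts <- matrix(0L, length(rows), nrow(sm),
                     dimnames = list(rows, sm$sample_id))
    abund <- matrix(0, length(rows), nrow(sm),
                    dimnames = list(rows, sm$sample_id))
    present <- in_dataset[[d]]
    for (j in seq_len(nrow(sm))) {
      base <- paste(sm$participant[j], sm$site[j], sep = "-")
      a <- numeric(length(rows))
      a[seq_len(n_vc)] <- exp(z_by_ds[[d]][, base])
      if (n_host) a[n_vc + seq_len(n_host)] <- exp(z_host[, base])
      a[!present] <- 0
      viral <- c(rep(TRUE, n_vc), rep(FALSE, n_host))
      ## rescale the viral abundance mass to the dataset's stated share
      vm <- spec$viral_mass[[d]]
      sv <- sum(a[viral]); sh <- sum(a[!viral])
      if (sv > 0 && sh > 0)
        a[viral] <- a[viral] * (vm / (1 - vm)) * (sh / sv)
      abund[, j] <- a / sum(a)
      lib <- spec$lib_size[[d]]
      host_reads <- 0L
      if (d == "MG") {
        hf <- host_frac_of(sm$inflammation_grade[j])
        host_reads <- rbinom(1, lib, hf)
      }
      mapped <- as.integer(lib - host_reads)
      w <- a * len
      counts[, j] <- as.integer(rmultinom(1, mapped, w / sum(w)))
      qc_host[[sm$sample_id[j]]] <- data.frame(
        sample_id = sm$sample_id[j], host_reads = host_reads,
        total_reads = lib)
      mk <- spec$marker_rate_per_million[d]
      if (!is.na(mk))
        qc_marker[[sm$sample_id[j]]] <- data.frame(
          sample_id = sm$sample_id[j],
          marker_reads = rpois(1, mk * mapped / 1e6),
          total_reads = mapped)
    }
    breadth <- 1 - exp(-(counts * spec$read_length) / len)
    breadth[counts == 0] <- 0
    matrices[[d]] <- omics_matrix(counts, breadth, d, sm)
    true_abund[[d]] <- abund
  }

  ## gene-level MT counts: a VC's MT reads allocated to its transcribed
  ## genes by length, plus stray single counts on non-transcribed genes
  genes <- genomes$genes
  gtx <- genomes$truth$genes$true_transcribed[
    match(genes$gene_id, genomes$truth$genes$gene_id)]
  mt <- matrices$MT
  gene_counts <- NULL
  if (gene_level && !is.null(mt)) {
    gene_counts <- matrix(0L, nrow(genes), ncol(mt$counts),
                          dimnames = list(genes$gene_id, colnames(mt$counts)))
    glen <- genes$end - genes$start + 1L
    for (v in seq_len(n_vc)) {
      gi <- which(genes$contig_id == tr$rep_contig_id[v])
      if (!length(gi)) next
      vc_counts <- mt$counts[tr$rep_contig_id[v], ]
      txi <- gi[gtx[gi]]
      for (j in seq_along(vc_counts)) {
        total <- round(vc_counts[j] * 0.8)
        if (length(txi) && total > 0)
          gene_counts[txi, j] <- as.integer(
            rmultinom(1, total, glen[txi] / sum(glen[txi])))
        leak <- gi[!gtx[gi]]
        if (length(leak) && vc_counts[j] > 0)
          gene_counts[leak, j] <- gene_counts[leak, j] +
            rbinom(length(leak), 1L, spec$leak_prob)
      }
    }
  }
  list(matrices = matrices, gene_counts = gene_counts, samples = samples,
       qc = list(host = do.call(rbind, unname(qc_host)),
                 marker = do.call(rbind, unname(qc_marker))),
       abundance = true_abund)
}

#' Generate a full synthetic community (genomes + counts)
#' @param spec A [community_spec()].
#' @return Concatenation of [generate_genomes()] and [simulate_counts()]
#'   outputs.
#' @export
simulate_community <- function(spec = community_spec()) {
  genomes <- generate_genomes(spec)
  counts <- simulate_counts(spec, genomes)
  c(genomes, counts)
}

#' Write the ground-truth label table
#'
#' @param truth The `truth` element of [generate_genomes()] output.
#' @param path Output TSV path.
#' @return The label data.frame, invisibly.
#' @export
truth_report <- function(truth, path = NULL) {
  tab <- truth$labels
  if (!is.null(path)) write_bio_tsv(tab, path)
  invisible(tab)
}
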