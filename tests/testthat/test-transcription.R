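make_profile <- function(counts, dataset, participants, sites, len = NULL) {
  ids <- paste(participants, sites, dataset, sep = "-")
  colnames(counts) <- ids
  sm <- sample_sheet(data.frame(sample_id = ids, participant = participants,
                                site = sites, dataset = dataset,
                                inflammation_grade = NA_integer_))
  om <- omics_matrix(counts, (counts > 0) * 1, dataset, sm)
  meta <- data.frame(contig_id = rownames(counts),
                     length_bp = len %||% rep(1000L, nrow(counts)),
                     source = "metavirome", is_viral = TRUE, quality = "high",
                     taxonomy_order = "Caudovirales", taxonomy_family = "y")
  list(nra = compute_nra(om, contig_set(meta)), contigs = contig_set(meta))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("TA calling respects threshold, quality scope and conventions", {
  counts <- matrix(c(5000L, 1L, 0L, 800L), 4, 1,
                   dimnames = list(c("hi", "lo", "zero", "lowq"), NULL))
  p <- make_profile(counts, "MT", "P1", "PC")
  p$contigs$meta$quality[4] <- "low"
  act <- call_ta(p$nra, p$contigs)
  calls <- setNames(act$vc_level$is_TA, act$vc_level$vc_id)
  expect_true(calls[["hi"]])              # 5e-6-scale NRA is TA
  expect_false(calls[["zero"]])           # zero NRA is not
  expect_false("lowq" %in% names(calls))  # low quality: never evaluated
  # threshold boundary: >= by default, > when strict
  nra_lo <- p$nra$nra["lo", 1]
  at <- call_ta(p$nra, p$contigs, ta_threshold = nra_lo)
  expect_true(at$vc_level$is_TA[at$vc_level$vc_id == "lo"])
  at2 <- call_ta(p$nra, p$contigs, ta_threshold = nra_lo, strict = TRUE)
  expect_false(at2$vc_level$is_TA[at2$vc_level$vc_id == "lo"])
  # TA set is monotone non-increasing in the threshold
  set.seed(41)
  cm <- matrix(rpois(40, 3) * 100L, 20, 2,
               dimnames = list(paste0("v", 1:20), NULL))
  pp <- make_profile(cm, "MT", c("P1", "P1"), c("PC", "DC"))
  thr <- sort(runif(5, 0, 0.1))
  n_ta <- vapply(thr, function(t)
    sum(call_ta(pp$nra, pp$contigs, ta_threshold = t)$vc_level$is_TA),
    numeric(1))
  expect_true(all(diff(n_ta) <= 0))
  # no MT samples: empty with warning
  expect_warning(e <- call_ta(NULL, p$contigs), "no MT samples")
  expect_equal(nrow(e$vc_level), 0)
})

test_that("transcribed-gene calls use the >1 rule within TA VCs only", {
  counts <- matrix(c(5000L, 10L), 2, 1, dimnames = list(c("ta", "silent"), NULL))
  p <- make_profile(counts, "MT", "P1", "PC")
  act <- call_ta(p$nra, p$contigs, ta_threshold = 0.01)  # only "ta" passes
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      contig_id = c("ta", "ta", "silent"),
                      start = 1L, end = 300L, strand = "+", db = "VOG",
                      term_id = "VOG1", term_name = "Integrase")
  gc <- matrix(c(2L, 1L, 100L), 3, 1,
               dimnames = list(genes$gene_id, colnames(p$nra$nra)))
  st <- call_transcribed_genes(gc, genes, act)
  expect_identical(st$status[st$gene_id == "g1"], "transcribed")      # 2 > 1
  expect_identical(st$status[st$gene_id == "g2"], "not_transcribed")  # 1 fails
  expect_identical(st$status[st$gene_id == "g3"], "not_evaluated")    # non-TA
  # the three states partition evaluated genes
  expect_setequal(unique(st$status),
                  c("transcribed", "not_transcribed", "not_evaluated"))
})

test_that("transcription ratios pair by site and exclude undefined cells", {
  mt <- make_profile(matrix(c(10L, 10L, 0L, 20L), 2,
                            dimnames = list(c("a", "b"), NULL)),
                     "MT", c("P1", "P1"), c("PC", "DC"))
  mg <- make_profile(matrix(c(10L, 10L, 5L, 0L), 2,
                            dimnames = list(c("a", "b"), NULL)),
                     "MG", c("P1", "P1"), c("PC", "DC"))
  rt <- transcription_ratio_table(mt$nra, mg$nra)
  pc_a <- rt$ratios[rt$ratios$id == "a" & rt$ratios$site == "PC", ]
  expect_equal(pc_a$ratio, 1)   # equal NRA -> ratio 1
  dc_b <- rt$ratios[rt$ratios$id == "b" & rt$ratios$site == "DC", ]
  expect_true(is.na(dc_b$ratio))  # MG zero -> undefined
  sb <- rt$summary[rt$summary$id == "b", ]
  expect_equal(sb$n_undefined, 1)
})

test_that("group ratio means and Wilcoxon recover planted contrast", {
  # two crAss-like stand-ins with planted mean MT/MG ratios 0.6 vs 0.2,
  # measured over >= 50 genes each
  set.seed(42)
  n <- 60
  ids <- c(paste0("A_g", 1:n), paste0("B_g", 1:n))
  mg_counts <- matrix(rpois(2 * n * 2, 2000) + 500L, 2 * n, 2,
                      dimnames = list(ids, NULL))
  ratio_true <- c(rep(0.6, n), rep(0.2, n)) * exp(rnorm(2 * n, 0, 0.25))
  mt_counts <- matrix(as.integer(round(mg_counts * ratio_true)), 2 * n, 2,
                      dimnames = list(ids, NULL))
  mt <- make_profile(mt_counts, "MT", c("P1", "P1"), c("PC", "DC"))
  mg <- make_profile(mg_counts, "MG", c("P1", "P1"), c("PC", "DC"))
  rt <- transcription_ratio_table(mt$nra, mg$nra)
  cmpr <- compare_transcription_ratios(rt, paste0("A_g", 1:n), paste0("B_g", 1:n))
  # NRA renormalization rescales both groups by a common per-sample factor,
  # preserving the planted 3x contrast; recover means within +-0.1 of the
  # rescaled targets and a decisive Wilcoxon
  scale <- (cmpr$mean1 + cmpr$mean2) / 0.8
  expect_equal(cmpr$mean1, 0.6 * scale, tolerance = 0.1 / 0.6)
  expect_equal(cmpr$mean2, 0.2 * scale, tolerance = 0.1 / 0.2)
  expect_lt(cmpr$p_value, 0.05)
})

test_that("multiomic correlations: identity, degeneracy, generator ordering", {
  mt <- make_profile(matrix(c(100L, 50L, 10L, 200L, 30L, 5L), 3,
                            dimnames = list(c("a", "b", "c"), NULL)),
                     "MT", c("P1", "P1"), c("PC", "DC"))
  # identical profiles -> r = 1
  mc <- multiomic_correlations(list(A = mt$nra, B = mt$nra))
  expect_equal(mc$r, 1)
  # constant profile -> undefined, flagged as NA
  const <- make_profile(matrix(10L, 3, 2, dimnames = list(c("a", "b", "c"), NULL)),
                        "MG", c("P1", "P1"), c("PC", "DC"))
  mc2 <- multiomic_correlations(list(A = mt$nra, B = const$nra))
  expect_true(is.na(mc2$r))
  # generator coupling: r(MT, MG) > r(MG, MV) in >= 90% of seeded runs
  world <- default_world()
  tr <- world$gen$truth$labels
  wins <- 0; runs <- 10
  for (s in seq_len(runs)) {
    cnt <- simulate_counts(world$spec, world$gen, seed = 500 + s,
                           gene_level = FALSE)
    nra <- lapply(cnt$matrices, compute_nra, contigs = world$gen$contigs)
    mc <- multiomic_correlations(nra, ids = tr$rep_contig_id)
    r <- setNames(mc$r, mc$pair)
    wins <- wins + (r[["MG-MT"]] > r[["MG-MV"]])
  }
  expect_gte(wins / runs, 0.9)
})

test_that("MT Chao1 falls below MG Chao1 when TA VCs are a strict subset", {
  # restrict to prophages, the VCs present in the metagenome, so that the
  # transcriptionally active set is a strict subset of the MG-present set
  world <- default_world()
  tr <- world$gen$truth$labels
  viral_rows <- tr$rep_contig_id[tr$true_lifestyle != "free"]
  mg <- world$cnt$matrices$MG$counts[viral_rows, ]
  mt <- world$cnt$matrices$MT$counts[viral_rows, ]
  chao_mg <- mean(apply(mg, 2, chao1))
  chao_mt <- mean(apply(mt, 2, chao1))
  expect_lt(chao_mt, chao_mg)
})
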