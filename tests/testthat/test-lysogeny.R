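test_that("integrase detection is a case-insensitive substring rule", {
  genes <- data.frame(
    gene_id = paste0("g", 1:5),
    contig_id = c("v1", "v1", "v2", "v3", "v4"),
    start = 1L, end = 500L, strand = "+",
    db = c("VOG", "pVOG", "VOG", "VOG", "none"),
    term_id = c("VOG00035", "pVOG0275", "VOG11667", "VOG00123", NA),
    term_name = c("Integrase", "integrase",
                  "DDE-type integrase/transposase/recombinase",
                  "major capsid protein", NA))
  det <- detect_integrase(genes)
  flags <- setNames(det$by_contig$has_integrase, det$by_contig$contig_id)
  expect_true(flags[["v1"]])
  expect_true(flags[["v2"]])   # substring match inside a composite term
  expect_false(flags[["v3"]])  # capsid-only contig not flagged
  expect_equal(det$n_integrase_genes, 3)
  expect_equal(det$n_contigs_with, 2)
  expect_setequal(as.character(det$census$term_id),
                  c("VOG00035", "pVOG0275", "VOG11667"))
  # exact term list override
  det2 <- detect_integrase(genes, terms = "VOG00035")
  expect_equal(det2$n_integrase_genes, 1)
})

test_that("gene_family_stats arithmetic and LR identities hold", {
  st <- gene_family_stats(71, 102, 148, 297)
  expect_equal(st$sensitivity, 71 / 102)
  expect_equal(st$specificity, 1 - 148 / 297)
  expect_equal(st$likelihood_ratio, oracle_lr(71, 102, 148, 297),
               tolerance = 1e-15)
  # LR from counts equals LR from (sens, spec) to 1e-12
  expect_equal(st$likelihood_ratio,
               st$sensitivity / (1 - st$specificity), tolerance = 1e-12)
  # equal proportions give LR exactly 1 (rational arithmetic)
  st_eq <- gene_family_stats(3, 6, 7, 14)
  expect_identical(st_eq$likelihood_ratio, 1)
  # uninformative family: sens 0.5, spec 0.5 -> LR 1
  expect_equal(gene_family_stats(5, 10, 5, 10)$likelihood_ratio, 1)
  # absent from all NI -> infinite
  expect_identical(gene_family_stats(4, 10, 0, 10)$likelihood_ratio, Inf)
  expect_error(gene_family_stats(1, 0, 1, 5), "empty")
  # oracle equivalence on 100 random count sets, to 1e-12
  set.seed(51)
  for (r in 1:100) {
    b <- sample(5:200, 1); d <- sample(5:200, 1)
    a <- sample.int(b, 1); c <- sample.int(d, 1)
    expect_equal(gene_family_stats(a, b, c, d)$likelihood_ratio,
                 oracle_lr(a, b, c, d), tolerance = 1e-12)
  }
})

test_that("LR ranking handles infinities and group-size rescaling", {
  stats <- data.frame(
    term_name = c("f1", "f2", "f3"),
    n_IC_with = c(8, 5, 9), n_IC_total = 10, n_NI_with = c(0, 5, 3),
    n_NI_total = 10,
    sensitivity = c(0.8, 0.5, 0.9), specificity = c(1, 0.5, 0.7),
    likelihood_ratio = c(Inf, 1, 3))
  ranked <- integration_lr(stats)
  expect_identical(ranked$term_name, c("f1", "f3", "f2"))
  expect_identical(ranked$infinite, c(TRUE, FALSE, FALSE))
  # rescaling group sizes while preserving proportions preserves the ranking
  stats2 <- stats
  stats2[c("n_IC_with", "n_NI_with")] <- stats[c("n_IC_with", "n_NI_with")] * 3
  stats2[c("n_IC_total", "n_NI_total")] <- stats[c("n_IC_total", "n_NI_total")] * 3
  expect_identical(integration_lr(stats2)$term_name, ranked$term_name)
})

test_that("family_frequency recovers planted presence rates and LR", {
  world <- default_world()
  cls <- world$ic$classifications
  stats <- family_frequency(world$gen$genes, cls, world$gen$contigs)
  # prevalence floor: every family present in >= 10% of eligible VCs
  meta <- world$gen$contigs$meta
  elig <- meta$contig_id[meta$is_viral & meta$quality %in% c("complete", "high") &
                         meta$taxonomy_order == "Caudovirales"]
  n_elig <- sum(cls$vc_id %in% elig)
  expect_true(all(stats$n_IC_with + stats$n_NI_with >= 0.10 * n_elig))
  integ <- stats[stats$term_name == "Integrase", ]
  # recovered sensitivity equals the planted truth on the same subset
  tr <- world$gen$truth$labels
  k <- match(cls$vc_id[cls$vc_id %in% elig], tr$rep_contig_id)
  sub <- tr[k, ]
  planted <- gene_family_stats(
    sum(sub$true_integrase & sub$true_lifestyle != "free"),
    sum(sub$true_lifestyle != "free"),
    sum(sub$true_integrase & sub$true_lifestyle == "free"),
    sum(sub$true_lifestyle == "free"))
  expect_equal(integ$sensitivity, planted$sensitivity, tolerance = 0.05)
  expect_equal(integ$specificity, planted$specificity, tolerance = 0.05)
  expect_equal(integ$likelihood_ratio, planted$likelihood_ratio,
               tolerance = 0.15 / planted$likelihood_ratio)
  # per-kb frequencies are positive and finite for reported families
  expect_true(all(is.finite(stats$freq_per_kb_IC)))
  expect_error(family_frequency(world$gen$genes,
                                cls[cls$integration_class == "IC", ],
                                world$gen$contigs), "zero VCs")
})

test_that("transcribed-fraction contrast sorts by IC - NI difference", {
  gene_status <- data.frame(
    gene_id = paste0("g", 1:8),
    contig_id = rep(c("ic1", "ni1"), 4),
    sample_id = "s1",
    count = 5L,
    status = c("transcribed", "transcribed",      # famA: IC 1, NI varies
               "transcribed", "not_transcribed",
               "not_transcribed", "transcribed",  # famB
               "not_evaluated", "transcribed"))
  genes <- data.frame(gene_id = paste0("g", 1:8),
                      contig_id = rep(c("ic1", "ni1"), 4),
                      start = 1L, end = 100L, strand = "+", db = "VOG",
                      term_id = "t", term_name = rep(c("famA", "famB"), each = 4))
  cls <- data.frame(vc_id = c("ic1", "ni1"),
                    integration_class = c("IC", "NI"))
  out <- transcribed_fraction_contrast(gene_status, genes, cls)
  a <- out[out$term_name == "famA", ]
  expect_equal(a$frac_IC, 1)       # both famA IC instances transcribed
  expect_equal(a$frac_NI, 0.5)
  expect_equal(a$difference, 0.5)
  expect_true(all(diff(out$difference[!is.na(out$difference)]) <= 0))
  # equal fractions in both groups -> difference 0
  gs0 <- gene_status; gs0$status <- "transcribed"
  out0 <- transcribed_fraction_contrast(gs0, genes, cls)
  expect_true(all(out0$difference == 0))
})

test_that("planted IC transcription bonus is recovered across seeds", {
  # packaging protein 1 carries a +0.25 transcription bonus on prophages; the
  # IC - NI transcribed-fraction difference should be positive in >= 90% of
  # seeded runs. The scenario sets ta_fraction = 1 and a 1000-VC community so
  # the per-family gene counts carry the planted effect rather than
  # TA-calling sparsity; 10 regenerations (no sequences) for runtime.
  wins <- 0; runs <- 10
  for (s in seq_len(runs)) {
    spec_s <- community_spec(n_free_phages = 700, n_prophages = 300,
                             n_host_contigs = 100, ta_fraction = 1,
                             seed = 600 + s)
    gen_s <- generate_genomes(spec_s, sequences = FALSE)
    cnt_s <- simulate_counts(spec_s, gen_s)
    nra_mt <- compute_nra(cnt_s$matrices$MT, gen_s$contigs)
    act <- call_ta(nra_mt, gen_s$contigs)
    st <- call_transcribed_genes(cnt_s$gene_counts, gen_s$genes, act)
    tr <- gen_s$truth$labels
    cls_s <- data.frame(vc_id = tr$rep_contig_id,
                        integration_class = ifelse(tr$true_lifestyle == "free",
                                                   "NI", "IC"))
    out <- transcribed_fraction_contrast(st, gen_s$genes, cls_s)
    pk <- out[out$term_name == "packaging protein 1", ]
    if (nrow(pk) && !is.na(pk$difference) && pk$difference > 0)
      wins <- wins + 1
  }
  expect_gte(wins / runs, 0.9)
})
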