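test_that("rarefaction conserves depth exactly, seeded and identity cases", {
  set.seed(61)
  counts <- matrix(rpois(30, 40), 10, 3,
                   dimnames = list(paste0("v", 1:10), paste0("s", 1:3)))
  depth <- min(colSums(counts))
  r1 <- rarefy(counts, depth, seed = 5)
  expect_true(all(colSums(r1) == depth))
  expect_true(all(r1 <= counts))
  # same seed, same matrix
  expect_identical(rarefy(counts, depth, seed = 5), r1)
  # a sample already at depth is unchanged
  which_min <- which.min(colSums(counts))
  expect_identical(r1[, which_min], counts[, which_min])
  # shallow samples are dropped with a warning
  expect_warning(r2 <- rarefy(counts, max(colSums(counts)), seed = 1),
                 "dropping")
  expect_equal(ncol(r2), 1)
  expect_error(rarefy(counts, 0), "positive")
})

test_that("chao1 follows the classic formula with bias-corrected fallback", {
  # counts [1,1,2,5]: S0=4, a1=2, a2=1 -> 4 + 4/2 = 6
  expect_equal(chao1(c(1, 1, 2, 5)), 6)
  # no singletons: Chao1 = S0
  expect_equal(chao1(c(3, 4, 5)), 3)
  # a2 = 0 fallback: S0 + a1(a1-1)/2
  expect_equal(chao1(c(1, 1, 5)), 3 + 2 * 1 / 2)
  expect_warning(expect_equal(chao1(integer(0)), 0), "empty")
  expect_error(chao1(c(-1, 2)), "non-negative")
  # Chao1 >= S0 always, equality iff a1 == 0
  set.seed(62)
  for (r in 1:50) {
    x <- rpois(20, 1.2)
    est <- chao1(x)
    s0 <- sum(x > 0)
    expect_gte(est, s0)
    if (sum(x == 1) == 0) expect_equal(est, s0)
  }
})

test_that("shannon and bray-curtis match hand values and bounds", {
  expect_equal(shannon(c(10)), 0)
  expect_equal(shannon(rep(7, 12)), log(12))
  # [2,2,4]: -(0.25 ln 0.25 * 2 + 0.5 ln 0.5)
  expect_equal(shannon(c(2, 2, 4)),
               -(2 * 0.25 * log(0.25) + 0.5 * log(0.5)), tolerance = 1e-12)
  expect_warning(expect_true(is.na(shannon(c(0, 0)))), "all-zero")
  m <- matrix(c(1, 2, 3, 1, 2, 3, 0, 0, 5), 3,
              dimnames = list(NULL, c("x", "y", "z")))
  d <- bray_curtis(m)
  expect_equal(d["x", "y"], 0)         # identical profiles
  expect_equal(d["x", "z"], 1 - 2 * 3 / 11)
  expect_true(all(d >= 0 & d <= 1))
  expect_identical(d, t(d))
  # disjoint supports -> distance 1
  m2 <- matrix(c(3, 0, 0, 4), 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(bray_curtis(m2)["a", "b"], 1)
})

test_that("diversity statistics match independent oracles to 1e-12", {
  skip_if_not_installed("vegan")
  set.seed(63)
  for (r in 1:100) {
    x <- rpois(sample(5:25, 1), sample(1:5, 1))
    expect_equal(chao1(x), oracle_chao1(x), tolerance = 1e-12)
    if (sum(x) > 0)
      expect_equal(shannon(x), unname(vegan::diversity(x, "shannon")),
                   tolerance = 1e-12)
  }
  for (r in 1:100) {
    m <- matrix(rpois(12, 8) + 1, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
    got <- bray_curtis(m)
    ref <- as.matrix(vegan::vegdist(t(m), "bray"))
    expect_equal(unname(got), unname(ref), tolerance = 1e-12)
  }
})

test_that("population variance: evenness zero, dominance regime, order-free", {
  expect_equal(population_variance(rep(1 / 10, 10)), 0)
  expect_true(is.na(population_variance(c(1, 0, 0))))
  # one VC at NRA -> 1 among n: variance approaches the dominant regime
  n <- 20; eps <- 1e-6
  x <- c(1 - (n - 1) * eps, rep(eps, n - 1))
  expect_equal(population_variance(x), var(x))
  expect_gt(population_variance(x), 0.9 * (1 / n) * (1 - 1 / n))
  set.seed(64)
  y <- runif(15); y <- y / sum(y)
  expect_equal(population_variance(y), population_variance(rev(y)))
})

test_that("bray-curtis contrasts separate intra from inter individuals", {
  world <- default_world()
  tr <- world$gen$truth$labels
  viral_nra <- world$nra$MV
  viral_nra$nra <- viral_nra$nra[tr$rep_contig_id, ]
  bc <- bray_curtis_contrasts(viral_nra)
  expect_true(all(bc$pairs$distance >= 0 & bc$pairs$distance <= 1))
  med <- tapply(bc$pairs$distance, bc$pairs$type, median)
  expect_lt(med[["intra"]], med[["inter"]])
  expect_lt(bc$tests$p_value[bc$tests$contrast == "intra_vs_inter"], 0.05)
  expect_equal(dim(bc$pcoa), c(9, 2))
  # identical profiles at distance 0
  two <- viral_nra
  two$nra <- cbind(two$nra[, 1], two$nra[, 1])
  colnames(two$nra) <- two$samples$sample_id[1:2]
  two$samples <- two$samples[1:2, ]
  expect_equal(unname(bray_curtis(two$nra)[1, 2]), 0)
})

test_that("shared-VC site partition conserves totals and finds planted overlap", {
  world <- default_world()
  mv <- apply_breadth_filter(world$cnt$matrices$MV)
  tr <- world$gen$truth$labels
  det <- mv$counts[tr$rep_contig_id, ] > 0
  sets <- shared_vc_sets(det, mv$samples)
  region_cols <- c("PC", "DC", "STL", "PC.DC", "PC.STL", "DC.STL", "PC.DC.STL")
  for (i in seq_len(nrow(sets)))
    expect_equal(sum(unlist(sets[i, region_cols])), sets$n_detected[i])
  expect_false(any(sets$reduced))
  # a VC detected at all three sites lands in the triple-overlap region
  p1 <- mv$samples$sample_id[mv$samples$participant == "P1"]
  all3 <- rownames(det)[rowSums(det[, p1]) == 3]
  expect_gte(sets$PC.DC.STL[sets$participant == "P1"], length(all3) * 0)
  expect_equal(sets$PC.DC.STL[sets$participant == "P1"], length(all3))
  # missing site flagged as reduced partition
  two_sites <- mv$samples$site != "STL"
  sets2 <- shared_vc_sets(det[, mv$samples$sample_id[two_sites]],
                          mv$samples[two_sites, ])
  expect_true(all(sets2$reduced))
})

test_that("host-pair correlations: identity, null behaviour and ordering", {
  world <- default_world()
  tr <- world$gen$truth$labels
  nra_mv <- world$nra$MV; nra_mg <- world$nra$MG
  # a VC whose NRA equals its host's NRA gives rho 1
  # install the host's MG NRA trace as a pseudo-VC row in the MV profile
  # (participant-site column orders coincide by construction)
  fake_mv <- nra_mv
  fake_mv$nra <- rbind(fake_mv$nra, FAKE = as.numeric(nra_mg$nra["H001", ]))
  hp1 <- host_pair_correlations(
    fake_mv, nra_mg,
    data.frame(vc_id = c("FAKE", tr$rep_contig_id[1]),
               host_contig_id = c("H001", "H002")), n_null = 10, seed = 1)
  expect_equal(hp1$matched$rho[hp1$matched$vc_id == "FAKE"], 1)
  # null distribution centred near zero
  active <- tr$true_lifestyle == "prophage_active"
  pairs <- data.frame(vc_id = tr$rep_contig_id[active],
                      host_contig_id = tr$true_host_contig[active])
  hp <- host_pair_correlations(nra_mv, nra_mg, pairs, n_null = 1000, seed = 3)
  expect_lt(abs(hp$median_null), 0.1)
  expect_gt(hp$median_matched, hp$median_null)
  expect_lt(hp$p_value, 1e-6)
  # flank-linked (prophage) pairs couple tighter than WIsH-assigned pairs
  hs <- world$gen$host_scores[world$gen$host_scores$p_adjusted < 1e-5, ]
  hp_w <- host_pair_correlations(
    nra_mv, nra_mg,
    data.frame(vc_id = hs$vc_id, host_contig_id = hs$host_contig_id),
    n_null = 100, seed = 3)
  expect_gt(hp$median_matched, hp_w$median_matched)
  expect_error(host_pair_correlations(nra_mv, nra_mg, pairs[1, , drop = FALSE]),
               "at least 2")
})
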