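test_that("genotype accuracy counts unordered genotype matches", {
  sites <- toy_sites(10)
  truth <- phased_genome(sites, rep(1L, 10), rep(0L, 10))
  perfect <- phased_genome(sites, rep(0L, 10), rep(1L, 10))  # phase-swapped
  expect_equal(genotype_accuracy(perfect, truth)$genome_wide_accuracy, 100)
  one_off <- phased_genome(sites, c(rep(1L, 9), 1L), c(rep(0L, 9), 1L))
  r <- genotype_accuracy(one_off, truth)
  expect_equal(r$genome_wide_accuracy, 90)
  expect_equal(r$n_sites_compared, 10)
  # half-called predictions count as discordant, not excluded
  half <- phased_genome(sites, c(rep(1L, 9), NA), c(rep(0L, 9), NA))
  expect_equal(genotype_accuracy(half, truth)$genome_wide_accuracy, 90)
  expect_error(genotype_accuracy(perfect, truth, mask = rep(FALSE, 10)),
               class = "wgr_empty_mask_error")
})

test_that("stratified accuracies aggregate exactly to the overall accuracy", {
  set.seed(221)
  n <- 400
  sites <- toy_sites(n, spacing = 1e5)
  truth <- phased_genome(sites, rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
  pred_h1 <- truth$hap1; pred_h2 <- truth$hap2
  flip <- sample(n, 37)
  pred_h1[flip] <- 1L - pred_h1[flip]
  pred <- phased_genome(sites, pred_h1, pred_h2)
  af <- af_table(sites$chrom, sites$pos,
                 sample(c(0.0002, 0.3), n, replace = TRUE))
  r <- genotype_accuracy(pred, truth, af = af, prs_sites = sites[1:50, ])
  tru <- dosages(truth)
  n_het <- sum(tru == 1); n_hom <- n - n_het
  agg <- (r$by_genotype[["het"]] * n_het + r$by_genotype[["hom"]] * n_hom) / n
  expect_equal(agg, r$genome_wide_accuracy, tolerance = 1e-9)
  rarity <- classify_rare(af_lookup(af, sites))
  agg2 <- (r$by_rarity[["rare"]] * sum(rarity == "rare") +
           r$by_rarity[["common"]] * sum(rarity == "common")) / n
  expect_equal(agg2, r$genome_wide_accuracy, tolerance = 1e-9)
  # permutation invariance in site order is inherent: compare to a shuffled
  # reconstruction of the same comparison
  expect_equal(genotype_accuracy(pred, truth)$genome_wide_accuracy,
               r$genome_wide_accuracy)
})

test_that("PRS concordance behaves like a squared correlation", {
  x <- c(0.1, 0.5, -0.3, 1.2, 0.8)
  expect_equal(prs_concordance(x, x), 1)
  expect_equal(prs_concordance(x, -x), 1)  # sign-invariant by construction
  expect_equal(prs_concordance(x, 2 * x + 3), 1)
  expect_error(prs_concordance(x[1:2], x[1:2]), class = "wgr_concordance_error")
  expect_error(prs_concordance(x, rep(1, 5)), class = "wgr_zero_variance_error")
})

test_that("embryo-vs-truth PRS concordance is high under day-5 noise", {
  set.seed(222)
  r2 <- c()
  fam <- simulate_family(6, n_sites = 3000, n_array = 1200, n_chromosomes = 2,
                         noise = "day5", seed = 223)
  obs <- lapply(fam$embryos, `[[`, "obs")
  sc <- phase_parents(fam$mother, fam$father, obs, fam$map, noise_profile("day5"))
  mph <- merge_with_truth_phase(sc$mother, fam$mother)
  pph <- merge_with_truth_phase(sc$father, fam$father)
  # a dozen random PRS models over the family's sites
  models <- lapply(1:12, function(m) {
    idx <- sort(sample(nrow(fam$sites), 40))
    prs_model(paste0("m", m), fam$sites$chrom[idx], fam$sites$pos[idx],
              fam$sites$alt[idx], rnorm(40, 0, 0.15))
  })
  emb_scores <- truth_scores <- c()
  for (i in seq_along(fam$embryos)) {
    path <- decode_transmission(obs[[i]], mph, pph, fam$map, noise_profile("day5"))
    rec <- fill_genome(path, mph, pph)
    for (m in models) {
      emb_scores <- c(emb_scores, raw_prs(rec, m, af = fam$af_table)$raw_score)
      truth_scores <- c(truth_scores, raw_prs(fam$embryos[[i]]$truth, m)$raw_score)
    }
  }
  expect_gte(prs_concordance(emb_scores, truth_scores), 0.9)
})

test_that("breakpoint scoring handles the degenerate noiseless cases", {
  fam <- simulate_family(1, n_sites = 1000, n_array = 500, n_chromosomes = 1,
                         noise = "none", seed = 224)
  e <- fam$embryos[[1]]
  path <- decode_transmission(e$obs, fam$mother, fam$father, fam$map,
                              noise_profile("none"))
  for (parent in c("mother", "father")) {
    mei <- if (parent == "mother") e$meiosis_m else e$meiosis_p
    ba <- breakpoint_accuracy(path, mei, parent)
    expect_equal(ba$n_detected, ba$n_detectable)
    expect_equal(ba$n_false_positive, 0)
    # every detected crossover lies inside its reported interval by
    # construction; widths are positive
    det <- ba$crossovers[ba$crossovers$detected, , drop = FALSE]
    if (nrow(det)) expect_true(all(det$interval_width > 0))
  }
  # zero-crossover meiosis: no reported breakpoints for that parent
  no_xo <- list(`1` = list(start_hap = 1L, xo_pos = numeric()))
  class(no_xo) <- "true_meiosis"
  ba0 <- breakpoint_accuracy(path, no_xo, "mother")
  expect_equal(ba0$n_true, 0)
})

test_that("breakpoint detection does not improve with allele dropout", {
  rates <- c(0, 0.1, 0.25)
  det_rate <- vapply(rates, function(ado) {
    prof <- noise_profile(ado = ado, error = 0, missing = 0)
    det <- tot <- 0
    for (k in 1:12) {
      fam <- simulate_family(1, n_sites = 800, n_array = 400, n_chromosomes = 1,
                             noise = "none", seed = 230 + k)
      e <- fam$embryos[[1]]
      obs <- make_observation(e$truth, fam$array_sites, prof, seed = 250 + k)
      path <- decode_transmission(obs, fam$mother, fam$father, fam$map, prof)
      ba <- breakpoint_accuracy(path, e$meiosis_m, "mother")
      det <- det + ba$n_detected; tot <- tot + ba$n_detectable
    }
    if (tot == 0) NA else det / tot
  }, 0)
  expect_true(all(diff(det_rate) <= 1e-9))
})

test_that("comparing a genome to itself is perfect", {
  fam <- simulate_family(1, n_sites = 200, n_array = 100, noise = "none", seed = 225)
  g <- fam$embryos[[1]]$truth
  expect_equal(genotype_accuracy(g, g)$genome_wide_accuracy, 100)
  s <- rnorm(10)
  expect_equal(prs_concordance(s, s), 1)
})
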