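test_that("decode matches exhaustive path enumeration on small chromosomes", {
  set.seed(401)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    inst <- random_hmm_instance(n)
    path <- decode_transmission(inst$obs, inst$mother, inst$father, inst$map,
                                inst$profile)
    em <- oracle_emissions(inst)
    d <- diff(cm_at(inst$map, "1", inst$sites$pos))
    orc <- oracle_hmm(em, oracle_haldane(d))
    expect_equal(path$loglik, orc$loglik, tolerance = 1e-9)
    expect_equal(path$viterbi_loglik, orc$viterbi_loglik, tolerance = 1e-9)
    expect_equal(path$sites$m_post_hap1, colSums(orc$posterior[c(1, 3), , drop = FALSE]),
                 tolerance = 1e-9, ignore_attr = TRUE)
    expect_equal(path$sites$p_post_hap1, colSums(orc$posterior[c(1, 2), , drop = FALSE]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("state posteriors are normalized", {
  set.seed(402)
  inst <- random_hmm_instance(30)
  em <- wgr:::state_emissions(inst$obs$call, inst$mother$hap1, inst$mother$hap2,
                              inst$father$hap1, inst$father$hap2, inst$profile)
  r <- haldane_r(diff(cm_at(inst$map, "1", inst$sites$pos)))
  dec <- wgr:::hmm_decode(em, r)
  expect_equal(colSums(dec$posterior), rep(1, 30), tolerance = 1e-9)
})

test_that("noiseless decoding recovers the true meiosis exactly", {
  set.seed(403)
  fam <- simulate_family(1, n_sites = 1500, n_array = 700, n_chromosomes = 2,
                         noise = "none", seed = 11)
  e <- fam$embryos[[1]]
  path <- decode_transmission(e$obs, fam$mother, fam$father, fam$map,
                              noise_profile("none"))
  # at every informative site, the Viterbi haplotype equals the truth
  for (parent in c("mother", "father")) {
    mei <- if (parent == "mother") e$meiosis_m else e$meiosis_p
    het_col <- if (parent == "mother") "m_het" else "p_het"
    hap_col <- if (parent == "mother") "m_hap" else "p_hap"
    for (ch in unique(path$sites$chrom)) {
      sel <- path$sites$chrom == ch & path$sites[[het_col]]
      true_hap <- wgr:::hap_index_at(path$sites$pos[sel],
                                     mei[[ch]]$start_hap, mei[[ch]]$xo_pos)
      expect_equal(path$sites[[hap_col]][sel], as.integer(true_hap))
    }
    ba <- breakpoint_accuracy(path, mei, parent)
    expect_equal(ba$n_detected, ba$n_detectable)
    expect_equal(ba$n_false_positive, 0)
  }
})

test_that("a chromosome with no informative sites is a typed error", {
  sites <- toy_sites(5)
  m <- toy_parent(sites, rep(0L, 5), rep(0L, 5))
  f <- toy_parent(sites, rep(1L, 5), rep(1L, 5))
  obs <- embryo_obs(sites, rep(1L, 5))
  expect_error(
    decode_transmission(obs, m, f, uniform_map(sites), noise_profile("day5")),
    class = "wgr_uninformative_error"
  )
})

test_that("swapping one parent's haplotype labels leaves genotypes invariant", {
  fam <- simulate_family(1, n_sites = 800, n_array = 400, n_chromosomes = 1,
                         noise = "day5", seed = 21)
  e <- fam$embryos[[1]]
  prof <- noise_profile("day5")
  rec1 <- fill_genome(decode_transmission(e$obs, fam$mother, fam$father,
                                          fam$map, prof),
                      fam$mother, fam$father)
  mother_sw <- phased_genome(fam$mother$sites, fam$mother$hap2, fam$mother$hap1)
  rec2 <- fill_genome(decode_transmission(e$obs, mother_sw, fam$father,
                                          fam$map, prof),
                      mother_sw, fam$father)
  expect_equal(dosages(rec1), dosages(rec2))
  expect_equal(rec1$confidence, rec2$confidence, tolerance = 1e-9)
})

test_that("genotype accuracy does not improve as allele dropout rises", {
  accs <- vapply(c(0, 0.05, 0.1, 0.2), function(ado) {
    prof <- noise_profile(ado = ado, error = 0, missing = 0, label = "ado")
    acc <- vapply(1:20, function(k) {
      fam <- simulate_family(1, n_sites = 1000, n_array = 250,
                             n_chromosomes = 2, noise = "none", seed = 600 + k)
      e <- fam$embryos[[1]]
      obs <- make_observation(e$truth, fam$array_sites, prof, seed = 700 + k)
      path <- decode_transmission(obs, fam$mother, fam$father, fam$map, prof)
      rec <- fill_genome(path, fam$mother, fam$father)
      genotype_accuracy(rec, e$truth)$genome_wide_accuracy
    }, 0)
    mean(acc)
  }, 0)
  expect_true(all(diff(accs) <= 1e-9))
})

test_that("aneuploid-flagged chromosomes carry no predictions", {
  fam <- simulate_family(1, n_sites = 600, n_array = 300, n_chromosomes = 2,
                         noise = "none",
                         aneuploid_spec = list(list(embryo = 1, chrom = "2")),
                         seed = 31)
  e <- fam$embryos[[1]]
  expect_equal(e$obs$aneuploid, "2")
  path <- decode_transmission(e$obs, fam$mother, fam$father, fam$map,
                              noise_profile("none"))
  expect_equal(path$aneuploid, "2")
  rec <- fill_genome(path, fam$mother, fam$father)
  on2 <- rec$sites$chrom == "2"
  expect_true(all(!rec$predicted[on2]))
  expect_true(all(is.na(dosages(rec)[on2])))
  expect_true(all(rec$predicted[!on2]))
})

test_that("high-confidence filter applies Mendelian-consistency rules", {
  sites <- toy_sites(4)
  # trios (mother, father, child) as dosage triples per site:
  # AA x AA -> AB impossible; AB x AB -> AA fine; AB x AA -> BB impossible;
  # missing child call excluded
  m <- c(0L, 1L, 1L, 1L)
  f <- c(0L, 1L, 0L, 1L)
  c_ <- c(1L, 0L, 2L, NA)
  mask <- high_confidence_filter(sites, m, f, c_)
  expect_equal(mask, c(FALSE, TRUE, FALSE, FALSE))
  mask2 <- high_confidence_filter(sites, m, f, c(1L, 0L, 1L, 0L),
                                  low_quality = c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(mask2, c(FALSE, FALSE, TRUE, TRUE))
})

test_that("rarity classification uses a strict 0.1% threshold", {
  expect_equal(classify_rare(c(0.0005, 0.001, NA, 0.5)),
               c("rare", "common", "rare", "common"))
})
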