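toy_model <- function(weights, sites, beta = log(1.6)) {
  prs_model("toy", sites$chrom, sites$pos, sites$alt, weights,
            beta_per_sd = beta)
}

test_that("raw PRS is the weighted sum of effect dosages", {
  sites <- toy_sites(2)
  g <- phased_genome(sites, c(1L, 1L), c(1L, 0L))  # dosages 2, 1
  m <- toy_model(c(0.1, 0.2), sites)
  r <- raw_prs(g, m)
  expect_equal(r$raw_score, 0.1 * 2 + 0.2 * 1)
  expect_equal(r$n_sites_used, 2L)
  expect_equal(r$n_sites_af_adjusted, 0L)
})

test_that("unpredicted sites contribute the expected dosage from allele frequency", {
  sites <- toy_sites(2)
  g <- phased_genome(sites, c(1L, NA), c(1L, NA))  # second site unpredicted
  m <- toy_model(c(0.1, 0.2), sites)
  af <- af_table(sites$chrom, sites$pos, c(0.5, 0.25))
  r <- raw_prs(g, m, af = af)
  expect_equal(r$raw_score, 0.1 * 2 + 0.2 * (2 * 0.25))
  expect_equal(r$n_sites_used, 1L)
  expect_equal(r$n_sites_af_adjusted, 1L)
  # all sites unpredicted: the score is entirely the population expectation
  g0 <- phased_genome(sites, c(NA, NA), c(NA, NA))
  r0 <- raw_prs(g0, m, af = af)
  expect_equal(r0$raw_score, 2 * 0.1 * 0.5 + 2 * 0.2 * 0.25)
  expect_equal(r0$n_sites_used, 0L)
  # no genotype and no AF: contributes zero, with a warning
  expect_warning(r_na <- raw_prs(g0, m), class = "wgr_prs_missing_warning")
  expect_equal(r_na$raw_score, 0)
})

test_that("raw PRS is linear in the model weights", {
  set.seed(201)
  sites <- toy_sites(12)
  g <- phased_genome(sites, rbinom(12, 1, 0.5), rbinom(12, 1, 0.5))
  w1 <- rnorm(12); w2 <- rnorm(12)
  s1 <- raw_prs(g, toy_model(w1, sites))$raw_score
  s2 <- raw_prs(g, toy_model(w2, sites))$raw_score
  s12 <- raw_prs(g, toy_model(w1 + w2, sites))$raw_score
  expect_equal(s12, s1 + s2, tolerance = 1e-12)
})

test_that("effect-allele orientation is resolved against ref/alt", {
  sites <- toy_sites(1)  # ref A, alt G
  g <- phased_genome(sites, 1L, 0L)  # alt dosage 1
  m_alt <- prs_model("x", "1", sites$pos, "G", 0.4)
  m_ref <- prs_model("x", "1", sites$pos, "A", -0.4)
  s_alt <- raw_prs(g, m_alt)$raw_score
  s_ref <- raw_prs(g, m_ref)$raw_score
  # flipping allele and negating the weight shifts the score by -2w but
  # preserves differences between genomes
  g2 <- phased_genome(sites, 1L, 1L)
  expect_equal(s_alt - raw_prs(g2, m_alt)$raw_score,
               s_ref - raw_prs(g2, m_ref)$raw_score, tolerance = 1e-12)
  # an effect allele matching neither ref nor alt is fatal
  m_bad <- prs_model("x", "1", sites$pos, "C", 0.4)
  expect_error(raw_prs(g, m_bad), class = "wgr_prs_model_error")
})

make_panel <- function(n_ind = 120, n_sites = 300, seed = 202) {
  set.seed(seed)
  sites <- toy_sites(n_sites, spacing = 1e5)
  # two populations with diverged allele frequencies
  p_a <- runif(n_sites, 0.1, 0.9)
  p_b <- pmin(pmax(p_a + rnorm(n_sites, 0, 0.25), 0.02), 0.98)
  pops <- rep(c("POPA", "POPB"), each = n_ind / 2)
  geno <- t(vapply(seq_len(n_ind), function(i) {
    p <- if (pops[i] == "POPA") p_a else p_b
    rbinom(n_sites, 2, p)
  }, numeric(n_sites)))
  list(model = fit_pc_model(geno, sites, pops), geno = geno, sites = sites,
       pops = pops, p_a = p_a, p_b = p_b)
}

test_that("projecting a panel individual reproduces its panel PC scores", {
  pan <- make_panel()
  g <- list(sites = pan$sites, dosage = pan$geno[5, ])
  sc <- project_pcs(g, pan$model)
  expect_equal(sc, unname(pan$model$ref_scores[5, ]), tolerance = 1e-6)
})

test_that("an embryo from population A parents projects into the A cluster", {
  pan <- make_panel()
  set.seed(203)
  hap <- function() as.integer(runif(nrow(pan$sites)) < pan$p_a)
  mother <- phased_genome(pan$sites, hap(), hap())
  father <- phased_genome(pan$sites, hap(), hap())
  emb <- simulate_embryo_unlinked(mother, father, seed = 204)
  sc <- project_pcs(emb, pan$model)
  cent <- pan$model$centroids
  d <- sqrt(rowSums(sweep(cent, 2, sc)^2))
  expect_equal(names(which.min(d)), "POPA")
})

test_that("insufficient PC panel coverage is a typed error", {
  pan <- make_panel()
  g <- list(sites = pan$sites[1:50, ], dosage = pan$geno[1, 1:50])
  expect_error(project_pcs(g, pan$model), class = "wgr_pc_coverage_error")
})

test_that("centering annihilates a PC-linear cohort and standardization is exact", {
  pan <- make_panel()
  pcs <- pan$model$ref_scores
  raw <- 2.5 + 3 * pcs[, 1]  # raw PRS an exact linear function of PC1
  fitted <- fit_centering(pan$model, raw, pcs)
  centered <- raw - cbind(1, pcs[, 1:4]) %*% fitted$centering
  expect_lt(max(abs(centered)), 1e-9)
  # with zero coefficients and unit SD, standardization is the identity
  ident <- pan$model
  ident$centering <- c(0, 0, 0, 0, 0)
  ident$pop_sd <- c(all = 1)
  expect_equal(center_and_standardize(1.23, pcs[1, ], ident, "all"), 1.23)
  # centering an already-centered cohort is idempotent
  fitted2 <- fit_centering(fitted, as.vector(centered), pcs)
  centered2 <- as.vector(centered) - cbind(1, pcs[, 1:4]) %*% fitted2$centering
  expect_lt(max(abs(centered2 - centered)), 1e-9)
})

test_that("standardized control scores have mean 0 and SD near 1", {
  set.seed(205)
  n <- 2000
  pcs <- matrix(rnorm(n * 4), n, 4)
  raw <- 0.4 + 0.8 * pcs[, 2] + rnorm(n)
  pan <- make_panel()
  fitted <- fit_centering(pan$model, raw, pcs)
  std <- center_and_standardize(raw, pcs, fitted, rep("all", n))
  expect_lt(abs(mean(std)), 3 / sqrt(n))
  expect_gt(sd(std), 0.9)
  expect_lt(sd(std), 1.1)
})

test_that("the PRS-to-OR transform obeys its closed forms", {
  expect_equal(or_from_prs(1, log(1.6)), 1.6)
  expect_equal(or_from_prs(0, log(1.6)), 1)
  expect_equal(or_from_prs(-1, log(1.3)), 1 / 1.3)
  x <- seq(-3, 3, 0.5)
  expect_true(all(diff(or_from_prs(x, log(1.2))) > 0))
  expect_equal(or_from_prs(-x, log(1.5)) * or_from_prs(x, log(1.5)),
               rep(1, length(x)), tolerance = 1e-12)
})

test_that("model QC separates strong, null and perfectly separating scores", {
  set.seed(206)
  # perfectly separating score
  status <- rep(0:1, each = 300)
  score <- status * 10 + runif(600)
  qc <- validate_model(score, status)
  expect_equal(qc$auc, 1)
  expect_equal(qc$verdict, "pass")
  # a score independent of status has AUC near 0.5 and fails
  null <- simulate_score_cohort(4000, or_per_sd = 1, seed = 207)
  qn <- validate_model(null$score, null$status)
  expect_lt(abs(qn$auc - 0.5), 0.05)
  expect_equal(qn$verdict, "fail")
})

test_that("validate_model recovers the generating per-SD odds ratio", {
  cohort <- simulate_score_cohort(5000, or_per_sd = 2.0, intercept = -1,
                                  seed = 208)
  qc <- validate_model(cohort$score, cohort$status)
  expect_lt(abs(qc$or_per_sd - 2.0) / 2.0, 0.15)
  expect_equal(qc$verdict, "pass")
  expect_gte(qc$top_bottom_or, 2)
})

test_that("QC requires a minimally sized cohort", {
  expect_error(validate_model(rnorm(15), c(rep(1, 5), rep(0, 10))),
               class = "wgr_qc_cohort_error")
})
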