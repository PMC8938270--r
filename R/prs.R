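#' Compute a raw polygenic risk score
#'
#' The raw score is the weighted sum of effect-allele dosages over the
#' model's variants. Effect-allele orientation is resolved against the
#' genome's site table: when the effect allele is the reference allele the
#' dosage counted is `2 - alt dosage` (scoring files mix orientations).
#' Model variants that cannot be predicted in the genome — absent from its
#' site list, on an unpredicted (aneuploid) chromosome, or missing — are
#' adjusted with the population allele frequency: they contribute the
#' expected effect-allele dosage `2 * AF`. A variant with neither a
#' genotype nor a frequency contributes zero, with a warning.
#'
#' @param genome a [phased_genome()] / `reconstructed_genome`, or a list
#'   with elements `sites` and `dosage`.
#' @param model a [prs_model()].
#' @param af optional [af_table()] of effect-allele population frequencies
#'   used for unpredicted sites. Frequencies are taken to refer to the
#'   alternate allele where the site's ref/alt orientation is known from
#'   the genome, and to the effect allele for sites absent from the genome.
#' @return list: `raw_score`, `n_sites_used` (genotyped), and
#'   `n_sites_af_adjusted`.
#' @examples
#' # weights (0.1, 0.2) at dosages (2, 1) -> 0.4
#' @export
raw_prs <- function(genome, model, af = NULL) {
  stopifnot(inherits(model, "prs_model"))
  v <- model$variants
  if (is.list(genome) && !is.null(genome$dosage) && !inherits(genome, "phased_genome")) {
    sites <- genome$sites; dos <- genome$dosage
  } else {
    sites <- genome$sites; dos <- dosages(genome)
  }
  idx <- match(paste0(v$chrom, ":", v$pos), site_key(sites))
  af_vals <- if (is.null(af)) rep(NA_real_, nrow(v)) else
    af_table_lookup_keys(af, paste0(v$chrom, ":", v$pos))

  score <- 0; used <- 0L; adjusted <- 0L; zeroed <- 0L
  for (i in seq_len(nrow(v))) {
    j <- idx[i]
    d <- if (!is.na(j)) dos[j] else NA
    if (!is.na(j) && !is.na(d)) {
      eff <- effect_dosage(d, v$effect_allele[i], sites$ref[j], sites$alt[j])
      score <- score + v$weight[i] * eff
      used <- used + 1L
    } else {
      p <- af_vals[i]
      if (!is.na(j) && !is.na(p)) {
        # orientation known: table frequency refers to the alt allele
        if (v$effect_allele[i] == sites$ref[j]) p <- 1 - p
      }
      if (!is.na(p)) {
        score <- score + v$weight[i] * 2 * p
        adjusted <- adjusted + 1L
      } else {
        zeroed <- zeroed + 1L
      }
    }
  }
  if (zeroed > 0) {
    wgr_warn(sprintf("%d model site(s) with neither genotype nor allele frequency contributed 0", zeroed),
             "prs_missing")
  }
  list(raw_score = score, n_sites_used = used, n_sites_af_adjusted = adjusted)
}

#' @noRd
effect_dosage <- function(alt_dosage, effect, ref, alt) {
  if (effect == alt) return(alt_dosage)
  if (effect == ref) return(2L - alt_dosage)
  wgr_stop(sprintf("effect allele %s matches neither ref (%s) nor alt (%s)",
                   effect, ref, alt), "prs_model")
}

#' @noRd
af_table_lookup_keys <- function(table, keys) {
  table$af[match(keys, paste0(table$chrom, ":", table$pos))]
}

#' Fit an ancestry principal-component model on a reference panel
#'
#' Genotypes are centered at twice the panel allele frequency and scaled by
#' the binomial standard deviation `sqrt(2p(1-p))` before the singular value
#' decomposition, so loadings are orthonormal over the standardized panel.
#' Projection of new genomes uses the same centering/scaling (with
#' mean-imputation of missing panel sites), which makes projecting a panel
#' individual reproduce its own panel score.
#'
#' @param geno dosage matrix, individuals x panel sites.
#' @param sites [site_table()] of the panel sites (columns of `geno`).
#' @param populations character vector of population labels, one per
#'   individual.
#' @param K number of components retained (at least 4; the centering
#'   regression uses the first four).
#' @return object of class `pc_model`: `sites`, panel allele frequencies
#'   `af`, `loadings`, per-individual `ref_scores`, population `centroids`,
#'   and empty slots for the centering fit ([fit_centering()]).
#' @export
fit_pc_model <- function(geno, sites, populations, K = 4) {
  stopifnot(ncol(geno) == nrow(sites), nrow(geno) == length(populations), K >= 4)
  p <- pmin(pmax(colMeans(geno, na.rm = TRUE) / 2, 1e-6), 1 - 1e-6)
  X <- sweep(geno, 2, 2 * p)
  X <- sweep(X, 2, sqrt(2 * p * (1 - p)), "/")
  X[is.na(X)] <- 0
  sv <- svd(X, nu = 0, nv = K)
  loadings <- sv$v
  scores <- X %*% loadings
  colnames(scores) <- paste0("PC", seq_len(K))
  centroids <- do.call(rbind, lapply(split(seq_len(nrow(scores)), populations),
                                     function(i) colMeans(scores[i, , drop = FALSE])))
  structure(list(sites = sites, af = p, loadings = loadings, K = K,
                 ref_scores = scores, populations = populations,
                 centroids = centroids,
                 centering = NULL, pop_sd = NULL),
            class = "pc_model")
}

#' Project a genome onto reference principal components
#'
#' Requires genotypes at 80% or more of the panel sites; missing panel sites
#' are mean-imputed at the panel allele frequency.
#'
#' @param genome a [phased_genome()] or list with `sites` and `dosage`.
#' @param model a [fit_pc_model()] result.
#' @return numeric vector of the first K PC scores.
#' @export
project_pcs <- function(genome, model) {
  stopifnot(inherits(model, "pc_model"))
  if (is.list(genome) && !is.null(genome$dosage) && !inherits(genome, "phased_genome")) {
    sites <- genome$sites; dos <- genome$dosage
  } else {
    sites <- genome$sites; dos <- dosages(genome)
  }
  idx <- match(site_key(model$sites), site_key(sites))
  d <- ifelse(is.na(idx), NA, dos[idx])
  coverage <- mean(!is.na(d))
  if (coverage < 0.8) {
    wgr_stop(sprintf("only %.0f%% of PC panel sites genotyped (need >= 80%%)",
                     100 * coverage), "pc_coverage")
  }
  p <- model$af
  d[is.na(d)] <- 2 * p[is.na(d)]
  x <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  as.vector(x %*% model$loadings)
}

#' Fit the ancestry-centering regression for a PRS
#'
#' Ordinary least squares of the raw PRS on the first four PC scores,
#' fitted on control individuals only, following the convention that the
#' ancestry-predicted component of the score is subtracted before
#' standardization. Also records the per-population standard deviation of
#' the centered score, used as the standardization denominator.
#'
#' @param model a `pc_model`.
#' @param raw_scores raw PRS of the control cohort.
#' @param pc_scores matrix of their PC scores (>= 4 columns).
#' @param populations population labels for the controls (default: a single
#'   pooled population `"all"`).
#' @return the `pc_model` with `centering` (intercept + 4 coefficients) and
#'   `pop_sd` filled in.
#' @export
fit_centering <- function(model, raw_scores, pc_scores,
                          populations = NULL) {
  stopifnot(inherits(model, "pc_model"), ncol(pc_scores) >= 4)
  pcs <- pc_scores[, 1:4, drop = FALSE]
  fit <- stats::lm.fit(cbind(1, pcs), raw_scores)
  coefs <- fit$coefficients
  centered <- raw_scores - cbind(1, pcs) %*% coefs
  if (is.null(populations)) populations <- rep("all", length(raw_scores))
  pop_sd <- vapply(split(centered, populations), stats::sd, 0)
  model$centering <- as.vector(coefs)
  model$pop_sd <- pop_sd
  model
}

#' Center and standardize a raw PRS
#'
#' Subtracts the ancestry-predicted score (the [fit_centering()] regression
#' on the first four PCs) and divides by the standard deviation of the
#' centered score in the reference population most closely related to the
#' individual — chosen by nearest population centroid in PC1-4 Euclidean
#' distance when no label is supplied.
#'
#' @param raw_score raw PRS value(s).
#' @param pc_scores PC score vector (single genome) or matrix (one row per
#'   genome).
#' @param model a `pc_model` with a fitted centering.
#' @param population optional population label; must match a name of the
#'   model's `pop_sd`.
#' @return numeric standardized score(s), in SD units.
#' @export
center_and_standardize <- function(raw_score, pc_scores, model,
                                   population = NULL) {
  if (is.null(model$centering)) {
    wgr_stop("centering regression not fitted; call fit_centering() first", "centering")
  }
  pcs <- if (is.matrix(pc_scores)) pc_scores[, 1:4, drop = FALSE] else
    matrix(pc_scores[1:4], nrow = length(raw_score), ncol = 4, byrow = TRUE)
  centered <- raw_score - as.vector(cbind(1, pcs) %*% model$centering)
  if (is.null(population)) {
    if (is.null(model$centroids)) {
      wgr_stop("no population label and no PC centroids to fall back on", "population")
    }
    pick <- function(row) {
      d2 <- rowSums(sweep(model$centroids[, 1:4, drop = FALSE], 2, row)^2)
      rownames(model$centroids)[which.min(d2)]
    }
    population <- apply(pcs, 1, pick)
  }
  if (!all(population %in% names(model$pop_sd))) {
    wgr_stop(sprintf("population '%s' has no standard deviation in the model",
                     setdiff(population, names(model$pop_sd))[1]), "population")
  }
  as.vector(centered / model$pop_sd[population])
}

#' Convert a standardized PRS into an odds ratio
#'
#' `OR = exp(beta * PRS)`, where `beta` is the log odds ratio per standard
#' deviation of the standardized score. A score of 0 (the population mean)
#' maps to OR 1; the transform is strictly increasing and symmetric:
#' `OR(-x) * OR(x) = 1`.
#'
#' @param standardized_score standardized PRS (SD units).
#' @param beta_per_sd log OR per SD (e.g. `log(1.6)`).
#' @return odds ratio(s).
#' @examples
#' or_from_prs(1, log(1.6))   # 1.6
#' or_from_prs(0, log(1.6))   # 1
#' @export
or_from_prs <- function(standardized_score, beta_per_sd) {
  stopifnot(is.finite(beta_per_sd))
  exp(beta_per_sd * standardized_score)
}

#' Validate a PRS model on a case/control cohort
#'
#' Applies the model quality gates: area under the ROC curve at least 0.6,
#' increasing odds ratio across score deciles, and an odds ratio of at
#' least 2 between the top and bottom deciles. Decile odds ratios are
#' computed against the pooled middle deciles (5-6) as reference; the
#' increase-per-decile gate is assessed as a significantly positive trend
#' of log decile OR on decile index (weighted least squares, one-sided
#' p < 0.05), which is robust to per-decile sampling noise at cohort sizes
#' far below biobank scale; the strictly pairwise non-decrease indicator is
#' also reported. The per-SD effect size is estimated by logistic
#' regression of status on the SD-scaled score.
#'
#' @param scores numeric PRS values.
#' @param status 0/1 disease status.
#' @return list of class `prs_qc`: `auc`, `or_per_sd`, `decile_or`,
#'   `top_bottom_or`, `monotone_trend_p`, `monotone_strict`, `verdict`
#'   (`"pass"`, `"fail"` or `"indeterminate"`).
#' @export
validate_model <- function(scores, status) {
  status <- as.integer(status)
  stopifnot(length(scores) == length(status), all(status %in% 0:1))
  if (sum(status == 1) < 10 || sum(status == 0) < 10) {
    wgr_stop("need at least 10 cases and 10 controls for model QC", "qc_cohort")
  }
  auc <- as.numeric(pROC::auc(status, scores, quiet = TRUE,
                              direction = "<", levels = c(0, 1)))
  z <- scores / stats::sd(scores)
  fit <- stats::glm(status ~ z, family = stats::binomial())
  or_per_sd <- exp(stats::coef(fit)[["z"]])

  dec <- cut(scores, breaks = stats::quantile(scores, probs = seq(0, 1, 0.1)),
             include.lowest = TRUE, labels = FALSE)
  tab_case <- tapply(status, dec, sum)
  tab_n <- tapply(status, dec, length)
  if (length(tab_case) < 10 || any(is.na(tab_case))) {
    return(structure(list(auc = auc, or_per_sd = or_per_sd, decile_or = NULL,
                          top_bottom_or = NA, monotone_trend_p = NA,
                          monotone_strict = NA, verdict = "indeterminate"),
                     class = "prs_qc"))
  }
  odds <- function(cases, n) {
    # Haldane-Anscombe correction keeps empty cells finite
    (cases + 0.5) / (n - cases + 0.5)
  }
  ref_odds <- odds(sum(tab_case[5:6]), sum(tab_n[5:6]))
  decile_or <- odds(tab_case, tab_n) / ref_odds
  top_bottom_or <- odds(tab_case[10], tab_n[10]) / odds(tab_case[1], tab_n[1])

  lo <- log(decile_or)
  # inverse-variance weights with the same Haldane-Anscombe correction, so
  # pure-case / pure-control deciles keep finite positive weight
  w <- 1 / (1 / (tab_case + 0.5) + 1 / (tab_n - tab_case + 0.5))
  tfit <- stats::lm(lo ~ seq_along(lo), weights = w)
  sm <- summary(tfit)$coefficients
  slope <- sm[2, 1]
  p_two <- sm[2, 4]
  trend_p <- if (slope > 0) p_two / 2 else 1 - p_two / 2
  monotone_strict <- all(diff(decile_or) >= 0)

  verdict <- if (auc >= 0.6 && trend_p < 0.05 && top_bottom_or >= 2) "pass" else "fail"
  structure(list(auc = auc, or_per_sd = or_per_sd,
                 decile_or = as.numeric(decile_or),
                 top_bottom_or = as.numeric(top_bottom_or),
                 monotone_trend_p = trend_p,
                 monotone_strict = monotone_strict,
                 verdict = verdict),
            class = "prs_qc")
}

#' @export
print.prs_qc <- function(x, ...) {
  cat(sprintf("<prs_qc> AUC %.3f | OR/SD %.2f | top/bottom decile OR %.2f | verdict: %s\n",
              x$auc, x$or_per_sd, x$top_bottom_or, x$verdict))
  invisible(x)
}

#' Simulate a case/control cohort with a known per-SD score effect
#'
#' Standard-normal scores; disease status drawn from a logistic model
#' `logit P(case) = intercept + log(or_per_sd) * score`. Used for
#' parameter-recovery checks of [validate_model()].
#'
#' @param n cohort size.
#' @param or_per_sd generating odds ratio per SD of the score.
#' @param intercept log odds of disease at the mean score.
#' @param seed optional RNG seed.
#' @return data.frame with `score` and `status`.
#' @export
simulate_score_cohort <- function(n, or_per_sd, intercept = -1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  score <- stats::rnorm(n)
  p <- stats::plogis(intercept + log(or_per_sd) * score)
  data.frame(score = score, status = stats::rbinom(n, 1, p))
}
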