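#' Read / construct a monogenic risk panel
#'
#' Tab-separated with header columns: gene, chrom, pos, ref, alt, condition,
#' alpha_carrier (carrier main-effect log OR at PRS = 0), beta_carrier and
#' beta_noncarrier (per-SD PRS log ORs in each stratum). The pathogenic
#' allele is the alternate allele of each row. No default effect sizes are
#' assumed: every beta must be supplied.
#'
#' @param path file path.
#' @return data.frame of class `monogenic_panel`.
#' @export
read_monogenic_panel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  monogenic_panel(df)
}

#' @rdname read_monogenic_panel
#' @param df data.frame with the columns above.
#' @export
monogenic_panel <- function(df) {
  need <- c("gene", "chrom", "pos", "ref", "alt", "condition",
            "alpha_carrier", "beta_carrier", "beta_noncarrier")
  if (!all(need %in% names(df))) {
    wgr_stop(paste("monogenic panel must have columns:",
                   paste(need, collapse = ", ")), "panel")
  }
  df$chrom <- normalize_chrom(as.character(df$chrom))
  df$pos <- as.integer(df$pos)
  for (col in c("alpha_carrier", "beta_carrier", "beta_noncarrier")) {
    if (any(!is.finite(df[[col]]))) wgr_stop(sprintf("non-finite %s", col), "panel")
  }
  class(df) <- c("monogenic_panel", "data.frame")
  df
}

#' Call pathogenic-variant carrier status from a reconstructed genome
#'
#' An embryo is a carrier of a panel variant when its predicted dosage of
#' the pathogenic (alternate) allele is at least 1. A panel site that is
#' not predicted — absent from the reconstruction or on an aneuploid
#' chromosome — yields status `"unknown"`, never a silent non-carrier call.
#'
#' @param genome a `reconstructed_genome` (or any [phased_genome()]).
#' @param panel a [monogenic_panel()].
#' @return data.frame: gene, condition, site, `status`
#'   (`"carrier"`/`"noncarrier"`/`"unknown"`) and pathogenic-allele dosage.
#' @export
call_carriers <- function(genome, panel) {
  idx <- match(paste0(panel$chrom, ":", panel$pos), site_key(genome$sites))
  dos <- dosages(genome)
  predicted <- if (!is.null(genome$predicted)) genome$predicted else
    rep(TRUE, nrow(genome$sites))
  d <- ifelse(is.na(idx), NA, ifelse(predicted[idx], dos[idx], NA))
  status <- ifelse(is.na(d), "unknown",
                   ifelse(d >= 1, "carrier", "noncarrier"))
  data.frame(gene = panel$gene, condition = panel$condition,
             site = paste0(panel$chrom, ":", panel$pos),
             status = status, dosage = d, stringsAsFactors = FALSE)
}

#' Combine monogenic carrier status and PRS into one odds ratio
#'
#' Carrier-stratified logistic combination: the log odds ratio is the
#' carrier main effect (for carriers) plus the stratum-specific per-SD PRS
#' slope times the standardized score,
#' `OR = exp(alpha_carrier * 1[carrier] + beta_stratum * PRS)` with
#' `beta_stratum = beta_carrier` for carriers and `beta_noncarrier`
#' otherwise. A non-carrier at the population-mean score is the reference
#' class (OR 1). For `"unknown"` carrier status both branch ORs are
#' returned.
#'
#' @param standardized_prs standardized PRS (SD units).
#' @param carrier `TRUE`, `FALSE`, or `"unknown"`.
#' @param alpha_carrier carrier main-effect log OR at PRS = 0.
#' @param beta_carrier,beta_noncarrier per-SD PRS log OR in each stratum.
#' @return for known status, a single odds ratio; for `"unknown"`, a named
#'   vector with both `carrier` and `noncarrier` branch ORs.
#' @export
combined_or <- function(standardized_prs, carrier, alpha_carrier,
                        beta_carrier, beta_noncarrier) {
  for (b in c(alpha_carrier, beta_carrier, beta_noncarrier)) {
    if (!is.finite(b)) wgr_stop("missing or non-finite panel effect size", "panel")
  }
  branch <- function(is_carrier) {
    exp(alpha_carrier * is_carrier +
        (if (is_carrier) beta_carrier else beta_noncarrier) * standardized_prs)
  }
  if (identical(carrier, "unknown")) {
    return(c(carrier = branch(TRUE), noncarrier = branch(FALSE)))
  }
  branch(isTRUE(carrier) || identical(carrier, "carrier"))
}

#' Summarize risk across a family's embryos
#'
#' Per condition: the minimum and maximum combined OR, their fold
#' difference, the embryos ranked by OR, and a flag for the inadvertent
#' transfer scenario — embryos whose PRS percentile within the family is
#' below 50 (and that would therefore look favorable under PRS-only
#' screening) yet carry a pathogenic variant.
#'
#' @param reports data.frame with one row per embryo x condition:
#'   columns `embryo`, `condition`, `standardized_prs`, `carrier`
#'   (logical), `odds_ratio`.
#' @return list of class `family_report`: `summary` (per condition: min OR,
#'   max OR, fold), `ranked` (embryos sorted by OR within condition, with
#'   `prs_percentile` and `low_prs_carrier` flag).
#' @export
family_report <- function(reports) {
  need <- c("embryo", "condition", "standardized_prs", "carrier", "odds_ratio")
  if (!all(need %in% names(reports))) {
    wgr_stop(paste("reports must have columns:", paste(need, collapse = ", ")),
             "report")
  }
  if (nrow(reports) < 1) wgr_stop("need at least 1 embryo", "report")
  pieces <- split(reports, reports$condition)
  summary <- do.call(rbind, lapply(pieces, function(d) {
    data.frame(condition = d$condition[1],
               n_embryos = nrow(d),
               min_or = min(d$odds_ratio), max_or = max(d$odds_ratio),
               fold = max(d$odds_ratio) / min(d$odds_ratio))
  }))
  rownames(summary) <- NULL
  ranked <- do.call(rbind, lapply(pieces, function(d) {
    d <- d[order(d$odds_ratio), , drop = FALSE]
    pr <- 100 * (rank(d$standardized_prs, ties.method = "average") - 0.5) / nrow(d)
    d$prs_percentile <- pr
    d$low_prs_carrier <- pr < 50 & d$carrier
    d
  }))
  rownames(ranked) <- NULL
  structure(list(summary = summary, ranked = ranked), class = "family_report")
}

#' @export
print.family_report <- function(x, ...) {
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf("%s: OR %.2f-%.2f across %d embryos (%.1f-fold)\n",
                s$condition, s$min_or, s$max_or, s$n_embryos, s$fold))
  }
  n_flag <- sum(x$ranked$low_prs_carrier)
  if (n_flag) cat(sprintf("  %d embryo(s) below the 50th PRS percentile carry a pathogenic variant\n", n_flag))
  invisible(x)
}
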