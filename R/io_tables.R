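#' Population allele-frequency table
#'
#' Maps sites to a population alternate-allele frequency (gnomAD-style).
#' Sites absent from the table are queryable and return `NA` ("absent"),
#' which [classify_rare()] treats as rare.
#'
#' @param chrom,pos site coordinates.
#' @param af frequencies in \[0, 1\].
#' @return data.frame of class `af_table`.
#' @export
af_table <- function(chrom, pos, af) {
  af <- as.numeric(af)
  if (any(is.na(af)) || any(af < 0 | af > 1)) {
    wgr_stop("allele frequencies must lie in [0, 1]", "af_table")
  }
  df <- data.frame(chrom = normalize_chrom(as.character(chrom)),
                   pos = as.integer(pos), af = af, stringsAsFactors = FALSE)
  class(df) <- c("af_table", "data.frame")
  df
}

#' Look up allele frequencies for a set of sites
#'
#' @param table an [af_table()].
#' @param sites a [site_table()].
#' @return numeric vector of frequencies, `NA` where the site is absent.
#' @export
af_lookup <- function(table, sites) {
  table$af[match(site_key(sites), paste0(table$chrom, ":", table$pos))]
}

#' Read a genetic map file
#'
#' Three whitespace-separated columns — chromosome, physical position,
#' cumulative cM — with an optional header line, the convention of public
#' (sex-specific) genetic-map distributions. Decreasing cM within a
#' chromosome is fatal.
#'
#' @param path file path.
#' @return a [genetic_map()].
#' @export
read_genetic_map <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(trimws(first), "\\s+")[[1]][2])))
  df <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(df) < 3) wgr_stop("genetic map needs 3 columns: chr pos cM", "genetic_map")
  genetic_map(df[[1]], df[[2]], df[[3]])
}

#' @rdname read_genetic_map
#' @param map a [genetic_map()].
#' @export
write_genetic_map <- function(map, path) {
  utils::write.table(stats::setNames(as.data.frame(map), c("chr", "pos", "cM")),
                     path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Construct a polygenic risk score model
#'
#' A PRS is a weighted sum of effect-allele dosages; weights are per-allele
#' log odds ratios from the model's source publication. `beta_per_sd` is the
#' per-standard-deviation effect size (log OR per SD of the centered,
#' standardized score) used by [or_from_prs()].
#'
#' @param condition condition name.
#' @param chrom,pos,effect_allele,weight per-variant model columns.
#' @param other_allele optional non-effect allele.
#' @param beta_per_sd log odds ratio per SD of standardized PRS.
#' @param sites optional analysis [site_table()]; model variants absent from
#'   it are flagged `predictable = FALSE` (they are retained, and contribute
#'   their population expectation to the score — see [raw_prs()]).
#' @return object of class `prs_model`.
#' @export
prs_model <- function(condition, chrom, pos, effect_allele, weight,
                      other_allele = NA_character_, beta_per_sd = NA_real_,
                      sites = NULL) {
  weight <- as.numeric(weight)
  if (any(!is.finite(weight))) wgr_stop("non-finite PRS weight", "prs_model")
  v <- data.frame(chrom = normalize_chrom(as.character(chrom)),
                  pos = as.integer(pos),
                  effect_allele = toupper(as.character(effect_allele)),
                  other_allele = toupper(as.character(other_allele)),
                  weight = weight, stringsAsFactors = FALSE)
  key <- paste0(v$chrom, ":", v$pos)
  if (anyDuplicated(key)) {
    wgr_stop("duplicate (chrom, pos) rows in PRS model", "prs_model")
  }
  v$predictable <- if (is.null(sites)) TRUE else key %in% site_key(sites)
  structure(list(condition = condition, variants = v,
                 beta_per_sd = beta_per_sd), class = "prs_model")
}

#' Read a PGS-Catalog-style scoring file
#'
#' Tab-separated with a header naming at least `chr_name`, `chr_position`,
#' `effect_allele` and `effect_weight` (`other_allele` honored when
#' present); `#` lines are metadata and skipped. Non-numeric weights and
#' duplicated positions are fatal.
#'
#' @param path file path.
#' @param condition condition label (default: file base name).
#' @param beta_per_sd per-SD effect size to attach (log OR per SD).
#' @param sites optional analysis [site_table()] for predictability flags.
#' @return a [prs_model()].
#' @export
read_prs_model <- function(path, condition = NULL, beta_per_sd = NA_real_,
                           sites = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("chr_name", "chr_position", "effect_allele", "effect_weight")
  if (!all(need %in% names(df))) {
    wgr_stop(paste("scoring file must have columns:", paste(need, collapse = ", ")),
             "prs_model")
  }
  w <- suppressWarnings(as.numeric(df$effect_weight))
  if (any(is.na(w))) {
    wgr_stop(sprintf("non-numeric effect_weight in row(s) %s",
                     paste(utils::head(which(is.na(w)), 3), collapse = ", ")),
             "prs_model")
  }
  prs_model(condition %||% sub("\\.[^.]*$", "", basename(path)),
            df$chr_name, df$chr_position, df$effect_allele, w,
            other_allele = if ("other_allele" %in% names(df)) df$other_allele else NA,
            beta_per_sd = beta_per_sd, sites = sites)
}

#' @rdname read_prs_model
#' @param model a [prs_model()].
#' @export
write_prs_model <- function(model, path) {
  v <- model$variants
  out <- data.frame(chr_name = v$chrom, chr_position = v$pos,
                    effect_allele = v$effect_allele,
                    other_allele = v$other_allele,
                    effect_weight = format(v$weight, digits = 17))
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read / write a site-to-allele-frequency table
#'
#' Two tab-separated columns with header: `site` (`chrom:pos`) and `af`.
#' @param path file path.
#' @return an [af_table()].
#' @export
read_af_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("site", "af") %in% names(df))) {
    wgr_stop("AF table must have columns: site, af", "af_table")
  }
  parts <- strsplit(df$site, ":", fixed = TRUE)
  af_table(vapply(parts, `[`, "", 1), as.integer(vapply(parts, `[`, "", 2)),
           as.numeric(df$af))
}

#' @rdname read_af_table
#' @param table an [af_table()].
#' @export
write_af_table <- function(table, path) {
  out <- data.frame(site = paste0(table$chrom, ":", table$pos),
                    af = format(table$af, digits = 17))
  utils::write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Write transmission segments as a BED-like interval file
#'
#' Columns: chrom, start, end (half-open, 0-based — the BED convention,
#' unlike the package's internal 1-based inclusive coordinates), parent,
#' haplotype index, mean posterior. Overlapping segments for one parent on
#' one chromosome are fatal on both write and read.
#'
#' @param path file path.
#' @param x a `transmission_path` or its `segments` data.frame.
#' @export
write_segments <- function(x, path) {
  segs <- if (inherits(x, "transmission_path")) x$segments else x
  check_segment_overlap(segs)
  out <- data.frame(chrom = segs$chrom, start = segs$start - 1, end = segs$end,
                    parent = segs$parent, hap = segs$hap,
                    mean_posterior = format(segs$mean_posterior, digits = 17))
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_segments
#' @return `read_segments`: data.frame (chrom, parent, start, end, hap,
#'   mean_posterior) in 1-based inclusive coordinates.
#' @export
read_segments <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "parent",
                                        "hap", "mean_posterior"))
  segs <- data.frame(chrom = as.character(df$chrom), parent = df$parent,
                     start = df$start + 1, end = df$end,
                     hap = as.integer(df$hap),
                     mean_posterior = as.numeric(df$mean_posterior),
                     stringsAsFactors = FALSE)
  check_segment_overlap(segs)
  segs
}

#' @noRd
check_segment_overlap <- function(segs) {
  for (key in unique(paste(segs$chrom, segs$parent))) {
    s <- segs[paste(segs$chrom, segs$parent) == key, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] <= s$end[-nrow(s)])) {
      wgr_stop(sprintf("overlapping segments for %s", key), "segments")
    }
  }
  invisible(segs)
}

#' Read / write an embryo array-call table
#'
#' Tab-separated with header: chrom, pos, ref, alt, call; calls are VCF-style
#' unphased genotypes (`0/0`, `0/1`, `1/1`) with `./.` for a no-call, which
#' maps to the distinct missing state, never to hom-ref. Aneuploid
#' chromosome flags are carried in a `##aneuploid=` header line.
#'
#' @param obs an [embryo_obs()].
#' @param path file path.
#' @export
write_array_obs <- function(obs, path) {
  gt <- c("0/0", "0/1", "1/1")[obs$call + 1L]
  gt[is.na(gt)] <- "./."
  con <- file(path, "w")
  on.exit(close(con))
  if (length(obs$aneuploid)) {
    writeLines(paste0("##aneuploid=", paste(obs$aneuploid, collapse = ",")), con)
  }
  writeLines("chrom\tpos\tref\talt\tcall", con)
  writeLines(paste(obs$sites$chrom, obs$sites$pos, obs$sites$ref,
                   obs$sites$alt, gt, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_array_obs
#' @export
read_array_obs <- function(path) {
  lines <- readLines(path)
  aneu <- character()
  meta <- grepl("^##", lines)
  for (l in lines[meta]) {
    if (grepl("^##aneuploid=", l)) {
      aneu <- strsplit(sub("^##aneuploid=", "", l), ",")[[1]]
    }
  }
  df <- utils::read.table(text = lines[!meta], header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "integer", "character",
                                         "character", "character"))
  call <- match(df$call, c("0/0", "0/1", "1/1")) - 1L
  if (any(is.na(call) & df$call != "./.")) {
    wgr_stop("array calls must be 0/0, 0/1, 1/1 or ./.", "array_obs")
  }
  embryo_obs(site_table(df$chrom, df$pos, df$ref, df$alt), call,
             aneuploid = aneu)
}
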