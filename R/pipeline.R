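#' Run configuration for the reconstruction pipeline
#'
#' A validated, YAML-serializable description of one pipeline run. Two
#' modes: `"simulate"` generates a synthetic family fixture in the run
#' directory ([simulate_family()]), `"files"` consumes user-supplied inputs
#' (parents VCF, per-embryo array-call tables, genetic map, optional AF
#' table, PRS scoring file and monogenic panel). A seed is mandatory —
#' every stochastic stage draws from it.
#'
#' @param mode `"simulate"` or `"files"`.
#' @param seed integer seed (mandatory).
#' @param noise noise preset name or list with `ado`, `error`, `missing`.
#' @param simulate list of [simulate_family()] arguments (simulate mode).
#' @param inputs list of paths: `parents_vcf`, `mother`, `father` (sample
#'   names), `embryos` (character vector of array-call tables), `map`,
#'   optionally `af`, `truth_vcf` + `truth_sample` (files mode).
#' @param prs optional list: `model` (scoring file path), `beta_per_sd`,
#'   `population`; in simulate mode a small model over simulated sites may
#'   be generated with `n_model_sites`.
#' @param n_replicates embryo-simulation replicates for the PRS
#'   distribution stage (default 500).
#' @param k_pcs number of principal components (>= 4).
#' @param phasing `"embryo"` (parental-support phasing from sibling
#'   embryos, anchored to any external phase present) or `"truth"` (use the
#'   parents' phase as given — e.g. simulated truth or reference-panel
#'   phased input — directly).
#' @return list of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "files"), seed, noise = "day5",
                       simulate = list(), inputs = list(), prs = NULL,
                       n_replicates = 500, k_pcs = 4,
                       phasing = c("embryo", "truth")) {
  phasing <- match.arg(phasing)
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    wgr_stop("a seed is mandatory in the run configuration", "config")
  }
  if (mode == "files") {
    need <- c("parents_vcf", "mother", "father", "embryos", "map")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) {
      wgr_stop(paste("files mode requires inputs:", paste(miss, collapse = ", ")),
               "config")
    }
  }
  if (k_pcs < 4) wgr_stop("k_pcs must be at least 4", "config")
  cfg <- list(mode = mode, seed = as.integer(seed), noise = noise,
              simulate = simulate, inputs = inputs, prs = prs,
              n_replicates = n_replicates, k_pcs = k_pcs, phasing = phasing)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y[intersect(names(y),
                                  names(formals(run_config)))])
}

#' @rdname run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the whole pipeline end to end
#'
#' Stages: obtain inputs (simulate or load) -> phase both parents from
#' sibling embryos -> decode each embryo's transmitted haplotypes and fill
#' its genome -> optional PRS scoring and embryo-distribution simulation ->
#' evaluate against truth when available. All outputs, a log, and a
#' manifest (configuration hash, per-stage counts, headline metrics) are
#' written into `out_dir`. Deterministic given the config seed; the
#' manifest contains no timestamps so identical runs produce identical
#' manifests.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created; must not exist unless
#'   `overwrite`).
#' @param overwrite allow writing into an existing directory.
#' @return the manifest, invisibly.
#' @export
run_end_to_end <- function(config, out_dir, overwrite = FALSE) {
  stopifnot(inherits(config, "run_config"))
  if (dir.exists(out_dir) && !overwrite) {
    wgr_stop(sprintf("run directory %s already exists", out_dir), "config")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message("[wgr] ", line)
  }
  set.seed(config$seed)
  noise <- if (is.character(config$noise)) noise_profile(config$noise) else
    noise_profile(config$noise$ado, config$noise$error, config$noise$missing,
                  config$noise$label %||% "custom")

  # ---- stage: inputs -------------------------------------------------------
  if (config$mode == "simulate") {
    fam <- do.call(simulate_family,
                   c(config$simulate, list(noise = noise, seed = config$seed)))
    say("simulated family: %d embryos, %d sites (%d on array)",
        length(fam$embryos), nrow(fam$sites), nrow(fam$array_sites))
    write_vcf(fam$sites, list(mother = fam$mother, father = fam$father),
              file.path(out_dir, "parents.vcf"))
    write_genetic_map(fam$map, file.path(out_dir, "map.txt"))
    write_af_table(fam$af_table, file.path(out_dir, "af.tsv"))
    for (i in seq_along(fam$embryos)) {
      write_array_obs(fam$embryos[[i]]$obs,
                      file.path(out_dir, sprintf("embryo%02d.calls.tsv", i)))
    }
    mother <- fam$mother; father <- fam$father
    mother_gt <- father_gt <- NULL
    obs_list <- lapply(fam$embryos, `[[`, "obs")
    map <- fam$map; af <- fam$af_table
    truth_list <- lapply(fam$embryos, `[[`, "truth")
  } else {
    vcf <- read_vcf(config$inputs$parents_vcf,
                    samples = c(config$inputs$mother, config$inputs$father))
    mother <- as_phased_genome(vcf, config$inputs$mother)
    father <- as_phased_genome(vcf, config$inputs$father)
    # genotype (dosage) view, independent of whether the VCF is phased
    mother_gt <- list(sites = vcf$sites, dosage = vcf$dosage[, config$inputs$mother])
    father_gt <- list(sites = vcf$sites, dosage = vcf$dosage[, config$inputs$father])
    obs_list <- lapply(config$inputs$embryos, read_array_obs)
    map <- read_genetic_map(config$inputs$map)
    af <- if (!is.null(config$inputs$af)) read_af_table(config$inputs$af) else NULL
    truth_list <- NULL
    say("loaded %d embryos over %d parental sites", length(obs_list),
        nrow(mother$sites))
  }

  # ---- stage: parental phasing --------------------------------------------
  if (config$phasing == "truth") {
    all_phased <- function(g) !any(is.na(g$hap1[is_het(g)]))
    if (!all_phased(mother) || !all_phased(father)) {
      wgr_stop("phasing = 'truth' requires fully phased parental input", "config")
    }
    mother_ph <- mother; father_ph <- father
    sc_m <- sc_p <- list(confidence = NULL)
    say("using supplied parental phase directly")
  } else {
    sc <- phase_parents(mother_gt %||% mother, father_gt %||% father,
                        obs_list, map, noise)
    sc_m <- sc$mother; sc_p <- sc$father
    say("phased parents: %d / %d het array sites scaffolded",
        sum(!is.na(sc_m$confidence)), sum(!is.na(sc_p$confidence)))
    # anchor any available external/truth phase to the scaffold labeling
    all_phased <- function(g) !any(is.na(g$hap1[is_het(g)]))
    if (config$mode == "simulate" || (all_phased(mother) && all_phased(father))) {
      mother_ph <- merge_with_truth_phase(sc_m, mother)
      father_ph <- merge_with_truth_phase(sc_p, father)
    } else {
      mother_ph <- sc_m$genome; father_ph <- sc_p$genome
    }
  }
  write_phased_vcf(mother_ph, file.path(out_dir, "mother.phased.vcf"),
                   sample = "mother", phase_confidence = sc_m$confidence)
  write_phased_vcf(father_ph, file.path(out_dir, "father.phased.vcf"),
                   sample = "father", phase_confidence = sc_p$confidence)

  # ---- stage: reconstruction ----------------------------------------------
  recons <- vector("list", length(obs_list))
  paths <- vector("list", length(obs_list))
  n_segments <- 0L
  for (i in seq_along(obs_list)) {
    path <- decode_transmission(obs_list[[i]], mother_ph, father_ph, map, noise)
    paths[[i]] <- path
    recons[[i]] <- fill_genome(path, mother_ph, father_ph,
                               mother_phase_conf = sc_m$confidence,
                               father_phase_conf = sc_p$confidence)
    write_reconstruction(recons[[i]],
                         file.path(out_dir, sprintf("embryo%02d.recon.vcf", i)),
                         sample = sprintf("embryo%02d", i))
    write_segments(path, file.path(out_dir, sprintf("embryo%02d.segments.bed", i)))
    n_segments <- n_segments + nrow(path$segments)
    say("embryo %d: %d sites predicted, %d segments, %d breakpoints",
        i, sum(recons[[i]]$predicted), nrow(path$segments), nrow(path$breakpoints))
  }

  # ---- stage: evaluation ---------------------------------------------------
  accuracy <- NULL
  if (!is.null(truth_list)) {
    accs <- vapply(seq_along(recons), function(i) {
      genotype_accuracy(recons[[i]], truth_list[[i]])$genome_wide_accuracy
    }, 0)
    # accuracy restricted to sites the observed data can determine (outside
    # breakpoint-uncertainty intervals and undetectable-crossover regions)
    det <- vapply(seq_along(recons), function(i) {
      m <- truth_determined_mask(paths[[i]], mother$sites,
                                 fam$embryos[[i]]$meiosis_m,
                                 fam$embryos[[i]]$meiosis_p)
      genotype_accuracy(recons[[i]], truth_list[[i]], mask = m)$genome_wide_accuracy
    }, 0)
    accuracy <- list(per_embryo = accs, mean = mean(accs),
                     determined_per_embryo = det, determined_mean = mean(det))
    say("genome-wide accuracy: mean %.3f%% (range %.3f-%.3f%%); %.3f%% at determined sites",
        mean(accs), min(accs), max(accs), mean(det))
  }

  manifest <- list(
    package = "wgr",
    version = as.character(utils::packageVersion("wgr")),
    config = unclass(config),
    config_hash = config_hash(config),
    n_embryos = length(obs_list),
    n_sites = nrow(mother$sites),
    n_segments = n_segments,
    accuracy = accuracy
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(manifest)
}

#' @noRd
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}
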