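# Orchestration of the full evaluation loop:
#   simulate -> corrupt -> impute -> reconstruct -> evaluate
# Each stage reads the previous stage's files from the run directory and
# writes its own, so chained stage calls are exactly what run_pipeline()
# executes. One master seed; each stochastic stage derives its own child
# seed deterministically (see derive_seed()), so re-running a late stage
# never perturbs earlier draws.

#' Build a pipeline configuration
#'
#' Collects all tunable parameters of the evaluation loop with their
#' defaults. Probabilities are validated here; a recorded copy is written
#' into every run manifest.
#'
#' @param seed master integer seed for the whole run.
#' @param n_founders,n_progeny,design,generations mating design (see
#'   [sim_pedigree()]).
#' @param n_chrom,markers_per_chrom,length_cM,spacing genetic map (see
#'   [sim_genetic_map()]).
#' @param maf,ibs_fraction founder panel (see [sim_founders()]).
#' @param error_rate global genotyping error rate induced in the known
#'   genotypes.
#' @param missingness per-locus missingness: a single constant rate, a
#'   profile tibble (`marker`, `f_miss`) or a path to a profile TSV.
#' @param impute_rho,impute_error_rate,rsq_threshold imputation stage (see
#'   [impute_genotypes()]); `impute_error_rate`/`hmm_error_rate` default to
#'   the injected `error_rate`.
#' @param hmm_R,hmm_error_rate origin decoding stage (see
#'   [decode_origins()]).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_founders = 8L, n_progeny = 100L,
                            design = "outcross", generations = 2L,
                            n_chrom = 1L, markers_per_chrom = 200L,
                            length_cM = 150, spacing = "random",
                            maf = c(0.2, 0.5), ibs_fraction = 0,
                            error_rate = 0.006, missingness = 0.1,
                            impute_rho = 1, impute_error_rate = NULL,
                            rsq_threshold = 0.8,
                            hmm_R = NULL, hmm_error_rate = NULL) {
  stopifnot_scalar_prob(error_rate, "error_rate")
  cfg <- list(
    seed = as.integer(seed),
    n_founders = n_founders, n_progeny = n_progeny, design = design,
    generations = generations,
    n_chrom = n_chrom, markers_per_chrom = markers_per_chrom,
    length_cM = length_cM, spacing = spacing,
    maf = maf, ibs_fraction = ibs_fraction,
    error_rate = error_rate, missingness = missingness,
    impute_rho = impute_rho,
    impute_error_rate = impute_error_rate %||% error_rate,
    rsq_threshold = rsq_threshold,
    # default switch intensity: one origin switch per Morgan per homologue
    # per recombinant meiosis beyond the founder generation
    hmm_R = hmm_R %||% max(1, generations - 1),
    hmm_error_rate = hmm_error_rate %||% error_rate
  )
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) {
    abort(paste0("unknown config keys: ", paste(unknown, collapse = ", ")))
  }
  do.call(pipeline_config, vals)
}

run_paths <- function(dir) {
  list(
    map = file.path(dir, "map.tsv"),
    founders = file.path(dir, "founders.tsv"),
    founders_vcf = file.path(dir, "founders.vcf.gz"),
    pedigree = file.path(dir, "pedigree.csv"),
    missingness = file.path(dir, "missingness.tsv"),
    truth_vcf = file.path(dir, "known.vcf.gz"),
    truth_origins = file.path(dir, "known_origins.tsv"),
    observed_vcf = file.path(dir, "observed.vcf.gz"),
    realized = file.path(dir, "realized_rates.tsv"),
    imputed_vcf = file.path(dir, "imputed.vcf.gz"),
    quality = file.path(dir, "imputation_quality.tsv"),
    inferred_origins = file.path(dir, "inferred_origins.tsv"),
    posterior = file.path(dir, "posterior.tsv"),
    logprob = file.path(dir, "path_logprob.tsv"),
    metrics = file.path(dir, "metrics"),
    manifest = file.path(dir, "manifest.json")
  )
}

read_manifest <- function(dir) {
  p <- run_paths(dir)$manifest
  if (file.exists(p)) jsonlite::read_json(p) else list()
}

update_manifest <- function(dir, stage, info, config = NULL) {
  p <- run_paths(dir)$manifest
  man <- read_manifest(dir)
  if (!is.null(config)) man$config <- unclass(config)
  man$package_version <- as.character(utils::packageVersion("haplomosaic"))
  man$stages[[stage]] <- info
  jsonlite::write_json(man, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man)
}

require_files <- function(paths) {
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing)) {
    abort(paste0("required input file(s) missing: ",
                 paste(unlist(missing), collapse = ", ")))
  }
}

#' Pipeline stages
#'
#' Each stage consumes the previous stage's files in `dir` and writes its
#' own, identically to the corresponding step inside [run_pipeline()] (which
#' simply chains them). Stage-specific seeds are derived from the master
#' seed in the config by fixed offsets, so stages can be re-run in
#' isolation.
#'
#' * `pipeline_simulate`: genetic map, founder panel (TSV + phased VCF),
#'   pedigree, missingness profile, and the known origin-labelled
#'   population (phased VCF + origins TSV).
#' * `pipeline_corrupt`: observed genotypes (unphased VCF with `./.`) and
#'   realized per-locus error/missingness rates.
#' * `pipeline_impute`: imputed VCF with dosages and the per-marker quality
#'   table with the retained flag.
#' * `pipeline_reconstruct`: inferred origins TSV (same schema as the known
#'   origins), per-marker posterior summary, per-path log-probabilities.
#' * `pipeline_evaluate`: metrics JSON and TSV tables.
#'
#' @param config a `pipeline_config`.
#' @param dir run directory.
#' @return each stage returns its main in-memory product, invisibly.
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
pipeline_simulate <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- run_paths(dir)
  seed <- derive_seed(config$seed, "simulate")
  map <- sim_genetic_map(config$n_chrom, config$markers_per_chrom,
                         config$length_cM, spacing = config$spacing,
                         seed = seed)
  founders <- sim_founders(map, config$n_founders, maf = config$maf,
                           ibs_fraction = config$ibs_fraction,
                           seed = seed + 1L)
  ped <- sim_pedigree(config$n_founders, config$n_progeny,
                      design = config$design,
                      generations = config$generations)
  pop <- sim_population(ped, founders, map, seed = seed + 2L)
  miss <- config$missingness
  profile <- if (is.character(miss)) {
    read_missingness(miss)
  } else if (is.data.frame(miss)) {
    miss
  } else {
    sim_missingness(map, mean_rate = miss, seed = seed + 3L)
  }
  write_genetic_map(map, p$map)
  write_founders(founders, p$founders)
  write_vcf(founders, p$founders_vcf, map = map)
  write_pedigree(ped, p$pedigree)
  write_missingness(profile, p$missingness)
  write_vcf(pop, p$truth_vcf)
  write_origins(pop, p$truth_origins)
  update_manifest(dir, "simulate",
                  list(seed = seed, n_markers = nrow(map),
                       n_individuals = length(pop$ids)),
                  config = config)
  invisible(pop)
}

#' @rdname pipeline_stages
#' @export
pipeline_corrupt <- function(config, dir) {
  p <- run_paths(dir)
  require_files(p[c("map", "founders", "truth_vcf", "missingness")])
  seed <- derive_seed(config$seed, "corrupt")
  map <- read_genetic_map(p$map)
  truth <- read_vcf(p$truth_vcf)
  profile <- read_missingness(p$missingness)
  obs <- induce_errors(truth$geno, config$error_rate, map = map, seed = seed)
  obs <- induce_missing(obs, profile, seed = seed + 1L)
  write_vcf(obs, p$observed_vcf)
  readr::write_tsv(realized_rates(obs), p$realized)
  update_manifest(dir, "corrupt",
                  list(seed = seed, error_rate = config$error_rate,
                       realized_error = mean(obs$realized$realized_error),
                       realized_missing = mean(obs$realized$realized_missing)))
  invisible(obs)
}

#' @rdname pipeline_stages
#' @export
pipeline_impute <- function(config, dir) {
  p <- run_paths(dir)
  require_files(p[c("map", "founders", "observed_vcf")])
  map <- read_genetic_map(p$map)
  founders <- read_founders(p$founders)
  obs <- read_vcf(p$observed_vcf)
  imp <- impute_genotypes(obs$geno, founders, map = map,
                          rho = config$impute_rho,
                          error_rate = config$impute_error_rate,
                          rsq_threshold = config$rsq_threshold)
  imp <- filter_markers(imp, config$rsq_threshold)
  write_vcf(imp, p$imputed_vcf)
  readr::write_tsv(imp$quality, p$quality)
  g <- glance(imp)
  update_manifest(dir, "impute",
                  list(rho = config$impute_rho,
                       rsq_threshold = config$rsq_threshold,
                       n_markers = g$n_markers, n_retained = g$n_retained,
                       n_filtered = g$n_filtered))
  invisible(imp)
}

#' @rdname pipeline_stages
#' @export
pipeline_reconstruct <- function(config, dir) {
  p <- run_paths(dir)
  require_files(p[c("map", "founders", "imputed_vcf", "quality")])
  map <- read_genetic_map(p$map)
  founders <- read_founders(p$founders)
  imp <- read_vcf(p$imputed_vcf)
  quality <- readr::read_tsv(p$quality, col_types = "cdl", progress = FALSE)
  retained <- quality$marker[quality$retained]
  keep <- map$marker %in% retained
  dec <- decode_origins(imp$geno[keep, , drop = FALSE], founders,
                        map = map[keep, , drop = FALSE],
                        R = config$hmm_R,
                        error_rate = config$hmm_error_rate)
  write_origins(dec$inferred, p$inferred_origins)
  write_posterior(dec, p$posterior)
  readr::write_tsv(dec$logprob, p$logprob)
  update_manifest(dir, "reconstruct",
                  list(R = config$hmm_R,
                       error_rate = config$hmm_error_rate,
                       n_markers = sum(keep),
                       n_individuals = length(dec$inferred$ids)))
  invisible(dec)
}

#' @rdname pipeline_stages
#' @export
pipeline_evaluate <- function(config, dir) {
  p <- run_paths(dir)
  require_files(p[c("map", "founders", "truth_origins", "inferred_origins")])
  map <- read_genetic_map(p$map)
  founders <- read_founders(p$founders)
  # inferred origins live on the retained marker subset
  inf_tb <- readr::read_tsv(p$inferred_origins, col_types = "ccccc",
                            progress = FALSE)
  sub_map <- map[map$marker %in% unique(inf_tb$marker), , drop = FALSE]
  inferred <- read_origins(p$inferred_origins, founders, sub_map)
  known <- read_origins(p$truth_origins, founders, map)
  known <- subset_markers(known, sub_map$marker)
  decoding <- NULL
  if (file.exists(p$posterior)) {
    post <- readr::read_tsv(p$posterior, col_types = "ccccd",
                            progress = FALSE)
    cert <- matrix(NA_real_, nrow(sub_map), length(inferred$ids),
                   dimnames = list(sub_map$marker, inferred$ids))
    cert[cbind(match(post$marker, sub_map$marker),
               match(post$id, inferred$ids))] <- post$certainty
    decoding <- list(certainty = cert)
  }
  met <- evaluate_reconstruction(known, inferred, founders)
  if (!is.null(decoding)) {
    met$per_marker$mean_certainty <- rowMeans(decoding$certainty)
  }
  write_metrics(met, p$metrics)
  g <- glance(met)
  update_manifest(dir, "evaluate",
                  list(mean_aaa = g$mean_aaa, mean_gaa = g$mean_gaa,
                       mean_paa = g$mean_paa, ccc = g$ccc))
  invisible(met)
}

#' Run the full evaluation pipeline
#'
#' Executes simulate, corrupt, impute, reconstruct and evaluate in order in
#' `dir` (chaining the [pipeline_stages] exactly), persisting every
#' intermediate file plus a JSON manifest recording the package version,
#' seeds, parameters and per-stage marker counts. A stage failure aborts
#' with the stage name; files from completed stages are retained.
#'
#' @param config a `pipeline_config`.
#' @param dir run directory (created if needed; defaults to a fresh
#'   temporary directory).
#' @return a list with the final `metrics`, the run `dir` and the
#'   `manifest`.
#' @examples
#' cfg <- pipeline_config(seed = 7, n_founders = 2, n_progeny = 5,
#'                        design = "biparental_f1", markers_per_chrom = 30,
#'                        error_rate = 0, missingness = 0)
#' res <- run_pipeline(cfg)
#' glance(res$metrics)
#' @export
run_pipeline <- function(config, dir = tempfile("haplomosaic_run_")) {
  stages <- list(simulate = pipeline_simulate, corrupt = pipeline_corrupt,
                 impute = pipeline_impute, reconstruct = pipeline_reconstruct,
                 evaluate = pipeline_evaluate)
  out <- NULL
  for (nm in names(stages)) {
    out <- tryCatch(stages[[nm]](config, dir), error = function(e) {
      abort(paste0("pipeline stage '", nm, "' failed: ",
                   conditionMessage(e)))
    })
  }
  list(metrics = out, dir = dir, manifest = read_manifest(dir))
}
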