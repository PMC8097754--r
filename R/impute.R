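# Missing-genotype imputation with a Li-Stephens-style haploid-pair HMM over
# the founder haplotypes as reference panel, followed by the ratio-of-
# variances imputation quality estimate and the R-squared marker filter.
# The quality score is computed without truth, as imputation software does
# in practice; truth-based concordance is a separate diagnostic available
# from simulations.

#' Impute missing genotypes from the founder haplotype panel
#'
#' Each individual is modelled as an ordered pair of mosaic copies of the
#' reference haplotypes. The pair process is decoded by scaled
#' forward-backward; missing genotypes are replaced by the posterior-maximal
#' genotype (ties towards the smaller dosage, deterministically), dosages
#' are posterior expectations of the allele-1 count, and observed genotypes
#' pass through unchanged. The per-homologue switch probability over an
#' interval of d Morgans is `1 - exp(-rho d)` spread over haplotypes
#' uniformly; the mismatch emission probability is the genotyping error
#' rate.
#'
#' @param obs an `observed_genotypes` object (or markers x individuals
#'   dosage matrix with `map`).
#' @param founders the `founder_panel` used as reference haplotypes.
#' @param map genetic map (taken from `obs` when it carries one).
#' @param rho haplotype switch intensity per Morgan (> 0).
#' @param error_rate emission mismatch probability; defaults to the
#'   pipeline's global genotyping error rate.
#' @param rsq_threshold quality threshold stored for [filter_markers()].
#' @return an `imputation_result`: `imputed` (no missing values), `dosage`
#'   in `[0, 2]`, the `quality` tibble (`marker`, `rsq`, `retained`), the
#'   observation mask and the map.
#' @examples
#' map <- sim_genetic_map(n_markers = 40, seed = 1)
#' fnd <- sim_founders(map, 4, seed = 2)
#' pop <- sim_population(sim_pedigree(4, 20), fnd, map, seed = 3)
#' obs <- induce_missing(induce_errors(pop, 0.006, seed = 4), 0.1, seed = 5)
#' imp <- impute_genotypes(obs, fnd)
#' @export
impute_genotypes <- function(obs, founders, map = NULL, rho = 1,
                             error_rate = 0.006, rsq_threshold = 0.8) {
  if (inherits(obs, "observed_genotypes")) {
    map <- obs$map
    g <- obs$geno
  } else {
    if (is.null(map)) abort("`map` is required when `obs` is a bare matrix")
    g <- as_geno_matrix(obs)
  }
  if (rho <= 0) abort("`rho` must be positive")
  stopifnot_scalar_prob(error_rate, "error_rate")
  validate_founders(founders)
  fa <- founder_alleles(founders)
  if (!all(map$marker %in% rownames(fa))) {
    abort("reference haplotypes do not cover the markers being imputed")
  }
  fa <- fa[map$marker, , drop = FALSE]
  H <- ncol(fa)
  prior <- rep(1 / H, H)
  prior_joint <- rep(1 / (H * H), H * H)
  N <- ncol(g)
  L <- nrow(map)

  imputed <- g
  dosage <- matrix(NA_real_, L, N, dimnames = dimnames(g))
  for (idx in chrom_index(map)) {
    implied <- implied_genotypes(fa[idx, , drop = FALSE])
    cube <- joint_transition_cube(map$cM[idx], rho, prior)
    # genotype-class indicators over states, for posterior-maximal calls
    cls <- lapply(0:2, function(cc) t(implied == cc))
    for (i in seq_len(N)) {
      gv <- g[idx, i]
      dec <- decode_chrom(gv, implied, cube, prior_joint, error_rate,
                          viterbi = FALSE, posterior = TRUE)
      dosage[idx, i] <- pmin(pmax(colSums(dec$gamma * t(implied)), 0), 2)
      miss <- is.na(gv)
      if (any(miss)) {
        pg <- vapply(cls, function(ind) {
          colSums(dec$gamma * ind)
        }, numeric(length(idx)))
        imputed[idx, i][miss] <- max.col(pg[miss, , drop = FALSE],
                                         ties.method = "first") - 1L
      }
    }
  }
  quality <- estimate_rsq(dosage, map) %>%
    dplyr::mutate(retained = .data$rsq >= rsq_threshold)
  structure(list(
    imputed = imputed, dosage = dosage, quality = quality,
    observed_mask = !is.na(g), map = map, rho = rho,
    error_rate = error_rate, rsq_threshold = rsq_threshold
  ), class = "imputation_result")
}

#' @export
print.imputation_result <- function(x, ...) {
  cat("<imputation_result> ", nrow(x$imputed), " markers x ", ncol(x$imputed),
      " individuals; ", sum(!x$observed_mask), " calls imputed; ",
      sum(x$quality$retained), "/", nrow(x$quality),
      " markers pass rsq >= ", x$rsq_threshold, "\n", sep = "")
  invisible(x)
}

#' Estimate per-marker imputation quality R-squared
#'
#' The ratio-of-variances estimator used by imputation software: the
#' empirical variance of the imputed dosage across individuals divided by
#' the expected binomial variance `2 p (1 - p)` at the dosage-based allele
#' frequency `p`. Defined as 0 at monomorphic markers (`p` of 0 or 1); can
#' slightly exceed 1 by sampling noise.
#'
#' @param x an `imputation_result` or a markers x individuals dosage matrix.
#' @param map genetic map (required for a bare matrix).
#' @return tibble (`marker`, `rsq`).
#' @export
estimate_rsq <- function(x, map = NULL) {
  if (inherits(x, "imputation_result")) {
    d <- x$dosage; map <- x$map
  } else {
    d <- x
    if (is.null(map)) abort("`map` is required when `x` is a bare matrix")
  }
  p <- rowMeans(d) / 2
  denom <- 2 * p * (1 - p)
  v <- apply(d, 1, var)
  rsq <- ifelse(denom <= .Machine$double.eps, 0, v / denom)
  tibble::tibble(marker = map$marker, rsq = as.numeric(rsq))
}

#' Filter markers on estimated imputation quality
#'
#' Retains markers with `rsq >= threshold`. Errors if any chromosome would
#' be left with no retained marker, since downstream decoding is
#' chromosome-wise.
#'
#' @param result an `imputation_result`.
#' @param threshold quality threshold (default 0.8).
#' @return the `imputation_result` with its `quality$retained` mask and
#'   threshold updated; retained marker ids via [retained_markers()].
#' @export
filter_markers <- function(result, threshold = 0.8) {
  if (!inherits(result, "imputation_result")) {
    abort("`result` must be an imputation_result")
  }
  q <- result$quality %>% dplyr::mutate(retained = .data$rsq >= threshold)
  by_chrom <- split(q$retained, factor(result$map$chrom,
                                       levels = unique(result$map$chrom)))
  none <- names(by_chrom)[!vapply(by_chrom, any, logical(1))]
  if (length(none)) {
    abort(paste0("no markers retained on chromosome(s): ",
                 paste(none, collapse = ", ")))
  }
  result$quality <- q
  result$rsq_threshold <- threshold
  result
}

#' Retained marker ids after quality filtering
#' @param result an `imputation_result`.
#' @return character vector of marker ids with `retained == TRUE`.
#' @export
retained_markers <- function(result) {
  result$quality$marker[result$quality$retained]
}

#' Tidy an imputation result
#' @param x an `imputation_result`.
#' @param ... unused.
#' @return long tibble (`id`, `marker`, `imputed`, `dosage`, `observed`).
#' @export
tidy.imputation_result <- function(x, ...) {
  N <- ncol(x$imputed)
  tibble::tibble(
    id = rep(colnames(x$imputed), each = nrow(x$imputed)),
    marker = rep(x$map$marker, N),
    imputed = as.integer(x$imputed),
    dosage = as.vector(x$dosage),
    observed = as.vector(x$observed_mask)
  )
}

#' One-row imputation summary
#' @param x an `imputation_result`.
#' @param ... unused.
#' @return tibble with marker counts and mean quality.
#' @export
glance.imputation_result <- function(x, ...) {
  tibble::tibble(
    n_markers = nrow(x$quality),
    n_retained = sum(x$quality$retained),
    n_filtered = sum(!x$quality$retained),
    mean_rsq = mean(x$quality$rsq),
    frac_imputed = mean(!x$observed_mask)
  )
}

#' Restrict objects to a marker subset
#'
#' @param pop an `origin_diplotypes`, `observed_genotypes`,
#'   `imputation_result` or `founder_panel`.
#' @param markers marker ids to keep (map order preserved).
#' @return the subsetted object.
#' @export
subset_markers <- function(pop, markers) UseMethod("subset_markers")

#' @export
subset_markers.observed_genotypes <- function(pop, markers) {
  keep <- pop$map$marker %in% markers
  if (!any(keep)) abort("no markers left after subsetting")
  new_observed_genotypes(pop$geno[keep, , drop = FALSE],
                         pop$map[keep, , drop = FALSE],
                         pop$realized[keep, , drop = FALSE])
}

#' @export
subset_markers.imputation_result <- function(pop, markers) {
  keep <- pop$map$marker %in% markers
  if (!any(keep)) abort("no markers left after subsetting")
  pop$imputed <- pop$imputed[keep, , drop = FALSE]
  pop$dosage <- pop$dosage[keep, , drop = FALSE]
  pop$observed_mask <- pop$observed_mask[keep, , drop = FALSE]
  pop$quality <- pop$quality[keep, , drop = FALSE]
  pop$map <- pop$map[keep, , drop = FALSE]
  pop
}

#' @export
subset_markers.founder_panel <- function(pop, markers) {
  new_founder_panel(pop[pop$marker %in% markers, , drop = FALSE])
}
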