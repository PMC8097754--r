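# Corruption of known genotypes: a global genotyping-error rate and
# per-locus missingness, with realized per-locus rates reported, mimicking
# analysis in practice. Errors are injected first, then missingness; a
# masked call may have been flipped first (the flip is then unobservable),
# and realized error frequencies are reported pre-masking.

new_observed_genotypes <- function(geno, map, realized) {
  structure(list(geno = geno, map = map, realized = realized),
            class = "observed_genotypes")
}

#' @export
print.observed_genotypes <- function(x, ...) {
  cat("<observed_genotypes> ", nrow(x$geno), " markers x ", ncol(x$geno),
      " individuals; ", sum(is.na(x$geno)), " missing calls\n", sep = "")
  invisible(x)
}

#' Tidy observed genotypes
#' @param x an `observed_genotypes` object.
#' @param ... unused.
#' @return a long tibble (`id`, `chrom`, `marker`, `geno`), `geno` being the
#'   allele-1 dosage 0/1/2 or `NA` when missing.
#' @export
tidy.observed_genotypes <- function(x, ...) {
  tibble::tibble(
    id = rep(colnames(x$geno), each = nrow(x$geno)),
    chrom = rep(x$map$chrom, ncol(x$geno)),
    marker = rep(x$map$marker, ncol(x$geno)),
    geno = as.integer(x$geno)
  )
}

#' Realized per-locus corruption rates
#' @param obs an `observed_genotypes` object.
#' @return tibble (`marker`, `realized_error`, `realized_missing`).
#' @export
realized_rates <- function(obs) obs$realized

as_geno_matrix <- function(x) {
  if (inherits(x, "origin_diplotypes")) geno_matrix(x)
  else if (inherits(x, "observed_genotypes")) x$geno
  else if (is.matrix(x)) x
  else abort("expected a genotype matrix, origin_diplotypes or observed_genotypes")
}

#' Induce genotyping errors at a global rate
#'
#' Each non-missing genotype call is independently perturbed with
#' probability `error_rate`; a perturbed call is replaced by one of the
#' other two unphased genotype states chosen uniformly (the
#' least-informative substitution model, symmetric for the decoder's
#' emission model). The realized per-locus flip fraction is recorded.
#'
#' @param truth an `origin_diplotypes`, genotype matrix (markers x
#'   individuals, dosage 0/1/2) or `observed_genotypes`.
#' @param error_rate global per-call error probability in `[0, 1)`.
#' @param map genetic map (required when `truth` is a bare matrix).
#' @param seed optional integer seed.
#' @return an `observed_genotypes` object.
#' @examples
#' map <- sim_genetic_map(n_markers = 30, seed = 1)
#' fnd <- sim_founders(map, 2, seed = 2)
#' pop <- sim_population(sim_pedigree(2, 10, "biparental_f1"), fnd, map, seed = 3)
#' obs <- induce_errors(pop, 0.006, seed = 4)
#' @export
induce_errors <- function(truth, error_rate, map = NULL, seed = NULL) {
  stopifnot_scalar_prob(error_rate, "error_rate")
  if (is.null(map)) {
    if (inherits(truth, "origin_diplotypes")) map <- truth$map
    else if (inherits(truth, "observed_genotypes")) map <- truth$map
    else abort("`map` is required when `truth` is a bare matrix")
  }
  g <- as_geno_matrix(truth)
  if (nrow(g) != nrow(map)) abort("genotype matrix does not match the map")
  with_seed(seed, {
    observed <- !is.na(g)
    flip <- observed & matrix(runif(length(g)) < error_rate, nrow(g))
    if (any(flip)) {
      # replace by one of the other two genotype states, uniformly
      shift <- sample.int(2L, sum(flip), replace = TRUE)
      g[flip] <- (g[flip] + shift) %% 3L
    }
    realized <- tibble::tibble(
      marker = map$marker,
      realized_error = unname(rowSums(flip) / pmax(rowSums(observed), 1L)),
      realized_missing = unname(rowMeans(is.na(g)))
    )
    new_observed_genotypes(g, map, realized)
  })
}

#' Induce missing data from a per-locus missingness profile
#'
#' Each call at marker l is set to missing independently with probability
#' `f_miss[l]`. Realized per-locus missing fractions are recorded; realized
#' error frequencies (from a prior [induce_errors()] pass) are untouched.
#'
#' @param obs an `observed_genotypes` object (or matrix plus `map`).
#' @param profile a missingness profile tibble (`marker`, `f_miss`) covering
#'   every marker, or a single constant rate.
#' @param map genetic map (required for a bare matrix).
#' @param seed optional integer seed.
#' @return an `observed_genotypes` object.
#' @export
induce_missing <- function(obs, profile, map = NULL, seed = NULL) {
  if (inherits(obs, "observed_genotypes")) {
    map <- obs$map
    realized_error <- obs$realized$realized_error
    g <- obs$geno
  } else {
    if (is.null(map)) abort("`map` is required when `obs` is a bare matrix")
    realized_error <- rep(0, nrow(map))
    g <- as_geno_matrix(obs)
  }
  if (is.numeric(profile) && length(profile) == 1L) {
    stopifnot_scalar_prob(profile, "profile", allow_one = TRUE)
    f <- rep(profile, nrow(map))
  } else {
    if (!all(c("marker", "f_miss") %in% names(profile))) {
      abort("missingness profile needs columns `marker` and `f_miss`")
    }
    pos <- match(map$marker, profile$marker)
    if (anyNA(pos)) abort("missingness profile does not cover every marker")
    f <- profile$f_miss[pos]
  }
  if (any(f < 0 | f > 1)) abort("missingness rates must be in [0, 1]")
  with_seed(seed, {
    mask <- matrix(runif(length(g)) < f, nrow(g))  # f recycles down columns
    g[mask] <- NA_integer_
    realized <- tibble::tibble(
      marker = map$marker,
      realized_error = realized_error,
      realized_missing = unname(rowMeans(is.na(g)))
    )
    new_observed_genotypes(g, map, realized)
  })
}
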