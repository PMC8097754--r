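# Ancestral-origin reconstruction: a joint HMM over ordered founder pairs,
# decoded per individual per chromosome by log-space Viterbi (the haplotype
# map) and by scaled forward-backward (posterior parent certainty).
#
# The two homologues' origin processes are independent Markov chains; the
# switch intensity R is the expected number of origin switches per Morgan on
# one homologue, reflecting the meioses accumulated in the pedigree. The
# first marker of each chromosome uses the prior; chromosomes are decoded
# independently.

#' Build the ordered founder-pair state space
#'
#' States are all ordered pairs (homologue-0 origin, homologue-1 origin)
#' enumerated lexicographically by founder index, so state
#' `s = (i - 1) * P + j` pairs founder i on homologue 0 with founder j on
#' homologue 1.
#'
#' @param founders a `founder_panel` or character vector of founder ids.
#' @param prior per-founder prior probabilities for one homologue (defaults
#'   to uniform); must sum to 1.
#' @return an `origin_state_space`: list with `founder_ids`, a `states`
#'   tibble (`state`, `hom0`, `hom1`) and the homologue `prior`.
#' @export
origin_states <- function(founders, prior = NULL) {
  ids <- if (inherits(founders, "founder_panel")) founder_ids(founders)
         else as.character(founders)
  P <- length(ids)
  if (P < 2) abort("need >= 2 founders")
  if (is.null(prior)) prior <- rep(1 / P, P)
  if (length(prior) != P || abs(sum(prior) - 1) > 1e-8 || any(prior < 0)) {
    abort("`prior` must be a probability vector over the founders")
  }
  structure(list(
    founder_ids = ids,
    states = tibble::tibble(
      state = seq_len(P * P),
      hom0 = ids[rep(seq_len(P), each = P)],
      hom1 = ids[rep(seq_len(P), times = P)]
    ),
    prior = prior
  ), class = "origin_state_space")
}

#' Transition probabilities of the joint origin chain
#'
#' For one homologue over an interval of `d_cM` centimorgans,
#' `P(stay) = exp(-R d) + (1 - exp(-R d)) * prior_same` and
#' `P(switch to j) = (1 - exp(-R d)) * prior_j` with `d` in Morgans. The
#' joint transition over ordered founder pairs is the product of the two
#' independent homologue processes; rows sum to 1.
#'
#' @param d_cM inter-marker distance in centimorgans (>= 0).
#' @param R switch intensity per Morgan per homologue (> 0).
#' @param prior per-founder prior for one homologue.
#' @return the joint transition matrix (P^2 x P^2), with the per-homologue
#'   matrix attached as attribute `"homologue"`.
#' @export
origin_transition <- function(d_cM, R, prior) {
  if (R <= 0) abort("`R` must be positive")
  if (d_cM < 0) abort("`d_cM` must be non-negative")
  m <- homologue_transition(d_cM / 100, R, prior)
  structure(kronecker(m, m), homologue = m)
}

#' Error-tolerant emission probabilities for the origin HMM
#'
#' Each state implies a true genotype (the unordered allele pair of its two
#' founders at the marker). The observed unphased call matches with
#' probability `1 - error_rate`, each of the other two genotype states has
#' probability `error_rate / 2`, and a missing observation is uninformative
#' (likelihood 1 for every state).
#'
#' @param obs observed allele-1 dosage (0/1/2) or `NA`.
#' @param implied_geno implied dosage of each state at this marker (vector
#'   over states).
#' @param error_rate assumed genotyping error probability in `[0, 1)`.
#' @return vector of per-state likelihoods.
#' @export
origin_emission <- function(obs, implied_geno, error_rate) {
  stopifnot_scalar_prob(error_rate, "error_rate")
  if (is.na(obs)) return(rep(1, length(implied_geno)))
  ifelse(implied_geno == obs, 1 - error_rate, error_rate / 2)
}

resolve_decode_input <- function(obs, map) {
  if (inherits(obs, "imputation_result")) {
    list(geno = obs$imputed, map = obs$map)
  } else if (inherits(obs, "observed_genotypes")) {
    list(geno = obs$geno, map = obs$map)
  } else if (inherits(obs, "origin_diplotypes")) {
    list(geno = geno_matrix(obs), map = obs$map)
  } else if (is.matrix(obs)) {
    if (is.null(map)) abort("`map` is required when `obs` is a bare matrix")
    list(geno = obs, map = map)
  } else {
    abort("unsupported input type for decoding")
  }
}

#' Reconstruct ancestral origins for every individual
#'
#' Decodes each individual chromosome-by-chromosome under the joint
#' founder-pair HMM: the Viterbi path gives the inferred haplotype map
#' (ties broken towards the lowest state index, reproducibly), and
#' forward-backward posteriors give per-marker parent certainty, defined as
#' the difference between the posterior probabilities of the two most likely
#' founders. The per-marker founder distribution pools the two homologues:
#' `q_l(f) = (P(hom0 = f) + P(hom1 = f)) / 2`.
#'
#' @param obs genotypes to decode: an `imputation_result`,
#'   `observed_genotypes`, `origin_diplotypes` or a markers x individuals
#'   dosage matrix.
#' @param founders the `founder_panel` used as ancestral haplotypes.
#' @param map genetic map (taken from `obs` when it carries one).
#' @param R switch intensity per Morgan per homologue.
#' @param error_rate assumed genotyping error rate of the emissions.
#' @param prior per-founder homologue prior (default uniform).
#' @return an `origin_decoding`: the `inferred` origin-labelled diplotypes,
#'   a markers x individuals `certainty` matrix, the `top_founder` matrix,
#'   a `logprob` tibble per individual and chromosome, and the state space.
#' @examples
#' map <- sim_genetic_map(n_markers = 60, seed = 1)
#' fnd <- sim_founders(map, 4, seed = 2)
#' pop <- sim_population(sim_pedigree(4, 5), fnd, map, seed = 3)
#' dec <- decode_origins(pop, fnd)
#' @export
decode_origins <- function(obs, founders, map = NULL, R = 1,
                           error_rate = 0.006, prior = NULL) {
  inp <- resolve_decode_input(obs, map)
  map <- inp$map
  g <- inp$geno
  validate_founders(founders)
  fa <- founder_alleles(founders)
  if (!all(map$marker %in% rownames(fa))) {
    abort("founder panel does not cover the markers being decoded")
  }
  fa <- fa[map$marker, , drop = FALSE]
  if (nrow(g) != nrow(map)) abort("genotypes do not match the map")
  ss <- origin_states(founders, prior)
  P <- length(ss$founder_ids)
  S <- P * P
  # joint prior in lexicographic state order: pi[s] = prior[i] * prior[j]
  prior_joint <- ss$prior[rep(seq_len(P), each = P)] *
    ss$prior[rep(seq_len(P), times = P)]
  stopifnot_scalar_prob(error_rate, "error_rate")

  N <- ncol(g)
  ids <- colnames(g)
  if (is.null(ids)) ids <- sprintf("I%04d", seq_len(N))
  L <- nrow(map)
  hom0 <- rep(seq_len(P), each = P)
  hom1 <- rep(seq_len(P), times = P)
  # founder-pooling matrix: q = A %*% gamma with A[f, s] counting homologues
  A <- matrix(0, P, S)
  A[cbind(hom0, seq_len(S))] <- A[cbind(hom0, seq_len(S))] + 0.5
  A[cbind(hom1, seq_len(S))] <- A[cbind(hom1, seq_len(S))] + 0.5

  o1 <- matrix(NA_integer_, L, N); o2 <- matrix(NA_integer_, L, N)
  certainty <- matrix(NA_real_, L, N)
  top_founder <- matrix(NA_integer_, L, N)
  lp <- list()
  for (idx in chrom_index(map)) {
    implied <- implied_genotypes(fa[idx, , drop = FALSE])
    cube <- joint_transition_cube(map$cM[idx], R, ss$prior)
    for (i in seq_len(N)) {
      dec <- decode_chrom(g[idx, i], implied, cube, prior_joint, error_rate)
      o1[idx, i] <- hom0[dec$path]
      o2[idx, i] <- hom1[dec$path]
      q <- A %*% dec$gamma
      top_idx <- max.col(t(q), ties.method = "first")
      top1 <- q[cbind(top_idx, seq_len(ncol(q)))]
      q[cbind(top_idx, seq_len(ncol(q)))] <- -1
      top2 <- do.call(pmax, asplit(q, 1))
      certainty[idx, i] <- top1 - top2
      top_founder[idx, i] <- top_idx
      lp[[length(lp) + 1L]] <- tibble::tibble(
        id = ids[i], chrom = map$chrom[idx[1]],
        logprob = dec$logprob, loglik = dec$loglik
      )
    }
  }
  inferred <- new_origin_diplotypes(
    map = map, founder_ids = ss$founder_ids, ids = ids,
    origin = list(o1, o2),
    allele = list(matrix(fa[cbind(rep(seq_len(L), N), as.vector(o1))], L, N),
                  matrix(fa[cbind(rep(seq_len(L), N), as.vector(o2))], L, N))
  )
  dimnames(certainty) <- list(map$marker, ids)
  dimnames(top_founder) <- list(map$marker, ids)
  structure(list(
    inferred = inferred, certainty = certainty,
    top_founder = top_founder, logprob = dplyr::bind_rows(lp),
    states = ss, map = map, R = R, error_rate = error_rate
  ), class = "origin_decoding")
}

#' @export
print.origin_decoding <- function(x, ...) {
  cat("<origin_decoding> ", length(x$inferred$ids), " individuals x ",
      nrow(x$map), " markers; ", length(x$states$founder_ids),
      " founders, R = ", x$R, ", error_rate = ", x$error_rate, "\n", sep = "")
  invisible(x)
}

#' Tidy an origin decoding into a per-marker posterior summary
#'
#' @param x an `origin_decoding`.
#' @param ... unused.
#' @return tibble (`id`, `chrom`, `marker`, `top_founder`, `certainty`).
#' @export
tidy.origin_decoding <- function(x, ...) {
  N <- ncol(x$certainty); L <- nrow(x$certainty)
  tibble::tibble(
    id = rep(colnames(x$certainty), each = L),
    chrom = rep(x$map$chrom, N),
    marker = rep(x$map$marker, N),
    top_founder = x$states$founder_ids[as.vector(x$top_founder)],
    certainty = as.vector(x$certainty)
  )
}

#' Per-individual decoding summary
#'
#' @param x an `origin_decoding`.
#' @param ... unused.
#' @return tibble (`id`, `logprob`, `loglik`, `mean_certainty`).
#' @export
glance.origin_decoding <- function(x, ...) {
  x$logprob %>%
    dplyr::group_by(.data$id) %>%
    dplyr::summarise(logprob = sum(.data$logprob),
                     loglik = sum(.data$loglik), .groups = "drop") %>%
    dplyr::left_join(
      tibble::tibble(id = colnames(x$certainty),
                     mean_certainty = colMeans(x$certainty)),
      by = "id"
    )
}

#' Convert a decoded state path into an origin-labelled diplotype
#'
#' Inferred origins are the path's two founder components per homologue;
#' inferred alleles are read from the founder panel at the labelled origin.
#'
#' @param path integer vector (length L) of joint state indices, or an
#'   L x N matrix for several individuals.
#' @param founders the `founder_panel`.
#' @param map the genetic map the path is ordered by.
#' @param ids individual ids (defaults to column names or `I0001`...).
#' @return an `origin_diplotypes` object.
#' @export
path_to_diplotype <- function(path, founders, map, ids = NULL) {
  fa <- founder_alleles(founders)[map$marker, , drop = FALSE]
  P <- ncol(fa)
  pm <- if (is.matrix(path)) path else matrix(path, ncol = 1)
  if (nrow(pm) != nrow(map)) abort("path length does not match the map")
  if (any(pm < 1 | pm > P * P)) abort("path contains invalid state indices")
  if (is.null(ids)) {
    ids <- colnames(pm)
    if (is.null(ids)) ids <- sprintf("I%04d", seq_len(ncol(pm)))
  }
  hom0 <- rep(seq_len(P), each = P)
  hom1 <- rep(seq_len(P), times = P)
  L <- nrow(map); N <- ncol(pm)
  o1 <- matrix(hom0[pm], L, N); o2 <- matrix(hom1[pm], L, N)
  new_origin_diplotypes(
    map = map, founder_ids = colnames(fa), ids = ids,
    origin = list(o1, o2),
    allele = list(matrix(fa[cbind(rep(seq_len(L), N), as.vector(o1))], L, N),
                  matrix(fa[cbind(rep(seq_len(L), N), as.vector(o2))], L, N))
  )
}
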