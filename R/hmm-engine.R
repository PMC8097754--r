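# Shared machinery for the two haplotype HMMs in the package. Both the
# imputer (states = ordered pairs of reference haplotypes) and the origin
# decoder (states = ordered pairs of founders) model the two homologues as
# independent Markov chains whose product forms the joint chain; they differ
# only in the switch intensity and prior.

# per-homologue transition matrix over H origins for one marker interval:
# P(stay) = exp(-rate d) + (1 - exp(-rate d)) * prior_same
# P(switch to j) = (1 - exp(-rate d)) * prior_j, with d in Morgans
homologue_transition <- function(d_morgans, rate, prior) {
  if (d_morgans < 0) abort("marker distances must be non-negative")
  H <- length(prior)
  e <- exp(-rate * d_morgans)
  m <- (1 - e) * matrix(prior, H, H, byrow = TRUE)
  diag(m) <- diag(m) + e
  m
}

# joint transition over ordered pairs; state s = (i-1)*H + j pairs homologue-0
# origin i with homologue-1 origin j, lexicographic by origin index
joint_transition <- function(d_morgans, rate, prior) {
  m <- homologue_transition(d_morgans, rate, prior)
  kronecker(m, m)
}

# S x S x (L-1) transition cube for one chromosome (cM positions `pos`)
joint_transition_cube <- function(pos, rate, prior) {
  H <- length(prior)
  S <- H * H
  d <- diff(pos) / 100
  cube <- array(0, c(S, S, max(length(d), 1L)))
  if (length(d) == 0) return(cube)
  # identical spacings share one matrix
  ud <- unique(d)
  mats <- lapply(ud, joint_transition, rate = rate, prior = prior)
  for (k in seq_along(d)) cube[, , k] <- mats[[match(d[k], ud)]]
  cube
}

# implied genotype (allele-1 dosage) of every joint state at every marker:
# L x S matrix from an L x H haplotype matrix
implied_genotypes <- function(hap) {
  H <- ncol(hap)
  i <- rep(seq_len(H), each = H)   # homologue 0
  j <- rep(seq_len(H), times = H)  # homologue 1
  hap[, i, drop = FALSE] + hap[, j, drop = FALSE]
}

# emission matrix S x L for one individual's genotype vector on one
# chromosome: P(obs | state) = 1 - eps if obs equals the state's implied
# genotype, eps/2 otherwise, and 1 when obs is missing
emission_matrix <- function(gvec, implied, eps) {
  E <- matrix(eps / 2, nrow(implied), ncol(implied))
  hit <- implied == gvec          # gvec recycles down columns (per marker row)
  hit[is.na(hit)] <- FALSE
  E[hit] <- 1 - eps
  E[is.na(gvec), ] <- 1
  t(E)
}

# decode one individual on one chromosome; returns any of viterbi path,
# posterior gamma and log-likelihood
decode_chrom <- function(gvec, implied, cube, prior_joint, eps,
                         viterbi = TRUE, posterior = TRUE) {
  out <- list()
  if (all(is.na(gvec))) {
    L <- length(gvec); S <- length(prior_joint)
    warn("chromosome with all markers missing; decoding falls back to the prior")
    if (viterbi) {
      out$path <- rep(which.max(prior_joint), L)
      out$logprob <- NA_real_
    }
    if (posterior) {
      out$gamma <- matrix(prior_joint, S, L)
      out$loglik <- 0
    }
    return(out)
  }
  E <- emission_matrix(gvec, implied, eps)
  if (viterbi) {
    v <- hmm_viterbi_cpp(log(E), log(cube), log(prior_joint))
    out$path <- v$path
    out$logprob <- v$logprob
  }
  if (posterior) {
    fb <- hmm_forward_backward_cpp(E, cube, prior_joint)
    out$gamma <- fb$gamma
    out$loglik <- fb$loglik
  }
  out
}
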