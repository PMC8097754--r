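# Exhaustive-enumeration oracle for the joint-origin HMM, independent of the
# package's decoding path: scores every state path explicitly.
#
# E  : S x L emission probabilities
# Tl : list of L-1 transition matrices (S x S)
# pi : length-S prior
# Returns the max log-probability, the set of optimal paths, the path-sum
# posterior matrix (S x L) and the total log-likelihood.
bf_decode <- function(E, Tl, pi, tol = 1e-9) {
  S <- nrow(E); L <- ncol(E)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), L)))
  logp <- log(pi[paths[, 1]]) + log(E[cbind(paths[, 1], 1)])
  if (L > 1) {
    for (l in 2:L) {
      logp <- logp + log(Tl[[l - 1]][cbind(paths[, l - 1], paths[, l])]) +
        log(E[cbind(paths[, l], l)])
    }
  }
  mx <- max(logp)
  w <- exp(logp - mx)
  total <- sum(w)
  gamma <- vapply(seq_len(L), function(l) {
    g <- rowsum(w, factor(paths[, l], levels = seq_len(S)))[, 1]
    g / total
  }, numeric(S))
  list(
    logprob = mx,
    optimal_paths = paths[logp >= mx - tol, , drop = FALSE],
    gamma = gamma,
    loglik = log(total) + mx
  )
}

# Build emissions/transitions for a random joint-origin instance the same
# way the spec defines them (closed forms, not package internals beyond the
# documented formulas), for cross-checking the decoder.
bf_origin_instance <- function(P, L, R, eps, geno, d_cM, hap) {
  S <- P * P
  hom0 <- rep(seq_len(P), each = P)
  hom1 <- rep(seq_len(P), times = P)
  implied <- hap[, hom0, drop = FALSE] + hap[, hom1, drop = FALSE]
  E <- matrix(NA_real_, S, L)
  for (l in seq_len(L)) {
    E[, l] <- if (is.na(geno[l])) rep(1, S) else
      ifelse(implied[l, ] == geno[l], 1 - eps, eps / 2)
  }
  Tl <- lapply(d_cM, function(d) {
    e <- exp(-R * d / 100)
    m <- (1 - e) * matrix(1 / P, P, P)
    diag(m) <- diag(m) + e
    kronecker(m, m)
  })
  list(E = E, Tl = Tl, pi = rep(1 / S, S),
       hom0 = hom0, hom1 = hom1, implied = implied)
}

# random small decoding instance: returns inputs for both the oracle and
# decode_origins()
random_small_instance <- function(P = NULL, L = NULL) {
  if (is.null(P)) P <- sample(2:3, 1)
  if (is.null(L)) L <- sample(2:6, 1)
  d_cM <- runif(L - 1, 0.5, 40)
  map <- tibble::tibble(
    chrom = "chr1",
    marker = sprintf("m%02d", seq_len(L)),
    cM = cumsum(c(0, d_cM)),
    bp = as.integer(round(cumsum(c(0, d_cM)) * 1e6)) + seq_len(L)
  )
  hap <- matrix(rbinom(L * P, 1, 0.5), L, P,
                dimnames = list(map$marker, paste0("F", seq_len(P))))
  geno <- sample(c(0:2, NA), L, replace = TRUE,
                 prob = c(0.3, 0.3, 0.3, 0.1))
  R <- runif(1, 0.3, 3)
  eps <- runif(1, 0.01, 0.3)
  founders <- haplomosaic:::new_founder_panel(
    dplyr::bind_cols(tibble::tibble(marker = map$marker),
                     tibble::as_tibble(hap))
  )
  list(P = P, L = L, map = map, hap = hap, geno = geno, R = R, eps = eps,
       d_cM = d_cM, founders = founders)
}
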