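test_that("the state space enumerates ordered founder pairs lexicographically", {
  ss <- origin_states(c("A", "B", "C"))
  expect_equal(nrow(ss$states), 9)
  # state s = (i - 1) * P + j pairs founder i (hom0) with founder j (hom1)
  expect_equal(ss$states$hom0, rep(c("A", "B", "C"), each = 3))
  expect_equal(ss$states$hom1, rep(c("A", "B", "C"), times = 3))
  expect_equal(ss$prior, rep(1 / 3, 3))
  expect_error(origin_states("A"), ">= 2 founders")
  expect_error(origin_states(c("A", "B"), prior = c(0.7, 0.7)), "probability")
})

test_that("transition matrices match the closed form and its limits", {
  prior <- rep(1 / 2, 2)
  # d = 0: identity (no distance, no switch)
  expect_equal(origin_transition(0, 1, prior), diag(4), ignore_attr = TRUE)

  # d -> infinity: rows converge to the joint prior
  Tinf <- origin_transition(1e7, 1, prior)
  expect_equal(unclass(Tinf), matrix(1 / 4, 4, 4), ignore_attr = TRUE,
               tolerance = 1e-12)

  # closed form at P = 2, R = 1, d = 50 cM:
  # per-homologue stay = e^{-0.5} + (1 - e^{-0.5}) / 2
  m <- attr(origin_transition(50, 1, prior), "homologue")
  stay <- exp(-0.5) + (1 - exp(-0.5)) / 2
  expect_equal(diag(m), rep(stay, 2), tolerance = 1e-12)
  expect_equal(m[1, 2], (1 - exp(-0.5)) / 2, tolerance = 1e-12)

  # joint = kronecker of the homologue processes; rows sum to 1
  Tj <- origin_transition(17, 2.5, c(0.2, 0.3, 0.5))
  expect_equal(unclass(Tj),
               kronecker(attr(Tj, "homologue"), attr(Tj, "homologue")),
               ignore_attr = TRUE)
  expect_equal(rowSums(Tj), rep(1, 9), tolerance = 1e-12)
  expect_error(origin_transition(10, 0, prior), "positive")
  expect_error(origin_transition(-1, 1, prior), "non-negative")
})

test_that("emissions are error-tolerant and missing data is uninformative", {
  implied <- c(0, 1, 1, 2)
  expect_equal(origin_emission(1, implied, 0.006),
               c(0.003, 0.994, 0.994, 0.003))
  expect_equal(origin_emission(NA, implied, 0.006), rep(1, 4))
  # zero assumed error: hard match/mismatch
  expect_equal(origin_emission(2, implied, 0), c(0, 0, 0, 1))
  expect_error(origin_emission(1, implied, 1), "probability")
})

test_that("decoding matches the exhaustive enumeration oracle on random instances", {
  set.seed(101)
  for (rep in 1:25) {
    inst <- random_small_instance()
    g <- matrix(inst$geno, ncol = 1, dimnames = list(inst$map$marker, "I1"))
    if (all(is.na(inst$geno))) next
    dec <- decode_origins(g, inst$founders, map = inst$map, R = inst$R,
                          error_rate = inst$eps)
    bf <- bf_decode(bf_origin_instance(inst$P, inst$L, inst$R, inst$eps,
                                       inst$geno, inst$d_cM, inst$hap)$E,
                    bf_origin_instance(inst$P, inst$L, inst$R, inst$eps,
                                       inst$geno, inst$d_cM, inst$hap)$Tl,
                    rep(1 / inst$P^2, inst$P^2))
    # Viterbi log-probability equals the enumerated maximum
    expect_equal(dec$logprob$logprob, bf$logprob, tolerance = 1e-9)
    # forward-backward log-likelihood equals the enumerated path sum
    expect_equal(dec$logprob$loglik, bf$loglik, tolerance = 1e-9)
    # the decoded path is one of the enumeration's optimal paths
    P <- inst$P
    path <- (match(dec$inferred$origin[[1]][, 1], seq_len(P)) - 1L) * P +
      match(dec$inferred$origin[[2]][, 1], seq_len(P))
    hits <- apply(bf$optimal_paths, 1, function(p) all(p == path))
    expect_true(any(hits))
  }
})

test_that("certainty is top1 minus top2 of the pooled founder posterior", {
  set.seed(102)
  inst <- random_small_instance(P = 3, L = 4)
  g <- matrix(inst$geno, ncol = 1, dimnames = list(inst$map$marker, "I1"))
  dec <- decode_origins(g, inst$founders, map = inst$map, R = inst$R,
                        error_rate = inst$eps)
  bf <- bf_decode(bf_origin_instance(3, 4, inst$R, inst$eps, inst$geno,
                                     inst$d_cM, inst$hap)$E,
                  bf_origin_instance(3, 4, inst$R, inst$eps, inst$geno,
                                     inst$d_cM, inst$hap)$Tl,
                  rep(1 / 9, 9))
  hom0 <- rep(1:3, each = 3); hom1 <- rep(1:3, times = 3)
  for (l in 1:4) {
    q <- vapply(1:3, function(f) {
      sum(bf$gamma[hom0 == f, l]) / 2 + sum(bf$gamma[hom1 == f, l]) / 2
    }, numeric(1))
    srt <- sort(q, decreasing = TRUE)
    expect_equal(dec$certainty[l, 1], srt[1] - srt[2], tolerance = 1e-9)
    expect_equal(dec$top_founder[l, 1], which.max(q))
  }
  # certainty is a probability gap
  expect_true(all(dec$certainty >= -1e-12 & dec$certainty <= 1 + 1e-12))
})

test_that("exact ties break deterministically towards the lowest state index", {
  # two founders with identical haplotypes make every state equally likely;
  # the decoder must return state 1 (founder 1 on both homologues)
  map <- tiny_map(5, length_cM = 40)
  hap <- matrix(0L, 5, 2, dimnames = list(map$marker, c("F1", "F2")))
  fnd <- panel_from_matrix(map, hap)
  g <- matrix(0L, 5, 1, dimnames = list(map$marker, "I1"))
  dec <- decode_origins(g, fnd, map = map, R = 1, error_rate = 0.01)
  expect_true(all(dec$inferred$origin[[1]] == 1L))
  expect_true(all(dec$inferred$origin[[2]] == 1L))
  # and twice in a row gives the identical object
  expect_identical(dec$inferred,
                   decode_origins(g, fnd, map = map, R = 1,
                                  error_rate = 0.01)$inferred)
})

test_that("path_to_diplotype reads alleles off the labelled founder", {
  map <- tiny_map(4)
  hap <- cbind(F1 = c(0L, 1L, 0L, 1L), F2 = c(1L, 1L, 0L, 0L))
  rownames(hap) <- map$marker
  fnd <- panel_from_matrix(map, hap)
  # states at P = 2: 1=(1,1), 2=(1,2), 3=(2,1), 4=(2,2)
  d <- path_to_diplotype(c(1L, 2L, 4L, 3L), fnd, map, ids = "X")
  expect_equal(as.vector(d$origin[[1]]), c(1L, 1L, 2L, 2L))
  expect_equal(as.vector(d$origin[[2]]), c(1L, 2L, 2L, 1L))
  expect_equal(as.vector(d$allele[[1]]), c(0L, 1L, 0L, 0L))
  expect_equal(as.vector(d$allele[[2]]), c(0L, 1L, 0L, 1L))
  expect_error(path_to_diplotype(c(1L, 5L, 1L, 1L), fnd, map), "invalid")
  expect_error(path_to_diplotype(c(1L, 1L), fnd, map), "does not match")
})

test_that("decoding is invariant to which homologue carries which origin", {
  # unphased genotypes cannot distinguish (i, j) from (j, i): the swapped
  # Viterbi path has the same log-probability and certainty is unchanged
  sc <- small_scene(P = 3, n = 4, L = 40, n_chrom = 1)
  g <- geno_matrix(sc$pop)
  dec <- decode_origins(g, sc$founders, map = sc$map, R = 1,
                        error_rate = 0.006)
  P <- 3
  for (i in seq_len(ncol(g))) {
    path <- (dec$inferred$origin[[1]][, i] - 1L) * P +
      dec$inferred$origin[[2]][, i]
    swapped <- (dec$inferred$origin[[2]][, i] - 1L) * P +
      dec$inferred$origin[[1]][, i]
    inst <- bf_origin_instance(P, nrow(g), 1, 0.006, g[, i],
                               diff(sc$map$cM), founder_alleles(sc$founders))
    logp <- function(p) {
      lp <- log(inst$pi[p[1]]) + log(inst$E[p[1], 1])
      for (l in 2:length(p)) {
        lp <- lp + log(inst$Tl[[l - 1]][p[l - 1], p[l]]) +
          log(inst$E[p[l], l])
      }
      lp
    }
    expect_equal(logp(swapped), logp(path), tolerance = 1e-9)
  }
})

test_that("decoding a clean dense population recovers the simulated origins", {
  sc <- small_scene(P = 4, n = 15, L = 120, n_chrom = 1, seed = 7)
  dec <- decode_origins(sc$pop, sc$founders, R = 1, error_rate = 0.006)
  m <- evaluate_reconstruction(sc$pop, dec)
  expect_gt(mean(m$per_individual$aaa), 95)
  # pooled parent certainty is high where both homologues share one origin
  # and collapses towards 0 at heterozygous-origin sites (two founders tie
  # at 0.5 each, by the definition of the pooled distribution)
  hom_same <- dec$inferred$origin[[1]] == dec$inferred$origin[[2]]
  expect_gt(mean(dec$certainty[hom_same]), 0.7)
  expect_lt(mean(dec$certainty[!hom_same]), 0.3)
})

test_that("an all-missing chromosome falls back to the prior with a warning", {
  map <- sim_genetic_map(n_chrom = 2, n_markers = 8, length_cM = 50, seed = 9)
  fnd <- sim_founders(map, 2, seed = 10)
  g <- matrix(NA_integer_, 16, 1, dimnames = list(map$marker, "I1"))
  g[9:16, 1] <- 1L
  expect_warning(dec <- decode_origins(g, fnd, map = map),
                 "all markers missing")
  # prior fallback: lowest state, zero certainty on the missing chromosome
  expect_true(all(dec$inferred$origin[[1]][1:8, 1] == 1L))
  expect_equal(unname(dec$certainty[1:8, 1]), rep(0, 8), tolerance = 1e-12)
})

test_that("tidy and glance expose the documented decoding summaries", {
  sc <- small_scene(P = 3, n = 3, L = 20, n_chrom = 2)
  dec <- decode_origins(sc$pop, sc$founders)
  td <- tidy(dec)
  expect_equal(names(td), c("id", "chrom", "marker", "top_founder",
                            "certainty"))
  expect_equal(nrow(td), nrow(sc$map) * 3)
  expect_true(all(td$top_founder %in% founder_ids(sc$founders)))
  gl <- glance(dec)
  expect_equal(gl$id, sc$pop$ids)
  # Viterbi path probability can never exceed the total likelihood
  expect_true(all(gl$logprob <= gl$loglik + 1e-9))
  expect_true(all(gl$mean_certainty >= 0 & gl$mean_certainty <= 1))
})
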