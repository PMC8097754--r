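# Golden values in this file are computed by hand from the metric
# definitions; the constructions are small enough to verify on paper.

test_that("AAA matches a hand-scored four-marker example (87.5%)", {
  map <- tiny_map(4)
  hap <- cbind(F1 = c(0L, 0L, 1L, 1L), F2 = c(1L, 1L, 0L, 0L))
  rownames(hap) <- map$marker
  fnd <- panel_from_matrix(map, hap)
  known <- make_diplotypes(map, fnd, matrix(c(1L, 1L, 1L, 1L)),
                           matrix(c(2L, 2L, 2L, 2L)))
  # marker scores: (1,2)vs(1,2)=2; (1,2)vs(2,1)=2 swapped;
  # (1,2)vs(1,1)=1; (1,2)vs(1,2)=2  ->  7/8 = 87.5%
  inf <- make_diplotypes(map, fnd, matrix(c(1L, 2L, 1L, 1L)),
                         matrix(c(2L, 1L, 1L, 2L)))
  expect_equal(calc_aaa(known, inf)$aaa, 87.5)
})

test_that("identity scores 100 on AAA/GAA and correlation 1 on CCC", {
  sc <- small_scene(P = 4, n = 10, L = 60, n_chrom = 2, seed = 5)
  m <- evaluate_reconstruction(sc$pop, sc$pop, sc$founders)
  expect_equal(m$per_individual$aaa, rep(100, 10))
  expect_equal(m$per_individual$gaa, rep(100, 10))
  # self-phase is trivially concordant wherever it is evaluated
  expect_true(all(m$per_individual$paa == 100 |
                    is.na(m$per_individual$paa)))
  expect_equal(m$ccc$ccc, 1)
  expect_equal(m$per_marker$aaa, rep(100, nrow(sc$map)))
})

test_that("GAA exceeds AAA exactly under planted identity-by-state (95 vs 100)", {
  map <- tiny_map(20)
  hap <- cbind(F1 = rep(0L, 20), F2 = rep(1L, 20), F3 = rep(1L, 20))
  hap[1:18, 3] <- 1L - hap[1:18, 2]     # F3 differs except markers 19-20
  rownames(hap) <- map$marker
  fnd <- panel_from_matrix(map, hap)
  known <- make_diplotypes(map, fnd, matrix(rep(1L, 20)),
                           matrix(rep(2L, 20)))
  # inferred swaps F2 -> F3 at the two IBS markers only
  i_h1 <- c(rep(2L, 18), 3L, 3L)
  inf <- make_diplotypes(map, fnd, matrix(rep(1L, 20)), matrix(i_h1))
  # AAA: 18 markers score 2, 2 markers score 1 -> 38/40 = 95%
  expect_equal(calc_aaa(known, inf)$aaa, 95)
  # GAA: F3 is IBS with F2 there, so every genotype still matches
  expect_equal(calc_gaa(known, inf, fnd)$gaa, 100)
  expect_equal(calc_gaa(known, inf)$gaa, 100)
})

test_that("PAA matches a hand-scored phase-switch example (2/3)", {
  map <- tiny_map(4)
  hap <- cbind(F1 = rep(0L, 4), F2 = rep(1L, 4))
  rownames(hap) <- map$marker
  fnd <- panel_from_matrix(map, hap)
  known <- make_diplotypes(map, fnd, matrix(rep(1L, 4)), matrix(rep(2L, 4)))
  # all four sites are true hets with matching inferred genotype; the
  # inferred arrangement flips homologues half-way: match indicators
  # (T,T,F,F) -> consecutive concordance (T,F,T) = 2/3
  inf <- make_diplotypes(map, fnd, matrix(c(1L, 1L, 2L, 2L)),
                         matrix(c(2L, 2L, 1L, 1L)))
  out <- calc_paa(known, inf)
  expect_equal(out$paa, 100 * 2 / 3)
  expect_equal(out$n_pairs, 3L)
})

test_that("PAA is NA with no heterozygous evaluation sites", {
  map <- tiny_map(6)
  hap <- cbind(F1 = rep(0L, 6), F2 = rep(1L, 6))
  rownames(hap) <- map$marker
  fnd <- panel_from_matrix(map, hap)
  hom <- make_diplotypes(map, fnd, matrix(rep(1L, 6)), matrix(rep(1L, 6)))
  out <- calc_paa(hom, hom)
  expect_true(is.na(out$paa))
  expect_equal(out$n_pairs, 0L)
})

test_that("CCC matches the hand-computed Pearson correlation", {
  x <- c(5, 7, 9, 11, 13)
  y <- c(4, 7, 8, 12, 12)
  out <- calc_ccc(x, y)
  # Sxy = 42, Sxx = 40, Syy = 47.2  ->  r = 42 / sqrt(1888)
  expect_equal(out$ccc, 42 / sqrt(1888), tolerance = 1e-12)
  expect_equal(out$p_value, cor.test(x, y)$p.value)
  expect_equal(out$mean_known, 9)
  expect_equal(out$mean_inferred, 8.6)
  # correlation is shift-invariant but the reported means expose bias
  shifted <- calc_ccc(x, y + 3)
  expect_equal(shifted$ccc, out$ccc)
  expect_equal(shifted$mean_inferred, 11.6)
  # id-keyed tibbles are aligned before correlating
  ka <- tibble::tibble(id = c("a", "b", "c", "d", "e"), crossovers = x)
  kb <- tibble::tibble(id = rev(ka$id), crossovers = rev(y))
  expect_equal(calc_ccc(ka, kb)$ccc, out$ccc)
})

test_that("CCC warns and returns NA when a count vector is constant", {
  expect_warning(out <- calc_ccc(c(2, 2, 2, 2), c(1, 3, 2, 4)),
                 "zero variance")
  expect_true(is.na(out$ccc))
  expect_error(calc_ccc(1:5, 1:4), "paired")
  expect_error(calc_ccc(1:2, 2:3), ">= 3")
})

test_that("percentage metrics are invariant to swapping the inferred homologues", {
  sc <- small_scene(P = 4, n = 8, L = 50, n_chrom = 2, seed = 11)
  dec <- decode_origins(sc$pop, sc$founders)
  inf <- dec$inferred
  swapped <- inf
  swapped$origin <- rev(inf$origin)
  swapped$allele <- rev(inf$allele)
  expect_equal(calc_aaa(sc$pop, swapped), calc_aaa(sc$pop, inf))
  expect_equal(calc_gaa(sc$pop, swapped, sc$founders),
               calc_gaa(sc$pop, inf, sc$founders))
  expect_equal(calc_paa(sc$pop, swapped), calc_paa(sc$pop, inf))
})

test_that("per-individual GAA is bounded below by the full-pair AAA fraction", {
  sc <- small_scene(P = 4, n = 12, L = 60, n_chrom = 2, seed = 13)
  dec <- decode_origins(sc$pop, sc$founders)
  gaa <- calc_gaa(sc$pop, dec$inferred, sc$founders)$gaa
  score <- haplomosaic:::origin_match_score(sc$pop, dec$inferred)
  both_right <- 100 * colMeans(score == 2)
  expect_true(all(gaa >= both_right - 1e-9))
})

test_that("the regional profile localizes a planted IBS dip", {
  map <- tiny_map(30, length_cM = 120)
  set.seed(17)
  hap <- cbind(F1 = rep(0L, 30), F2 = rbinom(30, 1, 0.5),
               F3 = rbinom(30, 1, 0.5))
  rownames(hap) <- map$marker
  fnd <- panel_from_matrix(map, hap)
  known <- make_diplotypes(map, fnd,
                           matrix(rep(1L, 60), 30),
                           matrix(rep(2L, 60), 30), ids = c("a", "b"))
  # inferred mislabels homologue 1 as F3 only inside markers 11-20
  i_h1 <- matrix(rep(2L, 60), 30)
  i_h1[11:20, ] <- 3L
  inf <- make_diplotypes(map, fnd, matrix(rep(1L, 60), 30), i_h1,
                         ids = c("a", "b"))
  prof <- marker_profile(known, inf)
  expect_equal(names(prof), c("chrom", "marker", "cM", "aaa",
                              "mean_certainty"))
  expect_equal(prof$aaa[-(11:20)], rep(100, 20))
  expect_equal(prof$aaa[11:20], rep(50, 10))
  expect_true(all(is.na(prof$mean_certainty)))
})

test_that("evaluation objects expose tidy, glance and plots", {
  sc <- small_scene(P = 4, n = 10, L = 60, n_chrom = 2, seed = 19)
  dec <- decode_origins(sc$pop, sc$founders)
  m <- evaluate_reconstruction(sc$pop, dec, sc$founders)
  expect_s3_class(tidy(m), "tbl_df")
  expect_equal(nrow(tidy(m)), 10)
  gl <- glance(m)
  expect_equal(gl$n, 10)
  expect_true(gl$mean_gaa >= gl$mean_aaa - 1e-9)
  expect_true(gl$min_marker_aaa <= gl$mean_aaa + 1e-9)
  # the decoding feeds certainty into the profile
  expect_false(anyNA(m$per_marker$mean_certainty))
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(plot_metric_distributions(m), "ggplot")
  expect_output(print(m), "mean AAA")
})

test_that("metric functions reject mismatched inputs", {
  sc <- small_scene(P = 3, n = 4, L = 20, n_chrom = 1, seed = 23)
  sub <- subset_markers(sc$pop, sc$map$marker[1:10])
  expect_error(calc_aaa(sc$pop, sub), "different marker sets")
  other <- sc$pop
  other$ids <- paste0("x", other$ids)
  expect_error(calc_aaa(sc$pop, other), "different individuals")
})
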