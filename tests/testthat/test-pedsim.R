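test_that("a 0 cM chromosome never recombines and a 100 cM chromosome is Poisson(1)", {
  # zero-length chromosome: gamete equals a single whole parental homologue
  map0 <- tibble::tibble(chrom = "chr1", marker = c("a", "b"),
                         cM = c(0, 0), bp = c(1L, 2L))
  parent <- list(origin = cbind(c(1L, 1L), c(2L, 2L)),
                 allele = cbind(c(0L, 0L), c(1L, 1L)))
  set.seed(1)
  for (i in 1:20) {
    g <- sim_gamete(parent, map0)
    expect_true(all(g$origin == g$origin[1]))
    expect_equal(nrow(g$breakpoints), 0)
  }

  # Monte-Carlo moments of the crossover count on a 100 cM chromosome
  map <- tiny_map(2, length_cM = 100)
  set.seed(2)
  counts <- replicate(1e4, nrow(sim_gamete(parent, map)$breakpoints))
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / 1e4))      # SE of the mean
  expect_lt(abs(var(counts) - 1), 3 * sqrt(3 / 1e4))       # Var(Pois)=mean
})

test_that("gamete origin is constant when the parent is origin-homozygous", {
  map <- tiny_map(30)
  parent <- list(origin = cbind(rep(3L, 30), rep(3L, 30)),
                 allele = cbind(rbinom(30, 1, 0.5), rbinom(30, 1, 0.5)))
  set.seed(3)
  for (i in 1:10) {
    expect_true(all(sim_gamete(parent, map)$origin == 3L))
  }
})

test_that("gamete simulation rejects a map/diplotype length mismatch", {
  map <- tiny_map(10)
  parent <- list(origin = matrix(1L, 5, 2), allele = matrix(0L, 5, 2))
  expect_error(sim_gamete(parent, map), "does not match")
})

test_that("biparental F1s have origin pair {A,B} everywhere and hets exactly at parent differences", {
  map <- tiny_map(50)
  fnd <- sim_founders(map, 2, maf = c(0.3, 0.7), seed = 4)
  pop <- sim_population(sim_pedigree(2, 15, "biparental_f1"), fnd, map,
                        seed = 5)
  o <- cbind(as.vector(pop$origin[[1]]), as.vector(pop$origin[[2]]))
  expect_true(all(o[, 1] != o[, 2]))
  expect_setequal(unique(as.vector(o)), 1:2)
  a <- founder_alleles(fnd)
  het_expected <- a[, 1] != a[, 2]
  g <- geno_matrix(pop)
  for (i in seq_along(pop$ids)) {
    expect_equal(g[, i] == 1L, het_expected, ignore_attr = TRUE)
  }
})

test_that("simulated alleles always equal the founder allele at the labelled origin", {
  sc <- small_scene()
  fa <- founder_alleles(sc$founders)
  for (h in 1:2) {
    expected <- matrix(
      fa[cbind(rep(seq_len(nrow(sc$map)), length(sc$pop$ids)),
               as.vector(sc$pop$origin[[h]]))],
      nrow(sc$map))
    expect_equal(sc$pop$allele[[h]], expected, ignore_attr = TRUE)
  }
})

test_that("per-gamete crossover counts fit the Poisson model (chi-square GOF)", {
  map <- tiny_map(2, length_cM = 100)
  parent <- list(origin = cbind(rep(1L, 2), rep(2L, 2)),
                 allele = cbind(c(0L, 0L), c(1L, 1L)))
  set.seed(6)
  counts <- replicate(1e4, nrow(sim_gamete(parent, map)$breakpoints))
  kmax <- 5
  obs <- tabulate(pmin(counts, kmax) + 1L, nbins = kmax + 1L)
  p <- c(dpois(0:(kmax - 1), 1), 1 - ppois(kmax - 1, 1))
  gof <- chisq.test(obs, p = p)
  expect_gt(gof$p.value, 0.001)
})

test_that("crossover counting matches hand-enumerated origin changes", {
  map <- tiny_map(10)
  fnd <- panel_from_matrix(map, matrix(rbinom(30, 1, 0.5), 10, 3))
  # constant origins: zero crossovers
  d0 <- make_diplotypes(map, fnd, matrix(1L, 10), matrix(2L, 10))
  expect_equal(count_crossovers(d0)$crossovers, 0L)
  # single change on one homologue
  d1 <- make_diplotypes(map, fnd, matrix(c(rep(1L, 4), rep(3L, 6))),
                        matrix(2L, 10))
  expect_equal(count_crossovers(d1)$crossovers, 1L)
  # five changes at chosen adjacent positions across both homologues
  h0 <- c(1L, 2L, 2L, 3L, 3L, 3L, 1L, 1L, 1L, 1L)   # changes at 1-2, 3-4, 6-7
  h1 <- c(2L, 2L, 2L, 2L, 1L, 1L, 1L, 1L, 3L, 3L)   # changes at 4-5, 8-9
  d5 <- make_diplotypes(map, fnd, matrix(h0), matrix(h1))
  expect_equal(count_crossovers(d5)$crossovers, 5L)
})

test_that("crossovers are never counted across chromosome boundaries", {
  map <- sim_genetic_map(n_chrom = 2, n_markers = 5, length_cM = 50, seed = 7)
  fnd <- panel_from_matrix(map, matrix(rbinom(20, 1, 0.5), 10, 2))
  # origin switches between chr1 (all founder 1) and chr2 (all founder 2)
  d <- make_diplotypes(map, fnd, matrix(rep(c(1L, 2L), each = 5)),
                       matrix(rep(c(2L, 1L), each = 5)))
  expect_equal(count_crossovers(d)$crossovers, 0L)
})

test_that("marker thinning commutes with simulation truth", {
  sc <- small_scene()
  thinned_map <- thin_map(sc$map, 2)
  sub <- subset_markers(sc$pop, thinned_map$marker)
  expect_equal(sub$map$marker, thinned_map$marker)
  keep <- sc$map$marker %in% thinned_map$marker
  for (h in 1:2) {
    expect_equal(sub$origin[[h]], sc$pop$origin[[h]][keep, , drop = FALSE])
    expect_equal(sub$allele[[h]], sc$pop$allele[[h]][keep, , drop = FALSE])
  }
})

test_that("population simulation is deterministic given a seed and validates pedigree coverage", {
  sc <- small_scene()
  again <- sim_population(sc$ped, sc$founders, sc$map, seed = 44)
  expect_identical(again, sim_population(sc$ped, sc$founders, sc$map,
                                         seed = 44))
  bad_ped <- dplyr::bind_rows(sc$ped,
    tibble::tibble(id = "F9", mother = NA_character_,
                   father = NA_character_, generation = 0L))
  expect_error(sim_population(bad_ped, sc$founders, sc$map, seed = 1),
               "absent from the founder panel")
})

test_that("outcross crossover accumulation matches the latent breakpoint record", {
  map <- sim_genetic_map(n_chrom = 3, n_markers = 200, length_cM = 150,
                         seed = 8)
  fnd <- sim_founders(map, 4, seed = 9)
  pop <- sim_population(sim_pedigree(4, 100), fnd, map, seed = 10)
  counted <- count_crossovers(pop)
  # marker-resolution counts can only miss breakpoints (even numbers between
  # adjacent markers or switches between same-origin segments), never add
  latent_tb <- dplyr::count(
    dplyr::filter(pop$breakpoints, id %in% pop$ids), id, name = "latent")
  joined <- dplyr::left_join(counted, latent_tb, by = "id")
  joined$latent[is.na(joined$latent)] <- 0L
  expect_true(all(joined$crossovers <= joined$latent))
  # on a dense map most breakpoints are visible at marker resolution
  expect_gt(sum(joined$crossovers), 0.5 * sum(joined$latent))
})
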