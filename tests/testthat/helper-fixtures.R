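# Small in-code fixtures shared across test files.

tiny_map <- function(L = 10, n_chrom = 1, length_cM = 100, spacing = "even") {
  sim_genetic_map(n_chrom = n_chrom, n_markers = L, length_cM = length_cM,
                  spacing = spacing, seed = 99)
}

# build an origin_diplotypes object by hand from explicit origin matrices
# (L x N per homologue, founder indices); alleles read from the panel
make_diplotypes <- function(map, founders, origin_h0, origin_h1,
                            ids = NULL) {
  fa <- founder_alleles(founders)[map$marker, , drop = FALSE]
  o1 <- as.matrix(origin_h0); o2 <- as.matrix(origin_h1)
  L <- nrow(map); N <- ncol(o1)
  if (is.null(ids)) ids <- sprintf("X%03d", seq_len(N))
  haplomosaic:::new_origin_diplotypes(
    map = map, founder_ids = founder_ids(founders), ids = ids,
    origin = list(o1, o2),
    allele = list(
      matrix(fa[cbind(rep(seq_len(L), N), as.vector(o1))], L, N),
      matrix(fa[cbind(rep(seq_len(L), N), as.vector(o2))], L, N)
    )
  )
}

# founder panel with explicitly given haplotype matrix (L x P)
panel_from_matrix <- function(map, hap) {
  colnames(hap) <- paste0("F", seq_len(ncol(hap)))
  haplomosaic:::new_founder_panel(
    dplyr::bind_cols(tibble::tibble(marker = map$marker),
                     tibble::as_tibble(hap))
  )
}

# a small standard simulated scene used by several test files
small_scene <- function(P = 4, n = 12, L = 60, n_chrom = 2, seed = 42) {
  map <- sim_genetic_map(n_chrom = n_chrom, n_markers = L,
                         length_cM = 100, seed = seed)
  founders <- sim_founders(map, P, seed = seed + 1)
  ped <- sim_pedigree(P, n)
  pop <- sim_population(ped, founders, map, seed = seed + 2)
  list(map = map, founders = founders, ped = ped, pop = pop)
}
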