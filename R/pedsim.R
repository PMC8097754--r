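# Meiosis down the pedigree: known-truth, origin-labelled diplotypes.
#
# Crossovers follow the Haldane model: per chromosome the count is
# Poisson(length in Morgans) and breakpoint positions are uniform on the cM
# interval, with no interference and no obligate chiasma. This matches the
# Markov assumptions of the decoding model, keeping simulator and decoder
# coherent.

new_origin_diplotypes <- function(map, founder_ids, ids, origin, allele,
                                  breakpoints = NULL) {
  structure(
    list(map = map, founder_ids = founder_ids, ids = ids,
         origin = origin, allele = allele, breakpoints = breakpoints),
    class = "origin_diplotypes"
  )
}

#' @export
print.origin_diplotypes <- function(x, ...) {
  cat("<origin_diplotypes> ", length(x$ids), " individuals x ",
      nrow(x$map), " markers (", length(unique(x$map$chrom)),
      " chromosomes), ", length(x$founder_ids), " founders\n", sep = "")
  invisible(x)
}

#' Tidy an origin-labelled diplotype set into a long tibble
#'
#' @param x an `origin_diplotypes` object.
#' @param ... unused.
#' @return a tibble with one row per individual x marker x homologue:
#'   `id`, `chrom`, `marker`, `cM`, `homologue` (0/1), `origin` (founder id),
#'   `allele` (0/1).
#' @export
tidy.origin_diplotypes <- function(x, ...) {
  L <- nrow(x$map); N <- length(x$ids)
  purrr::map_dfr(1:2, function(h) {
    tibble::tibble(
      id = rep(x$ids, each = L),
      chrom = rep(x$map$chrom, N),
      marker = rep(x$map$marker, N),
      cM = rep(x$map$cM, N),
      homologue = h - 1L,
      origin = x$founder_ids[as.vector(x$origin[[h]])],
      allele = as.vector(x$allele[[h]])
    )
  }) %>% dplyr::arrange(.data$id)
}

#' Unphased genotype matrix of a diplotype set
#'
#' @param pop an `origin_diplotypes` object.
#' @return integer matrix, markers x individuals, of allele-1 dosages (0/1/2).
#' @export
geno_matrix <- function(pop) {
  g <- pop$allele[[1]] + pop$allele[[2]]
  dimnames(g) <- list(pop$map$marker, pop$ids)
  g
}

#' Extract one individual's diplotype
#'
#' @param pop an `origin_diplotypes` object.
#' @param id individual id.
#' @return a list with `origin` and `allele`, each an L x 2 matrix (one
#'   column per homologue).
#' @export
get_diplotype <- function(pop, id) {
  j <- match(id, pop$ids)
  if (is.na(j)) abort(paste0("unknown individual '", id, "'"))
  list(origin = cbind(pop$origin[[1]][, j], pop$origin[[2]][, j]),
       allele = cbind(pop$allele[[1]][, j], pop$allele[[2]][, j]))
}

#' Simulate one gamete from a parent diplotype
#'
#' Per chromosome, the crossover count is drawn Poisson with mean equal to
#' the chromosome's genetic length in Morgans and breakpoints are placed
#' uniformly on the cM interval (Haldane, no interference). The gamete
#' alternates between the parent's two homologues at the breakpoints; the
#' starting homologue is chosen with probability 1/2. Origin labels travel
#' with the chosen homologue.
#'
#' @param parent a list with `origin` and `allele` L x 2 matrices (see
#'   [get_diplotype()]).
#' @param map the genetic map the vectors are ordered by.
#' @return a list with integer vectors `origin` and `allele` (length L) and
#'   a tibble `breakpoints` (`chrom`, `homologue_switch_at`) of latent
#'   crossover positions in cM.
#' @export
sim_gamete <- function(parent, map) {
  L <- nrow(map)
  if (nrow(parent$origin) != L || nrow(parent$allele) != L) {
    abort("parent diplotype length does not match the genetic map")
  }
  origin <- integer(L); allele <- integer(L)
  bp <- list()
  for (idx in chrom_index(map)) {
    pos <- map$cM[idx]
    len_M <- (max(pos) - min(pos)) / 100
    n_co <- rpois(1L, len_M)
    breaks <- if (n_co > 0) sort(runif(n_co, min(pos), max(pos))) else numeric(0)
    start <- sample.int(2L, 1L)
    # homologue at each marker: start + number of breakpoints passed
    hom <- ((start - 1L) + findInterval(pos, breaks)) %% 2L + 1L
    take <- cbind(idx, hom)
    origin[idx] <- parent$origin[take]
    allele[idx] <- parent$allele[take]
    if (n_co > 0) {
      bp[[length(bp) + 1L]] <- tibble::tibble(
        chrom = map$chrom[idx[1]], homologue_switch_at = breaks
      )
    }
  }
  list(origin = origin, allele = allele,
       breakpoints = if (length(bp)) dplyr::bind_rows(bp) else
         tibble::tibble(chrom = character(0),
                        homologue_switch_at = numeric(0)))
}

#' Simulate a population of origin-labelled diplotypes down a pedigree
#'
#' Founders carry their own id as origin at every marker on both homologues
#' (inbred lines). Non-founders are built in generation order, receiving one
#' recombinant gamete from each parent via [sim_gamete()]. The result is the
#' known truth against which reconstructions are scored.
#'
#' @param ped a pedigree tibble (see [sim_pedigree()]).
#' @param founders a `founder_panel` covering the map.
#' @param map a genetic-map tibble.
#' @param seed optional integer seed; fixed seed gives bit-identical output.
#' @param keep which individuals to return: `"progeny"` (terminal
#'   generation only, the individuals metrics are about), `"non_founders"`
#'   or `"all"`.
#' @return an `origin_diplotypes` object with latent crossover breakpoints
#'   recorded for diagnostics.
#' @examples
#' map <- sim_genetic_map(n_markers = 50, seed = 1)
#' fnd <- sim_founders(map, 4, seed = 2)
#' ped <- sim_pedigree(4, 20)
#' pop <- sim_population(ped, fnd, map, seed = 3)
#' @export
sim_population <- function(ped, founders, map, seed = NULL,
                           keep = c("progeny", "non_founders", "all")) {
  keep <- match.arg(keep)
  validate_pedigree(ped)
  validate_founders(founders, map)
  f_ids <- founder_ids(founders)
  ped_f <- ped$id[ped$generation == 0L]
  if (!all(ped_f %in% f_ids)) {
    abort("pedigree references founders absent from the founder panel")
  }
  f_alleles <- founder_alleles(founders)
  L <- nrow(map)

  with_seed(seed, {
    store <- new.env(parent = emptyenv())
    for (f in ped_f) {
      fi <- match(f, f_ids)
      assign(f, list(
        origin = matrix(fi, L, 2L),
        allele = matrix(f_alleles[, fi], L, 2L)
      ), envir = store)
    }
    bks <- list()
    nonf <- ped[ped$generation > 0L, , drop = FALSE]
    nonf <- nonf[order(nonf$generation), , drop = FALSE]
    for (i in seq_len(nrow(nonf))) {
      gm <- sim_gamete(get(nonf$mother[i], envir = store), map)
      gf <- sim_gamete(get(nonf$father[i], envir = store), map)
      assign(nonf$id[i], list(
        origin = cbind(gm$origin, gf$origin),
        allele = cbind(gm$allele, gf$allele)
      ), envir = store)
      b <- dplyr::bind_rows(
        dplyr::mutate(gm$breakpoints, homologue = 0L),
        dplyr::mutate(gf$breakpoints, homologue = 1L)
      )
      if (nrow(b)) bks[[nonf$id[i]]] <- dplyr::mutate(b, id = nonf$id[i])
    }
    ids <- switch(keep,
                  all = ped$id,
                  non_founders = nonf$id,
                  progeny = nonf$id[nonf$generation == max(nonf$generation)])
    grab <- function(part, h) {
      m <- vapply(ids, function(id) get(id, envir = store)[[part]][, h],
                  integer(L))
      dim(m) <- c(L, length(ids))
      m
    }
    o1 <- grab("origin", 1); o2 <- grab("origin", 2)
    a1 <- grab("allele", 1); a2 <- grab("allele", 2)
    new_origin_diplotypes(
      map = map, founder_ids = f_ids, ids = ids,
      origin = list(o1, o2), allele = list(a1, a2),
      breakpoints = if (length(bks)) dplyr::bind_rows(bks) else NULL
    )
  })
}

#' Count crossovers in origin-labelled diplotypes
#'
#' A crossover is an origin change between adjacent markers on one
#' homologue; counts are summed over both homologues and all chromosomes,
#' never across chromosome boundaries. Counts are defined at marker
#' resolution: an even number of latent breakpoints falling between the same
#' adjacent marker pair is invisible, which is also how decoded paths are
#' scored.
#'
#' @param pop an `origin_diplotypes` object.
#' @return a tibble with columns `id` and `crossovers`; a per-chromosome,
#'   per-homologue breakdown is attached as attribute `"detail"`.
#' @export
count_crossovers <- function(pop) {
  idxs <- chrom_index(pop$map)
  detail <- purrr::map_dfr(seq_along(idxs), function(ci) {
    idx <- idxs[[ci]]
    purrr::map_dfr(1:2, function(h) {
      o <- pop$origin[[h]][idx, , drop = FALSE]
      n <- colSums(o[-1, , drop = FALSE] != o[-nrow(o), , drop = FALSE])
      tibble::tibble(id = pop$ids, chrom = pop$map$chrom[idx[1]],
                     homologue = h - 1L, n = as.integer(n))
    })
  })
  out <- detail %>%
    dplyr::group_by(.data$id) %>%
    dplyr::summarise(crossovers = sum(.data$n), .groups = "drop") %>%
    dplyr::arrange(match(.data$id, pop$ids))
  attr(out, "detail") <- detail
  out
}

# Origin and allele labels are per-marker, so restricting simulated truth
# to a marker subset commutes with simulation.
#' @export
subset_markers.origin_diplotypes <- function(pop, markers) {
  keep <- pop$map$marker %in% markers
  if (!any(keep)) abort("no markers left after subsetting")
  map2 <- pop$map[keep, , drop = FALSE]
  for (idx in chrom_index(map2)) {
    if (length(idx) < 2) {
      abort(paste0("marker subset leaves < 2 markers on ", map2$chrom[idx[1]]))
    }
  }
  new_origin_diplotypes(
    map = map2, founder_ids = pop$founder_ids, ids = pop$ids,
    origin = lapply(pop$origin, function(m) m[keep, , drop = FALSE]),
    allele = lapply(pop$allele, function(m) m[keep, , drop = FALSE]),
    breakpoints = pop$breakpoints
  )
}
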