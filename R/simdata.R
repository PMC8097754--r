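# Synthetic study inputs: genetic maps, inbred founder panels, pedigrees and
# per-locus missingness profiles. Everything downstream is testable from
# these generators alone; no external data is required.

#' Generate a synthetic genetic map
#'
#' Markers are placed on each chromosome either at sorted uniform-random cM
#' positions spanning `[0, length_cM]` (first and last marker pinned to the
#' endpoints) or at even spacing. Physical bp positions are derived from the
#' genetic positions at a fixed scale (default 1 cM = 1 Mb) and are only
#' labels for reporting: all computation uses cM.
#'
#' @param n_chrom number of chromosomes.
#' @param n_markers markers per chromosome (>= 2).
#' @param length_cM genetic length of each chromosome in centimorgans (> 0).
#' @param spacing `"random"` or `"even"`.
#' @param bp_per_cM physical scale used to label bp positions.
#' @param seed optional integer seed (used only for random spacing).
#' @return a tibble with columns `chrom`, `marker`, `cM`, `bp`, one row per
#'   marker, ordered by chromosome then position.
#' @examples
#' map <- sim_genetic_map(n_chrom = 2, n_markers = 50, length_cM = 100, seed = 1)
#' @export
sim_genetic_map <- function(n_chrom = 1, n_markers = 100, length_cM = 100,
                            spacing = c("random", "even"), bp_per_cM = 1e6,
                            seed = NULL) {
  spacing <- match.arg(spacing)
  if (n_markers < 2) abort("`n_markers` must be >= 2")
  if (length_cM <= 0) abort("`length_cM` must be positive")
  if (n_chrom < 1) abort("`n_chrom` must be >= 1")

  with_seed(seed, {
    rows <- lapply(seq_len(n_chrom), function(cc) {
      pos <- if (spacing == "even") {
        seq(0, length_cM, length.out = n_markers)
      } else if (n_markers == 2) {
        c(0, length_cM)
      } else {
        c(0, sort(runif(n_markers - 2L, 0, length_cM)), length_cM)
      }
      bp <- as.integer(round(pos * bp_per_cM)) + 1L
      # bp must be strictly increasing even when cM positions nearly coincide
      for (i in seq_along(bp)[-1]) {
        if (bp[i] <= bp[i - 1]) bp[i] <- bp[i - 1] + 1L
      }
      tibble::tibble(
        chrom = paste0("chr", cc),
        marker = sprintf("chr%d_m%04d", cc, seq_len(n_markers)),
        cM = pos,
        bp = bp
      )
    })
    map <- dplyr::bind_rows(rows)
    validate_genetic_map(map)
    map
  })
}

#' Validate a genetic map
#'
#' Checks the structural invariants of a genetic map: required columns,
#' genome-wide unique marker ids, at least two markers per chromosome,
#' non-decreasing cM and strictly increasing bp within chromosomes.
#'
#' @param map a genetic-map tibble (`chrom`, `marker`, `cM`, `bp`).
#' @return the map, invisibly, or an error describing the violation.
#' @export
validate_genetic_map <- function(map) {
  need <- c("chrom", "marker", "cM", "bp")
  if (!all(need %in% names(map))) {
    abort(paste("genetic map must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(map$marker)) abort("marker ids must be unique genome-wide")
  if (any(map$bp < 1)) abort("bp positions must be >= 1")
  if (any(map$cM < 0)) abort("cM positions must be >= 0")
  for (idx in chrom_index(map)) {
    if (length(idx) < 2) abort("each chromosome needs >= 2 markers")
    if (is.unsorted(map$cM[idx])) {
      abort("cM must be non-decreasing within a chromosome")
    }
    if (any(diff(map$bp[idx]) <= 0)) {
      abort("bp must be strictly increasing within a chromosome")
    }
  }
  invisible(map)
}

#' Thin a genetic map to every k-th marker
#'
#' Keeps every `step`-th marker within each chromosome (starting from the
#' first), the standard way to emulate a lower-density genotyping platform.
#'
#' @param map a genetic-map tibble.
#' @param step keep every `step`-th marker.
#' @return the thinned map tibble.
#' @export
thin_map <- function(map, step = 2L) {
  if (step < 1) abort("`step` must be >= 1")
  keep <- unlist(lapply(chrom_index(map), function(idx) {
    idx[seq(1L, length(idx), by = step)]
  }), use.names = FALSE)
  map[sort(keep), , drop = FALSE]
}

#' Generate an inbred founder panel
#'
#' Founders are fully inbred (homozygous at every marker), as after filtering
#' residual heterozygous sites from real parent lines. Each marker's allele-1
#' frequency is drawn uniformly from `maf`, then founder haplotypes are
#' independent Bernoulli draws. An identity-by-state (IBS) knob forces a
#' random fraction of markers to be identical between two designated
#' founders, the regime in which parent-of-origin becomes locally
#' unidentifiable.
#'
#' @param map a genetic-map tibble.
#' @param n_founders number of founders (>= 2).
#' @param maf length-2 interval from which per-marker allele frequencies are
#'   drawn.
#' @param ibs_fraction fraction of markers at which `ibs_pair` founders are
#'   forced identical-by-state.
#' @param ibs_pair indices of the two founders tied by `ibs_fraction`.
#' @param ibs_markers optional explicit marker ids to force IBS (overrides the
#'   random fraction; used to plant an IBS window).
#' @param seed optional integer seed.
#' @return a `founder_panel`: a tibble with column `marker` plus one 0/1
#'   column per founder (the single haplotype each inbred founder carries).
#' @examples
#' map <- sim_genetic_map(n_markers = 20, seed = 1)
#' founders <- sim_founders(map, n_founders = 4, seed = 2)
#' @export
sim_founders <- function(map, n_founders, maf = c(0.2, 0.5),
                         ibs_fraction = 0, ibs_pair = c(1L, 2L),
                         ibs_markers = NULL, seed = NULL) {
  if (n_founders < 2) abort("`n_founders` must be >= 2")
  if (nrow(map) == 0) abort("genetic map is empty")
  if (ibs_fraction < 0 || ibs_fraction > 1) {
    abort("`ibs_fraction` must be in [0, 1]")
  }
  L <- nrow(map)
  ids <- paste0("F", seq_len(n_founders))
  with_seed(seed, {
    p <- runif(L, min(maf), max(maf))
    alleles <- vapply(seq_len(n_founders),
                      function(f) rbinom(L, 1L, p), integer(L))
    if (!is.null(ibs_markers)) {
      pos <- match(ibs_markers, map$marker)
      if (anyNA(pos)) abort("`ibs_markers` contains unknown marker ids")
      alleles[pos, ibs_pair[2]] <- alleles[pos, ibs_pair[1]]
    } else if (ibs_fraction > 0) {
      n_ibs <- round(ibs_fraction * L)
      pos <- sample.int(L, n_ibs)
      alleles[pos, ibs_pair[2]] <- alleles[pos, ibs_pair[1]]
    }
    colnames(alleles) <- ids
    panel <- tibble::tibble(marker = map$marker) %>%
      dplyr::bind_cols(tibble::as_tibble(alleles))
    new_founder_panel(panel)
  })
}

new_founder_panel <- function(panel) {
  structure(panel, class = c("founder_panel", class(tibble::tibble())))
}

#' @export
print.founder_panel <- function(x, ...) {
  cat("<founder_panel> ", nrow(x), " markers x ", ncol(x) - 1L,
      " inbred founders\n", sep = "")
  NextMethod()
}

#' Founder ids of a panel
#' @param founders a `founder_panel`.
#' @return character vector of founder ids.
#' @export
founder_ids <- function(founders) setdiff(names(founders), "marker")

#' Founder allele matrix
#'
#' @param founders a `founder_panel`.
#' @return integer matrix, markers x founders, of 0/1 alleles.
#' @export
founder_alleles <- function(founders) {
  m <- as.matrix(founders[founder_ids(founders)])
  storage.mode(m) <- "integer"
  rownames(m) <- founders$marker
  m
}

#' Validate a founder panel against a map
#'
#' @param founders a `founder_panel`.
#' @param map optional genetic map the panel must cover, in order.
#' @return the panel, invisibly.
#' @export
validate_founders <- function(founders, map = NULL) {
  ids <- founder_ids(founders)
  if (length(ids) < 2) abort("a founder panel needs >= 2 founders")
  a <- founder_alleles(founders)
  if (!all(a %in% c(0L, 1L))) abort("founder alleles must be biallelic 0/1")
  if (!is.null(map) && !identical(founders$marker, map$marker)) {
    abort("founder panel markers do not match the genetic map")
  }
  invisible(founders)
}

#' Generate a mating design as a pedigree
#'
#' Two designs are provided. `"biparental_f1"` crosses founders 1 x 2 to give
#' `n_progeny` F1 individuals. `"outcross"` builds a multi-parent outcross:
#' generation 1 consists of F1s from a circular scheme over distinct founder
#' pairs (founder i x founder i+1), and each later generation outcrosses
#' pairs of distinct individuals from the previous generation, so terminal
#' progeny are admixed and non-inbred. The mating scheme is deterministic, so
#' a pedigree is fully specified by its arguments.
#'
#' @param n_founders number of founders available.
#' @param n_progeny number of terminal progeny.
#' @param design `"outcross"` or `"biparental_f1"`.
#' @param generations pedigree depth for the outcross design (>= 1; depth 2
#'   means founder crosses followed by one round of outcrossing among F1s).
#' @return a tibble with columns `id`, `mother`, `father`, `generation`;
#'   founders have `NA` parents and generation 0.
#' @examples
#' ped <- sim_pedigree(n_founders = 8, n_progeny = 100)
#' @export
sim_pedigree <- function(n_founders, n_progeny,
                         design = c("outcross", "biparental_f1"),
                         generations = 2L) {
  design <- match.arg(design)
  if (n_founders < 2) abort("`n_founders` must be >= 2")
  if (n_progeny < 1) abort("`n_progeny` must be >= 1")
  founders <- tibble::tibble(
    id = paste0("F", seq_len(n_founders)),
    mother = NA_character_, father = NA_character_, generation = 0L
  )
  if (design == "biparental_f1") {
    prog <- tibble::tibble(
      id = sprintf("I%04d", seq_len(n_progeny)),
      mother = "F1", father = "F2", generation = 1L
    )
    return(validate_pedigree(dplyr::bind_rows(founders, prog)))
  }
  if (generations < 1) abort("`generations` must be >= 1")
  prev <- founders$id
  rows <- list(founders)
  for (g in seq_len(generations)) {
    n_prev <- length(prev)
    # distinct-pair circular scheme; terminal generation gets n_progeny ids
    n_out <- if (g == generations) n_progeny else max(n_prev, 4L)
    k <- seq_len(n_out) - 1L
    mo <- prev[(k %% n_prev) + 1L]
    fa <- prev[((k + 1L + (k %/% n_prev)) %% n_prev) + 1L]
    # guarantee distinct parents (selfing never allowed)
    same <- mo == fa
    fa[same] <- prev[((match(mo[same], prev)) %% n_prev) + 1L]
    ids <- if (g == generations) {
      sprintf("I%04d", seq_len(n_out))
    } else {
      sprintf("G%d_%03d", g, seq_len(n_out))
    }
    rows[[g + 1L]] <- tibble::tibble(id = ids, mother = mo, father = fa,
                                     generation = g)
    prev <- ids
  }
  validate_pedigree(dplyr::bind_rows(rows))
}

#' Validate a pedigree
#'
#' Checks: unique ids, founders (generation 0) with no parents, non-founders
#' with both parents present and of strictly earlier generation (which also
#' forces acyclicity).
#'
#' @param ped a pedigree tibble (`id`, `mother`, `father`, `generation`).
#' @return the pedigree, invisibly.
#' @export
validate_pedigree <- function(ped) {
  need <- c("id", "mother", "father", "generation")
  if (!all(need %in% names(ped))) {
    abort(paste("pedigree must have columns", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(ped$id)) abort("pedigree ids must be unique")
  gen <- setNames(ped$generation, ped$id)
  founder <- ped$generation == 0L
  if (any(!is.na(ped$mother[founder]) | !is.na(ped$father[founder]))) {
    abort("founders (generation 0) must have no parents")
  }
  nonf <- ped[!founder, , drop = FALSE]
  if (any(is.na(nonf$mother) | is.na(nonf$father))) {
    abort("non-founders must have both parents")
  }
  if (any(!nonf$mother %in% ped$id) || any(!nonf$father %in% ped$id)) {
    abort("pedigree references unknown parents")
  }
  if (any(gen[nonf$mother] >= nonf$generation) ||
      any(gen[nonf$father] >= nonf$generation)) {
    abort("parents must be of strictly earlier generation")
  }
  invisible(ped)
}

#' Generate a per-locus missingness profile
#'
#' Emulates the heterogeneous per-locus missingness of sparse genotyping
#' platforms (e.g. genotyping-by-sequencing): per-marker missingness rates
#' are drawn from a Beta distribution with the requested mean, or set to a
#' constant.
#'
#' @param map a genetic-map tibble.
#' @param mean_rate mean per-locus missingness in `[0, 1]`.
#' @param shape Beta concentration; larger values give rates tighter around
#'   the mean. `Inf` (or `mean_rate` 0/1) gives a constant profile.
#' @param seed optional integer seed.
#' @return a tibble with columns `marker`, `f_miss`.
#' @export
sim_missingness <- function(map, mean_rate = 0.1, shape = 10, seed = NULL) {
  stopifnot_scalar_prob(mean_rate, "mean_rate", allow_one = TRUE)
  with_seed(seed, {
    f <- if (!is.finite(shape) || mean_rate %in% c(0, 1)) {
      rep(mean_rate, nrow(map))
    } else {
      stats::rbeta(nrow(map), mean_rate * shape, (1 - mean_rate) * shape)
    }
    tibble::tibble(marker = map$marker, f_miss = f)
  })
}
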