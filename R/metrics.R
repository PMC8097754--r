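# Scoring reconstructed haplotype maps against simulated truth.
#
# Four standard metrics: ancestral assignment accuracy (AAA), genotype
# assignment accuracy (GAA), phase assignment accuracy (PAA) and the
# correlation between known and inferred crossover counts (CCC), plus
# per-marker regional profiles and parent certainty.
#
# Homologue pairing: Viterbi phase labels are arbitrary relative to
# maternal/paternal labels, so AAA compares the unordered (multiset)
# founder pair per marker. PAA instead needs a homologue correspondence;
# it uses, per chromosome, the orientation that maximizes origin agreement.

check_same_markers <- function(known, inferred) {
  if (!identical(known$map$marker, inferred$map$marker)) {
    abort("known and inferred diplotypes are on different marker sets")
  }
  if (!identical(known$ids, inferred$ids)) {
    abort("known and inferred diplotypes cover different individuals")
  }
}

# per-marker x individual multiset-intersection score (0, 1 or 2) between
# known and inferred origin pairs
origin_match_score <- function(known, inferred) {
  k0 <- known$origin[[1]]; k1 <- known$origin[[2]]
  i0 <- inferred$origin[[1]]; i1 <- inferred$origin[[2]]
  m_id <- (k0 == i0) + (k1 == i1)
  m_sw <- (k0 == i1) + (k1 == i0)
  pmax(m_id, m_sw)
}

#' Ancestral assignment accuracy (AAA)
#'
#' The percentage of per-homologue marker assignments whose
#' founder-of-origin matches the truth. At each marker the score is the
#' multiset intersection (0, 1 or 2) between the unordered known and
#' inferred origin pairs; AAA is `100 * sum(score) / (2 L)`.
#'
#' @param known,inferred `origin_diplotypes` on the same markers and
#'   individuals.
#' @return tibble (`id`, `aaa`) with AAA as a percentage in `[0, 100]`.
#' @export
calc_aaa <- function(known, inferred) {
  check_same_markers(known, inferred)
  score <- origin_match_score(known, inferred)
  tibble::tibble(id = known$ids,
                 aaa = unname(100 * colSums(score) / (2 * nrow(known$map))))
}

#' Genotype assignment accuracy (GAA)
#'
#' Genotypes are assigned from the inferred parent-of-origin and the
#' founder panel; GAA is the percentage of markers whose inferred genotype
#' (unordered allele pair, i.e. dosage for biallelic markers) equals the
#' true genotype. A wrong origin whose founder is identical-by-state with
#' the right one still scores a genotype match, which is why GAA can exceed
#' AAA.
#'
#' @param known,inferred `origin_diplotypes` on the same markers and
#'   individuals.
#' @param founders optional `founder_panel`; when supplied, inferred
#'   genotypes are (re)read from the panel at the inferred origins rather
#'   than taken from the inferred allele vectors.
#' @return tibble (`id`, `gaa`).
#' @export
calc_gaa <- function(known, inferred, founders = NULL) {
  check_same_markers(known, inferred)
  if (!is.null(founders)) {
    fa <- founder_alleles(founders)[known$map$marker, , drop = FALSE]
    L <- nrow(fa); N <- length(inferred$ids)
    gi <- matrix(fa[cbind(rep(seq_len(L), N), as.vector(inferred$origin[[1]]))],
                 L, N) +
          matrix(fa[cbind(rep(seq_len(L), N), as.vector(inferred$origin[[2]]))],
                 L, N)
  } else {
    gi <- geno_matrix(inferred)
  }
  gk <- geno_matrix(known)
  tibble::tibble(id = known$ids, gaa = unname(100 * colMeans(gk == gi)))
}

# per chromosome, the homologue orientation (FALSE = identity, TRUE = swap)
# that maximizes origin agreement between known and inferred for one
# individual; identity wins ties
best_orientation <- function(k_o, i_o) {
  agree_id <- sum(k_o[, 1] == i_o[, 1]) + sum(k_o[, 2] == i_o[, 2])
  agree_sw <- sum(k_o[, 1] == i_o[, 2]) + sum(k_o[, 2] == i_o[, 1])
  agree_sw > agree_id
}

#' Phase assignment accuracy (PAA)
#'
#' Assessed only where phase is both defined and trusted: markers where the
#' true genotype is heterozygous and the inferred genotype equals the true
#' genotype. Within each chromosome the inferred homologues are first
#' oriented to the known ones (the orientation maximizing origin
#' agreement); then each consecutive pair of evaluation markers is
#' concordant when the inferred allele-to-homologue arrangement preserves
#' the known relative phase (identical at both, or swapped at both). PAA is
#' 100 times the concordant fraction over all such pairs; individuals with
#' fewer than two evaluation markers on every chromosome get `NA`.
#'
#' @param known,inferred `origin_diplotypes` on the same markers and
#'   individuals.
#' @return tibble (`id`, `paa`, `n_pairs`).
#' @export
calc_paa <- function(known, inferred) {
  check_same_markers(known, inferred)
  idxs <- chrom_index(known$map)
  N <- length(known$ids)
  conc <- integer(N); tot <- integer(N)
  gk <- geno_matrix(known); gi <- geno_matrix(inferred)
  for (idx in idxs) {
    for (i in seq_len(N)) {
      k_o <- cbind(known$origin[[1]][idx, i], known$origin[[2]][idx, i])
      i_o <- cbind(inferred$origin[[1]][idx, i], inferred$origin[[2]][idx, i])
      swap <- best_orientation(k_o, i_o)
      ia0 <- if (swap) inferred$allele[[2]][idx, i] else
        inferred$allele[[1]][idx, i]
      ka0 <- known$allele[[1]][idx, i]
      ev <- gk[idx, i] == 1L & gi[idx, i] == gk[idx, i]
      if (sum(ev) < 2) next
      m <- ka0[ev] == ia0[ev]      # arrangement agreement at each het site
      same <- m[-1] == m[-length(m)]
      conc[i] <- conc[i] + sum(same)
      tot[i] <- tot[i] + length(same)
    }
  }
  tibble::tibble(id = known$ids,
                 paa = ifelse(tot > 0, 100 * conc / tot, NA_real_),
                 n_pairs = tot)
}

#' Correlation between known and inferred crossover counts (CCC)
#'
#' Pearson correlation across individuals of total crossover counts (both
#' homologues, all chromosomes), with the standard t-based two-sided
#' p-value, plus both means and standard deviations (correlation is
#' insensitive to a systematic bias in counts; the means expose it).
#'
#' @param known_counts,inferred_counts crossover-count tibbles from
#'   [count_crossovers()] (or bare numeric vectors paired by individual).
#' @return one-row tibble (`ccc`, `p_value`, `mean_known`, `sd_known`,
#'   `mean_inferred`, `sd_inferred`, `n`).
#' @export
calc_ccc <- function(known_counts, inferred_counts) {
  x <- if (is.data.frame(known_counts)) known_counts$crossovers else
    known_counts
  y <- if (is.data.frame(inferred_counts)) inferred_counts$crossovers else
    inferred_counts
  if (is.data.frame(known_counts) && is.data.frame(inferred_counts)) {
    if (!identical(known_counts$id, inferred_counts$id)) {
      y <- inferred_counts$crossovers[match(known_counts$id,
                                            inferred_counts$id)]
    }
  }
  if (length(x) != length(y)) abort("count vectors must be paired")
  if (length(x) < 3) abort("need >= 3 individuals for a correlation")
  if (var(x) == 0 || var(y) == 0) {
    warn("zero variance in crossover counts; CCC undefined")
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- cor.test(x, y, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  tibble::tibble(ccc = r, p_value = p,
                 mean_known = mean(x), sd_known = stats::sd(x),
                 mean_inferred = mean(y), sd_inferred = stats::sd(y),
                 n = length(x))
}

#' Per-marker regional accuracy profile
#'
#' Per-marker AAA across individuals (and mean parent certainty when a
#' decoding is supplied), for regional appraisal: windows of
#' identity-by-state founders or low marker density show up as localized
#' dips in per-marker AAA and parent certainty.
#'
#' @param known,inferred `origin_diplotypes` on the same markers and
#'   individuals.
#' @param decoding optional `origin_decoding` carrying posterior parent
#'   certainty.
#' @return tibble (`chrom`, `marker`, `cM`, `aaa`, `mean_certainty`).
#' @export
marker_profile <- function(known, inferred, decoding = NULL) {
  check_same_markers(known, inferred)
  score <- origin_match_score(known, inferred)
  out <- tibble::tibble(
    chrom = known$map$chrom, marker = known$map$marker, cM = known$map$cM,
    aaa = 100 * rowMeans(score) / 2
  )
  out$mean_certainty <- if (!is.null(decoding)) {
    rowMeans(decoding$certainty)
  } else NA_real_
  out
}

#' Evaluate a reconstruction against the simulated truth
#'
#' Computes all per-individual metrics (AAA, GAA, PAA, known and inferred
#' crossover counts), the population summaries (metric means, CCC with
#' p-value) and the per-marker regional profile, in one object with
#' [tidy()], [glance()] and [autoplot()] methods.
#'
#' @param known truth `origin_diplotypes` from [sim_population()].
#' @param inferred reconstructed `origin_diplotypes`, or an
#'   `origin_decoding` (its Viterbi diplotypes are used and its posteriors
#'   feed the certainty profile).
#' @param founders optional `founder_panel` for genotype reassignment in
#'   GAA.
#' @return a `reconstruction_metrics` object.
#' @examples
#' map <- sim_genetic_map(n_markers = 80, seed = 1)
#' fnd <- sim_founders(map, 4, seed = 2)
#' pop <- sim_population(sim_pedigree(4, 10), fnd, map, seed = 3)
#' dec <- decode_origins(pop, fnd)
#' met <- evaluate_reconstruction(pop, dec, fnd)
#' glance(met)
#' @export
evaluate_reconstruction <- function(known, inferred, founders = NULL) {
  decoding <- NULL
  if (inherits(inferred, "origin_decoding")) {
    decoding <- inferred
    inferred <- inferred$inferred
  }
  check_same_markers(known, inferred)
  kc <- count_crossovers(known)
  ic <- count_crossovers(inferred)
  per_individual <- calc_aaa(known, inferred) %>%
    dplyr::left_join(calc_gaa(known, inferred, founders), by = "id") %>%
    dplyr::left_join(calc_paa(known, inferred), by = "id") %>%
    dplyr::left_join(dplyr::rename(kc, known_crossovers = "crossovers"),
                     by = "id") %>%
    dplyr::left_join(dplyr::rename(ic, inferred_crossovers = "crossovers"),
                     by = "id")
  ccc <- calc_ccc(kc, ic)
  profile <- marker_profile(known, inferred, decoding)
  structure(list(per_individual = per_individual, ccc = ccc,
                 per_marker = profile),
            class = "reconstruction_metrics")
}

#' @export
print.reconstruction_metrics <- function(x, ...) {
  g <- glance(x)
  cat("<reconstruction_metrics> ", nrow(x$per_individual), " individuals, ",
      nrow(x$per_marker), " markers\n", sep = "")
  cat(sprintf("  mean AAA %.2f%%  mean GAA %.2f%%  mean PAA %.2f%%\n",
              g$mean_aaa, g$mean_gaa, g$mean_paa))
  cat(sprintf("  CCC r = %.3f (p = %.3g); crossovers %.1f known vs %.1f inferred\n",
              g$ccc, g$ccc_p_value, g$mean_known_crossovers,
              g$mean_inferred_crossovers))
  invisible(x)
}

#' Per-individual metric table
#' @param x a `reconstruction_metrics` object.
#' @param ... unused.
#' @return the per-individual tibble.
#' @export
tidy.reconstruction_metrics <- function(x, ...) x$per_individual

#' One-row population summary of a reconstruction
#' @param x a `reconstruction_metrics` object.
#' @param ... unused.
#' @return one-row tibble with metric means (PAA averaged over individuals
#'   for which it is defined), CCC and crossover-count summaries.
#' @export
glance.reconstruction_metrics <- function(x, ...) {
  pi_ <- x$per_individual
  tibble::tibble(
    n = nrow(pi_),
    mean_aaa = mean(pi_$aaa),
    mean_gaa = mean(pi_$gaa),
    mean_paa = mean(pi_$paa, na.rm = TRUE),
    min_marker_aaa = min(x$per_marker$aaa),
    ccc = x$ccc$ccc,
    ccc_p_value = x$ccc$p_value,
    mean_known_crossovers = x$ccc$mean_known,
    sd_known_crossovers = x$ccc$sd_known,
    mean_inferred_crossovers = x$ccc$mean_inferred,
    sd_inferred_crossovers = x$ccc$sd_inferred
  )
}

#' Plot the per-marker accuracy and parent-certainty profile
#'
#' @param object a `reconstruction_metrics` object.
#' @param ... unused.
#' @return a ggplot: per-marker AAA (and scaled mean parent certainty when
#'   available) along each chromosome.
#' @export
autoplot.reconstruction_metrics <- function(object, ...) {
  pm <- object$per_marker
  p <- ggplot2::ggplot(pm, ggplot2::aes(x = .data$cM, y = .data$aaa)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "per-marker AAA (%)",
                  title = "Regional reconstruction accuracy") +
    ggplot2::theme_minimal()
  if (!all(is.na(pm$mean_certainty))) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(y = 100 * .data$mean_certainty),
      colour = "darkorange", linetype = "dashed"
    ) +
      ggplot2::labs(subtitle = "dashed: mean parent certainty x 100")
  }
  p
}

#' Plot per-individual metric distributions
#'
#' @param object a `reconstruction_metrics` object.
#' @param ... unused.
#' @return a ggplot of the AAA/GAA/PAA distributions across individuals.
#' @export
plot_metric_distributions <- function(object, ...) {
  object$per_individual %>%
    tidyr::pivot_longer(cols = c("aaa", "gaa", "paa"),
                        names_to = "metric", values_to = "value") %>%
    ggplot2::ggplot(ggplot2::aes(x = toupper(.data$metric), y = .data$value)) +
    ggplot2::geom_boxplot(fill = "grey85") +
    ggplot2::labs(x = NULL, y = "accuracy (%)") +
    ggplot2::theme_minimal()
}
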