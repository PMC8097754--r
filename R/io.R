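# Readers and writers for the pipeline's file formats. Conventions: VCF is
# 1-based; internal marker indices are 0-based within chromosomes; cM is the
# computational coordinate and bp positions are reporting labels.
#
# Formats:
#   genetic map   4-column TSV, no header: chrom, marker, cM, bp
#                 (PLINK .map column order, cM before bp)
#   pedigree      CSV with header id,mother,father,generation; founders have
#                 empty parent fields
#   missingness   2-column TSV with header: marker, f_miss
#   founders      TSV (marker x founder, 0/1) or VCF with phased GT
#   genotypes     VCF (phased GT for truth, unphased GT with ./. for
#                 observed data, GT:DS for imputed data)
#   origins       TSV: id, chrom, marker, origin_hom0, origin_hom1 -- one
#                 schema shared by known (simulated) and inferred (decoded)
#                 haplotype maps

#' Write / read a genetic map
#'
#' @param map a genetic-map tibble.
#' @param path file path (tab-separated, no header, columns chrom, marker,
#'   cM, bp).
#' @return `write_genetic_map` returns `path` invisibly; `read_genetic_map`
#'   returns a validated map tibble.
#' @export
write_genetic_map <- function(map, path) {
  validate_genetic_map(map)
  readr::write_tsv(map[, c("chrom", "marker", "cM", "bp")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname write_genetic_map
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) abort(paste0("map file not found: ", path))
  map <- readr::read_tsv(path, col_names = c("chrom", "marker", "cM", "bp"),
                         col_types = "ccdi", progress = FALSE)
  validate_genetic_map(map)
  map
}

#' Write / read a pedigree
#'
#' @param ped a pedigree tibble.
#' @param path CSV path (header `id,mother,father,generation`; empty parent
#'   fields for founders).
#' @return `write_pedigree` returns `path` invisibly; `read_pedigree` a
#'   validated pedigree tibble.
#' @export
write_pedigree <- function(ped, path) {
  validate_pedigree(ped)
  readr::write_csv(ped, path, na = "")
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  if (!file.exists(path)) abort(paste0("pedigree file not found: ", path))
  ped <- readr::read_csv(path, col_types = readr::cols(
    id = "c", mother = "c", father = "c", generation = "i"
  ), na = "", progress = FALSE)
  validate_pedigree(ped)
  ped
}

#' Write / read a per-locus missingness profile
#'
#' @param profile tibble (`marker`, `f_miss`).
#' @param path TSV path.
#' @return `write_missingness` returns `path` invisibly; `read_missingness`
#'   the profile tibble.
#' @export
write_missingness <- function(profile, path) {
  readr::write_tsv(profile[, c("marker", "f_miss")], path)
  invisible(path)
}

#' @rdname write_missingness
#' @export
read_missingness <- function(path) {
  if (!file.exists(path)) abort(paste0("missingness file not found: ", path))
  readr::read_tsv(path, col_types = "cd", progress = FALSE)
}

#' Write / read a founder panel as TSV
#'
#' @param founders a `founder_panel`.
#' @param path TSV path (column `marker` plus one 0/1 column per founder).
#' @return `write_founders` returns `path` invisibly; `read_founders` a
#'   `founder_panel`.
#' @export
write_founders <- function(founders, path) {
  readr::write_tsv(founders, path)
  invisible(path)
}

#' @rdname write_founders
#' @export
read_founders <- function(path) {
  if (!file.exists(path)) abort(paste0("founder file not found: ", path))
  panel <- readr::read_tsv(path, col_types = readr::cols(
    marker = "c", .default = "i"
  ), progress = FALSE)
  validate_founders(new_founder_panel(panel))
  new_founder_panel(panel)
}

vcf_meta <- function(samples, with_ds = FALSE) {
  c("##fileformat=VCFv4.2",
    "##source=haplomosaic",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (with_ds) {
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Imputed allele-1 dosage\">"
    })
}

vcf_fix <- function(map) {
  cbind(CHROM = map$chrom, POS = as.character(map$bp), ID = map$marker,
        REF = "A", ALT = "B", QUAL = ".", FILTER = ".", INFO = ".")
}

#' Write genotype data as VCF
#'
#' Phased VCF (GT like `0|1`) for origin-labelled diplotypes and founder
#' panels; unphased GT (with `./.` for missing) for observed genotype
#' matrices; `GT:DS` for imputation results. Biallelic markers are coded
#' REF=A, ALT=B. Output is bgzip-compatible gzipped VCF.
#'
#' @param x an `origin_diplotypes`, `founder_panel` (phased),
#'   `observed_genotypes` or `imputation_result` (unphased).
#' @param path output path (conventionally `.vcf.gz`).
#' @param map genetic map (required for a `founder_panel`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, map = NULL) {
  if (inherits(x, "origin_diplotypes")) {
    gt_body <- matrix(paste0(x$allele[[1]], "|", x$allele[[2]]),
                      nrow(x$map), dimnames = list(NULL, x$ids))
    map <- x$map
    with_ds <- FALSE
    fmt <- "GT"
  } else if (inherits(x, "founder_panel")) {
    if (is.null(map)) abort("`map` is required to write a founder VCF")
    a <- founder_alleles(x)[map$marker, , drop = FALSE]
    gt_body <- matrix(paste0(a, "|", a), nrow(a),
                      dimnames = list(NULL, colnames(a)))
    with_ds <- FALSE
    fmt <- "GT"
  } else if (inherits(x, "observed_genotypes")) {
    gt_body <- geno_to_gt(x$geno)
    map <- x$map
    with_ds <- FALSE
    fmt <- "GT"
  } else if (inherits(x, "imputation_result")) {
    gt_body <- geno_to_gt(x$imputed)
    gt_body[] <- paste0(gt_body, ":",
                        formatC(x$dosage, format = "g", digits = 15))
    dimnames(gt_body) <- list(NULL, colnames(x$imputed))
    map <- x$map
    with_ds <- TRUE
    fmt <- "GT:DS"
  } else {
    abort("unsupported object for VCF output")
  }
  gt <- cbind(FORMAT = fmt, gt_body)
  v <- methods::new("vcfR", meta = vcf_meta(colnames(gt_body), with_ds),
                    fix = vcf_fix(map), gt = gt)
  vcfR::write.vcf(v, path)
  invisible(path)
}

geno_to_gt <- function(g) {
  out <- matrix("./.", nrow(g), ncol(g), dimnames = dimnames(g))
  out[!is.na(g) & g == 0L] <- "0/0"
  out[!is.na(g) & g == 1L] <- "0/1"
  out[!is.na(g) & g == 2L] <- "1/1"
  out
}

#' Read a VCF into a genotype matrix (and dosages when present)
#'
#' @param path VCF path (plain or gzipped).
#' @return a list: `map` (chrom, marker, bp; cM absent from VCF), `geno`
#'   (markers x samples dosage matrix, `NA` for missing), `dosage` (when a
#'   DS field is present) and `phased` haplotype matrices `hap0`/`hap1`
#'   when every call is phased.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) abort(paste0("VCF not found: ", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  a0 <- substr(gt, 1, 1); a1 <- substr(gt, 3, 3)
  geno <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  ok <- !is.na(gt)
  geno[ok] <- as.integer(a0[ok]) + as.integer(a1[ok])
  out <- list(
    map = tibble::tibble(chrom = vcfR::getCHROM(v),
                         marker = vcfR::getID(v),
                         bp = vcfR::getPOS(v)),
    geno = geno
  )
  if (all(grepl("DS", v@gt[, "FORMAT"]))) {
    ds <- vcfR::extract.gt(v, element = "DS")
    out$dosage <- matrix(as.numeric(ds), nrow(ds), dimnames = dimnames(ds))
  }
  if (all(substr(gt[ok], 2, 2) == "|") && all(ok)) {
    out$hap0 <- matrix(as.integer(a0), nrow(gt), dimnames = dimnames(gt))
    out$hap1 <- matrix(as.integer(a1), nrow(gt), dimnames = dimnames(gt))
  }
  out
}

#' Read a phased founder VCF into a founder panel
#'
#' @param path VCF path written by [write_vcf()] for a `founder_panel`
#'   (phased, fully homozygous samples).
#' @return a `founder_panel`.
#' @export
read_founders_vcf <- function(path) {
  v <- read_vcf(path)
  if (is.null(v$hap0)) abort("founder VCF must be fully phased")
  if (any(v$hap0 != v$hap1)) {
    abort("founder VCF contains heterozygous calls; founders must be inbred")
  }
  panel <- tibble::tibble(marker = v$map$marker) %>%
    dplyr::bind_cols(tibble::as_tibble(v$hap0))
  validate_founders(new_founder_panel(panel))
  new_founder_panel(panel)
}

#' Write / read origin-labelled haplotype maps
#'
#' One schema shared by simulated truth and decoded reconstructions, so the
#' metrics stage consumes a single format.
#'
#' @param pop an `origin_diplotypes`.
#' @param path TSV path with header
#'   `id, chrom, marker, origin_hom0, origin_hom1`.
#' @return `write_origins` returns `path` invisibly.
#' @export
write_origins <- function(pop, path) {
  L <- nrow(pop$map); N <- length(pop$ids)
  readr::write_tsv(tibble::tibble(
    id = rep(pop$ids, each = L),
    chrom = rep(pop$map$chrom, N),
    marker = rep(pop$map$marker, N),
    origin_hom0 = pop$founder_ids[as.vector(pop$origin[[1]])],
    origin_hom1 = pop$founder_ids[as.vector(pop$origin[[2]])]
  ), path)
  invisible(path)
}

#' @rdname write_origins
#' @param founders the `founder_panel` used to restore allele vectors from
#'   origin labels.
#' @param map the genetic map (restores cM positions and marker order).
#' @export
read_origins <- function(path, founders, map) {
  if (!file.exists(path)) abort(paste0("origins file not found: ", path))
  tb <- readr::read_tsv(path, col_types = "ccccc", progress = FALSE)
  need <- c("id", "chrom", "marker", "origin_hom0", "origin_hom1")
  if (!all(need %in% names(tb))) {
    abort(paste0("origins file must have columns ",
                 paste(need, collapse = ", ")))
  }
  ids <- unique(tb$id)
  f_ids <- founder_ids(founders)
  L <- nrow(map)
  bad <- setdiff(unique(c(tb$origin_hom0, tb$origin_hom1)), f_ids)
  if (length(bad)) {
    abort(paste0("origins file references unknown founders: ",
                 paste(bad, collapse = ", ")))
  }
  o1 <- matrix(NA_integer_, L, length(ids))
  o2 <- matrix(NA_integer_, L, length(ids))
  row <- match(tb$marker, map$marker)
  if (anyNA(row)) abort("origins file references markers absent from the map")
  col <- match(tb$id, ids)
  o1[cbind(row, col)] <- match(tb$origin_hom0, f_ids)
  o2[cbind(row, col)] <- match(tb$origin_hom1, f_ids)
  if (anyNA(o1) || anyNA(o2)) {
    abort("origins file does not cover every individual x marker")
  }
  fa <- founder_alleles(founders)[map$marker, , drop = FALSE]
  N <- length(ids)
  new_origin_diplotypes(
    map = map, founder_ids = f_ids, ids = ids,
    origin = list(o1, o2),
    allele = list(matrix(fa[cbind(rep(seq_len(L), N), as.vector(o1))], L, N),
                  matrix(fa[cbind(rep(seq_len(L), N), as.vector(o2))], L, N))
  )
}

#' Write the per-marker posterior summary of a decoding
#'
#' @param decoding an `origin_decoding`.
#' @param path TSV path (`id`, `chrom`, `marker`, `top_founder`,
#'   `certainty`).
#' @return `path`, invisibly.
#' @export
write_posterior <- function(decoding, path) {
  readr::write_tsv(tidy(decoding), path)
  invisible(path)
}

#' Write a metrics report to machine- and human-readable files
#'
#' @param metrics a `reconstruction_metrics` object.
#' @param dir output directory; writes `metrics.json` (population summary),
#'   `metrics_per_individual.tsv` and `metrics_per_marker.tsv`.
#' @return `dir`, invisibly.
#' @export
write_metrics <- function(metrics, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(as.list(glance(metrics)),
                       file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  readr::write_tsv(metrics$per_individual,
                   file.path(dir, "metrics_per_individual.tsv"))
  readr::write_tsv(metrics$per_marker,
                   file.path(dir, "metrics_per_marker.tsv"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
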