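# Internal helpers shared across modules.

#' Derive a stage-specific child seed from a master seed
#'
#' Each stochastic pipeline stage draws from its own RNG stream, seeded
#' deterministically from the master seed, so re-running a late stage never
#' perturbs the draws of an earlier one. The derivation is a fixed LCG step
#' kept strictly below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stage stage name, one of `"simulate"`, `"corrupt"`, `"impute"`,
#'   `"reconstruct"`, `"evaluate"`.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stages <- c(simulate = 1, corrupt = 2, impute = 3, reconstruct = 4,
              evaluate = 5)
  if (!stage %in% names(stages)) {
    abort(paste0("unknown pipeline stage '", stage, "'"))
  }
  m <- 2147483647
  x <- (as.numeric(seed) %% m) * 48271 + stages[[stage]] * 7919
  as.integer(x %% m)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

stopifnot_scalar_prob <- function(x, name, allow_one = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 &&
    (x < 1 || (allow_one && x <= 1))
  if (!ok) {
    abort(paste0("`", name, "` must be a single probability in [0, ",
                 if (allow_one) "1]" else "1)"))
  }
  invisible(x)
}

# split a vector of per-marker values by chromosome, preserving map order
split_by_chrom <- function(x, map) {
  split(x, factor(map$chrom, levels = unique(map$chrom)))
}

chrom_index <- function(map) {
  split(seq_len(nrow(map)), factor(map$chrom, levels = unique(map$chrom)))
}
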