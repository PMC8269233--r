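#' Pipeline configuration
#'
#' Bundles the tunable constants of the analysis: rarefaction depths,
#' the detection rule, the relative-abundance class thresholds, and the
#' permutation/random-number settings. Defaults follow the study design the
#' package emulates: soil samples rarefied at 30,000 (bacteria) or 25,000
#' (fungi) reads, plant samples at 1,000 reads; taxa classed as rare below
#' 0.01% mean relative abundance and abundant above 1%.
#'
#' @param depth_soil_bacteria,depth_soil_fungi,depth_plant rarefaction depths
#'   (reads per sample) for soil and plant compartments.
#' @param min_count minimum read count for an ASV to count as detected in a
#'   sample (non-rarefied data).
#' @param min_reps minimum number of samples of a context in which the ASV
#'   must be detected.
#' @param class_thresholds length-2 increasing vector of relative-abundance
#'   fractions separating rare/intermediate and intermediate/abundant taxa.
#' @param n_permutations permutations for PERMANOVA.
#' @param rng_seed integer master seed; every stochastic stage derives its own
#'   stream from it (see [derive_seed()]).
#' @param out_dir default output directory for [run_all()].
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(depth_soil_bacteria = 30000,
                            depth_soil_fungi = 25000,
                            depth_plant = 1000,
                            min_count = 1,
                            min_reps = 1,
                            class_thresholds = c(1e-4, 1e-2),
                            n_permutations = 999,
                            rng_seed = 1L,
                            out_dir = "results") {
  stopifnot(depth_soil_bacteria > 0, depth_soil_fungi > 0, depth_plant > 0)
  if (length(class_thresholds) != 2L ||
      !all(class_thresholds > 0 & class_thresholds < 1) ||
      diff(class_thresholds) <= 0) {
    stop("class_thresholds must be two strictly increasing fractions in (0,1)")
  }
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  if (min_count < 1 || min_reps < 1) stop("min_count and min_reps must be >= 1")
  structure(list(
    depth_soil_bacteria = as.integer(depth_soil_bacteria),
    depth_soil_fungi = as.integer(depth_soil_fungi),
    depth_plant = as.integer(depth_plant),
    min_count = as.integer(min_count),
    min_reps = as.integer(min_reps),
    class_thresholds = as.numeric(class_thresholds),
    n_permutations = as.integer(n_permutations),
    rng_seed = as.integer(rng_seed),
    out_dir = out_dir
  ), class = "pipeline_config")
}

#' Derive a per-operation random seed
#'
#' All randomness in a run flows from one master seed; each stochastic
#' operation draws from its own stream whose seed is the master seed offset by
#' a small polynomial hash of the operation name. Stages are therefore
#' independently reproducible: re-running only the rarefaction, say, with the
#' same master seed gives the same draw regardless of what ran before it.
#'
#' @param seed integer master seed.
#' @param op character scalar naming the operation (e.g. `"rarefy"`).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, op) {
  stopifnot(is.character(op), length(op) == 1L)
  v <- utf8ToInt(op)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% 2147483647
  as.integer((abs(as.numeric(seed)) + h) %% 2147483647)
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched. seed = NULL means "use the ambient RNG".
with_rng <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
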