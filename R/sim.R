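#' Simulation configuration for the coalescence generator
#'
#' Parameters of the synthetic seed-by-soil sowing experiment the generator
#' emulates: four seed lots (two genotypes x two harvest years) with
#' contrasting richness, one high-diversity soil pool (S1) from which a
#' low-diversity pool (S2) is derived by dilution-to-extinction, class- and
#' channel-dependent Bernoulli transmission to root and stem, an external
#' "unknown origin" taxon pool, three replicates, and multinomial read
#' sampling at the study's depths.
#'
#' Default sizes anchor to the study conditions: 100 (Y1) and 250 (Y2) seed
#' ASVs per lot, ~800 soil ASVs with the diluted pool landing near 500;
#' lognormal species-abundance distributions with sigma 1.5; default
#' transmission probabilities follow the observed class pattern (soil to
#' root 0.95/0.40/0.28 for abundant/intermediate/rare, soil to stem
#' 0.86/0.40/0.29, seed channels rare-skewed and an order of magnitude
#' lower).
#'
#' @param n_seed_taxa named vector of per-year seed-lot richness.
#' @param n_soil_taxa richness of the undiluted (S1) soil pool.
#' @param seed_soil_overlap number of each seed lot's taxa shared with the
#'   soil pool.
#' @param lognormal_mu,lognormal_sigma log-abundance parameters of every
#'   pool's species-abundance distribution.
#' @param dilution_exponent serial-dilution exponent d applied to the S1 pool
#'   to create S2 (survival ~ Poisson(inoculum x abundance x 10^-d)).
#' @param inoculum_size cells inoculated at dilution 10^0.
#' @param p_transmission 3-d array `[class, source, compartment]` of
#'   per-taxon transmission probabilities (classes rare/intermediate/
#'   abundant, sources seed/soil, compartments root/stem).
#' @param rho rank-coupling in `[0, 1]` between source and seedling log
#'   abundance of transmitted taxa (1 = source ranks preserved, 0 = fully
#'   decoupled).
#' @param unknown_richness size of the external unknown-origin pool.
#' @param unknown_p per-taxon probability that an unknown-pool taxon joins a
#'   given seedling community.
#' @param unknown_share total relative-abundance share of unknown-pool taxa
#'   in a seedling.
#' @param depth_soil,depth_seed,depth_plant multinomial read depths per
#'   sample.
#' @param n_replicates replicates per context (A, B, C).
#' @param class_thresholds relative-abundance class cut points.
#' @param genotypes,years,soils,stages design levels.
#' @param rng_seed master seed; all stages derive their own streams.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_seed_taxa = c(Y1 = 100, Y2 = 250),
                       n_soil_taxa = 800,
                       seed_soil_overlap = 20,
                       lognormal_mu = 0,
                       lognormal_sigma = 1.5,
                       dilution_exponent = 6,
                       inoculum_size = 4e9,
                       p_transmission = default_p_transmission(),
                       rho = 0.2,
                       unknown_richness = 600,
                       unknown_p = 0.5,
                       unknown_share = 0.2,
                       depth_soil = 30000,
                       depth_seed = 5000,
                       depth_plant = 1000,
                       n_replicates = 3,
                       class_thresholds = c(1e-4, 1e-2),
                       genotypes = c("Boston", "Major"),
                       years = c("Y1", "Y2"),
                       soils = c("S1", "S2"),
                       stages = c("d07", "d14"),
                       rng_seed = 1L) {
  stopifnot(all(p_transmission >= 0 & p_transmission <= 1),
            depth_soil >= 1, depth_seed >= 1, depth_plant >= 1,
            lognormal_sigma > 0, rho >= 0, rho <= 1,
            unknown_p >= 0, unknown_p <= 1,
            unknown_share >= 0, unknown_share < 1,
            dilution_exponent >= 0, inoculum_size >= 1)
  if (seed_soil_overlap > min(c(n_seed_taxa, n_soil_taxa))) {
    stop("seed_soil_overlap exceeds the smallest pool size")
  }
  if (!all(years %in% names(n_seed_taxa))) {
    stop("n_seed_taxa must name every year level")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @export
default_p_transmission <- function() {
  a <- array(NA_real_,
             dim = c(3, 2, 2),
             dimnames = list(class = c("rare", "intermediate", "abundant"),
                             source = c("seed", "soil"),
                             compartment = c("root", "stem")))
  a[, "soil", "root"] <- c(0.28, 0.40, 0.95)
  a[, "soil", "stem"] <- c(0.29, 0.40, 0.86)
  a[, "seed", "root"] <- c(0.045, 0.030, 0.015)
  a[, "seed", "stem"] <- c(0.050, 0.035, 0.015)
  a
}

rlnorm_composition <- function(n, mu, sigma, prefix) {
  x <- stats::rlnorm(n, meanlog = mu, sdlog = sigma)
  stats::setNames(x / sum(x), paste0(prefix, "_", seq_len(n)))
}

#' Simulate the source community pools
#'
#' Draws the four seed-lot pools, the undiluted soil pool (S1), the diluted
#' soil pool (S2 = [dilute_pool()] of S1), and the external unknown-origin
#' pool, each with lognormal relative abundances normalised to 1. A
#' configured number of each seed lot's taxa is shared with the soil pool.
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed for this stage's stream.
#' @return list with `seed_pools` (named list per lot, names
#'   `genotype.year`), `soil_pools` (list `S1`, `S2`), `unknown_pool`, and
#'   `membership` (data.frame asv x pool flags).
#' @export
simulate_source_pools <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_rng(seed, {
    soil_s1 <- rlnorm_composition(cfg$n_soil_taxa, cfg$lognormal_mu,
                                  cfg$lognormal_sigma, "soil")
    soil_s2 <- dilute_pool(soil_s1, cfg$dilution_exponent, cfg$inoculum_size)
    seed_pools <- list()
    for (g in cfg$genotypes) for (y in cfg$years) {
      lot <- paste(g, y, sep = ".")
      n <- cfg$n_seed_taxa[[y]]
      shared <- sample(names(soil_s1), cfg$seed_soil_overlap)
      own <- paste0("seed", gsub("[^A-Za-z0-9]", "", lot), "_",
                    seq_len(n - cfg$seed_soil_overlap))
      x <- stats::rlnorm(n, cfg$lognormal_mu, cfg$lognormal_sigma)
      seed_pools[[lot]] <- stats::setNames(x / sum(x), c(shared, own))
    }
    unknown <- rlnorm_composition(cfg$unknown_richness, cfg$lognormal_mu,
                                  cfg$lognormal_sigma, "unk")
    all_asvs <- unique(c(names(soil_s1), unlist(lapply(seed_pools, names)),
                         names(unknown)))
    membership <- data.frame(asv = all_asvs,
                             in_soil_S1 = all_asvs %in% names(soil_s1),
                             in_soil_S2 = all_asvs %in% names(soil_s2),
                             in_unknown = all_asvs %in% names(unknown))
    for (lot in names(seed_pools)) {
      membership[[paste0("in_seed_", lot)]] <- all_asvs %in% names(seed_pools[[lot]])
    }
    list(seed_pools = seed_pools,
         soil_pools = list(S1 = soil_s1, S2 = soil_s2),
         unknown_pool = unknown,
         membership = membership)
  })
}

#' Dilution-to-extinction of a community pool
#'
#' Emulates serial 1:10 dilution followed by recolonisation to a fixed
#' biomass: each taxon's survivor count is Poisson with mean
#' `inoculum_size x abundance x 10^-exponent`; taxa with zero survivors go
#' extinct and the survivors' original relative abundances are renormalised
#' (regrowth restores total biomass, not the lost taxa).
#'
#' @param pool named composition vector summing to 1.
#' @param exponent dilution exponent d >= 0.
#' @param inoculum_size cells transferred at d = 0.
#' @param seed optional integer seed.
#' @return named composition of survivors summing to 1, with attributes
#'   `survivor_counts` (the per-taxon Poisson draw over all input taxa) and
#'   `n_extinct`.
#' @export
dilute_pool <- function(pool, exponent, inoculum_size, seed = NULL) {
  stopifnot(exponent >= 0, inoculum_size >= 1, abs(sum(pool) - 1) < 1e-8)
  with_rng(seed, {
    lambda <- inoculum_size * pool * 10^(-exponent)
    counts <- stats::rpois(length(pool), lambda)
    names(counts) <- names(pool)
    alive <- counts > 0
    if (!any(alive)) stop("dilution drove the whole pool extinct")
    out <- pool[alive] / sum(pool[alive])
    attr(out, "survivor_counts") <- counts
    attr(out, "n_extinct") <- sum(!alive)
    out
  })
}

#' Simulate one seedling community from its source pools
#'
#' Every source taxon is transmitted independently with the probability
#' configured for its true abundance class, source pool, and recipient
#' compartment (a taxon present in both pools may arrive via either
#' channel). Transmitted taxa get seedling abundances from a fresh lognormal
#' draw whose normal score is blended with the taxon's source-abundance
#' score with weight `rho` (Gaussian-copula style: `rho = 1` preserves
#' source ranks, `rho = 0` decouples them). Unknown-pool taxa join
#' independently with probability `unknown_p` and collectively receive the
#' `unknown_share` of relative abundance.
#'
#' @param seed_pool,soil_pool,unknown_pool named compositions.
#' @param cfg a [sim_config()].
#' @param compartment `"root"` or `"stem"`.
#' @param seed optional integer seed.
#' @return list with `composition` (named, sums to 1) and `truth`
#'   (data.frame per candidate taxon: pool memberships, per-channel
#'   transmission indicators, inclusion, class in each source).
#' @export
simulate_seedling <- function(seed_pool, soil_pool, unknown_pool, cfg,
                              compartment = c("root", "stem"), seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  compartment <- match.arg(compartment)
  with_rng(seed, {
    seed_cls <- classify_abundance(seed_pool, cfg$class_thresholds)
    soil_cls <- classify_abundance(soil_pool, cfg$class_thresholds)
    p_seed <- cfg$p_transmission[as.character(seed_cls), "seed", compartment]
    p_soil <- cfg$p_transmission[as.character(soil_cls), "soil", compartment]
    via_seed <- stats::runif(length(seed_pool)) < p_seed
    via_soil <- stats::runif(length(soil_pool)) < p_soil
    transmitted <- union(names(seed_pool)[via_seed], names(soil_pool)[via_soil])
    incl_unknown <- stats::runif(length(unknown_pool)) < cfg$unknown_p
    unknown_in <- names(unknown_pool)[incl_unknown]
    if (!length(transmitted) && (!length(unknown_in) || cfg$unknown_share == 0)) {
      stop("empty seedling community: nothing transmitted and no unknown-pool share")
    }

    comp <- numeric(0)
    if (length(transmitted)) {
      src_ab <- pmax(seed_pool[match(transmitted, names(seed_pool))],
                     soil_pool[match(transmitted, names(soil_pool))], na.rm = TRUE)
      n_t <- length(transmitted)
      q <- stats::qnorm((rank(src_ab, ties.method = "first") - 0.5) / n_t)
      eps <- stats::rnorm(n_t)
      latent <- cfg$rho * q + sqrt(1 - cfg$rho^2) * eps
      w <- exp(cfg$lognormal_sigma * latent)
      share <- if (length(unknown_in) && cfg$unknown_share > 0) 1 - cfg$unknown_share else 1
      comp <- stats::setNames(share * w / sum(w), transmitted)
    }
    if (length(unknown_in) && cfg$unknown_share > 0) {
      wu <- unknown_pool[unknown_in]
      share_u <- if (length(transmitted)) cfg$unknown_share else 1
      comp <- c(comp, stats::setNames(share_u * wu / sum(wu), unknown_in))
    }

    cand <- unique(c(names(seed_pool), names(soil_pool), names(unknown_pool)))
    truth <- data.frame(
      asv = cand,
      in_seed_pool = cand %in% names(seed_pool),
      in_soil_pool = cand %in% names(soil_pool),
      in_unknown_pool = cand %in% names(unknown_pool),
      seed_class = as.character(seed_cls[match(cand, names(seed_pool))]),
      soil_class = as.character(soil_cls[match(cand, names(soil_pool))]),
      transmitted_via_seed = cand %in% names(seed_pool)[via_seed],
      transmitted_via_soil = cand %in% names(soil_pool)[via_soil],
      included_unknown = cand %in% unknown_in,
      in_seedling = cand %in% names(comp),
      row.names = NULL)
    list(composition = comp, truth = truth)
  })
}

#' Multinomial read sampling
#'
#' @param composition named relative-abundance vector summing to 1.
#' @param depth number of reads to draw.
#' @param seed optional integer seed.
#' @return named integer count vector summing to `depth`.
#' @export
sample_reads <- function(composition, depth, seed = NULL) {
  if (depth < 1) stop("depth must be >= 1")
  if (abs(sum(composition) - 1) > 1e-6) stop("composition must sum to 1")
  with_rng(seed, {
    stats::setNames(stats::rmultinom(1, depth, composition)[, 1], names(composition))
  })
}

#' Generate a full synthetic coalescence dataset
#'
#' Builds the complete factorial sample set of the emulated design: 4 seed
#' lots and 2 soils sequenced in triplicate as source samples, and for every
#' soil x seed lot x stage x compartment one simulated seedling community
#' sequenced as 3 replicate samples (replicate variation enters only through
#' read sampling; the underlying community, and hence the transmission
#' truth, is fixed within a context). Deterministic given `cfg$rng_seed`.
#'
#' A random coalescent phylogeny over all taxa is attached so phylogenetic
#' diversity can be exercised end to end; it carries no transmission signal.
#'
#' @param cfg a [sim_config()].
#' @return list with `table` (a [feature_table()] of all samples, zero-total
#'   taxa dropped), `tree` (rooted `phylo` over every registry taxon), and
#'   `truth` (list: `pools`, per-context `seedlings`, and the config) of
#'   class `sim_truth`.
#' @export
generate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  seed0 <- cfg$rng_seed
  pools <- simulate_source_pools(cfg, derive_seed(seed0, "pools"))

  counts <- list(); meta <- list()
  add_sample <- function(id, reads, md) {
    counts[[id]] <<- reads
    meta[[id]] <<- md
  }
  reps <- LETTERS[seq_len(cfg$n_replicates)]

  for (lot in names(pools$seed_pools)) {
    gy <- strsplit(lot, ".", fixed = TRUE)[[1]]
    for (r in reps) {
      id <- paste("seed", lot, r, sep = ".")
      add_sample(id,
                 sample_reads(pools$seed_pools[[lot]], cfg$depth_seed,
                              derive_seed(seed0, paste0("reads.", id))),
                 data.frame(compartment = "seed", soil = NA, genotype = gy[1],
                            year = gy[2], stage = NA, replicate = r))
    }
  }
  for (s in cfg$soils) {
    for (r in reps) {
      id <- paste("soil", s, r, sep = ".")
      add_sample(id,
                 sample_reads(pools$soil_pools[[s]], cfg$depth_soil,
                              derive_seed(seed0, paste0("reads.", id))),
                 data.frame(compartment = "soil", soil = s, genotype = NA,
                            year = NA, stage = NA, replicate = r))
    }
  }

  seedling_truth <- list()
  for (s in cfg$soils) for (lot in names(pools$seed_pools)) {
    gy <- strsplit(lot, ".", fixed = TRUE)[[1]]
    for (st in cfg$stages) for (cp in c("root", "stem")) {
      ctx <- paste(cp, s, lot, st, sep = ".")
      sim <- simulate_seedling(pools$seed_pools[[lot]], pools$soil_pools[[s]],
                               pools$unknown_pool, cfg, cp,
                               derive_seed(seed0, paste0("seedling.", ctx)))
      seedling_truth[[ctx]] <- sim$truth
      for (r in reps) {
        id <- paste(ctx, r, sep = ".")
        add_sample(id,
                   sample_reads(sim$composition, cfg$depth_plant,
                                derive_seed(seed0, paste0("reads.", id))),
                   data.frame(compartment = cp, soil = s, genotype = gy[1],
                              year = gy[2], stage = st, replicate = r))
      }
    }
  }

  all_asvs <- sort(unique(unlist(lapply(counts, names))))
  m <- matrix(0L, nrow = length(counts), ncol = length(all_asvs),
              dimnames = list(names(counts), all_asvs))
  for (id in names(counts)) {
    m[id, names(counts[[id]])] <- as.integer(counts[[id]])
  }
  m <- m[, colSums(m) > 0, drop = FALSE]
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- names(counts)

  registry <- sort(unique(c(pools$membership$asv, colnames(m))))
  tree <- with_rng(derive_seed(seed0, "tree"), {
    tr <- ape::rcoal(length(registry))
    tr$tip.label <- sample(registry)
    tr
  })

  truth <- structure(list(pools = pools, seedlings = seedling_truth,
                          config = cfg), class = "sim_truth")
  list(table = feature_table(m, metadata = metadata), tree = tree, truth = truth)
}
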