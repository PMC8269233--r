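test_that("source pools are normalised compositions with the configured richness and overlap", {
  cfg <- sim_config(n_seed_taxa = c(Y1 = 30, Y2 = 50), n_soil_taxa = 120,
                    seed_soil_overlap = 5, unknown_richness = 40,
                    dilution_exponent = 2, inoculum_size = 1e6, rng_seed = 3)
  pools <- simulate_source_pools(cfg, seed = 3)
  expect_length(pools$seed_pools, 4)
  expect_length(pools$seed_pools[["Boston.Y1"]], 30)
  expect_length(pools$seed_pools[["Major.Y2"]], 50)
  expect_length(pools$soil_pools$S1, 120)
  for (p in c(pools$seed_pools, pools$soil_pools, list(pools$unknown_pool))) {
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  shared <- intersect(names(pools$seed_pools[["Boston.Y1"]]),
                      names(pools$soil_pools$S1))
  expect_length(shared, 5)

  cfg0 <- sim_config(seed_soil_overlap = 0, n_soil_taxa = 50,
                     n_seed_taxa = c(Y1 = 10, Y2 = 10), unknown_richness = 10)
  p0 <- simulate_source_pools(cfg0, seed = 1)
  expect_length(intersect(names(p0$seed_pools[[1]]), names(p0$soil_pools$S1)), 0)

  expect_error(sim_config(seed_soil_overlap = 60,
                          n_seed_taxa = c(Y1 = 10, Y2 = 10), n_soil_taxa = 50),
               "overlap")
})

test_that("dilution-to-extinction: survival matches the Poisson oracle and richness declines", {
  set.seed(5)
  x <- rlnorm(200, 0, 1.5)
  pool <- setNames(x / sum(x), paste0("t", 1:200))

  # survival probability oracle: 1 - exp(-lambda) per taxon
  lam <- 5e4 * pool * 10^-2
  exp_survivors <- sum(1 - exp(-lam))
  sd_survivors <- sqrt(sum((1 - exp(-lam)) * exp(-lam)))
  n_surv <- vapply(1:200, function(i) {
    length(dilute_pool(pool, 2, 5e4, seed = i))
  }, 0L)
  expect_lt(abs(mean(n_surv) - exp_survivors), 3 * sd_survivors / sqrt(200))

  # d = 0 with a huge inoculum keeps everything
  full <- dilute_pool(pool, 0, 1e9, seed = 1)
  expect_length(full, 200)
  expect_equal(sum(full), 1, tolerance = 1e-12)

  # richness is monotone non-increasing in d on average
  mean_rich <- vapply(c(0, 2, 4, 6), function(d) {
    mean(vapply(1:30, function(i) length(dilute_pool(pool, d, 1e7, seed = i)), 0L))
  }, 0)
  expect_true(all(diff(mean_rich) <= 0))

  # survivor counts attribute covers every input taxon
  dl <- dilute_pool(pool, 4, 1e7, seed = 9)
  expect_length(attr(dl, "survivor_counts"), 200)
  expect_identical(length(dl) + attr(dl, "n_extinct"), 200L)
})

test_that("seedling simulation respects transmission limits and the unknown pool", {
  mk_cfg <- function(p, rho = 0.2, unknown_share = 0.2, unknown_p = 0.5) {
    pt <- default_p_transmission(); pt[] <- p
    sim_config(p_transmission = pt, rho = rho, unknown_share = unknown_share,
               unknown_p = unknown_p, n_seed_taxa = c(Y1 = 10, Y2 = 10),
               n_soil_taxa = 40, unknown_richness = 15, seed_soil_overlap = 0)
  }
  pools <- simulate_source_pools(mk_cfg(0.5), seed = 2)

  # nothing transmitted: only unknown-pool taxa
  s0 <- simulate_seedling(pools$seed_pools[[1]], pools$soil_pools$S1,
                          pools$unknown_pool, mk_cfg(0), "root", seed = 4)
  expect_true(all(names(s0$composition) %in% names(pools$unknown_pool)))
  expect_equal(sum(s0$composition), 1, tolerance = 1e-12)

  # everything transmitted, ranks preserved, no unknown share
  cfg1 <- mk_cfg(1, rho = 1, unknown_share = 0)
  s1 <- simulate_seedling(pools$seed_pools[[1]], pools$soil_pools$S1,
                          pools$unknown_pool, cfg1, "root", seed = 4)
  src_union <- union(names(pools$seed_pools[[1]]), names(pools$soil_pools$S1))
  expect_setequal(names(s1$composition), src_union)
  src_ab <- pmax(pools$seed_pools[[1]][match(names(s1$composition),
                                             names(pools$seed_pools[[1]]))],
                 pools$soil_pools$S1[match(names(s1$composition),
                                           names(pools$soil_pools$S1))],
                 na.rm = TRUE)
  expect_identical(order(s1$composition), order(as.numeric(src_ab)))

  # nothing transmitted and no unknown share: empty community is an error
  expect_error(simulate_seedling(pools$seed_pools[[1]], pools$soil_pools$S1,
                                 pools$unknown_pool, mk_cfg(0, unknown_share = 0),
                                 "root", seed = 4),
               "empty seedling")
})

test_that("per-class Bernoulli transmission matches the binomial oracle", {
  # 1000 equal-abundance taxa all sit in the intermediate class (0.1% each)
  pool <- setNames(rep(1 / 1000, 1000), paste0("u", 1:1000))
  pt <- default_p_transmission()
  pt["intermediate", "soil", "root"] <- 0.9
  cfg <- sim_config(p_transmission = pt, unknown_share = 0.2,
                    n_seed_taxa = c(Y1 = 10, Y2 = 10), n_soil_taxa = 40,
                    unknown_richness = 15, seed_soil_overlap = 0)
  tiny_seed <- setNames(rep(0.1, 10), paste0("sd", 1:10))
  unk <- setNames(rep(1 / 15, 15), paste0("uk", 1:15))
  s <- simulate_seedling(tiny_seed, pool, unk, cfg, "root", seed = 42)
  frac <- mean(s$truth$transmitted_via_soil[s$truth$in_soil_pool])
  se <- sqrt(0.9 * 0.1 / 1000)
  expect_lt(abs(frac - 0.9), 3 * se)
})

test_that("multinomial read sampling has the right support, totals, and moments", {
  comp <- c(one = 1)
  r <- sample_reads(comp, 500, seed = 1)
  expect_identical(unname(r), 500L)

  set.seed(2)
  comp3 <- c(a = 0.5, b = 0.3, c = 0.2)
  draws <- vapply(1:10000, function(i) sample_reads(comp3, 50, seed = i), integer(3))
  expect_true(all(colSums(draws) == 50))
  for (i in 1:3) {
    mu <- 50 * comp3[i]
    se_mean <- sqrt(50 * comp3[i] * (1 - comp3[i]) / 10000)
    expect_lt(abs(mean(draws[i, ]) - mu), 3 * se_mean)
  }
  expect_error(sample_reads(comp3, 0), ">= 1")
  expect_error(sample_reads(c(0.5, 0.2), 10), "sum to 1")
})

test_that("generate_dataset builds the full factorial design deterministically with complete truth", {
  cfg <- sim_config(n_seed_taxa = c(Y1 = 15, Y2 = 25), n_soil_taxa = 60,
                    seed_soil_overlap = 5, unknown_richness = 20,
                    depth_soil = 2000, depth_seed = 500, depth_plant = 300,
                    dilution_exponent = 2, inoculum_size = 1e6, rng_seed = 11)
  ds <- generate_dataset(cfg)
  md <- ds$table$metadata
  expect_identical(sum(md$compartment %in% c("root", "stem")), 96L)
  expect_identical(sum(md$compartment == "seed"), 12L)
  expect_identical(sum(md$compartment == "soil"), 6L)
  expect_identical(nrow(unique(md[md$compartment == "seed", c("genotype", "year")])), 4L)
  expect_setequal(unique(md$soil[md$compartment == "soil"]), c("S1", "S2"))

  # determinism
  ds2 <- generate_dataset(cfg)
  expect_identical(ds$table$counts, ds2$table$counts)
  expect_identical(ds$tree$edge.length, ds2$tree$edge.length)

  # every observed seedling ASV has a truth record in its context
  plant_ids <- rownames(md)[md$compartment == "root" & md$soil == "S1" &
                              md$genotype == "Boston" & md$year == "Y1" &
                              md$stage == "d07"]
  obs <- colnames(ds$table$counts)[colSums(ds$table$counts[plant_ids, , drop = FALSE]) > 0]
  tr <- ds$truth$seedlings[["root.S1.Boston.Y1.d07"]]
  expect_true(all(obs %in% tr$asv))
  expect_true(all(obs %in% tr$asv[tr$in_seedling]))

  # the tree spans every registry taxon with non-negative branch lengths
  expect_true(all(colnames(ds$table$counts) %in% ds$tree$tip.label))
  expect_true(all(ds$tree$edge.length >= 0))
})

test_that("unknown-origin fraction tracks simulated truth at depth and inflates when shallow", {
  base <- list(n_seed_taxa = c(Y1 = 20, Y2 = 20), n_soil_taxa = 80,
               seed_soil_overlap = 5, unknown_richness = 40,
               dilution_exponent = 1, inoculum_size = 1e7,
               depth_seed = 5000, depth_plant = 20000, rng_seed = 19)
  # undersampling the source pool is what manufactures spurious "unknown"s
  deep <- generate_dataset(do.call(sim_config, c(base, list(depth_soil = 20000))))
  shallow <- generate_dataset(do.call(sim_config, c(base, list(depth_soil = 60))))

  unknown_frac <- function(ds) {
    ft <- ds$table
    sdl <- detect_presence(ft, list(compartment = "root", soil = "S1",
                                    genotype = "Boston", year = "Y1", stage = "d07"))
    seed <- detect_presence(ft, list(compartment = "seed",
                                     genotype = "Boston", year = "Y1"))
    soil <- detect_presence(ft, list(compartment = "soil", soil = "S1"))
    origin_membership(assign_origin(sdl, seed, soil))[["unknown"]]
  }
  truth_frac <- function(ds) {
    tr <- ds$truth$seedlings[["root.S1.Boston.Y1.d07"]]
    inc <- tr[tr$in_seedling, ]
    mean(inc$included_unknown & !inc$transmitted_via_seed & !inc$transmitted_via_soil)
  }
  expect_lt(abs(unknown_frac(deep) - truth_frac(deep)), 0.1)
  expect_gt(unknown_frac(shallow), unknown_frac(deep))
})
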