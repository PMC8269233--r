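test_that("detection follows the min_count / min_reps rule on non-rarefied counts", {
  m <- rbind("seed.A" = c(a = 0L, b = 5L, c = 0L, d = 5L),
             "seed.B" = c(a = 0L, b = 0L, c = 0L, d = 1L),
             "seed.C" = c(a = 3L, b = 0L, c = 0L, d = 0L))
  md <- data.frame(compartment = "seed", replicate = c("A", "B", "C"),
                   row.names = rownames(m))
  ft <- feature_table(m, metadata = md)

  ps <- detect_presence(ft, list(compartment = "seed"))
  expect_setequal(ps$asvs, c("a", "b", "d"))   # one detection suffices; c never seen

  ps2 <- detect_presence(ft, list(compartment = "seed"), min_reps = 2)
  expect_setequal(ps2$asvs, "d")               # b: (5,0,0) fails, d: (5,1,0) passes

  ps3 <- detect_presence(ft, list(compartment = "seed"), min_count = 2, min_reps = 2)
  expect_length(ps3$asvs, 0)

  expect_error(detect_presence(ft, list(compartment = "root")), "no samples match")
})

test_that("prevalence matrix conserves set sizes and rejects duplicate contexts", {
  sets <- list(presence_set(c("A", "B"), "ctx1"), presence_set(c("B", "C"), "ctx2"))
  pm <- prevalence_matrix(sets)
  expect_identical(dim(pm), c(3L, 2L))
  expect_identical(pm["B", ], c(ctx1 = 1L, ctx2 = 1L))
  expect_identical(colSums(pm), c(ctx1 = 2, ctx2 = 2))

  disj <- prevalence_matrix(list(presence_set("A", "p"), presence_set("B", "q")))
  expect_true(all(rowSums(disj) == 1))

  expect_error(prevalence_matrix(list(presence_set("A", "x"), presence_set("B", "x"))),
               "duplicate context")
  expect_error(prevalence_matrix(list(presence_set("A", "x"))), "at least 2")
})

test_that("exclusive intersection counts enumerate correctly and conserve the union", {
  pm <- prevalence_matrix(list(presence_set(c("A", "B"), "s1"),
                               presence_set(c("B", "C"), "s2")))
  ui <- upset_intersections(pm)
  expect_identical(sum(ui$count), 3L)
  expect_identical(ui$count[ui$combination == "s1 & s2"], 1L)
  expect_identical(ui$count[ui$combination == "s1"], 1L)
  expect_identical(ui$count[ui$combination == "s2"], 1L)

  same <- prevalence_matrix(list(presence_set(c("A", "B"), "u"),
                                 presence_set(c("A", "B"), "v")))
  us <- upset_intersections(same)
  expect_identical(us$combination, "u & v")
  expect_identical(us$count, 2L)
})

test_that("origin assignment is the expected partition of the seedling set", {
  om <- assign_origin(c("a", "b", "c", "d"), seed = c("a", "b"), soil = c("b", "c"))
  got <- setNames(as.character(om$assignment$category), om$assignment$asv)
  expect_identical(got, c(a = "seed_only", b = "both", c = "soil_only", d = "unknown"))
  expect_setequal(om$soil_detected, c("b", "c"))
  expect_setequal(om$seed_detected, c("a", "b"))

  om0 <- assign_origin(c("x", "y"), character(0), character(0))
  expect_true(all(om0$assignment$category == "unknown"))

  # categories partition the seedling set
  sizes <- table(om$assignment$category)
  expect_identical(sum(sizes), 4L)
})

test_that("membership and abundance fractions sum to one with consistent aggregates", {
  om <- assign_origin(c("a", "b", "c", "d"), seed = c("a", "b"), soil = c("b", "c"))
  memb <- origin_membership(om)
  expect_equal(unname(memb[c("seed_only", "soil_only", "both", "unknown")]),
               rep(0.25, 4))
  expect_equal(memb[["soil_detected"]], memb[["soil_only"]] + memb[["both"]])

  rel <- c(a = 0.1, b = 0.2, c = 0.3, d = 0.4)
  ab <- origin_abundance(om, rel)
  expect_equal(sum(ab[c("seed_only", "soil_only", "both", "unknown")]), 1,
               tolerance = 1e-9)
  # uniform abundances make abundance fractions equal membership fractions
  ab_u <- origin_abundance(om, c(a = 0.25, b = 0.25, c = 0.25, d = 0.25))
  expect_equal(ab_u, origin_membership(om))

  om_unk <- assign_origin(c("p", "q"), character(0), character(0))
  expect_equal(origin_membership(om_unk)[["unknown"]], 1)

  expect_error(origin_membership(assign_origin(character(0), "a", "b")), "empty")
  expect_error(origin_abundance(om, rel[1:2]), "missing")
})

test_that("mean relative abundance is zero-inclusive and normalised", {
  m <- rbind(s1 = c(a = 10L, b = 90L), s2 = c(a = 10L, b = 90L),
             s3 = c(a = 10L, b = 90L))
  md <- data.frame(compartment = rep("soil", nrow(m)), row.names = rownames(m))
  ft <- feature_table(m, metadata = md)
  rel <- mean_relative_abundance(ft, list(compartment = "soil"))
  expect_equal(rel[["a"]], 0.10)
  expect_equal(sum(rel), 1)

  m2 <- rbind(s1 = c(a = 30L, b = 70L), s2 = c(a = 0L, b = 100L))
  ft2 <- feature_table(m2, metadata = data.frame(compartment = rep("soil", 2),
                                                 row.names = rownames(m2)))
  rel2 <- mean_relative_abundance(ft2, list(compartment = "soil"))
  expect_equal(rel2[["a"]], 0.15)   # (0.30 + 0) / 2, zeros included

  m3 <- rbind(s1 = c(a = 1L, b = 1L), s2 = c(a = 0L, b = 0L))
  ft3 <- feature_table(m3, metadata = data.frame(compartment = rep("soil", 2),
                                                 row.names = rownames(m3)))
  expect_warning(rel3 <- mean_relative_abundance(ft3, list(compartment = "soil")),
                 "zero-total")
  expect_equal(rel3[["a"]], 0.5)
})

test_that("transmission success percentages, SE, and pooled view", {
  src <- presence_set(paste0("t", 1:10), "soil")
  r1 <- presence_set(c("t1", "t2", "t3", "zz"), "rep1")
  ts <- transmission_success(src, list(r1))
  expect_equal(ts$per_replicate, 30)
  expect_equal(ts$pooled, 30)

  ts0 <- transmission_success(src, presence_set(c("x", "y"), "r"))
  expect_equal(ts0$mean, 0)

  # replicates at 20 / 30 / 40 percent
  reps <- list(presence_set(paste0("t", 1:2), "a"),
               presence_set(paste0("t", 1:3), "b"),
               presence_set(paste0("t", 1:4), "c"))
  ts3 <- transmission_success(src, reps)
  expect_equal(ts3$mean, 30)
  expect_equal(ts3$se, 10 / sqrt(3), tolerance = 1e-12)
  expect_equal(ts3$pooled, 40)

  expect_error(transmission_success(presence_set(character(0), "empty"), reps),
               "empty source")
})

test_that("abundance classes: thresholds, boundaries, and totality", {
  cls <- classify_abundance(c(5e-5, 1e-4, 5e-3, 1e-2, 2e-2))
  expect_identical(as.character(cls),
                   c("rare", "intermediate", "intermediate", "intermediate", "abundant"))
  expect_error(classify_abundance(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(classify_abundance(c(-0.1)), "\\[0, 1\\]")

  set.seed(9)
  x <- runif(500)
  expect_false(anyNA(classify_abundance(x)))
  expect_identical(levels(classify_abundance(x)),
                   c("rare", "intermediate", "abundant"))
})

test_that("class-wise transmission rates count per class, undefined when class absent", {
  src <- c("a", "b", "c", "d", "e", "f")
  cls <- setNames(c("abundant", "abundant", "rare", "rare", "rare", "rare"), src)
  cr <- class_transmission_rates(src, cls, c("a", "b", "c", "zz"))
  expect_equal(cr$percentage[cr$class == "abundant"], 100)
  expect_equal(cr$percentage[cr$class == "rare"], 25)
  expect_true(is.na(cr$percentage[cr$class == "intermediate"]))
  expect_identical(cr$n_source[cr$class == "intermediate"], 0L)
  expect_error(class_transmission_rates(src, cls[1:3], "a"), "unclassified")
})

test_that("abundance pairing flags the 1:1 line strictly and drops non-transmitted taxa", {
  src_rel <- c(a = 0.005, b = 0.02, c = 0.3, d = 0.001)
  sdl_rel <- c(a = 0.03, b = 0.02, e = 0.5)
  pr <- abundance_pairing(src_rel, sdl_rel)
  expect_setequal(pr$asv, c("a", "b"))       # c, d not in seedling; e not in source
  expect_true(pr$above_line[pr$asv == "a"])
  expect_true(pr$became_abundant[pr$asv == "a"])
  expect_false(pr$above_line[pr$asv == "b"])  # equal abundances: strict inequality
  expect_identical(as.character(pr$source_class[pr$asv == "a"]), "intermediate")
})

test_that("taxonomic guild abundance aggregates matching genera", {
  m <- rbind(s1 = c(n1 = 4L, x1 = 96L), s2 = c(n1 = 6L, x1 = 94L))
  md <- data.frame(compartment = rep("soil", nrow(m)), row.names = rownames(m))
  tax <- data.frame(genus = c("Nitrosospira", "Massilia"),
                    row.names = c("n1", "x1"))
  ft <- feature_table(m, metadata = md, taxonomy = tax)

  r <- taxon_group_abundance(ft, list(compartment = "soil"),
                             c("Nitrosospira", "Nitrosovibrio"))
  expect_equal(r$mean, 5)
  expect_equal(r$se, 1)

  r0 <- taxon_group_abundance(ft, list(compartment = "soil"), "Nitrobacter")
  expect_equal(r0$mean, 0)
  rall <- taxon_group_abundance(ft, list(compartment = "soil"),
                                c("Nitrosospira", "Massilia"))
  expect_equal(rall$mean, 100)

  ft_notax <- feature_table(m, metadata = md)
  expect_error(taxon_group_abundance(ft_notax, list(compartment = "soil"), "X"),
               "taxonomy")
})

test_that("transmission statistics are invariant to relabeling and monotone in the seedling set", {
  set.seed(13)
  for (i in 1:25) {
    sets <- rand_instance(i)
    src <- sets[[1]]; sdl <- sets[[2]]
    ts <- transmission_success(src, list(sdl))

    # relabel every taxon consistently
    univ <- unique(unlist(sets))
    map <- setNames(paste0("R", seq_along(univ)), univ)
    ts_r <- transmission_success(map[src], list(unname(map[sdl])))
    expect_equal(ts$per_replicate, ts_r$per_replicate)

    # enlarging the seedling set never decreases the percentage
    extra <- unique(c(sdl, sample(univ, 2)))
    expect_gte(transmission_success(src, list(extra))$mean, ts$mean)
  }
})

test_that("set-algebra operations agree with brute-force enumeration on random instances", {
  for (i in 1:60) {
    sets <- rand_instance(i)
    keys <- names(sets)

    ui <- upset_intersections(prevalence_matrix(
      lapply(keys, function(k) presence_set(sets[[k]], k))))
    bf <- bf_upset(sets)
    got <- setNames(ui$count, ui$combination)
    expect_identical(got[order(names(got))],
                     bf[order(names(bf))])

    if (length(sets) >= 3) {
      om <- assign_origin(sets[[3]], sets[[1]], sets[[2]])
      bfo <- bf_assign_origin(sets[[3]], sets[[1]], sets[[2]])
      expect_identical(setNames(as.character(om$assignment$category),
                                om$assignment$asv), bfo)
    }
  }
})
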