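#' Full transmission analysis of a seed-by-soil design
#'
#' Runs the whole set-based source-tracking layer on a NON-rarefied feature
#' table: per-pool detection, prevalence/UpSet intersections per soil and
#' stage, origin assignment and membership/abundance fractions for every
#' seedling context (compartment x soil x seed lot x stage), per-replicate
#' transmission success from every source pool, class-wise transmission
#' rates, and source-vs-seedling abundance pairing at the final stage.
#'
#' Seedling contexts are conditioned on soil x stage x compartment; the seed
#' source pool of a seedling is the sown genotype x year lot, the soil pool
#' the pot's soil.
#'
#' @param ft a [feature_table()] with design metadata (non-rarefied counts).
#' @param config a [pipeline_config()] (detection rule and class
#'   thresholds).
#' @return named list of data.frames: `pool_sizes`, `upset`,
#'   `origin_fractions`, `transmission`, `class_rates`, `pairing`.
#' @export
transmission_analysis <- function(ft, config = pipeline_config()) {
  stopifnot(inherits(ft, "feature_table"))
  md <- ft$metadata
  if (is.null(md)) stop("feature table has no metadata")
  mc <- config$min_count; mr <- config$min_reps
  thr <- config$class_thresholds

  seed_md <- md[md$compartment == "seed", c("genotype", "year")]
  lots <- unique(seed_md[stats::complete.cases(seed_md), , drop = FALSE])
  soils <- sort(unique(as.character(md$soil[md$compartment == "soil"])))
  stages <- sort(unique(as.character(md$stage[md$compartment %in% c("root", "stem")])))
  comps <- intersect(c("root", "stem"), unique(as.character(md$compartment)))
  final_stage <- stages[length(stages)]
  if (!nrow(lots) || !length(soils) || !length(comps)) {
    stop("metadata lacks seed lots, soils, or seedling compartments")
  }

  detect1 <- function(filter) detect_presence(ft, filter, mc, mr)
  lot_key <- function(g, y) paste(g, y, sep = ".")

  seed_sets <- list()
  for (i in seq_len(nrow(lots))) {
    g <- as.character(lots$genotype[i]); y <- as.character(lots$year[i])
    seed_sets[[lot_key(g, y)]] <-
      detect1(list(compartment = "seed", genotype = g, year = y))
  }
  seed_all <- presence_set(sort(unique(unlist(lapply(seed_sets, `[[`, "asvs")))),
                           context = "compartment=seed")
  soil_sets <- lapply(stats::setNames(soils, soils), function(s) {
    detect1(list(compartment = "soil", soil = s))
  })

  pool_sizes <- data.frame(
    pool = c(names(seed_sets), names(soil_sets)),
    type = c(rep("seed", length(seed_sets)), rep("soil", length(soil_sets))),
    n_asvs = c(vapply(seed_sets, function(s) length(s$asvs), 0L),
               vapply(soil_sets, function(s) length(s$asvs), 0L)))

  # prevalence / UpSet intersections per soil x stage panel
  upset <- list()
  for (s in soils) for (st in stages) {
    panel <- list(
      presence_set(seed_all$asvs, "seed"),
      presence_set(soil_sets[[s]]$asvs, "soil"))
    for (cp in comps) {
      panel <- c(panel, list(presence_set(
        detect1(list(compartment = cp, soil = s, stage = st))$asvs, cp)))
    }
    ui <- upset_intersections(prevalence_matrix(panel))
    ui$soil <- s; ui$stage <- st
    upset[[paste(s, st)]] <- ui
  }
  upset <- do.call(rbind, c(upset, make.row.names = FALSE))

  origin <- list(); transmission <- list(); class_rates <- list()
  reps <- sort(unique(as.character(md$replicate[md$compartment %in% comps])))
  for (s in soils) for (i in seq_len(nrow(lots))) {
    g <- as.character(lots$genotype[i]); y <- as.character(lots$year[i])
    lk <- lot_key(g, y)
    soil_rel <- mean_relative_abundance(ft, list(compartment = "soil", soil = s))
    seed_rel <- mean_relative_abundance(ft, list(compartment = "seed",
                                                 genotype = g, year = y))
    for (st in stages) for (cp in comps) {
      flt <- list(compartment = cp, soil = s, genotype = g, year = y, stage = st)
      sdl <- detect1(flt)
      om <- assign_origin(sdl, seed_sets[[lk]], soil_sets[[s]])
      memb <- origin_membership(om)
      ab <- origin_abundance(om, mean_relative_abundance(ft, flt))
      origin[[length(origin) + 1L]] <- data.frame(
        compartment = cp, soil = s, genotype = g, year = y, stage = st,
        n_seedling_asvs = length(sdl$asvs),
        category = names(memb), membership = as.numeric(memb),
        abundance = as.numeric(ab), row.names = NULL)

      rep_sets <- lapply(reps, function(r) detect1(c(flt, list(replicate = r))))
      for (src_name in c(lk, s)) {
        src <- if (src_name == s) soil_sets[[s]] else seed_sets[[lk]]
        src_type <- if (src_name == s) "soil" else "seed"
        ts <- transmission_success(src, rep_sets)
        transmission[[length(transmission) + 1L]] <- data.frame(
          source = src_name, source_type = src_type, compartment = cp,
          soil = s, genotype = g, year = y, stage = st,
          n_source = ts$n_source, mean = ts$mean, se = ts$se,
          pooled = ts$pooled, n_transmitted_pooled = ts$n_transmitted_pooled)
        rel <- if (src_type == "soil") soil_rel else seed_rel
        cr <- class_transmission_rates(src, classify_abundance(rel, thr), sdl)
        cr <- cbind(data.frame(source = src_name, source_type = src_type,
                               compartment = cp, soil = s, genotype = g,
                               year = y, stage = st), cr)
        class_rates[[length(class_rates) + 1L]] <- cr
      }
    }
  }
  origin <- do.call(rbind, c(origin, make.row.names = FALSE))
  transmission <- do.call(rbind, c(transmission, make.row.names = FALSE))
  class_rates <- do.call(rbind, c(class_rates, make.row.names = FALSE))

  # source vs seedling abundance pairing at the final stage
  pairing <- list()
  for (cp in comps) {
    for (s in soils) {
      src_rel <- mean_relative_abundance(ft, list(compartment = "soil", soil = s))
      sdl_flt <- list(compartment = cp, soil = s, stage = final_stage)
      pr <- abundance_pairing(src_rel, mean_relative_abundance(ft, sdl_flt),
                              source = soil_sets[[s]], seedling = detect1(sdl_flt),
                              thresholds = thr)
      if (nrow(pr)) {
        pr <- cbind(data.frame(source = s, source_type = "soil",
                               compartment = cp, stage = final_stage), pr)
        pairing[[length(pairing) + 1L]] <- pr
      }
    }
    for (i in seq_len(nrow(lots))) {
      g <- as.character(lots$genotype[i]); y <- as.character(lots$year[i])
      lk <- lot_key(g, y)
      src_rel <- mean_relative_abundance(ft, list(compartment = "seed",
                                                  genotype = g, year = y))
      sdl_flt <- list(compartment = cp, genotype = g, year = y, stage = final_stage)
      pr <- abundance_pairing(src_rel, mean_relative_abundance(ft, sdl_flt),
                              source = seed_sets[[lk]], seedling = detect1(sdl_flt),
                              thresholds = thr)
      if (nrow(pr)) {
        pr <- cbind(data.frame(source = lk, source_type = "seed",
                               compartment = cp, stage = final_stage), pr)
        pairing[[length(pairing) + 1L]] <- pr
      }
    }
  }
  pairing <- if (length(pairing)) do.call(rbind, c(pairing, make.row.names = FALSE))
             else data.frame()

  list(pool_sizes = pool_sizes, upset = upset, origin_fractions = origin,
       transmission = transmission, class_rates = class_rates, pairing = pairing)
}

#' Run the whole pipeline
#'
#' Fixed stage order: simulate (or ingest) -> rarefy -> alpha diversity ->
#' beta diversity with dispersion and sequential PERMANOVA -> transmission.
#' Diversity stages read the rarefied view of the table; the transmission
#' stage always reads the non-rarefied counts (the detection convention), so
#' the pipeline holds both views of the same data. All result tables plus a
#' JSON manifest are written to `out_dir`; the run is byte-identical for a
#' fixed `config$rng_seed`. The manifest is flushed even when a stage fails.
#'
#' @param out_dir output directory.
#' @param config a [pipeline_config()].
#' @param sim a [sim_config()] to simulate input data, or `NULL` when
#'   supplying `table`; its `rng_seed` is overridden by `config$rng_seed`.
#' @param table a [feature_table()] or path to a count-table TSV.
#' @param metadata metadata data.frame or TSV path (when `table` is a path
#'   or lacks metadata).
#' @param tree optional `phylo` or newick path for Faith's PD.
#' @param table_orientation orientation flag for a table read from file.
#' @param overwrite clobber existing outputs.
#' @return invisibly, a list with all result tables and the manifest.
#' @export
run_all <- function(out_dir, config = pipeline_config(), sim = NULL,
                    table = NULL, metadata = NULL, tree = NULL,
                    table_orientation = "samples", overwrite = FALSE) {
  seed0 <- config$rng_seed
  notes <- list()
  digests <- NULL

  if (is.null(table)) {
    sim <- sim %||% sim_config()
    sim$rng_seed <- seed0
    ds <- generate_dataset(sim)
    ft <- ds$table; tree <- ds$tree
    notes$input <- "simulated"
  } else {
    if (is.character(table)) {
      digests <- c(digests, table = unname(tools::md5sum(table)))
      table <- read_feature_table(table, orientation = table_orientation)
    }
    ft <- table
    if (!is.null(metadata)) {
      if (is.character(metadata)) {
        digests <- c(digests, metadata = unname(tools::md5sum(metadata)))
        metadata <- read_sample_metadata(metadata)
      }
      ft <- feature_table(ft$counts, metadata = metadata, taxonomy = ft$taxonomy)
    }
    if (is.null(ft$metadata)) stop("a metadata table is required")
    if (is.character(tree)) {
      digests <- c(digests, tree = unname(tools::md5sum(tree)))
      tree <- read_phylo(tree)
    }
    notes$input <- "ingested"
  }

  tables <- list()
  status <- "ok"
  run_err <- NULL
  tryCatch({
    md <- ft$metadata
    is_soil <- md$compartment == "soil"
    rare_soil <- rarefy_table(subset_samples(ft, list(compartment = "soil")),
                              config$depth_soil_bacteria,
                              derive_seed(seed0, "rarefy.soil"))
    rare_rest <- rarefy_table(
      subset_samples(ft, list(compartment = c("seed", "root", "stem"))),
      config$depth_plant, derive_seed(seed0, "rarefy.plant"))
    notes$dropped_at_rarefaction <- c(attr(rare_soil, "dropped"),
                                      attr(rare_rest, "dropped"))

    metrics <- c("observed_richness", "chao1",
                 if (!is.null(tree)) "faith_pd")
    alpha <- rbind(alpha_diversity(rare_soil, metrics, tree = tree),
                   alpha_diversity(rare_rest, metrics, tree = tree))
    amd <- ft$metadata[alpha$sample_id, , drop = FALSE]
    tables$alpha_diversity <- cbind(alpha, amd)

    # group tests on alpha: seed lots by year; root/stem by soil
    atests <- list()
    for (m in metrics) {
      v <- alpha[alpha$metric == m, ]
      vmd <- ft$metadata[v$sample_id, , drop = FALSE]
      sel <- vmd$compartment == "seed"
      if (sum(sel) >= 4) {
        r <- compare_alpha(v$value[sel], vmd$year[sel], "anova")
        atests[[length(atests) + 1L]] <- data.frame(
          metric = m, compartment = "seed", factor = "year",
          method = "anova", statistic = r$statistic, p_value = r$p_value)
      }
      for (cp in c("root", "stem")) {
        sel <- vmd$compartment == cp
        if (sum(sel) >= 4 && length(unique(vmd$soil[sel])) > 1) {
          r <- compare_alpha(v$value[sel], vmd$soil[sel], "anova")
          atests[[length(atests) + 1L]] <- data.frame(
            metric = m, compartment = cp, factor = "soil",
            method = "anova", statistic = r$statistic, p_value = r$p_value)
        }
      }
    }
    tables$alpha_tests <- do.call(rbind, c(atests, make.row.names = FALSE))

    # beta diversity per seedling compartment
    perm <- list(); disp <- list(); ords <- list()
    for (cp in c("root", "stem")) {
      sub <- subset_samples(rare_rest, list(compartment = cp))
      d <- bray_curtis(transform_log10p1(sub))
      smd <- sub$metadata
      pt <- permanova_terms(d, smd,
                            c("soil", "stage", "genotype:year",
                              "soil:genotype:year"),
                            n_perm = config$n_permutations,
                            seed = derive_seed(seed0, paste0("permanova.", cp)))
      pt$compartment <- cp
      perm[[cp]] <- pt
      dc <- dispersion_to_centroid(d, smd$soil)
      disp[[cp]] <- data.frame(compartment = cp,
                               sample_id = rownames(sub$counts),
                               soil = smd$soil,
                               distance_to_centroid = as.numeric(dc$distances),
                               wilcoxon_p = dc$wilcoxon_p)
      ord <- pcoa_ordination(d)
      k <- min(2L, ncol(ord$coordinates))
      ords[[cp]] <- data.frame(compartment = cp,
                               sample_id = rownames(sub$counts),
                               ord$coordinates[, seq_len(k), drop = FALSE])
    }
    tables$permanova <- do.call(rbind, c(perm, make.row.names = FALSE))
    tables$dispersion <- do.call(rbind, c(disp, make.row.names = FALSE))
    tables$ordination <- do.call(rbind, c(ords, make.row.names = FALSE))

    tx <- transmission_analysis(ft, config)
    tables <- c(tables, tx)
  }, error = function(e) {
    status <<- "failed"
    run_err <<- conditionMessage(e)
  })

  notes$status <- status
  if (!is.null(run_err)) notes$error <- run_err
  manifest <- write_result_tables(tables, out_dir, config = config,
                                  seed = seed0, notes = notes,
                                  input_digests = digests,
                                  overwrite = overwrite)
  if (status == "failed") stop("pipeline failed (manifest flushed): ", run_err)
  invisible(list(tables = tables, manifest = manifest))
}
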