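#' Detect the ASVs present in a compartment context
#'
#' Presence/absence on NON-rarefied counts: an ASV is recorded as present in
#' a context (a metadata filter, e.g. all seed samples of one genotype and
#' year) when it reaches `min_count` reads in at least `min_reps` of the
#' context's samples. The defaults (1 read in 1 sample) extend the
#' one-of-three-replicates seed rule uniformly to every compartment, giving
#' the most exhaustive presence-absence analysis; both knobs are exposed.
#'
#' @param ft a [feature_table()] with metadata (non-rarefied counts).
#' @param filter named list selecting the context's samples (see
#'   [subset_samples()]).
#' @param min_count minimum reads per sample to count a detection.
#' @param min_reps minimum number of samples with a detection.
#' @return a `presence_set`: list with `asvs` (sorted character vector),
#'   `context` (key string), `n_samples`, and the rule parameters.
#' @export
detect_presence <- function(ft, filter, min_count = 1, min_reps = 1) {
  sel <- match_samples(ft, filter)
  if (min_reps > length(sel)) {
    warning("min_reps (", min_reps, ") exceeds the ", length(sel),
            " samples of the context; nothing can be detected")
  }
  hits <- colSums(ft$counts[sel, , drop = FALSE] >= min_count) >= min_reps
  presence_set(sort(colnames(ft$counts)[hits]),
               context = context_key(filter),
               n_samples = length(sel),
               min_count = min_count, min_reps = min_reps)
}

presence_set <- function(asvs, context, n_samples = NA_integer_,
                         min_count = NA_integer_, min_reps = NA_integer_) {
  structure(list(asvs = as.character(asvs), context = context,
                 n_samples = n_samples,
                 min_count = min_count, min_reps = min_reps),
            class = "presence_set")
}

context_key <- function(filter) {
  paste(names(filter),
        vapply(filter, function(v) paste(v, collapse = "|"), ""),
        sep = "=", collapse = ".")
}

#' @export
print.presence_set <- function(x, ...) {
  cat("presence_set [", x$context, "]: ", length(x$asvs), " ASVs\n", sep = "")
  invisible(x)
}

as_asv_set <- function(x) {
  if (inherits(x, "presence_set")) x$asvs else as.character(x)
}

#' Binary prevalence matrix across contexts
#'
#' Rows are the union of all ASVs, columns the contexts; entry 1 iff the ASV
#' is in the context's presence set.
#'
#' @param sets list of `presence_set`s (at least 2) with distinct context
#'   keys; a named list of character vectors also works.
#' @return binary integer matrix, ASVs x contexts.
#' @export
prevalence_matrix <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 contexts")
  keys <- vapply(seq_along(sets), function(i) {
    if (inherits(sets[[i]], "presence_set")) sets[[i]]$context
    else names(sets)[i] %||% as.character(i)
  }, "")
  if (anyDuplicated(keys)) {
    stop("duplicate context keys: ", paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  members <- lapply(sets, as_asv_set)
  all_asvs <- sort(unique(unlist(members)))
  m <- vapply(members, function(s) as.integer(all_asvs %in% s),
              integer(length(all_asvs)))
  m <- matrix(m, nrow = length(all_asvs), dimnames = list(all_asvs, keys))
  m
}

#' Exclusive intersection counts (UpSet-style)
#'
#' For every non-empty combination of contexts, the number of ASVs present in
#' exactly that combination; the counts sum to the number of distinct ASVs.
#'
#' @param pm binary prevalence matrix from [prevalence_matrix()].
#' @return data.frame with `combination` (context keys joined by `&`),
#'   `degree`, and `count`, sorted by decreasing count.
#' @export
upset_intersections <- function(pm) {
  pm <- as.matrix(pm)
  if (!all(pm %in% c(0, 1))) stop("prevalence matrix must be binary")
  if (any(rowSums(pm) == 0)) stop("prevalence matrix has ASVs in no context")
  pattern <- apply(pm, 1, function(r) paste(colnames(pm)[r == 1], collapse = " & "))
  tab <- table(pattern)
  out <- data.frame(combination = names(tab),
                    degree = lengths(strsplit(names(tab), " & ", fixed = TRUE)),
                    count = as.integer(tab), row.names = NULL)
  out[order(-out$count, out$combination), , drop = FALSE]
}

#' Assign each seedling ASV to its origin category
#'
#' Deterministic set algebra against the matched source pools: an ASV of the
#' seedling (root or stem) presence set is `both` when present in the sown
#' seed lot's pool and the pot's soil pool, `seed_only` / `soil_only` when in
#' exactly one, and `unknown` when detected in neither. The four categories
#' partition the seedling set; the aggregates `soil_detected`
#' (= soil_only + both) and `seed_detected` (= seed_only + both) are also
#' exposed.
#'
#' @param seedling `presence_set` (or character vector) of the seedling
#'   context.
#' @param seed source pool of the sown genotype x year seed lot.
#' @param soil source pool of the pot's soil.
#' @return an `origin_map`: list with `assignment` (data.frame `asv`,
#'   `category`), per-category id lists, and the context keys used.
#' @export
assign_origin <- function(seedling, seed, soil) {
  sdl <- as_asv_set(seedling); se <- as_asv_set(seed); so <- as_asv_set(soil)
  category <- ifelse(sdl %in% se & sdl %in% so, "both",
              ifelse(sdl %in% se, "seed_only",
              ifelse(sdl %in% so, "soil_only", "unknown")))
  assignment <- data.frame(asv = sdl, category = factor(category,
    levels = c("seed_only", "soil_only", "both", "unknown")))
  structure(list(
    assignment = assignment,
    seed_only = sdl[category == "seed_only"],
    soil_only = sdl[category == "soil_only"],
    both = sdl[category == "both"],
    unknown = sdl[category == "unknown"],
    soil_detected = sdl[category %in% c("soil_only", "both")],
    seed_detected = sdl[category %in% c("seed_only", "both")],
    seedling_context = if (inherits(seedling, "presence_set")) seedling$context else NA,
    seed_context = if (inherits(seed, "presence_set")) seed$context else NA,
    soil_context = if (inherits(soil, "presence_set")) soil$context else NA
  ), class = "origin_map")
}

#' @export
print.origin_map <- function(x, ...) {
  cat("origin_map [", x$seedling_context %||% "?", "]\n", sep = "")
  print(table(x$assignment$category))
  invisible(x)
}

#' Membership fraction of each origin category
#'
#' Share of the seedling presence set held by each origin category (counts
#' over the total seedling richness); the four fractions sum to 1, and the
#' soil/seed aggregates are reported alongside.
#'
#' @param om an [assign_origin()] result.
#' @return named numeric vector: `seed_only`, `soil_only`, `both`, `unknown`,
#'   `soil_detected`, `seed_detected`.
#' @export
origin_membership <- function(om) {
  stopifnot(inherits(om, "origin_map"))
  n <- nrow(om$assignment)
  if (n == 0) stop("empty seedling set: membership fractions undefined")
  frac <- table(om$assignment$category) / n
  c(seed_only = unname(frac["seed_only"]), soil_only = unname(frac["soil_only"]),
    both = unname(frac["both"]), unknown = unname(frac["unknown"]),
    soil_detected = unname(frac["soil_only"] + frac["both"]),
    seed_detected = unname(frac["seed_only"] + frac["both"]))
}

#' Mean relative abundance of each ASV in a context
#'
#' Per sample, counts are divided by the sample total; the per-ASV values are
#' then averaged arithmetically across the context's samples, including zero
#' counts (no occupancy conditioning). Computed on non-rarefied counts by
#' convention. Samples with zero total reads are excluded with a warning.
#'
#' @param ft a [feature_table()].
#' @param filter named list selecting the context's samples.
#' @return named numeric vector over all ASVs of the table; sums to 1.
#' @export
mean_relative_abundance <- function(ft, filter) {
  sel <- match_samples(ft, filter)
  counts <- ft$counts[sel, , drop = FALSE]
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    warning("excluding zero-total sample(s): ",
            paste(rownames(counts)[totals == 0], collapse = ", "))
    counts <- counts[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
    if (!nrow(counts)) stop("all selected samples have zero total reads")
  }
  rel <- sweep(counts, 1, totals, "/")
  colMeans(rel)
}

#' Relative-abundance fraction of each origin category
#'
#' Summed mean relative abundance of the ASVs in each origin category,
#' renormalised over the seedling presence set so the category fractions sum
#' to 1 (the seedling set may not carry all of a sample's reads).
#'
#' @param om an [assign_origin()] result.
#' @param rel named per-ASV mean relative abundance in the seedling context
#'   (from [mean_relative_abundance()]); must cover every seedling ASV.
#' @return named numeric vector as in [origin_membership()].
#' @export
origin_abundance <- function(om, rel) {
  stopifnot(inherits(om, "origin_map"))
  asvs <- om$assignment$asv
  if (!length(asvs)) stop("empty seedling set: abundance fractions undefined")
  missing <- setdiff(asvs, names(rel))
  if (length(missing) || anyNA(rel[asvs])) {
    stop("relative abundance missing for seedling ASV(s): ",
         paste(utils::head(c(missing, asvs[is.na(rel[asvs])]), 5), collapse = ", "))
  }
  total <- sum(rel[asvs])
  if (total == 0) stop("seedling ASVs have zero total relative abundance")
  sum_cat <- function(ids) sum(rel[ids]) / total
  c(seed_only = sum_cat(om$seed_only), soil_only = sum_cat(om$soil_only),
    both = sum_cat(om$both), unknown = sum_cat(om$unknown),
    soil_detected = sum_cat(om$soil_detected),
    seed_detected = sum_cat(om$seed_detected))
}

#' Transmission success from a source pool to seedling replicates
#'
#' Per replicate, the percentage of the source pool's ASVs detected in that
#' replicate's seedling set; summarised as mean +/- standard error (sample
#' SD over sqrt(n)) across replicates. The replicate-pooled percentage (the
#' union of the replicate sets against the source) is reported alongside,
#' since pooled and per-replicate views answer slightly different questions.
#'
#' @param source `presence_set` (or character vector) of the source pool
#'   (seed lot or soil); must be non-empty.
#' @param seedling_reps list of `presence_set`s, one per replicate, or a
#'   single set.
#' @return list with `per_replicate` (numeric vector of percentages), `mean`,
#'   `se`, `pooled` (percentage on the replicate union), `n_source`,
#'   `n_transmitted_pooled`.
#' @export
transmission_success <- function(source, seedling_reps) {
  src <- as_asv_set(source)
  if (!length(src)) stop("transmission undefined for empty source pool")
  if (inherits(seedling_reps, "presence_set") || is.character(seedling_reps)) {
    seedling_reps <- list(seedling_reps)
  }
  reps <- lapply(seedling_reps, as_asv_set)
  pct <- vapply(reps, function(r) 100 * length(intersect(src, r)) / length(src), 0)
  pooled_set <- unique(unlist(reps))
  n_trans <- length(intersect(src, pooled_set))
  list(per_replicate = pct,
       mean = mean(pct),
       se = if (length(pct) > 1) stats::sd(pct) / sqrt(length(pct)) else 0,
       pooled = 100 * n_trans / length(src),
       n_source = length(src),
       n_transmitted_pooled = n_trans)
}

#' Classify ASVs into rare / intermediate / abundant
#'
#' Rare below the low threshold (default mean relative abundance < 0.01%),
#' abundant strictly above the high threshold (> 1%), intermediate otherwise;
#' both boundary values fall in the intermediate class (the middle band is
#' read as a closed interval).
#'
#' @param rel numeric vector of mean relative abundances in `[0, 1]`.
#' @param thresholds increasing length-2 vector `(t_low, t_high)` as
#'   fractions.
#' @return factor with levels `rare`, `intermediate`, `abundant`, named as
#'   `rel`.
#' @export
classify_abundance <- function(rel, thresholds = c(1e-4, 1e-2)) {
  if (any(is.na(rel)) || any(rel < 0 | rel > 1)) {
    stop("relative abundances must lie in [0, 1]")
  }
  stopifnot(length(thresholds) == 2, diff(thresholds) > 0)
  cls <- ifelse(rel < thresholds[1], "rare",
         ifelse(rel > thresholds[2], "abundant", "intermediate"))
  out <- factor(cls, levels = c("rare", "intermediate", "abundant"))
  names(out) <- names(rel)
  out
}

#' Class-wise transmission rates
#'
#' For each abundance class of the source pool, the percentage of that
#' class's ASVs detected in the seedling set. Classes with no source members
#' are reported as `NA` (undefined), not 0.
#'
#' @param source `presence_set` (or character vector) of source ASVs.
#' @param classes factor/character of classes named by ASV, covering every
#'   source ASV (e.g. `classify_abundance()` of the source context's mean
#'   relative abundances).
#' @param seedling `presence_set` (or character vector) of the recipient.
#' @return data.frame with `class`, `n_source`, `n_transmitted`,
#'   `percentage`.
#' @export
class_transmission_rates <- function(source, classes, seedling) {
  src <- as_asv_set(source)
  sdl <- as_asv_set(seedling)
  missing <- setdiff(src, names(classes))
  if (length(missing)) {
    stop("unclassified source ASV(s): ", paste(utils::head(missing, 5), collapse = ", "))
  }
  cls <- factor(as.character(classes[src]),
                levels = c("rare", "intermediate", "abundant"))
  transmitted <- src %in% sdl
  n_source <- as.integer(table(cls))
  n_trans <- as.integer(tapply(transmitted, cls, sum, default = 0L))
  data.frame(class = levels(cls),
             n_source = n_source,
             n_transmitted = n_trans,
             percentage = ifelse(n_source > 0, 100 * n_trans / n_source, NA_real_))
}

#' Pair source and seedling abundances of transmitted ASVs
#'
#' For ASVs present in both the source pool and the seedling set, records the
#' source abundance class, both relative abundances, whether the ASV sits
#' above the 1:1 line (strictly more abundant in the seedling than in the
#' source), and whether it became abundant (> high threshold) in the
#' seedling.
#'
#' @param source_rel named per-ASV mean relative abundance in the source
#'   context.
#' @param seedling_rel named per-ASV mean relative abundance in the seedling
#'   context (by convention, the later sampling stage).
#' @param source,seedling optional presence sets restricting the pairing;
#'   default: ASVs with positive abundance on each side.
#' @param thresholds class thresholds passed to [classify_abundance()].
#' @return data.frame with `asv`, `source_class`, `source_rel`,
#'   `seedling_rel`, `above_line`, `became_abundant`.
#' @export
abundance_pairing <- function(source_rel, seedling_rel,
                              source = NULL, seedling = NULL,
                              thresholds = c(1e-4, 1e-2)) {
  src_set <- if (is.null(source)) names(source_rel)[source_rel > 0] else as_asv_set(source)
  sdl_set <- if (is.null(seedling)) names(seedling_rel)[seedling_rel > 0] else as_asv_set(seedling)
  transmitted <- intersect(src_set, sdl_set)
  src_cls <- classify_abundance(source_rel[src_set], thresholds)
  s_rel <- ifelse(transmitted %in% names(source_rel), source_rel[transmitted], NA_real_)
  p_rel <- ifelse(transmitted %in% names(seedling_rel), seedling_rel[transmitted], NA_real_)
  data.frame(asv = transmitted,
             source_class = factor(as.character(src_cls[transmitted]),
                                   levels = levels(src_cls)),
             source_rel = as.numeric(s_rel),
             seedling_rel = as.numeric(p_rel),
             above_line = as.numeric(p_rel) > as.numeric(s_rel),
             became_abundant = as.numeric(p_rel) > thresholds[2],
             row.names = NULL)
}

#' Aggregate relative abundance of a taxonomic group
#'
#' Summed relative abundance, per sample, of the ASVs whose genus belongs to
#' a guild (e.g. ammonia oxidisers Nitrosospira + Nitrosovibrio, or nitrite
#' oxidisers Nitrobacter + Nitrospira), expressed as a percentage; summarised
#' as mean +/- SE across the context's samples.
#'
#' @param ft a [feature_table()] with a taxonomy table holding a `genus`
#'   column.
#' @param filter named list selecting the context's samples.
#' @param genera character vector of genus names; an absent genus simply
#'   contributes nothing.
#' @return list with `per_sample` (named percentages), `mean`, `se`.
#' @export
taxon_group_abundance <- function(ft, filter, genera) {
  if (is.null(ft$taxonomy) || !"genus" %in% names(ft$taxonomy)) {
    stop("feature table has no taxonomy with a 'genus' rank")
  }
  sel <- match_samples(ft, filter)
  counts <- ft$counts[sel, , drop = FALSE]
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    warning("excluding zero-total sample(s): ",
            paste(rownames(counts)[totals == 0], collapse = ", "))
    counts <- counts[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  hit_asvs <- rownames(ft$taxonomy)[ft$taxonomy$genus %in% genera]
  hit_asvs <- intersect(colnames(counts), hit_asvs)
  pct <- if (length(hit_asvs)) {
    100 * rowSums(counts[, hit_asvs, drop = FALSE]) / totals
  } else {
    setNames(rep(0, nrow(counts)), rownames(counts))
  }
  list(per_sample = pct, mean = mean(pct),
       se = if (length(pct) > 1) stats::sd(pct) / sqrt(length(pct)) else 0)
}
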