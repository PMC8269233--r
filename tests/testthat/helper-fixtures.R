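# Fixtures are built in code; oracles here are deliberately naive
# (plain loops / exhaustive enumeration), independent of the package's
# implementation paths.

# small random feature table with full design metadata
rand_feature_table <- function(n_samples = 6, n_asvs = 10, seed = 1,
                               lambda = 5) {
  set.seed(seed)
  m <- matrix(rpois(n_samples * n_asvs, lambda), n_samples, n_asvs,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0("asv", seq_len(n_asvs))))
  md <- data.frame(
    compartment = rep_len(c("seed", "soil", "root", "stem"), n_samples),
    soil = rep_len(c("S1", "S2"), n_samples),
    genotype = rep_len(c("Boston", "Major"), n_samples),
    year = rep_len(c("Y1", "Y2"), n_samples),
    stage = rep_len(c("d07", "d14"), n_samples),
    replicate = rep_len(c("A", "B", "C"), n_samples),
    row.names = rownames(m))
  feature_table(m, metadata = md)
}

# tiny design table: 3 seed reps, 3 soil reps, root/stem x 3 reps
toy_design_table <- function(seed = 1, n_asvs = 12, lambda = 3) {
  set.seed(seed)
  ids <- c(paste0("seed.", c("A", "B", "C")),
           paste0("soil.", c("A", "B", "C")),
           paste0("root.", c("A", "B", "C")),
           paste0("stem.", c("A", "B", "C")))
  m <- matrix(rpois(length(ids) * n_asvs, lambda), length(ids), n_asvs,
              dimnames = list(ids, paste0("asv", seq_len(n_asvs))))
  md <- data.frame(
    compartment = rep(c("seed", "soil", "root", "stem"), each = 3),
    soil = "S1", genotype = "Boston", year = "Y1", stage = "d14",
    replicate = rep(c("A", "B", "C"), 4), row.names = ids)
  feature_table(m, metadata = md)
}

# ---- brute-force oracles ----

# origin category of each seedling ASV, one taxon at a time
bf_assign_origin <- function(seedling, seed, soil) {
  out <- character(length(seedling))
  for (i in seq_along(seedling)) {
    a <- seedling[i]
    in_seed <- any(seed == a)
    in_soil <- any(soil == a)
    out[i] <- if (in_seed && in_soil) "both"
      else if (in_seed) "seed_only"
      else if (in_soil) "soil_only"
      else "unknown"
  }
  stats::setNames(out, seedling)
}

# exclusive intersection counts by explicit subset enumeration
bf_upset <- function(sets) {
  stopifnot(!is.null(names(sets)))
  all_asvs <- unique(unlist(sets))
  keys <- names(sets)
  res <- list()
  for (k in seq_along(keys)) {
    combos <- utils::combn(keys, k, simplify = FALSE)
    for (cb in combos) {
      n <- 0L
      for (a in all_asvs) {
        inside <- vapply(keys, function(s) a %in% sets[[s]], TRUE)
        if (all(inside[cb]) && !any(inside[setdiff(keys, cb)])) n <- n + 1L
      }
      if (n > 0) res[[paste(cb, collapse = " & ")]] <- n
    }
  }
  unlist(res)
}

# per-replicate transmission percentages by counting matches
bf_transmission <- function(source, reps) {
  pct <- numeric(length(reps))
  for (r in seq_along(reps)) {
    hits <- 0L
    for (a in source) if (a %in% reps[[r]]) hits <- hits + 1L
    pct[r] <- 100 * hits / length(source)
  }
  pct
}

# class-wise transmission percentage by filtering then counting
bf_class_rates <- function(source, classes, seedling) {
  out <- list()
  for (cl in c("rare", "intermediate", "abundant")) {
    members <- source[classes[source] == cl]
    out[[cl]] <- if (!length(members)) NA_real_ else {
      100 * sum(members %in% seedling) / length(members)
    }
  }
  unlist(out)
}

# edge-walk Faith's PD: union of root-paths of the present tips
bf_faith_pd <- function(present, tree) {
  root <- ape::Ntip(tree) + 1L
  edges <- integer(0)
  for (tip in match(present, tree$tip.label)) {
    node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      edges <- union(edges, e)
      node <- tree$edge[e, 1]
    }
  }
  sum(tree$edge.length[edges])
}

# random presence-set instance for the oracle-equivalence battery
rand_instance <- function(seed, max_asvs = 30, max_contexts = 4) {
  set.seed(seed)
  universe <- paste0("t", seq_len(sample(5:max_asvs, 1)))
  n_ctx <- sample(2:max_contexts, 1)
  sets <- lapply(seq_len(n_ctx), function(i) {
    sample(universe, sample.int(length(universe), 1))
  })
  names(sets) <- paste0("ctx", seq_len(n_ctx))
  sets
}
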