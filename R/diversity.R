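#' Rarefy a feature table to even depth
#'
#' Subsamples each sample's reads without replacement to exactly `depth`
#' reads (a single draw, mirroring a one-shot rarefaction of the data set).
#' Samples whose total is below the depth are dropped and recorded in the
#' `dropped` attribute; samples exactly at depth are returned unchanged.
#'
#' @param ft a [feature_table()].
#' @param depth positive integer read depth.
#' @param seed optional integer seed for the draw (local RNG stream).
#' @return a `feature_table` whose rows each sum to `depth`, with attribute
#'   `dropped` listing removed sample ids.
#' @export
rarefy_table <- function(ft, depth, seed = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  if (length(depth) != 1L || depth < 1) stop("depth must be a positive integer")
  totals <- rowSums(ft$counts)
  keep <- totals >= depth
  if (!any(keep)) stop("no samples survive rarefaction at depth ", depth)
  dropped <- rownames(ft$counts)[!keep]
  if (length(dropped)) {
    message("rarefy_table: dropping ", length(dropped),
            " sample(s) below depth ", depth, ": ",
            paste(dropped, collapse = ", "))
  }
  counts <- ft$counts[keep, , drop = FALSE]
  rare <- with_rng(seed, t(apply(counts, 1, function(x) {
    picked <- sample(rep.int(seq_along(x), x), depth)
    tabulate(picked, nbins = length(x))
  })))
  dimnames(rare) <- dimnames(counts)
  storage.mode(rare) <- "integer"
  out <- feature_table(rare,
                       metadata = if (!is.null(ft$metadata)) ft$metadata[keep, , drop = FALSE],
                       taxonomy = ft$taxonomy)
  attr(out, "dropped") <- dropped
  attr(out, "depth") <- as.integer(depth)
  out
}

#' Chao1 richness estimator
#'
#' Bias-corrected form `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, where `F1` and
#' `F2` are the numbers of singletons and doubletons; defined even when no
#' doubletons are observed and equal to the observed richness when there are
#' no singletons. An all-zero vector gives 0.
#'
#' @param counts non-negative integer vector of per-ASV read counts in one
#'   sample.
#' @return estimated richness (numeric scalar).
#' @export
chao1 <- function(counts) {
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts))) {
    stop("chao1 requires non-negative integer counts")
  }
  s_obs <- sum(counts > 0)
  if (s_obs == 0) return(0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree spanning the present tips.
#' Root-inclusive by default (the path from the tips' most recent common
#' ancestor up to the tree root is counted), matching the convention of the
#' community-phylogenetics tools this wraps; set `include_root = FALSE` for
#' the MRCA-rooted variant.
#'
#' @param present character vector of present ASV ids (must all be tree tips).
#' @param tree a rooted `phylo` tree with branch lengths; extra tips are fine.
#' @param include_root logical, include the stem to the tree root.
#' @return summed branch length (numeric scalar); 0 for an empty set.
#' @export
faith_pd <- function(present, tree, include_root = TRUE) {
  validate_phylo(tree)
  present <- unique(as.character(present))
  if (!length(present)) return(0)
  missing <- setdiff(present, tree$tip.label)
  if (length(missing)) {
    stop("present ASVs missing from tree: ", paste(missing, collapse = ", "))
  }
  comm <- matrix(as.integer(tree$tip.label %in% present), nrow = 1,
                 dimnames = list("s", tree$tip.label))
  unname(faith_pd_all(comm, tree, include_root)[1])
}

# Postorder edge sweep over all samples at once. An edge contributes when the
# subtree below it holds at least one present tip (root-inclusive); the
# exclusive variant discounts the edges above the present tips' MRCA (those
# whose subtree holds all of them). Handles polytomies, including star trees.
faith_pd_all <- function(comm, tree, include_root = TRUE) {
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  comm <- comm[, tree$tip.label, drop = FALSE]
  cnt <- matrix(0L, nrow(comm), nnode)
  cnt[, seq_len(ntip)] <- (comm > 0) + 0L
  parent <- tree$edge[, 1]; child <- tree$edge[, 2]
  for (e in seq_along(parent)) {
    cnt[, parent[e]] <- cnt[, parent[e]] + cnt[, child[e]]
  }
  used <- cnt[, child, drop = FALSE] > 0
  pd <- as.numeric(used %*% tree$edge.length)
  if (!include_root) {
    total <- rowSums(comm > 0)
    spans_all <- cnt[, child, drop = FALSE] == total & total > 0
    pd <- pd - as.numeric(spans_all %*% tree$edge.length)
  }
  stats::setNames(pd, rownames(comm))
}

#' Per-sample alpha diversity
#'
#' Computes the requested metrics for every sample of a feature table.
#' `faith_pd` uses presence (count > 0) of each sample's ASVs and requires a
#' tree covering all observed ASVs.
#'
#' @param ft a [feature_table()], normally already rarefied.
#' @param metrics subset of `c("observed_richness", "chao1", "faith_pd")`.
#' @param tree rooted `phylo`, required iff `"faith_pd"` is requested.
#' @param include_root passed to [faith_pd()].
#' @return long data.frame with columns `sample_id`, `metric`, `value`,
#'   `depth` (the rarefaction depth attribute if present, else the sample
#'   total).
#' @export
alpha_diversity <- function(ft, metrics = c("observed_richness", "chao1"),
                            tree = NULL, include_root = TRUE) {
  stopifnot(inherits(ft, "feature_table"))
  allowed <- c("observed_richness", "chao1", "faith_pd")
  bad <- setdiff(metrics, allowed)
  if (length(bad)) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  if ("faith_pd" %in% metrics && is.null(tree)) {
    stop("faith_pd requested but no tree supplied")
  }
  depth <- attr(ft, "depth") %||% NA_integer_
  res <- list()
  if ("observed_richness" %in% metrics) {
    res$observed_richness <- apply(ft$counts, 1, function(x) sum(x > 0))
  }
  if ("chao1" %in% metrics) {
    res$chao1 <- apply(ft$counts, 1, chao1)
  }
  if ("faith_pd" %in% metrics) {
    observed <- colnames(ft$counts)[colSums(ft$counts) > 0]
    missing <- setdiff(observed, tree$tip.label)
    if (length(missing)) {
      stop("observed ASVs missing from tree: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) ", ..." else "")
    }
    pruned <- ape::keep.tip(tree, intersect(tree$tip.label, colnames(ft$counts)))
    comm <- ft$counts[, pruned$tip.label, drop = FALSE]
    res$faith_pd <- faith_pd_all(comm, pruned, include_root)
  }
  do.call(rbind, lapply(names(res), function(m) {
    data.frame(sample_id = rownames(ft$counts), metric = m,
               value = as.numeric(res[[m]]),
               depth = if (is.na(depth)) rowSums(ft$counts) else depth,
               row.names = NULL)
  }))
}

#' Group differences in an alpha-diversity estimator
#'
#' Fixed-effects one-way comparisons of a per-sample statistic between design
#' groups: ANOVA (type-I, factor order as given), Welch t test, or Wilcoxon
#' rank-sum.
#'
#' @param values numeric vector of per-sample values.
#' @param grouping factor (or coercible) of the same length.
#' @param method one of `"anova"`, `"ttest"`, `"wilcoxon"`.
#' @return list with `statistic`, `p_value`, `group_means`, `method`.
#' @export
compare_alpha <- function(values, grouping, method = c("anova", "ttest", "wilcoxon")) {
  method <- match.arg(method)
  grouping <- factor(grouping)
  if (length(values) != length(grouping)) stop("values and grouping differ in length")
  if (nlevels(droplevels(grouping)) < 2) stop("need at least 2 groups")
  grouping <- droplevels(grouping)
  sizes <- table(grouping)
  if (method %in% c("anova", "ttest") && any(sizes < 2)) {
    stop("each group needs >= 2 observations for ", method, ": ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  }
  if (method %in% c("ttest", "wilcoxon") && nlevels(grouping) != 2) {
    stop(method, " requires exactly 2 groups")
  }
  gm <- tapply(values, grouping, mean)
  out <- switch(method,
    anova = {
      fit <- stats::aov(values ~ grouping)
      tab <- summary(fit)[[1]]
      list(statistic = tab[["F value"]][1], p_value = tab[["Pr(>F)"]][1])
    },
    ttest = {
      tt <- stats::t.test(values ~ grouping)
      list(statistic = unname(tt$statistic), p_value = tt$p.value)
    },
    wilcoxon = {
      wt <- stats::wilcox.test(values ~ grouping, exact = NULL)
      list(statistic = unname(wt$statistic), p_value = wt$p.value)
    })
  list(statistic = out$statistic, p_value = out$p_value,
       group_means = gm, method = method)
}
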