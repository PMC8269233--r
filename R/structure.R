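#' log10(x + 1) transform
#'
#' The abundance transform applied before Bray-Curtis: elementwise
#' `log10(count + 1)` of (rarefied) counts.
#'
#' @param x a [feature_table()] or a non-negative numeric matrix.
#' @return a numeric matrix of the same shape.
#' @export
transform_log10p1 <- function(x) {
  m <- if (inherits(x, "feature_table")) x$counts else as.matrix(x)
  if (any(m < 0)) stop("negative values: log10+1 transform requires counts >= 0")
  log10(m + 1)
}

#' Bray-Curtis dissimilarity
#'
#' `BC(i, j) = sum |x_ik - x_jk| / sum (x_ik + x_jk)` over ASVs, via
#' [vegan::vegdist()]. A pair of all-zero samples (undefined ratio) is set to
#' 0 with a warning; such samples cannot occur after rarefaction.
#'
#' @param x non-negative numeric matrix (samples x ASVs), typically the
#'   log10+1-transformed counts, or a `feature_table`.
#' @return a `dist` object with sample labels.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "feature_table")) x$counts else as.matrix(x)
  if (nrow(m) < 2) stop("need at least 2 samples for a distance matrix")
  if (any(m < 0)) stop("Bray-Curtis requires non-negative values")
  d <- suppressWarnings(vegan::vegdist(m, method = "bray"))
  if (anyNA(d)) {
    warning("all-zero sample pair(s): Bray-Curtis undefined, set to 0")
    d[is.na(d)] <- 0
  }
  d
}

#' Principal-coordinate analysis
#'
#' Classical metric scaling: eigendecomposition of the Gower-centered matrix
#' `-1/2 J D^2 J` (via [stats::cmdscale()]); coordinates are eigenvectors
#' scaled by `sqrt(lambda)` for positive eigenvalues. Negative eigenvalues
#' (non-Euclidean distances) are reported, not corrected.
#'
#' @param d a `dist` object or symmetric zero-diagonal matrix.
#' @return list with `coordinates` (n x k matrix, k = number of positive
#'   eigenvalues), `eigenvalues` (all n, descending), and
#'   `proportion_explained` (per positive axis, relative to the sum of
#'   positive eigenvalues).
#' @export
pcoa_ordination <- function(d) {
  d <- as_dist_checked(d)
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- eig > max(eig) * 1e-12
  k <- sum(pos)
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords,
       eigenvalues = eig,
       proportion_explained = eig[seq_len(k)] / sum(eig[pos]))
}

as_dist_checked <- function(d) {
  if (inherits(d, "dist")) return(d)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-12) {
    stop("distance input must be symmetric")
  }
  if (max(abs(diag(m))) > 1e-12) stop("distance matrix must have zero diagonal")
  stats::as.dist(m)
}

#' Multivariate dispersion (distance to group centroid)
#'
#' Embeds the samples by PCoA and measures each sample's distance to its
#' group centroid, subtracting the imaginary-axis contribution from negative
#' eigenvalues and clipping at zero (Anderson's correction), via
#' [vegan::betadisper()] with `type = "centroid"`. For two groups the
#' distances are compared with a Wilcoxon rank-sum test.
#'
#' @param d a `dist` or symmetric matrix.
#' @param grouping factor of group labels aligned with the samples.
#' @param test run the two-group Wilcoxon comparison (error if more than two
#'   groups; compare pairs of groups separately in that case).
#' @return list with `distances` (named per sample), `grouping`, and when
#'   tested `wilcoxon_statistic`, `wilcoxon_p`.
#' @export
dispersion_to_centroid <- function(d, grouping, test = TRUE) {
  d <- as_dist_checked(d)
  grouping <- factor(grouping)
  if (length(grouping) != attr(d, "Size")) stop("grouping length must match samples")
  bd <- vegan::betadisper(d, grouping, type = "centroid")
  out <- list(distances = bd$distances, grouping = grouping)
  if (test) {
    if (nlevels(droplevels(grouping)) != 2) {
      stop("Wilcoxon comparison needs exactly 2 groups; ",
           "call dispersion_to_centroid on pairs of groups")
    }
    wt <- suppressWarnings(stats::wilcox.test(bd$distances ~ droplevels(grouping)))
    out$wilcoxon_statistic <- unname(wt$statistic)
    out$wilcoxon_p <- wt$p.value
  }
  out
}

#' Sequential PERMANOVA on a distance matrix
#'
#' Distance-based permutational multivariate ANOVA with type-I (sequential)
#' sums of squares in the stated term order, pseudo-F per term and a free
#' permutation test, via [vegan::adonis2()] with `by = "terms"`. R-squared per
#' term is its share of the total (Gower-centered) sum of squares; the term
#' and residual shares sum to one. Terms may be factors, numeric covariates,
#' or interactions written `a:b`.
#'
#' @param d a `dist` or symmetric matrix.
#' @param metadata data.frame of per-sample variables, rows aligned with `d`.
#' @param terms character vector of model terms in testing order, e.g.
#'   `c("soil", "stage", "genotype:year", "soil:genotype:year")`.
#' @param n_perm number of permutations (p-values are bounded below by
#'   `1/(n_perm + 1)`).
#' @param seed optional seed for the permutation stream.
#' @return data.frame with one row per term plus `Residual` and `Total`:
#'   columns `term`, `df`, `sum_sq`, `r_squared`, `pseudo_f`, `p_value`.
#'   Terms constant across the samples are reported with zero df and no test.
#' @export
permanova_terms <- function(d, metadata, terms, n_perm = 999, seed = NULL) {
  d <- as_dist_checked(d)
  if (n_perm < 1) stop("n_perm must be >= 1")
  metadata <- as.data.frame(metadata)
  if (nrow(metadata) != attr(d, "Size")) stop("metadata rows must match samples")
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  missing <- setdiff(vars, names(metadata))
  if (length(missing)) stop("terms not in metadata: ", paste(missing, collapse = ", "))

  # constant terms carry no variance: report them with 0 df, exclude from fit
  is_constant <- vapply(terms, function(tm) {
    v <- strsplit(tm, ":", fixed = TRUE)[[1]]
    all(vapply(v, function(x) length(unique(metadata[[x]])) < 2, TRUE))
  }, TRUE)
  fit_terms <- terms[!is_constant]
  if (!length(fit_terms)) {
    tot <- total_ss(d)
    out <- data.frame(term = c(terms, "Residual", "Total"),
                      df = c(rep(0L, length(terms)), attr(d, "Size") - 1L,
                             attr(d, "Size") - 1L),
                      sum_sq = c(rep(0, length(terms)), tot, tot),
                      r_squared = c(rep(0, length(terms)), 1, 1),
                      pseudo_f = NA_real_, p_value = NA_real_)
    return(out)
  }
  fml <- stats::as.formula(paste("d ~", paste(fit_terms, collapse = " + ")))
  env <- new.env(parent = parent.frame())
  assign("d", d, envir = env)
  environment(fml) <- env
  res <- with_rng(seed,
                  vegan::adonis2(fml, data = metadata, permutations = n_perm,
                                 by = "terms"))
  tab <- as.data.frame(res)
  out <- data.frame(term = rownames(tab),
                    df = tab$Df,
                    sum_sq = tab$SumOfSqs,
                    r_squared = tab$R2,
                    pseudo_f = tab$F,
                    p_value = tab[["Pr(>F)"]],
                    row.names = NULL)
  if (any(is_constant)) {
    zero <- data.frame(term = terms[is_constant], df = 0L, sum_sq = 0,
                       r_squared = 0, pseudo_f = NA_real_, p_value = NA_real_)
    out <- rbind(zero, out)
    ord <- c(terms, "Residual", "Total")
    out <- out[match(ord, out$term), ]
    rownames(out) <- NULL
  }
  out
}

# Total (Gower-centered) sum of squares of a distance matrix:
# sum of squared distances divided by n.
total_ss <- function(d) {
  n <- attr(d, "Size")
  sum(as.numeric(d)^2) / n
}
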