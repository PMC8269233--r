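#' ASV feature table
#'
#' The single carrier of observed data: a non-negative integer count matrix
#' (samples x ASVs) with aligned per-sample metadata and optional per-ASV
#' taxonomy. Metadata factors follow the sowing design vocabulary:
#' `compartment` in seed/soil/root/stem, `soil` in S1/S2, `genotype` in
#' Boston/Major, `year` in Y1/Y2, `stage` in d07/d14, `replicate` in A/B/C
#' (any factor other than `compartment` may be absent, e.g. for source
#' samples).
#'
#' @param counts integer matrix, samples as rows, ASVs as columns, with
#'   unique dimnames.
#' @param metadata data.frame with one row per sample; either rownames or a
#'   `sample_id` column identify samples. Rows for samples absent from
#'   `counts` are dropped with a warning; samples of `counts` missing from
#'   `metadata` are an error.
#' @param taxonomy optional data.frame of rank lineages with one row per ASV
#'   (rownames or an `asv_id` column).
#' @return an object of class `feature_table` with elements `counts`,
#'   `metadata`, `taxonomy`.
#' @export
feature_table <- function(counts, metadata = NULL, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have sample rownames and ASV colnames")
  }
  validate_counts(counts)
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate sample id: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate ASV id: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  storage.mode(counts) <- "integer"

  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if ("sample_id" %in% names(metadata)) {
      rownames(metadata) <- as.character(metadata$sample_id)
      metadata$sample_id <- NULL
    }
    if (anyDuplicated(rownames(metadata))) {
      stop("duplicate sample id in metadata: ",
           paste(unique(rownames(metadata)[duplicated(rownames(metadata))]), collapse = ", "))
    }
    missing <- setdiff(rownames(counts), rownames(metadata))
    if (length(missing)) {
      stop("samples present in counts but absent from metadata: ",
           paste(missing, collapse = ", "))
    }
    extra <- setdiff(rownames(metadata), rownames(counts))
    if (length(extra)) {
      warning("dropping ", length(extra),
              " metadata rows for samples not in the count table: ",
              paste(utils::head(extra, 5), collapse = ", "),
              if (length(extra) > 5) ", ..." else "")
    }
    metadata <- metadata[rownames(counts), , drop = FALSE]
    validate_metadata_vocab(metadata)
  }

  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    if ("asv_id" %in% names(taxonomy)) {
      rownames(taxonomy) <- as.character(taxonomy$asv_id)
      taxonomy$asv_id <- NULL
    }
    keep <- intersect(colnames(counts), rownames(taxonomy))
    taxonomy <- taxonomy[keep, , drop = FALSE]
  }

  structure(list(counts = counts, metadata = metadata, taxonomy = taxonomy),
            class = "feature_table")
}

validate_counts <- function(counts) {
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(is.na(counts) | counts < 0 | counts != floor(counts), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("invalid count at sample '%s', ASV '%s': %s (must be a non-negative integer)",
                 rownames(counts)[i] %||% i, colnames(counts)[j] %||% j,
                 format(counts[i, j])))
  }
  invisible(TRUE)
}

compartment_levels <- c("seed", "soil", "root", "stem")

design_vocab <- list(
  soil = c("S1", "S2"),
  genotype = c("Boston", "Major"),
  year = c("Y1", "Y2"),
  stage = c("d07", "d14"),
  replicate = c("A", "B", "C")
)

validate_metadata_vocab <- function(metadata) {
  if ("compartment" %in% names(metadata)) {
    vals <- unique(as.character(metadata$compartment))
    bad <- setdiff(vals[!is.na(vals)], compartment_levels)
    if (length(bad)) {
      stop("unknown compartment value(s): ", paste(bad, collapse = ", "),
           " (allowed: ", paste(compartment_levels, collapse = ", "), ")")
    }
  }
  for (f in names(design_vocab)) {
    if (f %in% names(metadata)) {
      vals <- unique(as.character(metadata[[f]]))
      bad <- setdiff(vals[!is.na(vals)], design_vocab[[f]])
      if (length(bad)) {
        warning("non-canonical ", f, " value(s): ", paste(bad, collapse = ", "))
      }
    }
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table: ", nrow(x$counts), " samples x ", ncol(x$counts),
      " ASVs (", format(sum(as.numeric(x$counts)), big.mark = ","), " reads)\n", sep = "")
  if (!is.null(x$metadata)) {
    cat("metadata factors:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  if (!is.null(x$taxonomy)) {
    cat("taxonomy ranks:", paste(names(x$taxonomy), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Select samples of a feature table by metadata values
#'
#' @param ft a [feature_table()].
#' @param filter named list of metadata values, e.g.
#'   `list(compartment = "seed", genotype = "Boston", year = "Y1")`; a sample
#'   is selected when all named factors match (vector values mean "any of").
#' @param drop_empty_asvs drop ASV columns with zero total in the selection.
#' @return a `feature_table` restricted to the matching samples.
#' @export
subset_samples <- function(ft, filter, drop_empty_asvs = FALSE) {
  sel <- match_samples(ft, filter)
  counts <- ft$counts[sel, , drop = FALSE]
  if (drop_empty_asvs) counts <- counts[, colSums(counts) > 0, drop = FALSE]
  feature_table(counts,
                metadata = if (!is.null(ft$metadata)) ft$metadata[sel, , drop = FALSE],
                taxonomy = ft$taxonomy)
}

match_samples <- function(ft, filter) {
  if (is.null(ft$metadata)) stop("feature table has no metadata to filter on")
  stopifnot(is.list(filter), !is.null(names(filter)))
  keep <- rep(TRUE, nrow(ft$counts))
  for (f in names(filter)) {
    if (!f %in% names(ft$metadata)) stop("no metadata factor named '", f, "'")
    keep <- keep & (as.character(ft$metadata[[f]]) %in% as.character(filter[[f]]))
  }
  sel <- which(keep)
  if (!length(sel)) {
    stop("no samples match filter: ",
         paste(names(filter), vapply(filter, function(v) paste(v, collapse = "|"), ""),
               sep = "=", collapse = ", "))
  }
  sel
}

#' Read an ASV count table from TSV
#'
#' Plain UTF-8 tab-separated values, `#` lines treated as comments, first
#' column holding ids. Both orientations are supported; the result is always
#' samples x ASVs.
#'
#' @param path file path.
#' @param orientation `"samples"` when rows are samples (default) or `"asvs"`
#'   when rows are ASVs (the common QIIME/BIOM dense export).
#' @return a [feature_table()] without metadata.
#' @export
read_feature_table <- function(path, orientation = c("samples", "asvs")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           check.names = FALSE, quote = "", stringsAsFactors = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate id in first column of ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- ids
  if (orientation == "asvs") m <- t(m)
  validate_counts(m)
  feature_table(m)
}

#' Read sample metadata from TSV
#'
#' Tab-separated, header row, one row per sample; the first column (or a
#' `sample_id` column) identifies samples. `compartment` values outside
#' seed/soil/root/stem are an error; other design factors are checked against
#' the canonical vocabulary with a warning.
#'
#' @param path file path.
#' @return a data.frame with sample ids as rownames.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  md <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, quote = "", stringsAsFactors = FALSE)
  idcol <- if ("sample_id" %in% names(md)) "sample_id" else names(md)[1]
  ids <- as.character(md[[idcol]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample id in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  rownames(md) <- ids
  md[[idcol]] <- NULL
  validate_metadata_vocab(md)
  md
}

#' Read a rooted phylogeny from a newick file
#'
#' Thin validating wrapper around [ape::read.tree()]. Tips absent from a
#' count table are allowed (consumers prune lazily); negative branch lengths
#' or duplicate tip labels are errors.
#'
#' @param path newick file path.
#' @return an `ape::phylo` tree.
#' @export
read_phylo <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("unparseable newick in ", path, ": ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("unparseable newick in ", path)
  validate_phylo(tree)
  tree
}

validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length in tree")
  invisible(tree)
}

#' Write result tables and a run manifest
#'
#' One TSV per named table (UTF-8, tab-separated, no quoting) plus a
#' `manifest.json` echoing the configuration, the master seed, package
#' version, per-table row counts and any logged notes (e.g. samples dropped
#' at rarefaction). Identical inputs and seed yield byte-identical TSVs.
#'
#' @param tables named list of data.frames.
#' @param dir output directory (created if needed).
#' @param config optional `pipeline_config` to echo.
#' @param seed optional master seed to record.
#' @param notes optional named list of free-form log entries.
#' @param input_digests optional named character vector of md5 digests of the
#'   input files.
#' @param overwrite allow clobbering existing files.
#' @return invisibly, the manifest list.
#' @export
write_result_tables <- function(tables, dir, config = NULL, seed = NULL,
                                notes = NULL, input_digests = NULL,
                                overwrite = FALSE) {
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables))) stop("tables must be named")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(names(tables), ".tsv"))
  exists <- file.exists(paths)
  if (any(exists) && !overwrite) {
    stop("output files already exist (use overwrite = TRUE): ",
         paste(basename(paths[exists]), collapse = ", "))
  }
  for (i in seq_along(tables)) {
    df <- as.data.frame(tables[[i]])
    utils::write.table(df, paths[i], sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  manifest <- list(
    package = "seedtrans",
    version = as.character(utils::packageVersion("seedtrans")),
    seed = seed,
    config = if (!is.null(config)) unclass(config),
    tables = lapply(tables, function(t) list(rows = nrow(as.data.frame(t)))),
    input_digests = as.list(input_digests),
    notes = notes
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null", digits = NA)
  invisible(manifest)
}
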