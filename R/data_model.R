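#' Construct a single omics dataset (one task)
#'
#' Bundles one study's feature matrix, phenotype vector and level/platform
#' labels. Feature columns are normalized to zero mean and unit (sample)
#' standard deviation; the phenotype is stored untransformed and centered at
#' fit time.
#'
#' @param X numeric matrix, samples in rows, features in columns. Column names
#'   (or `feature_ids`) identify features.
#' @param Y numeric response vector, one value per row of `X`. Binary traits
#'   are coded 0/1 and treated as numeric under squared loss.
#' @param dataset_id character scalar, unique study identifier.
#' @param level character scalar naming the omics level (e.g. `"snp"`,
#'   `"expression"`). Datasets sharing a level share one loss weight and split
#'   the platform weights.
#' @param platform character scalar naming the assay platform.
#' @param feature_ids optional character vector overriding `colnames(X)`.
#' @param normalize logical; standardize feature columns (default `TRUE`).
#'
#' @return An object of class `omics_dataset`: a list with elements `X`
#'   (normalized), `Y`, `dataset_id`, `level`, `platform`, `feature_ids`, `n`,
#'   `d`, and the normalization parameters (`center`, `scale`).
#' @export
omics_dataset <- function(X, Y, dataset_id, level, platform = "default",
                          feature_ids = NULL, normalize = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  Y <- as.numeric(Y)
  if (nrow(X) != length(Y))
    stop("dataset '", dataset_id, "': nrow(X) = ", nrow(X),
         " but length(Y) = ", length(Y))
  if (anyNA(X) || anyNA(Y))
    stop("dataset '", dataset_id, "': missing values are not supported")
  if (is.null(feature_ids)) feature_ids <- colnames(X)
  if (is.null(feature_ids))
    stop("dataset '", dataset_id, "': feature ids required (colnames or feature_ids)")
  feature_ids <- as.character(feature_ids)
  if (length(feature_ids) != ncol(X))
    stop("dataset '", dataset_id, "': feature_ids length does not match ncol(X)")
  if (anyDuplicated(feature_ids))
    stop("dataset '", dataset_id, "': duplicate feature ids")
  colnames(X) <- feature_ids
  center <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (normalize) {
    X <- normalize_features(X, dataset_id = dataset_id)
    center <- attr(X, "center"); scl <- attr(X, "scale")
  }
  structure(list(X = X, Y = Y, dataset_id = as.character(dataset_id),
                 level = as.character(level), platform = as.character(platform),
                 feature_ids = feature_ids, n = nrow(X), d = ncol(X),
                 center = center, scale = scl),
            class = "omics_dataset")
}

#' Standardize feature columns
#'
#' Centers every column to mean zero and scales it to unit standard deviation,
#' using the sample (n-1) convention. The centering and scaling vectors are
#' attached as attributes `center` and `scale` so they can be reapplied to
#' held-out samples.
#'
#' @param X numeric matrix (samples x features).
#' @param dataset_id optional label used in error messages.
#' @return The standardized matrix with attributes `center` and `scale`.
#' @export
normalize_features <- function(X, dataset_id = NULL) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  bad <- which(!is.finite(scl) | scl == 0)
  if (length(bad)) {
    nm <- colnames(X)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("constant feature column(s)",
         if (!is.null(dataset_id)) paste0(" in dataset '", dataset_id, "'"),
         ": ", paste(utils::head(nm, 5), collapse = ", "),
         if (length(nm) > 5) ", ..." else "")
  }
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  attr(Xs, "center") <- ctr
  attr(Xs, "scale") <- scl
  Xs
}

#' Sample-size platform weights within one omics level
#'
#' Datasets measured at the same level on different platforms are weighted by
#' relative sample size, `delta_j = n_j / sum(n)`, so larger studies dominate
#' the shared loss for that level.
#'
#' @param sample_sizes integer vector of per-dataset sample sizes at one level.
#' @return Numeric vector of weights summing to 1.
#' @export
platform_weights <- function(sample_sizes) {
  if (length(sample_sizes) == 0) stop("no sample sizes supplied")
  n <- as.numeric(sample_sizes)
  if (any(!is.finite(n)) || any(n < 1)) stop("all sample sizes must be >= 1")
  n / sum(n)
}

#' Assemble a multi-study collection
#'
#' Orders the datasets, indexes omics levels, and computes the per-level
#' platform weights (`delta`) and level weights (`omega`, all 1 by default:
#' every level is assumed to carry equally important signal).
#'
#' @param datasets list of [omics_dataset()] objects.
#' @param omega optional named numeric vector of level weights (names = level
#'   labels); defaults to 1 for every level.
#' @param link link function tag; only `"identity"` is supported.
#' @return An object of class `study_collection`: list with `datasets`,
#'   `T` (number of tasks), `K` (number of levels), `levels`, `level_index`,
#'   `omega` (per dataset), `delta` (per dataset), `weights`
#'   (`omega * delta`, per dataset), and `link`.
#' @export
study_collection <- function(datasets, omega = NULL, link = "identity") {
  if (!length(datasets)) stop("empty dataset list")
  if (!all(vapply(datasets, inherits, TRUE, "omics_dataset")))
    stop("all elements must be omics_dataset objects")
  ids <- vapply(datasets, `[[`, "", "dataset_id")
  if (anyDuplicated(ids)) stop("duplicate dataset_id: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  if (!identical(link, "identity")) stop("only the identity link is supported")
  lev <- vapply(datasets, `[[`, "", "level")
  levels <- unique(lev)
  lev_idx <- match(lev, levels)
  n <- vapply(datasets, `[[`, 0L, "n")
  delta <- numeric(length(datasets))
  for (k in seq_along(levels)) {
    at <- which(lev_idx == k)
    delta[at] <- platform_weights(n[at])
  }
  if (is.null(omega)) {
    om_lv <- stats::setNames(rep(1, length(levels)), levels)
  } else {
    if (is.null(names(omega)) || !all(levels %in% names(omega)))
      stop("omega must be a named vector covering every level")
    if (any(omega < 0)) stop("omega weights must be non-negative")
    om_lv <- omega[levels]
  }
  om <- as.numeric(om_lv[lev_idx])
  names(datasets) <- ids
  structure(list(datasets = datasets, T = length(datasets), K = length(levels),
                 levels = levels, level_index = lev_idx,
                 omega = om, delta = delta, weights = om * delta, link = link),
            class = "study_collection")
}

#' @export
print.study_collection <- function(x, ...) {
  cat("study_collection:", x$T, "dataset(s) across", x$K, "level(s)\n")
  for (i in seq_along(x$datasets)) {
    d <- x$datasets[[i]]
    cat(sprintf("  %-12s level=%-10s platform=%-10s n=%5d d=%6d delta=%.3f\n",
                d$dataset_id, d$level, d$platform, d$n, d$d, x$delta[i]))
  }
  invisible(x)
}

#' Build the gene grouping index over a study collection
#'
#' Maps every feature of every dataset to a gene, and every gene to its index
#' set in the stacked coefficient vector (one cross-task group per gene). The
#' groups are non-overlapping and cover all features; this partition is
#' asserted at build time.
#'
#' @param collection a [study_collection()].
#' @param annotation data frame with columns `feature_id`, `dataset_id`,
#'   `gene_id` mapping every feature of every dataset to a gene.
#' @return An object of class `gene_group_index`: list with `gene_ids`
#'   (length Q), `stacked` (integer vector, gene index of every stacked
#'   coefficient position), `task_offsets` (0-based start of each task block),
#'   `slices` (per gene, the stacked positions), `membership` (per gene, per
#'   dataset column positions), `Q`, `dim`.
#' @export
build_gene_index <- function(collection, annotation) {
  stopifnot(inherits(collection, "study_collection"))
  annotation <- as.data.frame(annotation)
  need <- c("feature_id", "dataset_id", "gene_id")
  if (!all(need %in% names(annotation)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  key <- paste(annotation$feature_id, annotation$dataset_id, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (feature_id, dataset_id) pairs in annotation")
  d <- vapply(collection$datasets, `[[`, 0L, "d")
  offsets <- c(0L, cumsum(d))[seq_along(d)]
  total <- sum(d)
  gene_of <- character(total)
  for (i in seq_along(collection$datasets)) {
    ds <- collection$datasets[[i]]
    ann <- annotation[annotation$dataset_id == ds$dataset_id, ]
    g <- ann$gene_id[match(ds$feature_ids, ann$feature_id)]
    if (anyNA(g))
      stop("dataset '", ds$dataset_id, "': ", sum(is.na(g)),
           " feature(s) missing from annotation, e.g. ",
           ds$feature_ids[which(is.na(g))[1]])
    gene_of[offsets[i] + seq_len(ds$d)] <- g
  }
  gene_ids <- sort(unique(gene_of))
  stacked <- match(gene_of, gene_ids)
  slices <- split(seq_len(total), factor(stacked, levels = seq_along(gene_ids)))
  names(slices) <- gene_ids
  membership <- lapply(seq_along(gene_ids), function(q) {
    lapply(seq_along(collection$datasets), function(i) {
      at <- slices[[q]]
      at <- at[at > offsets[i] & at <= offsets[i] + d[i]]
      at - offsets[i]
    })
  })
  names(membership) <- gene_ids
  idx <- structure(list(gene_ids = gene_ids, stacked = stacked,
                        task_offsets = offsets, task_dims = d,
                        slices = slices, membership = membership,
                        Q = length(gene_ids), dim = total),
                   class = "gene_group_index")
  stopifnot(sum(lengths(idx$slices)) == total,
            !anyDuplicated(unlist(idx$slices, use.names = FALSE)))
  idx
}

#' @export
print.gene_group_index <- function(x, ...) {
  cat("gene_group_index:", x$Q, "genes over", length(x$task_dims),
      "task(s),", x$dim, "stacked coefficients\n")
  invisible(x)
}

#' Load a study collection from a manifest
#'
#' Reads a YAML manifest listing per-dataset files, loads the tab-delimited
#' feature matrices and phenotypes, drops features that have no gene
#' annotation (with a message), normalizes features, and builds the gene
#' grouping index.
#'
#' Manifest schema (paths relative to the manifest file):
#' ```yaml
#' datasets:
#'   - dataset_id: snp_a
#'     level: snp
#'     platform: chip1
#'     X: snp_a_X.tsv    # TSV: sample_id column + one column per feature
#'     Y: snp_a_Y.tsv    # TSV: sample_id, value
#' ```
#'
#' @param manifest_path path to the YAML manifest.
#' @param annotation_path path to a three-column TSV
#'   (`feature_id`, `dataset_id`, `gene_id`).
#' @return list with elements `collection` ([study_collection()]) and
#'   `groups` ([build_gene_index()] result).
#' @export
load_study_collection <- function(manifest_path, annotation_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  if (!file.exists(annotation_path)) stop("annotation not found: ", annotation_path)
  man <- yaml::read_yaml(manifest_path)
  if (is.null(man$datasets) || !length(man$datasets))
    stop("manifest lists no datasets")
  base <- dirname(normalizePath(manifest_path))
  ann <- utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  need <- c("feature_id", "dataset_id", "gene_id")
  if (!all(need %in% names(ann)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(paste(ann$feature_id, ann$dataset_id, sep = "\r")))
    stop("duplicate (feature_id, dataset_id) pairs in annotation")
  datasets <- lapply(man$datasets, function(entry) {
    for (f in c("dataset_id", "level", "X", "Y"))
      if (is.null(entry[[f]])) stop("manifest entry missing field '", f, "'")
    xp <- file.path(base, entry$X); yp <- file.path(base, entry$Y)
    if (!file.exists(xp)) stop("missing file: ", xp)
    if (!file.exists(yp)) stop("missing file: ", yp)
    xt <- utils::read.delim(xp, stringsAsFactors = FALSE, check.names = FALSE)
    yt <- utils::read.delim(yp, stringsAsFactors = FALSE)
    X <- as.matrix(xt[, -1, drop = FALSE])
    rownames(X) <- xt[[1]]
    yv <- yt[[2]][match(xt[[1]], yt[[1]])]
    if (anyNA(yv)) stop("dataset '", entry$dataset_id,
                        "': phenotype missing for some samples")
    keep <- colnames(X) %in% ann$feature_id[ann$dataset_id == entry$dataset_id]
    if (!all(keep)) {
      warning(sum(!keep), " unannotated feature(s) dropped from dataset '",
              entry$dataset_id, "'", call. = FALSE)
      X <- X[, keep, drop = FALSE]
    }
    if (!ncol(X)) stop("dataset '", entry$dataset_id, "': no annotated features")
    omics_dataset(X, yv, entry$dataset_id, entry$level,
                  platform = entry$platform %||% "default")
  })
  collection <- study_collection(datasets)
  groups <- build_gene_index(collection, ann)
  list(collection = collection, groups = groups)
}

#' Write a study collection to disk
#'
#' Writes per-dataset feature/phenotype TSVs, the annotation TSV and a YAML
#' manifest into `dir`, in the dialect read by [load_study_collection()].
#'
#' @param collection a [study_collection()].
#' @param groups the matching [build_gene_index()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_collection <- function(collection, groups, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  ann <- list()
  for (i in seq_along(collection$datasets)) {
    ds <- collection$datasets[[i]]
    sid <- rownames(ds$X)
    if (is.null(sid)) sid <- paste0(ds$dataset_id, "_s", seq_len(ds$n))
    xf <- paste0(ds$dataset_id, "_X.tsv"); yf <- paste0(ds$dataset_id, "_Y.tsv")
    xt <- data.frame(sample_id = sid, ds$X, check.names = FALSE)
    utils::write.table(xt, file.path(dir, xf), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample_id = sid, value = ds$Y),
                       file.path(dir, yf), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    entries[[i]] <- list(dataset_id = ds$dataset_id, level = ds$level,
                         platform = ds$platform, X = xf, Y = yf)
    off <- groups$task_offsets[i]
    ann[[i]] <- data.frame(
      feature_id = ds$feature_ids, dataset_id = ds$dataset_id,
      gene_id = groups$gene_ids[groups$stacked[off + seq_len(ds$d)]])
  }
  utils::write.table(do.call(rbind, ann), file.path(dir, "annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(list(datasets = entries), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Restrict a collection to one omics level
#'
#' @param collection a [study_collection()].
#' @param groups the matching gene index.
#' @param level level label to keep, or `NULL` for all.
#' @return list with the restricted `collection` and rebuilt `groups`.
#' @export
subset_collection <- function(collection, groups, level = NULL) {
  if (is.null(level)) return(list(collection = collection, groups = groups))
  keep <- which(vapply(collection$datasets, `[[`, "", "level") == level)
  if (!length(keep)) stop("no dataset at level '", level, "'")
  ann <- collection_annotation(collection, groups)
  sub <- study_collection(lapply(collection$datasets[keep], function(ds) {
    # already normalized; rebuild without re-checking constant columns
    omics_dataset(ds$X, ds$Y, ds$dataset_id, ds$level, ds$platform,
                  normalize = FALSE)
  }))
  list(collection = sub,
       groups = build_gene_index(
         sub, ann[ann$dataset_id %in% names(collection$datasets)[keep], ]))
}

#' Annotation table of a collection
#'
#' Reconstructs the (feature_id, dataset_id, gene_id) table from a collection
#' and its gene index.
#' @param collection a [study_collection()].
#' @param groups the matching gene index.
#' @return data frame with columns `feature_id`, `dataset_id`, `gene_id`.
#' @export
collection_annotation <- function(collection, groups) {
  out <- lapply(seq_along(collection$datasets), function(i) {
    ds <- collection$datasets[[i]]
    off <- groups$task_offsets[i]
    data.frame(feature_id = ds$feature_ids, dataset_id = ds$dataset_id,
               gene_id = groups$gene_ids[groups$stacked[off + seq_len(ds$d)]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a stacked coefficient vector into per-task blocks
#'
#' @param C stacked numeric vector of length `sum(d_i)`.
#' @param groups a gene index carrying the task offsets.
#' @return list of per-task numeric vectors.
#' @export
split_tasks <- function(C, groups) {
  lapply(seq_along(groups$task_dims), function(i)
    C[groups$task_offsets[i] + seq_len(groups$task_dims[i])])
}
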