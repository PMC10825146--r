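# Omics dataset container and cross-system pairing index.

#' Construct an omics dataset
#'
#' The basic container used throughout the package: a samples x features
#' matrix together with per-sample metadata. Metadata must carry a
#' `sample_id` and a `system` column (the cell line or species); condition
#' information is either a precomputed `condition` column or the triplet
#' `perturbagen`/`dose`/`time` (study modes with diagnosis/protection/
#' vaccination labels use those columns instead and set the pairing key
#' explicitly).
#'
#' @param matrix numeric samples x features matrix (counts in count mode)
#' @param samples data.frame of per-sample metadata, one row per matrix row
#' @param feature_ids character vector of feature names (defaults to
#'   `colnames(matrix)`)
#' @param mode one of `"zscore"`, `"count"`, `"serology"`
#' @return an object of class `omics_dataset`
#' @export
#' @examples
#' m <- matrix(rnorm(6), 2, 3, dimnames = list(NULL, c("g1", "g2", "g3")))
#' meta <- data.frame(sample_id = c("s1", "s2"), system = "A",
#'                    perturbagen = "drugA", dose = "1uM", time = "24h")
#' ds <- omics_dataset(m, meta)
#' dim(ds$matrix)
omics_dataset <- function(matrix, samples, feature_ids = colnames(matrix),
                          mode = c("zscore", "count", "serology")) {
  mode <- match.arg(mode)
  matrix <- as.matrix(matrix)
  if (!is.data.frame(samples)) samples <- as.data.frame(samples)
  if (nrow(matrix) != nrow(samples)) {
    stop("matrix has ", nrow(matrix), " rows but metadata has ",
         nrow(samples), " rows")
  }
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(matrix)))
  if (length(feature_ids) != ncol(matrix)) {
    stop("feature_ids length does not match the number of matrix columns")
  }
  if (anyNA(matrix)) stop("matrix contains missing values")
  if (mode == "count") {
    if (any(matrix < 0) || any(matrix != round(matrix))) {
      stop("count mode requires non-negative integer entries")
    }
  }
  if (!"sample_id" %in% names(samples)) {
    samples$sample_id <- paste0("s", seq_len(nrow(samples)))
  }
  if (!"system" %in% names(samples)) stop("metadata must carry a 'system' column")
  if (!"condition" %in% names(samples)) {
    if (all(c("perturbagen", "dose", "time") %in% names(samples))) {
      samples$condition <- condition_key(samples$perturbagen, samples$dose,
                                         samples$time)
    } else if ("protection" %in% names(samples)) {
      samples$condition <- condition_key(samples$protection)
    } else if ("diagnosis" %in% names(samples)) {
      samples$condition <- condition_key(samples$diagnosis)
    } else {
      stop("metadata must carry either a 'condition' column or columns ",
           "from which one can be built (perturbagen/dose/time, ",
           "protection, or diagnosis)")
    }
  }
  colnames(matrix) <- feature_ids
  structure(list(matrix = matrix, samples = samples,
                 feature_ids = as.character(feature_ids), mode = mode),
            class = "omics_dataset")
}

#' @export
print.omics_dataset <- function(x, ...) {
  cat("omics_dataset:", nrow(x$matrix), "samples x", ncol(x$matrix),
      "features; mode =", x$mode, "\n")
  cat("systems:", paste(unique(x$samples$system), collapse = ", "), "\n")
  cat("conditions:", length(unique(x$samples$condition)), "\n")
  invisible(x)
}

#' Canonical condition key
#'
#' Builds the exact-match pairing key from its components: fields are
#' lower-cased, surrounding/internal whitespace is collapsed, and components
#' are joined with `|`. Matching across systems is exact string equality of
#' this key (no dose-unit conversion).
#'
#' @param ... character vectors of key components (e.g. perturbagen, dose,
#'   time), recycled to a common length
#' @return character vector of normalized keys
#' @export
#' @examples
#' condition_key("DrugA", " 1uM", "24h")
condition_key <- function(...) {
  parts <- lapply(list(...), function(p) {
    p <- tolower(trimws(as.character(p)))
    gsub("[[:space:]]+", " ", p)
  })
  do.call(paste, c(parts, sep = "|"))
}

#' Build the cross-system pairing index
#'
#' Enumerates every pair of samples that shares a condition key while coming
#' from two different systems ("paired conditions"). The per-batch `mask` of
#' positives used by the mutual-information loss is derived from these pairs
#' with [pair_mask()].
#'
#' @param data an `omics_dataset` containing both systems, or a list of two
#'   datasets (one per system) which are concatenated by row
#' @param by metadata column holding the pairing key; defaults to
#'   `"condition"`. Serology studies pair by protection status regardless of
#'   species: pass `by = "protection"` (or build the dataset with a
#'   protection-based condition key).
#' @return an object of class `pair_index` with elements `positive_pairs`
#'   (two-column integer matrix of row indices into the combined dataset),
#'   `systems`, `keys`, and `n` (total samples)
#' @export
#' @examples
#' m <- matrix(0, 4, 2)
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    system = c("A", "A", "B", "B"),
#'                    condition = c("c1", "c2", "c1", "c3"))
#' build_pair_index(omics_dataset(m, meta))$positive_pairs
build_pair_index <- function(data, by = "condition") {
  if (is.list(data) && !inherits(data, "omics_dataset")) {
    data <- bind_datasets(data[[1]], data[[2]])
  }
  meta <- data$samples
  if (!by %in% names(meta)) stop("metadata has no column '", by, "'")
  keys <- condition_key(meta[[by]])
  systems <- as.character(meta$system)
  n <- nrow(meta)
  pairs <- matrix(integer(0), 0L, 2L)
  for (k in unique(keys)) {
    idx <- which(keys == k)
    if (length(idx) < 2L) next
    grid <- expand.grid(i = idx, j = idx)
    grid <- grid[systems[grid$i] != systems[grid$j] & grid$i < grid$j, ,
                 drop = FALSE]
    if (nrow(grid)) pairs <- rbind(pairs, as.matrix(grid))
  }
  dimnames(pairs) <- list(NULL, c("i", "j"))
  structure(list(positive_pairs = pairs, systems = systems, keys = keys,
                 n = n),
            class = "pair_index")
}

#' Positive mask for a batch
#'
#' Square binary matrix over the given batch rows: entry (a, b) is 1 when the
#' corresponding samples form a positive (same condition, different system)
#' pair. Symmetric with a zero diagonal.
#'
#' @param pairs a `pair_index`
#' @param batch_idx integer vector of dataset row indices forming the batch
#' @return binary matrix of dimension `length(batch_idx)` squared
#' @export
pair_mask <- function(pairs, batch_idx = seq_len(pairs$n)) {
  b <- length(batch_idx)
  pos <- match(seq_len(pairs$n), batch_idx)
  m <- matrix(0, b, b)
  pp <- pairs$positive_pairs
  if (nrow(pp)) {
    ii <- pos[pp[, 1L]]
    jj <- pos[pp[, 2L]]
    keep <- !is.na(ii) & !is.na(jj)
    if (any(keep)) {
      m[cbind(ii[keep], jj[keep])] <- 1
      m[cbind(jj[keep], ii[keep])] <- 1
    }
  }
  m
}

#' Concatenate two datasets by row
#'
#' Feature spaces need not match; the combined matrix is block-padded only
#' when features are identical, otherwise the matrices are kept per system in
#' the `blocks` attribute and the combined `matrix` is NULL. Used mainly to
#' build a pairing index spanning two systems.
#' @param a,b `omics_dataset` objects
#' @return `omics_dataset`-like object with stacked metadata
#' @export
bind_datasets <- function(a, b) {
  common_cols <- intersect(names(a$samples), names(b$samples))
  meta <- rbind(a$samples[common_cols], b$samples[common_cols])
  same_features <- identical(a$feature_ids, b$feature_ids)
  out <- list(
    matrix = if (same_features) rbind(a$matrix, b$matrix) else NULL,
    samples = meta,
    feature_ids = if (same_features) a$feature_ids else
      list(a$feature_ids, b$feature_ids),
    mode = a$mode,
    blocks = list(a$matrix, b$matrix)
  )
  class(out) <- "omics_dataset"
  out
}

# ---- readers / writers ------------------------------------------------------

#' Read an omics dataset from delimited text files
#'
#' Expects a samples x features table (first column = sample_id) and a
#' metadata sidecar table keyed by `sample_id`. A sparse Matrix-Market
#' triplet file (`.mtx`) plus a one-column feature file may be given instead
#' of the dense table for count data.
#'
#' @param matrix_file path to a TSV/CSV matrix (or `.mtx` file)
#' @param metadata_file path to the metadata table
#' @param features_file feature names, one per line (required for `.mtx`)
#' @param mode dataset mode, see [omics_dataset()]
#' @return an `omics_dataset`
#' @export
read_omics <- function(matrix_file, metadata_file, features_file = NULL,
                       mode = "zscore") {
  meta <- as.data.frame(data.table::fread(metadata_file))
  if (grepl("\\.mtx$", matrix_file)) {
    m <- as.matrix(Matrix::readMM(matrix_file))
    if (is.null(features_file)) stop("features_file is required with .mtx input")
    feats <- readLines(features_file)
    colnames(m) <- feats
  } else {
    tab <- data.table::fread(matrix_file)
    ids <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    rownames(m) <- ids
    meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  }
  omics_dataset(m, meta, feature_ids = colnames(m), mode = mode)
}

#' Write an omics dataset to delimited text files
#'
#' Mirrors [read_omics()]: dense TSV matrix (or `.mtx` when `sparse = TRUE`)
#' plus a metadata TSV.
#'
#' @param data an `omics_dataset`
#' @param matrix_file,metadata_file output paths
#' @param features_file feature-name output (written when `sparse = TRUE`)
#' @param sparse write the matrix in Matrix-Market triplet format
#' @return invisibly, the input dataset
#' @export
write_omics <- function(data, matrix_file, metadata_file,
                        features_file = NULL, sparse = FALSE) {
  if (sparse) {
    Matrix::writeMM(Matrix::Matrix(data$matrix, sparse = TRUE), matrix_file)
    if (!is.null(features_file)) writeLines(data$feature_ids, features_file)
  } else {
    tab <- data.table::data.table(sample_id = data$samples$sample_id,
                                  as.data.frame(data$matrix))
    data.table::fwrite(tab, matrix_file, sep = "\t")
  }
  data.table::fwrite(data.table::as.data.table(data$samples), metadata_file,
                     sep = "\t")
  invisible(data)
}
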