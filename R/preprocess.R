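# Filtering and transformation rules for raw sample tables.

#' Quality filtering of perturbation signatures
#'
#' Applies the replicate/QC/TAS filtering rules used for L1000-style
#' perturbation signatures:
#' \enumerate{
#'   \item more than three replicates (`n_replicates >= min_replicates`,
#'     default 4, the strict reading of "more than three");
#'   \item at least half of the replicates passed quality control
#'     (`n_passed_qc >= ceiling(qc_fraction * n_replicates)`);
#'   \item not flagged as a statistical outlier;
#'   \item transcriptional activity score `tas >= tas_threshold` (boundary
#'     inclusive; skipped for control signatures);
#'   \item among technical replicates of the same condition, only the
#'     signature with the highest TAS (the "exemplar") is retained.
#' }
#' Record order is preserved and the operation is idempotent.
#'
#' @param records data.frame with columns `sample_id`, `condition` (or
#'   `perturbagen`/`dose`/`time`), `n_replicates`, `n_passed_qc`,
#'   `is_outlier`, `tas`, and optionally `is_control`
#' @param tas_threshold minimum TAS, default 0.3
#' @param min_replicates minimum replicate count, default 4
#' @param qc_fraction required fraction of replicates passing QC, default
#'   0.5; the count is rounded up (`ceiling`) for odd replicate numbers
#' @return the filtered data.frame, rows in original order
#' @export
#' @examples
#' recs <- data.frame(sample_id = c("a", "b"), condition = c("c1", "c2"),
#'                    n_replicates = c(4, 4), n_passed_qc = c(2, 2),
#'                    is_outlier = FALSE, tas = c(0.30, 0.29))
#' filter_l1000(recs)$sample_id  # "a": the 0.3 boundary is inclusive
filter_l1000 <- function(records, tas_threshold = 0.3, min_replicates = 4,
                         qc_fraction = 0.5) {
  records <- as.data.frame(records)
  if (!"condition" %in% names(records)) {
    if (!all(c("perturbagen", "dose", "time") %in% names(records))) {
      stop("records need a 'condition' column or perturbagen/dose/time columns")
    }
    records$condition <- condition_key(records$perturbagen, records$dose,
                                       records$time)
  }
  is_control <- if ("is_control" %in% names(records)) {
    isTRUE_vec(records$is_control)
  } else rep(FALSE, nrow(records))
  if (!"tas" %in% names(records)) {
    stop("records carry no 'tas' field; TAS is required for non-control ",
         "signatures")
  }
  missing_tas <- is.na(records$tas) & !is_control
  if (any(missing_tas)) {
    stop("missing TAS for sample(s): ",
         paste(records$sample_id[missing_tas], collapse = ", "))
  }
  keep <- records$n_replicates >= min_replicates &
    records$n_passed_qc >= ceiling(qc_fraction * records$n_replicates) &
    !isTRUE_vec(records$is_outlier) &
    (is_control | records$tas >= tas_threshold)
  out <- records[keep, , drop = FALSE]
  # exemplar selection: one max-TAS signature per condition
  if (nrow(out)) {
    tas_for_max <- ifelse(is.na(out$tas), -Inf, out$tas)
    keep2 <- rep(FALSE, nrow(out))
    for (k in unique(out$condition)) {
      idx <- which(out$condition == k)
      keep2[idx[which.max(tas_for_max[idx])]] <- TRUE
    }
    out <- out[keep2, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) !is.na(x) & x else as.logical(x) %in% TRUE
}

#' Log-transform a count matrix
#'
#' Elementwise `log10(count + 1)`, the rescaling applied to single-cell count
#' data before encoding. Monotone and invertible on its domain (see
#' [inv_log_transform_counts()]).
#'
#' @param x non-negative numeric matrix
#' @return transformed matrix of the same shape
#' @export
#' @examples
#' log_transform_counts(matrix(c(0, 9, 99, 999), 2, 2))
log_transform_counts <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("counts must be non-negative")
  log10(x + 1)
}

#' @rdname log_transform_counts
#' @export
inv_log_transform_counts <- function(x) 10^as.matrix(x) - 1

#' Preprocess serology feature panels
#'
#' Human panels are z-scored per feature. Non-human-primate (NHP) panels are
#' first log-transformed (`log10(MFI + 1)`), then the per-feature median of
#' the control samples is subtracted, and finally each feature is z-scored.
#' By default the standardization statistics are computed on the full data
#' matrix (matching a global preprocessing workflow); pass `stats_rows` to
#' compute mean/sd on a training subset only, for leakage-safe pipelines.
#'
#' @param data numeric samples x features matrix
#' @param controls control-sample matrix with the same features (NHP mode)
#' @param mode `"human"` or `"nhp"`
#' @param stats_rows optional integer rows used to estimate mean/sd
#' @return standardized matrix; every column has mean 0 and sd 1 (over
#'   `stats_rows` when given)
#' @export
preprocess_serology <- function(data, controls = NULL,
                                mode = c("human", "nhp"),
                                stats_rows = NULL) {
  mode <- match.arg(mode)
  x <- as.matrix(data)
  if (mode == "nhp") {
    if (is.null(controls)) stop("NHP mode requires a control matrix")
    controls <- as.matrix(controls)
    if (ncol(controls) != ncol(x)) {
      stop("controls must have the same features as the data matrix")
    }
    x <- log_transform_counts(x)
    med <- apply(log_transform_counts(controls), 2L, stats::median)
    x <- sweep(x, 2L, med)
  }
  rows <- if (is.null(stats_rows)) seq_len(nrow(x)) else stats_rows
  mu <- colMeans(x[rows, , drop = FALSE])
  sd_ <- apply(x[rows, , drop = FALSE], 2L, stats::sd)
  zero_var <- sd_ == 0 | is.na(sd_)
  if (any(zero_var)) {
    nm <- colnames(x)
    if (is.null(nm)) nm <- paste0("f", seq_len(ncol(x)))
    stop("zero-variance feature(s): ", paste(nm[zero_var], collapse = ", "))
  }
  sweep(sweep(x, 2L, mu), 2L, sd_, "/")
}
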