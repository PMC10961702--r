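# CSV interchange readers/writers for the workflow's tabular formats.
# Comma-separated, UTF-8, header row mandatory; unknown columns are
# preserved, missing required columns are a schema error naming the column,
# and duplicated keys are an error listing the offending keys.

read_csv_checked <- function(path, required, key = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("schema error in ", basename(path),
         ": missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!is.null(key)) {
    keys <- do.call(paste, c(df[key], sep = "|"))
    dup <- unique(keys[duplicated(keys)])
    if (length(dup) > 0L) {
      stop("duplicate key row(s) in ", basename(path), " for (",
           paste(key, collapse = ", "), "): ",
           paste(utils::head(dup, 5L), collapse = "; "),
           if (length(dup) > 5L) " ..." else "")
    }
  }
  df
}

write_csv_checked <- function(x, path, required) {
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L) {
    stop("cannot write: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read/write a pathway AUC table
#'
#' Long-format CSV with columns `chemical_id`, `model_name`, `mode`, `auc`;
#' one record per (chemical, model, mode).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_auc_table <- function(path) {
  df <- read_csv_checked(path, c("chemical_id", "model_name", "mode", "auc"),
                         key = c("chemical_id", "model_name", "mode"))
  if (any(df$auc < 0, na.rm = TRUE)) stop("AUC values must be non-negative")
  df
}

#' @rdname read_auc_table
#' @param x Data frame to write.
#' @export
write_auc_table <- function(x, path) {
  write_csv_checked(x, path, c("chemical_id", "model_name", "mode", "auc"))
}

#' Read/write an activity-call table
#'
#' Columns `chemical_id`, `model_name`, `mode`, `call` (0/1).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_call_table <- function(path) {
  df <- read_csv_checked(path, c("chemical_id", "model_name", "mode", "call"),
                         key = c("chemical_id", "model_name", "mode"))
  if (!all(df$call %in% c(0L, 1L))) stop("calls must be binary 0/1")
  df
}

#' @rdname read_call_table
#' @param x Data frame to write.
#' @export
write_call_table <- function(x, path) {
  write_csv_checked(x, path, c("chemical_id", "model_name", "mode", "call"))
}

#' Read/write a model summary table
#'
#' Columns `model_name`, `mode`, `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#' `specificity`, `mcc`, `balanced_accuracy` (the output of
#' [evaluate_all_models()]).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_summary_table <- function(path) {
  read_csv_checked(path,
                   c("model_name", "mode", "tp", "fp", "tn", "fn",
                     "sensitivity", "specificity", "mcc",
                     "balanced_accuracy"),
                   key = c("model_name", "mode"))
}

#' @rdname read_summary_table
#' @param x Data frame to write.
#' @export
write_summary_table <- function(x, path) {
  write_csv_checked(x, path,
                    c("model_name", "mode", "tp", "fp", "tn", "fn",
                      "sensitivity", "specificity", "mcc",
                      "balanced_accuracy"))
}

#' Read/write fingerprints
#'
#' CSV with columns `chemical_id` and `bits` (a contiguous 0/1 string, one
#' fixed length per file).
#'
#' @param path File path.
#' @return Chemicals x bits 0/1 matrix with chemical ids as rownames.
#' @export
read_fingerprints <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  # bits must stay character: leading zeros are significant
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(c("chemical_id", "bits"), names(df))
  if (length(missing) > 0L) {
    stop("schema error in ", basename(path),
         ": missing required column(s): ", paste(missing, collapse = ", "))
  }
  dup <- unique(df$chemical_id[duplicated(df$chemical_id)])
  if (length(dup) > 0L) {
    stop("duplicate key row(s) in ", basename(path), " for (chemical_id): ",
         paste(utils::head(dup, 5L), collapse = "; "))
  }
  bits <- as.character(df$bits)
  if (length(unique(nchar(bits))) != 1L) {
    stop("all fingerprints must have the same bit length")
  }
  if (!all(grepl("^[01]+$", bits))) {
    stop("fingerprint bits must be 0/1 strings")
  }
  m <- matrix(
    as.integer(unlist(strsplit(bits, "", fixed = TRUE), use.names = FALSE)),
    nrow = nrow(df), byrow = TRUE,
    dimnames = list(df$chemical_id, NULL))
  m
}

#' @rdname read_fingerprints
#' @param x Fingerprint matrix (rownames = chemical ids).
#' @export
write_fingerprints <- function(x, path) {
  df <- data.frame(
    chemical_id = rownames(x),
    bits = apply(x, 1L, paste, collapse = ""),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read/write cluster assignments
#'
#' Columns `chemical_id`, `cluster_id`.
#'
#' @param path File path.
#' @return Named vector mapping chemical_id to cluster id.
#' @export
read_clusters <- function(path) {
  df <- read_csv_checked(path, c("chemical_id", "cluster_id"),
                         key = "chemical_id")
  stats::setNames(df$cluster_id, df$chemical_id)
}

#' @rdname read_clusters
#' @param x Named vector (chemical_id -> cluster id) or a data frame with
#'   the two columns.
#' @export
write_clusters <- function(x, path) {
  if (!is.data.frame(x)) {
    x <- data.frame(chemical_id = names(x), cluster_id = unname(x),
                    stringsAsFactors = FALSE)
  }
  write_csv_checked(x, path, c("chemical_id", "cluster_id"))
}

#' Read/write cluster activity labels
#'
#' Columns `cluster_id`, `label`, `n_agonist`, `n_antagonist`, `n_both`,
#' `n_inactive` (the output of [label_clusters()]).
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_cluster_labels <- function(path) {
  read_csv_checked(path,
                   c("cluster_id", "label", "n_agonist", "n_antagonist",
                     "n_both", "n_inactive"),
                   key = "cluster_id")
}

#' @rdname read_cluster_labels
#' @param x Data frame to write.
#' @export
write_cluster_labels <- function(x, path) {
  write_csv_checked(x, path,
                    c("cluster_id", "label", "n_agonist", "n_antagonist",
                      "n_both", "n_inactive"))
}

#' Read an assay roster CSV
#'
#' Columns `assay` (A1..A14), `endpoint_name`, `role`,
#' `in_agonist_pathway`, `in_antagonist_pathway`. A copy of the default
#' roster ships in `inst/extdata/ar_assay_roster.csv`.
#'
#' @param path File path.
#' @return Validated roster data frame.
#' @export
read_roster <- function(path) {
  df <- read_csv_checked(path,
                         c("assay", "endpoint_name", "role",
                           "in_agonist_pathway", "in_antagonist_pathway"),
                         key = "assay")
  validate_roster(df)
  df
}

#' @rdname read_roster
#' @param x Roster data frame.
#' @export
write_roster <- function(x, path) {
  validate_roster(x)
  write_csv_checked(x, path,
                    c("assay", "endpoint_name", "role",
                      "in_agonist_pathway", "in_antagonist_pathway"))
}

#' Long-format AUC table from a surrogate AUC matrix
#'
#' Helper for exporting a chemicals x models AUC matrix as the long CSV
#' interchange format.
#'
#' @param m Chemicals x models matrix (dimnames required).
#' @param mode Mode label for every record.
#' @return Long data frame with `chemical_id`, `model_name`, `mode`, `auc`.
#' @export
auc_matrix_to_long <- function(m, mode) {
  data.frame(
    chemical_id = rep(rownames(m), times = ncol(m)),
    model_name = rep(colnames(m), each = nrow(m)),
    mode = mode,
    auc = as.vector(m),
    stringsAsFactors = FALSE
  )
}
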