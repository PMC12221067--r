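#' Feature tables
#'
#' A feature table is a tibble with one row per sample: a `sample_id`
#' character column first, then one numeric column per named feature, and
#' optionally a final integer `label` column with the binary class (1 =
#' positive / TLE). All pipeline stages that consume or produce tabular
#' features use this layout, so results chain with the pipe.
#'
#' @param values numeric matrix, samples x features.
#' @param feature_names character vector of unique feature names; defaults
#'   to the matrix column names.
#' @param sample_ids character vector of sample ids; defaults to `s1..sn`.
#' @param labels optional 0/1 integer vector, one per sample.
#' @param allow_missing allow `NA` sentinels for missing features (used by
#'   [extract_features()] for regions absent on every slice); by default
#'   values must be finite.
#' @return A tibble of class `feature_table`.
#' @export
feature_table <- function(values, feature_names = colnames(values),
                          sample_ids = NULL, labels = NULL,
                          allow_missing = FALSE) {
  values <- as.matrix(values)
  if (is.null(feature_names)) {
    feature_names <- paste0("f", seq_len(ncol(values)))
  }
  if (anyDuplicated(feature_names)) {
    stop("duplicate feature names: ",
         paste(unique(feature_names[duplicated(feature_names)]),
               collapse = ", "))
  }
  if (length(feature_names) != ncol(values)) {
    stop("feature_names length must match the number of columns")
  }
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(values)))
  if (length(sample_ids) != nrow(values)) {
    stop("sample_ids length must match the number of rows")
  }
  if (allow_missing) {
    if (any(is.nan(values) | is.infinite(values))) {
      stop("feature values must be finite or NA")
    }
  } else if (!all(is.finite(values))) {
    stop("feature values must be finite")
  }
  df <- as.data.frame(values, optional = TRUE)
  names(df) <- feature_names
  tbl <- tibble::as_tibble(df)
  tbl <- dplyr::bind_cols(tibble::tibble(sample_id = as.character(sample_ids)),
                          tbl)
  if (!is.null(labels)) {
    if (length(labels) != nrow(values)) {
      stop("labels length must match the number of samples")
    }
    if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
    tbl$label <- as.integer(labels)
  }
  class(tbl) <- c("feature_table", class(tbl))
  tbl
}

#' Extract the numeric feature matrix / names / labels from a feature table
#'
#' @param table a [feature_table()] (or any data frame with the same layout).
#' @return `ft_values()` the samples x features matrix; `ft_names()` the
#'   feature names; `ft_labels()` the integer labels or `NULL`.
#' @export
ft_values <- function(table) {
  keep <- setdiff(names(table), c("sample_id", "label"))
  m <- as.matrix(as.data.frame(table)[keep])
  rownames(m) <- table$sample_id
  m
}

#' @rdname ft_values
#' @export
ft_names <- function(table) setdiff(names(table), c("sample_id", "label"))

#' @rdname ft_values
#' @export
ft_labels <- function(table) {
  if ("label" %in% names(table)) as.integer(table$label) else NULL
}

#' Read / write feature tables as CSV
#'
#' CSV layout: header row; first column `sample_id`; one column per feature;
#' optional final column `label`. Roundtrips are lossless to ~1e-12 relative
#' tolerance (values are written with full precision).
#'
#' @param table a [feature_table()].
#' @param path CSV path.
#' @return `read_feature_table()` returns a [feature_table()].
#' @export
write_feature_table <- function(table, path) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "label"
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("read_feature_table: no such file: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("read_feature_table: empty file: ", path)
  nfield <- lengths(strsplit(lines, ",", fixed = TRUE))
  if (length(unique(nfield)) > 1L) {
    bad <- which(nfield != nfield[1])[1]
    stop("read_feature_table: ragged row ", bad, " in ", path,
         " (", nfield[bad], " fields, expected ", nfield[1], ")")
  }
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(sample_id = "character"))
  has_label <- "label" %in% names(df)
  feats <- setdiff(names(df), c("sample_id", "label"))
  feature_table(as.matrix(df[feats]), feature_names = feats,
                sample_ids = df$sample_id,
                labels = if (has_label) df$label else NULL)
}
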