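#' Pipeline configuration
#'
#' Builds the nested parameter record used by every pipeline stage, with
#' defaults for each block and a global random seed. Unknown keys are
#' rejected (strict schema) so that config typos fail loudly instead of
#' silently falling back to defaults.
#'
#' @param ... named overrides; either whole blocks (`preprocess = list(...)`)
#'   or left at their defaults.
#' @param seed global random seed (integer).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., seed = 1L) {
  defaults <- list(
    seed = as.integer(seed),
    preprocess = list(
      skull_strip = TRUE,
      threshold_method = "otsu",     # otsu | quantile
      threshold_quantile = 0.5,
      morph_radius = 2,
      bias_correct = TRUE,
      smoothing_sigma_mm = 8,
      bias_max_iter = 30,
      bias_tol = 1e-4,
      normalize = TRUE,
      median_filter = TRUE,
      median_window = 3
    ),
    fpcm = list(
      c = 3,                          # GM / WM / CSF tissue clusters
      M = 2,
      Q = 2,
      eta = "auto",
      eta_scale = 1,
      epsilon = 1e-5,
      max_iter = 100,
      init = "quantile",              # quantile | kmeanspp
      seed = NULL
    ),
    features = list(
      lbp_bins = 256,
      slice_mode = "mid"              # which slice(s) of each 3-D mask
    ),
    dgwo = list(
      n_agents = 10,
      max_iter = 30,
      c1_start = 2, c1_end = 0,
      c3_start = 0.9, c3_end = 0.4,
      c4 = 1.5, c5 = 1.5,
      a_start = 2, a_end = 0,
      switch_threshold = 0.5,
      binarize_threshold = 0.5,
      position_update = "speed",      # speed (Eq 10) | algorithm1
      cv_folds = 3,
      seed = NULL
    ),
    haetn = list(
      conv_filters = 64,
      conv_kernel = 3,
      pool = 2,
      lstm_hidden = 128,
      attn_heads = 8,
      ffn_hidden = 2048,
      transformer_dropout = 0.1,
      dense_units = 64,
      dense_dropout = 0.5,
      n_classes = 2,
      input_mode = "slice_sequence",  # slice_sequence | feature_sequence
      fuse_handcrafted = FALSE,
      two_residual = FALSE,
      epochs = 20,
      batch_size = 32,
      learning_rate = 0.01,
      momentum = 0.9,
      clip_norm = 1,
      seed = NULL
    ),
    eval = list(
      k = 5,
      seed = NULL
    )
  )
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = "")
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

merge_config <- function(base, override, path) {
  if (!length(override)) return(base)
  if (is.null(names(override)) || any(names(override) == "")) {
    stop("config entries must be named (at '", path, "')")
  }
  unknown <- setdiff(names(override), names(base))
  if (length(unknown)) {
    stop("unknown config key(s) at '", path, "': ",
         paste(unknown, collapse = ", "))
  }
  for (k in names(override)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]]))) {
      if (!is.list(override[[k]])) {
        stop("config key '", paste0(path, k), "' must be a block")
      }
      base[[k]] <- merge_config(base[[k]], override[[k]],
                                paste0(path, k, "/"))
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read a pipeline configuration from YAML or JSON
#'
#' The file may specify any subset of keys; the remainder take their
#' defaults. Unknown keys are rejected.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", tolower(path))) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  seed <- if (!is.null(raw$seed)) raw$seed else 1L
  raw$seed <- NULL
  do.call(pipeline_config, c(raw, list(seed = seed)))
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config> seed =", x$seed, "\n")
  for (blk in setdiff(names(x), "seed")) {
    cat("  $", blk, ": ", length(x[[blk]]), " parameters\n", sep = "")
  }
  invisible(x)
}
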