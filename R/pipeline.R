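#' End-to-end desk-scale pipeline run
#'
#' Runs the whole detection pipeline on a synthetic cohort: phantom
#' generation (class-1 subjects carry a bright lesion-like blob inside the
#' temporal-lobe-like atlas region), preprocessing, FPCM segmentation,
#' atlas labelling, per-region feature extraction, DGWO feature selection,
#' training of a width-reduced HAETN on the selected features (each
#' subject's selected feature vector enters as a length-1 feature
#' sequence), and stratified k-fold evaluation producing the per-fold
#' metric table.
#'
#' Problem sizes default to desk scale (small grids, few subjects, reduced
#' network width) so a full run completes in minutes on one CPU; every
#' stage honours the config seed.
#'
#' @param config a [pipeline_config()].
#' @param n_per_class phantom subjects per class.
#' @param shape phantom grid.
#' @param lesion_contrast intensity added inside the lesion blob for
#'   class-1 subjects.
#' @param verbose print stage progress.
#' @return A list with `features` (cohort [feature_table()]), `selection`
#'   (`dgwo_selection`), `cv` (`kfold_eval`), `segmentations` (first
#'   subject's labels, for inspection), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         n_per_class = 6,
                         shape = c(32, 32, 16),
                         lesion_contrast = 0.35,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  seed <- config$seed
  atlas <- make_toy_atlas(shape, n_regions = 4)
  roi_ids <- as.integer(names(atlas$legend))
  rows <- vector("list", 2 * n_per_class)
  y <- rep(c(0L, 1L), each = n_per_class)
  first_seg <- NULL
  for (s in seq_along(y)) {
    say("subject ", s, " / ", length(y))
    ph <- make_phantom(shape = shape, bias_amplitude = 0.15,
                       bias_smoothness_vox = 8,
                       impulse_fraction = 0.01, gaussian_sd = 0.02,
                       seed = seed + 1000L + s)
    x <- ph$vol$data
    if (y[s] == 1L) {
      # lesion blob inside the temporal-lobe-like slab (region id 1)
      region1 <- atlas$labels$labels == 1L
      ctr <- round(colMeans(which(region1, arr.ind = TRUE)))
      rad <- max(2, round(min(shape) / 8))
      g <- voxel_grid(shape) + 1
      ball <- array(rowSums(sweep(g, 2, ctr)^2) <= rad^2, shape)
      x[ball & region1] <- x[ball & region1] + lesion_contrast
      ph$vol$data <- x
    }
    pre <- preprocess_pipeline(ph$vol, config)
    seg <- fpcm_segment(pre$vol, mask = pre$intermediates$mask,
                        params = utils::modifyList(config$fpcm,
                                                   list(seed = seed + s)))
    lab <- aal_label(seg$labels, atlas)
    if (is.null(first_seg)) first_seg <- list(seg = seg, regions = lab)
    masks <- region_masks(lab$regions, roi_ids)
    rows[[s]] <- extract_features(pre$vol, masks,
                                  sample_id = sprintf("subj%02d", s))
  }
  features <- dplyr::bind_rows(rows)
  features$label <- y
  # drop missing/constant columns before selection (sentinels stay logged)
  keep <- vapply(ft_names(features), function(nm) {
    v <- features[[nm]]
    all(is.finite(v)) && stats::sd(v) > 0
  }, logical(1))
  sel_tbl <- feature_table(ft_values(features)[, keep, drop = FALSE],
                           feature_names = ft_names(features)[keep],
                           sample_ids = features$sample_id, labels = y)
  class(sel_tbl) <- class(features)
  say("feature selection over ", sum(keep), " features")
  sel_cfg <- utils::modifyList(config$dgwo, list(seed = seed))
  selection <- dgwo_select(sel_tbl, sel_cfg)
  Xsel <- ft_values(sel_tbl)[, selection$mask == 1, drop = FALSE]
  say("training + cross-validated evaluation")
  hcfg <- utils::modifyList(config$haetn, list(
    input_mode = "feature_sequence", seed = seed))
  hcfg <- do.call(haetn_config, hcfg)
  ds_x <- lapply(seq_len(nrow(Xsel)), function(i) matrix(Xsel[i, ], nrow = 1))
  # fold models standardise features with train-fold statistics (leak-free)
  factory <- function(tr_x, tr_y) {
    Xtr <- do.call(rbind, tr_x)
    mu <- colMeans(Xtr)
    sd <- apply(Xtr, 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
    zs <- lapply(tr_x, function(r) (r - mu) / sd)
    model <- train_haetn(list(x = zs, y = tr_y), hcfg, val_fraction = 0)
    list(model = model, mu = mu, sd = sd)
  }
  predictor <- function(fit, te_x) {
    zs <- lapply(te_x, function(r) (r - fit$mu) / fit$sd)
    predict_haetn(fit$model, zs)
  }
  cv <- kfold_evaluate(list(x = ds_x, y = y), factory, predictor,
                       k = config$eval$k,
                       seed = if (is.null(config$eval$seed)) seed
                              else config$eval$seed)
  list(features = features, selection = selection, cv = cv,
       segmentations = first_seg, config = config)
}
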