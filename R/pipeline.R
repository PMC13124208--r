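#' Pipeline configuration
#'
#' Assembles every stage's parameters with seeded defaults. Modality
#' routing sends MRI and CT images through histogram equalization
#' ([adhe()]) and PET and DTI images through the speckle denoiser
#' ([etvb_denoise()]).
#'
#' @param n_per_class phantoms per class (default 20, i.e. 100 images)
#' @param phantom base [phantom_spec()] supplying size, contrast and noise;
#'   the default uses moderate noise (speckle sd 0.15, additive sd 0.02)
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "preprocess", "extract", "select", "classify",
#'   "evaluate")`
#' @param extractor_epochs,extractor_lr,extractor_batch training protocol of
#'   the feature extractor
#' @param extractor_augment use label-preserving augmentation (flips and
#'   small shifts) when training the extractor (default TRUE)
#' @param net a [net_config()] for the extractor
#' @param dso_grid,dso_epochs,sparsity_alpha dove-swarm feature selection
#'   settings
#' @param dbn_layers,dbn_pretrain_epochs,dbn_finetune_epochs,dbn_lr deep
#'   belief network settings
#' @param split train/validation/test fractions (stratified)
#' @param seed master seed; all stage seeds derive from it
#' @param out_dir output directory for artifacts (created on demand;
#'   a temporary directory when `NULL`)
#' @return a `pipeline_config` list
#' @export
pipeline_config <- function(n_per_class = 20L,
                            phantom = phantom_spec(speckle_sigma = 0.15,
                                                   additive_sigma = 0.02),
                            stages = c("simulate", "preprocess", "extract",
                                       "select", "classify", "evaluate"),
                            extractor_epochs = 20L, extractor_lr = 1e-3,
                            extractor_batch = 10L, extractor_augment = TRUE,
                            net = net_config(),
                            dso_grid = c(5L, 5L), dso_epochs = 25L,
                            sparsity_alpha = 0.05,
                            dbn_layers = c(64L, 32L),
                            dbn_pretrain_epochs = 20L,
                            dbn_finetune_epochs = 150L, dbn_lr = 0.01,
                            split = c(0.6, 0.2, 0.2), seed = 1L,
                            out_dir = NULL) {
  if (length(stages)) stages <- match.arg(stages, several.ok = TRUE)
  if (abs(sum(split) - 1) > 1e-9) stop("pipeline_config: split must sum to 1")
  structure(list(n_per_class = as.integer(n_per_class), phantom = phantom,
                 stages = stages, extractor_epochs = as.integer(extractor_epochs),
                 extractor_lr = extractor_lr,
                 extractor_batch = as.integer(extractor_batch),
                 extractor_augment = isTRUE(extractor_augment), net = net,
                 dso_grid = as.integer(dso_grid),
                 dso_epochs = as.integer(dso_epochs),
                 sparsity_alpha = sparsity_alpha,
                 dbn_layers = as.integer(dbn_layers),
                 dbn_pretrain_epochs = as.integer(dbn_pretrain_epochs),
                 dbn_finetune_epochs = as.integer(dbn_finetune_epochs),
                 dbn_lr = dbn_lr, split = split, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level YAML keys override the corresponding [pipeline_config()]
#' arguments; `phantom:` and `net:` sub-maps override [phantom_spec()] and
#' [net_config()] fields.
#'
#' @param path YAML file
#' @return a `pipeline_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$phantom)) {
    args$phantom <- do.call(phantom_spec, y$phantom)
    y$phantom <- NULL
  }
  if (!is.null(y$net)) {
    args$net <- do.call(net_config, y$net)
    y$net <- NULL
  }
  do.call(pipeline_config, c(args, y))
}

#' Stratified train/validation/test split
#'
#' @param labels integer class labels
#' @param fractions length-3 fractions summing to 1
#' @param seed RNG seed
#' @return character vector (`"train"`, `"val"`, `"test"`) aligned with
#'   `labels`
#' @export
stratified_split <- function(labels, fractions = c(0.6, 0.2, 0.2), seed = 1L) {
  with_seed(seed, {
    out <- character(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      n <- length(idx)
      n_tr <- round(fractions[1] * n)
      n_va <- round(fractions[2] * n)
      out[idx] <- c(rep("train", n_tr), rep("val", n_va),
                    rep("test", n - n_tr - n_va))
    }
    out
  })
}

# route one image through its modality's preprocessor
preprocess_by_modality <- function(img) {
  if (img_modality(img) %in% c("MRI", "CT")) adhe(img)
  else etvb_denoise(img)$image
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order: simulate phantoms, preprocess by
#' modality (equalization for MRI/CT, speckle denoising for PET/DTI), train
#' the residual attention extractor on the training split and extract
#' per-image feature vectors, select features with the dove swarm (fitness
#' evaluated on the training split only), train the deep belief network on
#' the selected training features, and score the held-out test split. All
#' artifacts (feature table, selection mask, predictions, metrics report,
#' manifest) are written to the output directory and hashed, so identical
#' config + seed reruns are hash-identical.
#'
#' @param config a [pipeline_config()]
#' @return a `pipeline_result` list: `report` (test-split [metrics()]),
#'   `confusion`, `val_accuracy`, `selected` (feature indices), `paths`,
#'   `hashes`, `split`, plus the trained models
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  st <- config$stages
  out_dir <- config$out_dir %||% file.path(tempdir(),
    sprintf("mndpipe_run_%d", config$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  result <- list(paths = character(0))
  if (!length(st) || !"simulate" %in% st) {
    result$hashes <- character(0)
    class(result) <- "pipeline_result"
    return(result)
  }

  ds <- make_dataset(config$n_per_class, config$phantom,
                     seed = derive_seed(config$seed, 11))
  labels <- ds$labels
  images <- ds$images
  split <- stratified_split(labels, config$split, seed = derive_seed(config$seed, 13))
  result$split <- split

  if ("preprocess" %in% st)
    images <- lapply(images, preprocess_by_modality)

  features <- NULL
  if ("extract" %in% st) {
    tr <- split == "train"
    net <- train_res4net(images[tr], labels[tr], config$net,
                         epochs = config$extractor_epochs,
                         lr = config$extractor_lr,
                         batch_size = config$extractor_batch,
                         seed = derive_seed(config$seed, 17),
                         augment = config$extractor_augment)
    features <- extract_features(net, images)
    result$extractor <- net
    fpath <- file.path(out_dir, "features.csv")
    ftab <- data.frame(filename = ds$manifest$filename, label = labels,
                       split = split, features)
    write.csv(ftab, fpath, row.names = FALSE)
    result$paths <- c(result$paths, features = fpath)
  }

  selected <- NULL
  if ("select" %in% st && !is.null(features)) {
    tr <- split == "train"
    sel <- dso_select_features(features[tr, , drop = FALSE], labels[tr],
                               config = swarm_config(config$dso_grid[1],
                                                     config$dso_grid[2],
                                                     dim = ncol(features),
                                                     max_epochs = config$dso_epochs,
                                                     init = "random",
                                                     seed = derive_seed(config$seed, 19)),
                               sparsity_alpha = config$sparsity_alpha,
                               seed = derive_seed(config$seed, 19))
    selected <- sel$selected
    result$selection <- sel
    mpath <- file.path(out_dir, "mask.json")
    jsonlite::write_json(list(selected_indices = sel$selected,
                              cv_score = sel$cv_score,
                              evaluations = sel$evaluations),
                         mpath, auto_unbox = TRUE, digits = NA)
    result$paths <- c(result$paths, mask = mpath)
  }
  result$selected <- selected

  if ("classify" %in% st && !is.null(features)) {
    keep <- selected %||% seq_len(ncol(features))
    tr <- split == "train"
    xtr <- scale_unit(features[tr, keep, drop = FALSE])
    xall <- scale_unit(features[, keep, drop = FALSE], from = xtr)
    model <- dbn_pretrain(xtr, layer_sizes = config$dbn_layers,
                          epochs = config$dbn_pretrain_epochs,
                          seed = derive_seed(config$seed, 23))
    model <- dbn_finetune(model, xtr, labels[tr],
                          epochs = config$dbn_finetune_epochs,
                          lr = config$dbn_lr,
                          seed = derive_seed(config$seed, 29))
    pred <- dbn_predict(model, xall)
    result$dbn <- model
    ppath <- file.path(out_dir, "predictions.csv")
    ptab <- data.frame(filename = ds$manifest$filename, split = split,
                       true = labels, predicted = pred$label)
    colnames(pred$prob) <- paste0("p_", MND_CLASSES)
    ptab <- cbind(ptab, pred$prob)
    write.csv(ptab, ppath, row.names = FALSE)
    result$paths <- c(result$paths, predictions = ppath)
    result$predictions <- ptab

    if ("evaluate" %in% st) {
      te <- split == "test"; va <- split == "val"
      cm <- confusion(labels[te], pred$label[te])
      rep <- metrics(cm)
      result$confusion <- cm
      result$report <- rep
      result$val_accuracy <- if (any(va)) mean(pred$label[va] == labels[va]) else NA_real_
      rpath <- file.path(out_dir, "report.json")
      write_metrics_json(rep, rpath)
      cpath <- file.path(out_dir, "confusion.csv")
      write.csv(as.data.frame(unclass(cm)), cpath)
      result$paths <- c(result$paths, report = rpath, confusion = cpath)
    }
  }

  man_path <- file.path(out_dir, "manifest.csv")
  write.csv(ds$manifest, man_path, row.names = FALSE)
  result$paths <- c(result$paths, manifest = man_path)
  result$hashes <- tools::md5sum(unname(result$paths))
  names(result$hashes) <- names(result$paths)
  result$out_dir <- out_dir
  class(result) <- "pipeline_result"
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  if (!is.null(x$report)) {
    cat(sprintf("  test accuracy %.3f, macro-F1 %.3f (n = %d)\n",
                x$report$accuracy, x$report$macro_f1, x$report$total))
  }
  if (!is.null(x$selected))
    cat("  selected features:", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}
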