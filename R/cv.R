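# Experimental protocol: stratified 8:2 split, five-fold cross-validation
# on the training set producing models M1..Mk, per-model test predictions,
# and box-cluster majority voting across the fold models. Augmentation is
# applied inside each fold's training subset only, never to validation or
# test images, so no derived image leaks across a partition boundary.

#' Stratified train/test split
#'
#' Splits by each image's majority class (multi-label images make exact
#' stratification impossible); per-stratum test counts are allocated by
#' largest remainder so `|test| = round((1 - ratio) * N)` exactly.
#' With fewer than 5 images stratification is refused and a plain random
#' split is used with a warning.
#'
#' @param index A `dataset_index`.
#' @param ratio Training fraction (default 0.8).
#' @param seed RNG seed; the split is deterministic given it.
#' @return List with `train` and `test` `dataset_index`es.
#' @export
split_dataset <- function(index, ratio = 0.8, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1, nrow(index$files) >= 2L)
  N <- nrow(index$files)
  n_test <- round((1 - ratio) * N)
  strata <- vapply(index$files$label, function(p) {
    b <- read_yolo_labels(p)
    if (nrow(b) == 0L) return(-1L)
    tab <- table(b$class_id)
    as.integer(names(tab)[which.max(tab)])
  }, integer(1))
  test_rows <- with_seed(seed, {
    if (N < 5L) {
      warning("fewer than 5 images: falling back to plain random split")
      sample(N, n_test)
    } else {
      groups <- split(seq_len(N), strata)
      quota <- vapply(groups, length, integer(1)) * n_test / N
      base <- floor(quota)
      rem <- quota - base
      extra <- n_test - sum(base)
      if (extra > 0) {
        give <- order(rem, decreasing = TRUE)[seq_len(extra)]
        base[give] <- base[give] + 1L
      }
      unlist(lapply(seq_along(groups), function(g) {
        take <- min(base[g], length(groups[[g]]))
        if (take == 0L) integer() else sample(groups[[g]], take)
      }), use.names = FALSE)
    }
  })
  # largest-remainder rounding can undershoot when a stratum saturates
  short <- n_test - length(test_rows)
  if (short > 0) {
    pool <- setdiff(seq_len(N), test_rows)
    test_rows <- c(test_rows, with_seed(seed + 1L, sample(pool, short)))
  }
  list(train = subset_index(index, setdiff(seq_len(N), test_rows)),
       test = subset_index(index, sort(test_rows)))
}

subset_index <- function(index, rows) {
  dataset_index(index$dir, index$files[rows, , drop = FALSE], index$n_classes,
                index$status)
}

#' Assign training images to k folds
#'
#' Random non-overlapping, jointly exhaustive folds whose sizes differ by
#' at most one.
#'
#' @param train_index A `dataset_index`.
#' @param k Number of folds (default 5).
#' @param seed RNG seed.
#' @return An object of class `fold_plan` with the `image_id -> fold`
#'   assignment.
#' @export
fold_plan <- function(train_index, k = 5L, seed = 1L) {
  N <- nrow(train_index$files)
  stopifnot(k >= 2L, N >= k)
  assignment <- with_seed(seed, {
    setNames(rep_len(seq_len(k), N)[sample(N)], train_index$files$image_id)
  })
  structure(list(k = as.integer(k), assignment = assignment,
                 seed = as.integer(seed)), class = "fold_plan")
}

#' Train one model per cross-validation fold
#'
#' Each fold's model trains on the other `k - 1` folds (optionally after
#' balancing augmentation of those training images only, written to a
#' fold-private directory) and logs validation mAP@.5 on its held-out
#' fold.
#'
#' @param train_index A `dataset_index`.
#' @param plan A [fold_plan()] covering it.
#' @param detector_cfg A [detector_config()].
#' @param train_cfg A [train_config()].
#' @param augment_policy Optional [augmentation_policy()]; `NULL` disables
#'   augmentation.
#' @param work_dir Directory for fold-private augmented files.
#' @param verbose Print progress.
#' @return A list of `k` checkpoints, each with `model`, `fold` and
#'   `val_ids`.
#' @export
kfold_train <- function(train_index, plan, detector_cfg,
                        train_cfg = train_config(), augment_policy = NULL,
                        work_dir = tempfile("folds"), verbose = FALSE) {
  stopifnot(all(train_index$files$image_id %in% names(plan$assignment)))
  folds <- plan$assignment[train_index$files$image_id]
  lapply(seq_len(plan$k), function(f) {
    val_rows <- which(folds == f)
    tr_rows <- which(folds != f)
    idx <- train_index
    if (!is.null(augment_policy)) {
      sub <- subset_index(train_index, tr_rows)
      aug_dir <- file.path(work_dir, sprintf("fold%d", f))
      aug <- balance_dataset(sub, augment_policy, out_dir = aug_dir)
      # train on the augmented subset; validate on the untouched fold
      idx <- dataset_index(train_index$dir,
                           rbind(aug$files,
                                 train_index$files[val_rows, , drop = FALSE]),
                           train_index$n_classes, aug$status)
      tr_rows <- seq_len(nrow(aug$files))
      val_rows <- nrow(aug$files) + seq_along(val_rows)
    }
    model <- build_detector(detector_cfg)
    if (verbose) message("fold ", f, ": ", length(tr_rows), " train / ",
                         length(val_rows), " val images")
    model <- train_detector(model, idx, train_cfg, val_rows = val_rows,
                            train_rows = tr_rows, verbose = verbose)
    list(model = model, fold = f,
         val_ids = idx$files$image_id[val_rows])
  })
}

#' Voting policy for ensemble fusion
#'
#' @param iou_thresh Detections across models cluster together when their
#'   IoU with the cluster seed reaches this value.
#' @param min_votes Minimum number of distinct contributing models for a
#'   cluster to be emitted (default 3 of 5).
#' @return An object of class `vote_policy`.
#' @export
vote_policy <- function(iou_thresh = 0.5, min_votes = 3L) {
  stopifnot(min_votes >= 1L)
  structure(list(iou_thresh = iou_thresh, min_votes = as.integer(min_votes)),
            class = "vote_policy")
}

#' Fuse the fold models' predictions by box-cluster majority voting
#'
#' All models' detections on an image are clustered greedily by
#' descending score (a detection joins the first existing cluster whose
#' seed it overlaps with IoU >= `iou_thresh`, else starts a new one).
#' Clusters backed by at least `min_votes` distinct models are emitted
#' with the majority class among their members (ties broken by the
#' higher summed score), the mean box and mean score of the
#' majority-class members. This reduces to plain label voting when every
#' model emits a single box, is idempotent, and with `min_votes = 1` and
#' one model is the identity up to ordering.
#'
#' @param pred_sets List of detection data frames, one per model.
#' @param policy A [vote_policy()].
#' @return A fused detection `data.frame`.
#' @export
ensemble_vote <- function(pred_sets, policy = vote_policy()) {
  all <- do.call(rbind, lapply(seq_along(pred_sets), function(m) {
    d <- pred_sets[[m]]
    if (nrow(d) == 0L) return(NULL)
    cbind(d, model = m)
  }))
  if (is.null(all) || nrow(all) == 0L) return(empty_detections())
  out <- list()
  for (img in unique(all$image_id)) {
    d <- all[all$image_id == img, , drop = FALSE]
    d <- d[order_detections(d), , drop = FALSE]
    corners <- boxes_to_corners(d)
    seeds <- integer()            # row index of each cluster's seed
    members <- list()
    for (i in seq_len(nrow(d))) {
      joined <- FALSE
      for (cidx in seq_along(seeds)) {
        if (iou_one_vs_many(corners[i, ], corners[seeds[cidx], , drop = FALSE]) >=
            policy$iou_thresh) {
          members[[cidx]] <- c(members[[cidx]], i)
          joined <- TRUE
          break
        }
      }
      if (!joined) {
        seeds <- c(seeds, i)
        members[[length(seeds)]] <- i
      }
    }
    for (cidx in seq_along(seeds)) {
      mem <- d[members[[cidx]], , drop = FALSE]
      if (length(unique(mem$model)) < policy$min_votes) next
      score_by_class <- tapply(mem$score, mem$class_id, sum)
      votes <- table(mem$class_id)
      top <- names(votes)[votes == max(votes)]
      win <- if (length(top) == 1L) top else
        top[which.max(score_by_class[top])]
      mm <- mem[mem$class_id == as.integer(win), , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        image_id = img, class_id = as.integer(win), score = mean(mm$score),
        cx = mean(mm$cx), cy = mean(mm$cy), w = mean(mm$w), h = mean(mm$h))
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) empty_detections() else res[order_detections(res), ,
                                                drop = FALSE]
}

#' Run a full experiment
#'
#' Orchestrates generate (optional) -> split -> five-fold training (with
#' fold-private augmentation) -> per-model test prediction -> ensemble
#' voting -> evaluation, writing `folds.json`, `preds_M<i>.json`,
#' `preds_vote.json`, `report.json` and `train_log.csv` under `out_dir`.
#' Fully reproducible from the config.
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   `out_dir`; `dataset` (either `dir`, or `spec` + `n_images` to
#'   generate); `split` (`ratio`, `seed`); `k`; `detector` (arguments of
#'   [detector_config()]; anchors default to [kmeans_anchors()] on the
#'   training split); `train` (arguments of [train_config()]); `augment`
#'   (`TRUE`, `FALSE` or arguments of [augmentation_policy()]); `vote`
#'   (arguments of [vote_policy()]); `eval` (`score_thresh`, `nms_iou`,
#'   `op_thresh`).
#' @param verbose Print per-stage progress.
#' @return An `experiment_report` list: the ensemble `eval_report`, per
#'   model mAP@.5, the fold plan and file paths.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("experiment stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  out_dir <- config$out_dir %||% tempfile("experiment")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  index <- stage("dataset", {
    if (!is.null(config$dataset$dir)) {
      read_dataset_index(config$dataset$dir)
    } else {
      spec <- do.call(slide_spec, config$dataset$spec %||% list())
      generate_dataset(spec, config$dataset$n_images %||% 200L,
                       file.path(out_dir, "data"))
    }
  })
  sp <- stage("split", {
    split_dataset(index, config$split$ratio %||% 0.8,
                  config$split$seed %||% 1L)
  })
  det_args <- config$detector %||% list()
  det_args$n_classes <- det_args$n_classes %||% index$n_classes
  if (is.null(det_args$anchors)) {
    det_args$anchors <- stage("anchors", {
      kmeans_anchors(sp$train, det_args$input_size %||% c(320L, 320L),
                     seed = config$split$seed %||% 1L)
    })
  }
  dcfg <- stage("config", do.call(detector_config, det_args))
  tcfg <- do.call(train_config, config$train %||% list())
  k <- config$k %||% 5L
  plan <- stage("folds", fold_plan(sp$train, k, config$split$seed %||% 1L))
  pol <- if (isTRUE(config$augment)) {
    augmentation_policy()
  } else if (is.list(config$augment)) {
    do.call(augmentation_policy, config$augment)
  } else NULL
  ckpts <- stage("kfold_train", {
    kfold_train(sp$train, plan, dcfg, tcfg, pol,
                work_dir = file.path(out_dir, "aug"), verbose = verbose)
  })
  ev <- config$eval %||% list()
  preds <- stage("predict", {
    lapply(ckpts, function(ck) {
      predict_dataset(ck$model, sp$test,
                      score_thresh = ev$score_thresh %||% 0.05,
                      nms_iou = ev$nms_iou %||% 0.45)
    })
  })
  vpol <- do.call(vote_policy, config$vote %||% list())
  voted <- stage("vote", ensemble_vote(preds, vpol))
  gts <- index_ground_truth(sp$test)
  cells <- nrow(sp$test$files) * total_anchor_cells(dcfg)
  report <- stage("evaluate", {
    map_suite(voted, gts, score_thresh = ev$op_thresh %||% 0.25,
              total_cells = cells)
  })
  per_model <- vapply(preds, function(d) {
    map_suite(d, gts, score_thresh = ev$op_thresh %||% 0.25)$map50
  }, numeric(1))

  # artifacts
  jsonlite::write_json(as.list(plan$assignment),
                       file.path(out_dir, "folds.json"), auto_unbox = TRUE)
  for (i in seq_along(preds)) {
    jsonlite::write_json(preds[[i]],
                         file.path(out_dir, sprintf("preds_M%d.json", i)),
                         digits = NA)
  }
  jsonlite::write_json(voted, file.path(out_dir, "preds_vote.json"),
                       digits = NA)
  logs <- do.call(rbind, lapply(seq_along(ckpts), function(i) {
    cbind(fold = i, ckpts[[i]]$model$train_log)
  }))
  write.csv(logs, file.path(out_dir, "train_log.csv"), row.names = FALSE)
  jsonlite::write_json(list(map50 = report$map50, map5095 = report$map5095,
                            precision = report$precision,
                            recall = report$recall, mcc = report$mcc,
                            auc = report$auc, per_model_map50 = per_model),
                       file.path(out_dir, "report.json"), auto_unbox = TRUE,
                       digits = NA)
  structure(list(report = report, per_model_map50 = per_model, plan = plan,
                 checkpoints = ckpts, out_dir = out_dir,
                 test_index = sp$test, train_index = sp$train,
                 detector_config = dcfg),
            class = "experiment_report")
}

#' Canonical desk-scale experiment configuration
#'
#' The package's reference benchmark: a two-class synthetic slide dataset
#' (120 slides, 128 x 128 px, 1--3 cells per image, moderate class
#' imbalance and blur), an 8:2 split, five folds trained for 8 epochs
#' each (Adam, learning rate 0.002 with warmup/cosine schedule, batch 4),
#' fold-private balancing augmentation, and 3-of-5 box-cluster voting.
#' The full configuration enables the balancing augmentation and both
#' attention blocks; `attention = FALSE, augment = FALSE` gives the bare
#' ablation detector.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param out_dir Output directory for [run_experiment()] artifacts.
#' @param attention Enable squeeze-excitation + efficient channel
#'   attention.
#' @param augment Enable fold-private balancing augmentation.
#' @return A config list for [run_experiment()].
#' @export
desk_experiment_config <- function(seed = 1L, out_dir = tempfile("experiment"),
                                   attention = TRUE, augment = TRUE) {
  seed <- as.integer(seed) %% 100000L
  list(
    out_dir = out_dir,
    dataset = list(spec = list(n_classes = 2L, image_size = c(128L, 128L),
                               cells_per_image = c(1L, 3L),
                               class_weights = c(0.65, 0.35),
                               blur_sigma = c(0, 1), seed = seed + 11L),
                   n_images = 120L),
    split = list(ratio = 0.8, seed = seed + 3L),
    k = 5L,
    detector = list(input_size = c(128L, 128L), seed = seed + 5L,
                    use_se = attention, use_eca = attention),
    train = list(epochs = 8L, lr = 0.002, batch_size = 4L,
                 weights = loss_weights(box = 0.5, cls = 1), seed = seed + 7L),
    augment = if (augment) list(balance_ratio = 0.75, budget = 70L,
                                seed = seed + 9L) else FALSE,
    vote = list(min_votes = 3L),
    eval = list(score_thresh = 0.02)
  )
}
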