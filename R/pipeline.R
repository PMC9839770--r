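# Orchestration of teacher-student self-training: split the labelled data,
# train the teacher supervised, pseudo-label the pool, optionally CCS-crop
# and 5-way augment, train the student, and evaluate everything on a
# held-out, human/ground-truth-labelled test set.  Pool ground truth is
# carried along only as "hidden truth" for auditing pseudo-label fidelity;
# it never reaches a training loop.

#' Data split specification for self-training experiments
#'
#' @param test_fraction Fraction of the dataset held out for testing
#'   (test count = \code{round(test_fraction * N)}).
#' @param n_teacher Number of labelled pairs used to train the teacher.
#' @param n_pseudo Number of pool images to pseudo-label for the student;
#'   \code{NULL} means the whole pool.
#' @param seed Seed fixing split membership.
#' @return A \code{split_spec} list.
#' @export
split_spec <- function(test_fraction = 0.10, n_teacher = 20L, n_pseudo = NULL,
                       seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1, n_teacher >= 1)
  structure(list(test_fraction = test_fraction,
                 n_teacher = as.integer(n_teacher),
                 n_pseudo = if (is.null(n_pseudo)) NULL else as.integer(n_pseudo),
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' Split labelled pairs into teacher, unlabelled pool and test sets
#'
#' Pool entries have their mask moved to \code{hidden_truth}: downstream
#' stages treat them as unlabelled, and the hidden truth is used only to
#' audit pseudo-label fidelity.
#'
#' @param pairs List of labelled entries \code{list(id, image, mask)}.
#' @param spec A \code{\link{split_spec}}.
#' @return \code{list(teacher, pool, test)} of disjoint entry lists.
#' @export
split_dataset <- function(pairs, spec = split_spec()) {
  n <- length(pairs)
  n_test <- round(spec$test_fraction * n)
  if (spec$n_teacher + n_test > n)
    stop(sprintf("insufficient data: need %d teacher + %d test, have %d",
                 spec$n_teacher, n_test, n), call. = FALSE)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(draw_seed(spec$seed, 2L))
  test_idx <- sort(sample(n, n_test))
  rest <- setdiff(seq_len(n), test_idx)
  teach_idx <- sort(sample(rest, spec$n_teacher))
  pool_idx <- setdiff(rest, teach_idx)
  pool <- lapply(pairs[pool_idx], function(e)
    list(id = e$id, image = e$image, hidden_truth = e$mask))
  list(teacher = pairs[teach_idx], pool = pool, test = pairs[test_idx])
}

#' Generate pseudo labels for unlabelled images with a trained teacher
#'
#' @param teacher A trained model implementing the backbone contract.
#' @param pool List of entries \code{list(id, image, hidden_truth?)}.
#' @param threshold Probability cut for binarising teacher output.
#' @return List of pseudo pairs \code{list(id, image, mask, empty,
#'   hidden_truth, threshold)}; \code{empty} flags an all-background pseudo
#'   mask (the CCS stage skips those).
#' @export
generate_pseudo_labels <- function(teacher, pool, threshold = 0.5) {
  lapply(pool, function(e) {
    m <- predict_mask(teacher, e$image, threshold = threshold)
    list(id = e$id, image = e$image, mask = m, empty = sum(m) == 0L,
         hidden_truth = e$hidden_truth, threshold = threshold)
  })
}

#' Mean foreground IoU of pseudo labels against hidden pool truth
#'
#' @param pseudo Output of \code{\link{generate_pseudo_labels}} for a pool
#'   carrying hidden truth.
#' @return Mean per-image foreground IoU.
#' @export
pseudo_label_fidelity <- function(pseudo) {
  ious <- vapply(pseudo, function(p) {
    if (is.null(p$hidden_truth)) return(NA_real_)
    iou_score(confusion_counts(p$mask, p$hidden_truth))
  }, 0)
  mean(ious, na.rm = TRUE)
}

default_backbone <- function(seed) unet_tiny(seed = seed)

entry_pairs <- function(entries) {
  lapply(entries, function(e) list(image = e$image, mask = e$mask))
}

eval_on_test <- function(model, test, threshold = 0.5) {
  preds <- lapply(test, function(e) predict_mask(model, e$image, threshold))
  truths <- lapply(test, function(e) e$mask)
  ids <- vapply(test, function(e) e$id, "")
  list(micro = evaluate_dataset(preds, truths, mode = "micro", ids = ids),
       per_image = evaluate_dataset(preds, truths, mode = "per_image",
                                    ids = ids))
}

check_isolation <- function(manifests) {
  test <- manifests$test_ids
  leaked <- intersect(test, c(manifests$teacher_ids, manifests$pseudo_ids))
  if (length(leaked))
    stop("test-set isolation violated for ids: ",
         paste(leaked, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Supervised training baseline
#'
#' Trains one model on labelled data and evaluates it on the held-out test
#' split.  With \code{use = "all_train"} the model sees the whole 90\% train
#' side (the fully supervised reference); with \code{use = "teacher_subset"}
#' it sees only the teacher subset, giving the labelled-budget-matched
#' baseline that self-training must beat.
#'
#' @param dataset Labelled entries \code{list(id, image, mask)}.
#' @param split A \code{\link{split_spec}}.
#' @param config A \code{\link{train_config}}.
#' @param backbone Factory \code{function(seed)} returning an untrained
#'   model (default: \code{\link{unet_tiny}}).
#' @param use Which labelled pairs to train on (see above).
#' @param seed Run seed (model init and training stream).
#' @return A \code{run_report} (see \code{\link{run_self_training}}) with
#'   \code{mode = "supervised"}; the trained model is in \code{$student}.
#' @export
run_supervised_baseline <- function(dataset, split = split_spec(),
                                    config = train_config(),
                                    backbone = default_backbone,
                                    use = c("all_train", "teacher_subset"),
                                    seed = 1L) {
  use <- match.arg(use)
  sp <- split_dataset(dataset, split)
  train_entries <- if (use == "teacher_subset") sp$teacher else
    c(sp$teacher, lapply(sp$pool, function(e)
      list(id = e$id, image = e$image, mask = e$hidden_truth)))
  cfg <- config; cfg$seed <- draw_seed(seed, 12L)
  model <- backbone(draw_seed(seed, 14L))
  fit <- model_fit(model, entry_pairs(train_entries), cfg)
  manifests <- list(teacher_ids = vapply(train_entries, function(e) e$id, ""),
                    pseudo_ids = character(0),
                    test_ids = vapply(sp$test, function(e) e$id, ""))
  check_isolation(manifests)
  structure(list(mode = "supervised", seed = seed, use = use,
                 split = split, config = config,
                 optimiser = "adam (fixed learning rate)",
                 student = fit$model, student_fit = fit[c("curves", "best_epoch", "epochs_run")],
                 student_metrics = eval_on_test(fit$model, sp$test),
                 manifests = manifests),
            class = "run_report")
}

#' Run teacher-student self-training
#'
#' Standard mode trains the teacher on the labelled full frames and the
#' student on full-frame pseudo pairs (plus the real labelled pairs when
#' \code{include_real}).  CCS mode trains the teacher on the union of
#' labelled full frames and their centroid crops; pseudo pairs are
#' centroid-cropped around the teacher's predicted components and expanded by
#' the five-way augmentation before student training (real labelled pairs,
#' when included, get the same treatment).  Both modes evaluate teacher and
#' student on the held-out real-labelled test set by full-frame inference.
#'
#' @param dataset Labelled entries \code{list(id, image, mask)}.
#' @param split A \code{\link{split_spec}}.
#' @param mode \code{"ccs"} or \code{"standard"}.
#' @param crop_size CCS window side (default 32).
#' @param aug_spec An \code{\link{augmentation_spec}} for CCS mode.
#' @param config A \code{\link{train_config}} used for both models.
#' @param backbone Factory \code{function(seed)} returning an untrained model.
#' @param include_real Also feed the real labelled pairs to the student.
#' @param augment_teacher In CCS mode, expand the teacher's centroid crops by
#'   the five-way augmentation as well (default TRUE); the teacher always
#'   additionally sees the labelled full frames.
#' @param student_full_frames In CCS mode, additionally feed full-frame
#'   pseudo/real pairs to the student (default FALSE: crops only).
#' @param pseudo_threshold Binarisation threshold for pseudo labels.
#' @param eval_crops Additionally evaluate the student on centroid crops of
#'   the test images (windows placed from ground-truth centroids), reported
#'   as \code{student_metrics_crops}.  Full-frame evaluation is always
#'   performed and is the primary report.
#' @param seed Run seed.
#' @return A \code{run_report}: mode, manifests, trained \code{teacher} and
#'   \code{student}, their fit curves, test-set \code{teacher_metrics} and
#'   \code{student_metrics} (micro and per-image), and
#'   \code{pseudo_fidelity} (mean fg IoU of pseudo masks vs hidden truth).
#' @export
run_self_training <- function(dataset, split = split_spec(),
                              mode = c("ccs", "standard"),
                              crop_size = 32L,
                              aug_spec = augmentation_spec(),
                              config = train_config(),
                              backbone = default_backbone,
                              include_real = TRUE,
                              augment_teacher = TRUE,
                              student_full_frames = FALSE,
                              pseudo_threshold = 0.5,
                              eval_crops = FALSE,
                              seed = 1L) {
  mode <- match.arg(mode)
  sp <- split_dataset(dataset, split)

  # --- teacher ---
  teacher_pairs <- entry_pairs(sp$teacher)
  if (mode == "ccs") {
    tcrops <- ccs_sample_dataset(sp$teacher, crop_size)
    if (augment_teacher) tcrops <- augment_dataset(tcrops, aug_spec)
    teacher_pairs <- c(teacher_pairs,
                       lapply(tcrops,
                              function(cr) list(image = cr$image, mask = cr$mask)))
  }
  tcfg <- config; tcfg$seed <- draw_seed(seed, 11L)
  teacher_fit <- model_fit(backbone(draw_seed(seed, 13L)), teacher_pairs, tcfg)
  teacher <- teacher_fit$model

  # --- pseudo labels ---
  pool <- sp$pool
  if (!is.null(split$n_pseudo)) {
    if (split$n_pseudo > length(pool))
      stop(sprintf("insufficient pool: need %d pseudo, have %d",
                   split$n_pseudo, length(pool)), call. = FALSE)
    old <- .Random.seed_save(); set.seed(draw_seed(seed, 15L))
    pool <- pool[sort(sample(length(pool), split$n_pseudo))]
    .Random.seed_restore(old)
  }
  pseudo <- generate_pseudo_labels(teacher, pool, threshold = pseudo_threshold)
  fidelity <- if (length(pseudo)) pseudo_label_fidelity(pseudo) else NA_real_

  # --- student training set ---
  if (mode == "ccs") {
    crops <- ccs_sample_dataset(pseudo, crop_size)
    if (length(pseudo) > 0L && length(crops) == 0L)
      stop("all pseudo masks are empty after CCS; check teacher quality",
           call. = FALSE)
    student_items <- augment_dataset(crops, aug_spec)
    if (include_real)
      student_items <- c(student_items,
                         augment_dataset(ccs_sample_dataset(sp$teacher, crop_size),
                                         aug_spec))
    if (student_full_frames) {
      student_items <- c(student_items,
                         lapply(pseudo, function(p) list(image = p$image, mask = p$mask)),
                         if (include_real) entry_pairs(sp$teacher))
    }
  } else {
    student_items <- lapply(pseudo, function(p) list(image = p$image, mask = p$mask))
    if (include_real) student_items <- c(student_items, entry_pairs(sp$teacher))
  }
  if (length(student_items) == 0L)
    stop("student training set is empty", call. = FALSE)
  scfg <- config; scfg$seed <- draw_seed(seed, 12L)
  student_fit <- model_fit(backbone(draw_seed(seed, 14L)),
                           lapply(student_items, function(e)
                             list(image = e$image, mask = e$mask)), scfg)
  student <- student_fit$model

  manifests <- list(teacher_ids = vapply(sp$teacher, function(e) e$id, ""),
                    pseudo_ids = vapply(pseudo, function(p) p$id, ""),
                    test_ids = vapply(sp$test, function(e) e$id, ""))
  check_isolation(manifests)

  structure(list(mode = paste0(mode, "_self_training"), seed = seed,
                 split = split, config = config, crop_size = crop_size,
                 optimiser = "adam (fixed learning rate)",
                 teacher = teacher, student = student,
                 teacher_fit = teacher_fit[c("curves", "best_epoch", "epochs_run")],
                 student_fit = student_fit[c("curves", "best_epoch", "epochs_run")],
                 teacher_metrics = eval_on_test(teacher, sp$test),
                 student_metrics = eval_on_test(student, sp$test),
                 student_metrics_crops = if (eval_crops) {
                   tc <- ccs_sample_dataset(sp$test, crop_size)
                   evaluate_dataset(
                     lapply(tc, function(cr) predict_mask(student, cr$image)),
                     lapply(tc, function(cr) cr$mask),
                     mode = "micro",
                     ids = vapply(tc, function(cr)
                       sprintf("%s_c%02d", cr$id, cr$component), ""))
                 },
                 pseudo_fidelity = fidelity,
                 n_student_items = length(student_items),
                 manifests = manifests),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report %s, seed %d>\n", x$mode, x$seed))
  if (!is.null(x$teacher_metrics))
    cat(sprintf("  teacher: mIoU %.3f fgIoU %.3f | pseudo fidelity %.3f\n",
                x$teacher_metrics$micro$miou, x$teacher_metrics$micro$iou_fg,
                x$pseudo_fidelity))
  cat(sprintf("  student: mPA %.3f mIoU %.3f fgIoU %.3f Dice %.3f\n",
              x$student_metrics$micro$mpa, x$student_metrics$micro$miou,
              x$student_metrics$micro$iou_fg, x$student_metrics$micro$dice))
  invisible(x)
}

#' Sweep labelled and pseudo-labelled budgets
#'
#' Runs self-training over a grid of teacher-labelled counts,
#' pseudo-labelled counts and seeds, with split membership (and hence the
#' test set) shared across cells.  Infeasible cells are skipped with a
#' message.
#'
#' @param dataset Labelled entries.
#' @param labelled_counts Integer vector of teacher budgets.
#' @param pseudo_counts Integer vector of pseudo-label budgets.
#' @param seeds Integer vector of run seeds.
#' @param mode,crop_size,config,backbone,aug_spec Passed to
#'   \code{\link{run_self_training}}.
#' @param split_seed Seed fixing split membership across all cells.
#' @param test_fraction Held-out fraction.
#' @return data.frame with one row per completed run: budgets, seed, teacher
#'   and student summary metrics.
#' @export
#' @rdname run_sweeps
#' @param sweep Sweep result data.frame.
#' @param path Output TSV path.
#' @param value Metric column to tabulate (default student mIoU).
#' @export
write_sweep_table <- function(sweep, path, value = "student_miou") {
  cells <- unique(sweep[c("n_teacher", "n_pseudo")])
  seeds <- sort(unique(sweep$seed))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- sweep$n_teacher == cells$n_teacher[i] &
      sweep$n_pseudo == cells$n_pseudo[i]
    vals <- vapply(seeds, function(s) {
      v <- sweep[sel & sweep$seed == s, value]
      if (length(v)) v else NA_real_
    }, 0)
    out <- data.frame(n_teacher = cells$n_teacher[i],
                      n_pseudo = cells$n_pseudo[i])
    out[paste0("seed", seeds)] <- as.list(vals)
    out$mean <- mean(vals, na.rm = TRUE)
    out
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

run_sweeps <- function(dataset, labelled_counts, pseudo_counts, seeds,
                       mode = "ccs", crop_size = 32L,
                       config = train_config(),
                       backbone = default_backbone,
                       aug_spec = augmentation_spec(),
                       split_seed = 1L, test_fraction = 0.10) {
  grid <- expand.grid(n_teacher = labelled_counts, n_pseudo = pseudo_counts,
                      seed = seeds)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    sp <- split_spec(test_fraction = test_fraction, n_teacher = g$n_teacher,
                     n_pseudo = g$n_pseudo, seed = split_seed)
    rep <- tryCatch(
      run_self_training(dataset, split = sp, mode = mode,
                        crop_size = crop_size, aug_spec = aug_spec,
                        config = config, backbone = backbone, seed = g$seed),
      error = function(e) {
        message(sprintf("skipping cell n_teacher=%d n_pseudo=%d seed=%d: %s",
                        g$n_teacher, g$n_pseudo, g$seed, conditionMessage(e)))
        NULL
      })
    if (is.null(rep)) next
    rows[[length(rows) + 1L]] <- data.frame(
      n_teacher = g$n_teacher, n_pseudo = g$n_pseudo, seed = g$seed,
      mode = mode,
      teacher_miou = rep$teacher_metrics$micro$miou,
      teacher_iou_fg = rep$teacher_metrics$micro$iou_fg,
      student_mpa = rep$student_metrics$micro$mpa,
      student_miou = rep$student_metrics$micro$miou,
      student_iou_fg = rep$student_metrics$micro$iou_fg,
      student_dice = rep$student_metrics$micro$dice,
      pseudo_fidelity = rep$pseudo_fidelity)
  }
  do.call(rbind, rows)
}
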