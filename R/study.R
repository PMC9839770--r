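# A self-contained, scaled-down benchmark study on synthetic radiographs:
# the three training regimes (CCS self-training, standard self-training,
# labelled-budget-matched supervised baseline) on one seeded dataset, over
# several run seeds.  This is what the acceptance script and the end-to-end
# tests execute.

#' Run the scaled-down self-training benchmark study
#'
#' Generates a synthetic dataset (default: 120 frames of 96 x 96 pixels with
#' lesions of side ~8), splits it into 20 teacher-labelled images, a pool of
#' which 60 are pseudo-labelled, and ~12 held-out test images, then for each
#' run seed trains and evaluates (a) CCS-mode self-training, (b) standard
#' self-training, and (c) a supervised baseline restricted to the teacher
#' subset.  All randomness derives from \code{seed}.
#'
#' @param seed Master seed; dataset, split and run streams derive from it.
#' @param n_seeds Number of independent training repetitions.
#' @param n_images,frame,lesion_side Synthetic dataset scale.
#' @param n_teacher,n_pseudo Labelled/pseudo-labelled budgets.
#' @param crop_size CCS window side.
#' @param config A \code{\link{train_config}} (its seed field is overridden
#'   per run).
#' @return List with \code{runs} (data.frame, one row per seed with student
#'   and baseline test metrics and pseudo-label fidelity), \code{means}
#'   (named list of column means) and \code{reports} (the per-seed
#'   \code{run_report} triples).
#' @export
run_benchmark_study <- function(seed = 1L, n_seeds = 3L, n_images = 120L,
                                frame = 96L, lesion_side = 8,
                                n_teacher = 20L, n_pseudo = 60L,
                                crop_size = 32L, config = train_config()) {
  cfg <- synthetic_config(height = frame, width = frame, n_teeth = 4L,
                          lesion_side_mean = lesion_side, lesion_side_sd = 1.5,
                          seed = draw_seed(seed, 21L))
  dataset <- generate_dataset(n_images, cfg)
  split <- split_spec(n_teacher = n_teacher, n_pseudo = n_pseudo,
                      seed = draw_seed(seed, 22L))
  rows <- list(); reports <- list()
  for (k in seq_len(n_seeds)) {
    rs <- draw_seed(seed, 30L + k)
    ccs <- run_self_training(dataset, split, mode = "ccs",
                             crop_size = crop_size, config = config,
                             seed = rs)
    std <- run_self_training(dataset, split, mode = "standard",
                             config = config, seed = rs)
    base <- run_supervised_baseline(dataset, split, config = config,
                                    use = "teacher_subset", seed = rs)
    rows[[k]] <- data.frame(
      run = k,
      ccs_student_iou_fg = ccs$student_metrics$micro$iou_fg,
      ccs_student_miou = ccs$student_metrics$micro$miou,
      ccs_student_mpa = ccs$student_metrics$micro$mpa,
      ccs_student_dice = ccs$student_metrics$micro$dice,
      std_student_iou_fg = std$student_metrics$micro$iou_fg,
      std_student_miou = std$student_metrics$micro$miou,
      baseline_iou_fg = base$student_metrics$micro$iou_fg,
      baseline_miou = base$student_metrics$micro$miou,
      pseudo_fidelity = ccs$pseudo_fidelity)
    reports[[k]] <- list(ccs = ccs, standard = std, baseline = base)
  }
  runs <- do.call(rbind, rows)
  list(runs = runs, means = as.list(colMeans(runs[-1])),
       reports = reports, dataset_config = cfg, split = split)
}
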