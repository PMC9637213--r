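# Split, metrics, grid runner -------------------------------------------------

fake_manifest <- function(n_c, n_p) {
  data.frame(subject_id = c(sprintf("C%02d", seq_len(n_c)),
                            sprintf("P%02d", seq_len(n_p))),
             group = rep(c("control", "pd"), c(n_c, n_p)))
}

test_that("stratified split: per-group rounding, determinism, persistence", {
  man <- fake_manifest(25, 25)
  sp <- stratified_split(man, 0.6, seed = 3L)
  expect_length(sp$learning_ids, 30L)
  expect_length(sp$validation_ids, 20L)
  grp <- setNames(man$group, man$subject_id)
  expect_equal(sum(grp[sp$learning_ids] == "pd"), 15L)
  expect_equal(sum(grp[sp$validation_ids] == "control"), 10L)
  expect_identical(stratified_split(man, 0.6, seed = 3L), sp)
  expect_false(identical(stratified_split(man, 0.6, seed = 4L)$learning_ids,
                         sp$learning_ids))

  sp2 <- stratified_split(fake_manifest(2, 2), 0.5, seed = 1L)
  expect_length(sp2$learning_ids, 2L)
  expect_length(sp2$validation_ids, 2L)

  expect_error(stratified_split(man, 1.2), "learning_fraction")

  path <- withr::local_tempfile(fileext = ".json")
  save_split(sp, path)
  back <- load_split(path)
  expect_equal(back$learning_ids, sp$learning_ids)
  # tampering is caught by the hash
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  j$learning_ids[1] <- j$validation_ids[1]
  jsonlite::write_json(j, path, auto_unbox = TRUE)
  expect_error(load_split(path), "hash mismatch")
})

test_that("metrics match their definitions on stored predictions", {
  truth <- rep(c("pd", "control"), c(10, 10))
  pred <- c(rep("pd", 7), rep("control", 3), rep("control", 10))
  res <- classifier_metrics(pred, truth)
  expect_equal(c(res$tp, res$fn, res$tn, res$fp), c(7, 3, 10, 0))
  expect_equal(res$accuracy, 85)
  expect_equal(res$sensitivity, 70)
  expect_equal(res$specificity, 100)
  # identities recomputed from stored predictions
  expect_equal(res$accuracy,
               100 * mean(res$predicted == res$truth))
  all_right <- classifier_metrics(truth, truth)
  expect_equal(c(all_right$accuracy, all_right$sensitivity,
                 all_right$specificity), c(100, 100, 100))
})

test_that("swapping group labels swaps sensitivity and specificity", {
  set.seed(101)
  truth <- sample(c("control", "pd"), 30, replace = TRUE)
  pred <- sample(c("control", "pd"), 30, replace = TRUE)
  flip <- function(x) ifelse(x == "pd", "control", "pd")
  a <- classifier_metrics(pred, truth)
  b <- classifier_metrics(flip(pred), flip(truth))
  expect_equal(a$accuracy, b$accuracy)
  expect_equal(a$sensitivity, b$specificity)
  expect_equal(a$specificity, b$sensitivity)
})

test_that("grid runner emits one row per cell with consistent metrics", {
  cfg <- small_config(seed = 111L, n_per_group = 4L)
  coh <- generate_cohort(cfg)
  split <- stratified_split(coh$manifest, 0.5, seed = 2L)
  sets <- list(csp1 = list(type = "csp", components = "MxPMnC1"),
               fz = list(type = "laplacian",
                         masks = list(Fz = laplacian_mask("Fz", 1))))
  res <- suppressWarnings(
    run_grid(coh$records, coh$manifest, split, grid = cfg$grid,
             high_hz = 20, length_ms = c(250, 500),
             feature_sets = sets, classifiers = c("lda", "bayes")))
  expect_equal(nrow(res), 1L * 2L * 2L * 2L)
  # metric identities on every row
  n_valid <- length(split$validation_ids)
  expect_equal(res$accuracy, 100 * (res$tp + res$tn) / n_valid)
  expect_equal(res$sensitivity, 100 * res$tp / (res$tp + res$fn))
  expect_equal(res$specificity, 100 * res$tn / (res$tn + res$fp))
  expect_setequal(unique(res$type), c("csp", "laplacian"))
})

test_that("null band widens with the number of searched configurations", {
  b1 <- null_accuracy_band(20, 1)
  b2 <- null_accuracy_band(20, 100)
  expect_lt(b1[["upper"]], b2[["upper"]])
  expect_gt(b1[["lower"]], b2[["lower"]])
  expect_true(b2[["upper"]] <= 100 && b2[["lower"]] >= 0)
})

test_that("Monte-Carlo null calibration on a toy cohort stays inside the band", {
  grid <- toy_grid_3x3()
  amp <- rbind(control = c(Standard = 3, Novelty = 0, Target = 0),
               pd = c(Standard = 3, Novelty = 0, Target = 0))
  n_exceed <- 0L
  n_reps <- 10L
  n_cells <- 4L
  for (rep in seq_len(n_reps)) {
    cfg <- synthetic_config(
      n_per_group = 6L, grid = grid, duration_s = 20,
      events_per_task = c(Standard = 3L, Novelty = 1L, Target = 1L),
      erp_amplitude = amp, erp_center = "B2", noise_sigma = 2,
      source_gain = c(control = 0, pd = 0), seed = 200L + rep)
    coh <- generate_cohort(cfg)
    split <- stratified_split(coh$manifest, 0.6, seed = rep)
    sets <- list(csp1 = list(type = "csp", components = "MxPMnC1"),
                 b2 = list(type = "laplacian",
                           masks = list(B2 = laplacian_mask("B2", 1))))
    res <- suppressWarnings(
      run_grid(coh$records, coh$manifest, split, grid = grid,
               high_hz = 20, length_ms = 250,
               feature_sets = sets, classifiers = c("lda", "bayes")))
    expect_equal(nrow(res), n_cells)
    band <- null_accuracy_band(length(split$validation_ids), n_cells)
    if (max(res$accuracy) > band[["upper"]]) n_exceed <- n_exceed + 1L
  }
  # each rep exceeds with probability <= 5%; allow slack for correlation
  expect_lte(n_exceed, 3L)
})
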