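test_that("turning angles are signed, left-positive, and zero on straight tracks", {
  # three collinear, equally spaced fixes heading north: middle angle 0
  f <- mk_fixes(c(0, 3, 6), c(0, 1000, 2000))
  feat <- extract_features(f, candidate_structure("geometry", 1))
  expect_equal(unname(feat$x[1, "turning_angle_o0"]), 0, tolerance = 1e-6)

  # east-then-north dog-leg: a left turn of +pi/2
  p0 <- c(51, 3)
  p1 <- geosphere::destPoint(cbind(p0[2], p0[1]), 90, 800, a = 6371008.8, f = 0)
  p2 <- geosphere::destPoint(p1, 0, 800, a = 6371008.8, f = 0)
  f2 <- data.frame(individual_id = "X", pair_id = "P", sex = "male",
                   colony_id = "C",
                   timestamp = t_origin + c(0, 180, 360),
                   lat = c(p0[1], p1[1, 2], p2[1, 2]),
                   lon = c(p0[2], p1[1, 1], p2[1, 1]),
                   ground_speed = NA, acc_class = NA, habitat = NA,
                   true_behaviour = NA)
  feat2 <- extract_features(f2, candidate_structure("geometry", 1))
  expect_equal(unname(feat2$x[1, "turning_angle_o0"]), pi / 2,
               tolerance = 0.01)
  # step length matches the constructed 800 m hop
  expect_equal(unname(feat2$x[1, "step_length_o0"]), 800, tolerance = 1)
})

test_that("windowed feature matrices replicate per-point features across the window", {
  f <- mk_fixes(3 * (0:9), seq(0, 9000, by = 1000))
  f1 <- extract_features(f, candidate_structure("geometry", 1))
  f3 <- extract_features(f, candidate_structure("geometry", 3))
  expect_equal(ncol(f3$x), 3 * ncol(f1$x))
  expect_equal(nrow(f3$x), nrow(f1$x) - 2)
  f5 <- extract_features(f, candidate_structure("geometry", 5))
  expect_equal(ncol(f5$x), 5 * ncol(f1$x))
})

test_that("there are exactly 12 candidate structures and geometry is always included", {
  st <- all_structures()
  expect_equal(length(st), 12)
  labels <- vapply(st, pairforage:::structure_label, character(1))
  expect_equal(length(unique(labels)), 12)
  expect_true(all(vapply(st, function(s) "geometry" %in% s$streams,
                         logical(1))))
  expect_error(candidate_structure("geometry", 2), "window")
})

test_that("individual-level splits never leak an individual across halves and are seed-stable", {
  cfg <- sim_config(days = 1, n_pairs = 5)
  sim <- simulate_colony(cfg, seed = 4, fixes = TRUE)
  set.seed(101)
  sp <- split_by_individual(sim$fixes, 0.5)
  expect_length(intersect(unique(sp$train$individual_id),
                          unique(sp$validate$individual_id)), 0)
  expect_equal(length(sp$train_ids), 5)
  set.seed(101)
  sp2 <- split_by_individual(sim$fixes, 0.5)
  expect_identical(sp$train_ids, sp2$train_ids)
})

test_that("classification metrics match hand-derived values from a fixed confusion matrix", {
  cm <- matrix(c(45, 5, 0,
                 10, 30, 10,
                 0, 5, 45), 3, 3, byrow = TRUE,
               dimnames = list(c("commute", "forage", "rest"),
                               c("commute", "forage", "rest")))
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, 0.80, tolerance = 1e-12)
  expect_equal(m$kappa, 0.70, tolerance = 1e-12)
  expect_equal(unname(m$precision["commute"]), 45 / 55, tolerance = 1e-12)
  expect_equal(unname(m$recall["commute"]), 0.90, tolerance = 1e-12)

  # perfect predictions
  perfect <- diag(c(10, 20, 30))
  mp <- classification_metrics(perfect)
  expect_equal(mp$accuracy, 1)
  expect_equal(mp$kappa, 1)

  # all predictions a single class: chance-level kappa 0
  one <- matrix(0, 3, 3); one[, 1] <- c(10, 20, 30)
  mo <- classification_metrics(one)
  expect_equal(mo$kappa, 0, tolerance = 1e-12)
})

test_that("kappa is invariant under simultaneous row/column permutation", {
  set.seed(8)
  cm <- matrix(rpois(9, 20), 3, 3)
  k0 <- classification_metrics(cm)$kappa
  for (i in 1:5) {
    pm <- sample(3)
    expect_equal(classification_metrics(cm[pm, pm])$kappa, k0,
                 tolerance = 1e-12)
  }
})

test_that("training errors when a behaviour class is missing and selection traces all 12 structures", {
  cfg <- sim_config(days = 1, n_pairs = 2)
  sim <- simulate_colony(cfg, seed = 14, fixes = TRUE)
  only_rest <- sim$fixes[sim$fixes$true_behaviour == "rest", ]
  only_rest <- only_rest[order(only_rest$individual_id, only_rest$timestamp), ]
  expect_error(train_select(only_rest), "absent")

  set.seed(61)
  m <- train_select(sim$fixes, num_trees = 50, max_depth = c(4), folds = 2)
  expect_equal(nrow(m$selection), 12)
  expect_s3_class(m, "behaviour_model")
  expect_gte(m$internal_kappa, 0.8)
})

test_that("prediction appends a behaviour column aligned to the input rows", {
  cfg <- sim_config(days = 1, n_pairs = 3)
  sim <- simulate_colony(cfg, seed = 19, fixes = TRUE)
  set.seed(71)
  halves <- split_by_individual(sim$fixes, 0.5)
  m <- train_select(halves$train,
                    structures = list(candidate_structure(c("geometry", "body"), 3)),
                    num_trees = 50, max_depth = 6, folds = 2)
  pred <- predict(m, halves$validate)
  expect_equal(nrow(pred), nrow(halves$validate))
  filled <- !is.na(pred$pred_behaviour)
  expect_gt(mean(filled), 0.95)
  acc <- mean(pred$pred_behaviour[filled] == pred$true_behaviour[filled])
  expect_gt(acc, 0.85)
  rep <- evaluate(m, halves$validate)
  expect_s3_class(rep, "training_report")
  expect_gte(rep$accuracy, 0.85)
  expect_equal(rep$accuracy,
               sum(diag(rep$confusion)) / sum(rep$confusion))
})

test_that("unseen categorical levels encode as zeros with a warning", {
  cfg <- sim_config(days = 1, n_pairs = 2)
  sim <- simulate_colony(cfg, seed = 25, fixes = TRUE)
  st <- candidate_structure(c("geometry", "habitat"), 1)
  feat <- extract_features(sim$fixes, st)
  odd <- sim$fixes
  odd$habitat[1:50] <- "volcano"
  expect_warning(extract_features(odd, st, levels = feat$levels), "unseen")
})
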