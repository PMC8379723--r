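#' Candidate input structures for the behaviour classifier
#'
#' A candidate structure is a combination of feature streams (path geometry
#' always; optionally habitat and/or body movement) and a symmetric input
#' window of 1, 3 or 5 points: 4 stream sets x 3 windows = 12 candidates.
#'
#' @param streams Character subset of `c("geometry", "habitat", "body")`;
#'   `"geometry"` is always included.
#' @param window Odd window size: 1, 3 or 5.
#' @return A list of class `candidate_structure`.
#' @export
candidate_structure <- function(streams = "geometry", window = 1) {
  streams <- union("geometry", streams)
  stopifnot(all(streams %in% c("geometry", "habitat", "body")),
            window %in% c(1, 3, 5))
  structure(list(streams = sort(streams), window = as.integer(window)),
            class = "candidate_structure")
}

#' @rdname candidate_structure
#' @return `all_structures()`: the list of all 12 candidates.
#' @export
all_structures <- function() {
  sets <- list("geometry",
               c("geometry", "habitat"),
               c("geometry", "body"),
               c("geometry", "habitat", "body"))
  out <- list()
  for (s in sets) for (w in c(1, 3, 5))
    out[[length(out) + 1]] <- candidate_structure(s, w)
  out
}

structure_label <- function(st)
  paste0(paste(st$streams, collapse = "+"), " / w", st$window)

#' Trajectory features for behaviour classification
#'
#' Per-fix features: step length (m, great-circle distance from the previous
#' fix), signed turning angle (radians, left turn positive, from the change
#' in initial bearings at the focal fix), and -- depending on the structure's
#' streams -- ground speed plus accelerometer class (body) and habitat
#' class. A window of k points concatenates the features of the focal fix and
#' its (k-1)/2 neighbours on each side; rows without full context (track
#' ends) are dropped. Categorical features are one-hot encoded; the level
#' sets are recorded so that prediction-time encoding matches (unseen levels
#' encode as all zeros with a warning).
#'
#' @param fixes Fix `data.frame`, time-sorted within individuals, with a
#'   `true_behaviour` (or `label`) column when used for training.
#' @param structure A [candidate_structure()].
#' @param levels Optional encoding levels from a fitted model.
#' @return List with numeric `x` (feature matrix), `y` (labels or NULL),
#'   `individual_id` per row, and the categorical `levels` used.
#' @export
extract_features <- function(fixes, structure = candidate_structure(),
                             levels = NULL) {
  half <- (structure$window - 1L) %/% 2L
  per_ind <- lapply(split(seq_len(nrow(fixes)), fixes$individual_id), function(ix) {
    f <- fixes[ix, , drop = FALSE]
    n <- nrow(f)
    if (n < max(3, structure$window)) {
      warning("skipping individual ", f$individual_id[1],
              ": too few fixes for window ", structure$window)
      return(NULL)
    }
    step <- c(NA, great_circle_km(f$lat[-n], f$lon[-n],
                                  f$lat[-1], f$lon[-1]) * 1000)
    b_in <- c(NA, bearing_deg(f$lat[-n], f$lon[-n], f$lat[-1], f$lon[-1]))
    b_out <- c(b_in[-1], NA)
    turn <- .wrap_angle_deg(b_in - b_out) * pi / 180   # left turn positive
    base <- data.frame(step_length = step, turning_angle = turn)
    if ("body" %in% structure$streams) {
      base$ground_speed <- f$ground_speed
      base$acc_class <- as.character(f$acc_class)
    }
    if ("habitat" %in% structure$streams)
      base$habitat <- as.character(f$habitat)
    lab <- if (!is.null(f$true_behaviour)) as.character(f$true_behaviour)
           else if (!is.null(f$label)) as.character(f$label) else NULL
    list(base = base, lab = lab, id = f$individual_id[1], n = n, ix = ix)
  })
  per_ind <- Filter(Negate(is.null), per_ind)
  if (!length(per_ind)) stop("no individual has enough fixes")

  cat_cols <- intersect(c("acc_class", "habitat"), names(per_ind[[1]]$base))
  if (is.null(levels)) {
    levels <- lapply(cat_cols, function(cc)
      sort(unique(stats::na.omit(unlist(lapply(per_ind, function(p) p$base[[cc]]))))))
    names(levels) <- cat_cols
  }

  rows_x <- list(); rows_y <- list(); rows_id <- list(); rows_ix <- list()
  for (p in per_ind) {
    enc <- .encode_features(p$base, levels)
    n <- nrow(enc)
    # valid focal rows: turning angle defined (2..n-1) and window context
    lo <- 2L + half; hi <- n - 1L - half
    if (hi < lo) next
    focal <- lo:hi
    offs <- -half:half
    xw <- do.call(cbind, lapply(offs, function(o) {
      m <- enc[focal + o, , drop = FALSE]
      colnames(m) <- paste0(colnames(enc), "_o", o)
      m
    }))
    keep <- stats::complete.cases(xw)
    rows_x[[length(rows_x) + 1]] <- xw[keep, , drop = FALSE]
    if (!is.null(p$lab))
      rows_y[[length(rows_y) + 1]] <- p$lab[focal][keep]
    rows_id[[length(rows_id) + 1]] <- rep(p$id, sum(keep))
    rows_ix[[length(rows_ix) + 1]] <- p$ix[focal][keep]
  }
  list(x = do.call(rbind, rows_x),
       y = if (length(rows_y)) unlist(rows_y) else NULL,
       individual_id = unlist(rows_id),
       row = unlist(rows_ix),
       levels = levels, structure = structure)
}

.wrap_angle_deg <- function(a) {
  w <- (a + 180) %% 360 - 180
  # map -180 to +180 so angles lie in (-180, 180]
  w[!is.na(w) & w == -180] <- 180
  w
}

.encode_features <- function(base, levels) {
  num <- base[, setdiff(names(base), names(levels)), drop = FALSE]
  mats <- list(as.matrix(num))
  for (cc in names(levels)) {
    if (is.null(base[[cc]])) next
    lv <- levels[[cc]]
    v <- base[[cc]]
    unseen <- !is.na(v) & !(v %in% lv)
    if (any(unseen))
      warning("unseen ", cc, " level(s) at prediction time: ",
              paste(unique(v[unseen]), collapse = ", "),
              " (encoded as all zeros)")
    m <- matrix(0, nrow(base), length(lv),
                dimnames = list(NULL, paste0(cc, "_", lv)))
    hit <- which(!is.na(v) & v %in% lv)
    m[cbind(hit, match(v[hit], lv))] <- 1
    mats[[length(mats) + 1]] <- m
  }
  do.call(cbind, mats)
}

#' Split a fix table by individual
#'
#' Randomly assigns whole individuals to a training or validation half, so no
#' individual contributes fixes to both sides.
#'
#' @param fixes Fix `data.frame`.
#' @param fraction Fraction of individuals assigned to training.
#' @return List with `train` and `validate` fix `data.frame`s and the id
#'   assignment.
#' @export
split_by_individual <- function(fixes, fraction = 0.5) {
  ids <- unique(fixes$individual_id)
  stopifnot(length(ids) >= 2)
  n_train <- round(fraction * length(ids))
  n_train <- min(max(n_train, 1), length(ids) - 1)
  train_ids <- sample(ids, n_train)
  list(train = fixes[fixes$individual_id %in% train_ids, , drop = FALSE],
       validate = fixes[!fixes$individual_id %in% train_ids, , drop = FALSE],
       train_ids = train_ids,
       validate_ids = setdiff(ids, train_ids))
}

#' Train the behaviour classifier with structure and hyperparameter selection
#'
#' For each of the 12 candidate input structures, tunes the number of trees
#' and the tree depth of a random-forest classifier by grouped
#' cross-validation on the training individuals only (folds split by
#' individual, so tuning mirrors the individual-level validation), then
#' selects the structure with the highest internal Cohen's kappa and refits
#' it on the full training set. Validation data must never enter this
#' function.
#'
#' @param train_fixes Training fix `data.frame` with behaviour labels
#'   (`true_behaviour` or `label`); all three classes must be present.
#' @param structures List of candidates (default [all_structures()]).
#' @param num_trees,max_depth Tuning grids (`max_depth` 0 = unlimited).
#' @param folds Number of grouped CV folds.
#' @return A `behaviour_model`: the fitted ranger forest, the selected
#'   structure, encoding levels, the tuned parameters, and a 12-row
#'   `selection` trace (structure label, best parameters, internal kappa and
#'   accuracy).
#' @export
train_select <- function(train_fixes, structures = all_structures(),
                         num_trees = c(100, 300), max_depth = c(0, 8),
                         folds = 5) {
  lab_col <- if (!is.null(train_fixes$true_behaviour)) "true_behaviour" else "label"
  classes <- c("rest", "commute", "forage")
  present <- classes %in% unique(as.character(train_fixes[[lab_col]]))
  if (!all(present))
    stop("class(es) absent from training data: ",
         paste(classes[!present], collapse = ", "))

  grid <- expand.grid(num_trees = num_trees, max_depth = max_depth)
  trace <- list(); best <- NULL
  for (st in structures) {
    feat <- extract_features(train_fixes, st)
    fold_of <- .grouped_folds(feat$individual_id, folds)
    scores <- apply(grid, 1, function(g) {
      ks <- vapply(seq_len(max(fold_of)), function(f) {
        tr <- fold_of != f; va <- fold_of == f
        if (!any(va) || length(unique(feat$y[tr])) < 2) return(NA_real_)
        fit <- ranger::ranger(x = feat$x[tr, , drop = FALSE],
                              y = factor(feat$y[tr], levels = classes),
                              num.trees = g[["num_trees"]],
                              max.depth = g[["max_depth"]],
                              num.threads = 1)
        pred <- predict(fit, data = feat$x[va, , drop = FALSE],
                        num.threads = 1)$predictions
        cm <- table(factor(feat$y[va], levels = classes),
                    factor(pred, levels = classes))
        classification_metrics(cm)$kappa
      }, numeric(1))
      mean(ks, na.rm = TRUE)
    })
    gi <- which.max(scores)
    trace[[length(trace) + 1]] <- data.frame(
      structure = structure_label(st), window = st$window,
      streams = paste(st$streams, collapse = "+"),
      num_trees = grid$num_trees[gi], max_depth = grid$max_depth[gi],
      internal_kappa = scores[gi], stringsAsFactors = FALSE)
    if (is.null(best) || scores[gi] > best$kappa + 1e-12) {
      best <- list(structure = st, num_trees = grid$num_trees[gi],
                   max_depth = grid$max_depth[gi], kappa = scores[gi],
                   feat = feat)
    }
  }
  fit <- ranger::ranger(x = best$feat$x,
                        y = factor(best$feat$y, levels = classes),
                        num.trees = best$num_trees, max.depth = best$max_depth,
                        num.threads = 1)
  structure(list(forest = fit, structure = best$structure,
                 levels = best$feat$levels, classes = classes,
                 num_trees = best$num_trees, max_depth = best$max_depth,
                 internal_kappa = best$kappa,
                 selection = do.call(rbind, trace)),
            class = "behaviour_model")
}

.grouped_folds <- function(ids, folds) {
  u <- unique(ids)
  k <- min(folds, length(u))
  assign <- sample(rep(seq_len(k), length.out = length(u)))
  assign[match(ids, u)]
}

#' @export
print.behaviour_model <- function(x, ...) {
  cat(sprintf("<behaviour_model: %s, %d trees, depth %s, internal kappa %.3f>\n",
              structure_label(x$structure), x$num_trees,
              if (x$max_depth == 0) "unlimited" else x$max_depth,
              x$internal_kappa))
  invisible(x)
}

#' Predict behaviour classes for a fix table
#'
#' @param object A `behaviour_model`.
#' @param fixes Fix `data.frame`.
#' @param ... Unused.
#' @return `fixes` with a `pred_behaviour` column (NA where the window had no
#'   full context).
#' @export
predict.behaviour_model <- function(object, fixes, ...) {
  feat <- extract_features(fixes, object$structure, levels = object$levels)
  pred <- predict(object$forest, data = feat$x, num.threads = 1)$predictions
  fixes$pred_behaviour <- NA_character_
  fixes$pred_behaviour[feat$row] <- as.character(pred)
  fixes
}

#' Evaluate a behaviour model on held-out individuals
#'
#' @param model A `behaviour_model`.
#' @param validate_fixes Labelled fixes from individuals not used in
#'   training.
#' @return A list (class `training_report`): confusion matrix (rows = truth,
#'   columns = prediction), accuracy, Cohen's kappa, per-class precision,
#'   recall and specificity, plus the selected structure.
#' @export
evaluate <- function(model, validate_fixes) {
  feat <- extract_features(validate_fixes, model$structure,
                           levels = model$levels)
  if (is.null(feat$y)) stop("validation fixes carry no labels")
  pred <- predict(model$forest, data = feat$x, num.threads = 1)$predictions
  cm <- table(truth = factor(feat$y, levels = model$classes),
              prediction = factor(pred, levels = model$classes))
  out <- classification_metrics(cm)
  out$structure <- structure_label(model$structure)
  class(out) <- "training_report"
  out
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf("<training_report: accuracy %.3f, kappa %.3f%s>\n",
              x$accuracy, x$kappa,
              if (!is.null(x$structure)) paste0(", ", x$structure) else ""))
  print(x$confusion)
  invisible(x)
}

#' Agreement metrics from a confusion matrix
#'
#' Accuracy, Cohen's kappa `(p_o - p_e) / (1 - p_e)` with expected agreement
#' from the marginal products, and per-class precision (column-correct over
#' column total of predictions), recall (row-correct over row total of
#' truths) and specificity. Rows are truths, columns predictions. Classes
#' absent from the validation truths get `NA` recall, flagged by a warning.
#'
#' @param confusion Square numeric matrix or table.
#' @return List with `confusion`, `accuracy`, `kappa`, `precision`,
#'   `recall`, `specificity`.
#' @export
classification_metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  stopifnot(nrow(cm) == ncol(cm))
  n <- sum(cm)
  p_o <- sum(diag(cm)) / n
  row_m <- rowSums(cm); col_m <- colSums(cm)
  p_e <- sum(row_m * col_m) / n^2
  kappa <- if (abs(1 - p_e) < 1e-15) {
    if (p_o >= 1 - 1e-15) 1 else NA_real_
  } else (p_o - p_e) / (1 - p_e)
  precision <- ifelse(col_m > 0, diag(cm) / col_m, NA_real_)
  recall <- ifelse(row_m > 0, diag(cm) / row_m, NA_real_)
  if (any(row_m == 0))
    warning("class(es) absent from truths: recall undefined for ",
            paste(rownames(cm)[row_m == 0], collapse = ", "))
  specificity <- vapply(seq_len(nrow(cm)), function(k) {
    tn <- n - row_m[k] - col_m[k] + cm[k, k]
    neg <- n - row_m[k]
    if (neg > 0) tn / neg else NA_real_
  }, numeric(1))
  names(precision) <- names(recall) <- rownames(cm)
  names(specificity) <- rownames(cm)
  list(confusion = cm, accuracy = p_o, kappa = kappa,
       precision = precision, recall = recall, specificity = specificity)
}
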