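# Dyad-aware nested stratified cross-validated linear SVM predicting each
# individual's dyad type, with training-only preprocessing (median imputation,
# [-1, 1] scaling, zero-variance pruning), class-weighted squared-hinge loss,
# an inner-loop ROC-optimised decision threshold, and a dyad-level label
# permutation test.

#' Build the classification feature matrix
#'
#' One row per individual; columns are the nine individual and six dyadic
#' features of each task, concatenated task-wise (default) or averaged over
#' tasks. Dyadic values are repeated for both dyad members; mixed dyads are
#' the positive class. Individuals missing a task are excluded with a warning.
#'
#' @param feature_table Feature table as from [compute_feature_table()].
#' @param aggregate `"concat"` (default; `2 x 15` columns) or `"mean"`.
#' @return A `feature_matrix`: list with `X` (numeric matrix), `y` (factor
#'   with levels `non_autistic`, `mixed`), `dyad_id`, `participant_id`.
#' @export
build_feature_matrix <- function(feature_table,
                                 aggregate = c("concat", "mean")) {
  aggregate <- match.arg(aggregate)
  feats <- setdiff(feature_table_columns(),
                   c("participant_id", "dyad_id", "task", "group",
                     "dyad_type"))
  ft <- feature_table
  tasks_present <- sort(unique(ft$task))
  cnt <- table(ft$participant_id)
  complete <- names(cnt)[cnt == length(tasks_present)]
  dropped <- setdiff(unique(ft$participant_id), complete)
  if (length(dropped)) {
    warning("excluding ", length(dropped),
            " individual(s) missing a task: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    ds_log("warn", "feature matrix: excluded ", length(dropped),
           " individual(s) missing a task")
  }
  ft <- ft[ft$participant_id %in% complete, ]
  ids <- sort(unique(ft$participant_id))
  task_order <- intersect(TASKS, tasks_present)
  if (aggregate == "concat") {
    blocks <- lapply(task_order, function(tk) {
      sub <- ft[ft$task == tk, ]
      sub <- sub[match(ids, sub$participant_id), ]
      m <- as.matrix(sub[, feats])
      colnames(m) <- paste(feats, tk, sep = ".")
      m
    })
    X <- do.call(cbind, blocks)
  } else {
    X <- do.call(cbind, lapply(feats, function(f)
      tapply(ft[[f]], ft$participant_id, mean)[ids]))
    colnames(X) <- feats
  }
  rownames(X) <- ids
  meta <- ft[match(ids, ft$participant_id), ]
  y <- factor(meta$dyad_type, levels = c("non_autistic", "mixed"))
  structure(list(X = X, y = y, dyad_id = meta$dyad_id,
                 participant_id = ids), class = "feature_matrix")
}

# stratified assignment of dyads to k folds: per class, shuffled dyads are
# chunked into k near-equal parts and the parts dealt to a random fold order
assign_stratified <- function(dyads, labels, k) {
  fold <- stats::setNames(integer(length(dyads)), dyads)
  for (cl in unique(labels)) {
    d <- sample(dyads[labels == cl])
    sizes <- rep(length(d) %/% k, k)
    extra <- length(d) %% k
    if (extra > 0) {
      bump <- sample.int(k, extra)
      sizes[bump] <- sizes[bump] + 1L
    }
    ord <- sample.int(k)
    pos <- 1L
    for (j in seq_len(k)) {
      if (sizes[ord[j]] == 0L) next
      take <- d[pos:(pos + sizes[ord[j]] - 1L)]
      fold[take] <- ord[j]
      pos <- pos + sizes[ord[j]]
    }
  }
  fold
}

#' Build a dyad-aware nested stratified cross-validation plan
#'
#' Assigns dyads (never individuals) to folds, so both members of a dyad
#' always share a fold; per outer fold the class ratio is kept within one
#' dyad of the global ratio. The outer loop has `outer_folds` folds repeated
#' over `outer_perms` permutations; for each outer training partition an
#' inner plan with `inner_folds` folds (capped at the number of training
#' dyads) is drawn.
#'
#' @param dyad_ids Character vector of dyad ids (one entry per dyad).
#' @param labels Dyad labels, same length (`mixed` / `non_autistic`).
#' @param outer_folds,outer_perms,inner_folds,inner_perms CV structure
#'   (defaults 7, 10, 10, 1).
#' @param seed Integer seed; the plan is deterministic given it.
#' @return A `cv_plan`: list of permutations, each with `outer` (named fold
#'   vector over dyads) and `inner` (per outer fold, named fold vector over
#'   the training dyads).
#' @export
make_cv_plan <- function(dyad_ids, labels, outer_folds = 7L,
                         outer_perms = 10L, inner_folds = 10L,
                         inner_perms = 1L, seed = 1L) {
  stopifnot(length(dyad_ids) == length(labels), !anyDuplicated(dyad_ids))
  labels <- as.character(labels)
  for (cl in unique(labels)) if (sum(labels == cl) < outer_folds)
    stop("stratification infeasible: class '", cl, "' has ",
         sum(labels == cl), " dyads but ", outer_folds,
         " outer folds require at least one per fold", call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("stratification infeasible: need two classes", call. = FALSE)
  set.seed(seed)
  perms <- lapply(seq_len(outer_perms), function(p) {
    repeat {
      outer <- assign_stratified(dyad_ids, labels, outer_folds)
      ok <- all(vapply(seq_len(outer_folds), function(f)
        length(unique(labels[outer == f])) == 2L, logical(1)))
      if (ok) break
    }
    inner <- lapply(seq_len(outer_folds), function(f) {
      tr <- dyad_ids[outer != f]
      trl <- labels[outer != f]
      k <- min(inner_folds, length(tr))
      assign_stratified(tr, trl, k)
    })
    list(outer = outer, inner = inner)
  })
  structure(list(perms = perms, outer_folds = outer_folds,
                 outer_perms = outer_perms, inner_folds = inner_folds,
                 inner_perms = inner_perms, dyad_ids = dyad_ids,
                 labels = labels, seed = seed), class = "cv_plan")
}

## ---- preprocessing (training rows only) --------------------------------

preprocess_fit <- function(X) {
  med <- apply(X, 2, stats::median, na.rm = TRUE)
  med[is.na(med)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- med[j]
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  keep <- hi - lo > 1e-12
  list(median = med, lo = lo, hi = hi, keep = keep)
}

preprocess_apply <- function(X, prep) {
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- prep$median[j]
  X <- X[, prep$keep, drop = FALSE]
  lo <- prep$lo[prep$keep]; hi <- prep$hi[prep$keep]
  sweep(sweep(X, 2, (lo + hi) / 2), 2, (hi - lo) / 2, "/")
}

## ---- linear SVM, squared hinge loss, squared-norm penalty --------------

# minimises 0.5 ||w||^2 + C * sum_i cw_i * max(0, 1 - y_i (x_i w + b))^2
# (smooth convex primal; L-BFGS with analytic gradient, tolerance-driven)
svm_l2l2_fit <- function(X, y, C, class_weights = NULL) {
  yy <- ifelse(y == levels(y)[2L], 1, -1)
  if (is.null(class_weights)) {
    n <- length(yy)
    class_weights <- c(n / (2 * sum(yy < 0)), n / (2 * sum(yy > 0)))
  }
  cw <- ifelse(yy > 0, class_weights[2L], class_weights[1L])
  d <- ncol(X)
  fn <- function(th) {
    w <- th[-1L]
    m <- 1 - yy * (drop(X %*% w) + th[1L])
    m[m < 0] <- 0
    0.5 * sum(w^2) + C * sum(cw * m^2)
  }
  gr <- function(th) {
    w <- th[-1L]
    m <- 1 - yy * (drop(X %*% w) + th[1L])
    act <- m > 0
    gmult <- numeric(length(yy))
    gmult[act] <- -2 * C * cw[act] * m[act] * yy[act]
    c(sum(gmult), w + drop(crossprod(X, gmult)))
  }
  opt <- stats::optim(numeric(d + 1L), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = 200, factr = 1e4))
  list(b = opt$par[1L], w = opt$par[-1L], levels = levels(y))
}

svm_decision <- function(model, X) drop(X %*% model$w) + model$b

#' Balanced accuracy
#'
#' Arithmetic mean of sensitivity and specificity.
#'
#' @param sensitivity,specificity Rates in `[0, 1]`.
#' @return The balanced accuracy.
#' @export
balanced_accuracy <- function(sensitivity, specificity) {
  if (any(!is.finite(c(sensitivity, specificity))) ||
      any(c(sensitivity, specificity) < 0) ||
      any(c(sensitivity, specificity) > 1))
    stop("sensitivity and specificity must lie in [0, 1]", call. = FALSE)
  (sensitivity + specificity) / 2
}

bac_of <- function(pred_pos, is_pos) {
  sens <- mean(pred_pos[is_pos]); spec <- mean(!pred_pos[!is_pos])
  if (is.nan(sens) || is.nan(spec)) return(NA_real_)
  balanced_accuracy(sens, spec)
}

# Youden-J optimal threshold on scores (positive class should score high)
youden_threshold <- function(scores, is_pos) {
  if (!any(is_pos) || all(is_pos)) return(0)
  cand <- sort(unique(scores))
  cand <- c(cand[1L] - 1e-8,
            (cand[-1L] + cand[-length(cand)]) / 2,
            cand[length(cand)] + 1e-8)
  j <- vapply(cand, function(th) {
    sens <- mean(scores[is_pos] > th)
    spec <- mean(scores[!is_pos] <= th)
    sens + spec - 1
  }, numeric(1))
  cand[which.max(j)]
}

# rank-based AUC (Mann-Whitney)
auc_mw <- function(scores, is_pos) {
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[is_pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fit and evaluate the nested cross-validated linear SVM
#'
#' Within every outer training partition, preprocessing (median imputation,
#' `[-1, 1]` scaling, zero-variance pruning) is estimated on training rows
#' only; the inner loop selects the penalty `C` maximising the pooled
#' inner out-of-fold balanced accuracy, and the decision threshold is shifted
#' to the Youden-J optimum of the inner out-of-fold scores before predicting
#' the outer test dyads. Misclassification penalties are weighted inversely
#' to class frequencies. Per-individual decision scores are averaged over the
#' outer permutations and labels decided by majority vote (ties broken by the
#' mean score).
#'
#' @param fm A `feature_matrix` from [build_feature_matrix()].
#' @param plan A `cv_plan` from [make_cv_plan()] (or `NULL` to build one from
#'   `seed`).
#' @param grid Penalty grid (default `2^(-6:6)`).
#' @param seed Seed used only when `plan` is `NULL`.
#' @param optimize_threshold Shift the decision threshold to the inner
#'   out-of-fold Youden-J optimum (default `TRUE`). With a single-value
#'   `grid` and `optimize_threshold = FALSE` the inner loop is skipped
#'   entirely — the lean configuration used for large permutation batches.
#' @param details Keep per-fold diagnostics (chosen `C`, threshold, kept
#'   features, scaling bounds) for leakage auditing.
#' @return A `classifier_report`: list with `individuals` (per-individual
#'   mean decision score, majority label, true label), `balanced_accuracy`,
#'   `sensitivity`, `specificity`, `auc`, and optionally `details`.
#' @export
fit_predict_nested <- function(fm, plan = NULL, grid = 2^(-6:6), seed = 1L,
                               optimize_threshold = TRUE, details = FALSE) {
  X <- fm$X; y <- fm$y; dyads <- fm$dyad_id
  dyad_ids <- unique(dyads)
  dyad_lab <- as.character(y)[match(dyad_ids, dyads)]
  if (is.null(plan))
    plan <- make_cv_plan(dyad_ids, dyad_lab, seed = seed)
  pos <- "mixed"
  n <- nrow(X)
  score_mat <- matrix(NA_real_, n, length(plan$perms))
  pred_mat <- matrix(NA, n, length(plan$perms))
  diag_list <- list()
  for (p in seq_along(plan$perms)) {
    pp <- plan$perms[[p]]
    for (f in seq_len(plan$outer_folds)) {
      test_dyads <- names(pp$outer)[pp$outer == f]
      tr_rows <- which(!dyads %in% test_dyads)
      te_rows <- which(dyads %in% test_dyads)
      Xtr_raw <- X[tr_rows, , drop = FALSE]
      ytr <- droplevels(factor(y[tr_rows], levels = levels(y)))
      inner <- pp$inner[[f]]
      run_inner <- length(grid) > 1L || optimize_threshold
      # inner loop: pooled out-of-fold scores per penalty value
      oof <- matrix(NA_real_, length(tr_rows), length(grid))
      if (run_inner) for (g in seq_len(max(inner))) {
        hold_dyads <- names(inner)[inner == g]
        itr <- which(!dyads[tr_rows] %in% hold_dyads)
        ite <- which(dyads[tr_rows] %in% hold_dyads)
        if (length(ite) == 0L || length(unique(ytr[itr])) < 2L) next
        prep_i <- preprocess_fit(Xtr_raw[itr, , drop = FALSE])
        if (!any(prep_i$keep)) next
        Xi <- preprocess_apply(Xtr_raw[itr, , drop = FALSE], prep_i)
        Xh <- preprocess_apply(Xtr_raw[ite, , drop = FALSE], prep_i)
        for (ci in seq_along(grid)) {
          mod <- svm_l2l2_fit(Xi, ytr[itr], grid[ci])
          oof[ite, ci] <- svm_decision(mod, Xh)
        }
      }
      is_pos_tr <- ytr == pos
      bacs <- apply(oof, 2, function(sc) {
        ok <- !is.na(sc)
        if (!any(ok)) return(NA_real_)
        bac_of(sc[ok] > 0, is_pos_tr[ok])
      })
      best <- if (all(is.na(bacs))) which.min(abs(log(grid))) else
        which(bacs == max(bacs, na.rm = TRUE))[1L]
      thr <- 0
      if (optimize_threshold && any(!is.na(oof[, best]))) {
        ok <- !is.na(oof[, best])
        thr <- youden_threshold(oof[ok, best], is_pos_tr[ok])
      }
      prep <- preprocess_fit(Xtr_raw)
      if (!any(prep$keep))
        stop("all features pruned: zero variance in every column",
             call. = FALSE)
      pruned <- sum(!prep$keep)
      if (pruned > 0)
        ds_log("debug", "outer fold ", f, " perm ", p, ": pruned ", pruned,
               " zero-variance feature(s)")
      mod <- svm_l2l2_fit(preprocess_apply(Xtr_raw, prep), ytr, grid[best])
      sc <- svm_decision(mod, preprocess_apply(X[te_rows, , drop = FALSE],
                                               prep)) - thr
      score_mat[te_rows, p] <- sc
      pred_mat[te_rows, p] <- sc > 0
      if (details)
        diag_list[[length(diag_list) + 1L]] <- list(
          perm = p, fold = f, C = grid[best], threshold = thr,
          keep = prep$keep, lo = prep$lo, hi = prep$hi, median = prep$median)
    }
  }
  mean_score <- rowMeans(score_mat, na.rm = TRUE)
  vote <- rowMeans(pred_mat, na.rm = TRUE)
  pred_pos <- ifelse(vote == 0.5, mean_score > 0, vote > 0.5)
  is_pos <- y == pos
  sens <- mean(pred_pos[is_pos])
  spec <- mean(!pred_pos[!is_pos])
  rep <- list(
    individuals = data.frame(
      participant_id = fm$participant_id, dyad_id = dyads,
      label = as.character(y), mean_score = mean_score,
      predicted = ifelse(pred_pos, pos, "non_autistic"),
      stringsAsFactors = FALSE),
    balanced_accuracy = balanced_accuracy(sens, spec),
    sensitivity = sens, specificity = spec,
    auc = auc_mw(mean_score, is_pos))
  if (details) rep$details <- diag_list
  structure(rep, class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(paste0("<classifier_report> balanced accuracy %.3f ",
                     "(sensitivity %.3f, specificity %.3f), AUC %.3f\n"),
              x$balanced_accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

#' Label permutation test for the nested classifier
#'
#' Permutes dyad labels (both members relabelled together) while keeping the
#' cross-validation fold structure intact, re-runs the full nested pipeline
#' for each permutation, and returns
#' `p = (1 + #\{permuted BAC >= observed BAC\}) / (1 + n_perm)`.
#'
#' @param fm A `feature_matrix`.
#' @param plan A `cv_plan` (reused unchanged across permutations).
#' @param n_perm Number of permutations (5,000 at study scale; reduce for
#'   desk-scale runs).
#' @param grid Penalty grid passed to [fit_predict_nested()].
#' @param seed Integer seed for the permutations.
#' @param observed_bac Observed balanced accuracy; computed if `NULL`.
#' @param ... Further arguments (e.g. `optimize_threshold`) passed to
#'   [fit_predict_nested()] for the observed and every permuted run alike.
#' @return List with `p_value`, `observed_bac`, `perm_bac` (vector).
#' @export
label_permutation_test <- function(fm, plan, n_perm = 5000L, grid = 2^(-6:6),
                                   seed = 1L, observed_bac = NULL, ...) {
  if (n_perm < 1L) stop("config error: n_perm must be >= 1", call. = FALSE)
  if (is.null(observed_bac))
    observed_bac <- fit_predict_nested(fm, plan, grid, ...)$balanced_accuracy
  dyad_ids <- unique(fm$dyad_id)
  dyad_lab <- as.character(fm$y)[match(dyad_ids, fm$dyad_id)]
  set.seed(seed)
  perm_bac <- vapply(seq_len(n_perm), function(i) {
    lab_p <- sample(dyad_lab)
    y_p <- factor(lab_p[match(fm$dyad_id, dyad_ids)],
                  levels = levels(fm$y))
    fm_p <- fm; fm_p$y <- y_p
    fit_predict_nested(fm_p, plan, grid, ...)$balanced_accuracy
  }, numeric(1))
  list(p_value = (1 + sum(perm_bac >= observed_bac)) / (1 + n_perm),
       observed_bac = observed_bac, perm_bac = perm_bac)
}
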