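# Survival decision trees for prognostic cut-point discovery.
#
# Recursive binary splitting on continuous scores; at every node each
# candidate threshold is the midpoint between consecutive sorted unique
# predictor values, and the chosen split maximizes the two-sample
# log-rank chi-square statistic subject to a minimum node size.  Model
# selection uses k-fold cross-validation: one tree per fold trained on
# the other k-1 folds, held-out "prognostic accuracy" measured as the
# concordance index between terminal-node risk ordering and held-out
# survival, and the highest-accuracy tree returned.

# Log-rank chi-square for every candidate threshold of one predictor.
# Vectorized: at-risk and event incidence matrices over pooled event
# times multiplied against threshold membership.
logrank_scan <- function(x, time, event, min_node_size = 1L) {
  n <- length(x)
  ux <- sort(unique(x))
  if (length(ux) < 2L) {
    return(data.frame(threshold = numeric(0), stat = numeric(0)))
  }
  thr <- (ux[-1L] + ux[-length(ux)]) / 2
  n_left <- cumsum(tabulate(match(x, ux), nbins = length(ux)))[-length(ux)]
  keep <- n_left >= min_node_size & (n - n_left) >= min_node_size
  thr <- thr[keep]
  if (length(thr) == 0L) {
    return(data.frame(threshold = numeric(0), stat = numeric(0)))
  }
  et <- sort(unique(time[event == 1L]))
  if (length(et) == 0L) {
    return(data.frame(threshold = thr, stat = rep(0, length(thr))))
  }
  A <- outer(et, time, function(a, b) b >= a) * 1
  D <- outer(et, time, `==`) * rep(event, each = length(et))
  M <- outer(x, thr, `<=`) * 1
  n1 <- A %*% M
  d1 <- D %*% M
  nn <- rowSums(A)
  dd <- rowSums(D)
  O <- colSums(d1)
  E <- colSums(dd * n1 / nn)
  V <- colSums(dd * (n1 / nn) * (1 - n1 / nn) *
                 (nn - dd) / pmax(nn - 1, 1))
  stat <- ifelse(V > 1e-12, (O - E)^2 / V, 0)
  data.frame(threshold = thr, stat = stat)
}

# Single two-sample log-rank statistic (chi-square, 1 df) used when a
# grouping is already in hand; shares the machinery above.
logrank_chisq <- function(time, event, group) {
  g <- as.integer(factor(group))
  sc <- logrank_scan(g, time, event)
  if (nrow(sc) == 0L) return(0)
  sc$stat[1L]
}

order_predictors <- function(nms) {
  c(intersect(TREE_PREDICTORS, nms), setdiff(nms, TREE_PREDICTORS))
}

#' Fit a survival decision tree by log-rank splitting
#'
#' @param scores data.frame or matrix of continuous predictors, one
#'   row per patient. Columns named `snas`, `cytoplasmic`, `cnr` are
#'   scanned in that order (ties between predictors break toward the
#'   earlier one; ties within a predictor toward the smaller
#'   threshold).
#' @param times follow-up in months.
#' @param events event flags (1 = death).
#' @param max_depth maximum split depth (default 3).
#' @param min_node_size minimum members per terminal node (default 20).
#' @return a `survival_tree`: node list (split predictor, threshold,
#'   log-rank improvement, terminal risk = events per person-month),
#'   the root threshold/predictor and raw per-predictor importance.
#' @export
fit_survival_tree <- function(scores, times, events, max_depth = 3L,
                              min_node_size = 20L) {
  X <- as.data.frame(scores)
  preds <- order_predictors(names(X))
  n <- nrow(X)
  if (n < 2L * min_node_size) {
    stop("need at least 2 * min_node_size patients", call. = FALSE)
  }
  if (sum(events) < 1L) {
    stop("cannot fit a survival tree with no events", call. = FALSE)
  }
  if (any(times < 0)) stop("negative follow-up times", call. = FALSE)

  nodes <- list()
  counter <- new.env()
  counter$next_id <- 1L
  importance <- setNames(rep(0, length(preds)), preds)

  grow <- function(idx, depth) {
    id <- counter$next_id
    counter$next_id <- id + 1L
    node <- list(id = id, depth = depth, n = length(idx),
                 events = sum(events[idx]),
                 risk = sum(events[idx]) / max(sum(times[idx]), 1e-12),
                 terminal = TRUE, predictor = NA_character_,
                 threshold = NA_real_, stat = NA_real_,
                 left = NA_integer_, right = NA_integer_)
    if (depth < max_depth && length(idx) >= 2L * min_node_size &&
        sum(events[idx]) >= 1L) {
      best <- list(stat = 0, predictor = NA_character_,
                   threshold = NA_real_)
      for (p in preds) {
        sc <- logrank_scan(X[[p]][idx], times[idx], events[idx],
                           min_node_size)
        if (nrow(sc) == 0L) next
        j <- which.max(sc$stat)
        if (sc$stat[j] > best$stat + 1e-12) {
          best <- list(stat = sc$stat[j], predictor = p,
                       threshold = sc$threshold[j])
        }
      }
      if (!is.na(best$predictor) && best$stat > 0) {
        node$terminal <- FALSE
        node$predictor <- best$predictor
        node$threshold <- best$threshold
        node$stat <- best$stat
        importance[best$predictor] <<-
          importance[best$predictor] + best$stat
        nodes[[id]] <<- node # reserve slot before children
        li <- idx[X[[best$predictor]][idx] <= best$threshold]
        ri <- idx[X[[best$predictor]][idx] > best$threshold]
        node$left <- grow(li, depth + 1L)
        node$right <- grow(ri, depth + 1L)
      }
    }
    nodes[[id]] <<- node
    id
  }
  root_id <- grow(seq_len(n), 0L)
  root <- nodes[[root_id]]
  structure(list(
    nodes = nodes,
    predictors = preds,
    max_depth = as.integer(max_depth),
    min_node_size = as.integer(min_node_size),
    root_predictor = root$predictor,
    root_threshold = root$threshold,
    raw_importance = importance,
    n = n
  ), class = "survival_tree")
}

#' @export
print.survival_tree <- function(x, ...) {
  cat("Survival tree (log-rank splitting), n =", x$n, "\n")
  show <- function(id, indent) {
    nd <- x$nodes[[id]]
    pad <- strrep("  ", indent)
    if (nd$terminal) {
      cat(sprintf("%s<leaf> n=%d events=%d risk=%.4g\n", pad, nd$n,
                  nd$events, nd$risk))
    } else {
      cat(sprintf("%s%s <= %.4g (LR %.2f, n=%d)\n", pad, nd$predictor,
                  nd$threshold, nd$stat, nd$n))
      show(nd$left, indent + 1L)
      show(nd$right, indent + 1L)
    }
  }
  show(1L, 0L)
  invisible(x)
}

#' Terminal-node risk for new patients
#'
#' @param object a `survival_tree`.
#' @param newdata data.frame with the tree's predictor columns.
#' @param ... unused.
#' @return data.frame with terminal `node` id and `risk` (events per
#'   person-month in that node, on the training data).
#' @export
predict.survival_tree <- function(object, newdata, ...) {
  X <- as.data.frame(newdata)
  walk <- function(row) {
    id <- 1L
    repeat {
      nd <- object$nodes[[id]]
      if (nd$terminal) return(c(nd$id, nd$risk))
      id <- if (X[[nd$predictor]][row] <= nd$threshold) nd$left
            else nd$right
    }
  }
  out <- t(vapply(seq_len(nrow(X)), walk, numeric(2L)))
  data.frame(node = as.integer(out[, 1L]), risk = out[, 2L])
}

#' Normalized variable importance of a survival tree
#'
#' Raw importance of a predictor is the summed log-rank improvement of
#' its splits; values are normalized by the maximum so the strongest
#' predictor scores 1. Predictors never split score 0.
#'
#' @param model a `survival_tree`.
#' @return named numeric in `[0, 1]`.
#' @export
variable_importance <- function(model) {
  if (!inherits(model, "survival_tree")) {
    stop("`model` must be a fitted survival_tree", call. = FALSE)
  }
  raw <- model$raw_importance
  if (max(raw) <= 0) return(raw * 0)
  raw / max(raw)
}

#' Select a survival tree by k-fold cross-validation
#'
#' Patients are randomly partitioned into `k` folds (sizes differing by
#' at most one). One tree is trained per fold on the remaining `k - 1`
#' folds, its prognostic accuracy measured as the concordance index of
#' terminal-node risk ranking on the held-out fold, and the
#' highest-accuracy tree returned together with its root split.
#'
#' @param data data.frame holding predictor columns plus follow-up and
#'   event columns.
#' @param predictors predictor column names (default the three score
#'   predictors present in `data`).
#' @param time_col,event_col outcome column names.
#' @param k number of folds (default 10).
#' @param seed fold-assignment seed.
#' @param max_depth,min_node_size passed to [fit_survival_tree()].
#' @return a `cv_result`: fold assignment, per-fold model and held-out
#'   accuracy, selected index, selected tree and its root
#'   predictor/threshold.
#' @export
select_model_cv <- function(data, predictors = NULL,
                            time_col = "bcss_time",
                            event_col = "bcss_event", k = 10L,
                            seed = 1L, max_depth = 3L,
                            min_node_size = 20L) {
  n <- nrow(data)
  if (n < 50L) stop("cross-validated selection needs n >= 50", call. = FALSE)
  if (is.null(predictors)) {
    predictors <- intersect(TREE_PREDICTORS, names(data))
  }
  if (length(predictors) == 0L) stop("no predictor columns", call. = FALSE)
  time <- data[[time_col]]; event <- data[[event_col]]
  folds <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  models <- vector("list", k)
  acc <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    tr <- folds != i
    if (sum(event[tr]) < 1L) {
      warning(sprintf("fold %d skipped: no events in its training set", i))
      next
    }
    fit <- fit_survival_tree(data[tr, predictors, drop = FALSE],
                             time[tr], event[tr],
                             max_depth = max_depth,
                             min_node_size = min_node_size)
    models[[i]] <- fit
    pr <- predict(fit, data[!tr, predictors, drop = FALSE])
    acc[i] <- if (length(unique(pr$risk)) < 2L) 0.5 else {
      survival::concordance(
        survival::Surv(time[!tr], event[!tr]) ~ pr$risk,
        reverse = TRUE)$concordance
    }
  }
  if (all(is.na(acc))) stop("no usable fold model", call. = FALSE)
  sel <- which.max(acc)
  structure(list(
    folds = folds,
    models = models,
    accuracy = acc,
    selected = sel,
    selected_model = models[[sel]],
    root_predictor = models[[sel]]$root_predictor,
    root_threshold = models[[sel]]$root_threshold,
    k = as.integer(k),
    seed = as.integer(seed)
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: selected fold %d (concordance %.3f)\n",
              x$k, x$selected, x$accuracy[x$selected]))
  cat(sprintf("Root split: %s at %.4g\n", x$root_predictor,
              x$root_threshold))
  invisible(x)
}

#' Reported form of a discovered threshold
#'
#' Continuous cut points discovered by the tree may be rounded to the
#' nearest integer for reporting and clinical use; this makes that
#' rounding an explicit, recorded step.
#'
#' @param threshold numeric threshold.
#' @param round_to `"none"` (default) or `"integer"`.
#' @return numeric threshold as reported.
#' @export
report_threshold <- function(threshold, round_to = c("none", "integer")) {
  round_to <- match.arg(round_to)
  if (round_to == "integer") round(threshold) else threshold
}
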