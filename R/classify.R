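#' Segment tables
#'
#' Segment-level bookkeeping uses a plain tibble with one row per intestinal
#' segment and the columns
#' `segment_id`, `subject_id`, `cohort`, `length_mm`, `extraction_failed`
#' (flagged by either rater), `duplicate_of` (`NA` for unique segments),
#' `reference_motility` (`"motile"`, `"lt50_motile"`, `"non_motile"`),
#' `reference_direction` (`"forward"`, `"backward"`, `"bidirectional"`;
#' present iff motile), `mean_velocity` and `mean_absolute_velocity`
#' (mm/s, from [aggregate_metrics()]).
#'
#' For classification the `lt50_motile` and `non_motile` classes are merged
#' into a single negative class, reflecting how ambiguous the boundary
#' between them is for human raters.
#'
#' @name segment_table
NULL

# 4-class reference label: non_motile (merged negative) or the direction
reference_class <- function(records) {
  ifelse(records$reference_motility == "motile",
         as.character(records$reference_direction), "non_motile")
}

motility_class_levels <- c("non_motile", "backward", "bidirectional", "forward")

#' Apply the segment exclusion rules
#'
#' Only unique segments longer than `min_length_mm` that neither rater
#' marked as a failed extraction enter the analysis. Exclusions are tallied
#' in this order: (1) segments with `length_mm <= min_length_mm`; (2) for
#' each pair of non-unique segments (linked by `duplicate_of`), the shorter
#' one; (3) segments flagged as extraction failures.
#'
#' @param records A [segment_table] tibble.
#' @param min_length_mm Minimum segment length (default 40 mm = 4 cm).
#' @return The included records, with the per-category tally as
#'   `attr(, "tally")` (see [exclusion_tally()]).
#' @export
apply_exclusion_filters <- function(records, min_length_mm = 40) {
  if (nrow(records) == 0) {
    out <- records
    attr(out, "tally") <- tibble::tibble(
      category = c("total", "short", "duplicate", "failed", "included"),
      n = c(0L, 0L, 0L, 0L, 0L)
    )
    return(out)
  }
  ids <- records$segment_id
  dup <- records$duplicate_of
  bad <- !is.na(dup) & (!(dup %in% ids) | dup == ids)
  if (any(bad))
    stop("duplicate_of references do not resolve", call. = FALSE)
  # duplicate links must form pairs: chains may close back onto their start
  # only as a mutual pair (a <-> b); longer cycles are an error
  chain <- stats::setNames(as.character(dup), ids)
  for (id in ids[!is.na(dup)]) {
    seen <- id
    cur <- id
    repeat {
      nxt <- chain[[cur]]
      if (is.null(nxt) || is.na(nxt)) break
      if (nxt %in% seen) {
        if (!(nxt == seen[1] && length(seen) <= 2))
          stop("circular duplicate references", call. = FALSE)
        break
      }
      seen <- c(seen, nxt)
      cur <- nxt
    }
  }

  short <- records$length_mm <= min_length_mm
  remaining <- records[!short, , drop = FALSE]

  # duplicates among the remaining: drop the shorter of each linked pair
  drop_dup <- rep(FALSE, nrow(remaining))
  rid <- remaining$segment_id
  for (i in seq_len(nrow(remaining))) {
    d <- remaining$duplicate_of[i]
    if (is.na(d)) next
    j <- match(d, rid)
    if (is.na(j)) next  # partner already excluded
    li <- remaining$length_mm[i]; lj <- remaining$length_mm[j]
    if (li < lj) drop_dup[i] <- TRUE
    else if (li > lj) drop_dup[j] <- TRUE
    else drop_dup[i] <- TRUE  # tie: the marked duplicate goes
  }
  n_dup <- sum(drop_dup)
  remaining <- remaining[!drop_dup, , drop = FALSE]

  failed <- isTRUE_vec(remaining$extraction_failed)
  included <- remaining[!failed, , drop = FALSE]

  attr(included, "tally") <- tibble::tibble(
    category = c("total", "short", "duplicate", "failed", "included"),
    n = c(nrow(records), sum(short), n_dup, sum(failed), nrow(included))
  )
  included
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Exclusion tally of a filtered segment table
#'
#' @param records Output of [apply_exclusion_filters()].
#' @return Tibble with columns `category`
#'   (total/short/duplicate/failed/included) and `n`.
#' @export
exclusion_tally <- function(records) attr(records, "tally")

# best accuracy-maximising threshold for `positive iff value > threshold`;
# ties broken towards the lowest threshold
best_threshold_1d <- function(values, positive) {
  v <- sort(unique(values))
  cand <- c(v[1] - 1, if (length(v) > 1) (head(v, -1) + tail(v, -1)) / 2)
  acc <- vapply(cand, function(th) mean((values > th) == positive), numeric(1))
  best <- which(acc == max(acc))[1]
  list(threshold = cand[best], accuracy = acc[best])
}

#' Fit the linear threshold classifiers
#'
#' Two one-dimensional linear classifiers: a threshold on the mean absolute
#' velocity separating motile from (merged) non-motile segments, and a pair
#' of cut points on the mean velocity separating backward, bidirectional
#' and forward peristalsis among motile segments. Both are fitted by
#' exhaustive accuracy-maximising search over midpoints of consecutive
#' sorted training values (deterministic; ties resolve to the lowest
#' motility threshold, and to the lowest upper then lower direction cut).
#'
#' The direction cuts are fitted on the reference-motile training records.
#'
#' @param train A [segment_table] tibble.
#' @return A `motility_thresholds` object.
#' @export
fit_thresholds <- function(train) {
  motile <- train$reference_motility == "motile"
  if (length(unique(motile)) < 2)
    stop("single-class training set for the motility classifier", call. = FALSE)
  m <- best_threshold_1d(train$mean_absolute_velocity, motile)

  tm <- train[motile, , drop = FALSE]
  dir <- factor(tm$reference_direction,
                levels = c("backward", "bidirectional", "forward"))
  if (length(unique(dir)) < 2)
    stop("single-class training set for the peristalsis classifier",
         call. = FALSE)
  mv <- tm$mean_velocity
  v <- sort(unique(mv))
  cand <- c(v[1] - 1,
            if (length(v) > 1) (head(v, -1) + tail(v, -1)) / 2,
            v[length(v)] + 1)
  # counts below each candidate cut (candidates never coincide with data)
  n_lt <- function(values) findInterval(cand, sort(values))
  blt <- n_lt(mv[dir == "backward"])
  mlt <- n_lt(mv[dir == "bidirectional"])
  flt <- n_lt(mv[dir == "forward"])
  n_fwd <- sum(dir == "forward")
  # correct(lower=i, upper=j>=i) = blt[i] + (mlt[j] - mlt[i]) + (n_fwd -
  # flt[j]) = a[i] + b[j] + n_fwd; maximise with a running max over i <= j
  a <- blt - mlt
  b <- mlt - flt
  best <- list(acc = -Inf, lower = NA_real_, upper = NA_real_)
  ai_best <- -Inf; i_best <- NA_integer_
  for (j in seq_along(cand)) {
    if (a[j] > ai_best) { ai_best <- a[j]; i_best <- j }
    correct <- ai_best + b[j] + n_fwd
    if (correct > best$acc) {
      best <- list(acc = correct, lower = cand[i_best], upper = cand[j])
    }
  }
  best$acc <- best$acc / nrow(tm)
  structure(
    list(
      motility_threshold = m$threshold,
      direction_lower = best$lower,
      direction_upper = best$upper,
      train_accuracy_motility = m$accuracy,
      train_accuracy_direction = best$acc,
      n_train = nrow(train)
    ),
    class = "motility_thresholds"
  )
}

#' @export
print.motility_thresholds <- function(x, ...) {
  cat(sprintf(
    paste0("<motility_thresholds>\n",
           "  motility:  |v|  > %.3f mm/s\n",
           "  direction: v < %.3f backward, v > %.3f forward\n"),
    x$motility_threshold, x$direction_lower, x$direction_upper
  ))
  invisible(x)
}

#' @export
tidy.motility_thresholds <- function(x, ...) {
  tibble::tibble(
    term = c("motility_threshold", "direction_lower", "direction_upper"),
    estimate = c(x$motility_threshold, x$direction_lower, x$direction_upper)
  )
}

#' @export
glance.motility_thresholds <- function(x, ...) {
  tibble::tibble(
    train_accuracy_motility = x$train_accuracy_motility,
    train_accuracy_direction = x$train_accuracy_direction,
    n_train = x$n_train
  )
}

#' Predict motility classes from fitted thresholds
#'
#' Hierarchical prediction: a segment whose mean absolute velocity does not
#' exceed the motility threshold is `non_motile` regardless of its mean
#' velocity; otherwise the direction cuts on the mean velocity assign
#' `backward`, `bidirectional` or `forward`.
#'
#' @param records A [segment_table] tibble with metric columns.
#' @param thresholds A [fit_thresholds()] object.
#' @return `records` with a `predicted_class` column.
#' @export
predict_motility <- function(records, thresholds) {
  pred <- ifelse(
    records$mean_absolute_velocity <= thresholds$motility_threshold,
    "non_motile",
    ifelse(records$mean_velocity < thresholds$direction_lower, "backward",
           ifelse(records$mean_velocity > thresholds$direction_upper,
                  "forward", "bidirectional"))
  )
  records$predicted_class <- factor(pred, levels = motility_class_levels)
  records
}

#' Subject-grouped k-fold assignment
#'
#' All segments from the same subject share a fold, so cross-validated
#' thresholds are never fitted on data from the subject they are evaluated
#' on. Subjects are shuffled deterministically by `seed` and dealt
#' round-robin, balancing fold sizes by subject count.
#'
#' @param records A [segment_table] tibble.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return `records` with an integer `fold` column.
#' @export
grouped_kfold <- function(records, k = 5, seed = 1L) {
  subjects <- sort(unique(records$subject_id))
  if (length(subjects) < k)
    stop(sprintf("fewer subjects (%d) than folds (%d)", length(subjects), k),
         call. = FALSE)
  perm <- with_local_seed(seed, sample(subjects))
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(perm)), perm)
  records$fold <- as.integer(fold_of[as.character(records$subject_id)])
  records
}

#' Cross-validated motility classification
#'
#' Five-fold cross-validation split by subject: for every fold, both
#' threshold classifiers are fitted on the remaining folds and applied to
#' the held-out segments, so each record is predicted exactly once by
#' thresholds fitted without its subject's data.
#'
#' @inheritParams grouped_kfold
#' @return A `cv_classification` tibble: the records plus `fold` and
#'   `predicted_class`; per-fold thresholds in `attr(, "thresholds")`.
#'   Use [glance()] for accuracy, Cohen's kappa and AUCs.
#' @export
cross_validate_classification <- function(records, k = 5, seed = 1L) {
  records <- grouped_kfold(records, k = k, seed = seed)
  th <- vector("list", k)
  records$predicted_class <- factor(NA_character_,
                                    levels = motility_class_levels)
  for (f in seq_len(k)) {
    train <- records[records$fold != f, , drop = FALSE]
    test_idx <- which(records$fold == f)
    if (length(test_idx) == 0) next
    th[[f]] <- fit_thresholds(train)
    pred <- predict_motility(records[test_idx, , drop = FALSE], th[[f]])
    records$predicted_class[test_idx] <- pred$predicted_class
  }
  attr(records, "thresholds") <- th
  class(records) <- c("cv_classification", class(records))
  records
}

#' @export
glance.cv_classification <- function(x, ...) {
  ref <- factor(reference_class(x), levels = motility_class_levels)
  pred <- x$predicted_class
  motile <- x$reference_motility == "motile"
  peristalsis <- ref %in% c("forward", "backward")
  tibble::tibble(
    accuracy = mean(as.character(pred) == as.character(ref)),
    kappa = cohens_kappa(pred, ref),
    auc_motility = roc_auc(x$mean_absolute_velocity, motile),
    auc_peristalsis = if (any(motile & peristalsis) &&
                          any(motile & !peristalsis))
      roc_auc(abs(x$mean_velocity[motile]), peristalsis[motile])
    else NA_real_,
    n = nrow(x)
  )
}

#' @export
tidy.cv_classification <- function(x, ...) {
  th <- attr(x, "thresholds")
  dplyr::bind_rows(lapply(seq_along(th), function(f) {
    if (is.null(th[[f]])) return(NULL)
    out <- tidy(th[[f]])
    out$fold <- f
    out
  }))
}

#' Area under the ROC curve
#'
#' Mann-Whitney concordance probability: the chance that a random positive
#' scores above a random negative, with ties counted as one half. Invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical (or coercible) positive-class indicator.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("roc_auc requires both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cohen's unweighted kappa
#'
#' Chance-corrected agreement between two categorical labelings:
#' `(p_o - p_e) / (1 - p_e)` with the expected agreement `p_e` from the
#' marginal products.
#'
#' @param labels_a,labels_b Equal-length label vectors over a shared
#'   alphabet.
#' @return Kappa; `NA` (with a warning) when both raters are constant and
#'   identical, where kappa is undefined.
#' @export
cohens_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length", call. = FALSE)
  lev <- union(levels(factor(labels_a)), levels(factor(labels_b)))
  a <- factor(labels_a, levels = lev)
  b <- factor(labels_b, levels = lev)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warning("kappa undefined: expected agreement is 1")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Contingency matrix of predicted versus reference classes
#'
#' @param x A `cv_classification` (or any records with `predicted_class`).
#' @return A table, reference classes in rows, predictions in columns, in
#'   the order non_motile / backward / bidirectional / forward.
#' @export
contingency_matrix <- function(x) {
  ref <- factor(reference_class(x), levels = motility_class_levels)
  pred <- factor(x$predicted_class, levels = motility_class_levels)
  table(reference = ref, predicted = pred)
}

#' Per-cohort summary statistics
#'
#' Medians and interquartile ranges of the mean absolute velocity, class
#' percentages (rounded half-up to integer percent), and a two-sample
#' Student's t-test on the mean absolute velocity between the first two
#' cohorts. Significance is declared at p < 0.001.
#'
#' @param records A [segment_table] tibble.
#' @param var_equal Equal-variance (Student's) t-test by default; `FALSE`
#'   gives the Welch variant.
#' @return A list with `stats` (per-cohort median/IQR), `percentages`
#'   (per-cohort reference-class percentages), `t_test` (statistic,
#'   p-value, significance flag).
#' @export
cohort_summary <- function(records, var_equal = TRUE) {
  grp <- split(records, records$cohort)
  if (any(vapply(grp, nrow, integer(1)) < 2))
    stop("each cohort needs at least 2 records", call. = FALSE)
  stats_tbl <- dplyr::bind_rows(lapply(names(grp), function(g) {
    v <- grp[[g]]$mean_absolute_velocity
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    tibble::tibble(cohort = g, n = length(v),
                   median = q[2], q25 = q[1], q75 = q[3])
  }))
  pct <- dplyr::bind_rows(lapply(names(grp), function(g) {
    cls <- factor(reference_class(grp[[g]]), levels = motility_class_levels)
    tab <- table(cls)
    tibble::tibble(
      cohort = g,
      class = names(tab),
      n = as.integer(tab),
      total = length(cls),
      percent = percent_round(as.integer(tab) / length(cls))
    )
  }))
  tt <- NULL
  if (length(grp) >= 2) {
    ht <- stats::t.test(grp[[1]]$mean_absolute_velocity,
                        grp[[2]]$mean_absolute_velocity,
                        var.equal = var_equal)
    tt <- list(statistic = unname(ht$statistic), p_value = ht$p.value,
               significant = ht$p.value < 0.001,
               cohorts = names(grp)[1:2],
               variant = if (var_equal) "student" else "welch")
  }
  list(stats = stats_tbl, percentages = pct, t_test = tt)
}
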