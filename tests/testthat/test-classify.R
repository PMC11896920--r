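make_records <- function(n, seed = 1) {
  withr::with_seed(seed, {
    tibble::tibble(
      segment_id = sprintf("seg%03d", seq_len(n)),
      subject_id = sprintf("P%02d", sample(1:max(5, n %/% 3), n, replace = TRUE)),
      cohort = sample(c("healthy", "crohns"), n, replace = TRUE),
      length_mm = runif(n, 20, 150),
      extraction_failed = runif(n) < 0.2,
      duplicate_of = NA_character_,
      reference_motility = sample(c("motile", "lt50_motile", "non_motile"),
                                  n, replace = TRUE),
      reference_direction = NA_character_,
      mean_velocity = rnorm(n),
      mean_absolute_velocity = abs(rnorm(n, 1.5))
    ) -> df
    df$reference_direction[df$reference_motility == "motile"] <-
      sample(c("forward", "backward", "bidirectional"),
             sum(df$reference_motility == "motile"), replace = TRUE)
    df
  })
}

test_that("exclusion filters reproduce the printed bookkeeping", {
  # 333 generated; 41 too short; 9 shorter duplicates; 69 rater failures
  n <- 333
  rec <- make_records(n, seed = 2)
  rec$length_mm <- runif(n, 41, 150)
  rec$extraction_failed <- FALSE
  rec$duplicate_of <- NA_character_
  rec$length_mm[1:41] <- runif(41, 5, 40)
  # 9 duplicate pairs among the remaining: partners are longer
  short_dup <- 42:50
  partner <- 51:59
  rec$duplicate_of[short_dup] <- rec$segment_id[partner]
  rec$length_mm[short_dup] <- rec$length_mm[partner] - 1
  rec$extraction_failed[60:128] <- TRUE
  inc <- apply_exclusion_filters(rec)
  tally <- exclusion_tally(inc)
  expect_equal(tally$n[tally$category == "total"], 333)
  expect_equal(tally$n[tally$category == "short"], 41)
  expect_equal(tally$n[tally$category == "duplicate"], 9)
  expect_equal(tally$n[tally$category == "failed"], 69)
  expect_equal(nrow(inc), 214)
})

test_that("empty input filters to empty output with zero tallies", {
  inc <- apply_exclusion_filters(make_records(5)[0, ])
  expect_equal(nrow(inc), 0)
  expect_true(all(exclusion_tally(inc)$n == 0))
})

test_that("filters agree with a brute-force set-difference oracle", {
  for (seed in 1:4) {
    rec <- make_records(60, seed = seed)
    # sprinkle duplicate pairs
    pick <- withr::with_seed(seed, sample(60, 10))
    a <- pick[1:5]; b <- pick[6:10]
    rec$duplicate_of[a] <- rec$segment_id[b]
    inc <- apply_exclusion_filters(rec, min_length_mm = 40)

    # independent reimplementation with set operations
    keep <- rec$segment_id[rec$length_mm > 40]
    sub <- rec[rec$segment_id %in% keep, ]
    for (i in seq_len(nrow(sub))) {
      d <- sub$duplicate_of[i]
      if (is.na(d) || !(d %in% sub$segment_id)) next
      j <- match(d, sub$segment_id)
      drop_id <- if (sub$length_mm[i] <= sub$length_mm[j])
        sub$segment_id[i] else sub$segment_id[j]
      keep <- setdiff(keep, drop_id)
    }
    sub <- rec[rec$segment_id %in% keep & !rec$extraction_failed, ]
    expect_setequal(inc$segment_id, sub$segment_id)
  }
})

test_that("ordering of the input does not change the filter outcome", {
  rec <- make_records(50, seed = 9)
  rec$duplicate_of[3] <- rec$segment_id[17]
  inc1 <- apply_exclusion_filters(rec)
  perm <- withr::with_seed(1, sample(nrow(rec)))
  inc2 <- apply_exclusion_filters(rec[perm, ])
  expect_setequal(inc1$segment_id, inc2$segment_id)
})

test_that("circular duplicate chains are rejected", {
  rec <- make_records(6, seed = 3)
  rec$duplicate_of <- c("seg002", "seg003", "seg001", NA, NA, NA)
  expect_error(apply_exclusion_filters(rec), "circular")
  rec2 <- make_records(4, seed = 3)
  rec2$duplicate_of[1] <- "nope"
  expect_error(apply_exclusion_filters(rec2), "resolve")
})

test_that("thresholds separate a separable training set perfectly", {
  tr <- tibble::tibble(
    reference_motility = rep(c("motile", "non_motile"), each = 6),
    reference_direction = c(rep(c("forward", "backward", "bidirectional"), 2),
                            rep(NA, 6)),
    mean_absolute_velocity = c(runif(6, 1.5, 3), runif(6, 0, 0.5)),
    mean_velocity = c(rep(c(2, -2, 0), 2), rep(0, 6))
  )
  th <- fit_thresholds(tr)
  expect_equal(th$train_accuracy_motility, 1)
  expect_equal(th$train_accuracy_direction, 1)
  pred <- predict_motility(tr, th)
  expect_equal(as.character(pred$predicted_class),
               ifelse(tr$reference_motility == "motile",
                      tr$reference_direction, "non_motile"))
})

test_that("threshold ties resolve to the lowest candidate", {
  # mav 1 (non), 2 (motile), 4 (non), 5 (motile): cutting at 1.5 or at 4.5
  # both give 3/4 accuracy; the lower cut must win
  tr <- tibble::tibble(
    reference_motility = c("non_motile", "motile", "non_motile", "motile"),
    reference_direction = c(NA, "forward", NA, "backward"),
    mean_absolute_velocity = c(1, 2, 4, 5),
    mean_velocity = c(0, 2, 0, -2)
  )
  th <- fit_thresholds(tr)
  expect_equal(th$train_accuracy_motility, 0.75)
  expect_equal(th$motility_threshold, 1.5)
})

test_that("with overlapping Gaussians the threshold nears the crossing point", {
  n <- 4000
  tr <- withr::with_seed(5, tibble::tibble(
    reference_motility = rep(c("non_motile", "motile"), each = n),
    reference_direction = c(rep(NA, n),
                            rep(c("forward", "backward"), n / 2)),
    mean_absolute_velocity = c(rnorm(n, 0), rnorm(n, 2)),
    mean_velocity = c(rnorm(n, 0), rep(c(3, -3), n / 2) + rnorm(n, 0, 0.5))
  ))
  th <- fit_thresholds(tr)
  # equal-variance Gaussians cross at the midpoint of the means
  expect_lt(abs(th$motility_threshold - 1), 0.25)
})

test_that("single-class training sets are rejected", {
  tr <- make_records(10, seed = 4)
  tr$reference_motility <- "motile"
  tr$reference_direction <- "forward"
  expect_error(fit_thresholds(tr), "single-class")
})

test_that("grouped folds keep subjects together and balance counts", {
  rec <- tibble::tibble(
    segment_id = sprintf("s%02d", 1:30),
    subject_id = rep(sprintf("P%02d", 1:10), each = 3),
    mean_velocity = 0, mean_absolute_velocity = 0
  )
  f <- grouped_kfold(rec, k = 5, seed = 3)
  per_subj <- tapply(f$fold, f$subject_id, function(x) length(unique(x)))
  expect_true(all(per_subj == 1))
  subj_per_fold <- table(tapply(f$fold, f$subject_id, unique))
  expect_true(all(subj_per_fold == 2))
  f2 <- grouped_kfold(rec, k = 5, seed = 3)
  expect_identical(f$fold, f2$fold)
  expect_error(grouped_kfold(rec[rec$subject_id %in% sprintf("P%02d", 1:3), ],
                             k = 5),
               "fewer subjects")
})

test_that("prediction is hierarchical: non-motile overrides direction", {
  th <- structure(list(motility_threshold = 1, direction_lower = -0.5,
                       direction_upper = 0.5), class = "motility_thresholds")
  rec <- tibble::tibble(mean_absolute_velocity = c(0.3, 2, 2),
                        mean_velocity = c(9, 1.5, 0))
  pred <- predict_motility(rec, th)
  expect_equal(as.character(pred$predicted_class),
               c("non_motile", "forward", "bidirectional"))
})

test_that("AUC equals exhaustive pair enumeration", {
  scores <- c(1, 2, 3, 1)
  labels <- c(TRUE, TRUE, TRUE, FALSE)
  # pairs (pos, neg): (2,1) and (3,1) concordant, (1,1) tied
  expect_equal(roc_auc(scores, labels), (2 + 0.5) / 3)

  for (seed in 1:5) {
    withr::with_seed(seed, {
      s <- sample(1:6, 30, replace = TRUE)
      l <- runif(30) < 0.4
    })
    if (!any(l) || all(l)) next
    brute <- mean(outer(s[l], s[!l], function(a, b)
      (a > b) + 0.5 * (a == b)))
    expect_equal(roc_auc(s, l), brute)
  }
})

test_that("AUC is ~0.5 for uninformative scores and monotone-invariant", {
  withr::with_seed(8, {
    s <- rnorm(4000)
    l <- runif(4000) < 0.5
  })
  expect_equal(roc_auc(s, l), 0.5, tolerance = 0.03)
  expect_identical(roc_auc(exp(s / 3), l), roc_auc(s, l))
  expect_error(roc_auc(s, rep(TRUE, length(s))), "both classes")
})

test_that("kappa has its closed-form values and symmetry", {
  a <- c("x", "y", "x", "y", "x", "y")
  expect_equal(cohens_kappa(a, a), 1)
  # one rater constant, the other balanced: po = pe -> kappa 0
  expect_equal(cohens_kappa(rep("x", 6), a), 0)
  for (seed in 1:5) {
    withr::with_seed(seed, {
      u <- sample(letters[1:3], 40, replace = TRUE)
      v <- sample(letters[1:3], 40, replace = TRUE)
    })
    tab <- table(factor(u, letters[1:3]), factor(v, letters[1:3]))
    po <- sum(diag(tab)) / 40
    pe <- sum(rowSums(tab) * colSums(tab)) / 40^2
    expect_equal(cohens_kappa(u, v), (po - pe) / (1 - pe))
    expect_equal(cohens_kappa(u, v), cohens_kappa(v, u))
  }
  expect_warning(k <- cohens_kappa(rep("x", 5), rep("x", 5)), "undefined")
  expect_true(is.na(k))
})

test_that("cross-validation predicts every record exactly once, by fold", {
  rec <- synthetic_cohort()
  cv <- cross_validate_classification(rec, k = 5, seed = 2)
  expect_false(anyNA(cv$predicted_class))
  expect_equal(nrow(cv), nrow(rec))
  th <- attr(cv, "thresholds")
  expect_length(th, 5)
  per_subj <- tapply(cv$fold, cv$subject_id, function(x) length(unique(x)))
  expect_true(all(per_subj == 1))
})

test_that("cohort percentages use half-up integer rounding", {
  rec <- make_records(214, seed = 6)
  rec$cohort <- rep(c("healthy", "crohns"), c(127, 87))
  cs <- cohort_summary(rec)
  expect_true(all(c("healthy", "crohns") %in% cs$stats$cohort))
  expect_true(all(cs$percentages$percent ==
                    floor(100 * cs$percentages$n / cs$percentages$total + 0.5)))
  expect_false(is.null(cs$t_test$p_value))
})

test_that("identical cohorts give t = 0 and p = 1", {
  rec <- tibble::tibble(
    cohort = rep(c("a", "b"), each = 4),
    reference_motility = "motile",
    reference_direction = "forward",
    mean_absolute_velocity = rep(c(1, 2, 3, 4), 2)
  )
  cs <- cohort_summary(rec)
  expect_equal(cs$t_test$statistic, 0)
  expect_equal(cs$t_test$p_value, 1)
  expect_false(cs$t_test$significant)
})
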