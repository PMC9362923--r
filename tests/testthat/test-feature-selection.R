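test_that("importance scores are normalized, sorted and seeded", {
  imp <- importance_scores(toy_features(), n_trees = 100, seed = 5)
  expect_equal(sum(imp$score), 1, tolerance = 1e-9)
  expect_true(all(imp$score >= 0))
  expect_equal(imp$score, imp$importance / sum(imp$importance))
  expect_false(is.unsorted(rev(imp$score)))
  expect_equal(imp$rank, seq_len(nrow(imp)))
  imp2 <- importance_scores(toy_features(), n_trees = 100, seed = 5)
  expect_identical(imp, imp2)
  # the feature that determines the label ranks first
  expect_equal(imp$feature[1], "f_signal")
})

test_that("degenerate importance inputs error", {
  one_class <- toy_features()
  one_class$class <- factor("a")
  expect_error(importance_scores(one_class), "2 classes")
  expect_error(importance_scores(data.frame(class = factor(c("a", "b")))),
               "empty")
})

test_that("threshold groups are nested and follow the filtering rule", {
  tab <- data.frame(feature = paste0("f", 1:4), importance = 1,
                    score = c(0.15, 0.05, 0.03, 0.01), rank = 1:4)
  groups <- group_by_thresholds(tab, c(0.1, 0.04, 0.02, 0))
  expect_named(groups, c("A", "B", "C", "D"))
  expect_equal(lengths(groups), c(A = 1L, B = 2L, C = 3L, D = 4L))
  for (i in 2:4) expect_true(all(groups[[i - 1]] %in% groups[[i]]))

  expect_error(group_by_thresholds(tab, c(0.04, 0.1)), "decreasing")
  expect_warning(g2 <- group_by_thresholds(tab, c(0.5, 0)), "empty")
  expect_named(g2, "A")
  expect_error(group_by_thresholds(tab, c(0.5, 0.4)), "empty")

  # nesting holds for random score vectors too
  set.seed(31)
  for (i in 1:20) {
    s <- stats::runif(30); s <- s / sum(s)
    tabr <- data.frame(feature = paste0("f", 1:30), importance = s,
                       score = sort(s, decreasing = TRUE), rank = 1:30)
    gr <- group_by_thresholds(tabr, c(0.05, 0.02, 0))
    expect_true(all(diff(lengths(gr)) >= 0))
  }
})

test_that("group selection maximizes accuracy with OOB and size tie-breaks", {
  grid <- c(100, 200, 400, 800)
  groups <- list(A = paste0("f", 1:2), B = paste0("f", 1:5),
                 C = paste0("f", 1:9))
  curves <- rbind(
    data.frame(group = "A", n_trees = grid, oob_error = 0.10,
               prediction_accuracy = c(0.90, 0.91, 0.91, 0.91)),
    data.frame(group = "B", n_trees = grid, oob_error = 0.05,
               prediction_accuracy = c(0.93, 0.95, 0.96, 0.96)),
    data.frame(group = "C", n_trees = grid, oob_error = 0.07,
               prediction_accuracy = c(0.92, 0.94, 0.955, 0.955)))
  sel <- select_group(curves, groups)
  expect_equal(sel$group, "B")
  expect_equal(sel$n_trees, 400)        # smallest tree count on the plateau

  # identical curves: the smallest group wins the tie
  same <- do.call(rbind, lapply(names(groups), function(g)
    data.frame(group = g, n_trees = grid, oob_error = 0.05,
               prediction_accuracy = 0.95)))
  expect_equal(select_group(same, groups)$group, "A")

  # brute-force oracle over random curves agrees on the winning group
  set.seed(17)
  for (i in 1:25) {
    rc <- do.call(rbind, lapply(names(groups), function(g)
      data.frame(group = g, n_trees = grid,
                 oob_error = round(stats::runif(4), 3),
                 prediction_accuracy = round(stats::runif(4), 3))))
    got <- select_group(rc, groups)$group
    peak <- vapply(names(groups), function(g)
      max(rc$prediction_accuracy[rc$group == g]), 0)
    oracle <- names(groups)[order(-peak,
      vapply(names(groups), function(g) {
        d <- rc[rc$group == g, ]
        min(d$oob_error[d$prediction_accuracy == max(d$prediction_accuracy)])
      }, 0), lengths(groups))][1]
    expect_equal(got, oracle)
  }
  bad <- curves; bad$oob_error[1] <- NaN
  expect_error(select_group(bad, groups), "non-finite")
})

test_that("oob curves cover the grid and stay in [0, 1]", {
  feats <- toy_features(n = 120)
  cv <- oob_curve(feats, c("f_signal", "f_weak"), tree_grid = c(30, 60),
                  seed = 2)
  expect_equal(cv$n_trees, c(30, 60))
  expect_true(all(cv$oob_error >= 0 & cv$oob_error <= 1))
  expect_true(all(cv$prediction_accuracy >= 0 &
                    cv$prediction_accuracy <= 1))
  expect_error(oob_curve(feats, "f_signal", tree_grid = numeric(0)),
               "nonempty")
  tiny <- toy_features(n = 6)
  expect_error(oob_curve(tiny, "f_signal", tree_grid = 10, seed = 1),
               "small")
})

test_that("bootstrap in-bag fraction matches inclusion probabilities", {
  # n = 1: the single sample is always in-bag
  expect_equal(bootstrap_fractions(n = 1, reps = 10, seed = 1)$in_bag_pct,
               100)
  # n = 2: expected distinct fraction 1 - (1/2)^2 = 0.75
  b2 <- bootstrap_fractions(n = 2, reps = 4000, seed = 2)
  expect_equal(b2$in_bag_pct, 75, tolerance = 0.02)
  # large n: 1 - 1/e and its complement, within half a percentage point
  b <- bootstrap_fractions(n = 10000, reps = 200, seed = 3)
  expect_lt(abs(b$in_bag_pct - 100 * (1 - exp(-1))), 0.5)
  expect_lt(abs(b$oob_pct - 100 * exp(-1)), 0.5)
  expect_equal(b$in_bag_pct + b$oob_pct, 100)
})
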