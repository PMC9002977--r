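table2_metrics <- function() {
  tibble::tibble(
    class = c("BHF", "FHF", "LHF", "BSF", "FSF", "LSF", "J", "S", "SB", "W"),
    precision = c(100, 76.19, 75, 95.83, 90.24, 86.79, 96.71, 96.77, 91.18, 97.21),
    recall = c(75, 88.89, 75, 95.83, 77.08, 95.83, 96.71, 96.77, 83.78, 97.63),
    specificity = c(100, 99.01, 99.71, 99.9, 99.6, 99.3, 99.01, 99.57, 99.7, 97.77),
    f1 = c(85.71, 82.05, 75, 95.83, 83.15, 91.09, 96.71, 96.77, 87.32, 97.42)
  )
}

test_that("confusion matrices count true/predicted pairs", {
  cm <- confusion(c("A", "B"), c("A", "B"), c("A", "B"))
  expect_equal(unname(cm), diag(2) * 1L)
  cm2 <- confusion("A", "B", c("A", "B"))
  expect_equal(cm2["A", "B"], 1L)
  expect_equal(sum(cm2), 1L)
  y <- sample(c("A", "B", "C"), 30, TRUE)
  p <- sample(c("A", "B", "C"), 30, TRUE)
  expect_equal(sum(confusion(y, p, c("A", "B", "C"))), 30L)
  expect_error(confusion("A", "D", c("A", "B")), "unknown")
  expect_error(confusion(c("A", "A"), "A", c("A")), "equal length")
})

test_that("one-vs-rest metrics reproduce direct arithmetic", {
  cm <- matrix(c(8L, 2L, 1L, 9L), 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  m <- per_class_metrics(cm)
  expect_equal(m$recall[1], 80)
  expect_equal(m$precision[1], 100 * 8 / 9, tolerance = 1e-10)
  expect_equal(round(m$precision[1], 2), 88.89)
  expect_equal(m$specificity[1], 90)

  perfect <- per_class_metrics(diag(c(5L, 7L)) |>
                                 `dimnames<-`(list(c("A", "B"), c("A", "B"))))
  expect_true(all(perfect$precision == 100 & perfect$recall == 100 &
                    perfect$specificity == 100 & perfect$f1 == 100))

  # F1 from printed precision/recall
  f1 <- 2 * 100 * 75 / (100 + 75)
  expect_equal(round(f1, 2), 85.71)

  # recall from the matrix equals diagonal over row sum
  expect_equal(m$recall, 100 * diag(cm) / rowSums(cm), ignore_attr = TRUE)
})

test_that("zero-denominator cells report 0 with a warning", {
  cm <- matrix(c(0L, 0L, 3L, 7L), 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  w <- testthat::capture_warnings(m <- per_class_metrics(cm))
  expect_true(any(grepl("zero denominator", w)))
  expect_equal(m$recall[1], 0)
  expect_equal(m$f1[1], 0)
})

# agreement with a value printed at two decimals (half-ties included)
expect_printed <- function(actual, printed) {
  expect_lt(abs(actual - printed), 0.0050001)
}

test_that("UAR is the plain mean of per-class recalls", {
  m <- table2_metrics()
  expect_printed(uar(m$recall), 88.25)
  expect_equal(uar(42), 42)
  t3 <- c(91.67, 97.22, 66.67, 95.83, 81.25, 89.58, 100)
  expect_printed(uar(t3), 88.89)
  expect_error(uar(numeric(0)), "empty")
})

test_that("UAR ignores class sample counts (unweightedness)", {
  y <- c(rep("A", 4), rep("B", 8))
  p <- c("A", "A", "A", "B", rep("B", 7), "A")
  u1 <- uar(per_class_metrics(confusion(y, p, c("A", "B")))$recall)
  # duplicate every window of class B: recalls unchanged, so UAR unchanged
  y2 <- c(y, rep("B", 8))
  p2 <- c(p, rep("B", 7), "A")
  u2 <- uar(per_class_metrics(confusion(y2, p2, c("A", "B")))$recall)
  expect_equal(u1, u2)
})

test_that("direction and severity roll-ups average their class partitions", {
  m <- table2_metrics()
  d <- direction_uar(m)
  expect_printed(d[["forward"]], 82.99)
  expect_printed(d[["backward"]], 85.42)
  expect_printed(d[["lateral"]], 85.42)
  s <- severity_uar(m)
  expect_printed(s[["hard"]], 79.63)
  expect_printed(s[["soft"]], 89.58)
  expect_printed(falls_only_average(m), 84.60)

  t3 <- tibble::tibble(
    class = c("BHF", "FHF", "LHF", "BSF", "FSF", "LSF", "ADL"),
    recall = c(91.67, 97.22, 66.67, 95.83, 81.25, 89.58, 100),
    precision = 0, specificity = 0, f1 = 0)
  expect_printed(falls_only_average(t3), 87.04)

  eq <- tibble::tibble(class = fallwatch:::fall_classes(), recall = 77,
                       precision = 0, specificity = 0, f1 = 0)
  expect_equal(unname(direction_uar(eq)), rep(77, 3))
  expect_equal(unname(severity_uar(eq)), rep(77, 2))
  # 3:3-weighted mean of hard and soft equals the falls-only average
  expect_equal(mean(severity_uar(m)), falls_only_average(m))
  expect_error(direction_uar(m[m$class != "BHF", ]), "missing fall class")
})

test_that("evaluation reports aggregate, print, tidy and serialise", {
  classes <- c("W", "J", "S", "SB", fallwatch:::fall_classes())
  withr::with_seed(8, {
    y <- sample(classes, 200, TRUE)
    p <- ifelse(stats::runif(200) < 0.8, y, sample(classes, 200, TRUE))
  })
  rep <- eval_report(y, p, classes)
  expect_equal(sum(rep$confusion), 200L)
  expect_equal(rep$uar, uar(rep$metrics$recall))
  expect_equal(mean(rep$severity), rep$falls_only)
  expect_equal(nrow(tidy(rep)), 10L)
  expect_equal(glance(rep)$uar, rep$uar)

  txt <- format_eval_text(rep)
  expect_true(any(grepl("Average", txt)))
  expect_true(any(grepl("Falls-only", txt)))

  js <- jsonlite::fromJSON(eval_report_json(rep))
  expect_equal(js$n, 200)
  expect_named(js$direction_uar, c("forward", "backward", "lateral"))
  expect_equal(js$uar, round(rep$uar, 2), tolerance = 0.005)

  plt <- ggplot2::autoplot(rep)
  expect_s3_class(plt, "ggplot")
})
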