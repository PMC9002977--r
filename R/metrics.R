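#' Confusion matrix
#'
#' @param y_true,y_pred Character (or factor) label vectors of equal
#'   length; every label must be in `classes`.
#' @param classes Ordered class labels fixing the row/column order.
#' @return A k x k integer matrix; rows are true classes, columns
#'   predicted classes.
#' @export
confusion <- function(y_true, y_pred, classes) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length")
  }
  bad <- setdiff(unique(c(y_true, y_pred)), classes)
  if (length(bad) > 0) {
    abort(paste0("unknown label(s): ", paste(bad, collapse = ", ")))
  }
  tt <- table(factor(y_true, levels = classes),
              factor(y_pred, levels = classes))
  m <- matrix(as.integer(tt), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  m
}

#' Per-class one-vs-rest metrics
#'
#' For each class: recall (sensitivity) `100 * TP / (TP + FN)`,
#' precision `100 * TP / (TP + FP)`, specificity `100 * TN / (TN + FP)`
#' and F1 `2 * P * R / (P + R)`, all in percent. Ratios with a zero
#' denominator are reported as 0 with a warning so macro averages stay
#' defined on degenerate splits.
#'
#' @param cm Confusion matrix from [confusion()].
#' @return A tibble: `class`, `precision`, `recall`, `specificity`,
#'   `f1` (percent).
#' @export
per_class_metrics <- function(cm) {
  classes <- rownames(cm)
  total <- sum(cm)
  safe_div <- function(num, den, what, cl) {
    if (den == 0) {
      warn(paste0(what, " undefined for class ", cl,
                  " (zero denominator); reporting 0"))
      return(0)
    }
    num / den
  }
  rows <- purrr::map(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    recall <- 100 * safe_div(tp, tp + fn, "recall", classes[i])
    precision <- 100 * safe_div(tp, tp + fp, "precision", classes[i])
    specificity <- 100 * safe_div(tn, tn + fp, "specificity", classes[i])
    f1 <- if (precision + recall == 0) 0 else {
      2 * precision * recall / (precision + recall)
    }
    tibble(class = classes[i], precision = precision, recall = recall,
           specificity = specificity, f1 = f1)
  })
  dplyr::bind_rows(rows)
}

#' Unweighted average recall
#'
#' The arithmetic mean of the per-class recalls, one term per class --
#' the headline metric. Being unweighted, it is invariant to class
#' sample counts.
#'
#' @param recalls Numeric vector of per-class recalls (percent).
#' @return UAR in percent.
#' @export
uar <- function(recalls) {
  if (length(recalls) == 0) abort("empty recall list")
  mean(recalls)
}

get_fall_recalls <- function(metrics) {
  need <- fall_classes()
  miss <- setdiff(need, metrics$class)
  if (length(miss) > 0) {
    abort(paste0("missing fall class(es): ", paste(miss, collapse = ", ")))
  }
  stats::setNames(metrics$recall[match(need, metrics$class)], need)
}

#' Fall roll-ups by direction and severity
#'
#' The six fall classes partition two ways: by direction (forward =
#' FHF, FSF; backward = BHF, BSF; lateral = LHF, LSF) and by severity
#' (hard = FHF, BHF, LHF; soft = FSF, BSF, LSF). Each roll-up is the
#' unweighted mean of its constituent class recalls;
#' `falls_only_average()` is the unweighted mean over all six.
#'
#' @param metrics Per-class metric tibble from [per_class_metrics()];
#'   all six fall classes must be present.
#' @return `direction_uar()`: named numeric (forward, backward,
#'   lateral); `severity_uar()`: named numeric (hard, soft);
#'   `falls_only_average()`: single number. All percent.
#' @name fall-rollups
NULL

#' @rdname fall-rollups
#' @export
direction_uar <- function(metrics) {
  r <- get_fall_recalls(metrics)
  c(forward = mean(r[c("FHF", "FSF")]),
    backward = mean(r[c("BHF", "BSF")]),
    lateral = mean(r[c("LHF", "LSF")]))
}

#' @rdname fall-rollups
#' @export
severity_uar <- function(metrics) {
  r <- get_fall_recalls(metrics)
  c(hard = mean(r[c("FHF", "BHF", "LHF")]),
    soft = mean(r[c("FSF", "BSF", "LSF")]))
}

#' @rdname fall-rollups
#' @export
falls_only_average <- function(metrics) {
  mean(get_fall_recalls(metrics))
}

#' Evaluation report
#'
#' Bundles the confusion matrix, per-class metrics, their macro
#' averages, the UAR and -- when all six fall classes are present --
#' the direction, severity and falls-only roll-ups.
#'
#' @inheritParams confusion
#' @return An object of class `fall_eval`.
#' @export
eval_report <- function(y_true, y_pred, classes) {
  cm <- confusion(y_true, y_pred, classes)
  metrics <- per_class_metrics(cm)
  has_falls <- all(fall_classes() %in% classes)
  structure(
    list(
      confusion = cm,
      metrics = metrics,
      macro = dplyr::summarise(metrics,
                               precision = mean(.data$precision),
                               recall = mean(.data$recall),
                               specificity = mean(.data$specificity),
                               f1 = mean(.data$f1)),
      uar = uar(metrics$recall),
      direction = if (has_falls) direction_uar(metrics),
      severity = if (has_falls) severity_uar(metrics),
      falls_only = if (has_falls) falls_only_average(metrics),
      n = length(y_true),
      classes = classes
    ),
    class = "fall_eval"
  )
}

#' @export
print.fall_eval <- function(x, ...) {
  cat(format_eval_text(x), sep = "\n")
  invisible(x)
}

#' Plain-text report table
#'
#' Renders the per-class metrics in the standard report layout (class,
#' precision, recall, specificity, F1, plus an Average row), all values
#' rounded half-up to two decimals.
#'
#' @param report A `fall_eval` object.
#' @return Character vector of lines.
#' @export
format_eval_text <- function(report) {
  stopifnot(inherits(report, "fall_eval"))
  f <- function(v) sprintf("%.2f", round_half_up(v, 2))
  header <- sprintf("%-8s %12s %12s %15s %12s", "Activity",
                    "Precision(%)", "Recall(%)", "Specificity(%)", "F1(%)")
  body <- sprintf("%-8s %12s %12s %15s %12s",
                  report$metrics$class, f(report$metrics$precision),
                  f(report$metrics$recall), f(report$metrics$specificity),
                  f(report$metrics$f1))
  avg <- sprintf("%-8s %12s %12s %15s %12s", "Average",
                 f(report$macro$precision), f(report$macro$recall),
                 f(report$macro$specificity), f(report$macro$f1))
  lines <- c(header, body, avg, "", sprintf("UAR: %s%%", f(report$uar)))
  if (!is.null(report$direction)) {
    lines <- c(lines,
               sprintf("Direction UAR: forward %s%%, backward %s%%, lateral %s%%",
                       f(report$direction[["forward"]]),
                       f(report$direction[["backward"]]),
                       f(report$direction[["lateral"]])),
               sprintf("Severity UAR: hard %s%%, soft %s%%",
                       f(report$severity[["hard"]]),
                       f(report$severity[["soft"]])),
               sprintf("Falls-only average recall: %s%%",
                       f(report$falls_only)))
  }
  lines
}

#' Machine-readable report
#'
#' @param report A `fall_eval` object.
#' @param path Optional path; when given, the JSON is written there.
#' @return JSON string (invisibly when `path` is given). Percentages
#'   rounded half-up to two decimals; the confusion matrix is included
#'   as counts.
#' @export
eval_report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "fall_eval"))
  r2 <- function(v) round_half_up(v, 2)
  obj <- list(
    classes = report$classes,
    n = report$n,
    confusion = unname(apply(report$confusion, 1, as.integer,
                             simplify = FALSE)),
    per_class = lapply(seq_len(nrow(report$metrics)), function(i) {
      m <- report$metrics[i, ]
      list(class = m$class, precision = r2(m$precision),
           recall = r2(m$recall), specificity = r2(m$specificity),
           f1 = r2(m$f1))
    }),
    macro = lapply(as.list(report$macro), r2),
    uar = r2(report$uar)
  )
  if (!is.null(report$direction)) {
    obj$direction_uar <- lapply(as.list(report$direction), r2)
    obj$severity_uar <- lapply(as.list(report$severity), r2)
    obj$falls_only_average <- r2(report$falls_only)
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @export
#' @method tidy fall_eval
#' @rdname fallwatch-tidiers
tidy.fall_eval <- function(x, ...) x$metrics

#' @export
#' @method glance fall_eval
#' @rdname fallwatch-tidiers
glance.fall_eval <- function(x, ...) {
  out <- tibble(n = x$n, uar = x$uar,
                macro_precision = x$macro$precision,
                macro_f1 = x$macro$f1)
  if (!is.null(x$direction)) {
    out <- dplyr::bind_cols(out, tibble(
      uar_forward = x$direction[["forward"]],
      uar_backward = x$direction[["backward"]],
      uar_lateral = x$direction[["lateral"]],
      uar_hard = x$severity[["hard"]],
      uar_soft = x$severity[["soft"]],
      falls_only = x$falls_only
    ))
  }
  out
}

#' Plot a confusion matrix
#'
#' @param object A `fall_eval` object.
#' @param ... Unused.
#' @return A ggplot heatmap of counts (true class on the y axis).
#' @export
#' @method autoplot fall_eval
autoplot.fall_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("true", "predicted", "count")
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$true,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(object$classes)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = sprintf("UAR %.2f%%", round_half_up(object$uar, 2))) +
    ggplot2::theme_minimal()
}
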