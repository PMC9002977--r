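#' Stratified train/validation/test split
#'
#' Splits windows into three disjoint, exhaustive partitions with
#' per-class proportions matching the requested fractions to within
#' rounding (largest-remainder allocation per class, each split kept
#' non-empty per class). Deterministic given `seed`.
#'
#' @param windows A window tibble.
#' @param fractions Named numeric vector `c(train=, validation=, test=)`;
#'   positive, summing to 1.
#' @param seed Integer seed for the per-class shuffles.
#' @return Named list of window tibbles: `train`, `validation`, `test`.
#' @export
stratified_split <- function(windows,
                             fractions = c(train = 0.70,
                                           validation = 0.15,
                                           test = 0.15),
                             seed = 1L) {
  stopifnot(is.data.frame(windows), nrow(windows) > 0)
  stopifnot(length(fractions) == 3, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-8)
  counts <- table(windows$label)
  too_few <- names(counts)[counts < 3]
  if (length(too_few) > 0) {
    abort(paste0("class(es) with fewer windows than splits: ",
                 paste(too_few, collapse = ", ")))
  }
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  assign_split <- rep(NA_character_, nrow(windows))
  for (cl in sort(names(counts))) {
    idx <- which(windows$label == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    raw <- fractions * n
    sizes <- floor(raw)
    rem <- n - sum(sizes)
    if (rem > 0) {
      order_frac <- order(raw - sizes, decreasing = TRUE)
      sizes[order_frac[seq_len(rem)]] <- sizes[order_frac[seq_len(rem)]] + 1
    }
    # keep every split non-empty for this class (possible since n >= 3)
    while (any(sizes == 0)) {
      sizes[which.max(sizes)] <- max(sizes) - 1
      sizes[which.min(sizes)] <- min(sizes) + 1
    }
    bounds <- cumsum(sizes)
    assign_split[idx[seq_len(bounds[1])]] <- "train"
    assign_split[idx[(bounds[1] + 1):bounds[2]]] <- "validation"
    assign_split[idx[(bounds[2] + 1):bounds[3]]] <- "test"
  }
  list(
    train = windows[assign_split == "train", , drop = FALSE],
    validation = windows[assign_split == "validation", , drop = FALSE],
    test = windows[assign_split == "test", , drop = FALSE]
  )
}
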