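#' Activity-code to class-label schemes
#'
#' SisFall activity codes are regrouped into four activities of daily
#' living -- walking (W), jogging (J), sitting (S) and standing (SB) --
#' and six fall classes labelled jointly by direction and severity:
#' forward/backward/lateral crossed with hard (direct impact) and soft
#' (impact dampened by some support). Two scheme variants exist:
#'
#' * `"ten_class"`: the four ADLs kept separate (10 classes).
#' * `"fall_vs_adl"`: the four ADLs pooled into a single `ADL` class
#'   (7 classes); fall labels are unchanged.
#'
#' Codes not covered by the relabelling (e.g. getting in and out of a
#' car) are *excluded*: [map_label()] returns `NA` for them and the
#' windowing stage skips them.
#'
#' @param variant `"ten_class"` or `"fall_vs_adl"`.
#'
#' @return An object of class `label_scheme`: a list with `variant`,
#'   `mapping` (named character vector, activity code -> label) and
#'   `class_set` (ordered character vector of output labels).
#' @examples
#' scheme <- label_scheme("ten_class")
#' map_label(c("D05", "F07", "D19"), scheme)
#' @export
label_scheme <- function(variant = c("ten_class", "fall_vs_adl")) {
  variant <- match.arg(variant)
  ten <- c(
    D01 = "W", D02 = "W", D03 = "J", D04 = "J",
    D05 = "W", D06 = "W",
    D07 = "S", D08 = "S", D09 = "S", D10 = "S",
    D11 = "S", D12 = "S", D13 = "S",
    D15 = "SB", D16 = "SB",
    F01 = "FHF", F02 = "BHF", F03 = "LHF",
    F04 = "FHF", F05 = "FHF",
    F06 = "FSF", F07 = "LSF", F08 = "FSF", F09 = "LSF",
    F10 = "FSF", F11 = "BSF", F12 = "LSF", F13 = "FSF",
    F14 = "BSF", F15 = "LSF"
  )
  if (variant == "ten_class") {
    mapping <- ten
    class_set <- c("W", "J", "S", "SB",
                   "FHF", "BHF", "LHF", "FSF", "BSF", "LSF")
  } else {
    mapping <- ifelse(ten %in% c("W", "J", "S", "SB"), "ADL", ten)
    names(mapping) <- names(ten)
    class_set <- c("ADL", "FHF", "BHF", "LHF", "FSF", "BSF", "LSF")
  }
  structure(
    list(variant = variant, mapping = mapping, class_set = class_set),
    class = "label_scheme"
  )
}

#' @export
print.label_scheme <- function(x, ...) {
  cat("<label_scheme: ", x$variant, ">\n", sep = "")
  cat("  classes:", paste(x$class_set, collapse = ", "), "\n")
  cat("  codes mapped:", length(x$mapping), "\n")
  invisible(x)
}

#' Map activity codes to class labels
#'
#' Total and deterministic over syntactically valid codes: codes covered
#' by the scheme return their class label, any other valid code returns
#' `NA_character_` (the "excluded" marker), never an error.
#'
#' @param code Character vector of activity codes (`"D01"`, `"F07"`, ...).
#' @param scheme A [label_scheme()].
#'
#' @return Character vector of labels, `NA` for excluded codes.
#' @export
map_label <- function(code, scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  ok <- grepl("^[DF][0-9]{2}$", code)
  if (!all(ok)) {
    abort(paste0("invalid activity code(s): ",
                 paste(unique(code[!ok]), collapse = ", ")))
  }
  unname(scheme$mapping[match(code, names(scheme$mapping))])
}

# The six fall classes in report order; shared by metrics and docs.
fall_classes <- function() c("FHF", "BHF", "LHF", "FSF", "BSF", "LSF")

# Table of source activity codes with their per-subject trial counts.
# Codes D01-D04 are single long (100 s) walking/jogging recordings; all
# other codes have five 12 s trials.
sisfall_code_table <- function() {
  codes <- names(label_scheme("ten_class")$mapping)
  tibble(
    code = codes,
    trials = ifelse(codes %in% c("D01", "D02", "D03", "D04"), 1L, 5L)
  )
}
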