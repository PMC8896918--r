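#' The standard grid of Bonn classification cases
#'
#' Sixteen two-class problems pitting combinations of the non-ictal Bonn
#' sets A-D against the ictal set E (plus the harder AB vs CD contrast),
#' and one three-class problem AB vs CD vs E. Case names use the
#' convention `"<group1>-<group2>[-<group3>]"`; for two-class cases the
#' last group is the designated positive (seizure) class.
#'
#' @return A list of `classification_case` objects, in the fixed order
#'   A-E, B-E, C-E, D-E, AB-E, AC-E, AD-E, BC-E, BD-E, CD-E, ABC-E,
#'   ABD-E, ACD-E, BCD-E, ABCD-E, AB-CD, AB-CD-E.
#' @export
#' @examples
#' length(build_cases())       # 17
#' build_cases()[["A-E"]]
build_cases <- function() {
  two_class <- c("A-E", "B-E", "C-E", "D-E", "AB-E", "AC-E", "AD-E",
                 "BC-E", "BD-E", "CD-E", "ABC-E", "ABD-E", "ACD-E",
                 "BCD-E", "ABCD-E", "AB-CD")
  names_all <- c(two_class, "AB-CD-E")
  cases <- lapply(names_all, classification_case)
  names(cases) <- names_all
  cases
}

#' Construct a classification case from its name
#'
#' Parses a name such as `"ABCD-E"` into ordered groups of set labels.
#' Groups must be disjoint and non-empty; the last group is the positive
#' class for two-class cases (and the one-vs-rest focus for three-class).
#'
#' @param name Case name: hyphen-separated groups of single-letter set
#'   labels, e.g. `"AB-CD-E"`.
#' @return An object of class `classification_case`: list with `name`,
#'   `class_groups` (list of character vectors) and `n_classes`.
#' @export
classification_case <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  if (length(parts) < 2L) stop("case name needs at least two groups: ", name)
  groups <- lapply(parts, function(p) strsplit(p, "")[[1]])
  if (any(lengths(groups) == 0L)) stop("empty class group in case: ", name)
  all_labels <- unlist(groups)
  if (anyDuplicated(all_labels)) {
    stop("class groups must be disjoint in case: ", name)
  }
  structure(
    list(name = name, class_groups = groups, n_classes = length(groups)),
    class = "classification_case"
  )
}

#' @export
print.classification_case <- function(x, ...) {
  cat(sprintf("<classification_case> %s: %d classes (%s)%s\n",
              x$name, x$n_classes,
              paste(vapply(x$class_groups, paste, character(1), collapse = ""),
                    collapse = " vs "),
              if (x$n_classes == 2L) " [positive = last group]" else ""))
  invisible(x)
}

# Map per-row set labels to 1-based class indices for a case; labels not in
# the case map to NA (rows to drop).
case_class_index <- function(case, set_labels) {
  idx <- rep(NA_integer_, length(set_labels))
  for (g in seq_along(case$class_groups)) {
    idx[set_labels %in% case$class_groups[[g]]] <- g
  }
  idx
}
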