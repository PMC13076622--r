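#' Rand Index and Adjusted Rand Index between two partitions
#'
#' RI is the fraction of item pairs on which the two partitions agree (both
#' together or both apart). ARI corrects RI for chance under the permutation
#' model via the contingency-table formula, scoring 0 in expectation for
#' random partitions and 1 for identical ones. When the chance-correction
#' denominator is zero (both partitions degenerate in the same way) ARI is
#' defined as 1.
#'
#' @param a,b Two partitions over the same items: named vectors, or tibbles
#'   with columns `tree_id` and a label column (`community` or `species`).
#' @return A one-row tibble with `rand_index`, `adjusted_rand_index`,
#'   `n_items`.
#' @examples
#' partition_agreement(c(a = 1, b = 1, c = 2, d = 2),
#'                     c(a = 1, b = 2, c = 1, d = 2))
#' @export
partition_agreement <- function(a, b) {
  a <- as_labels(a)
  b <- as_labels(b)
  common <- intersect(names(a), names(b))
  if (length(common) < 2L) {
    abort("need at least 2 shared items", class = "crowncluster_invalid_arg")
  }
  a <- a[common]
  b <- b[common]
  n <- length(common)
  tab <- table(a, b)
  s_ij <- sum(choose(tab, 2))
  s_a <- sum(choose(rowSums(tab), 2))
  s_b <- sum(choose(colSums(tab), 2))
  total <- choose(n, 2)
  ri <- (total + 2 * s_ij - s_a - s_b) / total
  expected <- s_a * s_b / total
  denom <- (s_a + s_b) / 2 - expected
  ari <- if (denom == 0) 1 else (s_ij - expected) / denom
  tibble(rand_index = ri, adjusted_rand_index = ari, n_items = n)
}

as_labels <- function(x) {
  if (inherits(x, "tree_communities")) x <- x$assignment
  if (is.data.frame(x)) {
    lab_col <- intersect(c("community", "species", "label"), names(x))[1L]
    if (is.na(lab_col) || !"tree_id" %in% names(x)) {
      abort("partition tibble needs tree_id plus community/species/label",
            class = "crowncluster_invalid_arg")
    }
    return(stats::setNames(as.character(x[[lab_col]]), x$tree_id))
  }
  if (is.null(names(x))) {
    names(x) <- as.character(seq_along(x))
  }
  stats::setNames(as.character(x), names(x))
}

#' Confusion matrix and macro-averaged classification scores
#'
#' Overall accuracy (trace over n), plus one-vs-rest precision, recall,
#' specificity and F1 per class, macro-averaged with equal class weights so a
#' majority class cannot dominate the summary. A class never predicted gets
#' precision 0 (with a warning) rather than being dropped, keeping macro
#' averages comparable across runs that miss classes.
#'
#' @param truth,predicted Named character vectors or tibbles (`tree_id` +
#'   label column) over the same items.
#' @param class_order Optional class ordering for the confusion matrix rows
#'   and columns; defaults to the sorted union of observed classes.
#' @return A list of class `classification_scores`: `confusion` (true x
#'   predicted), `accuracy`, `macro_recall`, `macro_precision`,
#'   `macro_specificity`, `macro_f1`, and the `per_class` tibble.
#' @export
classification_scores <- function(truth, predicted, class_order = NULL) {
  truth <- as_labels(truth)
  predicted <- as_labels(predicted)
  common <- intersect(names(truth), names(predicted))
  if (length(common) == 0L) {
    abort("no shared items between truth and predictions",
          class = "crowncluster_invalid_arg")
  }
  truth <- truth[common]
  predicted <- predicted[common]
  classes <- class_order %||% sort(union(truth, predicted))
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  cm <- table(truth = tf, predicted = pf)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  per <- purrr::map(classes, function(cl) {
    tp <- cm[cl, cl]
    fp <- sum(cm[, cl]) - tp
    fn <- sum(cm[cl, ]) - tp
    tn <- n - tp - fp - fn
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
    tibble(class = cl, precision = prec, recall = rec, specificity = spec)
  })
  per <- dplyr::bind_rows(per)
  if (any(is.na(per$precision))) {
    warn(paste0("classes never predicted get precision 0: ",
                paste(per$class[is.na(per$precision)], collapse = ", ")))
    per$precision[is.na(per$precision)] <- 0
  }
  per$recall[is.na(per$recall)] <- 0
  per$f1 <- ifelse(per$precision + per$recall == 0, 0,
                   2 * per$precision * per$recall /
                     (per$precision + per$recall))
  structure(
    list(confusion = cm, accuracy = acc,
         macro_recall = mean(per$recall),
         macro_precision = mean(per$precision),
         macro_specificity = mean(per$specificity, na.rm = TRUE),
         macro_f1 = mean(per$f1),
         per_class = per),
    class = "classification_scores"
  )
}

#' @export
print.classification_scores <- function(x, ...) {
  cat(sprintf(
    "<classification_scores> accuracy %.3f | macro P %.3f R %.3f F1 %.3f\n",
    x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' @rdname classification_scores
#' @param x A `classification_scores` object.
#' @param ... Unused.
#' @method glance classification_scores
#' @export
glance.classification_scores <- function(x, ...) {
  tibble(accuracy = x$accuracy, macro_precision = x$macro_precision,
         macro_recall = x$macro_recall,
         macro_specificity = x$macro_specificity, macro_f1 = x$macro_f1)
}
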