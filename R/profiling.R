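## --- qPCR profiling: detectability, global-mean normalization, ranking ---

validate_ct_matrix <- function(ct, arg = "ct") {
  if (!is.data.frame(ct) || ncol(ct) < 2)
    abort(sprintf("`%s` must be a data frame with a `mirna` column plus one column per subject.", arg))
  if (names(ct)[1] != "mirna")
    abort(sprintf("first column of `%s` must be `mirna` (got `%s`).", arg, names(ct)[1]))
  if (anyDuplicated(ct$mirna))
    abort(sprintf("duplicate miRNA identifiers in `%s`: %s", arg,
                  paste(unique(ct$mirna[duplicated(ct$mirna)]), collapse = ", ")))
  vals <- as.matrix(ct[, -1])
  if (!is.numeric(vals) || any(!is.finite(vals)))
    abort(sprintf("all Ct values in `%s` must be finite numbers.", arg))
  if (any(vals < 0))
    abort(sprintf("negative Ct values in `%s`.", arg))
  invisible(ct)
}

#' Detectability filter for qPCR Ct profiles
#'
#' A miRNA is called detectable when its Ct is strictly below `ct_max` in at
#' least `min_count` subjects (default rule: Ct < 35 in at least 4 of 5
#' subjects, i.e. `ceiling(0.8 * n_subjects)`).
#'
#' @param ct Ct matrix: data frame with first column `mirna` and one numeric
#'   column per subject.
#' @param ct_max Strict upper Ct threshold for a well to count as amplified.
#' @param min_count Minimum number of subjects below `ct_max`; defaults to
#'   `ceiling(0.8 * n_subjects)`.
#' @return A tibble with columns `mirna`, `n_below` (subjects with
#'   Ct < `ct_max`) and `detected` (logical), in input row order.
#' @examples
#' ct <- tibble::tibble(mirna = c("a", "b"),
#'                      S1 = c(30, 40), S2 = c(31, 40), S3 = c(33, 40),
#'                      S4 = c(34, 40), S5 = c(36, 40))
#' detect_mirnas(ct)
#' @export
detect_mirnas <- function(ct, ct_max = 35, min_count = NULL) {
  validate_ct_matrix(ct)
  n_subj <- ncol(ct) - 1
  if (is.null(min_count)) min_count <- ceiling(0.8 * n_subj)
  if (min_count < 1 || min_count > n_subj)
    abort(sprintf("`min_count` (%d) must be between 1 and the number of subjects (%d).",
                  min_count, n_subj))
  n_below <- rowSums(as.matrix(ct[, -1]) < ct_max)
  tibble(mirna = ct$mirna, n_below = as.integer(n_below),
         detected = n_below >= min_count)
}

## Accept either a character vector of ids or the tibble from detect_mirnas().
as_detected_ids <- function(detected) {
  if (is.data.frame(detected)) {
    if (!all(c("mirna", "detected") %in% names(detected)))
      abort("`detected` data frame must have columns `mirna` and `detected`.")
    return(detected$mirna[detected$detected])
  }
  as.character(detected)
}

#' Global-mean normalization of Ct values
#'
#' For each subject, the global mean is the mean Ct over the detected miRNA
#' panel, restricted to wells that amplified (Ct < `ct_max`) in that subject.
#' Relative expression is `global_mean - Ct`, so positive values mean more
#' abundant than the panel average (log2 scale, Ct units). Wells at or above
#' `ct_max` are returned as `NA` and excluded from all means, so present
#' values sum to zero within each subject.
#'
#' @param ct Ct matrix (see [detect_mirnas()]).
#' @param detected Detected miRNA ids: a character vector or the tibble
#'   returned by [detect_mirnas()].
#' @inheritParams detect_mirnas
#' @return A tibble of relative expression with the same layout as `ct`,
#'   restricted to detected miRNAs; undetected wells are `NA`.
#' @examples
#' ct <- tibble::tibble(mirna = c("a", "b", "c"), S1 = c(30, 32, 34))
#' normalize_global_mean(ct, c("a", "b", "c"))
#' @export
normalize_global_mean <- function(ct, detected, ct_max = 35) {
  validate_ct_matrix(ct)
  ids <- as_detected_ids(detected)
  missing_ids <- setdiff(ids, ct$mirna)
  if (length(missing_ids))
    abort(sprintf("detected ids not present in `ct`: %s",
                  paste(missing_ids, collapse = ", ")))
  if (length(ids) < 2)
    abort("need at least 2 detected miRNAs to compute a global mean.")
  sub <- ct[match(ids, ct$mirna), , drop = FALSE]
  vals <- as.matrix(sub[, -1])
  present <- vals < ct_max
  n_present <- colSums(present)
  if (any(n_present < 2))
    abort(sprintf("subject(s) with fewer than 2 detected values: %s",
                  paste(colnames(vals)[n_present < 2], collapse = ", ")))
  gm <- colSums(vals * present) / n_present
  rel <- sweep(-vals, 2, gm, `+`)
  rel[!present] <- NA_real_
  out <- dplyr::bind_cols(tibble(mirna = sub$mirna),
                          as_tibble(as.data.frame(rel)))
  names(out) <- names(ct)
  attr(out, "compartment") <- attr(ct, "compartment", exact = TRUE)
  out
}

#' Rank miRNAs by mean relative expression
#'
#' Orders miRNAs from most to least expressed by their across-subject mean of
#' present (non-`NA`) relative-expression values. Ties are broken
#' lexicographically by miRNA id so the ranking is deterministic.
#'
#' @param rel Relative-expression matrix from [normalize_global_mean()].
#' @return A tibble with columns `mirna`, `mean_rel_expr`, `rank`.
#' @examples
#' rel <- tibble::tibble(mirna = c("a", "b"), S1 = c(2, -2), S2 = c(0, 0))
#' rank_mirnas(rel)
#' @export
rank_mirnas <- function(rel) {
  if (!is.data.frame(rel) || nrow(rel) == 0)
    abort("`rel` must be a non-empty data frame.")
  means <- rowMeans(as.matrix(rel[, -1]), na.rm = TRUE)
  out <- tibble(mirna = rel$mirna, mean_rel_expr = means)
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_rel_expr), .data$mirna)
  out$rank <- seq_len(nrow(out))
  out
}

#' Correlation of miRNA abundance between compartments
#'
#' Pearson correlation of per-miRNA mean relative expression between the EV
#' and intracellular compartments, over the intersection of their detected
#' miRNA sets (one point per miRNA).
#'
#' @param rel_ev,rel_ic Relative-expression matrices from
#'   [normalize_global_mean()], one per compartment.
#' @return A one-row tibble with columns `estimate` (Pearson R) and `n`
#'   (shared miRNAs used).
#' @examples
#' rel <- tibble::tibble(mirna = letters[1:4], S1 = c(1, 2, 3, 4))
#' compartment_correlation(rel, rel)
#' @export
compartment_correlation <- function(rel_ev, rel_ic) {
  m_ev <- rank_mirnas(rel_ev)
  m_ic <- rank_mirnas(rel_ic)
  shared <- intersect(m_ev$mirna, m_ic$mirna)
  if (length(shared) < 3)
    abort(sprintf("need at least 3 shared detected miRNAs (got %d).",
                  length(shared)))
  x <- m_ev$mean_rel_expr[match(shared, m_ev$mirna)]
  y <- m_ic$mean_rel_expr[match(shared, m_ic$mirna)]
  if (sd(x) == 0 || sd(y) == 0)
    abort("zero variance in one compartment's mean relative expression.")
  tibble(estimate = cor(x, y), n = length(shared))
}
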