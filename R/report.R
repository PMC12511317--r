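#' Diagnostic-group arithmetic for a cohort count table
#'
#' Sums diagnostic subgroup counts into group totals and a grand
#' total: IBS subtype counts into the IBS total, non-classifiable
#' subgroups into their total, and all groups into the cohort size. The
#' bundled default table (`inst/extdata/cohort_counts.csv`) carries the
#' functional-bowel-disorder diagnostic breakdown used in the worked
#' examples: IBS subtypes C/M/D/U, functional constipation, functional
#' diarrhoea, and the non-classifiable remainder.
#'
#' @param counts data frame with columns `group`, `subgroup`, `count`, or a
#'   path to such a CSV. Default: the bundled table.
#' @return List with `by_group` (named totals), `ibs_total`,
#'   `non_classifiable_total`, and `grand_total`.
#' @export
cohort_report <- function(counts = system.file("extdata", "cohort_counts.csv",
                                               package = "phenonet")) {
  if (is.character(counts)) {
    counts <- utils::read.csv(counts, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("group", "subgroup", "count") %in% names(counts)))
  by_group <- tapply(counts$count, counts$group, sum)
  list(
    by_group = as.list(by_group),
    ibs_total = unname(by_group["ibs"]),
    non_classifiable_total = unname(by_group["non_classifiable"]),
    grand_total = sum(counts$count)
  )
}

#' Train/test size bookkeeping for an 80:20 split
#'
#' @param n cohort size.
#' @param test_fraction held-out fraction.
#' @return List with `n_train` and `n_test` (`n_test = round(0.2 n)`).
#' @export
split_sizes <- function(n, test_fraction = 0.2) {
  n_test <- round(test_fraction * n)
  list(n_train = n - n_test, n_test = n_test)
}
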