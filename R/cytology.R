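#' Conventional qualitative exfoliative-cytology call
#'
#' The baseline clinical rule: an aneuploid cell is a cell with DI >=
#' 2.3; a case is "positive" (for dysplasia or carcinoma) with more than
#' 5 aneuploid cells, "atypical" with 1 to 5, and "negative" with none.
#'
#' @param case a [di_case()].
#' @return list of class `qualitative_call` with `case_id`,
#'   `aneuploid_cell_count` and `call`.
#' @export
qualitative_call <- function(case) {
  stopifnot(inherits(case, "di_case"))
  n_aneu <- sum(case$di >= DI_ANEUPLOID_CUTOFF)
  call <- if (n_aneu > 5L) "positive" else if (n_aneu >= 1L) "atypical"
          else "negative"
  structure(list(case_id = case$case_id,
                 aneuploid_cell_count = as.integer(n_aneu),
                 call = call),
            class = "qualitative_call")
}

#' @export
print.qualitative_call <- function(x, ...) {
  cat(sprintf("%s: %s (%d aneuploid cell(s), DI >= 2.3)\n",
              x$case_id, x$call, x$aneuploid_cell_count))
  invisible(x)
}

#' Qualitative calls for a whole cohort
#'
#' @param cases a `di_cohort` or list of [di_case()] objects.
#' @return data frame with `case_id`, `label`, `aneuploid_cell_count`,
#'   `call`.
#' @export
qualitative_calls <- function(cases) {
  if (inherits(cases, "di_cohort")) cases <- cases$cases
  if (inherits(cases, "di_case")) cases <- list(cases)
  do.call(rbind, lapply(cases, function(cs) {
    qc <- qualitative_call(cs)
    data.frame(case_id = qc$case_id,
               label = if (is.null(cs$label)) NA_character_ else cs$label,
               aneuploid_cell_count = qc$aneuploid_cell_count,
               call = qc$call, stringsAsFactors = FALSE)
  }))
}
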