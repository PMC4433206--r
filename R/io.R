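MODEL_FORMAT_VERSION <- 1L
LABEL_TOKENS <- c("normal", "olk", "oscc", "unknown")

## TSV is the native format; comma-separated files are auto-detected
## from the header line.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a long-format DI table
#'
#' Reads a delimited table (TSV by default, comma auto-detected) with
#' one row per cell and header columns `case_id`, optional `cell_id`,
#' and `di`, returning one [di_case()] per distinct `case_id` with the
#' original cell order preserved. Non-positive or non-finite DI values
#' are rejected with an error naming the offending row; duplicate header
#' columns are rejected. Labels are joined from the manifest when one is
#' supplied.
#'
#' @param path path to the DI table.
#' @param manifest_path optional path to a manifest TSV with columns
#'   `case_id` and `label`.
#' @return list of [di_case()] objects.
#' @export
read_di_table <- function(path, manifest_path = NULL) {
  sep <- detect_sep(path)
  header <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  if (anyDuplicated(header))
    stop("duplicate header column(s): ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = NA, check.names = FALSE)
  if (!all(c("case_id", "di") %in% names(tab)))
    stop("DI table must have 'case_id' and 'di' columns", call. = FALSE)
  di <- suppressWarnings(as.numeric(tab$di))
  bad <- which(!is.finite(di) | di <= 0)
  if (length(bad) > 0L)
    stop("invalid DI value at data row ", bad[1], " (di = ",
         tab$di[bad[1]], "): DI must be a positive finite number",
         call. = FALSE)

  labels <- NULL
  if (!is.null(manifest_path)) {
    man <- read_manifest(manifest_path)
    labels <- stats::setNames(man$label, man$case_id)
  }
  ids <- unique(as.character(tab$case_id))
  lapply(ids, function(id) {
    rows <- tab$case_id == id
    lab <- if (!is.null(labels) && id %in% names(labels)) labels[[id]]
           else NULL
    di_case(id, di[rows], label = lab)
  })
}

#' Write a cohort as a long-format DI table
#'
#' One row per cell: `case_id`, `cell_id`, `di` and, for simulated
#' cases, `true_component`.
#'
#' @param cases a `di_cohort` or list of [di_case()] objects.
#' @param path output path (TSV).
#' @export
write_di_table <- function(cases, path) {
  if (inherits(cases, "di_cohort")) cases <- cases$cases
  if (inherits(cases, "di_case")) cases <- list(cases)
  tab <- do.call(rbind, lapply(cases, function(cs) {
    data.frame(case_id = cs$case_id, cell_id = seq_along(cs$di),
               di = format_full(cs$di),
               true_component = if (is.null(cs$true_component))
                 NA_integer_ else cs$true_component,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a cohort manifest
#'
#' The manifest records one row per case: `case_id`, `label` and, for
#' simulated cohorts, `n_cells` and the per-case `seed`.
#'
#' @param cohort a `di_cohort` (or a manifest data frame).
#' @param path file path (TSV).
#' @export
write_manifest <- function(cohort, path) {
  man <- if (inherits(cohort, "di_cohort")) cohort$manifest else cohort
  stopifnot(is.data.frame(man), all(c("case_id", "label") %in% names(man)))
  utils::write.table(man, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                           stringsAsFactors = FALSE)
  if (!all(c("case_id", "label") %in% names(man)))
    stop("manifest must have 'case_id' and 'label' columns", call. = FALSE)
  bad <- setdiff(unique(man$label), LABEL_TOKENS)
  if (length(bad) > 0L)
    stop("unknown label token(s) in manifest: ",
         paste(bad, collapse = ", "), call. = FALSE)
  man
}

format_full <- function(x) sprintf("%.17g", x)

#' Write / read a feature matrix
#'
#' Serialises the 16-bin feature matrix as TSV with the bins named by
#' their DI interval (`bin_0.0_0.5` ... `bin_7.5_8.0`). Values are
#' written at full double precision so a read-back reproduces the matrix
#' exactly.
#'
#' @param fm a `feature_matrix` data frame ([edtar_features()] output).
#' @param path file path (TSV).
#' @export
write_feature_matrix <- function(fm, path) {
  bins <- feature_bin_names()
  if (!all(c("case_id", bins) %in% names(fm)))
    stop("feature matrix must have case_id and the 16 bin_* columns",
         call. = FALSE)
  vals <- as.matrix(fm[, bins])
  if (any(!is.finite(vals)) || any(vals < FEATURE_FILLER))
    stop("feature values must be finite and >= ", FEATURE_FILLER,
         call. = FALSE)
  out <- fm[, c("case_id", intersect("label", names(fm)), bins)]
  for (b in bins) out[[b]] <- format_full(out[[b]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  fm <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  bins <- feature_bin_names()
  if (!all(bins %in% names(fm)))
    stop("feature matrix file is missing bin columns", call. = FALSE)
  for (b in bins) fm[[b]] <- as.numeric(fm[[b]])
  class(fm) <- c("feature_matrix", "data.frame")
  fm
}

#' Persist and restore a fitted risk model
#'
#' The archive is a versioned RDS container holding the preprocessing
#' parameters, the fitted kernel machine, its hyperparameters (cost and
#' sigma) and training metadata; OCRI computed before and after a
#' round-trip agrees exactly. Loading a file written with a different
#' format version, or a truncated file, fails with an explicit error and
#' never yields a partial model.
#'
#' @param model an `ocri_model` ([tune_and_train_svm()] output).
#' @param path file path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ocri_model"))
  saveRDS(list(format = "edtar_model",
               version = MODEL_FORMAT_VERSION, model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read model archive '", path, "': ",
         conditionMessage(e), call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "edtar_model"))
    stop("'", path, "' is not an edtar model archive", call. = FALSE)
  if (!identical(obj$version, MODEL_FORMAT_VERSION))
    stop("model archive version ", obj$version,
         " is incompatible with this package (expected ",
         MODEL_FORMAT_VERSION, ")", call. = FALSE)
  obj$model
}
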