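# Packaged study data (72 micropollutants with experimental and reference
# ANN-predicted rejections, fixed train/test/validation labels) and dataset
# assembly / CSV persistence.

#' Load the packaged 72-compound rejection dataset
#'
#' Returns the study's compound table: name, abbreviation, SMILES,
#' experimental rejection (percent), the reference ANN-predicted rejection,
#' train/test/validation label, and a censoring flag for the two rejections
#' reported as ">96" (stored as 96). The table is validated on load (72
#' rows, split sizes 50/11/11, value ranges, censored ids).
#'
#' @return data frame of class `ro_compounds` with columns `id`, `name`,
#'   `abbrev`, `smiles`, `rejection_ann`, `rejection_exp`, `censored`,
#'   `split`.
#' @export
load_fixture <- function() {
  path <- system.file("extdata", "ro_rejection_compounds.csv", package = "roqsar")
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("id", "name", "abbrev", "smiles", "rejection_ann",
              "rejection_exp", "censored", "split")
  if (!all(needed %in% names(rec))) stop("fixture file corrupted: missing columns")
  if (nrow(rec) != 72L || !identical(rec$id, 1:72)) {
    stop("fixture file corrupted: expected 72 sequential compound records")
  }
  counts <- table(factor(rec$split, levels = c("training", "test", "validation")))
  if (!identical(as.integer(counts), c(50L, 11L, 11L))) {
    stop("fixture file corrupted: split sizes must be 50/11/11")
  }
  if (!identical(which(rec$censored), c(47L, 63L))) {
    stop("fixture file corrupted: censored flags must mark ids 47 and 63")
  }
  if (any(rec$rejection_exp < 0 | rec$rejection_exp > 100) ||
      any(rec$rejection_ann < 0 | rec$rejection_ann > 100)) {
    stop("fixture file corrupted: rejections outside [0, 100]")
  }
  class(rec) <- c("ro_compounds", "data.frame")
  rec
}

#' Study metadata for the packaged dataset
#'
#' Operating constants of the filtration campaign (mass transfer
#' coefficient, concentration polarization coefficient, net transmembrane
#' pressure); metadata only, unused by any model.
#'
#' @return named list.
#' @export
load_study_meta <- function() {
  yaml::read_yaml(system.file("extdata", "ro_study_meta.yaml", package = "roqsar"))
}

#' Assemble a QSAR dataset from compound records and a descriptor table
#'
#' Aligns descriptor rows to compound records by compound name, picks the
#' response column, and bundles the design matrix, response, and split
#' labels. Censored responses enter as their numeric surrogate (96) with a
#' message.
#'
#' @param records an `ro_compounds` data frame (or compatible: needs `name`,
#'   `split`, and the response columns).
#' @param descriptors data frame from [descriptor_table()]: `compound` column
#'   plus numeric descriptor columns.
#' @param response `"experimental"` (measured rejections) or `"ann_reference"`
#'   (the packaged reference ANN predictions).
#' @return an object of class `ro_qsar_dataset`: list with `X` (numeric
#'   matrix, rownames = compound names), `y`, `splits` (factor with levels
#'   training/test/validation), `censored`, `meta`.
#' @export
assemble <- function(records, descriptors,
                     response = c("experimental", "ann_reference")) {
  response <- match.arg(response)
  stopifnot(is.data.frame(records), is.data.frame(descriptors))
  missing <- setdiff(records$name, descriptors$compound)
  if (length(missing)) {
    stop("descriptor table is missing compound(s): ", paste(missing, collapse = ", "))
  }
  idx <- match(records$name, descriptors$compound)
  desc_cols <- setdiff(names(descriptors), "compound")
  X <- as.matrix(descriptors[idx, desc_cols, drop = FALSE])
  rownames(X) <- records$name
  if (anyNA(X)) stop("descriptor table contains missing cells after alignment")
  y <- switch(response,
              experimental = records$rejection_exp,
              ann_reference = records$rejection_ann)
  censored <- if ("censored" %in% names(records)) records$censored else rep(FALSE, nrow(records))
  if (any(censored)) {
    message(sum(censored), " censored response value(s) entered as their numeric surrogate")
  }
  meta <- tryCatch(load_study_meta(), error = function(e) list())
  structure(list(X = X, y = y,
                 splits = factor(records$split, levels = c("training", "test", "validation")),
                 censored = censored, response = response, meta = meta),
            class = "ro_qsar_dataset")
}

#' @export
print.ro_qsar_dataset <- function(x, ...) {
  cat("<ro_qsar_dataset> ", nrow(x$X), " compounds x ", ncol(x$X),
      " descriptors; response: ", x$response, "\n", sep = "")
  print(table(x$splits))
  invisible(x)
}

#' Subset a QSAR dataset by split
#'
#' @param dataset an `ro_qsar_dataset`.
#' @param split one of `"training"`, `"test"`, `"validation"`.
#' @return the subsetted `ro_qsar_dataset`.
#' @export
dataset_split <- function(dataset, split = c("training", "test", "validation")) {
  split <- match.arg(split)
  keep <- dataset$splits == split
  out <- dataset
  out$X <- dataset$X[keep, , drop = FALSE]
  out$y <- dataset$y[keep]
  out$splits <- dataset$splits[keep]
  out$censored <- dataset$censored[keep]
  out
}

#' Write / read a QSAR dataset as one CSV
#'
#' Lossless round trip at full precision: descriptor columns plus dedicated
#' `response`, `split` and `censored` columns. Unknown extra columns present
#' in a read file are preserved untouched as an attribute.
#'
#' @param dataset an `ro_qsar_dataset`.
#' @param path file path.
#' @export
write_dataset_csv <- function(dataset, path) {
  df <- data.frame(compound = rownames(dataset$X),
                   as.data.frame(dataset$X, check.names = FALSE),
                   response = dataset$y,
                   split = as.character(dataset$splits),
                   censored = dataset$censored,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("compound", "response", "split", "censored")
  absent <- setdiff(needed, names(df))
  if (length(absent)) {
    stop("dataset CSV is missing required column(s): ", paste(absent, collapse = ", "))
  }
  desc_cols <- setdiff(names(df), needed)
  num <- vapply(df[desc_cols], is.numeric, logical(1))
  extra <- desc_cols[!num]
  desc_cols <- desc_cols[num]
  X <- as.matrix(df[, desc_cols, drop = FALSE])
  rownames(X) <- df$compound
  out <- structure(list(X = X, y = df$response,
                        splits = factor(df$split, levels = c("training", "test", "validation")),
                        censored = as.logical(df$censored),
                        response = "file", meta = list()),
                   class = "ro_qsar_dataset")
  if (length(extra)) attr(out, "extra_columns") <- df[extra]
  out
}
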