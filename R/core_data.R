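#' Convert an IC50 in nanomolar to pIC50
#'
#' pIC50 is the negative base-10 logarithm of the molar IC50.  For an IC50
#' expressed in nanomolar units this is `-log10(ic50 * 1e-9) = 9 - log10(ic50)`.
#'
#' @param ic50_nM Positive numeric vector of IC50 values in nanomolar.
#' @return Numeric vector of pIC50 values (unitless).
#' @examples
#' pic50_from_ic50(1)     # 9
#' pic50_from_ic50(1000)  # 6
#' @export
pic50_from_ic50 <- function(ic50_nM) {
  if (!is.numeric(ic50_nM)) {
    stop("ic50_nM must be numeric", call. = FALSE)
  }
  bad <- !is.finite(ic50_nM) | ic50_nM <= 0
  if (any(bad)) {
    stop("ic50_nM must be positive and finite; offending value(s): ",
         paste(utils::head(ic50_nM[bad], 5L), collapse = ", "),
         call. = FALSE)
  }
  9 - log10(ic50_nM)
}

#' Convert pIC50 back to IC50 in nanomolar
#'
#' Inverse of [pic50_from_ic50()].
#'
#' @param pic50 Numeric vector of pIC50 values.
#' @return IC50 values in nanomolar.
#' @export
ic50_from_pic50 <- function(pic50) {
  if (!is.numeric(pic50) || any(!is.finite(pic50))) {
    stop("pic50 must be finite numeric", call. = FALSE)
  }
  10^(9 - pic50)
}

#' Construct a QSAR dataset
#'
#' Bundles compound identifiers, a numeric descriptor matrix, and activities
#' (pIC50 and/or IC50 in nM) into a validated container.  When both activity
#' columns are supplied they must agree through the nanomolar pIC50
#' conversion.
#'
#' @param ids Character vector of unique compound identifiers.
#' @param descriptors Numeric matrix or data frame (one row per compound)
#'   with unique column names; no missing values allowed.
#' @param pic50 Optional numeric vector of pIC50 activities.
#' @param ic50_nM Optional positive numeric vector of IC50 values (nM).
#' @param partition Optional character vector (`"train"`/`"test"`), one entry
#'   per compound; usually filled later by [split_dataset()].
#' @return An object of class `qsar_dataset` with elements `ids`,
#'   `descriptors` (matrix), `descriptor_names`, `pic50`, `ic50_nM`,
#'   `partition`.
#' @export
qsar_dataset <- function(ids, descriptors, pic50 = NULL, ic50_nM = NULL,
                         partition = NULL) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate compound ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  descriptors <- as.matrix(descriptors)
  if (!is.numeric(descriptors)) {
    stop("descriptors must be numeric", call. = FALSE)
  }
  if (nrow(descriptors) != length(ids)) {
    stop("descriptor rows (", nrow(descriptors), ") != number of ids (",
         length(ids), ")", call. = FALSE)
  }
  if (is.null(colnames(descriptors)) || anyDuplicated(colnames(descriptors))) {
    stop("descriptors must have unique column names", call. = FALSE)
  }
  if (anyNA(descriptors) || any(!is.finite(descriptors))) {
    stop("descriptors contain missing or non-finite values; not imputed",
         call. = FALSE)
  }
  rownames(descriptors) <- ids
  if (!is.null(ic50_nM)) {
    if (length(ic50_nM) != length(ids)) stop("ic50_nM length mismatch", call. = FALSE)
    implied <- pic50_from_ic50(ic50_nM)
    if (is.null(pic50)) {
      pic50 <- implied
    } else if (any(abs(pic50 - implied) > 1e-9)) {
      stop("pic50 and ic50_nM disagree beyond 1e-9 through 9 - log10(ic50_nM)",
           call. = FALSE)
    }
  }
  if (!is.null(pic50)) {
    if (length(pic50) != length(ids) || any(!is.finite(pic50))) {
      stop("pic50 must be finite with one value per compound", call. = FALSE)
    }
    pic50 <- as.numeric(pic50)
  }
  if (!is.null(partition)) {
    partition <- check_partition(partition, ids)
  }
  structure(
    list(ids = ids, descriptors = descriptors,
         descriptor_names = colnames(descriptors),
         pic50 = pic50, ic50_nM = ic50_nM, partition = partition),
    class = "qsar_dataset")
}

check_partition <- function(partition, ids) {
  partition <- as.character(partition)
  if (length(partition) != length(ids)) {
    stop("partition must cover every compound", call. = FALSE)
  }
  if (!all(partition %in% c("train", "test"))) {
    stop("partition entries must be 'train' or 'test'", call. = FALSE)
  }
  names(partition) <- ids
  partition
}

#' @export
print.qsar_dataset <- function(x, ...) {
  cat("qsar_dataset:", length(x$ids), "compounds,",
      length(x$descriptor_names), "descriptors\n")
  if (!is.null(x$partition)) {
    cat("  partition:", sum(x$partition == "train"), "train /",
        sum(x$partition == "test"), "test\n")
  }
  if (!is.null(x$pic50)) {
    cat("  pIC50 range:", format(range(x$pic50), digits = 4), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.qsar_dataset <- function(x, ...) {
  df <- data.frame(id = x$ids, stringsAsFactors = FALSE)
  if (!is.null(x$ic50_nM)) df$ic50_nM <- x$ic50_nM
  if (!is.null(x$pic50)) df$pic50 <- x$pic50
  cbind(df, as.data.frame(x$descriptors, row.names = NULL))
}

#' Assign a train/test partition to a QSAR dataset
#'
#' Either the test compounds are named explicitly (`test_ids`, honoured
#' verbatim) or `n_test` of them are drawn uniformly without replacement
#' under `seed`.  The same seed always yields the same partition.
#'
#' @param dataset A [qsar_dataset()].
#' @param test_ids Optional character vector of compound ids for the test set.
#' @param n_test Optional number of test compounds (used with `seed`).
#' @param seed Integer seed for the random draw (required with `n_test > 0`).
#' @return The dataset with its `partition` element filled.
#' @export
split_dataset <- function(dataset, test_ids = NULL, n_test = NULL, seed = NULL) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  ids <- dataset$ids
  if (!is.null(test_ids)) {
    test_ids <- as.character(test_ids)
    if (anyDuplicated(test_ids)) {
      stop("duplicate test_ids", call. = FALSE)
    }
    unknown <- setdiff(test_ids, ids)
    if (length(unknown)) {
      stop("unknown test_ids: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (length(test_ids) >= length(ids)) {
      stop("test set must be smaller than the dataset", call. = FALSE)
    }
  } else {
    if (is.null(n_test)) stop("supply test_ids or n_test", call. = FALSE)
    n_test <- as.integer(n_test)
    if (n_test < 0 || n_test >= length(ids)) {
      stop("n_test must satisfy 0 <= n_test < n compounds", call. = FALSE)
    }
    if (n_test == 0L) {
      test_ids <- character(0)
    } else {
      if (is.null(seed)) stop("seed required for a random split", call. = FALSE)
      rng <- local_rng(seed)
      test_ids <- sample(ids, n_test)
      rng()
    }
  }
  partition <- ifelse(ids %in% test_ids, "test", "train")
  dataset$partition <- check_partition(partition, ids)
  dataset
}

# Seed the session RNG and return a restorer; keeps generators pure.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(as.integer(seed))
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
    invisible(NULL)
  }
}

#' Extract the train or test portion of a dataset
#'
#' @param dataset A partitioned [qsar_dataset()].
#' @param set `"train"` or `"test"`.
#' @return A list with `X` (descriptor matrix), `y` (pIC50), `ids`.
#' @export
dataset_subset <- function(dataset, set = c("train", "test")) {
  set <- match.arg(set)
  stopifnot(inherits(dataset, "qsar_dataset"))
  if (is.null(dataset$partition)) stop("dataset has no partition", call. = FALSE)
  keep <- dataset$partition == set
  list(X = dataset$descriptors[keep, , drop = FALSE],
       y = if (is.null(dataset$pic50)) NULL else dataset$pic50[keep],
       ids = dataset$ids[keep])
}

#' Read a QSAR dataset from CSV
#'
#' Expects a header row, an `id` column, at least one activity column
#' (`pic50` and/or `ic50_nM`), and numeric descriptor columns (all remaining
#' columns unless named explicitly).  Missing cells are rejected, not imputed.
#'
#' @param path CSV file path.
#' @param id_col,pic50_col,ic50_col,partition_col Column names.
#' @param descriptor_cols Optional character vector naming descriptor columns.
#' @return A [qsar_dataset()].
#' @export
read_qsar_csv <- function(path, id_col = "id", pic50_col = "pic50",
                          ic50_col = "ic50_nM", partition_col = "partition",
                          descriptor_cols = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!id_col %in% names(df)) {
    stop("missing required column '", id_col, "' in ", path, call. = FALSE)
  }
  have_pic50 <- pic50_col %in% names(df)
  have_ic50 <- ic50_col %in% names(df)
  if (!have_pic50 && !have_ic50) {
    stop("missing activity column: need '", pic50_col, "' or '", ic50_col,
         "'", call. = FALSE)
  }
  reserved <- c(id_col, pic50_col, ic50_col, partition_col)
  if (is.null(descriptor_cols)) {
    descriptor_cols <- setdiff(names(df), reserved)
  } else {
    missing_cols <- setdiff(descriptor_cols, names(df))
    if (length(missing_cols)) {
      stop("missing descriptor column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
  }
  if (!length(descriptor_cols)) stop("no descriptor columns found", call. = FALSE)
  desc <- df[descriptor_cols]
  non_num <- names(desc)[!vapply(desc, is.numeric, logical(1))]
  if (length(non_num)) {
    stop("non-numeric descriptor column(s): ",
         paste(non_num, collapse = ", "), call. = FALSE)
  }
  if (anyNA(desc)) {
    stop("missing descriptor cells in ", path, "; not imputed", call. = FALSE)
  }
  qsar_dataset(
    ids = df[[id_col]],
    descriptors = as.matrix(desc),
    pic50 = if (have_pic50) df[[pic50_col]] else NULL,
    ic50_nM = if (have_ic50) df[[ic50_col]] else NULL,
    partition = if (partition_col %in% names(df)) df[[partition_col]] else NULL)
}

#' Write a QSAR dataset to CSV
#'
#' Inverse of [read_qsar_csv()]: `read_qsar_csv(write_qsar_csv(x, f))`
#' restores all values at full precision.
#'
#' @param dataset A [qsar_dataset()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_qsar_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "qsar_dataset"))
  df <- as.data.frame(dataset)
  if (!is.null(dataset$partition)) df$partition <- unname(dataset$partition)
  write_csv_full(df, path)
  invisible(path)
}

# full-precision CSV writer shared by all table exporters
write_csv_full <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE,
                                                scientific = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Label compounds as active by a pIC50 threshold
#'
#' A compound is active iff its pIC50 strictly exceeds the threshold
#' (default 6.5), so a compound at exactly the threshold is inactive.
#'
#' @param pic50 Numeric vector of pIC50 values.
#' @param threshold Activity threshold in pIC50 units.
#' @return Logical vector.
#' @export
label_actives <- function(pic50, threshold = 6.5) {
  if (any(!is.finite(pic50))) stop("pic50 must be finite", call. = FALSE)
  pic50 > threshold
}
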