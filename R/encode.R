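#' Encode a subject table as a covariate design matrix
#'
#' Builds the N x p covariate matrix X entering the linear model
#' `y = X beta + T gamma + e`: an all-ones intercept column, one column per
#' continuous covariate (units as supplied), and one 0/1 indicator column per
#' observed level of each categorical covariate. Full-dummy coding is used —
#' no reference level is dropped — so the encoding matches the baseline tables
#' column for column. The resulting indicator sets are linearly dependent with
#' the intercept; that is permitted, because the Ds criterion only involves
#' the column space of X. A rank-revealing SVD supplies an orthonormal basis
#' of that space, making the criterion well-defined for any encoding.
#'
#' @param data Data frame with one row per subject. Must contain `id_col` with
#'   unique subject identifiers and every declared covariate column, with no
#'   missing values.
#' @param categorical Character vector of categorical covariate column names
#'   (may be empty). Levels are compared as exact strings and taken in sorted
#'   order (or factor-level order).
#' @param continuous Character vector of continuous covariate column names
#'   (may be empty); columns must be numeric.
#' @param id_col Name of the subject identifier column. Default `"subject_id"`.
#' @param rank_tol Singular-value threshold for rank detection. Default
#'   `max(singular value) * max(N, p) * .Machine$double.eps`.
#'
#' @return An object of class `covariate_matrix`: a list with the design
#'   matrix `X`, `column_names`, the N x r orthonormal `basis` of the column
#'   space, `rank`, `rank_tol`, dimensions `n` and `p`, the `subject_id`
#'   vector, and `notes` (character vector of warning records, e.g. constant
#'   continuous columns aliased with the intercept).
#'
#' @examples
#' subjects <- tibble::tibble(
#'   subject_id = paste0("S", 1:6),
#'   sex = rep(c("F", "M"), 3),
#'   age = c(31, 45, 28, 52, 39, 47)
#' )
#' cm <- encode_covariates(subjects, categorical = "sex", continuous = "age")
#' cm$rank  # 3: intercept + sex (1 free dummy) + age
#' @export
encode_covariates <- function(data, categorical = character(), continuous = character(),
                              id_col = "subject_id", rank_tol = NULL) {
  data <- validate_subjects(data, categorical = categorical, continuous = continuous,
                            id_col = id_col)
  n <- nrow(data)
  cols <- list(`(Intercept)` = rep(1, n))
  notes <- character()
  for (v in continuous) {
    x <- as.numeric(data[[v]])
    if (length(unique(x)) == 1L) {
      msg <- sprintf("continuous covariate '%s' is constant; it is aliased with the intercept", v)
      notes <- c(notes, msg)
      warn(msg)
    }
    cols[[v]] <- x
  }
  for (v in categorical) {
    x <- data[[v]]
    lev <- if (is.factor(x)) levels(droplevels(x)) else sort(unique(as.character(x)))
    x <- as.character(x)
    for (l in lev) {
      cols[[paste0(v, "=", l)]] <- as.numeric(x == l)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  sv <- svd(X)
  if (is.null(rank_tol)) {
    rank_tol <- max(sv$d) * max(dim(X)) * .Machine$double.eps
  }
  r <- sum(sv$d > rank_tol)
  structure(
    list(
      X = X,
      column_names = colnames(X),
      basis = sv$u[, seq_len(r), drop = FALSE],
      rank = r,
      rank_tol = rank_tol,
      n = n,
      p = ncol(X),
      subject_id = as.character(data[[id_col]]),
      notes = notes
    ),
    class = "covariate_matrix"
  )
}

#' @export
print.covariate_matrix <- function(x, ...) {
  cat(sprintf("<covariate_matrix> N = %d, p = %d, rank = %d\n", x$n, x$p, x$rank))
  cat("  columns:", paste(head(x$column_names, 8), collapse = ", "),
      if (x$p > 8) sprintf("... (%d more)", x$p - 8) else "", "\n")
  if (length(x$notes)) cat("  notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# Shared validation for in-memory tables and CSV ingestion. Returns the data
# (with the id column as character) or aborts with row/column diagnostics.
validate_subjects <- function(data, categorical = character(), continuous = character(),
                              id_col = "subject_id") {
  if (!is.data.frame(data)) abort("subject table must be a data frame")
  missing_cols <- setdiff(c(id_col, categorical, continuous), names(data))
  if (length(missing_cols)) {
    stopf("missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (nrow(data) < 2) abort("a subject table needs at least 2 rows")
  ids <- as.character(data[[id_col]])
  if (anyNA(ids) || anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stopf("subject identifiers must be unique and non-missing (offending: %s)",
          paste(head(c(dup, if (anyNA(ids)) "<NA>"), 5), collapse = ", "))
  }
  for (v in c(categorical, continuous)) {
    bad <- which(is.na(data[[v]]))
    if (length(bad)) {
      stopf("missing value in column '%s' at row %d (subject %s)", v, bad[1], ids[bad[1]])
    }
  }
  for (v in continuous) {
    if (!is.numeric(data[[v]])) {
      stopf("continuous covariate '%s' is not numeric; declare it categorical or fix the data", v)
    }
  }
  data[[id_col]] <- ids
  data
}
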