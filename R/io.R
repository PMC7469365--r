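#' Read and validate a subject covariate table from CSV
#'
#' Reads an RFC-4180 CSV with a header row and validates it as a subject
#' table: unique identifiers, at least two rows, no missing values in any
#' declared covariate column, numeric continuous columns. Row order is
#' preserved and defines the subject index.
#'
#' @param path CSV file path.
#' @param categorical,continuous Declared covariate column names.
#' @param id_col Subject identifier column (default `"subject_id"`).
#' @return A validated tibble.
#' @export
read_subject_table <- function(path, categorical = character(), continuous = character(),
                               id_col = "subject_id") {
  if (!file.exists(path)) stopf("no such file: %s", path)
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_subjects(data, categorical = categorical, continuous = continuous,
                    id_col = id_col)
}

#' Write an allocation table to CSV with a metadata sidecar
#'
#' Writes one row per subject with columns `subject_id,arm` (arm labels from
#' the design), plus a JSON sidecar at `<path>.meta.json` recording the seed,
#' the Ds-efficiency and any settings — enough to reproduce the allocation.
#'
#' @param allocation A `ds_optim` object, or an integer allocation vector (in
#'   which case `data`'s `id_col` supplies the identifiers).
#' @param path Output CSV path.
#' @param data Subject table (required when `allocation` is a bare vector).
#' @param spec A [design_spec()] (required when `allocation` is a bare
#'   vector).
#' @param X Optional [encode_covariates()] result; when given, the sidecar
#'   records the allocation's Ds-efficiency.
#' @param id_col Identifier column of `data`.
#' @param settings Named list merged into the sidecar.
#' @return `path`, invisibly.
#' @export
write_allocation <- function(allocation, path, data = NULL, spec = NULL, X = NULL,
                             id_col = "subject_id", settings = list()) {
  if (inherits(allocation, "ds_optim")) {
    out <- tidy(allocation)
    spec <- allocation$spec
    arm_of <- allocation$arm_of
    meta <- list(
      seed = allocation$seed,
      ds_efficiency = allocation$evaluation$ds_efficiency,
      n_restarts = allocation$n_restarts_run
    )
  } else {
    if (is.null(data) || is.null(spec)) {
      abort("a bare allocation vector needs `data` and `spec`")
    }
    arm_of <- check_allocation(allocation, spec)
    out <- tibble::tibble(
      subject_id = as.character(data[[id_col]]),
      arm = spec$arm_labels[arm_of]
    )
    meta <- list()
  }
  if (!is.null(X)) {
    meta$ds_efficiency <- ds_from_arms(X$basis, arm_of, spec)$ds_efficiency
  }
  readr::write_csv(out, path)
  meta$arm_sizes <- spec$arm_sizes
  meta$arm_labels <- spec$arm_labels
  meta <- c(meta, settings)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Per-arm covariate balance report
#'
#' Summarizes how well an allocation balances the covariates over the arms,
#' in the style of a baseline-characteristics table: an arm-by-level count
#' table for every categorical covariate, per-arm mean and sample (n-1)
#' standard deviation for every continuous covariate, and the allocation's
#' Ds-efficiency.
#'
#' @param data Subject table.
#' @param arm_of Integer allocation vector (or a `ds_optim` object).
#' @param spec A [design_spec()] (taken from `arm_of` if it is a `ds_optim`).
#' @param categorical,continuous Covariate column names to report on.
#' @param X Optional pre-computed [encode_covariates()] result; by default the
#'   declared covariates are encoded on the fly for the efficiency figure.
#' @param id_col Identifier column.
#' @return An object of class `balance_report`: list with
#'   `categorical_tables` (named list of level-by-arm count tibbles),
#'   `continuous_tables` (tibble: covariate, arm, n, mean, sd), `evaluation`
#'   (a `ds_eval`) and `spec`. [tidy()] returns one long tibble.
#' @examples
#' toy <- generate_toy(seed = 2, N = 12, t = 3, n_categorical_levels = 2)
#' rep <- balance_report(toy$table, initial_allocation(toy$spec, seed = 1),
#'                       toy$spec, categorical = "c1", continuous = "x1")
#' rep
#' @export
balance_report <- function(data, arm_of, spec = NULL,
                           categorical = character(), continuous = character(),
                           X = NULL, id_col = "subject_id") {
  if (inherits(arm_of, "ds_optim")) {
    if (is.null(spec)) spec <- arm_of$spec
    arm_of <- arm_of$arm_of
  }
  if (is.null(spec)) abort("spec is required when arm_of is a bare vector")
  arm_of <- check_allocation(arm_of, spec)
  data <- validate_subjects(data, categorical = categorical, continuous = continuous,
                            id_col = id_col)
  if (is.null(X)) {
    X <- encode_covariates(data, categorical = categorical, continuous = continuous,
                           id_col = id_col)
  }
  arm <- factor(spec$arm_labels[arm_of], levels = spec$arm_labels)
  categorical_tables <- lapply(
    setNames(categorical, categorical),
    function(v) {
      tibble::tibble(level = as.character(data[[v]]), arm = arm) |>
        dplyr::count(.data$level, .data$arm, .drop = FALSE) |>
        tidyr::pivot_wider(names_from = "arm", values_from = "n", values_fill = 0L)
    }
  )
  continuous_tables <- if (length(continuous)) {
    purrr::map_dfr(setNames(continuous, continuous), function(v) {
      tibble::tibble(arm = arm, value = data[[v]]) |>
        dplyr::group_by(.data$arm) |>
        dplyr::summarise(
          n = dplyr::n(),
          mean = mean(.data$value),
          sd = sd(.data$value),
          .groups = "drop"
        )
    }, .id = "covariate")
  } else {
    tibble::tibble(covariate = character(), arm = character(),
                   n = integer(), mean = numeric(), sd = numeric())
  }
  structure(
    list(
      categorical_tables = categorical_tables,
      continuous_tables = continuous_tables,
      evaluation = ds_from_arms(X$basis, arm_of, spec),
      spec = spec
    ),
    class = "balance_report"
  )
}

#' @export
print.balance_report <- function(x, ...) {
  cat(sprintf("<balance_report> Ds-efficiency %.4f\n", x$evaluation$ds_efficiency))
  for (v in names(x$categorical_tables)) {
    cat(sprintf("\n%s (counts by arm):\n", v))
    print(as.data.frame(x$categorical_tables[[v]]), row.names = FALSE)
  }
  if (nrow(x$continuous_tables)) {
    cat("\ncontinuous covariates (per-arm mean and sd):\n")
    print(as.data.frame(x$continuous_tables), row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Tidy a balance report into one long tibble
#'
#' @param x A `balance_report` object.
#' @param ... Unused.
#' @return A tibble with columns `covariate`, `level` (NA for continuous),
#'   `arm`, `n`, `mean`, `sd` (NA for categorical).
#' @method tidy balance_report
#' @export
tidy.balance_report <- function(x, ...) {
  cat_long <- purrr::map_dfr(
    setNames(names(x$categorical_tables), names(x$categorical_tables)),
    function(v) {
      x$categorical_tables[[v]] |>
        tidyr::pivot_longer(-"level", names_to = "arm", values_to = "n")
    },
    .id = "covariate"
  )
  if (nrow(cat_long)) {
    cat_long$mean <- NA_real_
    cat_long$sd <- NA_real_
  } else {
    cat_long <- tibble::tibble(covariate = character(), level = character(),
                               arm = character(), n = integer(),
                               mean = numeric(), sd = numeric())
  }
  cont_long <- x$continuous_tables
  if (nrow(cont_long)) cont_long$level <- NA_character_
  dplyr::bind_rows(cat_long, cont_long) |>
    dplyr::select("covariate", "level", "arm", "n", "mean", "sd")
}

#' Per-arm means of continuous covariates, plotted
#'
#' @param object A `balance_report` object.
#' @param ... Unused.
#' @return A ggplot object: per-arm mean with +/- one sd bars, one facet per
#'   continuous covariate.
#' @method autoplot balance_report
#' @export
autoplot.balance_report <- function(object, ...) {
  d <- object$continuous_tables
  if (!nrow(d)) abort("no continuous covariates in this report")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$arm, y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2
    ) +
    ggplot2::facet_wrap(~covariate, scales = "free_y") +
    ggplot2::labs(x = "arm", y = "mean (+/- sd)")
}
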