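# File formats: response-table and schedule CSV, JSON schedule export,
# YAML run configuration. CSV dialect: comma-separated, header, UTF-8,
# "." decimal, correctness 0/1, categorical fields lower_snake_case.

#' Read a response table from CSV
#'
#' @param path CSV file path.
#' @param col_map Optional named character vector mapping the canonical column
#'   names to the names used in the file (e.g.
#'   `c(participant_id = "subject")`), for re-analysing externally deposited
#'   data whose layout differs from the package dialect.
#' @return A validated response table.
#' @export
read_response_table <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (!col_map[[canon]] %in% names(df)) {
        stop("mapped column not in file: ", col_map[[canon]], call. = FALSE)
      }
      names(df)[names(df) == col_map[[canon]]] <- canon
    }
  }
  validate_response_table(df)
}

#' Write a response table to CSV
#'
#' @param rt A response table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_response_table <- function(rt, path) {
  rt <- validate_response_table(rt)
  readr::write_csv(rt[, RT_COLUMNS], path, progress = FALSE)
  invisible(path)
}

#' Write a schedule (encoding or test) to CSV
#'
#' @param schedule An `encoding_schedule` or `test_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule_csv <- function(schedule, path) {
  readr::write_csv(tibble::as_tibble(schedule), path, progress = FALSE)
  invisible(path)
}

#' Read a schedule written by [write_schedule_csv()]
#'
#' @param path CSV file path.
#' @return A tibble; classed as encoding or test schedule based on columns.
#' @export
read_schedule_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cls <- if ("presented_categories" %in% names(df)) {
    "encoding_schedule"
  } else if ("choice_ids" %in% names(df)) {
    "test_schedule"
  } else {
    stop("file is not a schedule CSV", call. = FALSE)
  }
  class(df) <- c(cls, class(df))
  df
}

#' Export a schedule as JSON
#'
#' @param schedule A schedule tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(tibble::as_tibble(schedule), path,
    dataframe = "rows", auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' Run configuration
#'
#' Bundles a master seed, model-parameter overrides, a generator spec, the
#' schedule parameters and the analysis parameters; round-trips losslessly
#' through YAML.
#'
#' @param seed Master seed.
#' @param params A [model_params()] object (or overrides as a list).
#' @param generator A [behavior_spec()] or NULL.
#' @param n_neutral,n_negative Event counts for schedule construction.
#' @param mode Encoding mode.
#' @param P_G,n_choices Analysis parameters.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1, params = model_params(), generator = NULL,
                       n_neutral = 36, n_negative = 36, mode = "pairs",
                       P_G = 1, n_choices = 6) {
  structure(
    list(
      seed = seed, params = params, generator = generator,
      n_neutral = n_neutral, n_negative = n_negative, mode = mode,
      P_G = P_G, n_choices = n_choices
    ),
    class = "run_config"
  )
}

#' Write a run configuration to YAML
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$params <- unclass(x$params)
  if (!is.null(x$generator)) {
    x$generator <- unclass(x$generator)
    x$generator$cells <- as.data.frame(x$generator$cells)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  params <- do.call(model_params, x$params %||% list())
  generator <- NULL
  if (!is.null(x$generator)) {
    gx <- x$generator
    cells <- if (!is.null(gx$cells)) tibble::as_tibble(gx$cells) else NULL
    generator <- behavior_spec(
      n_participants = gx$n_participants %||% 1,
      n_events = gx$n_events %||% 18,
      regime = gx$regime %||% "independent",
      marginal = gx$marginal %||% 0.8,
      q = gx$q %||% 0.5,
      shape1 = gx$shape1 %||% 2, shape2 = gx$shape2 %||% 2,
      g = gx$g %||% 1 / 6,
      cells = cells,
      seed = gx$seed
    )
  }
  run_config(
    seed = x$seed %||% 1, params = params, generator = generator,
    n_neutral = x$n_neutral %||% 36, n_negative = x$n_negative %||% 36,
    mode = x$mode %||% "pairs",
    P_G = x$P_G %||% 1, n_choices = x$n_choices %||% 6
  )
}
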