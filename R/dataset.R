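DATASET_COLUMNS <- c("index", "r_octanoic", "r_dep", "r_octanol", "r_pentanol",
                     "mean_speed_mm_s", "mean_droplet_count", "temperature_C",
                     "goal_x", "goal_y", "seed", "duration_s")

#' Create an (empty) exploration dataset
#'
#' The exploration dataset is the curiosity algorithm's only memory: an
#' append-only log of experiment records (formulation, observation, optional
#' goal, metadata), with contiguous indices starting at 0.
#'
#' @param metadata named list of run metadata (algorithm name, budget, bounds,
#'   seed, ...) stored in the JSON sidecar on save
#' @return an object of class `exploration_dataset`
#' @export
exploration_dataset <- function(metadata = list()) {
  records <- as.data.frame(
    setNames(rep(list(numeric(0)), length(DATASET_COLUMNS)), DATASET_COLUMNS))
  structure(list(records = records, metadata = metadata),
            class = "exploration_dataset")
}

#' Append one experiment record to a dataset
#'
#' @param ds an [exploration_dataset()]
#' @param formulation an [oil_formulation()]
#' @param observation a [behavior_observation()]
#' @param temperature_C experiment temperature in degrees Celsius, or `NA`
#' @param goal the goal-space 2-vector that selected this experiment, or
#'   `NULL` for random / bootstrap picks
#' @param seed integer seed used for the experiment
#' @param duration_s experiment duration in seconds
#' @return the dataset with one more record (index `n_records - 1`)
#' @export
add_record <- function(ds, formulation, observation, temperature_C = NA_real_,
                       goal = NULL, seed = NA_integer_, duration_s = 90) {
  stopifnot(inherits(ds, "exploration_dataset"))
  formulation <- oil_formulation(formulation)
  if (!is.null(goal)) {
    stopifnot(length(goal) == 2L, all(goal >= 0), all(goal <= 1))
  }
  row <- data.frame(
    index = as.numeric(nrow(ds$records)),
    r_octanoic = formulation[[1L]], r_dep = formulation[[2L]],
    r_octanol = formulation[[3L]], r_pentanol = formulation[[4L]],
    mean_speed_mm_s = observation[[1L]],
    mean_droplet_count = observation[[2L]],
    temperature_C = as.numeric(temperature_C),
    goal_x = if (is.null(goal)) NA_real_ else goal[[1L]],
    goal_y = if (is.null(goal)) NA_real_ else goal[[2L]],
    seed = as.numeric(seed), duration_s = as.numeric(duration_s))
  ds$records <- rbind(ds$records, row)
  ds
}

#' Number of records in a dataset
#' @param ds an [exploration_dataset()]
#' @return integer record count
#' @export
n_records <- function(ds) nrow(ds$records)

#' @export
print.exploration_dataset <- function(x, ...) {
  cat("<exploration_dataset> ", nrow(x$records), " records",
      if (!is.null(x$metadata$algorithm))
        paste0(" [", x$metadata$algorithm, "]"), "\n", sep = "")
  invisible(x)
}

# formulations as an n x 4 matrix / observations as an n x 2 matrix
dataset_formulations <- function(ds) {
  as.matrix(ds$records[, c("r_octanoic", "r_dep", "r_octanol", "r_pentanol")])
}

dataset_observations <- function(ds) {
  m <- as.matrix(ds$records[, c("mean_speed_mm_s", "mean_droplet_count")])
  colnames(m) <- c("speed", "count")
  m
}

# full-precision decimal text so that load(save(ds)) is bit-identical
fmt_full <- function(x) {
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

#' Save an exploration dataset to a CSV log with a JSON metadata sidecar
#'
#' One CSV row per experiment, written at full decimal precision so the
#' round-trip through text is lossless; run metadata goes to
#' `<path without extension>_meta.json`.
#'
#' @param ds an [exploration_dataset()]
#' @param path CSV file path
#' @return `path`, invisibly
#' @export
save_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "exploration_dataset"))
  rec <- ds$records
  out <- as.data.frame(lapply(rec, fmt_full), stringsAsFactors = FALSE)
  names(out) <- names(rec)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  meta_path <- paste0(tools::file_path_sans_ext(path), "_meta.json")
  jsonlite::write_json(ds$metadata, meta_path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Load an exploration dataset written by [save_dataset()]
#'
#' Malformed files raise a parse error naming the offending line and field;
#' formulation and observation invariants are enforced on load.
#'
#' @param path CSV file path
#' @return an [exploration_dataset()]
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), DATASET_COLUMNS)) {
    stop("parse error in ", path, ": expected columns ",
         paste(DATASET_COLUMNS, collapse = ","), call. = FALSE)
  }
  rec <- as.data.frame(lapply(raw, function(col) {
    col[col == ""] <- NA_character_
    as.numeric(col)
  }))
  names(rec) <- DATASET_COLUMNS
  ratio_cols <- c("r_octanoic", "r_dep", "r_octanol", "r_pentanol")
  for (i in seq_len(nrow(rec))) {
    line <- i + 1L  # header is line 1
    for (fld in ratio_cols) {
      v <- rec[[fld]][i]
      if (is.na(v) || v < 0) {
        stop("parse error in ", path, " line ", line, ", field ", fld,
             ": invalid ratio", call. = FALSE)
      }
    }
    if (abs(sum(rec[i, ratio_cols]) - 1) > 1e-9) {
      stop("parse error in ", path, " line ", line,
           ": ratios do not sum to 1", call. = FALSE)
    }
    for (fld in c("mean_speed_mm_s", "mean_droplet_count")) {
      v <- rec[[fld]][i]
      if (is.na(v) || v < 0) {
        stop("parse error in ", path, " line ", line, ", field ", fld,
             ": invalid observation", call. = FALSE)
      }
    }
    if (rec$index[i] != i - 1L) {
      stop("parse error in ", path, " line ", line,
           ": indices must be contiguous from 0", call. = FALSE)
    }
  }
  meta_path <- paste0(tools::file_path_sans_ext(path), "_meta.json")
  metadata <- if (file.exists(meta_path)) {
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  } else {
    list()
  }
  ds <- exploration_dataset(metadata = metadata)
  ds$records <- rec
  ds
}
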