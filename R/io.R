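# Tidy CSV interfaces.
#
# Lineage table schema (one row per lineage x frame):
#   lineage_id, time_h, length_um, fl_ch1, fl_ch2 (empty if absent),
#   division (0/1)
# Truth table schema: lineage_id, deleted (0/1), fate {restored, halted,
# none}. The condition/parameter echo is a YAML key-value file.

lineage_csv_cols <- c("lineage_id", "time_h", "length_um", "fl_ch1",
                      "fl_ch2", "division")

#' Write an experiment to tidy CSV files
#'
#' Writes `lineages.csv` (per-frame table), `truth.csv` (ground truth, when
#' present) and `condition.yaml` (condition, generator parameters and seed)
#' into `dir`.
#'
#' @param ex an `mm_experiment`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_experiment <- function(ex, dir) {
  stopifnot(inherits(ex, "mm_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  frames <- experiment_frames(ex)
  frames$division <- as.integer(frames$division)
  paths <- c(lineages = file.path(dir, "lineages.csv"),
             truth = file.path(dir, "truth.csv"),
             condition = file.path(dir, "condition.yaml"))
  data.table::fwrite(frames[, lineage_csv_cols], paths["lineages"])
  tr <- ex$truth
  data.table::fwrite(data.frame(lineage_id = tr$lineage_id,
                                deleted = as.integer(tr$deleted),
                                fate = tr$fate), paths["truth"])
  cond <- ex$condition; attributes(cond) <- list(names = names(cond))
  par <- ex$params; attributes(par) <- list(names = names(par))
  par <- par[!vapply(par, is.function, logical(1))]
  yaml::write_yaml(list(condition = cond, generator_params = par,
                        seed = ex$seed), paths["condition"])
  invisible(paths)
}

#' Read a tidy lineage CSV
#'
#' Parses and validates the per-frame lineage table: required columns,
#' numeric types, strictly increasing times within each lineage (rows are
#' sorted by lineage and time first, so shuffled files load identically),
#' positive lengths and 0/1 division flags.
#'
#' @param path path to a `lineages.csv`-schema file.
#' @return a data frame (`lineage_id`, `time_h`, `length_um`, `fl_ch1`,
#'   `fl_ch2`, `division` as logical), sorted by lineage and time.
#' @export
read_lineages <- function(path) {
  dt <- data.table::fread(path)
  missing_cols <- setdiff(setdiff(lineage_csv_cols, "fl_ch2"), names(dt))
  if (length(missing_cols) > 0)
    stop("lineage CSV is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!("fl_ch2" %in% names(dt))) dt$fl_ch2 <- NA_real_
  bad_div <- which(!(dt$division %in% c(0, 1)))
  if (length(bad_div) > 0)
    stop("malformed division flag (must be 0/1) at row(s): ",
         paste(head(bad_div, 5), collapse = ", "))
  data.table::setorder(dt, lineage_id, time_h)
  dup <- dt[, any(diff(time_h) <= 0), by = "lineage_id"]
  bad <- dup$lineage_id[dup$V1]
  if (length(bad) > 0)
    stop("non-increasing times within lineage(s): ",
         paste(head(bad, 5), collapse = ", "))
  if (any(dt$length_um <= 0))
    stop("non-positive cell length in lineage CSV")
  df <- data.table::setDF(dt[, lineage_csv_cols, with = FALSE])
  df$division <- as.logical(df$division)
  df
}

#' Split a tidy frames table into per-lineage frames
#'
#' @param frames a frames data frame (as returned by [read_lineages()] or
#'   [experiment_frames()]).
#' @return a named list of per-lineage data frames.
#' @export
split_lineages <- function(frames) {
  split(frames[, setdiff(names(frames), "lineage_id")],
        frames$lineage_id)
}

#' Read a ground-truth CSV
#'
#' @param path path to a `truth.csv`-schema file.
#' @return a data frame with `lineage_id`, `deleted` (logical), `fate`.
#' @export
read_truth <- function(path) {
  dt <- data.table::fread(path)
  need <- c("lineage_id", "deleted", "fate")
  if (!all(need %in% names(dt)))
    stop("truth CSV requires columns: ", paste(need, collapse = ", "))
  df <- data.table::setDF(dt)
  df$deleted <- as.logical(df$deleted)
  df
}
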