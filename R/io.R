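#' Read a decision ecology from a config file
#'
#' Reads a YAML or JSON key-value file (dialect chosen by extension, or by
#' content when the extension is ambiguous) and validates it into a
#' [decision_ecology()]. Exactly the keys `mu_minus`, `mu_plus`, `sigma`,
#' `p`, `c_tp`, `c_tn`, `c_fp`, `c_fn` are accepted; unknown keys are an
#' error so typos cannot silently fall back to defaults.
#'
#' @param path Path to the config file.
#' @return A [decision_ecology()].
#' @export
read_ecology_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- c("mu_minus", "mu_plus", "sigma", "p",
               "c_tp", "c_tn", "c_fp", "c_fn")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; allowed keys are: ", paste(allowed, collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(c("mu_minus", "mu_plus", "sigma", "p"), names(cfg))
  if (length(missing)) {
    stop("config is missing required key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  do.call(decision_ecology, cfg)
}

# 12 significant digits everywhere a float is serialized, so that
# write -> read round-trips are stable across platforms
.signif12 <- function(x) {
  if (is.numeric(x)) signif(x, 12) else x
}

#' Serialize a result to JSON or CSV
#'
#' Writes a `group_accuracy` result (or any named list of scalars) with
#' deterministic field ordering and floats at 12 significant digits.
#' JSON writes one object; CSV appends one row to `path`, adding the
#' header `n,q,p,a_plus,a_minus,method,accuracy,acc_plus,acc_minus,
#' std_error,seed` when the file does not yet exist, so repeated runs
#' accumulate a tidy results table.
#'
#' @param result A `group_accuracy` object or named list of scalars.
#' @param path Output file path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @seealso [read_result()]
#' @export
write_result <- function(result, path, format = c("json", "csv")) {
  format <- match.arg(format)
  if (inherits(result, "group_accuracy")) {
    row <- list(
      n = result$n, q = .signif12(result$q), p = .signif12(result$p),
      a_plus = .signif12(if (!is.null(result$point))
        result$point$a_plus else NA_real_),
      a_minus = .signif12(if (!is.null(result$point))
        result$point$a_minus else NA_real_),
      method = result$method,
      accuracy = .signif12(result$accuracy),
      acc_plus = .signif12(result$acc_plus),
      acc_minus = .signif12(result$acc_minus),
      std_error = .signif12(result$std_error),
      seed = result$seed
    )
  } else if (is.list(result) && !is.null(names(result))) {
    row <- lapply(result, .signif12)
  } else {
    stop("`result` must be a group_accuracy object or a named list",
         call. = FALSE)
  }
  if (format == "json") {
    jsonlite::write_json(row, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  } else {
    df <- as.data.frame(row, stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       col.names = !file.exists(path), append = file.exists(path),
                       qmethod = "double")
  }
  invisible(path)
}

#' Read back a serialized result
#'
#' Inverse of [write_result()]: reads a JSON object into a named list, or a
#' CSV results table into a data.frame.
#'
#' @param path File written by [write_result()].
#' @param format `"json"` or `"csv"` (guessed from the extension when
#'   missing).
#' @return A named list (JSON) or data.frame (CSV).
#' @export
read_result <- function(path, format = c("guess", "json", "csv")) {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "json"
  }
  if (format == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}

#' Export a ROC curve as CSV
#'
#' Writes the `threshold,fpr,tpr` table produced by [roc_curve()].
#'
#' @param roc Data.frame from [roc_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc_csv <- function(roc, path) {
  stopifnot(is.data.frame(roc),
            all(c("threshold", "fpr", "tpr") %in% names(roc)))
  utils::write.csv(roc[, c("threshold", "fpr", "tpr")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export an error-region map as long-format CSV
#'
#' Writes one row per grid cell with columns
#' `p,ratio,a_plus,a_minus,error_class`, so any plotting layer can
#' reconstruct the map.
#'
#' @param map An `error_region_map` from [region_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_map <- function(map, path) {
  stopifnot(inherits(map, "error_region_map"))
  cells <- map$cells[, c("p", "ratio", "a_plus", "a_minus", "error_class")]
  cells$p <- .signif12(cells$p)
  cells$ratio <- .signif12(cells$ratio)
  cells$a_plus <- .signif12(cells$a_plus)
  cells$a_minus <- .signif12(cells$a_minus)
  utils::write.csv(cells, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Quick base-graphics view of an error-region map
#'
#' A minimal image plot of the marked region over (prior, cost ratio), with
#' the ratio axis on a log scale. Intended for interactive inspection only;
#' the CSV export is the canonical output.
#'
#' @param x An `error_region_map`.
#' @param ... Passed on to [graphics::image()].
#' @export
plot.error_region_map <- function(x, ...) {
  z <- matrix(as.numeric(x$cells$marked),
              nrow = length(x$p_grid), ncol = length(x$ratio_grid))
  graphics::image(x = x$p_grid, y = log10(x$ratio_grid), z = z,
                  col = c("white", "grey60"),
                  xlab = "prior probability of state +",
                  ylab = "log10 cost ratio (c_fp / c_fn)",
                  main = sprintf("error region: %s", x$which), ...)
  graphics::abline(h = 0, v = 0.5, lty = 3)
  invisible(x)
}
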