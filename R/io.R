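# Data ingestion from delimited text and result serialization.

#' Read a grouped count dataset from a delimited file
#'
#' @param path CSV/TSV file with a header row.
#' @param response Name of the response column.
#' @param groups Named vector or `term`/`group` data frame mapping predictor
#'   columns to group labels (see [zinb_data()]), or a path to a two-column
#'   CSV with columns `term` and `group`.
#' @param zero_groups Optional separate grouping for the zero component.
#' @param sep Field separator (`","` default; use `"\t"` for TSV).
#' @return A [zinb_data()] object.
#' @export
read_zinb_data <- function(path, response, groups, zero_groups = NULL,
                           sep = ",") {
  if (!file.exists(path)) stop("missing_file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (is.character(groups) && length(groups) == 1 && file.exists(groups)) {
    groups <- utils::read.table(groups, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE)
  }
  if (is.null(zero_groups)) zero_groups <- groups
  if (!response %in% names(df)) {
    stop("missing_response_column: response column '", response,
         "' not found in ", path, call. = FALSE)
  }
  gmap <- normalize_group_map(groups)
  unmapped <- setdiff(setdiff(names(df), response), names(gmap))
  if (length(unmapped) > 0) {
    stop("unmapped_column: no group label for column(s) ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  zinb_data(df, response, groups, zero_groups)
}

#' Assemble (and hash) a run configuration
#'
#' Collects every control that affects a run into one serializable list and
#' attaches a hash of its canonical JSON form, so a run can be re-executed
#' bitwise-identically from its persisted configuration.
#'
#' @param ... Named configuration entries (penalty, criterion, solver
#'   controls, seeds, paths).
#' @return A `run_config` list with a `hash` attribute.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  if (length(cfg) && (is.null(names(cfg)) || any(names(cfg) == ""))) {
    stop("invalid_config: all entries must be named", call. = FALSE)
  }
  cfg <- cfg[order(names(cfg))]
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg A configuration list.
#' @export
config_hash <- function(cfg) {
  attributes(cfg) <- attributes(cfg)["names"]
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                           null = "null")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(json), tf)
  unname(tools::md5sum(tf))
}

#' Write fitted results to disk
#'
#' A `zinb_path` is written as a path table (`path.csv`: lambda, df, loglik,
#' criterion when selected, active-group count) plus a JSON coefficient dump
#' (`coefficients.json`) recording the explicit parameter ordering, the
#' selected index, the configuration hash and the package version. A
#' `zinb_study` is written as `replicates.csv` and `summary.csv`.
#'
#' @param x A `zinb_path` or `zinb_study` object.
#' @param outdir Output directory (created if needed).
#' @param config Optional [run_config()] echoed into the JSON metadata.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, outdir, config = NULL) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("unwritable_directory: ", outdir, call. = FALSE)
  }
  if (inherits(x, "zinb_path")) {
    pt <- x$points
    pt$n_active <- vapply(x$active, length, integer(1))
    if (!is.null(x$selection)) {
      pt$criterion <- x$selection$criterion
      pt$selected <- seq_len(nrow(pt)) == x$selection$index
    }
    f1 <- file.path(outdir, "path.csv")
    utils::write.csv(pt, f1, row.names = FALSE)
    meta <- list(
      parameter_ordering = "theta = (log_phi, beta0, beta, gamma0, gamma); dispersion on the log scale",
      penalty = x$spec$family, mode = x$mode, n = x$n,
      selected_index = if (is.null(x$selection)) NULL else x$selection$index,
      selected_lambda = if (is.null(x$selection)) NULL else x$selection$lambda,
      criterion = if (is.null(x$selection)) NULL else x$selection$criterion_name,
      active_groups = if (is.null(x$selection)) NULL else x$selection$active,
      coefficients = if (is.null(x$selection)) NULL else
        as.list(stats::setNames(x$selection$theta,
                                rownames(x$surrogate$H) %||%
                                  paste0("theta", seq_along(x$selection$theta)))),
      config = if (is.null(config)) NULL else unclass(config),
      config_hash = if (is.null(config)) NULL else attr(config, "hash"),
      package_version = as.character(utils::packageVersion("grpzinb")))
    f2 <- file.path(outdir, "coefficients.json")
    jsonlite::write_json(meta, f2, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
    return(invisible(c(f1, f2)))
  }
  if (inherits(x, "zinb_study")) {
    f1 <- file.path(outdir, "replicates.csv")
    f2 <- file.path(outdir, "summary.csv")
    utils::write.csv(x$replicates, f1, row.names = FALSE)
    utils::write.csv(x$summary, f2, row.names = FALSE)
    return(invisible(c(f1, f2)))
  }
  stop("write_results does not know how to serialize a ", class(x)[1],
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
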