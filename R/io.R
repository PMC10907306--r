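#' Controlled vocabulary of depth-interval labels
#' @return Character vector of accepted `depth` values.
#' @export
depth_labels <- function() c("0-10cm", "10-30cm", "0-30cm")

sample_table_mandatory <- c("block", "plot", "treatment", "year", "depth")

#' Read a soil sample table
#'
#' CSV dialect: comma-separated, UTF-8, '.' decimal, header mandatory; columns
#' `block, plot, treatment, year, depth` then one numeric column per element
#' (mg per kg dry soil). Unknown element columns are carried through. Rows
#' with negative concentrations are rejected (dropped and reported via the
#' `rejected` attribute and a message); structural problems (missing
#' column, non-numeric concentration, unknown treatment or depth label) are
#' errors naming the offending column/row.
#'
#' @param path CSV file path.
#' @return Validated data frame with attribute `rejected` (row numbers of the
#'   input file that were dropped).
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8", na.strings = "")
  missing <- setdiff(sample_table_mandatory, names(tab))
  if (length(missing))
    stop("sample table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  validate_sample_table(tab, path)
}

validate_sample_table <- function(tab, what = "sample table") {
  bad_treat <- !tab$treatment %in% c("control", "basalt", "lime")
  if (any(bad_treat))
    stop(what, ": unknown treatment label '",
         tab$treatment[which(bad_treat)[1]], "' at row ",
         which(bad_treat)[1], call. = FALSE)
  bad_depth <- !tab$depth %in% depth_labels()
  if (any(bad_depth))
    stop(what, ": depth label '", tab$depth[which(bad_depth)[1]],
         "' at row ", which(bad_depth)[1], " is not in the controlled ",
         "vocabulary (", paste(depth_labels(), collapse = ", "), ")",
         call. = FALSE)
  if (!is.numeric(tab$year))
    stop(what, ": column 'year' must be numeric", call. = FALSE)
  elements <- setdiff(names(tab), sample_table_mandatory)
  if (!length(elements))
    stop(what, ": no element concentration columns found", call. = FALSE)
  for (e in elements) {
    if (!is.numeric(tab[[e]]))
      stop(what, ": concentration column '", e, "' is not numeric (first ",
           "offending row: ",
           which(is.na(suppressWarnings(as.numeric(tab[[e]]))))[1], ")",
           call. = FALSE)
  }
  neg <- rowSums(sapply(elements, function(e) {
    x <- tab[[e]]
    !is.na(x) & x < 0
  })) > 0
  rejected <- which(neg)
  if (length(rejected)) {
    message("rejected ", length(rejected),
            " row(s) with negative concentrations: rows ",
            paste(utils::head(rejected, 10), collapse = ", "),
            if (length(rejected) > 10) ", ..." else "")
    tab <- tab[!neg, , drop = FALSE]
    rownames(tab) <- NULL
  }
  attr(tab, "rejected") <- rejected
  tab
}

#' @rdname read_sample_table
#' @param tab Sample table to write.
#' @export
write_sample_table <- function(tab, path) {
  stopifnot(is.data.frame(tab))
  utils::write.csv(tab, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every setting of a full accounting run. `samples` and `feedstock`
#' may be in-memory objects or file paths (CSV; feedstock also JSON).
#'
#' @param samples Sample table (data frame) or CSV path.
#' @param feedstock [rock_feedstock()] or file path.
#' @param schedule Named numeric: rock applied (t/ha) by application year.
#' @param output_dir Directory for result files; created if absent.
#' @param geometry [soil_layer_geometry()] of the sampled layer.
#' @param cations,baseline,baseline_year,aggregation,uncertainty,
#'   depth_below_factor,correlated_b Passed to [estimate_weathering()].
#' @param years Analysis years (default: all with rock applied).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(samples, feedstock, schedule, output_dir,
                            geometry = soil_layer_geometry(0.1, 10000, 1.2),
                            cations = c("Ca", "Mg"),
                            years = NULL,
                            baseline = "pretreatment",
                            baseline_year = NULL,
                            aggregation = "mean",
                            uncertainty = "sd",
                            depth_below_factor = 1,
                            correlated_b = FALSE) {
  structure(list(samples = samples, feedstock = feedstock,
                 schedule = schedule, output_dir = output_dir,
                 geometry = geometry, cations = cations, years = years,
                 baseline = baseline, baseline_year = baseline_year,
                 aggregation = aggregation, uncertainty = uncertainty,
                 depth_below_factor = depth_below_factor,
                 correlated_b = correlated_b),
            class = "pipeline_config")
}

#' Run the full accounting pipeline
#'
#' Reads (or takes) the input tables, runs [estimate_weathering()], and writes
#' `results.csv` (one row per year and cation), `cdr_series.csv` (the
#' cumulative CDR curve) and `manifest.json` (inputs, their checksums, the
#' configuration hash and package version) under `config$output_dir`. Outputs
#' are deterministic: rerunning with an identical configuration and inputs
#' reproduces them byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return The `ew_fit`, invisibly, with attribute `files` naming the outputs.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  input_files <- character()
  samples <- config$samples
  if (is.character(samples)) {
    input_files["samples"] <- samples
    samples <- read_sample_table(samples)
  } else {
    samples <- validate_sample_table(samples)
  }
  feedstock <- config$feedstock
  if (is.character(feedstock)) {
    input_files["feedstock"] <- feedstock
    feedstock <- read_feedstock(feedstock)
  }

  fit <- estimate_weathering(samples, feedstock,
                             geometry = config$geometry,
                             schedule = config$schedule,
                             cations = config$cations,
                             years = config$years,
                             baseline = config$baseline,
                             baseline_year = config$baseline_year,
                             aggregation = config$aggregation,
                             uncertainty = config$uncertainty,
                             depth_below_factor = config$depth_below_factor,
                             correlated_b = config$correlated_b)

  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  f_results <- file.path(config$output_dir, "results.csv")
  f_series <- file.path(config$output_dir, "cdr_series.csv")
  f_manifest <- file.path(config$output_dir, "manifest.json")
  utils::write.csv(as.data.frame(fit), f_results, row.names = FALSE)
  utils::write.csv(fit$series, f_series, row.names = FALSE)

  manifest <- list(
    package = "ewcdr",
    version = as.character(utils::packageVersion("ewcdr")),
    config_hash = config_hash(config),
    inputs = if (length(input_files))
      lapply(as.list(input_files), function(p)
        list(path = p, md5 = unname(tools::md5sum(p))))
      else "in-memory",
    settings = fit$settings,
    schedule = as.list(config$schedule),
    outputs = c("results.csv", "cdr_series.csv"))
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  attr(fit, "files") <- c(results = f_results, series = f_series,
                          manifest = f_manifest)
  invisible(fit)
}

# md5 of the configuration's canonical serialization (output_dir excluded, so
# the same analysis written elsewhere hashes identically)
config_hash <- function(config) {
  x <- unclass(config)
  x$output_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(x), collapse = "\n"), tmp)
  unname(tools::md5sum(tmp))
}
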