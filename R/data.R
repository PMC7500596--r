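#' Construct a biomarker + survival dataset
#'
#' Bundles per-subject biomarker values, observed times and event indicators
#' into the container used by every analysis function. The working convention
#' throughout the package is that *higher biomarker values mean higher risk*;
#' if the supplied marker is protective, set `higher_is_riskier = FALSE` and
#' the values are negated on entry (the orientation is recorded).
#'
#' @param biomarker numeric vector of biomarker values; must be finite.
#' @param time numeric vector of observed times (any consistent unit); must be
#'   non-negative.
#' @param event integer vector of event indicators: 1 = event observed,
#'   0 = censored.
#' @param higher_is_riskier if `FALSE`, biomarker values are negated so that
#'   the working convention holds.
#' @param min_n minimum number of subjects accepted (default 1; analysis entry
#'   points apply a stricter floor).
#' @return An object of class `biomarker_survival_data`: a list with elements
#'   `data` (data.frame with columns `biomarker`, `time`, `event`), `n`, and
#'   `flipped` (whether the marker was negated).
#' @examples
#' d <- biomarker_survival_data(rnorm(30), rexp(30), rbinom(30, 1, 0.5))
#' d$n
#' @export
biomarker_survival_data <- function(biomarker, time, event,
                                    higher_is_riskier = TRUE, min_n = 1L) {
  n <- length(biomarker)
  if (length(time) != n || length(event) != n)
    stop("biomarker, time and event must have equal length", call. = FALSE)
  if (n < min_n)
    stop(sprintf("dataset has %d subjects; at least %d required", n, min_n),
         call. = FALSE)
  biomarker <- as.numeric(biomarker)
  time <- as.numeric(time)
  event <- as.numeric(event)

  bad <- which(!is.finite(biomarker))
  if (length(bad))
    stop(sprintf("non-finite biomarker value in row(s): %s",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  bad <- which(!is.finite(time) | time < 0)
  if (length(bad))
    stop(sprintf("missing or negative time in row(s): %s",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  bad <- which(!(event %in% c(0, 1)))
  if (length(bad))
    stop(sprintf("event indicator outside {0, 1} in row(s): %s",
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)

  if (!isTRUE(higher_is_riskier)) biomarker <- -biomarker
  structure(
    list(data = data.frame(biomarker = biomarker, time = time,
                           event = as.integer(event)),
         n = n, flipped = !isTRUE(higher_is_riskier)),
    class = "biomarker_survival_data")
}

#' @export
print.biomarker_survival_data <- function(x, ...) {
  cat(sprintf("biomarker/survival dataset: %d subjects, %d events (%.1f%%)\n",
              x$n, sum(x$data$event), 100 * mean(x$data$event)))
  cat(sprintf("  time range [%g, %g]; biomarker range [%.3g, %.3g]%s\n",
              min(x$data$time), max(x$data$time),
              min(x$data$biomarker), max(x$data$biomarker),
              if (x$flipped) " (orientation flipped on input)" else ""))
  invisible(x)
}

#' Read a subject-level dataset from delimited text
#'
#' Reads a delimited table with a header row, maps the named columns and
#' validates every row. The delimiter is auto-detected among comma and tab
#' unless given. Missing values are an error by default, because silently
#' dropping rows shifts the biomarker quantiles used for enrichment cutoffs;
#' set `drop_missing = TRUE` to drop them with a message.
#'
#' @param path path to a CSV/TSV file with a header row.
#' @param biomarker_col,time_col,event_col column names.
#' @param higher_is_riskier if `FALSE`, biomarker values are negated
#'   (see [biomarker_survival_data()]).
#' @param sep field delimiter; `NULL` (default) auto-detects "," vs tab.
#' @param drop_missing drop rows with missing values instead of erroring.
#' @param min_n minimum number of subjects accepted (default 20).
#' @return A [biomarker_survival_data()] object.
#' @export
read_dataset <- function(path, biomarker_col = "biomarker", time_col = "time",
                         event_col = "event", higher_is_riskier = TRUE,
                         sep = NULL, drop_missing = FALSE, min_n = 20L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (lengths(regmatches(first, gregexpr("\t", first))) >
               lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
  }
  raw <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (col in c(biomarker_col, time_col, event_col))
    if (!col %in% names(raw))
      stop(sprintf("column '%s' not found in %s (columns: %s)", col, path,
                   paste(names(raw), collapse = ", ")), call. = FALSE)
  b <- suppressWarnings(as.numeric(raw[[biomarker_col]]))
  tm <- suppressWarnings(as.numeric(raw[[time_col]]))
  ev <- suppressWarnings(as.numeric(raw[[event_col]]))
  miss <- !is.finite(b) | !is.finite(tm) | !is.finite(ev)
  if (any(miss)) {
    if (drop_missing) {
      message(sprintf("dropping %d row(s) with missing values", sum(miss)))
      b <- b[!miss]; tm <- tm[!miss]; ev <- ev[!miss]
    } else {
      stop(sprintf("missing/non-numeric value in row(s): %s (use drop_missing = TRUE to drop)",
                   paste(head(which(miss), 5L), collapse = ", ")), call. = FALSE)
    }
  }
  biomarker_survival_data(b, tm, ev, higher_is_riskier = higher_is_riskier,
                          min_n = min_n)
}

# column order of the written results table; *_exact columns carry full
# precision so a round trip reproduces unrounded values
.table_columns <- c(
  "threshold", "biomarker_cutoff", "event_rate_pct", "event_rate_se",
  "sample_size", "sample_size_se", "total_screened", "total_cost",
  "cost_reduction_pct", "event_rate_pct_exact", "treatment_event_rate_pct_exact",
  "sample_size_exact", "total_screened_exact")

#' Write an enrichment results table to CSV
#'
#' Writes one row per screening threshold with the display-rounded metrics
#' (event rates to whole percent, patient counts to whole patients, half away
#' from zero) followed by full-precision companion columns. Full-precision
#' values are serialized with 17 significant digits so that writing and
#' re-reading reproduces them exactly.
#'
#' @param table an `enrichment_table` from [analyze()].
#' @param path output CSV path.
#' @return Invisibly, the data.frame that was written.
#' @export
write_enrichment_table <- function(table, path) {
  stopifnot(inherits(table, "enrichment_table"))
  df <- table$table
  if (!nrow(df)) stop("empty enrichment table", call. = FALSE)
  out <- data.frame(
    threshold = df$threshold,
    biomarker_cutoff = df$biomarker_cutoff,
    event_rate_pct = round_half_up(df$event_rate_pct_exact),
    event_rate_se = df$event_rate_se,
    sample_size = round_half_up(df$sample_size_exact),
    sample_size_se = df$sample_size_se,
    total_screened = round_half_up(df$total_screened_exact),
    total_cost = df$total_cost,
    cost_reduction_pct = df$cost_reduction_pct,
    event_rate_pct_exact = df$event_rate_pct_exact,
    treatment_event_rate_pct_exact = df$treatment_event_rate_pct_exact,
    sample_size_exact = df$sample_size_exact,
    total_screened_exact = df$total_screened_exact)
  # serialize full precision deterministically
  chr <- out
  for (col in names(chr)) chr[[col]] <-
    ifelse(is.na(out[[col]]), "NA", formatC(out[[col]], digits = 17, format = "g"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(names(chr), collapse = ","), con)
  writeLines(do.call(paste, c(unname(as.list(chr)), sep = ",")), con)
  invisible(out)
}
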