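#' @title Saturation-mutagenesis ddG post-processing
#'
#' @description
#' Structure-based stability predictors are typically run several times per
#' mutation because of stochastic side-chain sampling; the runs are averaged
#' and the mean ddG (kcal/mol, mutant minus wild type) is classified against
#' a threshold of twice the predictor's typical error — 1.6 kcal/mol for a
#' 0.8 kcal/mol error. Mutations with mean ddG strictly above the threshold
#' are destabilising, all others neutral (the boundary value itself counts
#' as neutral).
#' @name stability-scan
NULL

#' Average replicate ddG runs
#'
#' @param run_ddg numeric vector of per-run ddG values, kcal/mol
#' @return list with `mean_ddg` and `sd_ddg`
#' @export
aggregate_runs <- function(run_ddg) {
  if (!length(run_ddg) || !is.numeric(run_ddg))
    stop("need at least one ddG run value", call. = FALSE)
  list(mean_ddg = mean(run_ddg),
       sd_ddg = if (length(run_ddg) > 1L) stats::sd(run_ddg) else NA_real_)
}

#' Classify mutations as destabilising or neutral
#'
#' @param mean_ddg mean ddG value(s), kcal/mol
#' @param threshold classification threshold, kcal/mol
#' @param annotate_stabilizing also mark mutations with
#'   `mean_ddg <= -threshold` as `"stabilizing"` — an extra annotation
#'   beyond the two-class destabilising/neutral scheme
#' @return character vector of classifications
#' @export
classify_mutation <- function(mean_ddg, threshold = 1.6,
                              annotate_stabilizing = FALSE) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  out <- ifelse(mean_ddg > threshold, "destabilizing", "neutral")
  if (annotate_stabilizing)
    out[mean_ddg <= -threshold] <- "stabilizing"
  out
}

.run_cols <- function(table) grep("^run[0-9]+$", names(table), value = TRUE)

#' Aggregate and classify a ddG mutation table
#'
#' @param table data frame with columns `position`, `wild_type`, `mutant`
#'   and run columns `run1..runN` (any run count; predictors are normally
#'   run five times)
#' @param threshold classification threshold, kcal/mol
#' @param annotate_stabilizing see [classify_mutation()]
#' @return the table with `mean_ddg`, `sd_ddg` and `classification` added
#' @export
ddg_classify_table <- function(table, threshold = 1.6,
                               annotate_stabilizing = FALSE) {
  stopifnot(is.data.frame(table),
            all(c("position", "wild_type", "mutant") %in% names(table)))
  if (any(table$mutant == table$wild_type))
    stop("mutant must differ from wild type", call. = FALSE)
  runs <- .run_cols(table)
  if (!length(runs)) stop("no run1..runN columns found", call. = FALSE)
  m <- as.matrix(table[, runs, drop = FALSE])
  table$mean_ddg <- rowMeans(m)
  table$sd_ddg <- apply(m, 1, stats::sd)
  table$classification <- classify_mutation(table$mean_ddg, threshold,
                                            annotate_stabilizing)
  table
}

#' Per-position summary of a saturation scan
#'
#' @param table a classified table from [ddg_classify_table()] (or a raw
#'   table, which is classified first with default settings)
#' @param positions positions of interest; missing ones produce a warning,
#'   not a failure
#' @param flag_variants optional character vector like `"T360A"` naming
#'   single-mutant variants whose rows are returned separately
#' @return list with `summary` (per-position counts of destabilising /
#'   neutral mutations) and `flagged` (rows for the named variants)
#' @export
scan_summary <- function(table, positions = sort(unique(table$position)),
                         flag_variants = character()) {
  if (!"classification" %in% names(table))
    table <- ddg_classify_table(table)
  present <- positions[positions %in% table$position]
  absent <- setdiff(positions, present)
  if (length(absent))
    warning("position(s) absent from ddG table: ",
            paste(absent, collapse = ", "), call. = FALSE)
  rows <- lapply(present, function(p) {
    d <- table[table$position == p, , drop = FALSE]
    data.frame(position = p, wild_type = d$wild_type[1],
               n_mutations = nrow(d),
               n_destabilizing = sum(d$classification == "destabilizing"),
               n_neutral = sum(d$classification == "neutral"))
  })
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(position = integer(), wild_type = character(),
               n_mutations = integer(), n_destabilizing = integer(),
               n_neutral = integer())
  key <- paste0(table$wild_type, table$position, table$mutant)
  flagged <- table[key %in% flag_variants, , drop = FALSE]
  list(summary = summary, flagged = flagged)
}

#' Read a ddG table
#'
#' Delimited file with columns `position`, `wild_type`, `mutant`,
#' `run1..runN`; separator from the extension (`.tsv` = tab, else comma).
#'
#' @param path input file
#' @return data frame
#' @export
read_ddg <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  table <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  need <- c("position", "wild_type", "mutant")
  if (!all(need %in% names(table)))
    stop("ddG table lacks column(s): ",
         paste(setdiff(need, names(table)), collapse = ", "), call. = FALSE)
  table
}

#' Write classification table and summary
#'
#' @param classified table from [ddg_classify_table()]
#' @param tsv path for the per-mutation TSV
#' @param json path for the per-position JSON summary
#' @param ... passed to [scan_summary()]
#' @return the classified table, invisibly
#' @export
write_ddg_report <- function(classified, tsv = NULL, json = NULL, ...) {
  if (!is.null(tsv))
    utils::write.table(classified, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json)) {
    s <- scan_summary(classified, ...)
    jsonlite::write_json(list(summary = s$summary, flagged = s$flagged),
                         json, digits = NA)
  }
  invisible(classified)
}
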