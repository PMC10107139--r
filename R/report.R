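#' Combine scan summaries, envelopes and verdicts into a run report
#'
#' Joins the per-chromosome scan summaries with one or more simulation
#' envelopes, classifying the observed mean hybrid index against each.
#' The chromosome sets must agree; a mismatch is an error naming the
#' difference.
#'
#' @param summaries Tibble from [chrom_summary()] (must be non-empty).
#' @param envelopes Named list of `sim_envelope` objects (e.g.
#'   `list(SIM1 = ..., SIM2 = ...)`).
#' @param seed Master seed to record in the report.
#' @return A list of class `hi_report`: `table` (per-chromosome tibble with
#'   one verdict column per envelope), `seed`, `envelopes` (bounds only).
#' @export
report_run <- function(summaries, envelopes, seed = NA_integer_) {
  if (nrow(summaries) == 0L) stop("empty scan output: nothing to report")
  if (is.null(names(envelopes)) || any(names(envelopes) == "")) {
    stop("`envelopes` must be a named list")
  }
  tab <- summaries
  for (nm in names(envelopes)) {
    env <- envelopes[[nm]]
    extra_s <- setdiff(summaries$chrom, env$chrom)
    extra_e <- setdiff(env$chrom, summaries$chrom)
    if (length(extra_s) || length(extra_e)) {
      stop("chromosome sets differ for envelope '", nm, "': scan-only {",
           paste(extra_s, collapse = ","), "}, envelope-only {",
           paste(extra_e, collapse = ","), "}")
    }
    obs <- stats::setNames(summaries$mean_hi, summaries$chrom)
    v <- classify_hi(obs, env)
    tab[[paste0("verdict_", nm)]] <- v$classification[match(tab$chrom,
                                                            v$chrom)]
  }
  structure(
    list(
      table = tab,
      seed = seed,
      envelopes = lapply(envelopes, function(e)
        as.data.frame(e[, c("chrom", "lower", "upper", "n_replicates",
                            "alpha", "n_tests")]))
    ),
    class = "hi_report"
  )
}

#' Write / read a run report as JSON
#'
#' The JSON round-trips: reading a written report restores the same table,
#' seed and envelope bounds.
#'
#' @param report An `hi_report` from [report_run()].
#' @param path Output path.
#' @return `write_report_json()`: the path, invisibly. `read_report_json()`:
#'   an `hi_report`.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(
    list(
      seed = report$seed,
      table = as.data.frame(report$table),
      envelopes = report$envelopes
    ),
    path, auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      table = tibble::as_tibble(x$table),
      seed = if (is.null(x$seed)) NA_integer_ else x$seed,
      envelopes = x$envelopes
    ),
    class = "hi_report"
  )
}

#' @export
print.hi_report <- function(x, ...) {
  cat("Hybrid-index run report (seed ", x$seed, ")\n", sep = "")
  print(x$table, ...)
  invisible(x)
}
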