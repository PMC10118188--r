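#' Long-format observation tables
#'
#' The whole package operates on a single long-format table of stream
#' observations with one row per measurement: `site`, `group` (treatment
#' group label), `period` (`"pre"` or `"post"`), `year`, `replicate`
#' (integer index within site-year), `attribute` (response name, e.g.
#' `"DIN"`) and `value`. [as_baci_observations()] validates a data frame
#' and stamps the class; [read_observations()] / [write_observations()]
#' round-trip the table through delimited text.
#'
#' @param x A data.frame with columns `site`, `group`, `period`, `year`,
#'   `replicate`, `attribute`, `value`.
#' @return A data.frame of class `baci_observations`.
#' @export
as_baci_observations <- function(x) {
  needed <- c("site", "group", "period", "year", "replicate", "attribute",
              "value")
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0L) {
    stop("observation table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)[, needed]
  x$site <- as.character(x$site)
  x$group <- as.character(x$group)
  x$period <- as.character(x$period)
  x$attribute <- as.character(x$attribute)
  x$year <- as.integer(x$year)
  x$replicate <- as.integer(x$replicate)
  x$value <- as.numeric(x$value)
  if (anyNA(x$group) || any(!nzchar(x$group))) {
    stop("observation table contains missing group labels")
  }
  if (!all(x$period %in% c("pre", "post"))) {
    stop("period must be 'pre' or 'post'")
  }
  if (any(!is.finite(x$value))) {
    stop("observation values must be finite")
  }
  class(x) <- c("baci_observations", "data.frame")
  x
}

#' @rdname as_baci_observations
#' @param path File path of a delimited (CSV) observation table.
#' @export
read_observations <- function(path) {
  as_baci_observations(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname as_baci_observations
#' @param table An observation table.
#' @export
write_observations <- function(table, path) {
  table <- as_baci_observations(table)
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Collapse an observation table to site-year means
#'
#' The default analysis unit: replicate measurements within each
#' site-year-attribute cell are averaged first, so that each site
#' contributes one value per year and pseudo-replication from composite
#' samples is avoided. Rows keep their `group` and `period` labels.
#'
#' @param table An observation table (see [as_baci_observations()]).
#' @return A `baci_observations` table with `replicate = 1` throughout.
#' @export
site_year_means <- function(table) {
  table <- as_baci_observations(table)
  agg <- stats::aggregate(
    value ~ site + group + period + year + attribute,
    data = table, FUN = mean)
  agg$replicate <- 1L
  as_baci_observations(agg)
}
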