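# Schema-validated delimited-text readers for the tabular pipeline inputs.

.schemas <- list(
  catch_counts   = c("year", "stratum"),
  life_table     = c("age", "M", "selectivity", "weight", "maturity"),
  biomass_series = c("year", "biomass"),
  occurrences    = c("year", "presence", "temperature")
)

#' Read a typed pipeline table from delimited text
#'
#' @param path CSV/TSV file with a header
#' @param schema one of `"catch_counts"` (year, stratum, one count column
#'   per population), `"life_table"` (age, M, selectivity, weight,
#'   maturity), `"biomass_series"` (year, biomass), `"occurrences"` (year,
#'   presence, temperature; optional depth, population, row, col)
#' @param sep field separator, guessed from the extension by default
#' @return a validated typed object: [catch_count_table()], [life_table()],
#'   or a data.frame for biomass/occurrence schemas
#' @export
read_table <- function(path, schema = names(.schemas), sep = NULL) {
  schema <- match.arg(schema)
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  need <- .schemas[[schema]]
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    .stop_fmt("%s file %s lacks required column(s): %s",
              schema, path, paste(missing_cols, collapse = ", "))
  num_check <- function(cols) {
    for (cl in cols) {
      v <- suppressWarnings(as.numeric(df[[cl]]))
      if (any(is.na(v) & !is.na(df[[cl]])))
        .stop_fmt("non-numeric value in column '%s' of %s", cl, path)
      df[[cl]] <<- v
    }
  }
  switch(schema,
    catch_counts = {
      count_cols <- setdiff(names(df), c("year", "stratum"))
      if (!length(count_cols))
        .stop_fmt("catch_counts file %s has no population count columns", path)
      num_check(c("year", count_cols))
      catch_count_table(df$year, df$stratum, df[count_cols])
    },
    life_table = {
      num_check(need)
      life_table(df$age, df$M, df$selectivity, df$weight, df$maturity)
    },
    biomass_series = {
      num_check(need)
      if (any(df$biomass < 0)) .stop_fmt("negative biomass in %s", path)
      df[c("year", "biomass")]
    },
    occurrences = {
      num_check(intersect(c("year", "presence", "temperature", "depth",
                            "row", "col", "lon", "lat"), names(df)))
      if (!all(df$presence %in% c(0, 1)))
        .stop_fmt("presence must be 0/1 in %s", path)
      df
    })
}

#' Write a catch-count table as CSV
#' @param x a [catch_count_table()]
#' @param path output path
#' @export
write_catch_counts <- function(x, path) {
  df <- as.data.frame(x)[c("year", "stratum", attr(x, "populations"))]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a life table as CSV
#' @param lt a [life_table()]
#' @param path output path
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
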