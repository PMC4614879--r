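# Core domain containers and validators.
#
# Genotypes are stored as reference-allele dosage in {0, 1, 2}; NA marks a
# missing call. This is sufficient for a biallelic SNP panel and keeps the
# assignment likelihoods simple.

#' Construct a genotype table
#'
#' @param calls integer matrix, individuals x loci, entries in \{0,1,2\} or NA
#' @param individual_ids unique character vector, one per row
#' @param locus_ids unique character vector, one per column
#' @param group_labels optional character vector of population labels per
#'   individual (present for baseline samples, absent for mixed samples)
#' @return an object of class `genotype_table`
#' @export
genotype_table <- function(calls, individual_ids, locus_ids,
                           group_labels = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(individual_ids))
    .stop_fmt("calls has %d rows but %d individual ids",
              nrow(calls), length(individual_ids))
  if (ncol(calls) != length(locus_ids))
    .stop_fmt("calls has %d columns but %d locus ids",
              ncol(calls), length(locus_ids))
  if (anyDuplicated(individual_ids))
    .stop_fmt("duplicated individual id: %s",
              individual_ids[duplicated(individual_ids)][1L])
  if (anyDuplicated(locus_ids))
    .stop_fmt("duplicated locus id: %s", locus_ids[duplicated(locus_ids)][1L])
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad))
    .stop_fmt("genotype calls must be in {0,1,2} or NA (offending value %s)",
              calls[bad][1L])
  if (!is.null(group_labels)) {
    if (length(group_labels) != nrow(calls))
      .stop_fmt("group_labels must cover all %d individuals", nrow(calls))
    group_labels <- as.character(group_labels)
  }
  dimnames(calls) <- list(individual_ids, locus_ids)
  structure(
    list(calls = calls,
         individual_ids = as.character(individual_ids),
         locus_ids = as.character(locus_ids),
         group_labels = group_labels),
    class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d loci (%s)\n",
              nrow(x$calls), ncol(x$calls),
              if (is.null(x$group_labels)) "mixed sample"
              else sprintf("%d groups", length(unique(x$group_labels)))))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

#' Construct a life table of age-structured schedules
#'
#' @param ages consecutive integer ages, recruit age to max age
#' @param M natural mortality per year by age (>= 0)
#' @param selectivity relative fishing pattern by age (dimensionless, >= 0)
#' @param weight weight-at-age in kg (> 0)
#' @param maturity proportion mature at age, in \[0, 1\]
#' @return an object of class `life_table`
#' @export
life_table <- function(ages, M, selectivity, weight, maturity) {
  ages <- as.integer(ages)
  n <- length(ages)
  if (n < 1L) .stop_fmt("life table needs at least one age")
  if (!all(diff(ages) == 1L))
    .stop_fmt("ages must be consecutive integers")
  for (nm in c("M", "selectivity", "weight", "maturity")) {
    v <- get(nm)
    if (length(v) != n) .stop_fmt("%s must have length %d", nm, n)
    if (any(!is.finite(v))) .stop_fmt("%s contains non-finite values", nm)
  }
  if (any(M < 0)) .stop_fmt("natural mortality M must be >= 0")
  if (any(selectivity < 0)) .stop_fmt("selectivity must be >= 0")
  if (any(weight <= 0)) .stop_fmt("weight-at-age must be > 0")
  if (any(maturity < 0 | maturity > 1))
    .stop_fmt("maturity-at-age must be within [0, 1]")
  structure(
    data.frame(age = ages, M = as.numeric(M),
               selectivity = as.numeric(selectivity),
               weight = as.numeric(weight), maturity = as.numeric(maturity)),
    class = c("life_table", "data.frame"))
}

#' Construct a catch-count table
#'
#' One record per (year, stratum): counts of individuals assigned to each
#' population. `N` is derived as the row sum.
#'
#' @param year decimal year per record
#' @param stratum management-division label per record
#' @param counts matrix or data.frame of non-negative integer counts,
#'   columns named by population
#' @return an object of class `catch_count_table` (a data.frame with an
#'   attached `populations` attribute)
#' @export
catch_count_table <- function(year, stratum, counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("P", seq_len(ncol(counts)))
  if (any(counts < 0) || any(counts != round(counts)))
    .stop_fmt("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  df <- data.frame(year = as.numeric(year), stratum = as.character(stratum),
                   counts, N = as.integer(rowSums(counts)),
                   check.names = FALSE)
  structure(df, populations = colnames(counts),
            class = c("catch_count_table", "data.frame"))
}

#' Construct a yearly grid series
#'
#' @param years integer years, one per layer
#' @param layers list of numeric matrices (nrow x ncol), NA on land
#' @param mask logical matrix, TRUE for sea cells
#' @param cell_size_km cell edge length in km (default 50)
#' @return an object of class `grid_series`
#' @export
grid_series <- function(years, layers, mask, cell_size_km = 50) {
  years <- as.integer(years)
  if (length(layers) != length(years))
    .stop_fmt("need one layer per year (%d layers, %d years)",
              length(layers), length(years))
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  for (i in seq_along(layers)) {
    l <- as.matrix(layers[[i]])
    if (!identical(dim(l), dim(mask)))
      .stop_fmt("layer %d dimensions differ from mask", i)
    l[!mask] <- NA_real_
    layers[[i]] <- l
  }
  names(layers) <- as.character(years)
  structure(list(years = years, layers = layers, mask = mask,
                 cell_size_km = cell_size_km),
            class = "grid_series")
}

#' @export
print.grid_series <- function(x, ...) {
  cat(sprintf("grid_series: %d years (%d-%d), %dx%d grid, %g km cells, %d sea cells\n",
              length(x$years), min(x$years), max(x$years),
              nrow(x$mask), ncol(x$mask), x$cell_size_km, sum(x$mask)))
  invisible(x)
}
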