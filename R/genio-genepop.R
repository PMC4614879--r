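# Genepop 4.x reader/writer for biallelic SNP data.
#
# The format does not store population names; blocks are labelled P1..PK in
# order of appearance (overridable). Allele 1 is the reference allele and a
# genotype is stored as its reference-allele dosage.

#' Read a Genepop file
#'
#' Supports 2- and 3-digit allele codes and biallelic loci only. Missing
#' genotypes ("0000"/"000000") become NA. Each POP block becomes one group
#' label.
#'
#' @param path path to a Genepop 4.x file
#' @param pop_names optional character vector naming the POP blocks; defaults
#'   to P1..PK
#' @return a [genotype_table()]
#' @export
read_genepop <- function(path, pop_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) .stop_fmt("not a Genepop file: %s", path)
  body <- lines[-1L]  # first line is the title
  is_pop <- toupper(trimws(body)) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) .stop_fmt("no POP block found in %s", path)
  locus_lines <- body[seq_len(first_pop - 1L)]
  locus_ids <- trimws(unlist(strsplit(locus_lines, ",")))
  locus_ids <- locus_ids[nzchar(locus_ids)]
  if (anyDuplicated(locus_ids))
    .stop_fmt("duplicated locus name in %s", path)
  n_loci <- length(locus_ids)

  ind_lines <- body[seq.int(first_pop, length(body))]
  pop_idx <- cumsum(toupper(trimws(ind_lines)) == "POP")
  keep <- toupper(trimws(ind_lines)) != "POP"
  ind_lines <- ind_lines[keep]
  pop_idx <- pop_idx[keep]
  n_pops <- max(pop_idx)
  if (is.null(pop_names)) pop_names <- paste0("P", seq_len(n_pops))
  if (length(pop_names) != n_pops)
    .stop_fmt("pop_names has length %d but file has %d POP blocks",
              length(pop_names), n_pops)

  ids <- character(length(ind_lines))
  calls <- matrix(NA_integer_, length(ind_lines), n_loci)
  for (i in seq_along(ind_lines)) {
    parts <- strsplit(ind_lines[i], ",", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      .stop_fmt("malformed individual line (no comma): %s", ind_lines[i])
    ids[i] <- trimws(parts[1L])
    geno <- strsplit(trimws(paste(parts[-1L], collapse = " ")), "\\s+")[[1L]]
    if (length(geno) != n_loci)
      .stop_fmt("individual %s has %d genotypes, expected %d",
                ids[i], length(geno), n_loci)
    width <- nchar(geno)
    if (!all(width %in% c(4L, 6L)))
      .stop_fmt("individual %s: allele codes must be 2 or 3 digits", ids[i])
    half <- width %/% 2L
    a1 <- as.integer(substr(geno, 1L, half))
    a2 <- as.integer(substr(geno, half + 1L, width))
    if (anyNA(a1) || anyNA(a2))
      .stop_fmt("individual %s: non-numeric allele code", ids[i])
    bad <- which(a1 > 2L | a2 > 2L)
    if (length(bad))
      .stop_fmt("locus %s: allele code > 2 at a biallelic locus",
                locus_ids[bad[1L]])
    miss <- a1 == 0L | a2 == 0L
    dosage <- (a1 == 1L) + (a2 == 1L)
    dosage[miss] <- NA_integer_
    calls[i, ] <- dosage
  }
  if (anyDuplicated(ids))
    .stop_fmt("duplicated individual id: %s", ids[duplicated(ids)][1L])
  genotype_table(calls, ids, locus_ids, group_labels = pop_names[pop_idx])
}

#' Write a genotype table to a Genepop file
#'
#' Individuals are grouped by label (first-appearance order) into POP
#' blocks; a table without labels becomes one block. 2-digit allele codes,
#' allele 1 = reference.
#'
#' @param gt a [genotype_table()]
#' @param path output path
#' @param title first (comment) line of the file
#' @return `path`, invisibly
#' @export
write_genepop <- function(gt, path, title = "codmix genotypes") {
  stopifnot(inherits(gt, "genotype_table"))
  labels <- gt$group_labels %||% rep("P1", nrow(gt$calls))
  code <- c(`0` = "0202", `1` = "0102", `2` = "0101")
  out <- c(title, gt$locus_ids)
  for (lab in unique(labels)) {
    out <- c(out, "POP")
    for (i in which(labels == lab)) {
      g <- code[as.character(gt$calls[i, ])]
      g[is.na(g)] <- "0000"
      out <- c(out, paste0(gt$individual_ids[i], " ,  ",
                           paste(g, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}
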