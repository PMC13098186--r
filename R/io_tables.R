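# Tabular readers/writers. All TSVs carry headers and are UTF-8. The
# taxonomy reader centralizes the MISSING policy: blank, "unclassified",
# and "incertae sedis" cells all become NA so downstream lowest-common-rank
# logic never sees raw sentinel strings.

.missing_taxon_sentinels <- c("", "na", "incertae sedis", "unclassified")

.normalize_taxon <- function(x) {
  x <- trimws(as.character(x))
  x[tolower(x) %in% .missing_taxon_sentinels] <- NA_character_
  x
}

#' Read a genome taxonomy table
#'
#' Expects a TSV with header columns `genome_id`, `group`, `cultured`, and
#' the six ranks `superkingdom`, `phylum`, `class`, `order`, `family`,
#' `genus`. Blank, `unclassified`, or `incertae sedis` cells are mapped to
#' `NA` (missing). A missing Superkingdom is tolerated with a warning.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `genome_id`, `group`, `cultured`,
#'   `Superkingdom` ... `Genus`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character",
                          na.strings = character(0), check.names = FALSE)
  names(df) <- tolower(names(df))
  need <- c("genome_id", "group", "cultured", tolower(CA_RANKS))
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("taxonomy file missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$group), CA_GROUPS)
  if (length(bad) > 0L)
    stop("unknown group value: ", bad[1L])
  if (anyDuplicated(df$genome_id))
    stop("duplicate genome_id: ", df$genome_id[duplicated(df$genome_id)][1L])
  out <- data.frame(genome_id = df$genome_id,
                    group = df$group,
                    cultured = toupper(df$cultured) %in% c("TRUE", "T", "1"),
                    stringsAsFactors = FALSE)
  for (r in CA_RANKS) out[[r]] <- .normalize_taxon(df[[tolower(r)]])
  n_missing_sk <- sum(is.na(out$Superkingdom))
  if (n_missing_sk > 0L)
    warning(n_missing_sk, " genome(s) with missing Superkingdom kept")
  out
}

#' Read a dataset (metagenome/metatranscriptome) table
#'
#' TSV with columns `dataset_id`, `environment`, `datatype` and optionally
#' `study_id`. Environments must be one of the seven collapsed categories
#' (see [CA_ENVIRONMENTS]).
#'
#' @param path Path to the TSV file.
#' @return A data.frame of dataset records.
#' @export
read_datasets <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  need <- c("dataset_id", "environment", "datatype")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("dataset file missing column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$environment), CA_ENVIRONMENTS)
  if (length(bad) > 0L)
    stop("unknown environment: ", bad[1L])
  bad <- setdiff(unique(df$datatype), c("metagenome", "metatranscriptome"))
  if (length(bad) > 0L)
    stop("unknown datatype: ", bad[1L])
  if (anyDuplicated(df$dataset_id))
    stop("duplicate dataset_id: ", df$dataset_id[duplicated(df$dataset_id)][1L])
  if (is.null(df$study_id)) df$study_id <- df$dataset_id
  df[, c("dataset_id", "environment", "datatype", "study_id")]
}

#' Write a result table as TSV
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path Path to the file.
#' @return A data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    na.strings = "", check.names = FALSE)
}

#' Write an R object as JSON
#'
#' @param x An R list or vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read JSON written by [write_json()]
#' @param path Path to the file.
#' @return The parsed object.
#' @export
read_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
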