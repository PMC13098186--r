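#' Read a protein FASTA file
#'
#' Reads amino-acid sequences, preserving record order. Sequences are
#' uppercased and a single terminal `*` stop symbol is stripped. Duplicate
#' identifiers and empty sequences are rejected rather than coerced.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of sequences; names are the first
#'   whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate id ", dup[1L], " in ", path)
  if (any(!nzchar(seqs))) {
    bad <- ids[!nzchar(seqs)][1L]
    stop("empty sequence for id ", bad, " in ", path)
  }
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (residues per line).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Build a protein record table
#'
#' The central in-memory representation of putative CA proteins: one row
#' per sequence with its genome of origin and CA class.
#'
#' @param sequence_id,genome_id,ca_class,sequence Equal-length vectors.
#' @return A data.frame with columns `sequence_id`, `genome_id`,
#'   `ca_class`, `sequence`, `length`.
#' @export
protein_records <- function(sequence_id, genome_id, ca_class, sequence) {
  stopifnot(length(sequence_id) == length(genome_id),
            length(sequence_id) == length(ca_class),
            length(sequence_id) == length(sequence))
  if (anyDuplicated(sequence_id))
    stop("duplicate sequence_id: ", sequence_id[duplicated(sequence_id)][1L])
  bad <- setdiff(unique(ca_class), CA_CLASSES)
  if (length(bad) > 0L)
    stop("unknown ca_class value: ", bad[1L])
  if (any(!nzchar(sequence))) stop("empty sequence not allowed")
  data.frame(sequence_id = as.character(sequence_id),
             genome_id = as.character(genome_id),
             ca_class = as.character(ca_class),
             sequence = toupper(as.character(sequence)),
             length = nchar(sequence),
             stringsAsFactors = FALSE)
}
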