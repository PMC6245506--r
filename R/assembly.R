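#' Construct an assembly record
#'
#' An assembly record is the unit evaluated by the metric calculators: a
#' named set of contig (or scaffold) sequences belonging to one assembly.
#'
#' @param assembly_id Non-empty identifier for the assembly.
#' @param contigs Named character vector of nucleotide sequences
#'   (IUPAC letters tolerated, case-insensitive). Names are contig ids and
#'   must be unique; every sequence must have length >= 1.
#' @return An object of class `"assembly_record"`: a list with elements
#'   `assembly_id` and `contigs`.
#' @export
#' @examples
#' assembly_record("toy", c(a = "ACGT", b = "NNAC"))
assembly_record <- function(assembly_id, contigs) {
  if (!is.character(assembly_id) || length(assembly_id) != 1L ||
      is.na(assembly_id) || !nzchar(assembly_id))
    txstop("'assembly_id' must be a single non-empty string")
  if (!is.character(contigs) || length(contigs) == 0L)
    txstop("'contigs' must be a non-empty named character vector")
  ids <- names(contigs)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids))
    txstop("every contig must be named")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    txstop("duplicate contig id(s): ", paste(dup, collapse = ", "))
  if (any(nchar(contigs) < 1L))
    txstop("zero-length contig sequence(s) in assembly '", assembly_id, "'")
  structure(list(assembly_id = assembly_id, contigs = contigs),
            class = "assembly_record")
}

#' @export
print.assembly_record <- function(x, ...) {
  cat("Assembly '", x$assembly_id, "': ", length(x$contigs), " contigs, ",
      sum(nchar(x$contigs)), " nt total\n", sep = "")
  invisible(x)
}

#' Read an assembly from a FASTA file
#'
#' Multi-line sequences are concatenated; the contig id is the header token
#' before the first whitespace. An empty file, a file with zero records, or
#' a duplicated contig id is a hard error.
#'
#' @param path Path to a FASTA file.
#' @param assembly_id Assembly identifier; defaults to the file name without
#'   extension.
#' @return An [assembly_record()].
#' @export
read_assembly_fasta <- function(path,
                                assembly_id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) txstop("FASTA file not found: ", path)
  if (file.size(path) == 0L) txstop("FASTA file is empty: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) txstop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    txstop("duplicate contig id(s) in ", path, ": ", paste(dup, collapse = ", "))
  seqs <- as.character(set)
  names(seqs) <- ids
  assembly_record(assembly_id, seqs)
}
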