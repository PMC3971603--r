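# FASTQ / FASTA / sample-map ingestion.
#
# Reads are held in a plain data.frame with columns id, seq, qual (Phred+33
# string or NA), library, truth_source.  FASTA parsing goes through
# Biostrings; the FASTQ parser is line-based so malformed records can be
# reported with their line number.

new_reads <- function(id, seq, qual = NA_character_, library = NA_character_,
                      truth_source = NA_character_) {
  n <- length(id)
  data.frame(id = as.character(id), seq = as.character(seq),
             qual = rep_len(as.character(qual), n),
             library = rep_len(as.character(library), n),
             truth_source = rep_len(as.character(truth_source), n),
             stringsAsFactors = FALSE)
}

#' Read a FASTQ file
#'
#' Parses 4-line-per-record FASTQ with Sanger (Phred+33) qualities.  Record
#' order is preserved and `N` bases are retained.  Malformed records
#' (missing `@`/`+` markers, sequence/quality length mismatch) raise an
#' error naming the offending line.
#'
#' @param path path to an uncompressed FASTQ file.
#' @param library library name stored in the `library` column (default
#'   `NA`).
#' @return a data.frame with columns `id`, `seq`, `qual` (Phred+33 string),
#'   `library`, `truth_source`.
#' @export
read_fastq <- function(path, library = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) && lines[length(lines)] == "")
    lines <- lines[-length(lines)]
  if (length(lines) == 0)
    return(new_reads(character(0), character(0), character(0)))
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ: ", path, " has ", length(lines),
         " lines (not a multiple of 4); truncated near line ", length(lines))
  hi <- seq(1, length(lines), by = 4)
  hdr <- lines[hi]; seq <- lines[hi + 1]; plus <- lines[hi + 2]
  qual <- lines[hi + 3]
  bad <- which(substr(hdr, 1, 1) != "@")
  if (length(bad))
    stop("malformed FASTQ record at line ", hi[bad[1]],
         ": header does not start with '@'")
  bad <- which(substr(plus, 1, 1) != "+")
  if (length(bad))
    stop("malformed FASTQ record at line ", hi[bad[1]] + 2,
         ": separator line does not start with '+'")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop("malformed FASTQ record at line ", hi[bad[1]],
         ": sequence and quality lengths differ (",
         nchar(seq[bad[1]]), " vs ", nchar(qual[bad[1]]), ")")
  bad <- which(nchar(seq) == 0)
  if (length(bad))
    stop("malformed FASTQ record at line ", hi[bad[1]], ": empty sequence")
  id <- sub("\\s.*$", "", substring(hdr, 2))
  if (anyDuplicated(id))
    stop("duplicate read id in ", path, ": ", id[duplicated(id)][1])
  new_reads(id, validate_dna(seq, "read"), qual, library)
}

#' Write reads to a FASTQ file
#'
#' Reads without qualities are written with a constant quality of 30.
#'
#' @param reads a reads data.frame (see [read_fastq()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  miss <- is.na(qual)
  if (any(miss))
    qual[miss] <- vapply(nchar(reads$seq[miss]),
                         function(n) strrep(rawToChar(as.raw(30 + 33)), n), "")
  out <- rbind(paste0("@", reads$id), reads$seq, "+", qual)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Read a multi-FASTA reference set
#'
#' Headers are truncated at the first whitespace for the id; the full
#' header is kept as the description.  Wrapped sequence lines are allowed.
#' Duplicate ids are an error.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"` (default) or `"aa"`.  DNA records are
#'   upper-cased and restricted to A/C/G/T/N.
#' @return a data.frame with columns `id`, `desc`, `seq` and attribute
#'   `alphabet`, of class `reference_set`.
#' @export
read_fasta <- function(path, alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  desc <- names(set)
  id <- sub("\\s.*$", "", desc)
  if (anyDuplicated(id))
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  seq <- as.character(set)
  if (any(nchar(seq) == 0))
    stop("empty sequence for record ", id[nchar(seq) == 0][1])
  if (alphabet == "dna") seq <- validate_dna(seq, "record")
  else {
    seq <- toupper(seq)
    bad <- which(grepl("[^A-Z*]", seq))
    if (length(bad)) stop("record ", id[bad[1]], " is not amino-acid")
  }
  res <- data.frame(id = id, desc = desc, seq = unname(seq),
                    stringsAsFactors = FALSE)
  attr(res, "alphabet") <- alphabet
  class(res) <- c("reference_set", "data.frame")
  res
}

#' Write sequences to FASTA
#'
#' @param ids character vector of record ids.
#' @param seqs character vector of sequences (same length as `ids`).
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(ids, seqs, path, width = 70L) {
  stopifnot(length(ids) == length(seqs))
  set <- Biostrings::BStringSet(as.character(seqs))
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Parse a sample map
#'
#' A sample map is a two-column TSV relating read files to library names
#' (`<read file path>\t<library name>`); `#` comment lines are skipped.
#' Every named file must exist, each file may be listed only once, and the
#' map may not be empty.
#'
#' @param path path to the sample map file.
#' @param check_files verify listed files exist (default TRUE).
#' @return a data.frame with columns `file`, `library`, of class
#'   `sample_map`.
#' @export
parse_sample_map <- function(path, check_files = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0)
    stop("sample map ", path, " defines no libraries")
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    stop("sample map line ", keep[bad[1]], ": expected 2 tab-separated ",
         "columns, found ", lengths(parts)[bad[1]])
  files <- vapply(parts, `[[`, "", 1)
  libs <- trimws(vapply(parts, `[[`, "", 2))
  if (any(libs == ""))
    stop("sample map line ", keep[which(libs == "")[1]],
         ": empty library name")
  dup <- which(duplicated(files))
  if (length(dup))
    stop("sample map line ", keep[dup[1]], ": file listed twice: ",
         files[dup[1]])
  if (check_files) {
    base <- dirname(path)
    resolved <- ifelse(file.exists(files), files, file.path(base, files))
    miss <- which(!file.exists(resolved))
    if (length(miss))
      stop("sample map line ", keep[miss[1]], ": file not found: ",
           files[miss[1]])
    files <- resolved
  }
  res <- data.frame(file = files, library = libs, stringsAsFactors = FALSE)
  class(res) <- c("sample_map", "data.frame")
  res
}

#' Load all reads named by a sample map
#'
#' @param map a `sample_map` from [parse_sample_map()].
#' @return a single reads data.frame with the `library` column filled in.
#' @export
load_sample_reads <- function(map) {
  parts <- lapply(seq_len(nrow(map)), function(i)
    read_fastq(map$file[i], library = map$library[i]))
  reads <- do.call(rbind, parts)
  if (anyDuplicated(reads$id))
    stop("read id(s) duplicated across libraries: ",
         reads$id[duplicated(reads$id)][1])
  reads
}
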