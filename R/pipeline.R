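# End-to-end pipeline orchestration and downstream-tool exports.
#
# The pipeline is a pure function of (input files, configuration, seed):
# identical inputs give byte-identical outputs, verified by the md5
# manifest it returns.  Exports are the universal interchange the
# downstream ecology tools ingest: FASTA for alignment/phylogeny, an
# abundance TSV per level, and a MOTHUR "shared" file.

#' Build a pipeline configuration
#'
#' @param sample_map path to a sample map (see [parse_sample_map()]), or
#'   NULL when `reads` is supplied directly.
#' @param reads a reads data.frame used instead of reading FASTQ files.
#' @param out_dir output directory.
#' @param engine `"olc"` or `"dbg"`.
#' @param seed integer seed recorded in every output header and used for
#'   the down-sampling draw.
#' @param primer_f,primer_r PCR primers to trim (NULL skips trimming).
#' @param reference nucleotide reference set for chimera screening (NULL
#'   with `skip_chimera = FALSE` is an error).
#' @param protein_ref protein reference for frame identification (NULL
#'   uses the longest-ORF fallback).
#' @param skip_chimera skip the split-end chimera screen (default TRUE;
#'   appropriate when the community is not represented in any reference).
#' @param olc,dbg,trim,map named lists overriding stage parameters (passed
#'   to [olc_assemble()], [dbg_assemble()], [trim_primers()],
#'   [map_reads()]).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sample_map = NULL, reads = NULL, out_dir,
                            engine = c("olc", "dbg"), seed = 1,
                            primer_f = NULL, primer_r = NULL,
                            reference = NULL, protein_ref = NULL,
                            skip_chimera = TRUE, olc = list(),
                            dbg = list(), trim = list(), map = list()) {
  engine <- match.arg(engine)
  if (is.null(sample_map) && is.null(reads))
    stop("either sample_map or reads must be supplied")
  if (!skip_chimera && is.null(reference))
    stop("chimera screening requires a reference set")
  structure(list(sample_map = sample_map, reads = reads, out_dir = out_dir,
                 engine = engine, seed = seed, primer_f = primer_f,
                 primer_r = primer_r, reference = reference,
                 protein_ref = protein_ref, skip_chimera = skip_chimera,
                 olc = olc, dbg = dbg, trim = trim, map = map),
            class = "pipeline_config")
}

#' Parse a flat key=value configuration file
#'
#' Lines are `section.key=value` (e.g. `assemble.engine=olc`,
#' `olc.min_overlap_len=100`); `#` comments and blank lines are skipped.
#' Values are converted to numbers or logicals where they parse as such.
#'
#' @param path configuration file path.
#' @return a nested named list of sections.
#' @export
parse_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    else if (val %in% c("true", "TRUE", "false", "FALSE"))
      val <- as.logical(toupper(val))
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) out[[parts]] <- val
    else out[[parts[1]]][[paste(parts[-1], collapse = ".")]] <- val
  }
  out
}

stage_call <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

tsv_header <- function(seed, extra = character(0)) {
  c(paste0("# generated by otuforge ",
           as.character(utils::packageVersion("otuforge"))),
    paste0("# seed: ", seed), paste0("# ", extra))
}

write_abundance_tsv <- function(table, path, seed) {
  hdr <- tsv_header(seed, paste0("libraries: ",
                                 paste(colnames(table), collapse = ",")))
  body <- rbind(cbind(OTU = rownames(table),
                      `attributes<-`(table, list(dim = dim(table)))),
                c("UNMAPPED", attr(table, "unmapped")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("OTU", colnames(table)), collapse = "\t"), con)
  apply(body, 1, function(r) writeLines(paste(r, collapse = "\t"), con))
  invisible(path)
}

#' Export an abundance table in MOTHUR "shared" format
#'
#' Header `label  Group  numOtus  <otu ids...>`, one row per library with
#' the label, library name, OTU count and tab-separated integer counts in
#' a fixed OTU column order.
#'
#' @param table an `abundance_table`.
#' @param path output path.
#' @param label the shared-file label column value (default "asv0").
#' @return `path`, invisibly.
#' @export
export_mothur_shared <- function(table, path, label = "otu") {
  if (nrow(table) == 0) stop("table must be non-empty")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("label", "Group", "numOtus", rownames(table)),
                   collapse = "\t"), con)
  for (j in seq_len(ncol(table)))
    writeLines(paste(c(label, colnames(table)[j], nrow(table),
                       table[, j]), collapse = "\t"), con)
  invisible(path)
}

#' Read a MOTHUR "shared" file back into an abundance table
#'
#' @param path a shared-format file written by [export_mothur_shared()].
#' @return an `abundance_table` (unmapped counts zero).
#' @export
read_mothur_shared <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  hdr <- lines[[1]]
  if (length(hdr) < 4 || !identical(hdr[1:3], c("label", "Group",
                                                "numOtus")))
    stop("not a shared file: ", path)
  otus <- hdr[-(1:3)]
  rows <- lines[-1]
  libs <- vapply(rows, `[[`, "", 2)
  counts <- vapply(rows, function(r) as.integer(r[-(1:3)]),
                   integer(length(otus)))
  counts <- matrix(counts, nrow = length(otus),
                   dimnames = list(otus, libs))
  abundance_table(counts)
}

#' Export FASTA inputs for external alignment and phylogeny tools
#'
#' Writes the nucleotide and peptide OTU sets with the same stable ids
#' used in every abundance table, ready for multiple sequence alignment
#' and tree building.
#'
#' @param otus nucleotide OTU set (see [map_reads()]).
#' @param peptide_otus peptide OTU data.frame from [collapse_peptides()]
#'   (or NULL to skip).
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
export_alignment_and_tree_inputs <- function(otus, peptide_otus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ot <- as_otu_frame(otus)
  if (!nrow(ot)) stop("OTU set must be non-empty")
  p_nt <- file.path(dir, "otus_nt.fasta")
  write_fasta(ot$id, ot$consensus, p_nt)
  p_aa <- file.path(dir, "otus_aa.fasta")
  if (is.null(peptide_otus) || nrow(peptide_otus) == 0) {
    warning("no peptide OTUs; writing empty peptide FASTA")
    file.create(p_aa)
  } else {
    write_fasta(peptide_otus$id, peptide_otus$peptide, p_aa)
  }
  invisible(c(nt = p_nt, aa = p_aa))
}

#' Run the full assembly-and-profiling pipeline
#'
#' Executes trim -> assemble -> map -> (chimera screen) -> dereplicate ->
#' translate -> down-sample -> export, writing every artifact under the
#' configured output directory and returning a manifest of files with
#' content checksums.  Identical configuration and seed reproduce
#' identical checksums.
#'
#' @param config a `pipeline_config` from [pipeline_config()].
#' @return an object of class `pipeline_run`: list with the stage results
#'   (`otus`, `table`, `peptide_otus`, `peptide_table`, `downsampled`,
#'   assignments, reports) and `manifest` (data.frame `file`, `md5`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  reads <- stage_call("load", {
    if (!is.null(config$reads)) config$reads
    else load_sample_reads(parse_sample_map(config$sample_map))
  })

  trim_report <- NULL
  if (!is.null(config$primer_f)) {
    tr <- stage_call("trim", do.call(trim_primers, c(
      list(reads = reads, primer_f = config$primer_f,
           primer_r = config$primer_r), config$trim)))
    reads <- tr$reads
    trim_report <- tr$report
    write.table(trim_report, file.path(out, "trim_report.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  asm <- stage_call("assemble", {
    if (config$engine == "olc")
      do.call(olc_assemble, c(list(reads = reads), config$olc))
    else do.call(dbg_assemble, c(list(reads = reads), config$dbg))
  })
  otus <- as_otu_frame(asm)
  if (nrow(otus) == 0) stop("pipeline stage 'assemble' produced no OTUs")
  if (!is.null(config$primer_f))  # post-assembly primer-remnant sweep
    otus <- stage_call("trim", sweep_otu_primers(
      otus, config$primer_f, config$primer_r))$otus

  assignments <- stage_call("map", do.call(map_reads, c(
    list(reads = reads, otus = otus), config$map)))
  table <- stage_call("map", count_abundance(
    assignments, otu_ids = otus$id))
  write.table(assignments, file.path(out, "assignments.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (inherits(asm, "olc_assembly"))
    write.table(asm$tracking, file.path(out, "tracking.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  chimera_report <- NULL
  if (!config$skip_chimera) {
    verdicts <- stage_call("chimera", c3_classify(otus, config$reference))
    fc <- stage_call("chimera", filter_chimeras(otus, table, verdicts))
    otus <- fc$otus; table <- fc$table; chimera_report <- verdicts
    write.table(verdicts, file.path(out, "chimera_verdicts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (nrow(otus) == 0) stop("pipeline stage 'chimera' removed all OTUs")
  }

  dr <- stage_call("dereplicate", dereplicate_nt(otus, table))
  otus <- dr$otus; table <- dr$table

  frames <- stage_call("translate", find_frames(otus, config$protein_ref))
  cp <- stage_call("translate", collapse_peptides(frames, table))

  ds <- stage_call("downsample", downsample_abundance(table, seed))

  stage_call("export", {
    write_abundance_tsv(table, file.path(out, "abundance_nt.tsv"), seed)
    if (!is.null(cp$table))
      write_abundance_tsv(cp$table, file.path(out, "abundance_aa.tsv"),
                          seed)
    write_abundance_tsv(ds, file.path(out, "abundance_nt_downsampled.tsv"),
                        seed)
    export_mothur_shared(table, file.path(out, "shared_nt.tsv"))
    if (!is.null(cp$table) && nrow(cp$table))
      export_mothur_shared(cp$table, file.path(out, "shared_aa.tsv"),
                           label = "pep")
    export_alignment_and_tree_inputs(otus, cp$peptide_otus, out)
    write.table(frames, file.path(out, "frames.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  })

  files <- sort(list.files(out, full.names = TRUE))
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  structure(list(otus = otus, table = table, assignments = assignments,
                 frames = frames, peptide_otus = cp$peptide_otus,
                 peptide_table = cp$table, downsampled = ds,
                 trim_report = trim_report,
                 chimera_report = chimera_report, manifest = manifest,
                 out_dir = out, seed = seed, engine = config$engine),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("Pipeline run (", x$engine, " engine, seed ", x$seed, ")\n",
      sep = "")
  cat("  ", nrow(x$otus), "nucleotide OTUs,",
      nrow(x$peptide_otus %||% data.frame()), "peptide OTUs\n")
  cat("  ", nrow(x$manifest), "artifacts under", x$out_dir, "\n")
  invisible(x)
}
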