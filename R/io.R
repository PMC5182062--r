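# File-format interfaces: FASTA/FASTQ output, BED/TSV truth ledgers, flat
# key-value configs, and SAM/PAF alignment readers.

#' Write sequences to FASTA (60-column wrap)
#' @param seqs named character vector.
#' @param path output path.
#' @param header_comment optional comment line recorded after each name.
#' @export
write_fasta <- function(seqs, path, header_comment = NULL) {
  x <- Biostrings::DNAStringSet(seqs)
  if (!is.null(header_comment))
    names(x) <- paste(names(x), header_comment)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA path.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  stats::setNames(as.character(x), names(x))
}

#' Write reads to FASTQ (Phred+33, uniform quality)
#' @param reads data.frame from [simulate_reads()].
#' @param path output path (paired reads: `path` gets `_1`/`_2` suffixes).
#' @export
write_fastq <- function(reads, path) {
  emit <- function(names, seqs, p) {
    qual <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
    writeLines(paste0("@", names, "\n", seqs, "\n+\n", qual), p)
  }
  if ("seq2" %in% names(reads)) {
    base <- sub("(\\.[^.]+)?$", "", path)
    ext <- sub(paste0("^", gsub("([.\\\\])", "\\\\\\1", base)), "", path)
    emit(reads$name, reads$seq, paste0(base, "_1", ext))
    emit(reads$name, reads$seq2, paste0(base, "_2", ext))
  } else {
    emit(reads$name, reads$seq, path)
  }
  invisible(path)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param df data.frame with `chromosome`, `start`, `end` (1-based inclusive)
#'   and optional `name`, `score`, `strand` columns.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  bed <- data.frame(chrom = df$chromosome,
                    start = df$start - 1L,
                    end = df$end,
                    name = df$name %||% df$ies_id %||% ".",
                    score = df$score %||% 0L,
                    strand = df$strand %||% ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the ground-truth ledger of a simulated genome
#'
#' Emits `cbs.bed` (with strand), `ies.bed`, `nmc.bed` (all 0-based
#' half-open), a TSV ledger per feature table (1-based), and a flat
#' key-value config file into `dir`.
#'
#' @param truth `rearrangement_truth` object.
#' @param dir output directory (created if needed).
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cbs <- truth$cbs_sites; cbs$name <- cbs$variant
  write_bed(cbs, file.path(dir, "cbs.bed"))
  if (nrow(truth$ies_intervals))
    write_bed(truth$ies_intervals, file.path(dir, "ies.bed"))
  if (nrow(truth$nmc_intervals)) {
    nmc <- truth$nmc_intervals
    nmc$name <- sprintf("nmc%02d", seq_len(nrow(nmc)))
    write_bed(nmc, file.path(dir, "nmc.bed"))
  }
  for (tab in c("cbs_sites", "ies_intervals", "nmc_intervals",
                "gene_intervals", "gene_exons", "mac_segments")) {
    df <- truth[[tab]]
    if (!is.null(df) && nrow(df))
      utils::write.table(df, file.path(dir, paste0(tab, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_flat_config(truth$config, file.path(dir, "sim_config.txt"))
  invisible(dir)
}

write_flat_config <- function(config, path) {
  flat <- vapply(config, function(v)
    paste(format(v, scientific = FALSE, trim = TRUE), collapse = ","),
    character(1))
  writeLines(paste0(names(flat), "\t", flat), path)
  invisible(path)
}

#' Read PAF alignments into alignment blocks
#'
#' Parses the 12 mandatory PAF columns into the block table consumed by the
#' eliminated-sequence and tiling modules. Query is taken as the germline
#' (MIC) side and target as the somatic (MAC) side unless `swap = TRUE`.
#'
#' @param path PAF file.
#' @param swap logical; swap query/target roles.
#' @return data.frame of alignment blocks (`mic_id`, `mic_start`, `mic_end`,
#'   `mac_id`, `mac_start`, `mac_end`, `strand`, `length`, `identity`).
#' @export
read_paf <- function(path, swap = FALSE) {
  raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           fill = TRUE, header = FALSE)[, 1:12]
  names(raw) <- c("qname", "qlen", "qstart", "qend", "strand", "tname",
                  "tlen", "tstart", "tend", "nmatch", "alnlen", "mapq")
  blocks <- data.frame(
    mic_id = raw$qname, mic_start = raw$qstart + 1L, mic_end = raw$qend,
    mac_id = raw$tname, mac_start = raw$tstart + 1L, mac_end = raw$tend,
    strand = raw$strand,
    length = raw$alnlen,
    identity = 100 * raw$nmatch / pmax(raw$alnlen, 1L),
    stringsAsFactors = FALSE)
  if (swap) {
    blocks[, c("mic_id", "mic_start", "mic_end", "mac_id", "mac_start",
               "mac_end")] <-
      blocks[, c("mac_id", "mac_start", "mac_end", "mic_id", "mic_start",
                 "mic_end")]
  }
  blocks
}

#' Read SAM alignments into per-read alignment records
#'
#' Converts a (headered) SAM text file to the per-read alignment table used
#' by the read-evidence IES callers: one row per aligned record with
#' reference interval, strand, and soft-clip lengths at either end.
#'
#' @param path SAM file with `@SQ` headers.
#' @return data.frame with columns `read`, `chrom`, `start`, `end`, `strand`,
#'   `clip_left`, `clip_right`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L)
    return(data.frame(read = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), clip_left = integer(0),
                      clip_right = integer(0)))
  f <- strsplit(lines, "\t")
  rows <- lapply(f, function(x) {
    flag <- as.integer(x[2])
    if (bitwAnd(flag, 4L) > 0L) return(NULL)
    cigar <- x[6]
    ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
    toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
    lens <- as.integer(sub("[A-Z=]$", "", toks))
    kinds <- sub("^[0-9]+", "", toks)
    ref_span <- sum(lens[kinds %in% c("M", "D", "N", "=", "X")])
    data.frame(read = x[1], chrom = x[3], start = as.integer(x[4]),
               end = as.integer(x[4]) + ref_span - 1L,
               strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
               clip_left = if (kinds[1] %in% c("S", "H")) lens[1] else 0L,
               clip_right = if (kinds[length(kinds)] %in% c("S", "H"))
                 lens[length(kinds)] else 0L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
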