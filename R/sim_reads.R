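# Read simulation over simulated genomes, and an endpoint-level simulator of
# progeny-pool excision variability.

#' Simulate sequencing reads from a genome
#'
#' Draws uniformly positioned reads at the requested fold coverage. Single-end
#' mode emulates long somatic (Sanger-like) or short germline (Illumina-like)
#' reads depending on `read_length`; paired mode draws fragments of
#' `frag_insert` bp and reports both ends. Read names encode the true origin
#' (`contig:start:strand:index`) for diagnostics.
#'
#' @param genome named character vector of sequences.
#' @param config a [sim_config()]; `read_length`, `coverage` and
#'   `frag_insert` defaults come from it.
#' @param read_length,coverage,frag_insert overrides of the config values.
#' @param error_rate per-base substitution error probability.
#' @param paired logical, simulate read pairs.
#' @param seed integer seed; defaults to `config$seed + 2`.
#' @return data.frame with columns `name`, `seq` (and `seq2` for pairs).
#'   Contigs shorter than the read (or fragment) length yield no reads.
#' @export
simulate_reads <- function(genome, config,
                           read_length = config$read_length,
                           coverage = config$coverage,
                           frag_insert = config$frag_insert,
                           error_rate = 0, paired = FALSE,
                           seed = config$seed + 2L) {
  stopifnot(coverage > 0)
  if (read_length > max(nchar(genome)))
    stop("read_length ", read_length, " exceeds the longest sequence (",
         max(nchar(genome)), " bp)")
  set.seed(seed)
  out <- list()
  for (contig in names(genome)) {
    L <- nchar(genome[[contig]])
    span <- if (paired) frag_insert else read_length
    if (span > L) next
    n <- round(coverage * L / (read_length * (if (paired) 2 else 1)))
    if (n == 0L) next
    starts <- sample.int(L - span + 1L, n, replace = TRUE)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    if (paired) {
      r1 <- substring(genome[[contig]], starts, starts + read_length - 1L)
      r2 <- revcomp(substring(genome[[contig]], starts + span - read_length,
                              starts + span - 1L))
      swap <- strands == "-"
      tmp <- r1[swap]; r1[swap] <- r2[swap]; r2[swap] <- tmp
      out[[contig]] <- data.frame(
        name = sprintf("%s:%d:%s:%d", contig, starts, strands, seq_len(n)),
        seq = r1, seq2 = r2, stringsAsFactors = FALSE)
    } else {
      r <- substring(genome[[contig]], starts, starts + read_length - 1L)
      r[strands == "-"] <- revcomp(r[strands == "-"])
      out[[contig]] <- data.frame(
        name = sprintf("%s:%d:%s:%d", contig, starts, strands, seq_len(n)),
        seq = r, stringsAsFactors = FALSE)
    }
  }
  reads <- do.call(rbind, out)
  rownames(reads) <- NULL
  if (error_rate > 0 && nrow(reads)) {
    for (col in intersect(c("seq", "seq2"), names(reads)))
      reads[[col]] <- apply_substitution_errors(reads[[col]], error_rate)
  }
  reads
}

apply_substitution_errors <- function(seqs, rate) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    k <- stats::rbinom(1L, n, rate)
    if (k == 0L) return(s)
    pos <- sample.int(n, k)
    for (p in pos) {
      cur <- substr(s, p, p)
      substr(s, p, p) <- sample(setdiff(DNA_BASES, cur), 1L)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate progeny-pool excision endpoints at every IES site
#'
#' Emulates sequencing a pooled population of independently rearranged
#' somatic genomes: at each eliminated-segment site, `n_events` independent
#' excision events draw endpoints from the configured jitter model, and
#' `depth` reads are multinomially assigned to events. Identical endpoint
#' pairs are aggregated with their supporting read counts.
#'
#' @param truth `rearrangement_truth` with junction coordinates.
#' @param config [sim_config()] controlling the jitter model.
#' @param n_events independent rearrangement events per site.
#' @param depth reads sampled per site.
#' @param seed integer seed.
#' @return data.frame with columns `ies_id`, `chromosome`, `obs_start`,
#'   `obs_end`, `n_reads`.
#' @export
simulate_progeny_junctions <- function(truth, config = truth$config,
                                       n_events = 30L, depth = 40L,
                                       seed = config$seed + 3L) {
  set.seed(seed)
  ies <- truth$ies_intervals
  rows <- vector("list", nrow(ies))
  for (i in seq_len(nrow(ies))) {
    dl <- jitter_offsets(n_events, config)
    dr <- jitter_offsets(n_events, config)
    os <- ies$junction_start[i] + dl
    oe <- ies$junction_end[i] + dr
    counts <- as.integer(stats::rmultinom(1L, depth, rep(1, n_events)))
    key <- paste(os, oe)
    agg <- tapply(counts, key, sum)
    parts <- do.call(rbind, strsplit(names(agg), " "))
    rows[[i]] <- data.frame(
      ies_id = ies$ies_id[i], chromosome = ies$chromosome[i],
      obs_start = as.integer(parts[, 1]), obs_end = as.integer(parts[, 2]),
      n_reads = as.integer(agg), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
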