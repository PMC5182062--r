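# Cross-assembly tiling: joining germline scaffolds into chromosome-length
# super-assemblies using somatic contigs that bridge scaffold boundaries,
# plus windowed feature-density tracks.

#' Build a scaffold adjacency graph from cross-assembly alignment blocks
#'
#' When the terminal regions of two germline scaffolds align to adjacent,
#' essentially disjoint intervals of one somatic contig (consistent
#' orientation, separated by at most `max_gap` bp, overlapping by at most
#' `max_overlap` bp), the scaffolds are proposed as neighbours. The
#' symmetric rule proposes somatic-contig joins bridged by one germline
#' scaffold. A scaffold end with more than one distinct proposal is flagged
#' unresolved and contributes no accepted edge (repetitive sequence or
#' mis-assembly).
#'
#' @param blocks alignment blocks ([align_assemblies()] or [read_paf()]).
#' @param mic_lengths named lengths of the germline scaffolds.
#' @param mac_lengths named lengths of the somatic contigs.
#' @param min_identity,min_length block acceptance criteria (defaults 95 /
#'   1000, the published cross-assembly alignment thresholds).
#' @param end_window a block must end within this distance of a scaffold
#'   end to count as terminal (default 100 bp).
#' @param max_gap,max_overlap somatic-side separation limits for a join.
#' @return object of class `scaffold_graph`: list with `edges` (all
#'   proposals, `accepted`/`conflict` flags), `mac_edges` (somatic joins),
#'   and the input lengths.
#' @export
build_adjacency <- function(blocks, mic_lengths, mac_lengths,
                            min_identity = 95, min_length = 1000L,
                            end_window = 100L, max_gap = 2000L,
                            max_overlap = 50L) {
  b <- blocks[blocks$identity > min_identity & blocks$length > min_length, ,
              drop = FALSE]

  propose <- function(axis) {
    # axis "mac": walk each somatic contig, propose germline scaffold joins
    # axis "mic": walk each germline scaffold, propose somatic contig joins
    if (axis == "mac") {
      walk_id <- "mac_id"; walk_start <- "mac_start"; walk_end <- "mac_end"
      join_id <- "mic_id"; join_start <- "mic_start"; join_end <- "mic_end"
      join_len <- mic_lengths
    } else {
      walk_id <- "mic_id"; walk_start <- "mic_start"; walk_end <- "mic_end"
      join_id <- "mac_id"; join_start <- "mac_start"; join_end <- "mac_end"
      join_len <- mac_lengths
    }
    rows <- list()
    for (wid in unique(b[[walk_id]])) {
      sub <- b[b[[walk_id]] == wid, , drop = FALSE]
      sub <- sub[order(sub[[walk_start]]), , drop = FALSE]
      if (nrow(sub) < 2L) next
      for (j in seq_len(nrow(sub) - 1L)) {
        p <- sub[j, ]; q <- sub[j + 1L, ]
        if (p[[join_id]] == q[[join_id]]) next
        sep <- q[[walk_start]] - p[[walk_end]] - 1L
        if (sep > max_gap || sep < -max_overlap) next
        # each block must reach the facing end of its joined sequence
        p_len <- join_len[[p[[join_id]]]]
        q_len <- join_len[[q[[join_id]]]]
        # orientation decides which physical end faces the junction
        p_end <- if (p$strand == "+") "3p" else "5p"
        q_end <- if (q$strand == "+") "5p" else "3p"
        p_ok <- if (p$strand == "+") p_len - p[[join_end]] <= end_window
          else p[[join_start]] - 1L <= end_window
        q_ok <- if (q$strand == "+") q[[join_start]] - 1L <= end_window
          else q_len - q[[join_end]] <= end_window
        if (!p_ok || !q_ok) next
        rows[[length(rows) + 1L]] <- data.frame(
          id1 = p[[join_id]], end1 = p_end, id2 = q[[join_id]], end2 = q_end,
          bridge = wid,
          bridge_type = if (axis == "mac") "mic-join-bridged-by-mac"
            else "mac-join-bridged-by-mic",
          gap = sep, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(id1 = character(0), end1 = character(0),
                        id2 = character(0), end2 = character(0),
                        bridge = character(0), bridge_type = character(0),
                        gap = integer(0))
    out
  }

  finalize <- function(edges) {
    if (!nrow(edges)) {
      edges$support <- integer(0); edges$conflict <- logical(0)
      edges$accepted <- logical(0); return(edges)
    }
    # collapse duplicate proposals (multiple bridges for the same join)
    key <- apply(edges[, c("id1", "end1", "id2", "end2")], 1L, function(r) {
      a <- paste(r[1], r[2]); c2 <- paste(r[3], r[4])
      paste(sort(c(a, c2)), collapse = " | ")
    })
    agg <- do.call(rbind, lapply(split(seq_len(nrow(edges)), key), function(ix) {
      e <- edges[ix[1], , drop = FALSE]
      e$support <- length(ix)
      e$bridge <- paste(unique(edges$bridge[ix]), collapse = ",")
      e
    }))
    ends <- c(paste(agg$id1, agg$end1), paste(agg$id2, agg$end2))
    conflict_ends <- names(which(table(ends) > 1L))
    agg$conflict <- paste(agg$id1, agg$end1) %in% conflict_ends |
      paste(agg$id2, agg$end2) %in% conflict_ends
    agg$accepted <- !agg$conflict
    rownames(agg) <- NULL
    agg
  }

  structure(list(edges = finalize(propose("mac")),
                 mac_edges = finalize(propose("mic")),
                 mic_lengths = mic_lengths, mac_lengths = mac_lengths),
            class = "scaffold_graph")
}

#' @export
print.scaffold_graph <- function(x, ...) {
  cat(sprintf(
    "Scaffold graph: %d germline-join proposal(s) (%d accepted, %d in conflict)\n",
    nrow(x$edges), sum(x$edges$accepted), sum(x$edges$conflict)))
  cat(sprintf("  %d somatic-join proposal(s)\n", nrow(x$mac_edges)))
  invisible(x)
}

#' Order and orient scaffolds into super-assembly paths
#'
#' Walks the accepted adjacency edges into simple paths: one path per
#' connected component, each scaffold oriented so that consecutive ends
#' face each other. A cycle among accepted edges is an error (its edges
#' are listed). Unplaced scaffolds become singleton paths.
#'
#' @param graph a [build_adjacency()] result.
#' @param scaffolds named character vector of scaffold sequences (optional;
#'   enables joined FASTA output).
#' @param spacer_n number of `N` bases written between joined scaffolds in
#'   the layout/FASTA (default 100).
#' @return list: `paths` (data.frame path_id, order, scaffold,
#'   orientation), `layout` (AGP-like 1-based table with gap rows),
#'   `sequences` (joined super-assembly sequences, if `scaffolds` given),
#'   `unplaced`, `total_placed_length`.
#' @export
emit_superassembly <- function(graph, scaffolds = NULL, spacer_n = 100L) {
  edges <- graph$edges[graph$edges$accepted, , drop = FALSE]
  ids <- names(graph$mic_lengths)
  # detect cycles on the scaffold-level multigraph
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("id1", "id2")],
                                       directed = FALSE,
                                       vertices = ids)
    comp <- igraph::components(g)
    for (k in seq_len(comp$no)) {
      members <- names(comp$membership)[comp$membership == k]
      n_edges <- sum(edges$id1 %in% members | edges$id2 %in% members)
      if (n_edges >= length(members))
        stop("cycle detected among accepted joins: ",
             paste(paste(edges$id1[edges$id1 %in% members],
                         edges$id2[edges$id1 %in% members], sep = "--"),
                   collapse = ", "))
    }
  }
  # adjacency lookup per scaffold end
  edge_at <- list()
  for (j in seq_len(nrow(edges))) {
    e <- edges[j, ]
    edge_at[[paste(e$id1, e$end1)]] <- list(to = e$id2, to_end = e$end2)
    edge_at[[paste(e$id2, e$end2)]] <- list(to = e$id1, to_end = e$end1)
  }
  used <- character(0)
  paths <- list()
  for (seed_id in ids) {
    if (seed_id %in% used) next
    # walk left from the seed to a terminus, then right along the path
    cur <- seed_id; cur_or <- "+"; seen <- cur
    repeat {
      back_end <- if (cur_or == "+") "5p" else "3p"
      prev <- edge_at[[paste(cur, back_end)]]
      if (is.null(prev) || prev$to %in% seen) break
      cur_or <- if (prev$to_end == "3p") "+" else "-"
      cur <- prev$to
      seen <- c(seen, cur)
    }
    # now walk forward collecting the path
    path <- data.frame(scaffold = cur, orientation = cur_or,
                       stringsAsFactors = FALSE)
    used <- c(used, cur)
    repeat {
      fwd_end <- if (cur_or == "+") "3p" else "5p"
      nxt <- edge_at[[paste(cur, fwd_end)]]
      if (is.null(nxt) || nxt$to %in% used) break
      cur <- nxt$to
      cur_or <- if (nxt$to_end == "5p") "+" else "-"
      path <- rbind(path, data.frame(scaffold = cur, orientation = cur_or,
                                     stringsAsFactors = FALSE))
      used <- c(used, cur)
    }
    paths[[length(paths) + 1L]] <- path
  }
  path_df <- do.call(rbind, lapply(seq_along(paths), function(i) {
    p <- paths[[i]]
    data.frame(path_id = sprintf("superasm%02d", i), order = seq_len(nrow(p)),
               scaffold = p$scaffold, orientation = p$orientation,
               stringsAsFactors = FALSE)
  }))
  multi <- unlist(lapply(paths, function(p)
    if (nrow(p) > 1L) p$scaffold else character(0)))
  layout_rows <- list()
  seqs <- NULL
  if (!is.null(scaffolds)) seqs <- character(length(paths))
  for (i in seq_along(paths)) {
    p <- paths[[i]]
    pos <- 0L; part <- 0L
    pieces <- character(0)
    for (j in seq_len(nrow(p))) {
      if (j > 1L) {
        part <- part + 1L
        layout_rows[[length(layout_rows) + 1L]] <- data.frame(
          object = sprintf("superasm%02d", i), object_beg = pos + 1L,
          object_end = pos + spacer_n, part = part, type = "N",
          id = "scaffold-join-gap", orientation = ".",
          stringsAsFactors = FALSE)
        pos <- pos + spacer_n
        pieces <- c(pieces, strrep("N", spacer_n))
      }
      len <- graph$mic_lengths[[p$scaffold[j]]]
      part <- part + 1L
      layout_rows[[length(layout_rows) + 1L]] <- data.frame(
        object = sprintf("superasm%02d", i), object_beg = pos + 1L,
        object_end = pos + len, part = part, type = "W",
        id = p$scaffold[j], orientation = p$orientation[j],
        stringsAsFactors = FALSE)
      pos <- pos + len
      if (!is.null(scaffolds)) {
        s <- scaffolds[[p$scaffold[j]]]
        pieces <- c(pieces, if (p$orientation[j] == "-") revcomp(s) else s)
      }
    }
    if (!is.null(scaffolds)) seqs[i] <- paste(pieces, collapse = "")
  }
  if (!is.null(seqs)) names(seqs) <- sprintf("superasm%02d", seq_along(paths))
  list(paths = path_df,
       layout = do.call(rbind, layout_rows),
       sequences = seqs,
       unplaced = setdiff(ids, multi),
       total_placed_length = sum(unlist(graph$mic_lengths[multi])))
}

#' Windowed feature-density track
#'
#' Covered base pairs (union of overlapping feature spans, clipped to the
#' window) per sliding window along each chromosome. The final partial
#' window is included and flagged.
#'
#' @param features data.frame with `chromosome`, `start`, `end` (1-based
#'   inclusive).
#' @param chrom_lengths named integer vector.
#' @param window window span in bp (default 500 kb).
#' @param step slide increment in bp (default 100 kb).
#' @return data.frame: `chromosome`, `start`, `end`, `covered_bp`,
#'   `partial`.
#' @export
windowed_density <- function(features, chrom_lengths, window = 500000L,
                             step = 100000L) {
  stopifnot(window >= step)
  rows <- list()
  for (chrom in names(chrom_lengths)) {
    L <- chrom_lengths[[chrom]]
    f <- features[features$chromosome == chrom, , drop = FALSE]
    if (nrow(f) && any(f$end > L | f$start < 1L))
      stop("feature beyond chromosome end on ", chrom)
    covered <- S4Vectors::Rle(FALSE, L)
    if (nrow(f)) {
      red <- IRanges::reduce(IRanges::IRanges(f$start, f$end))
      covered <- IRanges::coverage(red, width = L) > 0L
    }
    starts <- seq(1L, max(1L, L), by = step)
    starts <- starts[starts <= L]
    ends <- pmin(starts + window - 1L, L)
    vals <- vapply(seq_along(starts), function(i)
      as.numeric(sum(covered[starts[i]:ends[i]])), numeric(1))
    rows[[length(rows) + 1L]] <- data.frame(
      chromosome = chrom, start = starts, end = ends, covered_bp = vals,
      partial = (ends - starts + 1L) < window, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a density track as bedGraph
#' @param track [windowed_density()] output.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  utils::write.table(
    data.frame(track$chromosome, track$start - 1L, track$end,
               track$covered_bp),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
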