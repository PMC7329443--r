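# Shared readers/writers. All tables are TSV with a header; '#' lines are
# comments. Genomic intervals are 0-based half-open (bedGraph convention).

#' Write a table as TSV
#'
#' @param x `data.frame` (matrix columns are flattened by the caller).
#' @param path Output file.
#' @param comments Optional character vector written as leading `#` lines.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#'
#' @param path File to read.
#' @return `data.frame`.
#' @export
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Read a gene annotation table
#'
#' Expects the columns of [generate_gene_table()] (`gene_id`, `length`,
#' `reads` at minimum).
#'
#' @param path TSV file.
#' @param read_length Read length attached as attribute (default 100).
#' @return Gene table `data.frame`.
#' @export
read_gene_table <- function(path, read_length = 100) {
  g <- read_tsv(path)
  need <- c("gene_id", "length", "reads")
  if (!all(need %in% names(g)))
    stop("read_gene_table: missing column(s): ",
         paste(setdiff(need, names(g)), collapse = ", "))
  attr(g, "read_length") <- read_length
  g
}

#' Read a FASTA file
#'
#' Wrapped lines are joined; sequences are uppercased; duplicate ids and
#' empty files are errors.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("read_fasta: empty file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("read_fasta: duplicate ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  setNames(toupper(as.character(set)), ids)
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @param width Line wrap width (default 70).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read a bedGraph coverage track
#'
#' Four columns (contig, start, end, depth), 0-based half-open. Intervals
#' are validated per contig: `end > start`, no overlaps; gaps are filled
#' with depth-0 cells of the track's cell size, with a warning.
#'
#' @param path bedGraph file (plain TSV, `#` comments allowed, no track
#'   header line).
#' @return A `coverage_track` `data.frame(contig, start, end, depth)` with
#'   attribute `cell` when cells are uniform.
#' @export
read_bedgraph <- function(path) {
  x <- read.delim(path, header = FALSE, comment.char = "#",
                  stringsAsFactors = FALSE)
  if (ncol(x) != 4) stop("read_bedgraph: expected 4 columns, got ", ncol(x))
  names(x) <- c("contig", "start", "end", "depth")
  if (any(x$end <= x$start))
    stop("read_bedgraph: interval end <= start")
  pieces <- lapply(split(x, x$contig), function(tr) {
    tr <- tr[order(tr$start), ]
    if (nrow(tr) > 1 && any(tr$start[-1] < tr$end[-nrow(tr)]))
      stop("read_bedgraph: overlapping intervals on ", tr$contig[1])
    gaps <- which(tr$start[-1] > tr$end[-nrow(tr)])
    if (length(gaps)) {
      warning("read_bedgraph: ", length(gaps), " gap(s) on ", tr$contig[1],
              " treated as depth 0")
      cell <- tr$end[1] - tr$start[1]
      fills <- do.call(rbind, lapply(gaps, function(i) {
        s <- seq(tr$end[i], tr$start[i + 1] - 1, by = cell)
        data.frame(contig = tr$contig[1], start = s,
                   end = pmin(s + cell, tr$start[i + 1]), depth = 0,
                   stringsAsFactors = FALSE)
      }))
      tr <- rbind(tr, fills)
      tr <- tr[order(tr$start), ]
    }
    tr
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  widths <- unique(out$end - out$start)
  structure(out, class = c("coverage_track", "data.frame"),
            cell = if (length(widths) == 1) widths else NULL)
}

#' Write a coverage track as bedGraph
#'
#' @param track `data.frame(contig, start, end, depth)`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_bedgraph <- function(track, path) {
  write.table(track[, c("contig", "start", "end", "depth")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a contig stats table with tetranucleotide columns
#'
#' Inverse of the flat layout written by [write_community_files()]:
#' columns named after canonical 4-mers are gathered back into the `tetra`
#' matrix column.
#'
#' @param path TSV file.
#' @return Contig stats `data.frame` with a `tetra` matrix column.
#' @export
read_contig_table <- function(path) {
  x <- read_tsv(path)
  kmers <- intersect(canonical_tetramers(), names(x))
  if (length(kmers)) {
    tet <- as.matrix(x[, kmers])
    rownames(tet) <- x$contig_id
    x <- x[, setdiff(names(x), kmers), drop = FALSE]
    x$tetra <- tet
  }
  x
}
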