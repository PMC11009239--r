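# Readers and writers for the pipeline's on-disk formats: FASTA (genomes and
# LTR libraries), BED6 (intervals and truth), MAF (alignment blocks),
# BedGraph-dialect TSV (coverage), presence TSV. Coordinates on disk are
# 0-based half-open throughout (BED/MAF convention), matching the in-memory
# tables.

#' Write / read genome FASTA
#'
#' @param genome named character vector, `DNAStringSet` or `sim_genome`.
#' @param path file path.
#' @return `read_genome_fasta()` returns a named character vector.
#' @export
write_genome_fasta <- function(genome, path) {
  genome <- .as_character_genome(genome)
  dss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(dss, path, width = 80L)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  out <- as.character(dss)
  names(out) <- sub("\\s.*$", "", names(dss))
  out
}

#' Write / read an LTR library FASTA (`>id#FAMILY` header dialect)
#'
#' @param library an `ltr_library` (or data.frame with `id`/`family`/`sequence`).
#' @param path file path.
#' @return `read_library_fasta()` returns an `ltr_library`-classed data.frame
#'   (family parsed from the token after `#`; `"unknown"` when absent).
#' @export
write_library_fasta <- function(library, path) {
  dss <- Biostrings::DNAStringSet(library$sequence)
  names(dss) <- paste0(library$id, "#", library$family)
  Biostrings::writeXStringSet(dss, path, width = 80L)
  invisible(path)
}

#' @rdname write_library_fasta
#' @export
read_library_fasta <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  hdr <- sub("\\s.*$", "", names(dss))
  has_fam <- grepl("#", hdr, fixed = TRUE)
  out <- data.frame(
    id = sub("#.*$", "", hdr),
    family = ifelse(has_fam, sub("^[^#]*#", "", hdr), "unknown"),
    sequence = as.character(dss), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("ltr_library", "data.frame"))
}

#' Write / read BED6
#'
#' @param df data.frame with `scaffold`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @param path file path.
#' @return `read_bed()` returns a data.frame with those six columns.
#' @export
write_bed <- function(df, path) {
  .check_intervals(df)
  out <- data.frame(df$scaffold, df$start, df$end,
                    df$name %||% ".", df$score %||% 0L, df$strand %||% ".")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("scaffold", "start", "end",
                                        "name", "score", "strand")[1:6])
  df
}

#' Write simulator truth as BED6 (`name` = element_id|kind|family)
#'
#' @param truth truth table from [simulate_genome()].
#' @param path file path.
#' @export
write_truth_bed <- function(truth, path) {
  df <- data.frame(scaffold = truth$scaffold, start = truth$start,
                   end = truth$end,
                   name = paste(truth$element_id, truth$kind, truth$family, sep = "|"),
                   score = 0L, strand = truth$strand, stringsAsFactors = FALSE)
  write_bed(df, path)
}

#' Write / read alignment blocks as MAF
#'
#' Blocks are the long-format table used by [classify_sharing()] (`block_id`,
#' `species`, `scaffold`, `start`, `end`, `strand`, `src_size`); the `s` line
#' `src` field is `species.scaffold`. Aligned text is emitted as a gapless
#' placeholder of `N`s: these blocks carry coordinate bookkeeping (from exact
#' simulation), not residue-level alignments.
#'
#' @param blocks block table.
#' @param path file path.
#' @return `read_maf()` returns a block table.
#' @export
write_maf <- function(blocks, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1 scoring=none", con)
  for (b in unique(blocks$block_id)) {
    rows <- blocks[blocks$block_id == b, , drop = FALSE]
    writeLines("a score=0", con)
    for (i in seq_len(nrow(rows))) {
      size <- as.integer(rows$end[i] - rows$start[i])
      writeLines(sprintf("s %s.%s %d %d %s %d %s",
                         rows$species[i], rows$scaffold[i],
                         as.integer(rows$start[i]), size,
                         rows$strand[i] %||% "+",
                         as.integer(rows$src_size[i] %||% rows$end[i]),
                         strrep("N", min(size, 1L))), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname write_maf
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  out <- NULL
  bid <- 0L
  in_block <- FALSE
  for (ln in lines) {
    if (startsWith(ln, "a")) {
      bid <- bid + 1L
      in_block <- TRUE
    } else if (startsWith(ln, "s ") && in_block) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      src <- f[2]
      dot <- regexpr(".", src, fixed = TRUE)
      species <- substr(src, 1, dot - 1L)
      scaffold <- substr(src, dot + 1L, nchar(src))
      start <- as.integer(f[3]); size <- as.integer(f[4])
      out <- rbind(out, data.frame(
        block_id = sprintf("block_%04d", bid), species = species,
        scaffold = scaffold, start = start, end = start + size,
        strand = f[5], src_size = as.integer(f[6]), stringsAsFactors = FALSE))
    } else if (!nzchar(trimws(ln))) {
      in_block <- FALSE
    }
  }
  if (is.null(out)) .stopf("no alignment blocks found in %s", path)
  rownames(out) <- NULL
  out
}

#' Write / read per-individual coverage as BedGraph-dialect TSV
#'
#' Four columns (scaffold, start, end, depth), 0-based half-open, run-length
#' encoded. `read_coverage_bedgraph()` needs the scaffold lengths to expand
#' back to per-position vectors (uncovered positions are depth 0).
#'
#' @param track named list of per-scaffold integer depth vectors (one
#'   individual).
#' @param path file path.
#' @param scaffold_lengths named vector of scaffold lengths.
#' @return `read_coverage_bedgraph()` returns a named list of per-scaffold
#'   integer depth vectors.
#' @export
write_coverage_bedgraph <- function(track, path) {
  rows <- NULL
  for (s in names(track)) {
    r <- rle(track[[s]])
    en <- cumsum(r$lengths)
    st <- en - r$lengths
    keep <- r$values != 0
    if (any(keep)) {
      rows <- rbind(rows, data.frame(scaffold = s, start = st[keep],
                                     end = en[keep], depth = r$values[keep]))
    }
  }
  if (is.null(rows)) rows <- data.frame(scaffold = character(0), start = integer(0),
                                        end = integer(0), depth = integer(0))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_coverage_bedgraph
#' @export
read_coverage_bedgraph <- function(path, scaffold_lengths) {
  track <- lapply(scaffold_lengths, function(n) integer(n))
  names(track) <- names(scaffold_lengths)
  if (file.size(path) > 0) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            col.names = c("scaffold", "start", "end", "depth"),
                            stringsAsFactors = FALSE)
    for (i in seq_len(nrow(df))) {
      track[[df$scaffold[i]]][(df$start[i] + 1L):df$end[i]] <- df$depth[i]
    }
  }
  track
}

#' Write / read a presence matrix TSV
#'
#' @param pm a `presence_matrix` or logical matrix.
#' @param path file path.
#' @return `read_presence_tsv()` returns a logical matrix (elements x
#'   individuals).
#' @export
write_presence_tsv <- function(pm, path) {
  m <- if (inherits(pm, "presence_matrix")) pm$present else pm
  df <- data.frame(element_id = rownames(m), ifelse(m, 1L, 0L),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_tsv
#' @export
read_presence_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE]) == 1
  rownames(m) <- df$element_id
  m
}
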