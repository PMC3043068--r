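#' Build a sequence-record tibble
#'
#' The package's common currency is a tibble with one row per sequence
#' record: `id` (unique label), `bases` (nucleotide string over A/C/G/T/N),
#' and optionally `quality` (Phred+33-encoded string, same length as
#' `bases`), `source` (dataset of origin, e.g. a cell label or
#' `"enrichment"`) and `mate` (id of the paired read). All functions that
#' take reads or contigs accept this shape.
#'
#' @param id Character vector of unique record ids.
#' @param bases Character vector of sequences (uppercased; non-ACGT become N).
#' @param quality Optional character vector of Phred+33 quality strings.
#' @param source Optional character vector of dataset labels.
#' @param mate Optional character vector of mate read ids (`NA` = unpaired).
#' @return A tibble with columns `id`, `bases`, `quality`, `source`, `mate`.
#' @examples
#' seq_tbl(c("a", "b"), c("ACGT", "GGCC"))
#' @export
seq_tbl <- function(id, bases, quality = NULL, source = NULL, mate = NULL) {
  id <- as.character(id)
  bases <- normalise_bases(as.character(bases))
  n <- length(id)
  if (length(bases) != n) abort("`id` and `bases` lengths differ")
  if (anyDuplicated(id)) abort("record ids must be unique")
  if (any(!nzchar(bases))) abort("empty sequences are not allowed")
  if (!is.null(quality)) {
    bad <- !is.na(quality) & nchar(quality) != nchar(bases)
    if (any(bad)) {
      abort(sprintf("quality length differs from sequence length for '%s'",
                    id[which(bad)[1]]))
    }
  }
  tb <- tibble(
    id = id, bases = bases,
    quality = if (is.null(quality)) NA_character_ else as.character(quality),
    source = if (is.null(source)) NA_character_ else as.character(source),
    mate = if (is.null(mate)) NA_character_ else as.character(mate)
  )
  validate_pairing(tb)
  tb
}

validate_pairing <- function(reads) {
  m <- reads$mate
  if (all(is.na(m))) return(invisible(reads))
  paired <- !is.na(m)
  back <- reads$mate[match(m[paired], reads$id)]
  if (any(is.na(back)) || any(back != reads$id[paired])) {
    abort("pairing must be symmetric: mate of my mate must be me")
  }
  invisible(reads)
}

#' Convert Phred+33 quality strings to integer scores
#'
#' @param quality Character vector of Phred+33 strings (NA allowed).
#' @return List of integer vectors (NULL for NA input).
#' @export
phred_to_int <- function(quality) {
  lapply(quality, function(q) {
    if (is.na(q)) return(NULL)
    utf8ToInt(q) - 33L
  })
}

#' @rdname phred_to_int
#' @param scores List of integer vectors of Phred scores.
#' @export
int_to_phred <- function(scores) {
  vapply(scores, function(s) intToUtf8(pmin(s, 93L) + 33L), character(1))
}

#' Read and write FASTA files
#'
#' `read_fasta()` returns one record per entry; the header token before the
#' first whitespace becomes the id and sequences are uppercased (ambiguity
#' codes become N). `write_fasta()` is its inverse.
#'
#' @param path File path.
#' @return `read_fasta()`: a sequence-record tibble (see [seq_tbl()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0) return(seq_tbl(character(), character()))
  hdr <- startsWith(lines, ">")
  if (!hdr[1]) abort(sprintf("parse error at line 1: expected '>' header, got '%s'",
                             substr(lines[1], 1, 40)))
  bad_hdr <- which(hdr & !grepl("^>\\S", lines))
  if (length(bad_hdr)) {
    abort(sprintf("parse error at line %d: malformed FASTA header", bad_hdr[1]))
  }
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  bases <- as.character(x)
  empty <- which(!nzchar(bases))
  if (length(empty)) {
    abort(sprintf("parse error near line %d: empty sequence for record '%s'",
                  which(hdr)[empty[1]], ids[empty[1]]))
  }
  seq_tbl(ids, bases)
}

#' @rdname read_fasta
#' @param records Sequence-record tibble.
#' @param width Line-wrap width for sequence lines.
#' @export
write_fasta <- function(records, path, width = 70) {
  x <- Biostrings::DNAStringSet(records$bases)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read and write FASTQ files (Phred+33)
#'
#' Four-line FASTQ records; qualities must match sequence lengths.
#'
#' @param path File path.
#' @param source Optional dataset label to attach to all reads.
#' @return `read_fastq()`: a sequence-record tibble with `quality` set.
#' @export
read_fastq <- function(path, source = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (length(lines) == 0) {
    return(seq_tbl(character(), character()))
  }
  if (length(lines) %% 4 != 0) {
    abort("parse error: FASTQ file length is not a multiple of 4 lines")
  }
  ids <- sub("^@", "", sub("\\s.*$", "", lines[seq(1, length(lines), 4)]))
  bases <- lines[seq(2, length(lines), 4)]
  qual <- lines[seq(4, length(lines), 4)]
  mismatch <- which(nchar(bases) != nchar(qual))
  if (length(mismatch)) {
    abort(sprintf(
      "parse error at line %d: quality length %d != sequence length %d for '%s'",
      (mismatch[1] - 1) * 4 + 4, nchar(qual[mismatch[1]]),
      nchar(bases[mismatch[1]]), ids[mismatch[1]]))
  }
  seq_tbl(ids, bases, quality = qual,
          source = if (is.null(source)) NULL else rep(source, length(ids)))
}

#' @rdname read_fastq
#' @param reads Sequence-record tibble with `quality` populated.
#' @export
write_fastq <- function(reads, path) {
  qual <- ifelse(is.na(reads$quality),
                 vapply(nchar(reads$bases),
                        function(n) strrep(rawToChar(as.raw(63L)), n),
                        character(1)),
                 reads$quality)
  out <- character(4 * nrow(reads))
  out[seq(1, length(out), 4)] <- paste0("@", reads$id)
  out[seq(2, length(out), 4)] <- reads$bases
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- qual
  writeLines(out, path)
  invisible(path)
}

#' Barcode specifications for demultiplexing
#'
#' One row per sample: a fixed-length barcode (default 10 bp) read off the
#' 5' end of each read, matched with up to `max_mismatch` errors.
#'
#' @param sample Character vector of sample names.
#' @param barcode Character vector of barcodes (equal lengths).
#' @param max_mismatch Maximum Hamming mismatches tolerated (default 1,
#'   i.e. one error in each 10 bp barcode).
#' @return A tibble with columns `sample`, `barcode`, `max_mismatch`.
#' @export
barcode_spec <- function(sample, barcode, max_mismatch = 1L) {
  barcode <- toupper(barcode)
  if (length(unique(nchar(barcode))) > 1) {
    abort("all barcodes must have the same length")
  }
  if (max_mismatch >= nchar(barcode[1])) {
    abort("`max_mismatch` must be smaller than the barcode length")
  }
  tibble(sample = as.character(sample), barcode = barcode,
         max_mismatch = as.integer(max_mismatch))
}

#' Demultiplex reads by 5' sample barcode
#'
#' A read is assigned to the sample whose barcode is within `max_mismatch`
#' Hamming distance of the read's leading bases; the barcode is trimmed from
#' assigned reads. Barcodes must be pairwise separated by more than
#' `2 * max_mismatch` so that assignment is unambiguous.
#'
#' @param reads Sequence-record tibble.
#' @param specs Barcode table from [barcode_spec()].
#' @return A list with `samples` (named list of read tibbles, barcode
#'   trimmed, `source` set to the sample) and `rejected` (unassigned reads).
#' @export
demultiplex <- function(reads, specs) {
  blen <- nchar(specs$barcode[1])
  mm <- specs$max_mismatch[1]
  nb <- nrow(specs)
  if (nb > 1) {
    for (i in seq_len(nb - 1)) {
      for (j in seq(i + 1, nb)) {
        if (hamming(specs$barcode[i], specs$barcode[j]) <= 2 * mm) {
          abort(sprintf(
            "barcodes '%s' and '%s' are within 2*max_mismatch; assignment would be ambiguous",
            specs$barcode[i], specs$barcode[j]))
        }
      }
    }
  }
  prefix <- substr(reads$bases, 1, blen)
  pm <- vapply(specs$barcode, function(b) {
    bv <- strsplit(b, "")[[1]]
    vapply(strsplit(prefix, ""), function(p) {
      if (length(p) < blen) return(blen)
      sum(p[seq_len(blen)] != bv)
    }, integer(1))
  }, integer(nrow(reads)))
  pm <- matrix(pm, nrow = nrow(reads))
  best <- apply(pm, 1, which.min)
  bestd <- pm[cbind(seq_len(nrow(reads)), best)]
  assigned <- bestd <= mm
  samples <- lapply(seq_len(nb), function(k) {
    sel <- which(assigned & best == k)
    out <- reads[sel, , drop = FALSE]
    out$bases <- substr(out$bases, blen + 1, nchar(out$bases))
    out$quality <- ifelse(is.na(out$quality), NA_character_,
                          substr(out$quality, blen + 1, nchar(out$quality)))
    keep <- nzchar(out$bases)
    out$source <- rep(specs$sample[k], nrow(out))
    out[keep, , drop = FALSE]
  })
  names(samples) <- specs$sample
  list(samples = samples, rejected = reads[!assigned, , drop = FALSE])
}
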