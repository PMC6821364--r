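## File formats and read demultiplexing. Sequencing reads carry an 8 bp
## sample barcode followed by the randomized operator region; quality
## strings are read but ignored throughout.

#' Read a FASTQ file
#' @param path FASTQ file (Sanger Phred+33; qualities are ignored).
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Write reads as FASTQ
#' @param seqs character vector of sequences.
#' @param path output file.
#' @param ids read identifiers; defaults to `read1..readN`.
#' @export
write_fastq <- function(seqs, path, ids = NULL) {
  ids <- ids %||% paste0("read", seq_along(seqs))
  out <- character(4L * length(seqs))
  out[seq(1L, length(out), 4L)] <- paste0("@", ids)
  out[seq(2L, length(out), 4L)] <- seqs
  out[seq(3L, length(out), 4L)] <- "+"
  out[seq(4L, length(out), 4L)] <- strrep("I", nchar(seqs))
  writeLines(out, path)
  invisible(path)
}

#' Demultiplex reads by exact 8 bp barcode and extract the randomized region
#'
#' Each read's first eight bases are compared against the barcode map;
#' reads whose barcode matches no sample, or whose extracted region
#' contains an ambiguous base, are routed to the discard tally. The sum of
#' per-sample read counts plus discards always equals the input read count.
#'
#' @param reads character vector of full-length reads (or a FASTQ path).
#' @param barcode_map named character vector: names are 8 bp barcodes,
#'   values are sample identifiers.
#' @param region_span `c(start, end)` 1-based inclusive coordinates of the
#'   randomized region within the read; `end = NA` runs to the read end
#'   (regions of 16-19 bp vary with the library length).
#' @param max_mismatch barcode mismatches tolerated (0 by default; if
#'   positive, a read is assigned to the uniquely nearest barcode within
#'   the budget and discarded on ties).
#' @return list with `samples` (named list of random-region character
#'   vectors), `tally` (per-sample counts), `discarded` and `n_input`.
#' @export
demultiplex <- function(reads, barcode_map, region_span = c(9L, NA),
                        max_mismatch = 0L) {
  if (length(reads) == 1L && file.exists(reads)) reads <- read_fastq(reads)
  if (anyDuplicated(names(barcode_map)))
    stop("duplicate barcode in barcode map")
  if (any(nchar(names(barcode_map)) != 8L))
    stop("barcodes must be exactly 8 bp")
  n_input <- length(reads)
  samples <- stats::setNames(vector("list", length(barcode_map)),
                             unname(barcode_map))
  for (i in seq_along(samples)) samples[[i]] <- character(0)
  if (n_input == 0L) {
    return(list(samples = samples,
                tally = stats::setNames(rep(0L, length(barcode_map)),
                                        unname(barcode_map)),
                discarded = 0L, n_input = 0L))
  }
  bc <- substr(reads, 1L, 8L)
  if (max_mismatch == 0L) {
    hit <- match(bc, names(barcode_map))
  } else {
    d <- adist(bc, names(barcode_map),
               costs = list(ins = 100, del = 100, sub = 1))
    best <- apply(d, 1L, min)
    hit <- apply(d, 1L, which.min)
    ties <- rowSums(d == best) > 1L
    hit[best > max_mismatch | ties] <- NA_integer_
  }
  start <- region_span[1L]
  end <- region_span[2L]
  region <- if (is.na(end)) substring(reads, start) else substring(reads, start, end)
  ok <- !is.na(hit) & !grepl("[^ACGT]", region)
  for (i in seq_along(barcode_map)) {
    samples[[unname(barcode_map)[i]]] <- region[which(ok & hit == i)]
  }
  tally <- vapply(samples, length, integer(1L))
  list(samples = samples, tally = tally,
       discarded = n_input - sum(tally), n_input = n_input)
}

#' Read an aligned (gap-filled) FASTA file
#'
#' Ingests the output of an external multiple sequence aligner. All records
#' must share one aligned length; sequences are upper-cased and restricted
#' to the {A, C, G, T, -} alphabet.
#'
#' @param path FASTA file.
#' @return named character vector with attribute `aligned_length`.
#' @export
read_aligned_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  if (length(seqs) == 0L) {
    return(structure(stats::setNames(character(0), character(0)),
                     aligned_length = NA_integer_))
  }
  w <- unname(nchar(seqs))
  if (length(unique(w)) != 1L) {
    off <- names(seqs)[which(w != w[1L])[1L]]
    stop(sprintf("ragged alignment: record '%s' has length %d, expected %d",
                 off, nchar(seqs[[which(w != w[1L])[1L]]]), w[1L]))
  }
  bad <- grepl("[^ACGT-]", seqs)
  if (any(bad))
    stop(sprintf("record '%s' contains characters outside {A,C,G,T,-}",
                 names(seqs)[which(bad)[1L]]))
  structure(seqs, aligned_length = w[1L])
}

#' Write gap-filled sequences as aligned FASTA
#' @param seqs named character vector over {A,C,G,T,-}.
#' @param path output file.
#' @export
write_aligned_fasta <- function(seqs, path) {
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  writeLines(paste0(">", ids, "\n", seqs), path)
  invisible(path)
}

#' Write a position weight matrix to a motif file
#'
#' @param pwm a [pwm] object (or bare 4 x W probability matrix).
#' @param path output file.
#' @param dialect `"meme"` (MEME minimal motif format) or `"tab"`
#'   (tab-separated matrix with a wildcard flag column).
#' @param name motif name recorded in the file.
#' @export
write_motif <- function(pwm, path, dialect = c("meme", "tab"), name = "motif1") {
  dialect <- match.arg(dialect)
  mat <- if (inherits(pwm, "pwm")) pwm$mat else pwm
  wild <- if (inherits(pwm, "pwm")) pwm$wildcard else rep(FALSE, ncol(mat))
  if (max(abs(colSums(mat) - 1)) > 1e-6)
    stop("PWM columns must be normalized (sum to 1)")
  if (dialect == "meme") {
    lines <- c("MEME version 4", "",
               "ALPHABET= ACGT", "",
               "strands: +", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", "",
               sprintf("MOTIF %s", name),
               sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                       ncol(mat)),
               apply(mat, 2L, function(col) paste(sprintf("%.6f", col), collapse = " ")))
  } else {
    lines <- c(paste(c("pos", DNA_BASES, "wildcard"), collapse = "\t"),
               vapply(seq_len(ncol(mat)), function(j) {
                 paste(c(j, sprintf("%.6g", mat[, j]), as.integer(wild[j])),
                       collapse = "\t")
               }, character(1L)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a motif file written by [write_motif()]
#' @param path motif file.
#' @param dialect `"meme"` or `"tab"`.
#' @return a [pwm] object.
#' @export
read_motif <- function(path, dialect = c("meme", "tab")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (dialect == "meme") {
    hdr <- grep("^letter-probability matrix", lines)
    if (length(hdr) != 1L) stop("not a MEME minimal motif file")
    w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[hdr]))
    rows <- lines[(hdr + 1L):(hdr + w)]
    mat <- t(vapply(strsplit(trimws(rows), " +"),
                    function(x) as.numeric(x), numeric(4L)))
    new_pwm(t(mat), wildcard = rep(FALSE, w))
  } else {
    dt <- utils::read.delim(path)
    new_pwm(t(as.matrix(dt[, DNA_BASES])), wildcard = dt$wildcard == 1L)
  }
}

#' Read a table of expression records
#'
#' Expected columns: clone_id, condition (uninduced/induced), ligand_conc,
#' od600, gfp_raw (additional columns pass through).
#'
#' @param path CSV file.
#' @export
read_expression_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("clone_id", "condition", "ligand_conc", "od600", "gfp_raw")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing expression columns: ", paste(miss, collapse = ", "))
  if (any(x$od600 <= 0)) stop("od600 must be positive")
  if (any(x$gfp_raw < 0)) stop("gfp_raw must be non-negative")
  x
}

#' Write a table of expression records
#' @param records data.frame of expression records.
#' @param path output CSV.
#' @export
write_expression_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
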