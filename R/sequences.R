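#' Construct a validated ORF set
#'
#' An ORF set is a data frame with one row per open reading frame, carrying
#' the DNA sequence, ribosomal/viral flags and the derived length (nt) and
#' GC percentage. Sequences are expected to be complete in-frame coding
#' sequences (frame 0, post-splicing).
#'
#' @param orf_id Character vector of unique identifiers.
#' @param sequence Character vector of DNA sequences (A/C/G/T).
#' @param is_ribosomal,is_viral Logical flags, recycled to length.
#' @param provenance Free-text label describing where the set came from.
#' @param validate If \code{TRUE} (default), reject records failing
#'   \code{\link{validate_orf}}.
#' @param min_length Minimum accepted length in nt (default 300).
#' @return An object of class \code{orf_set}: a data frame with columns
#'   \code{orf_id}, \code{sequence}, \code{is_ribosomal}, \code{is_viral},
#'   \code{length_nt}, \code{gc_percent}, \code{has_terminal_stop}.
#' @export
orf_set <- function(orf_id, sequence, is_ribosomal = FALSE, is_viral = FALSE,
                    provenance = "unspecified", validate = TRUE,
                    min_length = 300L) {
  orf_id <- as.character(orf_id)
  sequence <- toupper(as.character(sequence))
  if (anyDuplicated(orf_id))
    stop("duplicate ORF identifiers: ",
         paste(unique(orf_id[duplicated(orf_id)]), collapse = ", "))
  if (validate) {
    v <- validate_orf(sequence, min_length = min_length)
    if (!all(v$ok))
      stop("invalid ORF(s): ",
           paste(orf_id[!v$ok], v$reason[!v$ok], sep = ": ", collapse = "; "))
    term <- v$has_terminal_stop
  } else {
    term <- vapply(sequence, .has_terminal_stop, logical(1), USE.NAMES = FALSE)
  }
  out <- data.frame(
    orf_id = orf_id,
    sequence = sequence,
    is_ribosomal = rep_len(as.logical(is_ribosomal), length(orf_id)),
    is_viral = rep_len(as.logical(is_viral), length(orf_id)),
    length_nt = nchar(sequence),
    gc_percent = gc_percent(sequence),
    has_terminal_stop = term,
    stringsAsFactors = FALSE
  )
  attr(out, "provenance") <- provenance
  class(out) <- c("orf_set", "data.frame")
  out
}

#' @export
print.orf_set <- function(x, ...) {
  cat(sprintf("orf_set: %d ORFs (%s)\n", nrow(x),
              attr(x, "provenance") %||% "unspecified"))
  cat(sprintf("  length: %d-%d nt; GC: %.1f-%.1f%%; ribosomal: %d; viral: %d\n",
              min(x$length_nt), max(x$length_nt),
              min(x$gc_percent), max(x$gc_percent),
              sum(x$is_ribosomal), sum(x$is_viral)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.STOP_DNA <- c("TAA", "TAG", "TGA")

.has_terminal_stop <- function(seq) {
  n <- nchar(seq)
  n >= 3 && substr(seq, n - 2, n) %in% .STOP_DNA
}

#' Validate coding sequences
#'
#' A sequence is accepted when it is at least \code{min_length} nt long, a
#' multiple of 3 nt (frame 0), free of ambiguous bases (N), and contains no
#' in-frame stop codon before the final codon. A terminal stop codon is
#' optional; its presence is reported so callers can log the convention in
#' use.
#'
#' @param sequence Character vector of DNA sequences over \{A,C,G,T,N\}.
#' @param min_length Minimum length in nt (default 300, i.e. 100 codons).
#' @return A data frame with one row per sequence: \code{ok} (logical),
#'   \code{reason} (\code{NA} when ok; otherwise one of \code{"length"},
#'   \code{"frame"}, \code{"ambiguous base"}, \code{"internal stop"}),
#'   \code{has_terminal_stop}.
#' @examples
#' validate_orf(paste(rep("ATG", 100), collapse = ""))$ok       # TRUE
#' validate_orf(strrep("A", 299))$reason                        # "length"
#' @export
validate_orf <- function(sequence, min_length = 300L) {
  sequence <- toupper(as.character(sequence))
  n <- length(sequence)
  reason <- rep(NA_character_, n)
  term <- logical(n)
  for (i in seq_len(n)) {
    s <- sequence[i]
    len <- nchar(s)
    if (len < min_length) {
      reason[i] <- "length"
    } else if (len %% 3L != 0L) {
      reason[i] <- "frame"
    } else if (grepl("[^ACGT]", s)) {
      reason[i] <- "ambiguous base"
    } else {
      starts <- seq.int(1L, len - 3L, by = 3L)   # all but the final codon
      cod <- substring(s, starts, starts + 2L)
      if (any(cod %in% .STOP_DNA)) reason[i] <- "internal stop"
      term[i] <- substring(s, len - 2L, len) %in% .STOP_DNA
    }
  }
  data.frame(ok = is.na(reason), reason = reason,
             has_terminal_stop = term, stringsAsFactors = FALSE)
}

#' Read an ORF set from a FASTA file
#'
#' Reads DNA FASTA, validates every record with \code{\link{validate_orf}}
#' and returns the accepted records as an \code{\link{orf_set}}. Duplicate
#' identifiers and empty files are always fatal. In strict mode any invalid
#' record aborts; otherwise invalid records are skipped and returned in the
#' \code{"skipped"} attribute (a data frame of \code{orf_id}, \code{reason}),
#' optionally written as TSV.
#'
#' @param path Path to a FASTA file of DNA coding sequences.
#' @param strict Abort on the first invalid record (default \code{FALSE}).
#' @param min_length Minimum accepted length in nt.
#' @param skip_log Optional path; when given, skipped records are written
#'   there as a two-column TSV.
#' @return An \code{\link{orf_set}} with attribute \code{"skipped"}.
#' @export
read_orf_fasta <- function(path, strict = FALSE, min_length = 300L,
                           skip_log = NULL) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate ORF identifiers in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seq_chr <- as.character(seqs)
  v <- validate_orf(seq_chr, min_length = min_length)
  if (strict && !all(v$ok))
    stop("invalid ORF record(s): ",
         paste(ids[!v$ok], v$reason[!v$ok], sep = ": ", collapse = "; "))
  skipped <- data.frame(orf_id = ids[!v$ok], reason = v$reason[!v$ok],
                        stringsAsFactors = FALSE)
  if (nrow(skipped) > 0L)
    message(nrow(skipped), " record(s) skipped during FASTA validation")
  if (!is.null(skip_log))
    utils::write.table(skipped, skip_log, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  out <- orf_set(ids[v$ok], seq_chr[v$ok], provenance = path,
                 validate = FALSE, min_length = min_length)
  attr(out, "skipped") <- skipped
  out
}

#' Write an ORF set to FASTA
#'
#' @param orfs An \code{\link{orf_set}}.
#' @param path Output FASTA path.
#' @param width Line width for wrapped sequence (default 70).
#' @return \code{path}, invisibly.
#' @export
write_orf_fasta <- function(orfs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(orfs$sequence)
  names(x) <- orfs$orf_id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Split a coding sequence into RNA-alphabet codons
#'
#' @param sequence A single DNA coding sequence (length a multiple of 3).
#' @return Character vector of length \code{nchar(sequence)/3}: the in-frame
#'   codons in order, with T transliterated to U so that codon-indexed
#'   outputs use the RNA alphabet.
#' @examples
#' codons_of("ATGGCTTAA")  # "AUG" "GCU" "UAA"
#' @export
codons_of <- function(sequence) {
  stopifnot(length(sequence) == 1L)
  len <- nchar(sequence)
  if (len %% 3L != 0L) stop("sequence length is not a multiple of 3")
  starts <- seq.int(1L, len, by = 3L)
  chartr("T", "U", toupper(substring(sequence, starts, starts + 2L)))
}

#' GC percentage of sequences
#'
#' @param sequence Character vector of DNA sequences.
#' @return Percent G+C in \[0, 100\].
#' @export
gc_percent <- function(sequence) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  gc <- n - nchar(gsub("[GC]", "", sequence))
  100 * gc / n
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' GC-content bin of ORFs
#'
#' ORFs are grouped by GC percentage rounded to the nearest integer percent,
#' half away from zero, so e.g. 53.5 falls in the 54 bin.
#'
#' @param orfs An \code{\link{orf_set}} (or numeric GC percentages).
#' @return Integer GC bin per ORF.
#' @export
gc_group <- function(orfs) {
  gc <- if (is.numeric(orfs)) orfs else orfs$gc_percent
  as.integer(round_half_away(gc))
}

LENGTH_BREAKS <- c(300, 500, 1000, 2000, Inf)
LENGTH_LABELS <- c("300-499", "500-999", "1000-1999", ">=2000")

#' Length bin of ORFs
#'
#' Half-open nt-length bins \[300,500), \[500,1000), \[1000,2000), \[2000,Inf),
#' labelled "300-499", "500-999", "1000-1999", ">=2000". The short 300-499
#' class is the one contrasted against longer ORFs in codon-usage analyses;
#' the finer subdivision above 500 nt is for reporting.
#'
#' @param orfs An \code{\link{orf_set}} (or numeric lengths in nt).
#' @return Factor of length-bin labels.
#' @export
length_group <- function(orfs) {
  len <- if (is.numeric(orfs)) orfs else orfs$length_nt
  cut(len, breaks = LENGTH_BREAKS, labels = LENGTH_LABELS, right = FALSE)
}
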