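#' The four culture conditions
#'
#' Glucose or succinate as sole carbon source, sampled at 18 h (exponential)
#' or 72 h (stationary) of culture. All expression matrices carry exactly
#' these four columns, in this order; argmax/argmin ties are broken by it.
#'
#' @export
CONDITIONS <- c("G18", "S18", "G72", "S72")

#' Construct a four-condition expression matrix
#'
#' @param orf_id Character vector of unique ORF identifiers.
#' @param rpkm Numeric matrix or data frame of non-negative RPKM values with
#'   one row per ORF and columns G18, S18, G72, S72 (any order; reordered).
#' @return An object of class \code{expression_matrix}: a data frame with
#'   columns \code{orf_id}, \code{G18}, \code{S18}, \code{G72}, \code{S72}.
#' @export
expression_matrix <- function(orf_id, rpkm) {
  orf_id <- as.character(orf_id)
  if (anyDuplicated(orf_id)) stop("duplicate ORF identifiers")
  rpkm <- as.data.frame(rpkm)
  if (!all(CONDITIONS %in% names(rpkm)))
    stop("rpkm must have columns ", paste(CONDITIONS, collapse = ", "))
  rpkm <- rpkm[CONDITIONS]
  if (nrow(rpkm) != length(orf_id)) stop("orf_id / rpkm size mismatch")
  if (anyNA(rpkm)) stop("missing RPKM values")
  if (any(as.matrix(rpkm) < 0)) stop("negative RPKM values")
  out <- cbind(data.frame(orf_id = orf_id, stringsAsFactors = FALSE), rpkm)
  class(out) <- c("expression_matrix", "data.frame")
  out
}

.rpkm_matrix <- function(em) {
  m <- as.matrix(em[CONDITIONS])
  rownames(m) <- em$orf_id
  m
}

#' Reads per kilobase per million mapped reads
#'
#' RPKM for a feature with \code{reads} mapped reads out of
#' \code{library_size} total mapped reads in the library, over a feature of
#' \code{length_nt} nucleotides: \eqn{10^9 \cdot C / (N \cdot L)}.
#'
#' @param reads Read count mapped to the feature (C).
#' @param library_size Total mapped reads in the library (N), > 0.
#' @param length_nt Feature length in nt (L), > 0.
#' @return RPKM value(s).
#' @examples
#' compute_rpkm(1000, 1e6, 1000)  # 1000
#' @export
compute_rpkm <- function(reads, library_size, length_nt) {
  if (any(library_size <= 0)) stop("library_size must be > 0")
  if (any(length_nt <= 0)) stop("length_nt must be > 0")
  1e9 * reads / (library_size * length_nt)
}

#' Read a four-condition expression table from TSV
#'
#' Accepts either RPKM directly (columns \code{orf_id},
#' \code{rpkm_G18} ... \code{rpkm_S72}) or raw counts (columns
#' \code{reads_G18} ... \code{reads_S72} plus a two-line header giving the
#' per-condition library sizes:
#' \preformatted{#library_sizes	G18	S18	G72	S72
#' #	35000000	41000000	...}
#' in which case RPKM is computed with \code{\link{compute_rpkm}} using the
#' supplied ORF lengths.
#'
#' @param path TSV path.
#' @param lengths Named numeric vector of ORF lengths in nt; required when
#'   the table holds raw counts.
#' @return An \code{\link{expression_matrix}}.
#' @export
read_expression_tsv <- function(path, lengths = NULL) {
  first <- readLines(path, n = 2L)
  counts_mode <- startsWith(first[1], "#library_sizes")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (counts_mode) {
    hdr <- strsplit(first[1:2], "\t", fixed = TRUE)
    libs <- stats::setNames(as.numeric(hdr[[2]][-1]), hdr[[1]][-1])
    if (!all(CONDITIONS %in% names(libs)))
      stop("library-size header must name all four conditions")
    if (is.null(lengths)) stop("counts mode requires ORF lengths")
    L <- lengths[tab$orf_id]
    if (anyNA(L)) stop("missing lengths for some ORFs")
    if (!all(paste0("reads_", CONDITIONS) %in% names(tab)))
      stop("missing reads_* columns")
    rpkm <- lapply(CONDITIONS, function(cc)
      compute_rpkm(tab[[paste0("reads_", cc)]], libs[[cc]], L))
  } else {
    if (!all(paste0("rpkm_", CONDITIONS) %in% names(tab)))
      stop("missing rpkm_* columns")
    rpkm <- lapply(CONDITIONS, function(cc) tab[[paste0("rpkm_", cc)]])
  }
  names(rpkm) <- CONDITIONS
  expression_matrix(tab$orf_id, as.data.frame(rpkm))
}

#' Write an expression matrix as TSV
#'
#' @param em An \code{\link{expression_matrix}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_expression_tsv <- function(em, path) {
  out <- em
  names(out)[match(CONDITIONS, names(out))] <- paste0("rpkm_", CONDITIONS)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

EXPRESSION_BREAKS <- c(1, 31, 71, 101, 1000, Inf)
EXPRESSION_BINS <- c("1-30", "31-70", "71-100", "101-999", ">=1000")

#' Assign ORFs to expression-level groups
#'
#' Implements the grouping schemes used for codon-usage stratification:
#' \describe{
#'   \item{EC}{each condition separately: the ORF's RPKM under one condition}
#'   \item{HV}{the highest RPKM value among the four conditions}
#'   \item{AV}{the average RPKM value among the four conditions}
#' }
#' The binning statistic falls into half-open bins \[1,31), \[31,71),
#' \[71,101), \[101,1000), \[1000,Inf), labelled "1-30", "31-70", "71-100",
#' "101-999", ">=1000". Ribosomal ORFs go to the separate reference group
#' "R" and never enter the numbered bins. ORFs whose statistic is below
#' 1 RPKM are left unassigned (bin \code{NA}).
#'
#' @param em An \code{\link{expression_matrix}}.
#' @param scheme One of \code{"HV"}, \code{"AV"}, \code{"EC"}.
#' @param ribosomal_ids Identifiers of the ribosomal reference ORFs.
#' @param condition For \code{scheme = "EC"}, which condition to bin on.
#' @return A data frame of \code{orf_id}, \code{scheme}, \code{statistic},
#'   \code{bin} (factor with levels the five bins plus \code{"R"};
#'   \code{NA} = unassigned).
#' @export
assign_bins <- function(em, scheme = c("HV", "AV", "EC"),
                        ribosomal_ids = character(), condition = NULL) {
  scheme <- match.arg(scheme)
  m <- .rpkm_matrix(em)
  stat <- switch(scheme,
    HV = apply(m, 1, max),
    AV = rowMeans(m),
    EC = {
      if (is.null(condition) || !condition %in% CONDITIONS)
        stop("EC grouping needs condition in ", paste(CONDITIONS, collapse = ", "))
      m[, condition]
    })
  bad <- setdiff(ribosomal_ids, em$orf_id)
  if (length(bad)) stop("ribosomal_ids not in matrix: ", paste(bad, collapse = ", "))
  bin <- cut(stat, breaks = EXPRESSION_BREAKS, labels = EXPRESSION_BINS,
             right = FALSE)
  bin <- factor(bin, levels = c(EXPRESSION_BINS, "R"))
  bin[em$orf_id %in% ribosomal_ids] <- "R"
  scheme_label <- if (scheme == "EC") paste0("EC:", condition) else scheme
  data.frame(orf_id = em$orf_id, scheme = scheme_label,
             statistic = unname(stat), bin = bin, stringsAsFactors = FALSE)
}

SUMMARY_BINS <- c("1-30", "31-100", ">100")

#' Coarse expression summary percentages
#'
#' Percentages of ORFs that are low- to moderately expressed (1-30 RPKM),
#' quite highly to highly expressed (31-100 RPKM) and over-expressed
#' (>100 RPKM), either per condition or on the highest value among the four
#' conditions. Percentages are over ORFs with statistic >= 1; the number of
#' ORFs below 1 RPKM is returned in the \code{"n_below_1"} attribute so the
#' all-ORF denominator can be recovered.
#'
#' @param em An \code{\link{expression_matrix}}.
#' @param basis \code{"highest"} (one row) or \code{"per-condition"}
#'   (one row per condition).
#' @return Matrix of percentages with columns \code{"1-30"}, \code{"31-100"},
#'   \code{">100"}; rows sum to 100 up to exclusion of sub-1-RPKM ORFs.
#' @export
summary_bins <- function(em, basis = c("highest", "per-condition")) {
  basis <- match.arg(basis)
  m <- .rpkm_matrix(em)
  stat <- if (basis == "highest") cbind(highest = apply(m, 1, max)) else m
  pct <- t(apply(stat, 2, function(x) {
    b <- cut(x, breaks = c(1, 31, 101, Inf), labels = SUMMARY_BINS,
             right = FALSE)
    100 * as.vector(table(b)) / sum(!is.na(b))
  }))
  colnames(pct) <- SUMMARY_BINS
  attr(pct, "n_below_1") <- apply(stat, 2, function(x) sum(x < 1))
  pct
}

#' Expression fold-changes across the four conditions
#'
#' For each ORF, the ratio between its highest and lowest RPKM value among
#' the four conditions, annotated with the conditions in which the extremes
#' were observed as \code{"[max/min]"} (e.g. \code{"[S72/G72]"}). Ties are
#' broken by the fixed condition order G18, S18, G72, S72. ORFs with a zero
#' value in any condition have an undefined ratio and are flagged.
#'
#' @param em An \code{\link{expression_matrix}}.
#' @return Data frame of \code{orf_id}, \code{fold_change},
#'   \code{max_condition}, \code{min_condition}, \code{label},
#'   \code{defined}.
#' @export
fold_changes <- function(em) {
  m <- .rpkm_matrix(em)
  imax <- apply(m, 1, which.max)
  imin <- apply(m, 1, which.min)
  defined <- apply(m, 1, function(x) all(is.finite(x)) && all(x > 0))
  fc <- ifelse(defined, m[cbind(seq_len(nrow(m)), imax)] /
                        m[cbind(seq_len(nrow(m)), imin)], NA_real_)
  data.frame(
    orf_id = em$orf_id,
    fold_change = fc,
    max_condition = CONDITIONS[imax],
    min_condition = CONDITIONS[imin],
    label = ifelse(defined,
                   sprintf("[%s/%s]", CONDITIONS[imax], CONDITIONS[imin]),
                   NA_character_),
    defined = defined,
    stringsAsFactors = FALSE
  )
}

FOLD_BINS <- c("1-2", "2.1-5", "5.1-10", "10.1-50", ">50")

#' Fold-change bin percentages
#'
#' Percentages of ORFs whose max/min expression ratio falls in \[1,2],
#' (2,5], (5,10], (10,50] and (50,Inf), labelled "1-2", "2.1-5", "5.1-10",
#' "10.1-50", ">50". Upper-inclusive intervals follow the decimal bin labels.
#'
#' @param ratios Numeric fold-change ratios (>= 1), e.g. the
#'   \code{fold_change} column of \code{\link{fold_changes}}; \code{NA}
#'   (undefined) ratios are dropped.
#' @return Named numeric vector of percentages summing to 100.
#' @export
fold_change_bins <- function(ratios) {
  ratios <- ratios[!is.na(ratios)]
  if (any(ratios < 1)) stop("fold-change ratios must be >= 1")
  b <- cut(ratios, breaks = c(1, 2, 5, 10, 50, Inf), labels = FOLD_BINS,
           right = TRUE, include.lowest = TRUE)
  stats::setNames(100 * as.vector(table(b)) / length(ratios), FOLD_BINS)
}

#' Minimum-normalized expression display values
#'
#' Divides each ORF's four condition values by that ORF's minimum, so the
#' weakest condition maps to exactly 1 and the other values are fold-changes
#' relative to it (the transformation behind expression heat maps comparing
#' conditions). ORFs with a zero value are flagged and left \code{NA}.
#'
#' @param em An \code{\link{expression_matrix}}.
#' @return Data frame of \code{orf_id}, normalized \code{G18} ... \code{S72},
#'   and \code{defined}.
#' @export
normalized_display <- function(em) {
  m <- .rpkm_matrix(em)
  mins <- apply(m, 1, min)
  defined <- mins > 0
  norm <- m / mins
  norm[!defined, ] <- NA_real_
  out <- data.frame(orf_id = em$orf_id, norm, defined = defined,
                    row.names = NULL, stringsAsFactors = FALSE)
  out
}
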