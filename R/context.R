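#' Observed adjacent codon-pair counts
#'
#' Counts ordered pairs of in-frame adjacent codons (5' codon followed by its
#' 3' neighbour) over a group of ORFs. An ORF of k codons contributes exactly
#' k - 1 pairs; pairs never span two ORFs and there is no wrap-around, so the
#' first codon participates only as a 5' member and the last only as a 3'
#' member. With \code{include_stop = TRUE} (default) the terminal stop codon
#' is kept, so stop codons appear as 3' partners only.
#'
#' @param orfs An \code{\link{orf_set}}.
#' @param member_ids Group member identifiers; \code{NULL} = all.
#' @param include_stop Keep the terminal stop codon (default \code{TRUE}).
#' @return 64 x 64 integer matrix; rows are 5' codons, columns 3' codons,
#'   both in \code{\link{codons}()} order.
#' @export
pair_counts <- function(orfs, member_ids = NULL, include_stop = TRUE) {
  if (is.null(member_ids)) member_ids <- orfs$orf_id
  member_ids <- unique(member_ids)
  if (length(member_ids) == 0L) stop("empty member set")
  seqs <- orfs$sequence[match(member_ids, orfs$orf_id)]
  if (anyNA(seqs)) stop("ids not in ORF set")
  cods <- codons()
  stops <- c("UAA", "UAG", "UGA")
  acc <- integer(4096L)
  for (s in seqs) {
    idx <- match(codons_of(s), cods)
    k <- length(idx)
    if (!include_stop && cods[idx[k]] %in% stops) {
      idx <- idx[-k]
      k <- k - 1L
    }
    if (k < 2L) next
    cell <- (idx[-k] - 1L) * 64L + idx[-1L]
    acc <- acc + tabulate(cell, nbins = 4096L)
  }
  matrix(acc, nrow = 64L, ncol = 64L, byrow = TRUE,
         dimnames = list(codon5 = cods, codon3 = cods))
}

#' Expected codon-pair counts under independence
#'
#' Expected cell counts of the 5' x 3' codon contingency table under
#' independence of the two positions:
#' \eqn{e_{pq} = (\mathrm{row}_p \cdot \mathrm{col}_q) / N}.
#'
#' @param observed Square matrix of observed pair counts.
#' @return Matrix of expected counts with the same marginals
#'   (\eqn{\sum e = \sum o}).
#' @export
expected_counts <- function(observed) {
  n <- sum(observed)
  if (n <= 0) stop("empty observed table")
  outer(rowSums(observed), colSums(observed)) / n
}

#' Adjusted residuals of a contingency table
#'
#' The adjusted (standardized) residual of cell (p, q):
#' \deqn{r_{pq} = \frac{o_{pq} - e_{pq}}{\sqrt{e_{pq}\,(1 - p_p)\,(1 - q_q)}}}
#' with \eqn{p_p} and \eqn{q_q} the row and column marginal proportions.
#' Under independence the adjusted residual is approximately standard
#' normal, which is what makes the |r| > 3 bias rule interpretable. Cells
#' with zero expected count are undefined (\code{NA}). \code{mode =
#' "pearson"} returns the plain Pearson residual
#' \eqn{(o - e)/\sqrt{e}} for sensitivity analysis.
#'
#' @param observed Matrix of observed counts.
#' @param expected Matrix of expected counts; computed with
#'   \code{\link{expected_counts}} when \code{NULL}.
#' @param mode \code{"adjusted"} (default) or \code{"pearson"}.
#' @return Matrix of residuals, same shape as \code{observed}.
#' @export
adjusted_residuals <- function(observed, expected = NULL,
                               mode = c("adjusted", "pearson")) {
  mode <- match.arg(mode)
  if (is.null(expected)) expected <- expected_counts(observed)
  if (!identical(dim(observed), dim(expected))) stop("shape mismatch")
  n <- sum(observed)
  denom <- if (mode == "adjusted") {
    p <- rowSums(observed) / n
    q <- colSums(observed) / n
    sqrt(expected * outer(1 - p, 1 - q))
  } else {
    sqrt(expected)
  }
  r <- (observed - expected) / denom
  r[expected == 0] <- NA_real_
  r
}

#' Full 3' codon-context table for a group of ORFs
#'
#' Convenience wrapper building the observed, expected and adjusted-residual
#' 64 x 64 matrices for a group in one object.
#'
#' @inheritParams pair_counts
#' @param group_label Text label.
#' @param mode Residual mode, see \code{\link{adjusted_residuals}}.
#' @return An object of class \code{pair_context_table}: a list with
#'   \code{group_label}, \code{observed}, \code{expected}, \code{residual},
#'   \code{n_pairs}.
#' @export
pair_context_table <- function(orfs, member_ids = NULL, group_label = "group",
                               include_stop = TRUE,
                               mode = c("adjusted", "pearson")) {
  obs <- pair_counts(orfs, member_ids, include_stop = include_stop)
  exp <- expected_counts(obs)
  res <- adjusted_residuals(obs, exp, mode = mode)
  structure(list(group_label = group_label, observed = obs, expected = exp,
                 residual = res, n_pairs = sum(obs)),
            class = "pair_context_table")
}

#' @export
print.pair_context_table <- function(x, ...) {
  cat(sprintf("pair_context_table: group '%s', %d codon pairs\n",
              x$group_label, x$n_pairs))
  r <- x$residual[!is.na(x$residual)]
  cat(sprintf("  defined cells: %d/4096; |residual| > 3 in %d cells\n",
              length(r), sum(abs(r) > 3)))
  invisible(x)
}

#' Codon-pair bias calls
#'
#' Classifies every defined cell of a pair-context table: residual above
#' \code{+threshold} = preferred 3' context (the 3' codon follows the 5'
#' codon more often than expected), below \code{-threshold} = avoided, and
#' residuals in \[-threshold, +threshold\] are not statistically significant
#' (no bias). The default threshold of 3 standard units is the conventional
#' cutoff for 64 x 64 codon-context tables; a Bonferroni-style threshold can
#' be passed instead for stricter control.
#'
#' @param table A \code{\link{pair_context_table}}.
#' @param threshold Bias cutoff on the adjusted residual (default 3).
#' @return Long-format data frame: \code{codon5}, \code{codon3},
#'   \code{observed}, \code{expected}, \code{residual}, \code{call}
#'   (factor: preferred / no-bias / avoided). Undefined cells are omitted.
#' @export
bias_calls <- function(table, threshold = 3) {
  r <- table$residual
  keep <- which(!is.na(r))
  cods <- codons()
  idx <- arrayInd(keep, dim(r))
  call <- ifelse(r[keep] > threshold, "preferred",
                 ifelse(r[keep] < -threshold, "avoided", "no-bias"))
  data.frame(
    codon5 = cods[idx[, 1]], codon3 = cods[idx[, 2]],
    observed = table$observed[keep], expected = table$expected[keep],
    residual = r[keep],
    call = factor(call, levels = c("preferred", "no-bias", "avoided")),
    stringsAsFactors = FALSE
  )
}

#' Top preferred or avoided codon pairs
#'
#' The k codon pairs with the largest (preferred) or smallest (avoided)
#' adjusted residuals; ties are broken lexicographically on
#' (5' codon, 3' codon).
#'
#' @param table A \code{\link{pair_context_table}}.
#' @param k Number of pairs (default 5).
#' @param direction \code{"preferred"} or \code{"avoided"}.
#' @return Data frame of \code{codon5}, \code{codon3}, \code{residual},
#'   sorted. If fewer than k cells are defined, all are returned with a
#'   warning.
#' @export
top_pairs <- function(table, k = 5L, direction = c("preferred", "avoided")) {
  direction <- match.arg(direction)
  calls <- bias_calls(table)
  if (k > nrow(calls)) {
    warning("k exceeds defined cells; returning all ", nrow(calls))
    k <- nrow(calls)
  }
  key <- if (direction == "preferred") -calls$residual else calls$residual
  ord <- order(key, calls$codon5, calls$codon3)
  out <- calls[ord[seq_len(k)], c("codon5", "codon3", "residual")]
  rownames(out) <- NULL
  out
}

#' Differential display map between two groups' codon contexts
#'
#' Cell-wise difference of adjusted residuals between two pair-context
#' tables, with a similarity flag where the residuals differ by at most
#' \code{band} standard units (|delta| <= 3 by default). Cells undefined in
#' either table are undefined in the map.
#'
#' @param a,b \code{\link{pair_context_table}}s on the same 64 x 64 grid.
#' @param band Similarity half-width on the residual difference (default 3).
#' @return An object of class \code{differential_map}: a list with
#'   \code{label_a}, \code{label_b}, \code{delta} (64 x 64), \code{similar}
#'   (64 x 64 logical, \code{NA} where undefined).
#' @export
differential_map <- function(a, b, band = 3) {
  stopifnot(identical(dim(a$residual), dim(b$residual)))
  delta <- a$residual - b$residual
  similar <- abs(delta) <= band
  structure(list(label_a = a$group_label, label_b = b$group_label,
                 delta = delta, similar = similar),
            class = "differential_map")
}

.pair_long <- function(m, value = "value") {
  cods <- codons()
  out <- data.frame(codon5 = rep(cods, times = 64L),
                    codon3 = rep(cods, each = 64L),
                    stringsAsFactors = FALSE)
  out[[value]] <- as.vector(m)
  out
}

#' Write a pair-context table or differential map as long-format TSV
#'
#' Residuals are written at full precision; an extra integer-rounded column
#' (\code{residual_rounded}) matches the convention of printed codon-context
#' tables.
#'
#' @param x A \code{\link{pair_context_table}} or
#'   \code{\link{differential_map}}.
#' @param path Output path.
#' @param threshold Bias threshold for the \code{call} column.
#' @return \code{path}, invisibly.
#' @export
write_context_tsv <- function(x, path, threshold = 3) {
  if (inherits(x, "pair_context_table")) {
    out <- bias_calls(x, threshold = threshold)
    out$residual_rounded <- round_half_away(out$residual)
  } else if (inherits(x, "differential_map")) {
    out <- .pair_long(x$delta, "delta")
    out$similar <- as.vector(x$similar)
    out <- out[!is.na(out$delta), ]
  } else stop("unsupported object")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
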