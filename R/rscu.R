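#' Count codons over a group of ORFs
#'
#' Pools the in-frame codons of the selected ORFs (each member counted once,
#' set semantics) into a single per-codon count vector over the 64 codons.
#' Group-level codon usage statistics are computed from these pooled counts,
#' not from per-gene averages.
#'
#' @param orfs An \code{\link{orf_set}}.
#' @param member_ids Identifiers of the group members; \code{NULL} = all.
#' @return Named integer vector of length 64 (RNA-alphabet codons, in
#'   \code{\link{codons}()} order).
#' @export
count_codons <- function(orfs, member_ids = NULL) {
  if (is.null(member_ids)) member_ids <- orfs$orf_id
  member_ids <- unique(member_ids)
  if (length(member_ids) == 0L) stop("empty member set")
  missing <- setdiff(member_ids, orfs$orf_id)
  if (length(missing)) stop("ids not in ORF set: ", paste(missing, collapse = ", "))
  seqs <- orfs$sequence[match(member_ids, orfs$orf_id)]
  cods <- codons()
  idx <- unlist(lapply(seqs, function(s) match(codons_of(s), cods)),
                use.names = FALSE)
  stats::setNames(tabulate(idx, nbins = 64L), cods)
}

#' Relative synonymous codon usage table
#'
#' For codon \eqn{j} of amino acid \eqn{i} with synonymous family size
#' \eqn{n_i} and observed counts \eqn{x_{ij}},
#' \deqn{RSCU_{ij} = x_{ij} \, n_i / \sum_j x_{ij}.}
#' RSCU is 1 under uniform synonymous usage and equals \eqn{n_i} when a
#' single codon is used exclusively; single-codon families (Met, Trp) are
#' always 1. Stop codons form the 3-codon TER family. Codons of an amino
#' acid never observed in the group have undefined (\code{NA}) RSCU, never 0.
#'
#' @param counts Named per-codon counts over the 64 codons (as from
#'   \code{\link{count_codons}}).
#' @param group_label Text label for the group.
#' @param code Genetic code, as from \code{\link{genetic_code}}.
#' @return An object of class \code{rscu_table}: a data frame with one row
#'   per codon: \code{amino_acid} (three-letter, TER for stop), \code{aa}
#'   (one-letter), \code{codon}, \code{family_size}, \code{count},
#'   \code{rscu}. Attributes: \code{group_label}, \code{total_codons}.
#' @examples
#' orfs <- orf_set("x", paste0("ATG", strrep("GAAGAAGAAGAG", 25), "TAA"),
#'                 min_length = 9)
#' tab <- rscu_table(count_codons(orfs))
#' tab[tab$codon %in% c("GAA", "GAG"), "rscu"]  # 1.5, 0.5
#' @export
rscu_table <- function(counts, group_label = "group", code = genetic_code()) {
  cods <- codons()
  if (!all(cods %in% names(counts))) stop("counts must cover all 64 codons")
  counts <- counts[cods]
  aa <- code$codon_to_aa[cods]
  fam_tot <- tapply(counts, aa, sum)[aa]
  n_i <- code$family_size[aa]
  rscu <- ifelse(fam_tot > 0, counts * n_i / fam_tot, NA_real_)
  out <- data.frame(
    amino_acid = aa_name(aa), aa = unname(aa), codon = cods,
    family_size = unname(n_i), count = unname(as.integer(counts)),
    rscu = unname(rscu), stringsAsFactors = FALSE
  )
  attr(out, "group_label") <- group_label
  attr(out, "total_codons") <- as.integer(sum(counts))
  class(out) <- c("rscu_table", "data.frame")
  out
}

#' @export
print.rscu_table <- function(x, ...) {
  cat(sprintf("rscu_table: group '%s', %d codons counted\n",
              attr(x, "group_label"), attr(x, "total_codons")))
  NextMethod()
}

#' Codon preference classes within each synonymous family
#'
#' Classifies each codon within its family as the most common (the family
#' argmax, all of them on ties; single-codon families trivially), less
#' frequent (RSCU < 0.5), or intermediate (the remainder). The 0.5 cutoff
#' reproduces the three-way colour classes used in codon-usage displays; it
#' is a display convention, not an inferential threshold.
#'
#' @param table An \code{\link{rscu_table}}.
#' @param less_frequent_below RSCU cutoff for the "less frequent" class.
#' @return Factor (levels \code{most common}, \code{intermediate},
#'   \code{less frequent}) aligned with the table rows; \code{NA} for
#'   undefined RSCU.
#' @export
preference_classes <- function(table, less_frequent_below = 0.5) {
  cls <- rep(NA_character_, nrow(table))
  for (a in unique(table$aa)) {
    i <- which(table$aa == a)
    r <- table$rscu[i]
    if (all(is.na(r))) next
    top <- abs(r - max(r)) < 1e-12
    cls[i] <- ifelse(top, "most common",
                     ifelse(r < less_frequent_below, "less frequent",
                            "intermediate"))
  }
  factor(cls, levels = c("most common", "intermediate", "less frequent"))
}

#' RSCU ratio map between two groups
#'
#' Per-codon ratio of RSCU values between two groups, with a similarity flag
#' for ratios inside the \[0.9, 1.1\] band (the convention for "similar
#' codon usage" in comparative RSCU displays). Ratios are undefined when
#' either RSCU is undefined or the denominator RSCU is 0; undefined entries
#' are never flagged similar.
#'
#' @param a,b \code{\link{rscu_table}}s on the same genetic code
#'   (numerator and denominator respectively).
#' @param band Length-2 numeric similarity band (default \code{c(0.9, 1.1)}).
#' @return An object of class \code{ratio_map}: a data frame of
#'   \code{amino_acid}, \code{codon}, \code{ratio}, \code{similar}, with
#'   attributes \code{numerator_label} and \code{denominator_label}.
#' @export
ratio_map <- function(a, b, band = c(0.9, 1.1)) {
  stopifnot(identical(a$codon, b$codon))
  ratio <- ifelse(is.na(a$rscu) | is.na(b$rscu) | b$rscu == 0,
                  NA_real_, a$rscu / b$rscu)
  similar <- !is.na(ratio) & ratio >= band[1] & ratio <= band[2]
  out <- data.frame(amino_acid = a$amino_acid, codon = a$codon,
                    ratio = ratio, similar = similar,
                    stringsAsFactors = FALSE)
  attr(out, "numerator_label") <- attr(a, "group_label")
  attr(out, "denominator_label") <- attr(b, "group_label")
  class(out) <- c("ratio_map", "data.frame")
  out
}

#' Write an RSCU table (with preference classes) as TSV
#'
#' @param table An \code{\link{rscu_table}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_rscu_tsv <- function(table, path) {
  out <- data.frame(amino_acid = table$amino_acid, codon = table$codon,
                    count = table$count, rscu = table$rscu,
                    class = as.character(preference_classes(table)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
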