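#' Pipeline run configuration
#'
#' Bundles inputs and options for \code{\link{run_pipeline}}. Defaults
#' reproduce the documented behaviour of every stage: HV grouping on the
#' standard RPKM bins, ribosomal ORFs as the reference group, terminal stop
#' codons included in pair counting, adjusted residuals with the +/-3 bias
#' rule, and the 0.9-1.1 RSCU ratio similarity band.
#'
#' @param fasta Path to the ORF FASTA, or an \code{\link{orf_set}}.
#' @param expression Path to the expression TSV, or an
#'   \code{\link{expression_matrix}}.
#' @param flags Optional path to a flags TSV (columns \code{orf_id},
#'   \code{is_ribosomal}, \code{is_viral}), or a data frame; when absent the
#'   flags carried by the ORF set are used.
#' @param scheme Grouping scheme: \code{"HV"} (default), \code{"AV"} or
#'   \code{"EC"} (with \code{condition}).
#' @param condition Condition for EC grouping.
#' @param reference_group Group used as denominator of ratio maps and
#'   baseline of differential maps (default \code{"R"}).
#' @param include_stop Keep terminal stop codons in pair counting.
#' @param threshold Bias threshold on adjusted residuals.
#' @param residual_mode \code{"adjusted"} or \code{"pearson"}.
#' @param min_group_orfs Groups smaller than this are reported but skipped
#'   in codon analyses (default 2).
#' @param id_mismatch_tolerance Maximum tolerated fraction of expression ORF
#'   ids absent from the FASTA (default 0: any mismatch is fatal).
#' @param out_dir Output directory for the report bundle.
#' @param top_k Rows in the top-expressed tables (default 10).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A \code{run_config} list.
#' @export
run_config <- function(fasta, expression, flags = NULL,
                       scheme = c("HV", "AV", "EC"), condition = NULL,
                       reference_group = "R", include_stop = TRUE,
                       threshold = 3, residual_mode = "adjusted",
                       min_group_orfs = 2L, id_mismatch_tolerance = 0,
                       out_dir = "codoncontext_report", top_k = 10L,
                       seed = 1L) {
  structure(list(fasta = fasta, expression = expression, flags = flags,
                 scheme = match.arg(scheme), condition = condition,
                 reference_group = reference_group,
                 include_stop = include_stop, threshold = threshold,
                 residual_mode = residual_mode,
                 min_group_orfs = as.integer(min_group_orfs),
                 id_mismatch_tolerance = id_mismatch_tolerance,
                 out_dir = out_dir, top_k = as.integer(top_k),
                 seed = as.integer(seed)),
            class = "run_config")
}

.file_label <- function(x) gsub("[^0-9A-Za-z_.-]", "_", gsub(">=", "ge", x))

.load_inputs <- function(config) {
  orfs <- if (inherits(config$fasta, "orf_set")) config$fasta
          else read_orf_fasta(config$fasta)
  em <- if (inherits(config$expression, "expression_matrix")) config$expression
        else read_expression_tsv(config$expression)
  if (!is.null(config$flags)) {
    fl <- if (is.data.frame(config$flags)) config$flags
          else utils::read.delim(config$flags, stringsAsFactors = FALSE)
    i <- match(orfs$orf_id, fl$orf_id)
    if ("is_ribosomal" %in% names(fl))
      orfs$is_ribosomal <- ifelse(is.na(i), orfs$is_ribosomal,
                                  as.logical(fl$is_ribosomal[i]))
    if ("is_viral" %in% names(fl))
      orfs$is_viral <- ifelse(is.na(i), orfs$is_viral,
                              as.logical(fl$is_viral[i]))
  }
  missing <- setdiff(em$orf_id, orfs$orf_id)
  if (length(missing) / nrow(em) > config$id_mismatch_tolerance)
    stop(length(missing), " expression ORF id(s) absent from FASTA, e.g. ",
         paste(utils::head(missing, 3), collapse = ", "))
  if (length(missing)) {
    message("dropping ", length(missing), " expression rows without sequence")
    em <- expression_matrix(em$orf_id[!em$orf_id %in% missing],
                            em[!em$orf_id %in% missing, CONDITIONS])
  }
  list(orfs = orfs, em = em)
}

#' Run the full codon usage / codon context pipeline
#'
#' Executes every analysis stage on one dataset and writes a report bundle
#' to \code{config$out_dir}: expression summaries (coarse bins, fold-change
#' bins, top-expressed tables), group sizes under the selected scheme, one
#' RSCU table (with preference classes) and one codon-pair context table
#' (observed/expected/residual/bias call) per group, RSCU ratio maps and
#' context differential maps against the reference group, and a JSON
#' manifest (options, package version, input digests). The bundle is a pure
#' function of the inputs and options: reruns are digest-stable.
#'
#' @param config A \code{\link{run_config}}.
#' @return Invisibly, a list with the in-memory results: \code{orfs},
#'   \code{em}, \code{bins}, \code{group_sizes}, \code{rscu} (per group),
#'   \code{ratio} (per group), \code{context} (per group), \code{top_pairs},
#'   \code{differential}, \code{summary}, \code{fold_bins}, \code{top},
#'   \code{files}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  inp <- .load_inputs(config)
  orfs <- inp$orfs; em <- inp$em
  files <- character(0)
  emit <- function(name) {
    p <- file.path(config$out_dir, name)
    files[[length(files) + 1L]] <<- p
    p
  }

  rib_ids <- orfs$orf_id[orfs$is_ribosomal]
  bins <- assign_bins(em, scheme = config$scheme,
                      ribosomal_ids = intersect(rib_ids, em$orf_id),
                      condition = config$condition)
  group_sizes <- as.data.frame(table(bin = bins$bin), stringsAsFactors = FALSE)
  names(group_sizes) <- c("bin", "n_orfs")
  utils::write.table(group_sizes, emit("group_sizes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # expression summaries
  sm_h <- summary_bins(em, "highest")
  sm_c <- summary_bins(em, "per-condition")
  sm <- rbind(sm_h, sm_c)
  sm_out <- data.frame(basis = rownames(sm), sm, check.names = FALSE)
  utils::write.table(sm_out, emit("expression_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  fc <- fold_changes(em)
  fb <- fold_change_bins(fc$fold_change)
  utils::write.table(data.frame(bin = names(fb), percent = unname(fb)),
                     emit("fold_change_bins.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  top <- top_expressed(em, rib_ids, k = config$top_k)
  utils::write.table(top$highest, emit("top_expressed_rpkm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(top$fold_change, emit("top_fold_changes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # per-group codon analyses
  groups <- split(bins$orf_id, bins$bin)
  groups <- groups[vapply(groups, length, integer(1)) >= config$min_group_orfs]
  rscu_tabs <- list(); ctx_tabs <- list()
  for (g in names(groups)) {
    rscu_tabs[[g]] <- rscu_table(count_codons(orfs, groups[[g]]),
                                 group_label = g)
    write_rscu_tsv(rscu_tabs[[g]], emit(sprintf("rscu_%s.tsv", .file_label(g))))
    ctx_tabs[[g]] <- pair_context_table(orfs, groups[[g]], group_label = g,
                                        include_stop = config$include_stop,
                                        mode = config$residual_mode)
    write_context_tsv(ctx_tabs[[g]],
                      emit(sprintf("context_%s.tsv", .file_label(g))),
                      threshold = config$threshold)
  }

  top_pairs_tabs <- lapply(ctx_tabs, function(ct) {
    rbind(cbind(direction = "preferred", top_pairs(ct, 5, "preferred")),
          cbind(direction = "avoided", top_pairs(ct, 5, "avoided")))
  })
  for (g in names(top_pairs_tabs))
    utils::write.table(top_pairs_tabs[[g]],
                       emit(sprintf("top_pairs_%s.tsv", .file_label(g))),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  ref <- config$reference_group
  ratio_tabs <- list(); diff_tabs <- list()
  if (!ref %in% names(groups)) {
    warning("reference group '", ref,
            "' is empty or too small; ratio and differential maps omitted")
  } else {
    for (g in setdiff(names(groups), ref)) {
      ratio_tabs[[g]] <- ratio_map(rscu_tabs[[g]], rscu_tabs[[ref]])
      utils::write.table(ratio_tabs[[g]],
                         emit(sprintf("ratio_%s_vs_%s.tsv", .file_label(g),
                                      .file_label(ref))),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      diff_tabs[[g]] <- differential_map(ctx_tabs[[g]], ctx_tabs[[ref]],
                                         band = config$threshold)
      write_context_tsv(diff_tabs[[g]],
                        emit(sprintf("differential_%s_vs_%s.tsv",
                                     .file_label(g), .file_label(ref))))
    }
  }

  manifest <- list(
    package = "codoncontext",
    version = as.character(utils::packageVersion("codoncontext")),
    options = config[c("scheme", "condition", "reference_group",
                       "include_stop", "threshold", "residual_mode",
                       "min_group_orfs", "top_k", "seed")],
    inputs = list(
      fasta = if (is.character(config$fasta))
        list(path = config$fasta,
             md5 = unname(tools::md5sum(config$fasta))) else "in-memory",
      expression = if (is.character(config$expression))
        list(path = config$expression,
             md5 = unname(tools::md5sum(config$expression))) else "in-memory",
      n_orfs = nrow(orfs), n_expression = nrow(em)),
    groups = stats::setNames(as.list(vapply(groups, length, integer(1))),
                             names(groups))
  )
  jsonlite::write_json(manifest, emit("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(orfs = orfs, em = em, bins = bins,
                 group_sizes = group_sizes, rscu = rscu_tabs,
                 ratio = ratio_tabs, context = ctx_tabs,
                 top_pairs = top_pairs_tabs, differential = diff_tabs,
                 summary = sm_out, fold_bins = fb, top = top,
                 files = unlist(files)))
}

#' Top expressed ORFs and top fold-changes
#'
#' The k ORFs with the highest RPKM value among the four conditions
#' (annotated \code{"(S18)"}-style with the condition of the maximum), and
#' the k ORFs with the largest max/min fold-change (annotated
#' \code{"[S72/G72]"}-style). Ribosomal ORFs are excluded from both tables,
#' as usual when the ribosomal set serves as the highly-expressed reference.
#' Ties are broken by \code{orf_id}.
#'
#' @param em An \code{\link{expression_matrix}}.
#' @param ribosomal_ids Identifiers to exclude.
#' @param k Number of rows.
#' @return List of two data frames: \code{highest} (\code{orf_id},
#'   \code{rpkm}, \code{condition}, \code{annotation}) and
#'   \code{fold_change} (\code{orf_id}, \code{fold_change},
#'   \code{annotation}).
#' @export
top_expressed <- function(em, ribosomal_ids = character(), k = 10L) {
  stopifnot(k >= 1L)
  keep <- !em$orf_id %in% ribosomal_ids
  m <- .rpkm_matrix(em)[keep, , drop = FALSE]
  ids <- em$orf_id[keep]
  imax <- apply(m, 1, which.max)
  mx <- m[cbind(seq_len(nrow(m)), imax)]
  ord <- order(-mx, ids)[seq_len(min(k, length(ids)))]
  highest <- data.frame(
    orf_id = ids[ord], rpkm = mx[ord], condition = CONDITIONS[imax][ord],
    annotation = sprintf("(%s)", CONDITIONS[imax][ord]),
    stringsAsFactors = FALSE)
  fc <- fold_changes(expression_matrix(ids, as.data.frame(m)))
  fc <- fc[fc$defined, ]
  ordf <- order(-fc$fold_change, fc$orf_id)[seq_len(min(k, nrow(fc)))]
  fold <- data.frame(orf_id = fc$orf_id[ordf],
                     fold_change = fc$fold_change[ordf],
                     annotation = fc$label[ordf], stringsAsFactors = FALSE)
  list(highest = highest, fold_change = fold)
}

#' Recompute the headline expression and codon-usage summaries of a dataset
#'
#' One call that recomputes, from an ORF set and its four-condition
#' expression matrix, the quantities used to summarize a coding-sequence
#' expression study: the coarse expression percentages on the highest-value
#' basis, the >100 RPKM percentage per condition, the fold-change bin
#' percentages, the maximum fold-change (ribosomal ORFs excluded), the size
#' of the HV ">=1000" group, the highest RPKM value (ribosomal ORFs
#' excluded), and the RSCU of a chosen codon in the ribosomal group.
#'
#' @param orfs An \code{\link{orf_set}}.
#' @param em An \code{\link{expression_matrix}}.
#' @param ribosomal_ids Ribosomal reference ORF identifiers; defaults to the
#'   flags in \code{orfs}.
#' @param codon Codon whose ribosomal-group RSCU to report (default
#'   \code{"CGA"}).
#' @return Named list: \code{summary_highest}, \code{over100_per_condition},
#'   \code{fold_bin_percent}, \code{max_fold_change}, \code{hv_ge1000_n},
#'   \code{top_rpkm}, \code{rscu_ribosomal}.
#' @export
reproduce_study_summaries <- function(orfs, em, ribosomal_ids = NULL,
                                      codon = "CGA") {
  if (is.null(ribosomal_ids)) ribosomal_ids <- orfs$orf_id[orfs$is_ribosomal]
  sm_h <- summary_bins(em, "highest")
  sm_c <- summary_bins(em, "per-condition")
  fc <- fold_changes(em)
  fc_nr <- fc[!fc$orf_id %in% ribosomal_ids & fc$defined, ]
  bins <- assign_bins(em, "HV", ribosomal_ids = intersect(ribosomal_ids,
                                                          em$orf_id))
  te <- top_expressed(em, ribosomal_ids, k = 1L)
  rt <- rscu_table(count_codons(orfs, intersect(ribosomal_ids, orfs$orf_id)),
                   group_label = "R")
  list(
    summary_highest = sm_h[1, ],
    over100_per_condition = sm_c[, ">100"],
    fold_bin_percent = fold_change_bins(fc$fold_change),
    max_fold_change = max(fc_nr$fold_change),
    hv_ge1000_n = sum(bins$bin == ">=1000", na.rm = TRUE),
    top_rpkm = te$highest$rpkm[1],
    rscu_ribosomal = rt$rscu[rt$codon == codon]
  )
}
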