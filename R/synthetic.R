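#' Uniform within-family codon frequencies
#'
#' Baseline codon frequency vector assigning equal probability to every
#' synonymous codon of each amino acid (and of the TER family): the
#' no-codon-bias null.
#'
#' @param code Genetic code, as from \code{\link{genetic_code}}.
#' @return Named numeric vector over the 64 codons; values within each
#'   synonymous family sum to 1.
#' @export
uniform_codon_frequencies <- function(code = genetic_code()) {
  aa <- code$codon_to_aa
  stats::setNames(1 / code$family_size[aa], names(aa))
}

#' Specification of a synthetic ORF/expression dataset
#'
#' Fully parameterizes a generated dataset: number of ORFs, length
#' distribution (codon counts), per-amino-acid synonymous codon frequencies,
#' optional multiplicative codon-pair coupling, optional GC% target,
#' amino-acid composition, four-condition expression profile and seed. A
#' fixed seed makes \code{\link{generate_orfs}} and
#' \code{\link{generate_expression}} byte-reproducible.
#'
#' Generated ORFs start with AUG, end with a stop codon drawn from the TER
#' frequencies, and contain no internal stop. Internal codons follow a
#' first-order Markov chain whose stationary emission is
#' \code{amino_acid_frequencies x codon_frequencies} and whose transition
#' weights out of each 5' codon are multiplied by the coupling factors and
#' renormalized; with no coupling the chain degenerates to i.i.d. sampling.
#'
#' @param n_orfs Number of ORFs.
#' @param length_distribution List: either \code{list(type = "fixed",
#'   codons = k)} or \code{list(type = "lognormal", meanlog, sdlog,
#'   min_codons)} over total codon counts (start and stop included; minimum
#'   100 codons = 300 nt).
#' @param codon_frequencies Named 64-vector of within-family synonymous
#'   codon probabilities (each family sums to 1); default uniform.
#' @param amino_acid_frequencies Named probability vector over the 20 amino
#'   acids, used for internal codons; default uniform.
#' @param pair_coupling Data frame with columns \code{codon5}, \code{codon3},
#'   \code{factor} (> 0), multiplying the transition weight of the given
#'   ordered pair; \code{NULL} for no coupling. Stop codons are not valid 5'
#'   members.
#' @param gc_target Optional GC percent; codon frequencies are exponentially
#'   tilted toward GC-rich (or GC-poor) synonyms within each family so the
#'   expected GC of generated codons matches the target approximately.
#' @param expression List of expression-profile parameters:
#'   \code{base_meanlog}, \code{base_sdlog} (log-normal base RPKM, defaults
#'   5.54 and 1.2, putting roughly 88\% of ORFs above 100 RPKM on the
#'   highest-value basis once condition multipliers are applied),
#'   \code{multipliers} (length-4 non-negative vector applied to every ORF,
#'   or \code{NULL} for per-ORF log-normal condition multipliers with
#'   \code{condition_sdlog}, default 0.55, giving a median max/min
#'   fold-change near 3), \code{noise_sdlog} (log-normal measurement noise,
#'   default 0.1), \code{ribosomal_boost} (base multiplier for ribosomal
#'   ORFs, default 8).
#' @param ribosomal_fraction Fraction of ORFs flagged ribosomal.
#' @param seed Integer seed.
#' @return An object of class \code{synthetic_spec} (a validated list).
#' @export
synthetic_spec <- function(n_orfs = 300L,
                           length_distribution = list(type = "lognormal",
                                                      meanlog = log(150),
                                                      sdlog = 0.45,
                                                      min_codons = 100L),
                           codon_frequencies = NULL,
                           amino_acid_frequencies = NULL,
                           pair_coupling = NULL,
                           gc_target = NULL,
                           expression = list(),
                           ribosomal_fraction = 0.03,
                           seed = 1L) {
  code <- genetic_code()
  if (is.null(codon_frequencies))
    codon_frequencies <- uniform_codon_frequencies(code)
  if (!all(codons() %in% names(codon_frequencies)))
    stop("codon_frequencies must cover all 64 codons")
  codon_frequencies <- codon_frequencies[codons()]
  if (any(codon_frequencies < 0)) stop("negative codon frequencies")
  fam <- tapply(codon_frequencies, code$codon_to_aa, sum)
  if (any(abs(fam - 1) > 1e-6))
    stop("codon_frequencies must sum to 1 within each synonymous family")
  aas <- setdiff(names(code$family_size), "*")
  if (is.null(amino_acid_frequencies))
    amino_acid_frequencies <- stats::setNames(rep(1 / length(aas), length(aas)), aas)
  if (abs(sum(amino_acid_frequencies) - 1) > 1e-6)
    stop("amino_acid_frequencies must sum to 1")
  if (!is.null(pair_coupling)) {
    stopifnot(is.data.frame(pair_coupling),
              all(c("codon5", "codon3", "factor") %in% names(pair_coupling)))
    if (any(pair_coupling$factor <= 0)) stop("coupling factors must be > 0")
    if (any(code$codon_to_aa[pair_coupling$codon5] == "*"))
      stop("pair_coupling cannot use a stop codon at the 5' position")
  }
  expr <- utils::modifyList(
    list(base_meanlog = 5.54, base_sdlog = 1.2, multipliers = NULL,
         condition_sdlog = 0.55, noise_sdlog = 0.1, ribosomal_boost = 8),
    expression)
  if (!is.null(expr$multipliers)) {
    if (length(expr$multipliers) != 4L || any(expr$multipliers < 0))
      stop("multipliers must be 4 non-negative values")
  }
  structure(list(n_orfs = as.integer(n_orfs),
                 length_distribution = length_distribution,
                 codon_frequencies = codon_frequencies,
                 amino_acid_frequencies = amino_acid_frequencies,
                 pair_coupling = pair_coupling,
                 gc_target = gc_target,
                 expression = expr,
                 ribosomal_fraction = ribosomal_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# GC count (0..3) of each codon
.gc_count <- function(cods = codons()) {
  vapply(strsplit(cods, ""), function(b) sum(b %in% c("G", "C")), integer(1))
}

# exponentially tilt within-family codon frequencies so the expected GC of an
# emitted codon matches gc_target (percent); solved for the tilt parameter t
# in w_c = p_c * exp(t * gc_c) by uniroot
.tilt_to_gc <- function(codon_freq, aa_freq, code, gc_target) {
  gcc <- .gc_count()
  aa <- code$codon_to_aa
  tilted <- function(t) {
    w <- codon_freq * exp(t * gcc)
    fam <- tapply(w, aa, sum)[aa]
    w / fam
  }
  expected_gc <- function(t) {
    p <- tilted(t)
    emit <- p * ifelse(aa == "*", 0, aa_freq[aa])
    emit <- emit / sum(emit)
    100 * sum(emit * gcc) / 3
  }
  f <- function(t) expected_gc(t) - gc_target
  if (f(-25) > 0 || f(25) < 0) stop("gc_target unattainable by tilting")
  t <- stats::uniroot(f, c(-25, 25), tol = 1e-9)$root
  tilted(t)
}

# emission distribution of internal (sense) codons
.emission <- function(spec, code) {
  aa <- code$codon_to_aa
  cf <- spec$codon_frequencies
  if (!is.null(spec$gc_target))
    cf <- .tilt_to_gc(cf, spec$amino_acid_frequencies, code, spec$gc_target)
  emit <- ifelse(aa == "*", 0, spec$amino_acid_frequencies[aa] * cf)
  emit / sum(emit)
}

#' Generate a synthetic ORF set
#'
#' Draws in-frame coding sequences under a \code{\link{synthetic_spec}}:
#' AUG start, internal sense codons from the (possibly pair-coupled,
#' possibly GC-tilted) codon chain, and a terminal stop codon from the TER
#' frequencies. Output is deterministic for a fixed spec (seed included).
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return An \code{\link{orf_set}}; every record passes
#'   \code{\link{validate_orf}}.
#' @export
generate_orfs <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  code <- genetic_code()
  cods <- codons()
  set.seed(spec$seed)
  ld <- spec$length_distribution
  k <- switch(ld$type,
    fixed = rep.int(as.integer(ld$codons), spec$n_orfs),
    lognormal = {
      min_codons <- ld$min_codons %||% 100L
      pmax(min_codons,
           as.integer(round(stats::rlnorm(spec$n_orfs, ld$meanlog, ld$sdlog))))
    },
    stop("unknown length distribution type: ", ld$type))
  if (any(k < 100L)) stop("ORFs must have at least 100 codons (300 nt)")

  emit <- .emission(spec, code)
  sense <- which(emit > 0)
  p_sense <- emit[sense]
  aug <- match("AUG", cods)
  ter <- which(code$codon_to_aa == "*")
  p_ter <- spec$codon_frequencies[ter]
  p_ter <- p_ter / sum(p_ter)

  n_internal <- k - 2L
  total <- sum(n_internal)
  if (is.null(spec$pair_coupling)) {
    stream <- sample(sense, total, replace = TRUE, prob = p_sense)
  } else {
    # row-wise transition: base emission reweighted by the coupling factors
    P <- matrix(rep(p_sense, each = 64L), nrow = 64L,
                dimnames = list(cods, cods[sense]))
    for (i in seq_len(nrow(spec$pair_coupling))) {
      r <- match(spec$pair_coupling$codon5[i], cods)
      cl <- match(spec$pair_coupling$codon3[i], cods[sense])
      if (is.na(cl)) stop("coupled 3' codon has zero base emission")
      P[r, cl] <- P[r, cl] * spec$pair_coupling$factor[i]
    }
    P <- P / rowSums(P)
    cum <- t(apply(P, 1, cumsum))
    stream <- integer(total)
    u <- stats::runif(total)
    pos <- 0L
    for (i in seq_len(spec$n_orfs)) {
      st <- aug
      for (j in seq_len(n_internal[i])) {
        pos <- pos + 1L
        st <- sense[findInterval(u[pos], cum[st, ]) + 1L]
        stream[pos] <- st
      }
    }
  }
  stop_idx <- ter[sample.int(3L, spec$n_orfs, replace = TRUE, prob = p_ter)]
  ends <- cumsum(n_internal)
  starts <- ends - n_internal + 1L
  dna <- chartr("U", "T", cods)
  seqs <- vapply(seq_len(spec$n_orfs), function(i) {
    paste0("ATG",
           paste(dna[stream[starts[i]:ends[i]]], collapse = ""),
           dna[stop_idx[i]])
  }, character(1))
  n_rib <- round(spec$ribosomal_fraction * spec$n_orfs)
  rib <- logical(spec$n_orfs)
  rib[sample.int(spec$n_orfs, n_rib)] <- TRUE
  orf_set(sprintf("ORF%05d", seq_len(spec$n_orfs)), seqs,
          is_ribosomal = rib, provenance = "synthetic", validate = FALSE)
}

#' Generate a synthetic four-condition expression matrix
#'
#' RPKM(orf, condition) = base x condition multiplier x log-normal noise.
#' Base values are log-normal (ribosomal ORFs boosted, as expected of the
#' highly expressed reference set); condition multipliers are either a fixed
#' length-4 vector or per-ORF log-normal draws. Deterministic for a fixed
#' spec.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @param orfs The \code{\link{orf_set}} to cover (normally from
#'   \code{\link{generate_orfs}} with the same spec).
#' @return An \code{\link{expression_matrix}} over \code{orfs$orf_id}.
#' @export
generate_expression <- function(spec, orfs) {
  stopifnot(inherits(spec, "synthetic_spec"))
  e <- spec$expression
  n <- nrow(orfs)
  set.seed(spec$seed + 1L)
  base <- stats::rlnorm(n, e$base_meanlog, e$base_sdlog)
  base[orfs$is_ribosomal] <- base[orfs$is_ribosomal] * e$ribosomal_boost
  mult <- if (is.null(e$multipliers)) {
    matrix(stats::rlnorm(4L * n, 0, e$condition_sdlog), nrow = n)
  } else {
    matrix(rep(e$multipliers, each = n), nrow = n)
  }
  noise <- if (e$noise_sdlog > 0)
    matrix(stats::rlnorm(4L * n, 0, e$noise_sdlog), nrow = n)
  else matrix(1, nrow = n, ncol = 4L)
  rpkm <- base * mult * noise
  colnames(rpkm) <- CONDITIONS
  expression_matrix(orfs$orf_id, as.data.frame(rpkm))
}
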