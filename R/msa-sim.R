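#' Specification of a synthetic multiple sequence alignment
#'
#' Emulates an alignment of conserved orthologs: every column has a consensus
#' residue; each cell keeps the consensus, substitutes within the column's
#' residue set (the planted pattern position for pattern columns, the smallest
#' physicochemical class of the consensus for background columns), or
#' substitutes with a uniform residue across classes, at the stated rates.
#' Gaps are inserted independently at `gap_rate`.
#'
#' @param n_sequences number of aligned sequences.
#' @param length alignment width (columns).
#' @param pattern planted `pattern_expr` or pattern text (no variable gaps).
#' @param planted_at 1-based column of the first pattern position.
#' @param within_class_rate probability of an in-set substitution.
#' @param across_class_rate probability of a uniform (any-residue)
#'   substitution; applied before the within-class draw.
#' @param gap_rate per-cell gap probability.
#' @param table a [residue_class_table()].
#' @param seed integer seed.
#' @return validated list of class `msa_sim_spec`.
#' @export
msa_sim_spec <- function(n_sequences = 40, length = 60,
                         pattern = "[pi]-[ST]-[Omega]-[ST]-[Psi]-[zeta]-[zeta]-[Omega]",
                         planted_at = 20,
                         within_class_rate = 0.5,
                         across_class_rate = 0,
                         gap_rate = 0,
                         table = residue_class_table(),
                         seed = 1) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern, table)
  if (any(vapply(pattern$positions, function(p) p$type == "gap", FALSE)))
    stop("planted patterns may not contain variable gaps")
  np <- base::length(pattern$positions)
  if (planted_at < 1 || planted_at + np - 1 > length)
    stop("planted pattern (width ", np, " at column ", planted_at,
         ") does not fit in alignment of length ", length)
  rates <- c(within_class_rate, across_class_rate, gap_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  structure(list(n_sequences = as.integer(n_sequences),
                 length = as.integer(length), pattern = pattern,
                 planted_at = as.integer(planted_at),
                 within_class_rate = within_class_rate,
                 across_class_rate = across_class_rate,
                 gap_rate = gap_rate, table = table, seed = as.integer(seed)),
            class = "msa_sim_spec")
}

#' Simulate an alignment with a planted conserved pattern
#'
#' @param spec an [msa_sim_spec()].
#' @return named character vector of aligned sequences (class attribute
#'   `planted_at` gives the pattern's first column).
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "msa_sim_spec"))
  set.seed(spec$seed)
  L <- spec$length
  np <- length(spec$pattern$positions)
  pat_cols <- seq.int(spec$planted_at, length.out = np)
  # per-column residue sets and consensus
  sets <- vector("list", L)
  consensus <- character(L)
  for (j in seq_len(L)) {
    if (j %in% pat_cols) {
      p <- spec$pattern$positions[[match(j, pat_cols)]]
      sets[[j]] <- p$residues
      consensus[j] <- p$residues[sample.int(length(p$residues), 1)]
    } else {
      consensus[j] <- AA20[sample.int(20, 1)]
      cls <- .smallest_class(consensus[j], spec$table)
      sets[[j]] <- if (is.null(cls)) consensus[j] else spec$table[[cls]]
    }
  }
  seqs <- character(spec$n_sequences)
  for (i in seq_len(spec$n_sequences)) {
    chars <- consensus
    u <- stats::runif(L)
    across <- u < spec$across_class_rate
    within <- !across & (u < spec$across_class_rate + spec$within_class_rate)
    if (any(across))
      chars[across] <- AA20[sample.int(20, sum(across), replace = TRUE)]
    for (j in which(within))
      chars[j] <- sets[[j]][sample.int(length(sets[[j]]), 1)]
    if (spec$gap_rate > 0) {
      g <- stats::runif(L) < spec$gap_rate
      chars[g] <- "-"
    }
    seqs[i] <- paste(chars, collapse = "")
  }
  structure(stats::setNames(seqs, sprintf("seq%03d", seq_len(spec$n_sequences))),
            planted_at = spec$planted_at)
}
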