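AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Physicochemical residue-class table
#'
#' The normalized-symbol classes used to write conserved protein patterns:
#' Omega (aromatic), Psi (aliphatic), pi (small), zeta (hydrophilic),
#' Phi (hydrophobic), plus the charge classes `+` and `-`. Memberships follow
#' the standard normalized nomenclature and are overridable, since different
#' sources vary at the margins.
#'
#' @param overrides optional named list replacing individual classes.
#' @return named list of class `residue_class_table`; names are class symbols,
#'   values character vectors of one-letter residues.
#' @export
residue_class_table <- function(overrides = NULL) {
  tbl <- list(
    Omega = c("F", "W", "Y", "H"),
    Psi   = c("I", "L", "V", "M"),
    pi    = c("A", "G", "P", "S"),
    zeta  = c("D", "E", "H", "K", "N", "Q", "R", "S", "T"),
    Phi   = c("A", "C", "F", "I", "L", "M", "V", "W", "Y"),
    `+`   = c("K", "R", "H"),
    `-`   = c("D", "E"))
  if (!is.null(overrides)) for (nm in names(overrides))
    tbl[[nm]] <- overrides[[nm]]
  miss <- setdiff(AA20, unique(unlist(tbl)))
  if (length(miss))
    stop("class table leaves residues unclassified: ",
         paste(miss, collapse = ", "))
  structure(tbl, class = "residue_class_table")
}

#' Classes containing a residue
#'
#' @param residue one-letter residue code.
#' @param table a [residue_class_table()].
#' @param permissive if TRUE, unknown codes return `character(0)` instead of
#'   an error.
#' @return character vector of class symbols in table order.
#' @export
classify_residue <- function(residue, table = residue_class_table(),
                             permissive = FALSE) {
  if (!(residue %in% AA20)) {
    if (permissive) return(character(0))
    stop("unknown residue code '", residue, "'")
  }
  names(table)[vapply(table, function(s) residue %in% s, FALSE)]
}

# --- pattern expressions -----------------------------------------------------

.pos_literal <- function(r) list(type = "literal", residues = r)
.pos_set <- function(rs) list(type = "set", residues = sort(unique(rs)))
.pos_class <- function(sym, table) list(type = "class", class = sym,
                                        residues = table[[sym]])
.pos_wild <- function() list(type = "wildcard", residues = AA20)
.pos_gap <- function(m, n) list(type = "gap", min = m, max = n)

.new_pattern <- function(positions, table) {
  structure(list(positions = positions, table = table), class = "pattern_expr")
}

#' Parse a PROSITE-like pattern expression
#'
#' Positions are separated by `-`. A single letter is a literal; `x` is a
#' wildcard; `x(m,n)` is a variable gap of m to n wildcard positions;
#' `[...]` is either a class symbol from the table (e.g. `[Omega]`, `[pi]`,
#' `[+]`) or an explicit residue set (e.g. `[ST]`).
#'
#' @param text pattern string, e.g.
#'   `"[pi]-[ST]-[Omega]-[ST]-[Psi]-[zeta]-[zeta]-[Omega]"`.
#' @param table a [residue_class_table()].
#' @return object of class `pattern_expr`.
#' @export
parse_pattern <- function(text, table = residue_class_table()) {
  toks <- strsplit(gsub("\\s", "", text), "-(?![^\\[]*\\])", perl = TRUE)[[1]]
  pos <- vector("list", length(toks))
  for (i in seq_along(toks)) {
    t <- toks[i]
    if (t == "x") pos[[i]] <- .pos_wild()
    else if (grepl("^x\\([0-9]+,[0-9]+\\)$", t)) {
      mn <- as.integer(strsplit(gsub("^x\\(|\\)$", "", t), ",")[[1]])
      if (mn[1] > mn[2])
        stop("malformed pattern at position ", i, ": gap min > max in '", t, "'")
      pos[[i]] <- .pos_gap(mn[1], mn[2])
    } else if (grepl("^\\[[^]]+\\]$", t)) {
      inner <- gsub("^\\[|\\]$", "", t)
      if (inner %in% names(table)) pos[[i]] <- .pos_class(inner, table)
      else if (grepl("^[A-Z]+$", inner) && all(strsplit(inner, "")[[1]] %in% AA20))
        pos[[i]] <- .pos_set(strsplit(inner, "")[[1]])
      else stop("malformed pattern at position ", i, ": '", t, "'")
    } else if (grepl("^[A-Z]$", t) && t %in% AA20) {
      pos[[i]] <- .pos_literal(t)
    } else stop("malformed pattern at position ", i, ": '", t, "'")
  }
  .new_pattern(pos, table)
}

#' Format a pattern expression as text
#' @param pattern a `pattern_expr`.
#' @return character scalar in the syntax accepted by [parse_pattern()].
#' @export
format_pattern <- function(pattern) {
  paste(vapply(pattern$positions, function(p) switch(
    p$type,
    literal = p$residues,
    set = paste0("[", paste(p$residues, collapse = ""), "]"),
    class = paste0("[", p$class, "]"),
    wildcard = "x",
    gap = sprintf("x(%d,%d)", p$min, p$max)), ""), collapse = "-")
}

#' @export
print.pattern_expr <- function(x, ...) {
  cat("pattern:", format_pattern(x), "\n")
  invisible(x)
}

# smallest class (by member count, then table order) containing all residues
.smallest_class <- function(residues, table) {
  ok <- vapply(table, function(s) all(residues %in% s), FALSE)
  if (!any(ok)) return(NULL)
  cand <- names(table)[ok]
  cand[order(vapply(table[cand], length, 0L))][1]
}

#' Derive conserved patterns from a multiple sequence alignment
#'
#' Column classification: a column whose gap fraction exceeds 50% becomes a
#' wildcard; otherwise gaps are dropped and the column becomes a literal if
#' one residue reaches `min_literal_frac`, an explicit set if it holds at most
#' `max_set_size` distinct residues, the smallest physicochemical class
#' containing all its residues if one exists, and a wildcard otherwise.
#' Maximal runs of non-wildcard columns of length at least `min_window_len`
#' are returned as patterns.
#'
#' @param alignment character vector of equal-length aligned sequences
#'   (gap character `-`), or a path to an aligned FASTA file.
#' @param min_literal_frac frequency needed for a literal call (default 0.9).
#' @param max_set_size largest explicit residue set (default 2).
#' @param min_window_len minimum pattern length (default 3).
#' @param table a [residue_class_table()].
#' @return list of `pattern_expr` objects, each with attribute `start`
#'   (1-based first alignment column).
#' @export
derive_pattern <- function(alignment, min_literal_frac = 0.9,
                           max_set_size = 2, min_window_len = 3,
                           table = residue_class_table()) {
  if (is.character(alignment) && length(alignment) == 1 &&
      file.exists(alignment))
    alignment <- read_fasta(alignment)
  if (!length(alignment)) stop("empty alignment")
  L <- unique(nchar(alignment))
  if (length(L) != 1) stop("aligned sequences must have equal length")
  if (L == 0) stop("empty alignment")
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  cols <- vector("list", L)
  for (j in seq_len(L)) {
    col <- mat[, j]
    gap_frac <- mean(!(col %in% AA20))
    if (gap_frac > 0.5) { cols[[j]] <- .pos_wild(); next }
    col <- col[col %in% AA20]
    freq <- sort(base::table(col) / length(col), decreasing = TRUE)
    distinct <- names(freq)
    if (freq[1] >= min_literal_frac) cols[[j]] <- .pos_literal(distinct[1])
    else if (length(distinct) <= max_set_size) cols[[j]] <- .pos_set(distinct)
    else {
      cls <- .smallest_class(distinct, table)
      cols[[j]] <- if (is.null(cls)) .pos_wild() else .pos_class(cls, table)
    }
  }
  is_wild <- vapply(cols, function(p) p$type == "wildcard", FALSE)
  r <- rle(!is_wild)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (i in seq_along(r$values)) {
    if (!r$values[i] || r$lengths[i] < min_window_len) next
    p <- .new_pattern(cols[starts[i]:ends[i]], table)
    attr(p, "start") <- starts[i]
    out[[length(out) + 1L]] <- p
  }
  out
}

# fixed-length expansions of a pattern: list of lists of residue sets
.expand_pattern <- function(pattern) {
  gaps <- which(vapply(pattern$positions, function(p) p$type == "gap", FALSE))
  base <- lapply(pattern$positions, function(p)
    if (p$type == "gap") NULL else p$residues)
  if (!length(gaps)) return(list(Filter(Negate(is.null), base)))
  choices <- lapply(gaps, function(g)
    seq(pattern$positions[[g]]$min, pattern$positions[[g]]$max))
  combos <- expand.grid(choices)
  lapply(seq_len(nrow(combos)), function(ri) {
    out <- list()
    for (i in seq_along(pattern$positions)) {
      p <- pattern$positions[[i]]
      if (p$type == "gap") {
        len <- combos[ri, match(i, gaps)]
        if (len > 0) out <- c(out, rep(list(AA20), len))
      } else out <- c(out, list(p$residues))
    }
    out
  })
}

.empty_matches <- function() data.frame(seq_id = character(0),
                                        start = integer(0), end = integer(0),
                                        match = character(0),
                                        kind = character(0),
                                        stringsAsFactors = FALSE)

#' Scan sequences with a degenerate pattern
#'
#' Reports every (including overlapping) position where the pattern matches.
#' Variable gaps are resolved by enumerating all gap lengths; matches that
#' produce identical spans are reported once. Coordinates are 1-based and
#' inclusive.
#'
#' @param pattern a `pattern_expr` or pattern text for [parse_pattern()].
#' @param sequences named character vector of protein sequences, or a FASTA
#'   path.
#' @param kind label written to the `kind` column (default "pattern").
#' @return data.frame: seq_id, start, end, match, kind.
#' @export
scan_pattern <- function(pattern, sequences, kind = "pattern") {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences) && !grepl("^[A-Z]+$", sequences))
    sequences <- read_fasta(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  expansions <- .expand_pattern(pattern)
  res <- list()
  for (si in seq_along(sequences)) {
    chars <- strsplit(toupper(sequences[[si]]), "")[[1]]
    n <- length(chars)
    for (sets in expansions) {
      Lp <- length(sets)
      if (Lp == 0 || Lp > n) next
      ok <- rep(TRUE, n - Lp + 1L)
      for (p in seq_len(Lp)) {
        ok <- ok & (chars[seq.int(p, p + n - Lp)] %in% sets[[p]])
        if (!any(ok)) break
      }
      st <- which(ok)
      if (length(st))
        res[[length(res) + 1L]] <- data.frame(
          seq_id = names(sequences)[si], start = st, end = st + Lp - 1L,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(.empty_matches())
  out <- unique(do.call(rbind, res))
  out <- out[order(out$seq_id, out$start, out$end), , drop = FALSE]
  out$match <- vapply(seq_len(nrow(out)), function(i)
    substr(sequences[[out$seq_id[i]]], out$start[i], out$end[i]), "")
  out$kind <- kind
  rownames(out) <- NULL
  out
}

#' Scan for CRAC and CARC cholesterol-recognition motifs
#'
#' CRAC, read N to C, is `(L/V)-x(m,n)-Y-x(m,n)-(K/R)`; its mirrored analog
#' CARC is `(K/R)-x(m,n)-(Y/F/W)-x(m,n)-(L/V)`. The central aromatic defaults
#' to strict Y for CRAC and Y/F/W for CARC; both are configurable, as is the
#' spacing (default 1 to 5 wildcards on each side). All matches, including
#' overlapping ones, are reported with their kind.
#'
#' @param sequences named character vector or FASTA path.
#' @param spacing integer `(m, n)` gap bounds.
#' @param crac_center,carc_center allowed central aromatic residues.
#' @return data.frame: seq_id, start, end, match, kind (CRAC or CARC).
#' @export
scan_crac_carc <- function(sequences, spacing = c(1, 5),
                           crac_center = "Y",
                           carc_center = c("Y", "F", "W")) {
  stopifnot(length(spacing) == 2, spacing[1] <= spacing[2], spacing[1] >= 0)
  tb <- residue_class_table()
  gap <- .pos_gap(spacing[1], spacing[2])
  crac <- .new_pattern(list(.pos_set(c("L", "V")), gap, .pos_set(crac_center),
                            gap, .pos_set(c("K", "R"))), tb)
  carc <- .new_pattern(list(.pos_set(c("K", "R")), gap, .pos_set(carc_center),
                            gap, .pos_set(c("L", "V"))), tb)
  out <- rbind(scan_pattern(crac, sequences, kind = "CRAC"),
               scan_pattern(carc, sequences, kind = "CARC"))
  out <- out[order(out$seq_id, out$start, out$end, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# --- FASTA I/O (via Biostrings) ---------------------------------------------

#' Read protein sequences or an aligned FASTA file
#' @param path FASTA path.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#' @param sequences named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
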