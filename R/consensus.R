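#' Build the virtual consensus structure (frequency multiset)
#'
#' Aggregates the interaction sets of all models into a multiset: every
#' interaction observed in any model gets an entry carrying its occurrence
#' count `c` and fuzzy membership `p = c/N`, where `N` is the number of
#' contributing models.  Constraint flags start at `"none"`.
#'
#' @param sets List of [interaction_set()] objects (at least two: a
#'   consensus over fewer models carries no signal).
#' @param residues Optional residue universe (data frame `chain, number,
#'   icode, base` in unified order) enabling dot-bracket constraints and
#'   export.
#' @return A `consensus_multiset`: list with `n_models`, `entries` (data
#'   frame `key, kind, chain_i, num_i, icode_i, chain_j, num_j, icode_j, lw,
#'   count, membership, flag`) and `residues`.
#' @export
build_frequency_multiset <- function(sets, residues = NULL) {
  if (length(sets) < 2L) {
    stop_rnac("ensemble_too_small",
              "consensus requires at least two models; got %d", length(sets))
  }
  all <- do.call(rbind, lapply(sets, function(s)
    as.data.frame(s)[c("key", "kind", "chain_i", "num_i", "icode_i",
                       "chain_j", "num_j", "icode_j", "lw")]))
  counts <- table(all$key)
  entries <- all[!duplicated(all$key), , drop = FALSE]
  entries$count <- as.integer(counts[entries$key])
  entries$membership <- entries$count / length(sets)
  entries$flag <- "none"
  entries <- entries[order(entries$key), , drop = FALSE]
  rownames(entries) <- NULL
  cm <- list(n_models = length(sets), entries = entries, residues = residues)
  class(cm) <- "consensus_multiset"
  cm
}

#' @export
print.consensus_multiset <- function(x, ...) {
  cat(sprintf("<consensus_multiset> %d entries over %d models\n",
              nrow(x$entries), x$n_models))
  tab <- table(x$entries$kind)
  cat(paste(sprintf("  %s: %d", names(tab), tab), collapse = "\n"), "\n")
  invisible(x)
}

#' Threshold consensus subset
#'
#' Returns the keys of interactions observed in at least `n` models (the
#' confidence level).  Constraint-required entries are retained regardless
#' of their count; forbidden (`x`) entries are excluded regardless.
#'
#' @param cm A `consensus_multiset`.
#' @param n Confidence level, `1 <= n <= n_models`.
#' @param required_override Keep required entries irrespective of count
#'   (default `TRUE`).
#' @return Character vector of interaction keys.
#' @export
threshold_consensus <- function(cm, n, required_override = TRUE) {
  stopifnot(inherits(cm, "consensus_multiset"))
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n > cm$n_models) {
    stop_rnac("parameter_error",
              "confidence level must lie in [1, %d]; got %s",
              cm$n_models, format(n))
  }
  e <- cm$entries
  keep <- e$count >= n
  if (required_override) keep <- keep | e$flag == "required"
  keep <- keep & e$flag != "x_forbidden"
  e$key[keep]
}

# ---- dot-bracket constraints -------------------------------------------

BRACKET_OPEN <- c("(", "[", "{", "<")
BRACKET_CLOSE <- c(")", "]", "}", ">")

#' Parse an extended dot-bracket constraint
#'
#' Bracket families `()`, `[]`, `{}`, `<>` each match with their own stack,
#' so pseudoknots across families are allowed.  `.` marks an unconstrained
#' position and `x` a position forced to be unpaired (no canonical or
#' non-canonical pairing).
#'
#' @param db Dot-bracket string.
#' @param sequence_length Expected length.
#' @return A `constraint_2d`: list with `length`, `states` (character vector
#'   of `"free"`, `"forced_unpaired"`, or `"paired"`), and `pairs` (data
#'   frame `i, j` with `i < j`).
#' @export
#' @examples
#' parse_constraints("((.x.))", 7)
parse_constraints <- function(db, sequence_length) {
  stopifnot(is_string(db))
  chars <- strsplit(db, "")[[1L]]
  if (length(chars) != sequence_length) {
    stop_rnac("constraint_error",
              "constraint length %d does not match sequence length %d",
              length(chars), sequence_length)
  }
  ok <- chars %in% c(BRACKET_OPEN, BRACKET_CLOSE, ".", "x")
  if (!all(ok)) {
    stop_rnac("constraint_error",
              "invalid constraint character '%s' at position %d",
              chars[!ok][1L], which(!ok)[1L])
  }
  stacks <- rep(list(integer()), length(BRACKET_OPEN))
  pairs <- list()
  states <- ifelse(chars == "x", "forced_unpaired", "free")
  for (pos in seq_along(chars)) {
    ch <- chars[pos]
    fam <- match(ch, BRACKET_OPEN)
    if (!is.na(fam)) {
      stacks[[fam]] <- c(stacks[[fam]], pos)
      next
    }
    fam <- match(ch, BRACKET_CLOSE)
    if (!is.na(fam)) {
      if (!length(stacks[[fam]])) {
        stop_rnac("constraint_error",
                  "unbalanced '%s' at position %d", ch, pos)
      }
      i <- stacks[[fam]][length(stacks[[fam]])]
      stacks[[fam]] <- stacks[[fam]][-length(stacks[[fam]])]
      pairs[[length(pairs) + 1L]] <- c(i, pos)
      states[c(i, pos)] <- "paired"
    }
  }
  open_left <- which(lengths(stacks) > 0L)
  if (length(open_left)) {
    pos <- stacks[[open_left[1L]]][1L]
    stop_rnac("constraint_error", "unbalanced '%s' at position %d",
              BRACKET_OPEN[open_left[1L]], pos)
  }
  pairs <- if (length(pairs)) {
    m <- do.call(rbind, pairs)
    data.frame(i = m[, 1L], j = m[, 2L])[order(m[, 1L]), , drop = FALSE]
  } else data.frame(i = integer(), j = integer())
  rownames(pairs) <- NULL
  out <- list(length = sequence_length, states = states, pairs = pairs)
  class(out) <- "constraint_2d"
  out
}

# residue at unified sequence position -> (chain, number, icode)
position_residue <- function(residues, pos) {
  if (pos < 1L || pos > nrow(residues)) {
    stop_rnac("constraint_error",
              "constrained position %d outside sequence of length %d",
              pos, nrow(residues))
  }
  residues[pos, , drop = FALSE]
}

#' Apply a 2D constraint to a consensus multiset
#'
#' Every constrained base pair is flagged `required`; if absent from all
#' models it is created with count 0 and membership forced to 1.0, so that
#' weighted scoring treats it as a full consensus member.  Every pair
#' interaction (canonical or non-canonical) touching a forced-unpaired
#' (`x`) position is flagged `x_forbidden`: it leaves the consensus and
#' counts fully against models that contain it.  Stackings are never
#' constraint-flagged.
#'
#' @param cm A `consensus_multiset` built with a residue universe.
#' @param constraint A `constraint_2d` from [parse_constraints()].
#' @return The updated `consensus_multiset`.
#' @export
apply_constraints <- function(cm, constraint) {
  stopifnot(inherits(cm, "consensus_multiset"),
            inherits(constraint, "constraint_2d"))
  residues <- cm$residues
  if (is.null(residues)) {
    stop_rnac("constraint_error",
              "consensus carries no residue universe; rebuild with residues=")
  }
  if (constraint$length != nrow(residues)) {
    stop_rnac("constraint_error",
              "constraint length %d does not match residue count %d",
              constraint$length, nrow(residues))
  }
  e <- cm$entries
  # required pairs
  if (nrow(constraint$pairs)) {
    for (r in seq_len(nrow(constraint$pairs))) {
      ri <- position_residue(residues, constraint$pairs$i[r])
      rj <- position_residue(residues, constraint$pairs$j[r])
      key <- interaction("canonical_pair", ri$chain, ri$number,
                         rj$chain, rj$number,
                         icode_i = ri$icode, icode_j = rj$icode)$key
      hit <- match(key, e$key)
      if (is.na(hit)) {
        row <- interaction("canonical_pair", ri$chain, ri$number,
                           rj$chain, rj$number,
                           icode_i = ri$icode, icode_j = rj$icode)
        row <- row[c("key", "kind", "chain_i", "num_i", "icode_i",
                     "chain_j", "num_j", "icode_j", "lw")]
        row$count <- 0L
        row$membership <- 1.0
        row$flag <- "required"
        e <- rbind(e, row)
      } else {
        e$flag[hit] <- "required"
        e$membership[hit] <- 1.0
      }
    }
  }
  # forced-unpaired positions forbid any pairing of that residue
  xpos <- which(constraint$states == "forced_unpaired")
  if (length(xpos)) {
    banned <- residues[xpos, , drop = FALSE]
    bid <- paste(banned$chain, banned$number, banned$icode, sep = "\r")
    is_pair <- e$kind %in% c("canonical_pair", "noncanonical_pair")
    touch <- (paste(e$chain_i, e$num_i, e$icode_i, sep = "\r") %in% bid) |
      (paste(e$chain_j, e$num_j, e$icode_j, sep = "\r") %in% bid)
    clash <- is_pair & touch & e$flag == "required"
    if (any(clash)) {
      stop_rnac("constraint_error",
                "constraint both requires and forbids pair %s", e$key[clash][1L])
    }
    e$flag[is_pair & touch] <- "x_forbidden"
  }
  e <- e[order(e$key), , drop = FALSE]
  rownames(e) <- NULL
  cm$entries <- e
  cm
}

# ---- dot-bracket export ------------------------------------------------

# TRUE where pairs (i1,j1) and (i2,j2) cross (pseudoknot)
pairs_cross <- function(i1, j1, i2, j2) {
  (i1 < i2 & i2 < j1 & j1 < j2) | (i2 < i1 & i1 < j2 & j2 < j1)
}

#' Export the consensus as a dot-bracket secondary structure
#'
#' Canonical-pair entries are selected either by a threshold confidence
#' level `n` or, in weighted mode, by a membership cutoff (default 0.5, the
#' point where the fuzzy scoring rules switch from penalizing to rewarding
#' inclusion).  Selected pairs are sorted by descending membership (ties:
#' lexicographic key) and accepted greedily while both positions are unused;
#' bracket families are then assigned first-fit over `()`, `[]`, `{}`, `<>`
#' via the pseudoknot-conflict graph.
#'
#' @param cm A `consensus_multiset` carrying a residue universe.
#' @param confidence_level Threshold `n`; `NULL` for the membership cutoff.
#' @param cutoff Membership cutoff used when `confidence_level` is `NULL`.
#' @return Character vector of two strings: sequence line and structure line.
#' @export
consensus_to_dotbracket <- function(cm, confidence_level = NULL,
                                    cutoff = 0.5) {
  stopifnot(inherits(cm, "consensus_multiset"))
  residues <- cm$residues
  if (is.null(residues)) {
    stop_rnac("constraint_error",
              "consensus carries no residue universe; rebuild with residues=")
  }
  e <- cm$entries
  e <- e[e$kind == "canonical_pair" & e$flag != "x_forbidden", , drop = FALSE]
  if (!is.null(confidence_level)) {
    keep <- threshold_consensus(cm, confidence_level)
    e <- e[e$key %in% keep, , drop = FALSE]
  } else {
    e <- e[e$membership >= cutoff | e$flag == "required", , drop = FALSE]
  }
  rid <- paste(residues$chain, residues$number, residues$icode, sep = "\r")
  pos_i <- match(paste(e$chain_i, e$num_i, e$icode_i, sep = "\r"), rid)
  pos_j <- match(paste(e$chain_j, e$num_j, e$icode_j, sep = "\r"), rid)
  if (anyNA(pos_i) || anyNA(pos_j)) {
    stop_rnac("constraint_error",
              "consensus pair references a residue outside the universe")
  }
  ord <- order(-e$membership, e$key)
  used <- logical(nrow(residues))
  acc_i <- integer(); acc_j <- integer()
  for (r in ord) {
    i <- min(pos_i[r], pos_j[r]); j <- max(pos_i[r], pos_j[r])
    if (used[i] || used[j]) next
    used[c(i, j)] <- TRUE
    acc_i <- c(acc_i, i); acc_j <- c(acc_j, j)
  }
  struct <- rep(".", nrow(residues))
  if (length(acc_i)) {
    ord2 <- order(acc_i)
    acc_i <- acc_i[ord2]; acc_j <- acc_j[ord2]
    fam <- integer(length(acc_i))
    for (k in seq_along(acc_i)) {
      conflicts <- fam[seq_len(k - 1L)][
        pairs_cross(acc_i[seq_len(k - 1L)], acc_j[seq_len(k - 1L)],
                    acc_i[k], acc_j[k])]
      f <- setdiff(seq_along(BRACKET_OPEN), conflicts)[1L]
      if (is.na(f)) {
        stop_rnac("overflow_error",
                  "more than %d mutually crossing pair families",
                  length(BRACKET_OPEN))
      }
      fam[k] <- f
    }
    struct[acc_i] <- BRACKET_OPEN[fam]
    struct[acc_j] <- BRACKET_CLOSE[fam]
  }
  c(paste0(residues$base, collapse = ""), paste0(struct, collapse = ""))
}

#' Write the consensus multiset as CSV
#'
#' Key fields plus count, membership (6 decimals), and constraint flag.
#'
#' @param cm A `consensus_multiset`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_consensus_csv <- function(cm, path) {
  e <- cm$entries
  out <- e[c("kind", "chain_i", "num_i", "icode_i",
             "chain_j", "num_j", "icode_j", "lw", "count")]
  out$membership <- fmt_num(e$membership)
  out$constraint_flag <- e$flag
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
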