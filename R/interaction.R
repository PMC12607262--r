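INTERACTION_KINDS <- c("canonical_pair", "noncanonical_pair", "stacking")

#' Leontis-Westhof geometric families
#'
#' The twelve base-pair families: cis/trans orientation crossed with the
#' unordered pair of interacting edges (Watson-Crick, Hoogsteen, Sugar).
#' Codes are written `c`/`t` followed by two edge letters in `W < H < S`
#' priority, e.g. `"tWH"`.
#'
#' @return Character vector of the 12 canonical codes.
#' @export
#' @examples
#' lw_codes()
lw_codes <- function() {
  edges <- c("W", "H", "S")
  pairs <- c("WW", "WH", "WS", "HH", "HS", "SS")
  as.vector(outer(c("c", "t"), pairs, paste0))
}

# Accepts any of the 18 orientation x edge x edge strings, returns the
# canonical 12-family code (edges sorted W < H < S).  NA/"" pass through as "".
lw_normalize <- function(lw) {
  lw[is.na(lw)] <- ""
  out <- lw
  todo <- lw != ""
  if (!any(todo)) return(out)
  v <- lw[todo]
  ok <- grepl("^[ct][WHS][WHS]$", v)
  if (!all(ok)) {
    stop_rnac("lw_error", "invalid Leontis-Westhof code(s): %s",
              paste(unique(v[!ok]), collapse = ", "))
  }
  rank <- c(W = 1L, H = 2L, S = 3L)
  e1 <- substr(v, 2, 2); e2 <- substr(v, 3, 3)
  swap <- rank[e1] > rank[e2]
  out[todo] <- paste0(substr(v, 1, 1),
                      ifelse(swap, e2, e1),
                      ifelse(swap, e1, e2))
  out
}

# TRUE where residue (chain_i, num_i, icode_i) sorts after residue j;
# ordering is (chain label, number, insertion code), all lexicographic on
# chain/icode and numeric on number.
res_after <- function(chain_i, num_i, icode_i, chain_j, num_j, icode_j) {
  (chain_i > chain_j) |
    (chain_i == chain_j & num_i > num_j) |
    (chain_i == chain_j & num_i == num_j & icode_i > icode_j)
}

# canonical residue ordering + LW normalization + key column, vectorized
canonicalize_interactions <- function(df) {
  need <- c("kind", "chain_i", "num_i", "icode_i",
            "chain_j", "num_j", "icode_j", "lw")
  if (!"icode_i" %in% names(df)) df$icode_i <- ""
  if (!"icode_j" %in% names(df)) df$icode_j <- ""
  if (!"lw" %in% names(df)) df$lw <- ""
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_rnac("interaction_error", "interaction table lacks column(s): %s",
              paste(missing, collapse = ", "))
  }
  df <- df[need]
  for (col in c("kind", "chain_i", "icode_i", "chain_j", "icode_j", "lw")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  df$num_i <- as.integer(df$num_i)
  df$num_j <- as.integer(df$num_j)

  bad <- !df$kind %in% INTERACTION_KINDS
  if (any(bad)) {
    stop_rnac("interaction_error", "unknown interaction kind(s): %s",
              paste(unique(df$kind[bad]), collapse = ", "))
  }
  self <- df$chain_i == df$chain_j & df$num_i == df$num_j &
    df$icode_i == df$icode_j
  if (any(self)) {
    stop_rnac("interaction_error", "interaction of a residue with itself")
  }
  df$lw <- lw_normalize(df$lw)
  noncan <- df$kind == "noncanonical_pair"
  if (any(noncan & df$lw == "")) {
    stop_rnac("lw_error", "noncanonical_pair requires a Leontis-Westhof code")
  }
  df$lw[!noncan] <- ""

  swap <- res_after(df$chain_i, df$num_i, df$icode_i,
                    df$chain_j, df$num_j, df$icode_j)
  if (any(swap)) {
    tmp <- df[swap, c("chain_i", "num_i", "icode_i")]
    df[swap, c("chain_i", "num_i", "icode_i")] <-
      df[swap, c("chain_j", "num_j", "icode_j")]
    df[swap, c("chain_j", "num_j", "icode_j")] <- tmp
  }
  df$key <- paste(df$kind, df$chain_i, df$num_i, df$icode_i,
                  df$chain_j, df$num_j, df$icode_j, df$lw, sep = "|")
  df
}

#' Construct a single interaction record
#'
#' @param kind One of `"canonical_pair"`, `"noncanonical_pair"`, `"stacking"`.
#' @param chain_i,num_i,icode_i First residue: chain label, number, insertion
#'   code (`""` for none).
#' @param chain_j,num_j,icode_j Second residue.
#' @param lw Leontis-Westhof code, required iff `kind = "noncanonical_pair"`.
#' @return One-row data frame in canonical orientation with a `key` column.
#' @export
#' @examples
#' interaction("canonical_pair", "A", 1, "A", 10)
interaction <- function(kind, chain_i, num_i, chain_j, num_j,
                        icode_i = "", icode_j = "", lw = "") {
  canonicalize_interactions(data.frame(
    kind = kind, chain_i = chain_i, num_i = num_i, icode_i = icode_i,
    chain_j = chain_j, num_j = num_j, icode_j = icode_j, lw = lw,
    stringsAsFactors = FALSE))
}

#' Canonical identity key of an interaction
#'
#' The key is invariant under swapping the two residues and, for
#' non-canonical pairs, includes the Leontis-Westhof family.  Canonical pairs
#' and stackings are identified by their residue pair alone.
#'
#' @param x An interaction data frame (e.g. from [interaction()] or an
#'   interaction set).
#' @return Character vector of keys, one per row.
#' @export
#' @examples
#' interaction_key(interaction("stacking", "A", 5, "A", 4))
interaction_key <- function(x) {
  if (!is.data.frame(x)) {
    stop_rnac("interaction_error", "expected an interaction data frame")
  }
  if ("key" %in% names(x) && inherits(x, "interaction_set")) return(x$key)
  canonicalize_interactions(x)$key
}

#' Build a model interaction set
#'
#' Validates, canonicalizes and deduplicates interactions belonging to one
#' model.  Duplicate keys collapse to a single row (set semantics).
#'
#' @param df Data frame with columns `kind, chain_i, num_i, icode_i, chain_j,
#'   num_j, icode_j, lw` (insertion-code and `lw` columns optional).
#' @param model_id Model label.
#' @return A data frame of class `interaction_set`, sorted by key, with the
#'   model id in attribute `model_id`.
#' @export
interaction_set <- function(df, model_id) {
  stopifnot(is_string(model_id))
  if (nrow(df) == 0L) {
    out <- data.frame(kind = character(), chain_i = character(),
                      num_i = integer(), icode_i = character(),
                      chain_j = character(), num_j = integer(),
                      icode_j = character(), lw = character(),
                      key = character(), stringsAsFactors = FALSE)
  } else {
    out <- canonicalize_interactions(df)
    out <- out[!duplicated(out$key), , drop = FALSE]
    out <- out[order(out$key), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "model_id") <- model_id
  class(out) <- c("interaction_set", "data.frame")
  out
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(sprintf("<interaction_set> model '%s': %d interaction(s)\n",
              attr(x, "model_id"), nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Read an interaction table
#'
#' Imports per-model interaction annotations from CSV, the ingestion route
#' for annotations produced by external tools (FR3D, RNAView, BPNet, ...).
#' Expected header: `model_id,kind,chain_i,num_i,icode_i,chain_j,num_j,
#' icode_j,lw`; blank insertion-code fields mean "no insertion code".
#'
#' @param path CSV file path.
#' @return Named list of [interaction_set()] objects, one per `model_id`,
#'   in order of first appearance.
#' @export
read_interaction_table <- function(path) {
  if (!file.exists(path)) stop_rnac("io_error", "no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0L) {
    stop_rnac("table_error", "interaction table '%s' is empty", path)
  }
  need <- c("model_id", "kind", "chain_i", "num_i", "icode_i",
            "chain_j", "num_j", "icode_j", "lw")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_rnac("table_error", "interaction table '%s' lacks column(s): %s",
              path, paste(missing, collapse = ", "))
  }
  # row-level validation with line numbers (header is line 1)
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    line <- i + 1L
    if (!row$kind %in% INTERACTION_KINDS) {
      stop_rnac("table_error", "%s line %d: unknown kind '%s'",
                path, line, row$kind)
    }
    lw <- row$lw
    if (row$kind == "noncanonical_pair") {
      if (is.na(lw) || lw == "" || !grepl("^[ct][WHS][WHS]$", lw)) {
        stop_rnac("table_error",
                  "%s line %d: malformed Leontis-Westhof code '%s'",
                  path, line, lw)
      }
    } else if (!is.na(lw) && nzchar(lw) && !grepl("^[ct][WHS][WHS]$", lw)) {
      stop_rnac("table_error",
                "%s line %d: malformed Leontis-Westhof code '%s'",
                path, line, lw)
    }
    if (is.na(suppressWarnings(as.integer(row$num_i))) ||
        is.na(suppressWarnings(as.integer(row$num_j)))) {
      stop_rnac("table_error", "%s line %d: non-integer residue number",
                path, line)
    }
  }
  ids <- unique(df$model_id)
  sets <- lapply(ids, function(id) {
    interaction_set(df[df$model_id == id, -1L, drop = FALSE], model_id = id)
  })
  stats::setNames(sets, ids)
}

#' Write interaction sets to a CSV table
#'
#' Inverse of [read_interaction_table()]: one row per interaction per model.
#'
#' @param sets Named list of `interaction_set` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_interaction_table <- function(sets, path) {
  rows <- lapply(sets, function(s) {
    if (nrow(s) == 0L) return(NULL)
    cbind(model_id = attr(s, "model_id"),
          as.data.frame(s)[c("kind", "chain_i", "num_i", "icode_i",
                             "chain_j", "num_j", "icode_j", "lw")])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(model_id = character(), kind = character(),
                      chain_i = character(), num_i = integer(),
                      icode_i = character(), chain_j = character(),
                      num_j = integer(), icode_j = character(),
                      lw = character())
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
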