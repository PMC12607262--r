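ANALYSIS_SCOPES <- c("pairs_and_stacking", "all_pairs", "canonical_only")

#' Analysis configuration
#'
#' @param mode `"weighted"` (fuzzy consensus) or `"threshold"`.
#' @param confidence_level Integer confidence level `n`, required in
#'   threshold mode (an interaction must occur in at least `n` models).
#' @param scope Interaction scope: `"canonical_only"` (canonical pairs),
#'   `"all_pairs"` (canonical + non-canonical), or `"pairs_and_stacking"`
#'   (default: everything).
#' @param metric Primary ranking metric, `"INF"` (default) or `"F1"`.
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(mode = c("weighted", "threshold"),
                            confidence_level = NULL,
                            scope = ANALYSIS_SCOPES,
                            metric = c("INF", "F1")) {
  mode <- match.arg(mode)
  scope <- match.arg(scope)
  metric <- match.arg(metric)
  if (mode == "threshold") {
    if (is.null(confidence_level) || !is.numeric(confidence_level) ||
        length(confidence_level) != 1L || confidence_level < 1) {
      stop_rnac("parameter_error",
                "threshold mode requires a confidence_level >= 1")
    }
    confidence_level <- as.integer(confidence_level)
  }
  cfg <- list(mode = mode, confidence_level = confidence_level,
              scope = scope, metric = metric)
  class(cfg) <- "analysis_config"
  cfg
}

scope_kinds <- function(scope) {
  switch(scope,
         canonical_only = "canonical_pair",
         all_pairs = c("canonical_pair", "noncanonical_pair"),
         pairs_and_stacking = INTERACTION_KINDS)
}

filter_scope_keys <- function(keys, kinds) {
  keys[sub("\\|.*$", "", keys) %in% kinds]
}

#' Crisp confusion counts against a consensus subset
#'
#' `TP` = interactions in both the model and the consensus subset, `FP` =
#' only in the model, `FN` = only in the consensus.
#'
#' @param model An [interaction_set()] (or character vector of keys).
#' @param consensus Character vector of consensus keys.
#' @return List with integer `TP`, `FP`, `FN` (class `confusion_counts`).
#' @export
crisp_confusion <- function(model, consensus) {
  keys <- if (is.character(model)) model else interaction_key(model)
  out <- list(TP = sum(keys %in% consensus),
              FP = sum(!keys %in% consensus),
              FN = sum(!consensus %in% keys))
  class(out) <- "confusion_counts"
  out
}

#' Fuzzy confusion sums against a weighted consensus
#'
#' For every consensus entry with membership `p` (after constraint
#' overrides): if the model contains it, `p` is added to `TPsum` and `1 - p`
#' to `FPsum`; if the model lacks it, `p` is added to `FNsum`.  Entries
#' flagged `x_forbidden` leave the consensus: when a model contains one it
#' contributes a full unit to `FPsum`.  Model interactions absent from the
#' multiset altogether also count `FPsum += 1` (the `p -> 0` limit).
#'
#' @param model An [interaction_set()].
#' @param cm A `consensus_multiset`.
#' @param kinds Interaction kinds in scope (default: all).
#' @return List with `TPsum`, `FPsum`, `FNsum` (class `confusion_sums`).
#' @export
fuzzy_confusion <- function(model, cm, kinds = INTERACTION_KINDS) {
  stopifnot(inherits(cm, "consensus_multiset"))
  keys <- filter_scope_keys(interaction_key(model), kinds)
  e <- cm$entries[cm$entries$kind %in% kinds, , drop = FALSE]
  forbidden <- e$flag == "x_forbidden"
  active <- e[!forbidden, , drop = FALSE]
  present <- active$key %in% keys
  tp <- sum(active$membership[present])
  fp <- sum(1 - active$membership[present])
  fn <- sum(active$membership[!present])
  # forbidden interactions present in the model: full false positives
  fp <- fp + sum(e$key[forbidden] %in% keys)
  # model interactions unknown to the multiset: membership-zero limit
  fp <- fp + sum(!keys %in% e$key)
  out <- list(TPsum = tp, FPsum = fp, FNsum = fn)
  class(out) <- "confusion_sums"
  out
}

confusion_parts <- function(x) {
  if (inherits(x, "confusion_sums") ||
      all(c("TPsum", "FPsum", "FNsum") %in% names(x))) {
    c(tp = x$TPsum, fp = x$FPsum, fn = x$FNsum)
  } else {
    c(tp = x$TP, fp = x$FP, fn = x$FN)
  }
}

#' Interaction Network Fidelity
#'
#' `INF = sqrt(TP/(TP+FP) * TP/(TP+FN))`, the geometric mean of precision
#' and recall over interaction sets.  Degenerate conventions: an all-zero
#' confusion scores 1 (empty model vs empty consensus agree perfectly);
#' `TP = 0` with any `FP`/`FN` scores 0.
#'
#' @param x A `confusion_counts` or `confusion_sums` object (or list with
#'   `TP`/`FP`/`FN` or `TPsum`/`FPsum`/`FNsum`).
#' @return INF in `[0, 1]`.
#' @export
inf_score <- function(x) {
  p <- confusion_parts(x)
  if (p["tp"] == 0) return(if (p["fp"] == 0 && p["fn"] == 0) 1 else 0)
  unname(sqrt((p["tp"] / (p["tp"] + p["fp"])) *
              (p["tp"] / (p["tp"] + p["fn"]))))
}

#' F1-score over interaction sets
#'
#' `F1 = 2 TP / (2 TP + FP + FN)`, with the same degenerate conventions as
#' [inf_score()].
#'
#' @inheritParams inf_score
#' @return F1 in `[0, 1]`.
#' @export
f1_score <- function(x) {
  p <- confusion_parts(x)
  if (p["tp"] == 0) return(if (p["fp"] == 0 && p["fn"] == 0) 1 else 0)
  unname(2 * p["tp"] / (2 * p["tp"] + p["fp"] + p["fn"]))
}

#' Score and rank an ensemble of models against its consensus
#'
#' Every model is scored in the configured mode and scope; the ranking is
#' sorted by the primary metric in decreasing order with ties broken
#' lexicographically by model id.  Both INF and F1 are always reported.
#'
#' @param sets List of [interaction_set()] objects.
#' @param cm A `consensus_multiset`; built from `sets` when `NULL`.
#' @param cfg An [analysis_config()].
#' @return A `model_ranking` data frame with columns `rank, model_id, INF,
#'   F1` plus the confusion quantities (`TP/FP/FN` or `TPsum/FPsum/FNsum`);
#'   attributes `mode`, `scope`, `metric`.
#' @export
#' @examples
#' sets <- list(
#'   interaction_set(interaction("canonical_pair", "A", 1, "A", 10), "m1"),
#'   interaction_set(interaction("canonical_pair", "A", 1, "A", 10), "m2"))
#' rank_models(sets, cfg = analysis_config("weighted"))
rank_models <- function(sets, cm = NULL, cfg = analysis_config()) {
  if (!length(sets)) stop_rnac("empty_ensemble", "no models to rank")
  stopifnot(inherits(cfg, "analysis_config"))
  if (is.null(cm)) cm <- build_frequency_multiset(sets)
  kinds <- scope_kinds(cfg$scope)
  ids <- vapply(sets, attr, "", "model_id")

  if (cfg$mode == "threshold") {
    if (cfg$confidence_level > cm$n_models) {
      stop_rnac("parameter_error",
                "confidence level %d exceeds number of models %d",
                cfg$confidence_level, cm$n_models)
    }
    consensus <- filter_scope_keys(
      threshold_consensus(cm, cfg$confidence_level), kinds)
    conf <- lapply(sets, function(s)
      crisp_confusion(filter_scope_keys(interaction_key(s), kinds),
                      consensus))
    extra <- data.frame(TP = vapply(conf, `[[`, 0, "TP"),
                        FP = vapply(conf, `[[`, 0, "FP"),
                        FN = vapply(conf, `[[`, 0, "FN"))
  } else {
    conf <- lapply(sets, fuzzy_confusion, cm = cm, kinds = kinds)
    extra <- data.frame(TPsum = vapply(conf, `[[`, 0, "TPsum"),
                        FPsum = vapply(conf, `[[`, 0, "FPsum"),
                        FNsum = vapply(conf, `[[`, 0, "FNsum"))
  }
  out <- data.frame(model_id = ids,
                    INF = vapply(conf, inf_score, 0),
                    F1 = vapply(conf, f1_score, 0),
                    stringsAsFactors = FALSE)
  out <- cbind(out, extra)
  primary <- out[[cfg$metric]]
  ord <- order(-primary, out$model_id)
  out <- out[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "mode") <- cfg$mode
  attr(out, "scope") <- cfg$scope
  attr(out, "metric") <- cfg$metric
  class(out) <- c("model_ranking", "data.frame")
  out
}

#' Write a model ranking as CSV
#'
#' Scores are fixed at 6 decimals so identical runs are byte-identical.
#'
#' @param ranking A `model_ranking` from [rank_models()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(ranking, path) {
  out <- as.data.frame(ranking)
  for (col in setdiff(names(out), c("rank", "model_id", "TP", "FP", "FN"))) {
    out[[col]] <- fmt_num(out[[col]])
  }
  out$mode <- attr(ranking, "mode")
  out$scope <- attr(ranking, "scope")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
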