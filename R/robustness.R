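# draw one uniformly random interaction of a given kind over a residue
# universe (data frame chain, number, icode); NULL if the payload space for
# that kind is exhausted within the model
draw_absent_interaction <- function(set, residues, kind, max_tries = 2000L) {
  n <- nrow(residues)
  keys <- set$key
  for (t in seq_len(max_tries)) {
    ij <- sample.int(n, 2L)
    ri <- residues[ij[1L], ]; rj <- residues[ij[2L], ]
    lw <- if (kind == "noncanonical_pair") sample(lw_codes(), 1L) else ""
    cand <- interaction(kind, ri$chain, ri$number, rj$chain, rj$number,
                        icode_i = ri$icode, icode_j = rj$icode, lw = lw)
    if (!cand$key %in% keys) return(cand)
  }
  NULL
}

#' Apply one random noise operation to an ensemble
#'
#' Randomly selects a model, an interaction kind (canonical, non-canonical,
#' stacking), and an action ("add" or "remove").  An add draws uniform
#' random residue pairs (plus a uniform Leontis-Westhof family for
#' non-canonical pairs) until a previously absent interaction is found; a
#' remove deletes a uniformly chosen existing interaction of that kind.
#' Infeasible draws (nothing to remove, or a saturated payload space) are
#' resampled.  Exactly one interaction differs between input and output.
#' Uses the current RNG state.
#'
#' @param sets Named list of [interaction_set()] objects.
#' @param residues Residue universe data frame (`chain, number, icode`).
#' @return List with `sets` (perturbed ensemble) and `op` (list `model_id,
#'   kind, action, interaction`).
#' @export
perturb_once <- function(sets, residues) {
  stopifnot(length(sets) >= 1L)
  if (nrow(residues) < 2L) {
    stop_rnac("parameter_error", "residue universe needs >= 2 residues")
  }
  for (attempt in seq_len(1000L)) {
    mi <- sample.int(length(sets), 1L)
    kind <- sample(INTERACTION_KINDS, 1L)
    action <- sample(c("add", "remove"), 1L)
    set <- sets[[mi]]
    if (action == "remove") {
      idx <- which(set$kind == kind)
      if (!length(idx)) next
      pick <- idx[sample.int(length(idx), 1L)]
      payload <- as.data.frame(set)[pick, , drop = FALSE]
      df <- as.data.frame(set)[-pick, , drop = FALSE]
    } else {
      payload <- draw_absent_interaction(set, residues, kind)
      if (is.null(payload)) next
      df <- rbind(as.data.frame(set)[names(payload)], payload)
    }
    sets[[mi]] <- interaction_set(
      df[c("kind", "chain_i", "num_i", "icode_i",
           "chain_j", "num_j", "icode_j", "lw")],
      model_id = attr(set, "model_id"))
    return(list(sets = sets,
                op = list(model_id = attr(set, "model_id"), kind = kind,
                          action = action, interaction = payload)))
  }
  stop_rnac("parameter_error",
            "no feasible noise operation found (payload space exhausted)")
}

#' Noise-injection robustness simulation
#'
#' A reference ranking is computed once on the unaltered ensemble.  Each of
#' `n_runs` independent runs then applies `n_iterations` cumulative random
#' alterations ([perturb_once()]); after every alteration the ensemble is
#' re-ranked and the similarity of the noisy ranking to the reference is
#' recorded with each requested metric.  Noise level `n` therefore holds a
#' sample of `n_runs` similarity values after `n` total alterations.
#' Deterministic for a fixed `seed`: run `r` uses substream `seed + r`.
#'
#' @param sets Named list of [interaction_set()] objects (>= 2 models).
#' @param cfg An [analysis_config()].
#' @param n_runs Number of independent runs.
#' @param n_iterations Alterations per run.
#' @param seed Integer seed.
#' @param residues Residue universe; defaults to all residues referenced by
#'   the ensemble.
#' @param metrics Similarity metrics to record.
#' @param es_fraction,rbo_p Metric parameters.
#' @return A `noise_profile`: list with `reference` (model ids in reference
#'   order), `samples` (data frame `level, run, <metric>...`), and `params`.
#' @export
run_noise_simulation <- function(sets, cfg = analysis_config(),
                                 n_runs = 100L, n_iterations = 1000L,
                                 seed = 1L, residues = NULL,
                                 metrics = c("rho", "tau", "es", "rbo"),
                                 es_fraction = 0.25, rbo_p = 0.9) {
  if (length(sets) < 2L) {
    stop_rnac("ensemble_too_small", "robustness analysis needs >= 2 models")
  }
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (is.null(residues)) residues <- ensemble_residue_universe(sets)
  reference <- rank_models(sets, cfg = cfg)$model_id
  metric_fun <- list(
    rho = spearman_rho, tau = kendall_tau,
    es = function(a, b) enrichment_score(a, b, es_fraction),
    rbo = function(a, b) rank_biased_overlap(a, b, rbo_p))
  rows <- vector("list", n_runs * n_iterations)
  pos <- 0L
  for (r in seq_len(n_runs)) {
    set.seed(seed + r)
    cur <- sets
    for (it in seq_len(n_iterations)) {
      cur <- perturb_once(cur, residues)$sets
      noisy <- rank_models(cur, cfg = cfg)$model_id
      vals <- vapply(metrics, function(m) metric_fun[[m]](noisy, reference),
                     0)
      pos <- pos + 1L
      rows[[pos]] <- c(level = it, run = r, vals)
    }
  }
  samples <- as.data.frame(do.call(rbind, rows))
  out <- list(reference = reference, samples = samples,
              params = list(n_runs = n_runs, n_iterations = n_iterations,
                            seed = seed, metrics = metrics,
                            es_fraction = es_fraction, rbo_p = rbo_p,
                            mode = cfg$mode, scope = cfg$scope,
                            metric = cfg$metric))
  class(out) <- "noise_profile"
  out
}

#' @export
print.noise_profile <- function(x, ...) {
  p <- x$params
  cat(sprintf("<noise_profile> %d run(s) x %d iteration(s); metrics: %s\n",
              p$n_runs, p$n_iterations, paste(p$metrics, collapse = ", ")))
  invisible(x)
}

#' Per-level summary of a noise profile against a null model
#'
#' For every noise level and metric: the sample mean, Cohen's d against the
#' null batch-mean distribution, and a Welch t-test with Benjamini-Hochberg
#' adjustment across levels (per metric).
#'
#' @param profile A `noise_profile` from [run_noise_simulation()].
#' @param null A `null_model_ci` covering the same metrics.
#' @return Data frame `level, metric, mean, ci_lower, ci_upper, d, t, p,
#'   p_adj`.
#' @export
noise_significance <- function(profile, null) {
  stopifnot(inherits(profile, "noise_profile"),
            inherits(null, "null_model_ci"))
  s <- profile$samples
  levels <- sort(unique(s$level))
  out <- list()
  for (m in profile$params$metrics) {
    if (!m %in% colnames(null$batch_means)) {
      stop_rnac("parameter_error", "null model lacks metric '%s'", m)
    }
    nullrow <- null$ci[null$ci$metric == m, ]
    by_level <- lapply(levels, function(l) s[[m]][s$level == l])
    names(by_level) <- levels
    sig <- significance_profile(by_level, null$batch_means[, m])
    d <- vapply(by_level, function(x)
      effect_size(x, nullrow$mean, nullrow$sd)$d, 0)
    out[[m]] <- data.frame(level = levels, metric = m,
                           mean = vapply(by_level, mean, 0),
                           ci_lower = nullrow$lower,
                           ci_upper = nullrow$upper,
                           d = d, t = sig$t, p = sig$p, p_adj = sig$p_adj,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# union of residues referenced by an ensemble's interactions
ensemble_residue_universe <- function(sets) {
  all <- do.call(rbind, lapply(sets, function(s) {
    d <- as.data.frame(s)
    rbind(data.frame(chain = d$chain_i, number = d$num_i, icode = d$icode_i,
                     stringsAsFactors = FALSE),
          data.frame(chain = d$chain_j, number = d$num_j, icode = d$icode_j,
                     stringsAsFactors = FALSE))
  }))
  all <- all[!duplicated(paste(all$chain, all$number, all$icode, sep = "\r")),
             , drop = FALSE]
  all <- all[order(all$chain, all$number, all$icode), , drop = FALSE]
  rownames(all) <- NULL
  all
}

#' Generate a synthetic ensemble of interaction sets
#'
#' Emulates an ensemble of annotated models sharing a structural core: a
#' random set of `core_size` interactions present in every model, plus
#' per-model `Poisson(noise_rate)` random additions and deletions.
#' Reproducible under `seed`.
#'
#' @param n_models Number of models (>= 2).
#' @param n_residues Residues in the universe (single chain `A`, random
#'   ACGU bases).
#' @param core_size Interactions shared by all models.
#' @param noise_rate Expected additions (and deletions) per model.
#' @param seed Integer seed.
#' @return List with `sets` (named list of [interaction_set()]) and
#'   `residues` (the universe).
#' @export
#' @examples
#' ens <- synth_ensemble(4, 12, core_size = 8, noise_rate = 2, seed = 1)
#' names(ens$sets)
synth_ensemble <- function(n_models, n_residues, core_size, noise_rate = 0,
                           seed = 1L) {
  if (n_models < 2L) stop_rnac("ensemble_too_small", "need >= 2 models")
  if (core_size > choose(n_residues, 2L) * 3L) {
    stop_rnac("parameter_error",
              "core_size %d infeasible for %d residues", core_size,
              n_residues)
  }
  set.seed(seed)
  residues <- data.frame(chain = "A", number = seq_len(n_residues),
                         icode = "",
                         base = sample(c("A", "C", "G", "U"), n_residues,
                                       replace = TRUE),
                         stringsAsFactors = FALSE)
  empty <- interaction_set(data.frame(), "seed")
  core <- empty
  while (nrow(core) < core_size) {
    kind <- sample(INTERACTION_KINDS, 1L)
    cand <- draw_absent_interaction(core, residues, kind)
    if (is.null(cand)) {
      stop_rnac("parameter_error", "core_size %d infeasible", core_size)
    }
    core <- interaction_set(
      rbind(as.data.frame(core)[names(cand)], cand)[
        c("kind", "chain_i", "num_i", "icode_i",
          "chain_j", "num_j", "icode_j", "lw")], "seed")
  }
  ids <- sprintf("model%02d", seq_len(n_models))
  sets <- lapply(ids, function(id) {
    df <- as.data.frame(core)
    n_del <- min(stats::rpois(1L, noise_rate), nrow(df))
    if (n_del > 0L) df <- df[-sample.int(nrow(df), n_del), , drop = FALSE]
    s <- interaction_set(df[c("kind", "chain_i", "num_i", "icode_i",
                              "chain_j", "num_j", "icode_j", "lw")], id)
    n_add <- stats::rpois(1L, noise_rate)
    for (a in seq_len(n_add)) {
      cand <- draw_absent_interaction(s, residues,
                                      sample(INTERACTION_KINDS, 1L))
      if (is.null(cand)) break
      s <- interaction_set(
        rbind(as.data.frame(s)[names(cand)], cand)[
          c("kind", "chain_i", "num_i", "icode_i",
            "chain_j", "num_j", "icode_j", "lw")], id)
    }
    s
  })
  list(sets = stats::setNames(sets, ids), residues = residues)
}
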