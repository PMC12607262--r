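test_that("crisp confusion follows set algebra", {
  expect_equal(unclass(crisp_confusion(c("a", "b"), c("a", "c"))),
               list(TP = 1L, FP = 1L, FN = 1L))
  expect_equal(unclass(crisp_confusion(c("a", "b"), c("a", "b"))),
               list(TP = 2L, FP = 0L, FN = 0L))
  expect_equal(unclass(crisp_confusion(character(), c("a", "b", "c"))),
               list(TP = 0L, FP = 0L, FN = 3L))
})

test_that("fuzzy confusion accumulates p, 1-p, and p for TP/FP/FN", {
  sets <- xyz_ensemble()
  cm <- build_frequency_multiset(sets)
  cs <- fuzzy_confusion(sets$A, cm)
  expect_equal(cs$TPsum, 4 / 3)
  expect_equal(cs$FPsum, 2 / 3)
  expect_equal(cs$FNsum, 1 / 3)
  expect_equal(inf_score(cs), sqrt(8 / 15))
  expect_equal(f1_score(cs), 8 / 11)

  full <- build_frequency_multiset(sets[c("A", "A")])
  cs2 <- fuzzy_confusion(sets$A, full)
  expect_equal(cs2$FPsum, 0)
  expect_equal(cs2$FNsum, 0)
})

test_that("constraint flags reshape the fuzzy sums", {
  residues <- data.frame(chain = "A", number = 1:10, icode = "",
                         base = "G", stringsAsFactors = FALSE)
  sets <- xyz_ensemble()
  cm <- build_frequency_multiset(sets, residues = residues)
  # require the never-observed pair (3,8): each model gains FNsum += 1
  cm_req <- apply_constraints(cm, parse_constraints("..(....)..", 10))
  base <- fuzzy_confusion(sets$B, cm)
  with_req <- fuzzy_confusion(sets$B, cm_req)
  expect_equal(with_req$FNsum, base$FNsum + 1)
  expect_equal(with_req$TPsum, base$TPsum)

  # forbid position 1: the unanimous pair x = (1,10) becomes a full FP for
  # models containing it, and stops contributing to TPsum
  cm_x <- apply_constraints(cm, parse_constraints("x.........", 10))
  with_x <- fuzzy_confusion(sets$B, cm_x)
  expect_equal(with_x$TPsum, 0)
  expect_equal(with_x$FPsum, 1)
})

test_that("INF and F1 honor their degenerate conventions and bounds", {
  expect_equal(inf_score(list(TP = 0, FP = 0, FN = 0)), 1)
  expect_equal(f1_score(list(TP = 0, FP = 0, FN = 0)), 1)
  expect_equal(inf_score(list(TP = 0, FP = 2, FN = 0)), 0)
  expect_equal(f1_score(list(TP = 0, FP = 2, FN = 0)), 0)
  expect_equal(inf_score(list(TP = 1, FP = 1, FN = 1)), 0.5)
  expect_equal(f1_score(list(TP = 1, FP = 1, FN = 1)), 0.5)
  expect_equal(inf_score(list(TP = 5, FP = 0, FN = 0)), 1)
  set.seed(1)
  for (i in 1:50) {
    x <- list(TP = sample(0:9, 1), FP = sample(0:9, 1), FN = sample(0:9, 1))
    expect_true(inf_score(x) >= 0 && inf_score(x) <= 1)
    expect_true(f1_score(x) >= 0 && f1_score(x) <= 1)
    perfect <- x$FP == 0 && x$FN == 0
    expect_equal(inf_score(x) == 1, perfect)
    expect_equal(f1_score(x) == 1, perfect)
  }
})

test_that("fuzzy scoring reduces to crisp when all memberships are 1", {
  for (seed in 1:5) {
    ens <- synth_ensemble(4, 10, core_size = 8, noise_rate = 0, seed = seed)
    cm <- build_frequency_multiset(ens$sets)
    expect_true(all(cm$entries$membership == 1))
    cons <- threshold_consensus(cm, 4)
    for (s in ens$sets) {
      cc <- crisp_confusion(s, cons)
      cs <- fuzzy_confusion(s, cm)
      expect_equal(cs$TPsum, cc$TP)
      expect_equal(cs$FPsum, cc$FP)
      expect_equal(cs$FNsum, cc$FN)
      expect_equal(inf_score(cs), inf_score(cc))
      expect_equal(f1_score(cs), f1_score(cc))
    }
  }
})

test_that("threshold-mode scores match a brute-force set-algebra oracle", {
  trials <- 0L
  for (seed in 1:40) {
    ens <- synth_ensemble(n_models = 2 + seed %% 5, n_residues = 10,
                          core_size = 6 + seed %% 10,
                          noise_rate = 1 + seed %% 4, seed = 1000 + seed)
    cm <- build_frequency_multiset(ens$sets)
    for (n in unique(c(1L, 2L, length(ens$sets)))) {
      cfg <- analysis_config("threshold", confidence_level = n)
      rk <- rank_models(ens$sets, cm, cfg)
      cons <- threshold_consensus(cm, n)
      for (id in names(ens$sets)) {
        o <- oracle_crisp(ens$sets[[id]]$key, cons)
        row <- rk[rk$model_id == id, ]
        expect_equal(row$TP, o$TP)
        expect_equal(row$FP, o$FP)
        expect_equal(row$FN, o$FN)
        expect_equal(row$INF, inf_score(o))
        expect_equal(row$F1, f1_score(o))
        trials <- trials + 1L
      }
    }
  }
  expect_gte(trials, 200L)
})

test_that("adding an interaction with membership > 0.5 never lowers F1", {
  checked <- 0L
  for (seed in 1:30) {
    ens <- synth_ensemble(4, 10, core_size = 10, noise_rate = 3,
                          seed = 2000 + seed)
    cm <- build_frequency_multiset(ens$sets)
    for (id in names(ens$sets)) {
      s <- ens$sets[[id]]
      e <- cm$entries
      absent <- e[e$membership > 0.5 & !e$key %in% s$key, , drop = FALSE]
      if (!nrow(absent)) next
      before <- f1_score(fuzzy_confusion(s, cm))
      add <- absent[1, c("kind", "chain_i", "num_i", "icode_i",
                         "chain_j", "num_j", "icode_j", "lw")]
      s2 <- interaction_set(rbind(as.data.frame(s)[names(add)], add), id)
      after <- f1_score(fuzzy_confusion(s2, cm))
      expect_gte(after, before)
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 20L)
})

test_that("rankings sort by the primary metric with lexicographic ties", {
  sets <- xyz_ensemble()
  r <- rank_models(sets, cfg = analysis_config("weighted", metric = "F1"))
  expect_equal(r$model_id, c("B", "A", "C"))
  expect_equal(r$F1, c(3 / 4, 8 / 11, 8 / 11))

  # all models identical: everything scores 1, lexicographic order
  same <- list(C = sets$B, A = sets$B, B = sets$B)
  for (i in seq_along(same)) attr(same[[i]], "model_id") <- names(same)[i]
  r2 <- rank_models(same, cfg = analysis_config("weighted"))
  expect_equal(r2$model_id, c("A", "B", "C"))
  expect_true(all(r2$INF == 1))

  # threshold n = N: only the unanimous pair survives; B is perfect
  r3 <- rank_models(sets, cfg = analysis_config("threshold",
                                                confidence_level = 3))
  expect_equal(r3$INF[r3$model_id == "B"], 1)
  expect_equal(r3$F1[r3$model_id == "B"], 1)

  # permuting the input order changes no score
  r4 <- rank_models(rev(sets), cfg = analysis_config("weighted",
                                                     metric = "F1"))
  expect_equal(r4[order(r4$model_id), -1], r[order(r$model_id), -1],
               ignore_attr = TRUE)
})

test_that("interaction scope restricts what is scored", {
  sets <- xyz_ensemble()  # C holds the only stacking
  r_all <- rank_models(sets, cfg = analysis_config("weighted"))
  r_pairs <- rank_models(sets, cfg = analysis_config("weighted",
                                                     scope = "all_pairs"))
  cC_all <- r_all[r_all$model_id == "C", ]
  cC_pairs <- r_pairs[r_pairs$model_id == "C", ]
  expect_gt(cC_all$TPsum, cC_pairs$TPsum)  # stacking counted only in "all"
  expect_equal(r_pairs[r_pairs$model_id == "B", ]$F1,
               r_pairs[r_pairs$model_id == "C", ]$F1)
})
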