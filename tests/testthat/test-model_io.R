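test_that("multi-model PDB files split into one model per MODEL record", {
  path <- tempfile(fileext = ".pdb")
  write_helix_pdb(path, c("GC", "AU", "CG"), n_models = 2L)
  models <- load_ensemble(path)
  expect_length(models, 2L)
  stem <- tools::file_path_sans_ext(basename(path))
  expect_equal(vapply(models, function(m) m$model_id, ""),
               sprintf("%s#%d", stem, 1:2))
  expect_equal(nrow(models[[1]]$residues), 6L)
})

test_that("archives are unpacked and divided into individual models", {
  dir <- tempfile("arc_")
  dir.create(dir)
  for (k in 1:3) {
    write_helix_pdb(file.path(dir, sprintf("m%d.pdb", k)),
                    c("GC", "AU"), seed = k)
  }
  writeLines("not a structure", file.path(dir, "notes.txt"))
  tarball <- tempfile(fileext = ".tar.gz")
  old <- setwd(dir); on.exit(setwd(old))
  utils::tar(tarball, files = list.files(dir), compression = "gzip")
  setwd(old)
  expect_warning(models <- load_ensemble(tarball), "non-structure")
  expect_length(models, 3L)
  expect_setequal(vapply(models, function(m) m$model_id, ""),
                  c("m1", "m2", "m3"))
})

test_that("mmCIF _atom_site loops parse with auth fields and model numbers", {
  cif <- c(
    "data_test", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                            "label_atom_id", "label_alt_id", "label_comp_id",
                            "label_asym_id", "label_entity_id",
                            "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x",
                            "Cartn_y", "Cartn_z", "occupancy",
                            "B_iso_or_equiv", "auth_seq_id", "auth_asym_id",
                            "pdbx_PDB_model_num")),
    "ATOM 1 C \"C1'\" . G X 1 5 ? 10.0 10.0 10.0 1.00 0.00 5 X 1",
    "ATOM 2 N N9 . G X 1 5 ? 11.0 10.0 10.0 1.00 0.00 5 X 1",
    "ATOM 3 C \"C1'\" . C X 1 6 ? 20.0 10.0 10.0 1.00 0.00 6 X 1",
    "ATOM 4 C \"C1'\" . G X 1 5 ? 10.0 10.0 11.0 1.00 0.00 5 X 2",
    "ATOM 5 N N9 . G X 1 5 ? 11.0 10.0 11.0 1.00 0.00 5 X 2",
    "ATOM 6 C \"C1'\" . C X 1 6 ? 20.0 10.0 11.0 1.00 0.00 6 X 2")
  path <- tempfile(fileext = ".cif")
  writeLines(cif, path)
  models <- load_ensemble(path)
  expect_length(models, 2L)
  expect_equal(models[[1]]$residues$chain, c("X", "X"))
  expect_equal(models[[1]]$residues$number, c(5L, 6L))
  expect_equal(models[[1]]$residues$base, c("G", "C"))
  expect_equal(models[[2]]$atoms$z, rep(11, 3))
})

test_that("unparseable input raises a parse error naming the file", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("just some prose", "no structure here"), path)
  expect_error(load_ensemble(path), basename(path),
               class = "rnaconsensus_parse_error")
  expect_error(load_ensemble(tempfile()), class = "rnaconsensus_io_error")
})

test_that("unification renames chains, renumbers with gaps, clears icodes", {
  atoms <- data.frame(
    chain = rep(c("X", "Y"), each = 3),
    number = c(5L, 6L, 8L, 2L, 2L, 7L),
    icode = c("", "", "", "", "A", ""),
    resname = "G", elety = "C1'",
    x = 1:6, y = 0, z = 0, base = "G", stringsAsFactors = FALSE)
  m <- rnaconsensus:::new_structure_model("m", atoms)
  u <- unify_ensemble(list(m))[[1]]
  expect_equal(unique(u$residues$chain), c("A", "B"))
  expect_equal(u$residues$number, c(1L, 2L, 3L, 1L, 2L, 3L))
  expect_true(all(u$residues$icode == ""))
  # round-trip preservation and idempotence
  expect_equal(nrow(u$atoms), nrow(m$atoms))
  expect_equal(nrow(u$residues), nrow(m$residues))
  u2 <- unify_ensemble(list(u))[[1]]
  expect_equal(u2$atoms, u$atoms)
  map <- attr(u, "unification_map")
  expect_equal(map$old_number[map$new_chain == "A"], c(5L, 6L, 8L))
})

test_that("consistency verdicts cover agreement, divergence, chain mismatch", {
  path <- tempfile(fileext = ".pdb")
  write_helix_pdb(path, c("GC", "AU", "GU"), n_models = 3L)
  models <- unify_ensemble(load_ensemble(path))
  rep <- check_consistency(models)
  expect_true(rep$consistent)
  expect_equal(nrow(rep$divergent), 0L)

  # mutate one base: divergence at its concatenated-sequence position
  m2 <- models
  m2[[2]]$residues$base[4] <- "A"
  rep2 <- check_consistency(m2)
  expect_false(rep2$consistent)
  expect_equal(rep2$divergent$position, 4L)

  # same sequence, different chain layout
  m3 <- models
  m3[[3]]$residues$chain <- "A"
  rep3 <- check_consistency(m3)
  expect_false(rep3$consistent)
})

test_that("PDB limit checks flag all violations and accept boundaries", {
  m <- synthetic_helix_model(c("GC", "AU"))
  expect_length(check_pdb_limits(m), 0L)
  m$n_atoms_raw <- 100000L
  v <- check_pdb_limits(m)
  expect_match(v, "exceeds 99,999")
  m$n_atoms_raw <- 99999L
  expect_length(check_pdb_limits(m), 0L)

  many <- data.frame(chain = as.character(seq_len(63L)), number = 1L,
                     icode = "", resname = "A", elety = "C1'",
                     x = seq_len(63L) * 30, y = 0, z = 0, base = "A",
                     stringsAsFactors = FALSE)
  big <- rnaconsensus:::new_structure_model("big", many)
  big$n_atoms_raw <- 100001L
  v <- check_pdb_limits(big)
  expect_length(v, 2L)  # atoms and chains, reported together
})

test_that("written PDB round-trips through the loader", {
  m <- synthetic_helix_model(c("GC", "AU", "UA"), model_id = "rt")
  path <- tempfile(fileext = ".pdb")
  write_model_pdb(m, path)
  back <- load_ensemble(path)[[1]]
  expect_equal(nrow(back$atoms), nrow(m$atoms))
  expect_equal(back$residues$base, m$residues$base)
  expect_equal(back$atoms$x, round(m$atoms$x, 3))
})
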