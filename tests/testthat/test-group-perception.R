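test_that("atom groups reproduce the canonical worked assignments", {
  # ethanol C1
  g <- assign_atom_groups(parse_smiles("CCO"))
  expect_true(any(g$atom_type == "C sp3" & g$neighbours == "H2CO"))

  # cyclohexanemethanol multiset
  cm <- perceive_groups(parse_smiles("OCC1CCCCC1"))
  expect_equal(cm$count[cm$key == "C sp3|H2C2"], 5L)
  expect_equal(cm$count[cm$key == "C sp3|HC3"], 1L)
  expect_equal(cm$count[cm$key == "C sp3|H2CO"], 1L)
  expect_equal(cm$count[cm$key == "O(prim)|HC"], 1L)

  # glycine zwitterion
  gz <- assign_atom_groups(parse_smiles("[NH3+]CC([O-])=O"))
  expect_setequal(gz$key,
                  c("N(+) sp3|H3C", "C sp3|H2CN(+)", "C sp2|CO=O(-)"))

  # N-ethylpyridinium ring nitrogen
  pyr <- assign_atom_groups(parse_smiles("CC[n+]1ccccc1"))
  expect_true("N(+) aromatic|C:C2" %in% pyr$key)
  expect_equal(sum(pyr$key == "C aromatic|H:C:N(+)"), 2L)
})

test_that("hydroxy refinement follows the carbinol substitution count", {
  o_key <- function(smi) {
    g <- refine_hydroxy_groups(assign_atom_groups(parse_smiles(smi)),
                               parse_smiles(smi))
    g$key[grepl("^O", g$atom_type)]
  }
  expect_equal(o_key("CCCO"), "O(prim)|HC")
  expect_equal(o_key("CC(C)O"), "O(sec)|HC")
  expect_equal(o_key("CC(C)(C)O"), "O(tert)|HC")
  expect_equal(o_key("Oc1ccccc1"), "O|HC(pi)")   # phenol untouched

  # refinement changes labels, never the number of groups
  mol <- parse_smiles("CC(C)O")
  g0 <- assign_atom_groups(mol)
  g1 <- refine_hydroxy_groups(g0, mol)
  expect_equal(nrow(g0), nrow(g1))
  expect_equal(g0$atom, g1$atom)

  # no-op when the parameter table lacks refined types
  g2 <- refine_hydroxy_groups(g0, mol, refined_types = character(0))
  expect_equal(g2$key, g0$key)
})

test_that("endocyclic single bonds are counted once per bond, aromatics excluded", {
  endo <- function(smi) {
    count_special_groups(parse_smiles(smi))[["EndocyclicBonds"]]
  }
  expect_equal(endo("OCC1CCCCC1"), 6L)
  expect_equal(endo("c1ccccc1"), 0L)
  expect_equal(endo("C1CCCC1"), 5L)
  expect_equal(endo("C1=CCCCC1"), 5L)   # the ring double bond is not counted

  # adamantane: 12, cross-checked by exhaustive ring-bond enumeration
  ada <- parse_smiles("C1C2CC3CC1CC(C2)C3")
  expect_equal(endo("C1C2CC3CC1CC(C2)C3"), 12L)
  expect_equal(sum(ada$bonds$in_ring), 12L)

  # pi-conjugated five-membered heterocycles contribute nothing
  expect_equal(endo("c1cc[nH]c1"), 0L)
  expect_equal(endo("Cc1c[nH]c2ccccc12"), 0L)
})

test_that("topological angle fallback covers three- and four-membered rings", {
  expect_equal(count_special_groups(parse_smiles("C1CC1"))[["Angle60"]], 3L)
  expect_equal(count_special_groups(parse_smiles("C1CCC1"))[["Angle90"]], 4L)
  expect_equal(count_special_groups(parse_smiles("C1CCCC1"))[["Angle102"]], 0L)
})

test_that("geometric angle binning works on 3D input", {
  # equilateral triangle of carbons in the z = 0.5 plane: three 60 deg angles
  r <- 1.54 / sqrt(3)
  ang <- seq(0, 2 * pi, length.out = 4)[1:3]
  coords <- cbind(r * cos(ang), r * sin(ang), 0.5)
  sdf <- make_sdf3d(rep("C", 3), coords,
                    rbind(c(1, 2, 1), c(2, 3, 1), c(1, 3, 1)))
  mol <- read_sdf_text(sdf)[[1]]
  expect_true(mol$has_3d)
  sp <- count_special_groups(mol)
  expect_equal(sp[["Angle60"]], 3L)
  expect_equal(sp[["Angle90"]], 0L)

  # puckered cyclobutane: the four ring angles sit just below 90 deg
  coords4 <- cbind(c(0, 1.54, 1.54, 0), c(0, 0, 1.54, 1.54),
                   c(0.7, 0.3, 0.7, 0.3))
  sdf4 <- make_sdf3d(rep("C", 4), coords4,
                     rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(1, 4, 1)))
  sp4 <- count_special_groups(read_sdf_text(sdf4)[[1]])
  expect_equal(sp4[["Angle90"]], 4L)
  expect_equal(sp4[["Angle60"]], 0L)
})

test_that("polyol counting distinguishes the three conventions", {
  glycol <- parse_smiles("OCCO")
  expect_equal(count_special_groups(glycol, "n_minus_one")[["COHn"]], 1L)
  expect_equal(count_special_groups(glycol, "once")[["COHn"]], 1L)
  expect_equal(count_special_groups(glycol, "per_oh")[["COHn"]], 2L)

  glycerol <- parse_smiles("OCC(O)CO")
  expect_equal(count_special_groups(glycerol, "n_minus_one")[["COHn"]], 2L)
  expect_equal(count_special_groups(glycerol, "once")[["COHn"]], 1L)
  expect_equal(count_special_groups(glycerol, "per_oh")[["COHn"]], 3L)

  mono <- parse_smiles("CCO")
  expect_equal(count_special_groups(mono, "n_minus_one")[["COHn"]], 0L)
  expect_equal(count_special_groups(mono, "per_oh")[["COHn"]], 0L)
})

test_that("hydrogen bridges need 3D coordinates and a 3-bond separation", {
  # no coordinates: count is zero
  expect_equal(count_special_groups(parse_smiles("OCCO"))[["HHAcceptor"]], 0L)

  # hand-built gauche 1,2-ethanediol with one O-H pointing at the other O
  # heavy atoms: O1 C2 C3 O4; explicit H on O1 placed 2.0 A from O4
  coords <- rbind(
    c(0.0, 0.0, 0.5), c(1.4, 0.0, 0.5), c(2.0, 1.3, 0.5), c(3.4, 1.3, 0.5),
    c(2.6, 0.6, 0.5))  # the hydroxyl H, ~1 A from O1? placed near O4
  # H sits 1.0 A from O1 direction of O4:
  o1 <- coords[1, ]; o4 <- coords[4, ]
  h <- o1 + (o4 - o1) / sqrt(sum((o4 - o1)^2)) * 1.5
  coords[5, ] <- h
  sdf <- make_sdf3d(c("O", "C", "C", "O", "H"), coords,
                    rbind(c(1, 2, 1), c(2, 3, 1), c(3, 4, 1), c(1, 5, 1)))
  mol <- read_sdf_text(sdf)[[1]]
  d_h_o4 <- sqrt(sum((h - o4)^2))
  expect_lt(d_h_o4, 2.5)
  expect_equal(count_special_groups(mol)[["HHAcceptor"]], 1L)
})

test_that("group multiset is invariant under atom-order permutation", {
  pairs <- list(
    c("OCC1CCCCC1", "C1CCCCC1CO"),
    c("CC(C)O", "OC(C)C"),
    c("CC[n+]1ccn(C)c1.[B-](F)(F)(F)F", "[B-](F)(F)(F)F.C[n+]1ccn(CC)c1"),
    c("CCCCC(O)CC", "CCC(O)CCCC"))
  for (p in pairs) {
    expect_equal(group_multiset(p[1]), group_multiset(p[2]),
                 info = paste(p, collapse = " vs "))
  }
})

test_that("every backbone atom gets exactly one group", {
  for (smi in c("CCO", "OCC1CCCCC1", "CC(C)(C)O", "CSCCC([NH3+])C([O-])=O",
                "CC[n+]1ccccc1.[O-]S(=O)(=O)C(F)(F)F")) {
    mol <- parse_smiles(smi)
    g <- assign_atom_groups(mol)
    deg <- mol$atoms$hcount
    for (b in seq_len(nrow(mol$bonds))) {
      deg[mol$bonds$a1[b]] <- deg[mol$bonds$a1[b]] + 1L
      deg[mol$bonds$a2[b]] <- deg[mol$bonds$a2[b]] + 1L
    }
    expect_equal(nrow(g), sum(deg >= 2), info = smi)
    expect_equal(anyDuplicated(g$atom), 0L, info = smi)
  }
})

test_that("emitted neighbour strings occur literally in the shipped tables", {
  fx <- cp_fixtures()
  tabs <- list(liquid = cp_table("liquid"), solid = cp_table("solid"))
  set.seed(42)
  sample_rows <- sample(nrow(fx), 40)
  for (i in sample_rows) {
    counts <- perceive_groups(parse_smiles(fx$smiles[i]))
    atom_keys <- counts$key[counts$kind == "atom"]
    novel <- setdiff(atom_keys, tabs[[fx$phase[i]]]$key)
    expect_length(novel, 0)
    if (length(novel) > 0) {
      fail(paste0(fx$name[i], ": novel group string(s) ",
                  paste(novel, collapse = ", ")))
    }
  }
})
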