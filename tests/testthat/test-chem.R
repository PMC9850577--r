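# Molecular structure utilities: canonicalization, fingerprints, Tanimoto
# similarity, property oracles.

test_that("canonicalization unifies spellings and flags invalid text", {
  expect_equal(canonicalize_smiles("OCC"), canonicalize_smiles("CCO"))
  expect_equal(canonicalize_smiles("C1=CC=CC=C1"),
               canonicalize_smiles("c1ccccc1"))
  # idempotence
  c1 <- canonicalize_smiles("CC(=O)Oc1ccccc1C(=O)O")
  expect_equal(canonicalize_smiles(c1), c1)
  # invalidity is a value, not an exception
  expect_true(is.na(canonicalize_smiles("C(C")))
  expect_true(is.na(canonicalize_smiles("C1CC")))
  expect_true(is.na(canonicalize_smiles("xyz123")))
  expect_true(is.na(canonicalize_smiles("")))
  expect_equal(smiles_is_valid(c("CCO", "C(C")), c(TRUE, FALSE))
})

test_that("fingerprints are 2048-bit, deterministic, spelling-invariant", {
  f1 <- morgan_fingerprint("CCO")
  f2 <- morgan_fingerprint("CCO")
  expect_length(f1, 2048L)
  expect_true(all(f1 %in% c(0L, 1L)))
  expect_identical(as.integer(f1), as.integer(f2))
  # non-canonical spelling hashes identically
  expect_identical(as.integer(morgan_fingerprint("OCC")), as.integer(f1))
  expect_identical(as.integer(morgan_fingerprint("C1=CC=CC=C1")),
                   as.integer(morgan_fingerprint("c1ccccc1")))
  # chemically different molecules differ in at least one bit
  fb <- morgan_fingerprint("c1ccccc1")
  expect_gt(sum(as.integer(f1) != as.integer(fb)), 0L)
  expect_error(morgan_fingerprint("C(C"), "invalid")
})

test_that("tanimoto matches its set definition, is symmetric, handles 0/0", {
  mk <- function(on) { v <- integer(2048); v[on] <- 1L; v }
  expect_equal(tanimoto(mk(c(1, 5, 9)), mk(c(1, 5, 9))), 1)
  expect_equal(tanimoto(mk(1:4), mk(5:8)), 0)
  # on-bits {1,2} vs {2,3}: intersection 1, union 3
  expect_equal(tanimoto(mk(1:2), mk(2:3)), 1 / 3)
  # all-zero pair is defined as 0, not NaN
  expect_identical(tanimoto(integer(2048), integer(2048)), 0)
  expect_error(tanimoto(mk(1), integer(100)), "length")

  set.seed(7)
  for (i in 1:1000) {
    a <- mk(sample(2048, sample(0:40, 1)))
    b <- mk(sample(2048, sample(1:40, 1)))
    expect_identical(tanimoto(a, b), tanimoto(b, a))
    # denominator equals the popcount of the OR (set-based oracle)
    ia <- which(a == 1L); ib <- which(b == 1L)
    expect_equal(tanimoto(a, b),
                 if (length(union(ia, ib)) == 0) 0 else
                   length(intersect(ia, ib)) / length(union(ia, ib)))
  }
  expect_equal(tanimoto(morgan_fingerprint("CCO"),
                        morgan_fingerprint("CCO")), 1)
})

test_that("QED matches the reference toolkit and is spelling-invariant", {
  q <- qed_score("CC(=O)Oc1ccccc1C(=O)O")
  expect_gte(q, 0); expect_lte(q, 1)
  # reference value computed with RDKit's QED implementation
  ref <- as.numeric(system2("python", c("-c", shQuote(
    "from rdkit import Chem; from rdkit.Chem import QED; print(QED.qed(Chem.MolFromSmiles('CC(=O)Oc1ccccc1C(=O)O')))"
  )), stdout = TRUE))
  expect_equal(q, ref, tolerance = 1e-6)
  expect_equal(qed_score("OCC"), qed_score("CCO"))
  expect_true(all(qed_score(c("c1ccccc1", "CCN", "CC(C)Cc1ccc(cc1)C(C)C(=O)O"))
                  >= 0))
  expect_error(qed_score("C(C"), "invalid")
})

test_that("penalized logP follows the stated convention", {
  # independent assembly from the reference toolkit's components
  py <- paste(
    "import sys, os",
    "from rdkit import Chem, RDConfig",
    "from rdkit.Chem import Crippen",
    "sys.path.append(os.path.join(RDConfig.RDContribDir, 'SA_Score'))",
    "import sascorer",
    "m = Chem.MolFromSmiles(sys.argv[1])",
    "sizes = [len(r) for r in m.GetRingInfo().AtomRings()]",
    "cyc = max(0, (max(sizes) if sizes else 0) - 6)",
    "print(Crippen.MolLogP(m), sascorer.calculateScore(m), cyc)",
    sep = "\n")
  script <- tempfile(fileext = ".py"); writeLines(py, script)
  for (smi in c("C1CCCCCCC1", "CC(=O)Oc1ccccc1C(=O)O", "CCCCCC")) {
    parts <- as.numeric(strsplit(system2("python", c(script, shQuote(smi)),
                                         stdout = TRUE), " ")[[1]])
    expect_equal(penalized_logp(smi), parts[1] - parts[2] - parts[3],
                 tolerance = 1e-6, label = smi)
    # molecules whose largest ring has <= 6 atoms pay no cycle penalty
    if (smi != "C1CCCCCCC1") expect_equal(parts[3], 0)
  }
  # cyclooctane: largest ring 8 -> penalty 2
  parts <- as.numeric(strsplit(system2("python",
                                       c(script, shQuote("C1CCCCCCC1")),
                                       stdout = TRUE), " ")[[1]])
  expect_equal(parts[3], 2)
  # invariance to spelling
  expect_equal(penalized_logp("OCC"), penalized_logp("CCO"))
  # the z-scored variant is a different number but finite
  expect_true(is.finite(penalized_logp("CCO", normalized = TRUE)))
})

test_that("oracle constructors honour their contracts", {
  tab <- make_oracle("tabulated", table = c(CCO = 0.2, CCN = 0.7))
  expect_equal(oracle_score(tab, "CCO"), 0.2)
  expect_equal(oracle_score(tab, c("CCN", "CCO")), c(0.7, 0.2))
  expect_equal(oracle_score(tab, "OCC"), 0.2)  # canonical fallback
  expect_error(oracle_score(tab, "CCCCC"), "no entry")
  expect_error(make_oracle("nonsense"))

  qed <- make_oracle("qed")
  expect_equal(oracle_score(qed, "c1ccccc1"), qed_score("c1ccccc1"))
  expect_equal(qed$range, c(0, 1))

  cmd <- make_oracle("external-command", command = "awk '{print 0.5}'")
  expect_equal(oracle_score(cmd, c("CCO", "CCN")), c(0.5, 0.5))

  fn <- make_oracle("function", fn = function(s) nchar(s) / 100)
  expect_equal(oracle_score(fn, "CCO"), 0.03)
  expect_error(oracle_score(fn, "C(C"), "invalid")

  # score-table round trip
  path <- tempfile(fileext = ".tsv")
  write_score_table(c(CCO = 0.25, `c1ccccc1` = 0.5), path)
  expect_equal(read_score_table(path), c(CCO = 0.25, `c1ccccc1` = 0.5))
})

test_that("heavy-atom score counts atoms and is spelling-invariant", {
  expect_equal(heavy_atom_score("CCO"), 3 / 40)
  expect_equal(heavy_atom_score("c1ccccc1"), 6 / 40)
  expect_equal(heavy_atom_score("OCC"), heavy_atom_score("CCO"))
  expect_error(heavy_atom_score("C(C"), "invalid")
})
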