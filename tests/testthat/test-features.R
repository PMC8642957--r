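cfg0 <- feature_config() # full default set

test_that("RNA composition descriptors match hand values", {
  # sequences this short trigger the (intended) zero-fill warning for the
  # longest gapped windows; composition blocks are unaffected
  tab <- suppressWarnings(rna_features(c(S1 = "ATGC", S2 = "AAAA"), cfg0))
  expect_equal(tab["S1", "rna.gcContent"], 0.5)
  expect_equal(tab["S1", "rna.atgcRatio"], 1.0)
  expect_equal(unname(tab["S1", paste0("rna.zCurve.", c("x", "y", "z"))]),
               c(0, 0, 0))
  expect_equal(unname(tab["S1", c("rna.skew.gc", "rna.skew.at")]), c(0, 0))
  expect_equal(unname(tab["S2", paste0("rna.kmer.k1.", c("A", "C", "G", "T"))]),
               c(1, 0, 0, 0))
  expect_equal(unname(tab["S2", paste0("rna.zCurve.", c("x", "y", "z"))]),
               c(1, 1, 1))
})

test_that("gapped k-mer counts match the enumeration oracle", {
  # worked example: A_G with gap 1 in ACGTAC occurs once among 4 windows
  tab <- suppressWarnings(rna_features(c(S = "ACGTAC"), cfg0))
  expect_equal(tab["S", "rna.monoMonoKGap.g1.A_G"], 0.25)
  # whole mono-mono and di-mono blocks against brute force, random seqs
  set.seed(11)
  for (rep in 1:3) {
    s <- random_seq(30)
    tab <- rna_features(setNames(s, "R"), cfg0)
    for (g in 1:2) {
      or <- oracle_gap_counts(s, 1, g, 1)
      got <- tab["R", sprintf("rna.monoMonoKGap.g%d.%s", g,
                              paste0(rep(c("A", "C", "G", "T"), each = 4), "_",
                                     c("A", "C", "G", "T")))]
      expect_equal(unname(got), as.vector(t(or$counts)) / or$n_windows)
      or2 <- oracle_gap_counts(s, 2, g, 1)
      nm2 <- sprintf("rna.diMonoKGap.g%d.%s_%s", g,
                     rep(rownames(or2$counts), each = 4),
                     colnames(or2$counts))
      expect_equal(unname(tab["R", nm2]),
                   as.vector(t(or2$counts)) / or2$n_windows)
    }
  }
})

test_that("normalized composition blocks sum to one on clean sequences", {
  set.seed(7)
  rna <- setNames(vapply(1:4, function(i) random_seq(50), ""),
                  paste0("R", 1:4))
  tabr <- rna_features(rna, cfg0)
  for (k in 1:3) {
    block <- tabr[, grep(sprintf("^rna\\.kmer\\.k%d\\.", k),
                         colnames(tabr)), drop = FALSE]
    expect_equal(unname(rowSums(block)), rep(1, 4), tolerance = 1e-9)
  }
  for (fam in c("monoMonoKGap", "diDiKGap", "triDiKGap")) {
    for (g in 1:2) {
      block <- tabr[, grep(sprintf("^rna\\.%s\\.g%d\\.", fam, g),
                           colnames(tabr)), drop = FALSE]
      expect_equal(unname(rowSums(block)), rep(1, 4), tolerance = 1e-9)
    }
  }
  prot <- setNames(vapply(1:4, function(i)
    random_seq(40, strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]), ""),
    paste0("Q", 1:4))
  tabp <- protein_features(prot, cfg0)
  for (pre in c("^prot\\.aac\\.", "^prot\\.dipep\\.", "^prot\\.triad\\.")) {
    block <- tabp[, grep(pre, colnames(tabp)), drop = FALSE]
    expect_equal(unname(rowSums(block)), rep(1, 4), tolerance = 1e-9)
  }
})

test_that("descriptor ranges and reverse-complement antisymmetry hold", {
  set.seed(3)
  seqs <- setNames(vapply(1:6, function(i) random_seq(40), ""),
                   paste0("R", 1:6))
  tab <- rna_features(seqs, cfg0)
  zc <- tab[, paste0("rna.zCurve.", c("x", "y", "z"))]
  expect_true(all(zc >= -1 & zc <= 1))
  expect_true(all(tab[, "rna.gcContent"] >= 0 & tab[, "rna.gcContent"] <= 1))
  sk <- tab[, c("rna.skew.gc", "rna.skew.at")]
  expect_true(all(sk >= -1 & sk <= 1))
  rc <- vapply(seqs, function(s)
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = "")),
    "")
  tab_rc <- rna_features(setNames(rc, names(seqs)), cfg0)
  expect_equal(tab_rc[, "rna.skew.gc"], -tab[, "rna.skew.gc"])
  expect_equal(tab_rc[, "rna.skew.at"], -tab[, "rna.skew.at"])
})

test_that("feature tables are permutation-equivariant in the input order", {
  set.seed(5)
  seqs <- setNames(vapply(1:5, function(i) random_seq(30), ""),
                   paste0("R", 1:5))
  t1 <- rna_features(seqs, small_cfg())
  perm <- c(3, 1, 5, 2, 4)
  t2 <- rna_features(seqs[perm], small_cfg())
  expect_identical(t2, t1[perm, ])
})

test_that("protein descriptors match hand values", {
  tab <- suppressWarnings(protein_features(c(P1 = "AAAA", P2 = "ACDE"), cfg0))
  expect_equal(tab["P1", "prot.aac.A"], 1)
  expect_equal(sum(tab["P1", grep("^prot\\.aac\\.", colnames(tab))]), 1)
  # A is in conjoint group 1 -> triad (1,1,1) has all the mass
  expect_equal(tab["P1", "prot.triad.1_1_1"], 1)
  expect_equal(unname(tab["P2", paste0("prot.aac.", c("A", "C", "D", "E"))]),
               rep(0.25, 4))

  # CTD hydrophobicity on ARN: A neutral, R polar, N polar
  # (lag descriptors warn on such a short peptide; not under test here)
  t3 <- suppressWarnings(protein_features(c(P = "ARN"), cfg0))
  comp <- t3["P", paste0("prot.ctd.hydrophobicity.comp.",
                         c("polar", "neutral", "hydrophobic"))]
  expect_equal(unname(comp), c(2 / 3, 1 / 3, 0))
  tr <- t3["P", paste0("prot.ctd.hydrophobicity.trans.",
                       c("polar_neutral", "polar_hydrophobic",
                         "neutral_hydrophobic"))]
  expect_equal(unname(tr), c(0.5, 0, 0)) # A->R crosses, R->N does not
})

test_that("short sequences zero-fill infeasible lags with a warning", {
  expect_warning(tab <- protein_features(c(P = "ACD"), cfg0), "infeasible")
  qso_tau <- tab["P", paste0("prot.qso.tau", 3:10)]
  expect_true(all(qso_tau == 0))
  expect_true(all(is.finite(tab)))
})

test_that("feature names are deterministic and match table columns", {
  cfg <- feature_config(rna = "gcContent", protein = "AAC")
  expect_identical(feature_names(cfg, "rna"), "rna.gcContent")
  cfg1 <- feature_config(rna = "kTuple", k_tuple = 1, protein = "AAC")
  expect_identical(feature_names(cfg1, "rna"),
                   paste0("rna.kmer.k1.", c("A", "C", "G", "T")))
  expect_identical(feature_names(cfg0, "rna"), feature_names(cfg0, "rna"))
  tab <- rna_features(c(S = "ACGTACGT"), small_cfg())
  expect_identical(colnames(tab), feature_names(small_cfg(), "rna"))
  expect_error(feature_config(rna = character(0)), "at least one")
  expect_error(feature_config(rna = "bogus"), "unknown")
})

test_that("shipped descriptor tables match the in-code definitions", {
  scales <- read.delim(system.file("extdata", "aa_property_scales.tsv",
                                   package = "lpiboost"),
                       check.names = FALSE)
  internal <- t(lpiboost:::AA_SCALES)
  expect_equal(scales$aa, rownames(internal))
  expect_equal(as.matrix(scales[, -1]), internal, ignore_attr = TRUE)
  groups <- read.delim(system.file("extdata", "ctd_groups.tsv",
                                   package = "lpiboost"))
  for (i in seq_len(nrow(groups))) {
    expect_identical(
      groups$residues[i],
      unname(lpiboost:::CTD_GROUPS[[groups$property[i]]][groups$class[i]]))
  }
})
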