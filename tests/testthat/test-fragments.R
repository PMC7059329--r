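test_that("decomposition handles canonical single-ring and fused cases", {
  # benzene: one ring assembly, nothing else
  d <- decompose("c1ccccc1")
  expect_equal(nrow(d), 1)
  expect_equal(d$kind, "ring_assembly")
  expect_equal(d$fragment, canonical_smiles("c1ccccc1"))
  # acyclic molecules yield an empty set, not an error
  expect_equal(nrow(decompose("CCCCO")), 0)
  # decorated quinazoline: substituents stripped, quinazoline recovered
  d2 <- decompose("Cc1ccc2ncncc2c1")
  expect_true(canonical_smiles(QUINAZOLINE) %in%
                d2$fragment[d2$kind == "ring_assembly"])
  expect_error(decompose("junk(("), "invalid structure")
})

test_that("biphenyl gives two benzene assemblies plus a linked scaffold", {
  d <- decompose("c1ccccc1-c1ccccc1")
  ra <- d[d$kind == "ring_assembly", ]
  expect_equal(ra$fragment, canonical_smiles("c1ccccc1"))  # presence-unique
  bm <- d[d$kind == "bemis_murcko_assembly", ]
  expect_equal(nrow(bm), 1)
  expect_equal(bm$fragment, canonical_smiles("c1ccccc1-c1ccccc1"))
  # no bridged system in biphenyl or naphthalene (fused rings share 1 bond)
  expect_false("bridge_assembly" %in% d$kind)
  expect_false("bridge_assembly" %in% decompose("c1ccc2ccccc2c1")$kind)
})

test_that("bridged bicyclics are flagged as bridge assemblies", {
  # norbornane: two rings sharing two bonds
  d <- decompose("C1CC2CCC1C2")
  expect_true("bridge_assembly" %in% d$kind)
  # determinism: same canonical input, same fragment set
  expect_identical(decompose("C1CC2CCC1C2"), decompose("C1CC2CCC1C2"))
})

test_that("scaffold linkers join ring systems in Bemis-Murcko assemblies", {
  # two rings joined by a two-carbon linker, with a pendant tail
  d <- decompose("c1ccccc1CCC1CCCCC1CCO")
  bm <- d[d$kind == "bemis_murcko_assembly", ]
  expect_equal(nrow(bm), 1)
  expect_equal(bm$fragment, canonical_smiles("c1ccccc1CCC1CCCCC1"))
  # single ring system -> no Bemis-Murcko assembly
  expect_false("bemis_murcko_assembly" %in% decompose("Cc1ccccc1C")$kind)
})

test_that("class frequency reproduces the printed worked values", {
  expect_lt(abs(class_frequency(175, 1098, 189, 2799) - 2.3604), 1e-4)
  expect_lt(abs(class_frequency(14, 1701, 189, 2799) - 0.1219), 1e-4)
  expect_lt(abs(class_frequency(90, 1098, 120, 2799) - 1.9119), 1e-4)
  # fragment in every compound of both classes -> F1 = F2 = 1
  expect_equal(class_frequency(10, 10, 30, 30), 1)
  expect_error(class_frequency(0, 10, 0, 30), "positive")
})

test_that("information gain reproduces printed values and bounds", {
  expect_lt(abs(information_gain(0, 51, 1098, 1701) - 0.0132), 2e-4)
  expect_lt(abs(information_gain(0, 56, 1098, 1701) - 0.0146), 2e-4)
  expect_lt(abs(information_gain(175, 14, 1098, 1701) - 0.0665), 2e-4)
  # uninformative partitions
  expect_equal(information_gain(1098, 1701, 1098, 1701), 0)
  expect_equal(information_gain(0, 0, 1098, 1701), 0)
  ent_d <- -(1098 / 2799 * log2(1098 / 2799) +
               1701 / 2799 * log2(1701 / 2799))
  # IG bounded by the dataset entropy; perfect split attains it
  expect_equal(information_gain(1098, 0, 1098, 1701), ent_d)
  set.seed(1)
  for (i in 1:50) {
    n1 <- sample(5:50, 1); n0 <- sample(5:50, 1)
    c1 <- sample(0:n1, 1); c0 <- sample(0:n0, 1)
    ig <- information_gain(c1, c0, n1, n0)
    ent <- -sum(vapply(c(n1, n0) / (n1 + n0),
                       function(p) if (p > 0) p * log2(p) else 0, numeric(1)))
    expect_gte(ig, -1e-12)
    expect_lte(ig, ent + 1e-12)
  }
  # class-independent presence => IG = 0
  expect_equal(information_gain(20, 30, 40, 60), 0, tolerance = 1e-12)
})

test_that("fragment table counts presence per compound and obeys Eq-7 identity", {
  pf <- data.frame(scaffold = c(QUINAZOLINE, MORPHOLINE),
                   rate_inhibitor = c(0.7, 0.05),
                   rate_noninhibitor = c(0.05, 0.6))
  spec <- synthetic_spec(n_inhibitors = 30, n_noninhibitors = 30,
                         planted_fragments = pf, seed = 23)
  lib <- gen_compound_library(spec)
  tab <- fragment_table(lib[, c("smiles", "label")])
  fs <- attr(lib, "fragment_smiles")
  for (col in names(fs)) {
    row <- tab[tab$kind == "ring_assembly" & tab$fragment == fs[[col]], ]
    expect_equal(row$count_inhibitor, sum(lib[[col]] & lib$label == 1L))
    expect_equal(row$count_noninhibitor, sum(lib[[col]] & lib$label == 0L))
  }
  # algebraic identity of the frequency definition, every fragment
  n1 <- sum(lib$label == 1L); n0 <- sum(lib$label == 0L)
  expect_equal(tab$F1 * n1 + tab$F2 * n0, rep(n1 + n0, nrow(tab)))
  # sorted by IG descending; brute-force recount agrees
  expect_true(all(diff(tab$IG) <= 1e-12))
  ig2 <- mapply(information_gain, tab$count_inhibitor,
                tab$count_noninhibitor, n1, n0)
  expect_equal(tab$IG, unname(ig2))
})

test_that("inhibitor-only fragments hit the closed-form frequency", {
  # present only in class c => F_c = N_total / N_class regardless of count
  expect_equal(class_frequency(9, 1098, 9, 2799), 2799 / 1098)
  expect_equal(round(class_frequency(29, 1098, 29, 2799), 4), 2.5492)
  tab <- fragment_table(c(rep("Cc1ccc2ncncc2c1", 3), rep("CCCC1CCCCC1", 5)),
                        labels = c(1, 1, 1, 0, 0, 0, 0, 0))
  q <- tab[tab$fragment == canonical_smiles(QUINAZOLINE) &
             tab$kind == "ring_assembly", ]
  expect_equal(q$F1, 8 / 3)
  expect_equal(q$F2, 0)
})

test_that("ranking splits by strict frequency dominance", {
  tab <- data.frame(fragment = c("p", "n", "tie"), kind = "ring_assembly",
                    count_inhibitor = c(5, 1, 2),
                    count_noninhibitor = c(1, 5, 2),
                    F1 = c(2.4, 0.1, 1), F2 = c(0.1, 2.4, 1),
                    IG = c(0.07, 0.05, 0))
  r <- rank_fragments(tab, top_n = 10)
  expect_equal(r$positive$fragment, "p")
  expect_equal(r$negative$fragment, "n")  # tie excluded from both
  r0 <- rank_fragments(tab, top_n = 0)
  expect_equal(nrow(r0$positive), 0)
  expect_equal(nrow(r0$negative), 0)
})

test_that("misclassification enrichment filters and scales correctly", {
  train <- c(rep("Cc1ccncc1", 25), rep("CCC1CCCCC1", 75))   # 25% pyridine
  test <- c(rep("CCc1ccncc1", 4), rep("CC1CCCCC1", 16))
  mis <- c(rep("CCc1ccncc1", 3), "CC1CCCCC1")
  out <- misclassification_enrichment(train, test, mis)
  py <- out[out$fragment == canonical_smiles("c1ccncc1") &
              out$kind == "ring_assembly", ]
  expect_equal(py$count_misclassified, 3)
  expect_equal(py$or_train, 25)
  expect_equal(py$or_test, 20)
  expect_equal(py$or_misclassified, 75)
  # the ratio machinery reproduces the printed worked values
  expect_equal(round(100 * 125 / 2240, 2), 5.58)
  expect_equal(round(100 * 5 / 50, 2), 10)
  # cyclohexane occurs in only one misclassified compound -> dropped
  expect_false(canonical_smiles("C1CCCCC1") %in% out$fragment)
  expect_equal(nrow(misclassification_enrichment(train, test, character(0))),
               0)
})
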