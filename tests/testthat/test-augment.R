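manual_map <- function(lst, cutoff = 0.5) {
  out <- lapply(lst, function(x)
    data.frame(drug_id = names(x), dacs = unname(x), stringsAsFactors = FALSE))
  structure(out, cutoff = cutoff, class = "substitute_map")
}

test_that("substitute maps contain exactly the candidates above the cutoff", {
  u <- paste0("p", 1:6)
  orig <- lib_from_bits(c("o1", "o2"), list(c(1, 2, 3, 4), c(9, 10, 11, 12)),
                        nbits = 16,
                        targets = list(o1 = c("p1", "p2"), o2 = c("p5")))
  cand <- lib_from_bits(c("k1", "k2", "k3"),
                        list(c(1, 2, 3, 4), c(1, 2, 5, 6), c(13, 14)),
                        nbits = 16,
                        targets = list(k1 = c("p1", "p2"), k2 = "p1",
                                       k3 = "p6"))
  # scalar DACS oracle for every (original, candidate) pair
  dacs_oracle <- function(i, j)
    dacs_score(brute_tanimoto(orig$fingerprints[i, ], cand$fingerprints[j, ]),
               brute_mcc(orig$targets[[i]], cand$targets[[j]], u))
  for (cutoff in c(0.2, 0.6, 1.1)) {
    m <- build_substitute_map(orig, cand, u, cutoff)
    for (i in 1:2) {
      expected <- which(vapply(1:3, function(j) dacs_oracle(i, j), 0) >= cutoff)
      expect_setequal(m[[orig$drug_id[i]]]$drug_id, cand$drug_id[expected])
      # sorted by descending dacs
      expect_true(all(diff(m[[orig$drug_id[i]]]$dacs) <= 0))
    }
  }
  # cutoff above sqrt(2) is rejected; at sqrt(2) only identical pairs remain
  expect_error(build_substitute_map(orig, cand, u, 1.5), "cutoff")
  m2 <- build_substitute_map(orig, cand, u, sqrt(2))
  expect_equal(m2[["o1"]]$drug_id, "k1")   # identical chemistry and targets
  # a candidate with the original's own id is never its own substitute
  cand_self <- lib_from_bits(c("o1", "k9"), list(c(1, 2, 3, 4), c(1, 2, 3, 4)),
                             nbits = 16,
                             targets = list(o1 = c("p1", "p2"), k9 = c("p1", "p2")))
  m3 <- build_substitute_map(orig, cand_self, u, 0)
  expect_false("o1" %in% m3[["o1"]]$drug_id)
  expect_true("k9" %in% m3[["o1"]]$drug_id)
  # candidates without fingerprints are skipped with a warning
  fp <- cand$fingerprints; fp[2, ] <- NA
  cand_na <- drug_library(cand$drug_id, fingerprints = fp, targets = cand$targets)
  expect_warning(m4 <- build_substitute_map(orig, cand_na, u, 0), "k2")
  expect_false("k2" %in% m4[["o1"]]$drug_id)
})

test_that("augmentation inherits scores, respects positions, and drops self-pairs", {
  inst <- data.frame(instance_id = "I1", drug_a = "D1", drug_b = "D2",
                     cell_line = "C1", synergy_score = 30,
                     stringsAsFactors = FALSE)
  subs <- manual_map(list(D1 = c(S1 = 1.2, S2 = 0.8), D2 = c(S3 = 0.9)))
  aug <- augment_dataset(inst, subs)
  gen <- aug[aug$provenance == "augmented", ]
  expect_equal(nrow(aug), 4)             # original + 3 generated
  expect_equal(nrow(gen), 3)
  expect_setequal(paste(gen$drug_a, gen$drug_b),
                  c("D2 S1", "D2 S2", "D1 S3"))  # canonical order kept
  expect_equal(gen$synergy_score, rep(30, 3))    # score inheritance
  expect_equal(gen$cell_line, rep("C1", 3))
  expect_equal(gen$parent_id, rep("I1", 3))
  expect_setequal(gen$substituted_position, c("a", "a", "b"))
  # empty map: output equals input
  aug0 <- augment_dataset(inst, manual_map(setNames(list(), character(0))))
  expect_equal(nrow(aug0), 1)
  expect_equal(aug0$provenance, "original")
  # substitute equal to the partner drug: generated self-pair dropped
  subs_self <- manual_map(list(D1 = c(D2 = 1.0)))
  aug_self <- augment_dataset(inst, subs_self)
  expect_equal(nrow(aug_self), 1)
  # augmenting augmented data is refused
  expect_error(augment_dataset(aug, subs), "already-augmented")
})

test_that("duplicate generated instances deduplicate with originals winning", {
  inst <- data.frame(instance_id = c("I1", "I2"),
                     drug_a = c("D1", "D1"), drug_b = c("D2", "D3"),
                     cell_line = c("C1", "C1"), synergy_score = c(30, -25),
                     stringsAsFactors = FALSE)
  # D2 -> D3 recreates the original pair (D1, D3) on C1: original wins;
  # D3 -> D2 recreates (D1, D2) likewise
  subs <- manual_map(list(D2 = c(D3 = 0.9), D3 = c(D2 = 0.9)))
  expect_warning(aug <- augment_dataset(inst, subs), "conflict")
  expect_equal(nrow(aug), 2)
  expect_equal(aug$provenance, c("original", "original"))
  # two parents generating the same new pair: the first occurrence is kept
  subs2 <- manual_map(list(D2 = c(S1 = 0.9), D3 = c(S1 = 0.9)))
  expect_warning(aug2 <- augment_dataset(inst, subs2), "conflict")
  gen2 <- aug2[aug2$provenance == "augmented", ]
  expect_equal(nrow(gen2), 1)
  expect_equal(gen2$parent_id, "I1")
  expect_equal(gen2$synergy_score, 30)
})

test_that("the worked fixture's augmentation matches hand enumeration", {
  co <- worked_fixture()
  u <- co$universe
  # scalar oracle over the 4 x 2 original-candidate grid
  d <- sapply(co$candidates$drug_id, function(cj)
    sapply(co$drugs$drug_id, function(oi)
      dacs_score(
        brute_tanimoto(co$drugs$fingerprints[oi, ], co$candidates$fingerprints[cj, ]),
        brute_mcc(co$drugs$targets[[oi]], co$candidates$targets[[cj]], u))))
  cutoff <- 0.5
  m <- build_substitute_map(co$drugs, co$candidates, u, cutoff)
  for (oi in co$drugs$drug_id)
    expect_setequal(m[[oi]]$drug_id, colnames(d)[d[oi, ] >= cutoff])
  # s1 is chemically identical to d1 with identical targets
  expect_equal(d["d1", "s1"], sqrt(2))
  aug <- augment_dataset(co$instances, m)
  gen <- aug[aug$provenance == "augmented", ]
  # count law (pre-dedup, no self-pair drops possible: candidate ids are
  # disjoint from drug ids)
  n_sub <- vapply(m, nrow, 0L)
  expected_gen <- sum(n_sub[co$instances$drug_a] + n_sub[co$instances$drug_b])
  expect_lte(attr(aug, "n_generated"), expected_gen)
  # enumerate by hand: replicate the generation loop naively
  naive <- list()
  for (k in seq_len(nrow(co$instances))) for (pos in c("a", "b")) {
    repl <- co$instances[[paste0("drug_", pos)]][k]
    part <- co$instances[[paste0("drug_", setdiff(c("a", "b"), pos))]][k]
    for (s in m[[repl]]$drug_id) {
      if (s == part) next
      pr <- sort(c(s, part))
      naive[[length(naive) + 1L]] <- data.frame(
        drug_a = pr[1], drug_b = pr[2],
        cell_line = co$instances$cell_line[k],
        synergy_score = co$instances$synergy_score[k],
        stringsAsFactors = FALSE)
    }
  }
  naive <- do.call(rbind, naive)
  okey <- paste(co$instances$drug_a, co$instances$drug_b, co$instances$cell_line)
  nkey <- paste(naive$drug_a, naive$drug_b, naive$cell_line)
  keep <- !duplicated(nkey) & !(nkey %in% okey)
  expect_equal(nrow(gen), sum(keep))
  expect_setequal(paste(nkey[keep], naive$synergy_score[keep]),
                  paste(gen$drug_a, gen$drug_b, gen$cell_line, gen$synergy_score))
  # cell-line set invariance
  expect_setequal(unique(aug$cell_line), unique(co$instances$cell_line))
})

test_that("labeling applies inclusive cutoffs and reports class balance", {
  inst <- data.frame(synergy_score = c(20, 19.99, 0, -19.99, -20, 45, -33))
  lab <- label_instances(inst)
  expect_equal(attr(lab, "n_synergistic"), 2)
  expect_equal(attr(lab, "n_antagonistic"), 2)
  expect_equal(attr(lab, "n_excluded"), 3)
  expect_equal(lab$label[lab$synergy_score == 20], "synergistic")
  expect_equal(lab$label[lab$synergy_score == -20], "antagonistic")
  expect_error(label_instances(inst, syn_cut = -5, ant_cut = 5), "exceed")
  cb <- class_balance(2461, 749)
  expect_equal(cb$total, 3210)
  expect_equal(round(cb$pct_synergistic, 1), 76.7)
})

test_that("ratio-preserving augmentation keeps the class ratio and refuses leakage", {
  train <- data.frame(instance_id = paste0("I", 1:4),
                      label = c("synergistic", "synergistic", "synergistic",
                                "antagonistic"),
                      stringsAsFactors = FALSE)
  pool <- data.frame(instance_id = paste0("A", 1:40),
                     parent_id = rep(paste0("I", 1:4), 10),
                     label = rep(c("synergistic", "antagonistic"), c(24, 16)),
                     stringsAsFactors = FALSE)
  out <- ratio_preserving_augment(train, pool, seed = 3)
  added <- attr(out, "n_added")
  expect_equal(unname(added["synergistic"] / added["antagonistic"]), 3,
               tolerance = 0.35)  # 3:1 within one instance
  expect_true(abs(added["synergistic"] - 3 * added["antagonistic"]) <= 3)
  # determinism given the seed
  out2 <- ratio_preserving_augment(train, pool, seed = 3)
  expect_identical(out$instance_id, out2$instance_id)
  # empty pool: unchanged
  out0 <- ratio_preserving_augment(train, pool[0, ], seed = 1)
  expect_equal(nrow(out0), 4)
  # one-class pool: ratio bound forces zero additions, shortfall reported
  pool_s <- pool[pool$label == "synergistic", ]
  out1 <- ratio_preserving_augment(train, pool_s, seed = 1)
  expect_equal(nrow(out1), 4)
  expect_equal(attr(out1, "shortfall"), nrow(pool_s))
  # pool referencing a parent outside train is a leakage error
  bad <- pool; bad$parent_id[1] <- "I999"
  expect_error(ratio_preserving_augment(train, bad, seed = 1), "outside")
})

test_that("synergy distribution summaries use population statistics", {
  expect_equal(synergy_distribution_summary(c(10, 10))$mean, 10)
  expect_equal(synergy_distribution_summary(c(10, 10))$sd, 0)
  s <- synergy_distribution_summary(c(0, 20))
  expect_equal(s$mean, 10)
  expect_equal(s$sd, 10)          # population, not sample, sd
  expect_equal(sum(s$histogram$count), 2)
  expect_error(synergy_distribution_summary(numeric(0)), "scores")
})
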