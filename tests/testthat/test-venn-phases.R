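# Venn groups, phase assignment, accretion tables, urancestor repertoires.

test_that("venn_group canonicalises presence sets", {
  expect_equal(venn_group(c("A", "B", "E", "V")), "ABEV")
  expect_equal(venn_group(c("E", "A", "B")), "ABE")
  expect_equal(venn_group("B"), "B")
  expect_equal(venn_group(c("V", "E")), "EV")
  expect_error(venn_group(character(0)), "empty")
  expect_error(venn_group("X"), "letters")
  expect_equal(length(venn_labels()), 15)
})

test_that("presence_from_census applies the g > 0 rule per supergroup", {
  g <- matrix(c(3L, 1L, 0L, 0L,
                0L, 0L, 2L, 0L,
                1L, 1L, 1L, 1L), 4, 3,
              dimnames = list(c("a1", "b1", "e1", "v1"),
                              c("fAB", "fE", "fABEV")))
  ce <- census_matrix(g, c("A", "B", "E", "V"))
  expect_equal(venn_group(presence_from_census(ce, "fAB")), "AB")
  expect_equal(venn_group(presence_from_census(ce, "fE")), "E")
  expect_equal(venn_group(presence_from_census(ce, "fABEV")), "ABEV")
  expect_error(presence_from_census(ce, "nope"), "unknown")
})

test_that("phase assignment uses intervals closed at the older end", {
  expect_equal(assign_phase(3.8), 0L)
  expect_equal(assign_phase(3.7), 0L)
  expect_equal(assign_phase(3.6), 1L)   # internal boundary -> younger phase
  expect_equal(assign_phase(2.5), 3L)
  expect_equal(assign_phase(2.0), 4L)
  expect_equal(assign_phase(0.9), 5L)
  expect_equal(assign_phase(0), 5L)
  expect_error(assign_phase(4.2), "outside")
  expect_error(phase_config(c(3.8, 3.9, 0)), "decrease")
})

test_that("phase_table counts, totals and ratios are consistent", {
  mid <- c(3.7, 3.4, 2.85, 2.25, 1.45, 0.45)
  prot <- data.frame(age_gya = rep(mid, c(4, 2, 6, 0, 3, 5)),
                     venn = "ABEV")
  fam <- data.frame(age_gya = rep(mid, c(2, 1, 3, 0, 6, 2)),
                    venn = rep(c("ABEV", "ABE"), length.out = 14))
  vpt <- phase_table(prot, fam)
  ps <- vpt$phase_summary
  expect_equal(ps$prototypes, c(4, 2, 6, 0, 3, 5))
  expect_equal(ps$families, c(2, 1, 3, 0, 6, 2))
  # totals equal the sums over Venn labels
  expect_equal(as.numeric(tapply(vpt$counts$prototypes, vpt$counts$phase, sum)),
               as.numeric(ps$prototypes))
  expect_equal(sum(vpt$counts$families), 14)
  # ratios to two decimals, half away from zero; empty phase flagged
  expect_equal(ps$ratio, c(2, 2, 2, NA, 0.5, 2.5))
  expect_false(ps$ratio_defined[4])
})

test_that("urancestor repertoires nest and respect the phase cutoffs", {
  prot <- data.frame(prototype = paste0("P", 1:8),
                     age_gya = c(3.7, 3.75, 3.5, 3.3, 2.8, 1.5, 0.5, 0.1))
  luca <- urancestor_repertoire(prot, which = "LUCA")
  lucella <- urancestor_repertoire(prot, which = "LUCellA")
  expect_setequal(luca, c("P1", "P2"))
  expect_setequal(lucella, c("P1", "P2", "P3", "P4"))
  expect_true(all(luca %in% lucella))
  young <- data.frame(prototype = "P9", age_gya = 0.2)
  expect_length(urancestor_repertoire(young, which = "LUCA"), 0)
  expect_length(urancestor_repertoire(young, which = "LUCellA"), 0)
})

test_that("repertoire summaries count planted annotations exactly", {
  ann <- data.frame(prototype = paste0("P", 1:6),
                    loop_type = c("HH", "HH", "HH", "HH", "EH", "BN"),
                    disorder = c(rep("ordered", 5), "high"),
                    function_major = c(rep("Metabolism", 3),
                                       rep("Information", 2), NA))
  s <- summarize_repertoire(paste0("P", 1:4), ann)
  expect_equal(s$loop_type$count[s$loop_type$category == "HH"], 4)
  expect_equal(sum(s$loop_type$count), 4)
  expect_equal(sum(s$disorder$proportion), 1)
  # missing annotation becomes Other/Unknown, not dropped
  s6 <- summarize_repertoire(paste0("P", 1:6), ann)
  expect_equal(s6$function_major$count[
    s6$function_major$category == "Other/Unknown"], 1)
  expect_equal(sum(s6$function_major$count), 6)
  # planted frequencies recovered exactly
  expect_equal(s6$loop_type$proportion[s6$loop_type$category == "HH"], 4 / 6)
})

test_that("venn labels partition simulated families at zero dropout", {
  sim <- simulate_accretion(accretion_params(n_families = 15,
                                             group_sizes = c(A = 3, B = 3,
                                                             E = 3, V = 3),
                                             dropout = 0, seed = 12))
  got <- presence_from_census(sim$census, names(sim$truth$venn))
  expect_identical(unname(got), unname(sim$truth$venn))
})
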