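# Prototype mapping: e-value filter, modularity, ages, bipartite network.

mini_chronology <- function() {
  tab <- data.frame(family = c("f1", "f2", "f3", "f4"),
                    nd = c(0, 0.2, 0.2, 0.7),
                    age_gya = 3.8 - 3.8 * c(0, 0.2, 0.2, 0.7))
  structure(list(table = tab, clock = c(a = 3.8, b = -3.8)),
            class = "chronology")
}

test_that("the e-value filter is strict at the threshold", {
  tab <- data.frame(prototype = c("P1", "P1", "P2", "P3"),
                    family = c("f1", "f2", "f3", "f4"),
                    e_value = c(0.01, 0.0009, 0.001, 1e-8))
  res <- load_and_filter_mappings(tab)
  expect_equal(nrow(res$mappings), 2)          # 0.0009 kept, 0.001 dropped
  expect_setequal(res$mappings$prototype, c("P1", "P3"))
  expect_equal(res$n_dropped_rows, 2)
  expect_equal(res$dropped_prototypes, "P2")   # lost every row
  tab$e_value <- as.character(tab$e_value)
  tab$e_value[1] <- "not-a-number"
  expect_error(load_and_filter_mappings(tab), "malformed")
})

test_that("modularity follows the shared-time-of-origin definition", {
  ch <- mini_chronology()
  expect_equal(classify_modularity("f1", ch), "non-modular")
  expect_equal(classify_modularity(c("f2", "f3"), ch), "non-modular")
  expect_equal(classify_modularity(c("f1", "f4"), ch), "modular")
  expect_error(classify_modularity("nope", ch), "absent")
})

test_that("prototype age is the minimum mapped nd, via the clock", {
  ch <- mini_chronology()
  maps <- data.frame(prototype = c("P1", "P2", "P2"),
                     family = c("f1", "f2", "f4"),
                     e_value = 1e-6)
  ages <- assign_prototype_age(maps, ch)
  a1 <- ages[ages$prototype == "P1", ]
  expect_equal(a1$age_nd, 0)
  expect_equal(a1$age_gya, 3.8)
  expect_equal(a1$modularity, "non-modular")
  a2 <- ages[ages$prototype == "P2", ]
  expect_equal(a2$age_nd, 0.2)
  expect_equal(a2$modularity, "modular")
})

test_that("bipartite edges conserve rows and mark recruitments", {
  ch <- mini_chronology()
  maps <- data.frame(prototype = c("P1", "P2", "P2", "P3", "P3"),
                     family = c("f1", "f2", "f4", "f2", "f3"),
                     e_value = 1e-6)
  ed <- bipartite_edges(maps, ch)
  expect_equal(nrow(ed), nrow(maps))
  # modular P2: exactly one non-recruitment edge (its founding family)
  expect_equal(sum(!ed$is_recruitment[ed$prototype == "P2"]), 1)
  # non-modular P3 (f2, f3 share nd): no recruitment edges
  expect_false(any(ed$is_recruitment[ed$prototype == "P3"]))
  # age monotonicity: prototype age <= every mapped family nd
  expect_true(all(ed$prototype_nd <= ed$family_nd + 1e-12))
})

test_that("planted modularity is recovered perfectly on synthetic mappings", {
  sim <- simulate_accretion(accretion_params(n_families = 20,
                                             group_sizes = c(A = 2, B = 2,
                                                             E = 2, V = 2),
                                             dropout = 0, seed = 3))
  pm <- simulate_prototype_mappings(sim$truth, n_prototypes = 60,
                                    modular_fraction = 0.4, seed = 6)
  ch <- chronology_from_truth(sim$truth)
  filt <- load_and_filter_mappings(pm$mappings)
  # surviving rows are exactly the planted true links
  expect_true(all(filt$mappings$e_value < 0.001))
  ages <- assign_prototype_age(filt, ch)
  got <- setNames(ages$modularity, ages$prototype)
  expect_identical(unname(got[pm$truth$prototype]), pm$truth$modularity)
  # non-modular prototypes date exactly at their single family's nd
  nd <- setNames(ch$table$nd, ch$table$family)
  nm <- pm$truth$prototype[pm$truth$modularity == "non-modular"]
  for (p in nm) {
    fams <- filt$mappings$family[filt$mappings$prototype == p]
    expect_equal(ages$age_nd[ages$prototype == p], unname(min(nd[fams])))
  }
})

test_that("modular_fraction extremes force uniform classes", {
  sim <- simulate_accretion(accretion_params(n_families = 10,
                                             group_sizes = c(A = 2, B = 2,
                                                             E = 2, V = 2),
                                             dropout = 0, seed = 8))
  ch <- chronology_from_truth(sim$truth)
  p0 <- simulate_prototype_mappings(sim$truth, 25, modular_fraction = 0,
                                    seed = 2)
  a0 <- assign_prototype_age(load_and_filter_mappings(p0$mappings), ch)
  expect_true(all(a0$modularity == "non-modular"))
  p1 <- simulate_prototype_mappings(sim$truth, 25, modular_fraction = 1,
                                    seed = 2)
  a1 <- assign_prototype_age(load_and_filter_mappings(p1$mappings), ch)
  expect_true(all(a1$modularity == "modular"))
  expect_error(simulate_prototype_mappings(sim$truth, 5, modular_fraction = 2),
               "modular_fraction")
})
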