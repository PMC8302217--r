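lad <- species_ladder()
age_rank <- function(a) match(a, age_levels())

test_that("conservation ages follow the cumulative species ladder", {
  expect_equal(assign_age(make_profile("rat"))$age, "Muridae")
  expect_equal(assign_age(make_profile(c("rat", "human", "chimp")))$age, "Eutheria")
  expect_equal(assign_age(make_profile(c("rat", "human", "chimp", "opossum",
                                         "chick", "zebrafish")))$age, "Vertebrata")
  expect_equal(assign_age(make_profile(character()))$age, "mouse-specific")
  expect_equal(assign_age(make_profile(character()), mode = "deepest")$age,
               "mouse-specific")
  # gappy profile: strict stops at Muridae, deepest spans to Eutheria
  gap <- make_profile(c("rat", "human"))
  expect_equal(assign_age(gap, mode = "strict")$age, "Muridae")
  expect_equal(assign_age(gap, mode = "deepest")$age, "Eutheria")
})

test_that("age assignment is monotone and strict never exceeds deepest", {
  others <- c("rat", "human", "chimp", "opossum", "chick", "zebrafish")
  set.seed(11)
  for (i in 1:40) {
    present <- sample(others, sample(0:5, 1))
    extra <- sample(setdiff(others, present), 1)
    for (mode in c("strict", "deepest")) {
      before <- assign_age(make_profile(present), mode = mode)$age
      after <- assign_age(make_profile(c(present, extra)), mode = mode)$age
      expect_gte(age_rank(after), age_rank(before))
    }
    strict <- assign_age(make_profile(present), mode = "strict")$age
    deepest <- assign_age(make_profile(present), mode = "deepest")$age
    expect_lte(age_rank(strict), age_rank(deepest))
  }
})

test_that("the architecture table counts majority classes with ties to Other", {
  p1 <- make_profile("rat", gene = "m1", arch = "IG")
  tab <- architecture_table(list(p1))
  rat <- tab[tab$Genome == "rat", ]
  expect_equal(unlist(rat[c("IGs", "MEGs", "Others", "Total")], use.names = FALSE),
               c(1L, 0L, 0L, 1L))
  expect_equal(sum(tab$Total), 1L)
  # tie between IG and MEG orthologs falls to Other
  p2 <- make_profile("rat", gene = "m2")
  p2$orthologs$rat <- c("rat_o1", "rat_o2")
  p2$arch$rat <- c("IG", "MEG")
  tab2 <- architecture_table(list(p2))
  expect_equal(tab2$Others[tab2$Genome == "rat"], 1L)
  # empty input gives the all-zero table
  tab0 <- architecture_table(list())
  expect_true(all(tab0$Total == 0L))
})

test_that("profiles from a noise-free simulation recover the planted table", {
  cfg <- simulation_config(dup_rate = 0.3, loss_rate = 0.2, switch_prob = 0.2)
  hs <- simulate_families(lad, cfg, seed = 500, n = 30)
  genes <- do.call(rbind, lapply(hs, `[[`, "genes"))
  g <- true_orthology_graph(hs)
  calls <- data.frame(gene = genes$gene, class = genes$architecture,
                      stringsAsFactors = FALSE)
  profiles <- presence_profiles(g, calls)
  tab <- architecture_table(profiles)
  # independent recount from the raw orthology pairs
  pairs <- do.call(rbind, lapply(hs, `[[`, "ortho_pairs"))
  sp <- stats::setNames(genes$species, genes$gene)
  arch <- stats::setNames(genes$architecture, genes$gene)
  mouse_genes <- genes$gene[genes$species == "mouse"]
  for (s in setdiff(lad$species, "mouse")) {
    expected <- c(IG = 0L, MEG = 0L, Other = 0L)
    for (m in mouse_genes) {
      partners <- c(pairs$gene_b[pairs$gene_a == m & sp[pairs$gene_b] == s],
                    pairs$gene_a[pairs$gene_b == m & sp[pairs$gene_a] == s])
      if (length(partners) == 0L) next
      n_ig <- sum(arch[partners] == "IG")
      n_meg <- sum(arch[partners] == "MEG")
      cls <- if (n_ig > n_meg) "IG" else if (n_meg > n_ig) "MEG" else "Other"
      expected[cls] <- expected[cls] + 1L
    }
    row <- tab[tab$Genome == s, ]
    expect_equal(c(row$IGs, row$MEGs, row$Others), unname(expected))
  }
})

test_that("conservation fractions reproduce worked percentages from counts", {
  tab <- data.frame(Genome = c("rat", "zebrafish", "none"),
                    IGs = c(442L, 91L, 0L), MEGs = c(57L, 90L, 0L),
                    Others = c(2L, 39L, 0L),
                    Total = c(501L, 220L, 0L), stringsAsFactors = FALSE)
  expect_message(fr <- conservation_fractions(tab), "zero-total")
  expect_equal(fr$rows$pct_int[fr$rows$Genome == "rat"], 88)
  expect_equal(fr$rows$pct_int[fr$rows$Genome == "zebrafish"], 41)
  expect_equal(fr$rows$pct, round(100 * c(442 / 501, 91 / 220), 2))
  expect_equal(fr$pooled$pct, round(100 * 533 / 721, 2))
  # a zero-numerator row is 0%
  z <- conservation_fractions(data.frame(Genome = "x", IGs = 0L, MEGs = 10L,
                                         Others = 0L, Total = 10L))
  expect_equal(z$rows$pct_int, 0)
})
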