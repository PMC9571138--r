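test_that("menu disassembly flattens recipes, conserving day and total mass", {
  menu <- data.frame(day = c(1, 1), food = c("apple", "pasta_dish"),
                     amount = c(150, 200))
  book <- list(
    pasta_dish = data.frame(ingredient = c("pasta", "tomato_sauce", "oil"),
                            share = c(0.5, 0.3, 0.2)),
    tomato_sauce = data.frame(ingredient = c("tomato", "oil"),
                              share = c(0.9, 0.1)))
  flat <- disassemble_menu(menu, book)
  expect_equal(flat$amount[flat$food == "pasta"], 100)
  expect_equal(flat$amount[flat$food == "tomato"], 60 * 0.9)
  expect_equal(sum(flat$amount), sum(menu$amount))        # mass conserved
  expect_false(any(c("pasta_dish", "tomato_sauce") %in% flat$food))
  # identity on simple-food menus
  simple <- data.frame(day = 1:2, food = c("apple", "pasta"), amount = c(1, 2))
  expect_equal(disassemble_menu(simple, book), simple)
  expect_error(disassemble_menu(
    data.frame(day = 1, food = "dish", amount = 100, composite = TRUE), list()),
    "missing recipe")
})

test_that("daily totals weight by amount and recompute energy from macronutrients", {
  fcdb <- rbind(
    toy_ingredient("a", water = 60, available_carbohydrate = 20,
                   soluble_carbohydrate = 5, starch = 15, fiber = 2,
                   protein_total = 10, lipid_total = 5, sfa = 1, sodium = 100,
                   ash = 3),
    toy_ingredient("b", water = 80, available_carbohydrate = 12,
                   soluble_carbohydrate = 6, starch = 6, fiber = 1,
                   protein_total = 2, lipid_total = 1, sfa = 0.2, sodium = 50,
                   ash = 4))
  names(fcdb)[names(fcdb) == "ingredient"] <- "item"
  menu <- data.frame(day = 1, food = c("a", "b"), amount = c(50, 200))
  tot <- daily_totals(menu, fcdb)
  expect_equal(tot$protein_total, 9)
  expect_equal(tot$lipid_total, 0.5 * 5 + 2 * 1)
  # energy comes from the summed macronutrients, not summed food energies
  expect_equal(tot$energy_kcal,
               compute_energy(tot$available_carbohydrate, tot$protein_total,
                              tot$lipid_total, tot$fiber, "as_such")$energy_kcal)
  expect_error(daily_totals(data.frame(day = 1, food = "zz", amount = 1), fcdb),
               "not in the composition table")
})

test_that("substitution swaps composition sources only, gram amounts fixed", {
  b <- gen_menu(generator_config(seed = 9), scenario = "MC")
  # empty scope: arms identical
  same <- apply_substitution(b$menu, stats::setNames(character(), character()),
                             b$fcdb_gc, b$fcdb_gc)
  expect_equal(same$gc, same$gf)
  arms <- apply_substitution(b$menu, b$sub_map, b$fcdb_gc, b$fcdb_gf)
  # grams per day conserved by construction (same menu in both arms)
  expect_equal(arms$gc$day, arms$gf$day)
  # nutrients untouched by the cereal scope are bit-identical across arms
  expect_identical(arms$gc$vitamin_C, arms$gf$vitamin_C)
  expect_identical(arms$gc$calcium, arms$gf$calcium)
  # a +2 g lipid shift in one bread, 100 g/day, moves every day by exactly 2 g
  gc_tab <- b$fcdb_gc
  gf_tab <- gc_tab
  gf_tab$item <- ifelse(gf_tab$item == "bread_refined", "bread_refined_gf",
                        gf_tab$item)
  gf_tab$lipid_total[gf_tab$item == "bread_refined_gf"] <-
    gf_tab$lipid_total[gf_tab$item == "bread_refined_gf"] + 2
  menu <- data.frame(day = 1:7, food = "bread_refined", amount = 100)
  arms2 <- apply_substitution(menu, c(bread_refined = "bread_refined_gf"),
                              gc_tab, gf_tab)
  expect_equal(arms2$gf$lipid_total - arms2$gc$lipid_total, rep(2, 7))
})

test_that("the signed-rank test matches the exhaustive enumeration oracle", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(4:10, 1)
    d <- round(stats::rnorm(n), sample(0:1, 1))   # induces ties and zeros
    got <- wilcoxon_signed_rank(d)
    expect_equal(got$p.value, oracle_signed_rank_p(d), tolerance = 1e-12,
                 info = paste("case", i))
  }
  # tie-free data also reproduces the reference implementation exactly
  for (i in 1:20) {
    d <- stats::rnorm(sample(5:12, 1))
    got <- wilcoxon_signed_rank(d)
    ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
    expect_equal(got$statistic, unname(ref$statistic))
    expect_equal(got$p.value, ref$p.value, tolerance = 1e-12)
  }
  # all-zero differences short-circuit
  z <- wilcoxon_signed_rank(rep(0, 7))
  expect_equal(z$p.value, 1)
  expect_identical(z$method, "degenerate")
})

test_that("normality routing reproduces the closed-form paired t example", {
  d <- c(3, 1, 2, 4, 2, 3, 1)
  gc <- c(10, 12, 11, 13, 12, 10, 11)
  row <- route_paired_test(gc, gc + d)
  expect_identical(row$test, "paired_t")
  expect_equal(row$statistic, mean(d) / (sd(d) / sqrt(7)), tolerance = 1e-9)
  expect_equal(row$statistic, 5.435, tolerance = 1e-3)
  expect_lt(row$p_value, 0.01)
  expect_true(row$significant)
  # identical arms: p = 1, no test
  same <- route_paired_test(gc, gc)
  expect_equal(same$p_value, 1)
  expect_identical(same$test, "none")
  expect_false(same$significant)
})

test_that("menu comparison flags injected effects and nothing else at null", {
  b <- gen_menu(generator_config(seed = 13), scenario = "WC")
  arms <- apply_substitution(b$menu, b$sub_map, b$fcdb_gc, b$fcdb_gf)
  rows <- compare_menus(arms$gc, arms$gf)
  for (k in seq_len(nrow(b$effects))) {
    r <- rows[rows$nutrient == b$effects$nutrient[k], ]
    expect_true(r$significant, info = b$effects$nutrient[k])
    expect_equal(sign(r$gf_center - r$gc_center), b$effects$direction[k])
  }
  # non-cereal-sourced nutrients show no difference at all
  expect_equal(rows$p_value[rows$nutrient == "vitamin_C"], 1)
  # null menus: nothing significant anywhere
  b0 <- gen_menu(generator_config(seed = 13, effects = NULL), scenario = "WC")
  a0 <- apply_substitution(b0$menu, b0$sub_map, b0$fcdb_gc, b0$fcdb_gf)
  r0 <- compare_menus(a0$gc, a0$gf)
  expect_true(all(r0$p_value == 1))
  # significance flag is p < alpha by definition
  expect_equal(rows$significant, rows$p_value < 0.05)
})

test_that("the report grid bolds significant rows and italicizes medians", {
  rows <- data.frame(
    nutrient = c("lipid_total", "vitamin_D"),
    gc_center = c(67.1, 1.01), gc_spread = c(12.3, 0.83),
    gf_center = c(75.9, 1.02), gf_spread = c(10.2, 0.84),
    normal = c(TRUE, FALSE),
    test = c("paired_t", "wilcoxon_signed_rank"),
    statistic = c(2.5, 3), p_value = c(0.039, 0.798),
    significant = c(TRUE, FALSE), stringsAsFactors = FALSE)
  grid <- render_report(list(WC = rows))
  expect_true(grepl("\\*\\*0\\.039\\*\\*", grid[1, "WC_p"]))     # bold p
  expect_true(grepl("±", grid[1, "WC_GC"]))                      # mean ± SD
  expect_true(grepl("^\\*1\\.01 \\(0\\.83\\)\\*$", grid[2, "WC_GC"])) # median (IQR)
  expect_false(grepl("\\*\\*", grid[2, "WC_p"]))
  expect_error(render_report(rows[0, ]), "no comparison rows")
})
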