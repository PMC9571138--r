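test_that("recipe evaluation mixes, loses water and renormalizes mass", {
  ref <- toy_ref_db()
  # identity: one ingredient, no steps
  v <- evaluate_recipe(c(flourA = 100), ref)
  expect_equal(v[["protein_total"]], 10)
  expect_equal(v[["available_carbohydrate"]], 70)
  # mixture arithmetic
  v2 <- evaluate_recipe(c(proteinB = 50, sugar = 50), ref)
  expect_equal(v2[["protein_total"]], 10)
  # mass-balance bookkeeping: 100 g dough with 40 g water baked at yield 0.80
  # loses 20 g water; per 100 g as sold water = 20/0.8 = 25, others x1.25
  dough <- toy_ingredient("dough", water = 40, available_carbohydrate = 40,
                          soluble_carbohydrate = 4, starch = 36, fiber = 2,
                          protein_total = 8, lipid_total = 6, sfa = 1,
                          sodium = 200, ash = 4)
  steps <- data.frame(name = "baking", yield = 0.80, retention_key = NA)
  v3 <- evaluate_recipe(c(dough = 100), dough, steps = steps)
  expect_equal(v3[["water"]], 25)
  expect_equal(v3[["protein_total"]], 10)
  expect_equal(v3[["available_carbohydrate"]], 50)
  # as-sold mass closes to 100 g
  expect_equal(v3[["water"]] + v3[["protein_total"]] + v3[["lipid_total"]] +
                 v3[["available_carbohydrate"]] + v3[["fiber"]] + v3[["ash"]],
               100, tolerance = 1e-9)
  expect_error(evaluate_recipe(c(flourA = 60, sugar = 30), ref), "sum to 100")
  expect_error(evaluate_recipe(c(nothere = 100), ref), "unknown ingredient")
  # yield demanding more water than the formulation holds
  expect_error(evaluate_recipe(c(sugar = 100), ref,
                               steps = data.frame(name = "bake", yield = 0.5,
                                                  retention_key = NA)),
               "water")
})

test_that("single-ingredient recipe with matching label recovers weight 100", {
  ref <- toy_ref_db()
  label <- label_of_ingredient(ref, "flourA")
  rec <- recipe_spec("solo", data.frame(key = "flourA", rank = 1))
  sol <- estimate_weights(rec, ref, label)
  expect_equal(unname(sol$weights), 100)
  expect_lt(max(abs(sol$residuals)), 1e-9)
  expect_identical(sol$status, "converged")
})

test_that("two-ingredient toy matches the 0.1 g grid-search oracle", {
  ref <- toy_ref_db()
  label <- label_declaration(energy_kJ = NA, energy_kcal = NA, fat = 40,
                             saturates = 6, carbohydrate = 60, sugars = 60,
                             fiber = 0, protein = 0, salt = 0)
  rec <- recipe_spec("toy2", data.frame(key = c("sugar", "oil"), rank = 1:2))
  sol <- estimate_weights(rec, ref, label)
  expect_equal(unname(sol$weights), c(60, 40), tolerance = 1e-9)
  G <- ordered_weight_grid(2, 0.1)
  obj <- grid_objective(G, ref, c("sugar", "oil"), NULL, label)
  expect_equal(unname(sol$weights), unname(G[, which.min(obj)]),
               tolerance = 0.05)
  expect_lte(sol$objective, min(obj) + 1e-9)
})

test_that("optimizer never loses to the grid oracle on random 3-ingredient recipes", {
  ref <- toy_ref_db()
  keys <- c("flourA", "sugar", "oil")
  G <- ordered_weight_grid(3, 0.1)
  set.seed(11)
  for (i in 1:30) {
    w_true <- sort(runif(3), decreasing = TRUE)
    w_true <- w_true / sum(w_true) * 100
    v <- evaluate_recipe(stats::setNames(w_true, keys), ref)
    label <- round_label_eu(label_from_vector(v))
    rec <- recipe_spec("r3", data.frame(key = keys, rank = 1:3))
    sol <- estimate_weights(rec, ref, label)
    obj <- grid_objective(G, ref, keys, NULL, label)
    expect_lte(sol$objective, min(obj) + 1e-9)
  }
})

test_that("generated products are recovered exactly from unrounded labels", {
  cfg <- generator_config(seed = 1, label_rounding = FALSE)
  ref <- gen_reference_db(cfg)
  for (s in 1:10) {
    p <- gen_labeled_product(generator_config(seed = 500 + s,
                                              label_rounding = FALSE), ref)
    sol <- estimate_weights(p$recipe, ref, p$label)
    expect_lt(max(abs(sol$residuals)), 1e-6)
    expect_true(all(diff(sol$weights) <= 1e-9))        # rank ordering
    expect_equal(sum(sol$weights), 100, tolerance = 1e-9)
    # full-rank designs identify the true formulation
    M <- t(as.matrix(ref[match(names(p$true_weights), ref$ingredient),
                         c("lipid_total", "sfa", "available_carbohydrate",
                           "soluble_carbohydrate", "fiber", "protein_total",
                           "sodium")]))
    if (qr(M)$rank == length(p$true_weights)) {
      expect_equal(unname(sol$weights), unname(p$true_weights),
                   tolerance = 1e-6)
    }
  }
})

test_that("solutions are deterministic and honor declared percentages exactly", {
  cfg <- generator_config(seed = 5, label_rounding = TRUE)
  ref <- gen_reference_db(cfg)
  p <- gen_labeled_product(cfg, ref)
  s1 <- estimate_weights(p$recipe, ref, p$label)
  s2 <- estimate_weights(p$recipe, ref, p$label)
  expect_identical(s1$weights, s2$weights)
  expect_identical(s1$objective, s2$objective)

  # fix the first ingredient at its declared percentage
  ing <- p$recipe$ingredients
  ing$percent[1] <- round(p$true_weights[1], 1)
  rec_fixed <- recipe_spec(p$recipe$id, ing, p$recipe$steps)
  s3 <- estimate_weights(rec_fixed, ref, p$label)
  expect_equal(unname(s3$weights[1]), ing$percent[1], tolerance = 1e-9)
  expect_true(all(diff(s3$weights) <= 1e-9))
})

test_that("infeasible declarations fail before optimization", {
  ref <- toy_ref_db()
  label <- label_of_ingredient(ref, "flourA")
  # percentages that violate the label ordering
  expect_error(estimate_weights(
    recipe_spec("bad", data.frame(key = c("sugar", "oil"), rank = 1:2,
                                  percent = c(20, 60))),
    ref, label), "violate the rank ordering")
  expect_error(estimate_weights(
    recipe_spec("bad2", data.frame(key = c("sugar", "oil"), rank = 1:2,
                                   percent = c(80, 70))),
    ref, label), "exceed 100")
})

test_that("a moisture equality is honored and can only worsen the fit", {
  cfg <- generator_config(seed = 21, label_rounding = TRUE)
  ref <- gen_reference_db(cfg)
  p <- gen_labeled_product(cfg, ref)
  free <- estimate_weights(p$recipe, ref, p$label)
  target <- p$true_vector[["water"]]
  rec_m <- recipe_spec(p$recipe$id, p$recipe$ingredients, p$recipe$steps,
                       moisture_target = target)
  tied <- estimate_weights(rec_m, ref, p$label)
  v <- evaluate_recipe(tied$weights, ref, steps = p$recipe$steps)
  expect_equal(v[["water"]], target, tolerance = 1e-6)
  expect_gte(tied$objective, free$objective - 1e-12)
})

test_that("fit report applies EU-style declared-value tolerances", {
  ref <- toy_ref_db()
  label <- label_of_ingredient(ref, "flourA")
  rec <- recipe_spec("solo", data.frame(key = "flourA", rank = 1))
  sol <- estimate_weights(rec, ref, label)
  rep <- fit_report(sol, label)
  expect_true(all(rep$pass))
  expect_true(attr(rep, "overall_pass"))

  # threshold arithmetic on doctored residuals
  sol2 <- sol
  sol2$residuals["protein"] <- 1.4   # label 10 -> computed 11.4: 14% < 15%
  lab2 <- label
  lab2$protein <- 10
  rep2 <- fit_report(sol2, lab2)
  expect_true(rep2$pass[rep2$nutrient == "protein"])
  sol2$residuals["salt"] <- 0.5      # 0.5 > 0.375
  lab2$salt <- 1.0
  rep3 <- fit_report(sol2, lab2)
  expect_false(rep3$pass[rep3$nutrient == "salt"])
  expect_false(attr(rep3, "overall_pass"))
})
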