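#' Configuration for the synthetic-data generators
#'
#' Single seed surface for every generator: a fixed config yields
#' byte-identical outputs. The defaults describe the study conditions the
#' package is verified under: 7-day menus for a 2000 kcal diet, products of
#' 3-6 label-ordered ingredients, EU label rounding on, and multiplicative
#' GF-vs-GC effects on the nutrients for which the gluten-free reformulation
#' literature reports systematic differences (higher PUFA, linoleic acid and
#' vitamin E in GF cereal products; lower zinc in wholegrain GF products).
#'
#' @param seed integer RNG seed.
#' @param n_ingredients_range inclusive range of ingredient counts for
#'   generated products.
#' @param brands_per_item branded products per food item.
#' @param days days per menu (7).
#' @param label_rounding apply EU presentation rounding to generated labels.
#' @param jitter_cv coefficient of variation of brand-to-brand composition
#'   jitter.
#' @param wholegrain_share wholegrain share of cereal servings in the mixed
#'   (MC) scenario.
#' @param effects named multiplicative GF/GC effect factors applied to GF
#'   cereal-item components (`zinc` applies to wholegrain items only), or
#'   `NULL` for no injected effect.
#' @return List of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, n_ingredients_range = c(3L, 6L),
                             brands_per_item = 3L, days = 7L,
                             label_rounding = TRUE, jitter_cv = 0.05,
                             wholegrain_share = 0.6,
                             effects = list(pufa = 1.2, linoleic = 1.2,
                                            vitamin_E = 1.2, zinc = 0.7)) {
  stopifnot(jitter_cv >= 0, wholegrain_share >= 0, wholegrain_share <= 1)
  structure(list(seed = as.integer(seed),
                 n_ingredients_range = n_ingredients_range,
                 brands_per_item = brands_per_item, days = days,
                 label_rounding = label_rounding, jitter_cv = jitter_cv,
                 wholegrain_share = wholegrain_share, effects = effects),
            class = "generator_config")
}

# proximate templates per ingredient group: ranges (g/100 g); water closes
# the mass balance to 100 exactly. micro_scale scales the base micronutrient
# profile; origin routes protein/lipid to the animal or vegetable split.
ingredient_templates <- function() {
  t <- list(
    flour            = list(starch = c(58, 68), soluble = c(0.5, 2), protein = c(6, 11),
                            lipid = c(0.8, 2.5), fiber = c(2, 7), ash = c(0.4, 1.2),
                            micro_scale = 1, origin = "vegetable"),
    wholegrain_flour = list(starch = c(50, 60), soluble = c(1, 2.5), protein = c(8, 13),
                            lipid = c(1.5, 3), fiber = c(6, 11), ash = c(1, 2),
                            micro_scale = 2, origin = "vegetable"),
    legume_flour     = list(starch = c(40, 48), soluble = c(2, 4), protein = c(20, 25),
                            lipid = c(1.5, 3), fiber = c(10, 15), ash = c(2.5, 3.5),
                            micro_scale = 2.5, origin = "vegetable"),
    sugar            = list(starch = c(0, 0), soluble = c(99.5, 99.9), protein = c(0, 0),
                            lipid = c(0, 0), fiber = c(0, 0), ash = c(0, 0.05),
                            micro_scale = 0.02, origin = "vegetable"),
    oil              = list(starch = c(0, 0), soluble = c(0, 0), protein = c(0, 0),
                            lipid = c(99.5, 99.9), fiber = c(0, 0), ash = c(0, 0),
                            micro_scale = 0.02, origin = "vegetable"),
    butter           = list(starch = c(0, 0), soluble = c(0.5, 1), protein = c(0.5, 1),
                            lipid = c(80, 84), fiber = c(0, 0), ash = c(0.1, 0.3),
                            micro_scale = 0.3, origin = "animal"),
    egg              = list(starch = c(0, 0), soluble = c(0.3, 0.8), protein = c(11.5, 13),
                            lipid = c(8.5, 10.5), fiber = c(0, 0), ash = c(0.8, 1.1),
                            micro_scale = 1.5, origin = "animal"),
    milk_powder      = list(starch = c(0, 0), soluble = c(36, 39), protein = c(23, 26),
                            lipid = c(23, 26), fiber = c(0, 0), ash = c(5.5, 6),
                            micro_scale = 3, origin = "animal"),
    cocoa            = list(starch = c(8, 11), soluble = c(1, 2), protein = c(18, 21),
                            lipid = c(20, 23), fiber = c(25, 28), ash = c(5, 6),
                            micro_scale = 3, origin = "vegetable"),
    fruit_filling    = list(starch = c(0, 2), soluble = c(55, 65), protein = c(0.3, 0.8),
                            lipid = c(0, 0.3), fiber = c(1, 3), ash = c(0.2, 0.5),
                            micro_scale = 0.5, origin = "vegetable"),
    water            = list(starch = c(0, 0), soluble = c(0, 0), protein = c(0, 0),
                            lipid = c(0, 0), fiber = c(0, 0), ash = c(0, 0.02),
                            micro_scale = 0, origin = "vegetable"),
    salt             = list(starch = c(0, 0), soluble = c(0, 0), protein = c(0, 0),
                            lipid = c(0, 0), fiber = c(0, 0), ash = c(99.8, 99.9),
                            micro_scale = 0, origin = "vegetable")
  )
  t
}

# base micronutrient magnitudes (per 100 g) at micro_scale = 1
base_micros <- function() {
  c(sodium = 5, potassium = 300, calcium = 50, phosphorus = 150, iron = 1.5,
    zinc = 1.2, vitamin_D = 0.2, vitamin_E = 1.0, retinol_eq = 20,
    thiamin = 0.15, riboflavin = 0.1, niacin = 1.5, vitamin_B6 = 0.15,
    folate = 25, vitamin_C = 2)
}

# log-uniform draw within [lo, hi]; degenerate ranges pass through
runif_log <- function(n, lo, hi) {
  if (hi <= 0) return(rep(0, n))
  lo <- max(lo, hi * 1e-3)
  exp(stats::runif(n, log(lo), log(hi)))
}

gen_one_ingredient <- function(group, key) {
  tpl <- ingredient_templates()[[group]]
  draw <- function(r) if (r[2] == r[1]) r[1] else runif_log(1, r[1], r[2])
  starch <- draw(tpl$starch); soluble <- draw(tpl$soluble)
  protein <- draw(tpl$protein); lipid <- draw(tpl$lipid)
  fiber <- draw(tpl$fiber); ash <- draw(tpl$ash)
  available <- starch + soluble
  water <- 100 - (protein + lipid + available + fiber + ash)
  stopifnot(water >= -1e-9)
  water <- max(water, 0)
  # fatty-acid classes as fractions of total lipid
  fr <- c(stats::runif(1, 0.15, 0.45), stats::runif(1, 0.25, 0.5),
          stats::runif(1, 0.1, 0.3))
  fr <- fr / sum(fr) * stats::runif(1, 0.9, 0.95)
  micro <- base_micros() * tpl$micro_scale * runif_log(length(base_micros()), 0.5, 2)
  if (group == "salt") micro["sodium"] <- 39337   # NaCl is 39.3% sodium
  animal <- tpl$origin == "animal"
  v <- nutrient_vector(
    water = water, available_carbohydrate = available,
    soluble_carbohydrate = soluble, starch = starch, fiber = fiber,
    protein_total = protein,
    protein_animal = if (animal) protein else 0,
    protein_vegetable = if (animal) 0 else protein,
    lipid_total = lipid,
    lipid_animal = if (animal) lipid else 0,
    lipid_vegetable = if (animal) 0 else lipid,
    sfa = lipid * fr[1], mufa = lipid * fr[2], pufa = lipid * fr[3],
    oleic = lipid * fr[2] * 0.9, linoleic = lipid * fr[3] * 0.8,
    linolenic = lipid * fr[3] * 0.1, ash = ash,
    .data = as.list(micro))
  e <- compute_energy(available, protein, lipid, fiber, "as_such")
  v["energy_kcal"] <- e$energy_kcal
  v["energy_kJ"] <- e$energy_kJ
  cbind(data.frame(ingredient = key, group = group, stringsAsFactors = FALSE),
        as.data.frame(as.list(v)))
}

#' Generate a synthetic reference ingredient table
#'
#' Emulates the role of the national ingredient composition table the recipe
#' approach draws on: one row per ingredient, all components populated,
#' proximates + water + ash closing to 100 g exactly by construction.
#' Amounts are log-uniform draws inside documented physiological ranges per
#' ingredient group ([ingredient_templates()]).
#'
#' @param cfg a [generator_config()].
#' @param n_per_group ingredients generated per group.
#' @return Data frame with `ingredient` and `group` keys plus all component
#'   columns (as-such carbohydrate basis).
#' @export
gen_reference_db <- function(cfg = generator_config(), n_per_group = 2L) {
  set.seed(cfg$seed)
  groups <- names(ingredient_templates())
  rows <- list()
  for (g in groups) {
    for (i in seq_len(n_per_group)) {
      rows[[length(rows) + 1L]] <- gen_one_ingredient(g, paste0(g, "_", i))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' EU presentation rounding of a label panel
#'
#' Energies to integers; gram amounts to the nearest 1 g at or above
#' 10 g/100 g and to 0.1 g below; salt to 0.1 g at or above 1 g and 0.01 g
#' below. Half-up rounding throughout.
#'
#' @param label a [label_declaration()].
#' @return The rounded [label_declaration()].
#' @export
round_label_eu <- function(label) {
  rg <- function(x) {
    if (is.na(x)) return(x)
    if (x >= 10) round_half_up(x, 0) else round_half_up(x, 1)
  }
  label_declaration(
    energy_kJ = round_half_up(label$energy_kJ),
    energy_kcal = round_half_up(label$energy_kcal),
    fat = rg(label$fat), saturates = min(rg(label$saturates), rg(label$fat)),
    carbohydrate = rg(label$carbohydrate),
    sugars = min(rg(label$sugars), rg(label$carbohydrate)),
    fiber = rg(label$fiber), protein = rg(label$protein),
    salt = if (label$salt >= 1) round_half_up(label$salt, 1) else
      round_half_up(label$salt, 2))
}

#' Generate a labelled product with known ground truth
#'
#' Draws a ground-truth formulation (descending weights over 3-6 reference
#' ingredients, flour-led), evaluates it into the true as-sold composition
#' (with a baking water loss scaled to the formulation's water content), and
#' derives the label panel the solver will see — exactly, or EU-rounded when
#' `cfg$label_rounding` is on. The recipe's ingredient order is the true
#' weight order, so the generated label is always feasible for
#' [estimate_weights()] (the truth is a witness).
#'
#' @param cfg a [generator_config()].
#' @param ref_db reference table from [gen_reference_db()] (regenerated from
#'   `cfg` when `NULL`).
#' @param id product identifier.
#' @return List: `recipe` ([recipe_spec()]), `label` ([label_declaration()]),
#'   `true_weights` (named, g/100 g formulation), `true_vector` (as-sold).
#' @export
gen_labeled_product <- function(cfg = generator_config(), ref_db = NULL,
                                id = "synthetic_product") {
  if (is.null(ref_db)) ref_db <- gen_reference_db(cfg)
  set.seed(cfg$seed + 1L)
  n <- sample(seq(cfg$n_ingredients_range[1], cfg$n_ingredients_range[2]), 1)
  flours <- ref_db$ingredient[ref_db$group %in%
                                c("flour", "wholegrain_flour", "legume_flour")]
  majors <- ref_db$ingredient[!ref_db$group %in%
                                c("water", "salt", "flour", "wholegrain_flour",
                                  "legume_flour")]
  # salt is a minor, last-ranked ingredient (0.5-2% of the formulation) in
  # most products, never a bulk one
  with_salt <- stats::runif(1) < 0.8 && n >= 3
  n_major <- if (with_salt) n - 1 else n
  keys <- c(sample(flours, 1), sample(majors, n_major - 1))
  w <- sort(stats::rgamma(n_major, shape = 2) + 0.5, decreasing = TRUE)
  w <- w / sum(w)
  if (with_salt) {
    ws <- stats::runif(1, 0.5, 2)
    # keep the rank ordering feasible: salt below the smallest major weight
    ws <- min(ws, 0.95 * 100 * min(w) / (1 + min(w)))
    w <- c(w * (100 - ws), ws)
    keys <- c(keys, sample(ref_db$ingredient[ref_db$group == "salt"], 1))
  } else {
    w <- w * 100
  }
  names(w) <- keys
  # baking loses 40% of the formulation's water
  mix_water <- sum(ref_db$water[match(keys, ref_db$ingredient)] * w / 100)
  yield <- 1 - 0.4 * mix_water / 100
  steps <- data.frame(name = "baking", yield = yield, retention_key = "baking",
                      stringsAsFactors = FALSE)
  true_vec <- evaluate_recipe(w, ref_db, keys, steps)
  label <- label_from_vector(true_vec)
  if (cfg$label_rounding) label <- round_label_eu(label)
  recipe <- recipe_spec(id, ingredients = data.frame(key = keys, rank = seq_len(n),
                                                     stringsAsFactors = FALSE),
                        steps = steps)
  list(recipe = recipe, label = label, true_weights = w, true_vector = true_vec)
}

menu_food_templates <- function() {
  list(
    bread_refined    = list(cereal = TRUE, wholegrain = FALSE, group = "flour"),
    bread_wholegrain = list(cereal = TRUE, wholegrain = TRUE, group = "wholegrain_flour"),
    pasta_refined    = list(cereal = TRUE, wholegrain = FALSE, group = "flour"),
    pasta_wholegrain = list(cereal = TRUE, wholegrain = TRUE, group = "wholegrain_flour"),
    biscuits         = list(cereal = TRUE, wholegrain = FALSE, group = "flour"),
    milk             = list(cereal = FALSE, group = "milk"),
    fruit            = list(cereal = FALSE, group = "fruit"),
    vegetables       = list(cereal = FALSE, group = "vegetables"),
    legumes          = list(cereal = FALSE, group = "legumes"),
    meat             = list(cereal = FALSE, group = "meat"),
    fish             = list(cereal = FALSE, group = "fish"),
    olive_oil        = list(cereal = FALSE, group = "oil"),
    cheese           = list(cereal = FALSE, group = "cheese")
  )
}

# plausible per-100 g composition for a menu food, all 30+ components filled
gen_menu_food <- function(name, tpl) {
  base <- switch(tpl$group,
    flour = c(prot = 8, lip = 4, sol = 3, sta = 45, fib = 3, ash = 1.5, mic = 1),
    wholegrain_flour = c(prot = 9, lip = 5, sol = 3, sta = 40, fib = 7, ash = 2, mic = 2),
    milk = c(prot = 3.3, lip = 1.6, sol = 5, sta = 0, fib = 0, ash = 0.7, mic = 1),
    fruit = c(prot = 0.7, lip = 0.3, sol = 10, sta = 0.5, fib = 2.5, ash = 0.5, mic = 1.5),
    vegetables = c(prot = 1.8, lip = 0.3, sol = 3, sta = 1, fib = 3, ash = 0.9, mic = 2),
    legumes = c(prot = 8, lip = 0.7, sol = 1.5, sta = 14, fib = 7, ash = 1.2, mic = 2.5),
    meat = c(prot = 22, lip = 8, sol = 0, sta = 0, fib = 0, ash = 1.1, mic = 1.5),
    fish = c(prot = 20, lip = 6, sol = 0, sta = 0, fib = 0, ash = 1.2, mic = 1.5),
    oil = c(prot = 0, lip = 99.9, sol = 0, sta = 0, fib = 0, ash = 0, mic = 0.05),
    cheese = c(prot = 25, lip = 27, sol = 1, sta = 0, fib = 0, ash = 4, mic = 2))
  j <- function(x) x * stats::runif(1, 0.9, 1.1)
  protein <- j(base[["prot"]]); lipid <- j(base[["lip"]])
  soluble <- j(base[["sol"]]); starch <- j(base[["sta"]])
  fiber <- j(base[["fib"]]); ash <- j(base[["ash"]])
  available <- starch + soluble
  water <- max(100 - (protein + lipid + available + fiber + ash), 0)
  fr <- c(0.3, 0.45, 0.2) * stats::runif(3, 0.9, 1.1)
  fr <- fr / sum(fr) * 0.93
  animal <- tpl$group %in% c("milk", "meat", "fish", "cheese")
  micro <- base_micros() * base[["mic"]] * runif_log(length(base_micros()), 0.7, 1.4)
  if (tpl$cereal) micro["sodium"] <- 450 * stats::runif(1, 0.9, 1.1)
  if (tpl$group == "fruit") micro["vitamin_C"] <- 40 * stats::runif(1, 0.8, 1.2)
  v <- nutrient_vector(
    water = water, available_carbohydrate = available,
    soluble_carbohydrate = soluble, starch = starch, fiber = fiber,
    protein_total = protein,
    protein_animal = if (animal) protein else 0,
    protein_vegetable = if (animal) 0 else protein,
    lipid_total = lipid,
    lipid_animal = if (animal) lipid else 0,
    lipid_vegetable = if (animal) 0 else lipid,
    sfa = lipid * fr[1], mufa = lipid * fr[2], pufa = lipid * fr[3],
    oleic = lipid * fr[2] * 0.9, linoleic = lipid * fr[3] * 0.8,
    linolenic = lipid * fr[3] * 0.1, ash = ash,
    .data = as.list(micro))
  e <- compute_energy(available, protein, lipid, fiber, "as_such")
  v["energy_kcal"] <- e$energy_kcal
  v["energy_kJ"] <- e$energy_kJ
  cbind(data.frame(item = name, stringsAsFactors = FALSE),
        as.data.frame(as.list(v)))
}

apply_gf_effects <- function(row, effects, wholegrain) {
  if (is.null(effects)) return(row)
  for (nm in names(effects)) {
    if (nm == "zinc" && !wholegrain) next
    row[[nm]] <- row[[nm]] * effects[[nm]]
  }
  row
}

#' Generate a 7-day guideline menu with paired GC/GF composition tables
#'
#' Builds a synthetic stand-in for the weekly reference menu of a 2000 kcal
#' diet: cereal servings every day (bread at every day, pasta or biscuits on
#' scheduled days), plus dairy, fruit, vegetables, legumes, meat/fish and
#' olive oil at guideline-like frequencies, with mild day-to-day amount
#' variation. The scenario selects the cereal products: refined (RC),
#' wholegrain (WC), or mixed (MC, wholegrain assigned to the first
#' `wholegrain_share` fraction of cereal servings by day order). The GF
#' composition table duplicates the GC table except for the cereal items,
#' which carry the injected multiplicative effects of `cfg$effects` under
#' `*_gf` keys.
#'
#' @param cfg a [generator_config()].
#' @param scenario `"RC"`, `"MC"` or `"WC"`.
#' @return List: `menu` (day/food/amount data frame, simple foods),
#'   `sub_map` (named character vector over the cereal foods used),
#'   `fcdb_gc`, `fcdb_gf` (composition tables), `effects` (data frame
#'   `nutrient`/`direction` of injected ground truth for this scenario).
#' @export
gen_menu <- function(cfg = generator_config(), scenario = c("MC", "RC", "WC")) {
  scenario <- match.arg(scenario)
  set.seed(cfg$seed + 2L)
  tpls <- menu_food_templates()
  fcdb_gc <- do.call(rbind, lapply(names(tpls), function(nm)
    gen_menu_food(nm, tpls[[nm]])))
  cereal <- names(tpls)[vapply(tpls, `[[`, logical(1), "cereal")]
  gf_rows <- lapply(cereal, function(nm) {
    row <- fcdb_gc[fcdb_gc$item == nm, , drop = FALSE]
    row$item <- paste0(nm, "_gf")
    apply_gf_effects(row, cfg$effects, wholegrain = isTRUE(tpls[[nm]]$wholegrain))
  })
  fcdb_gf <- rbind(fcdb_gc, do.call(rbind, gf_rows))

  pick_cereal <- function(kind, slot) {
    # slot indexes cereal servings across the week for the MC assignment
    if (kind == "biscuits") return("biscuits")
    wg <- switch(scenario, RC = FALSE, WC = TRUE,
                 MC = slot <= round(cfg$wholegrain_share * 14))
    paste0(kind, if (wg) "_wholegrain" else "_refined")
  }
  rows <- list(); slot <- 0
  for (day in seq_len(cfg$days)) {
    add <- function(food, amount) {
      rows[[length(rows) + 1L]] <<- data.frame(day = day, food = food,
                                               amount = amount,
                                               stringsAsFactors = FALSE)
    }
    slot <- slot + 1
    add(pick_cereal("bread", slot), 120 * stats::runif(1, 0.85, 1.15))
    slot <- slot + 1
    add(pick_cereal("pasta", slot), 80 * stats::runif(1, 0.85, 1.15))
    if (day %% 2 == 1) add("biscuits", 30 * stats::runif(1, 0.8, 1.2))
    add("milk", 125 * stats::runif(1, 0.9, 1.1))
    add("fruit", 300 * stats::runif(1, 0.85, 1.15))
    add("vegetables", 250 * stats::runif(1, 0.85, 1.15))
    if (day %% 3 == 0) add("legumes", 120 * stats::runif(1, 0.9, 1.1))
    add(if (day %% 2 == 0) "fish" else "meat", 100 * stats::runif(1, 0.9, 1.1))
    if (day %% 3 == 1) add("cheese", 50 * stats::runif(1, 0.9, 1.1))
    add("olive_oil", 30 * stats::runif(1, 0.9, 1.1))
  }
  menu <- do.call(rbind, rows)
  used_cereal <- intersect(unique(menu$food), cereal)
  sub_map <- stats::setNames(paste0(used_cereal, "_gf"), used_cereal)
  eff <- cfg$effects
  wholegrain_used <- any(grepl("wholegrain", used_cereal))
  effects <- if (is.null(eff)) {
    data.frame(nutrient = character(), direction = numeric())
  } else {
    keep <- vapply(names(eff), function(nm) nm != "zinc" || wholegrain_used,
                   logical(1))
    data.frame(nutrient = names(eff)[keep],
               direction = sign(unlist(eff)[keep] - 1),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(menu = menu, sub_map = sub_map, fcdb_gc = fcdb_gc, fcdb_gf = fcdb_gf,
       effects = effects)
}
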