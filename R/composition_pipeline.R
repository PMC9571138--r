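#' Retention table
#'
#' Maps (process key, component code) to the fraction of a micronutrient
#' surviving that processing step. Missing entries default to 1 (no loss) and
#' are logged. Factors outside [0, 1] are a configuration error.
#'
#' @param table data frame with columns `process`, `component`, `factor`; or
#'   `NULL` for an all-ones table.
#' @return An object of class `retention_table`.
#' @export
#' @examples
#' retention_table(data.frame(process = "baking", component = "vitamin_C",
#'                            factor = 0.7))
retention_table <- function(table = NULL) {
  if (is.null(table)) {
    table <- data.frame(process = character(), component = character(),
                        factor = numeric(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("process", "component", "factor") %in% names(table)))
  if (any(table$factor < 0 | table$factor > 1)) {
    stop("retention factors must lie in [0, 1]")
  }
  bad <- setdiff(table$component, component_codes())
  if (length(bad)) stop("unknown component(s) in retention table: ",
                        paste(bad, collapse = ", "))
  structure(table, class = c("retention_table", "data.frame"))
}

#' Apply micronutrient retention factors
#'
#' Each micronutrient (mineral or vitamin component) is multiplied by the
#' product of the retention factors of the recipe's process steps. Proximates
#' are untouched: process water loss is handled by the yield factor in
#' [evaluate_recipe()].
#'
#' @param v nutrient vector.
#' @param steps process-step data frame with a `retention_key` column (steps
#'   with `NA` key are skipped).
#' @param table a [retention_table()].
#' @return The adjusted nutrient vector. Unresolved (process, component)
#'   pairs use factor 1 and are collected in attribute `"defaulted"`.
#' @export
apply_retention <- function(v, steps, table = retention_table()) {
  stopifnot(inherits(table, "retention_table"))
  if (is.null(steps) || nrow(steps) == 0) return(v)
  keys <- steps$retention_key[!is.na(steps$retention_key)]
  defaulted <- character()
  for (k in keys) {
    for (comp in micronutrient_codes()) {
      hit <- table$process == k & table$component == comp
      if (any(hit)) {
        v[comp] <- v[comp] * table$factor[which(hit)[1]]
      } else {
        defaulted <- c(defaulted, paste0(k, ":", comp))
      }
    }
  }
  attr(v, "defaulted") <- defaulted
  v
}

#' Rescale nutrient sub-profiles onto label totals
#'
#' The recipe calculation fixes the internal proportions of each sub-profile
#' (animal/vegetable protein and lipid origin, fatty acids, sugars) while the
#' declared label totals are authoritative. Each profile is therefore scaled
#' by label total / recipe total and the totals replaced by the label values;
#' within-profile proportions are preserved exactly. A profile whose recipe
#' total is zero while the label total is positive cannot be resolved: its
#' components are set missing and recorded in attribute `"unresolved"`.
#'
#' @param v recipe-derived nutrient vector.
#' @param label a [label_declaration()].
#' @return The rescaled vector.
#' @export
rescale_profiles <- function(v, label) {
  unresolved <- character()
  scale_profile <- function(v, total_code, label_total, members) {
    if (is.na(label_total)) return(v)
    recipe_total <- v[[total_code]]
    if (is.na(recipe_total)) return(v)
    if (recipe_total == 0) {
      if (label_total > 0) {
        v[members] <- NA_real_
        unresolved <<- c(unresolved, total_code)
        v[total_code] <- label_total
      }
      return(v)
    }
    s <- label_total / recipe_total
    v[members] <- v[members] * s
    v[total_code] <- label_total
    v
  }
  v <- scale_profile(v, "protein_total", label$protein,
                     c("protein_animal", "protein_vegetable"))
  v <- scale_profile(v, "lipid_total", label$fat,
                     c("lipid_animal", "lipid_vegetable", "sfa", "mufa", "pufa",
                       "oleic", "linoleic", "linolenic"))
  v <- scale_profile(v, "soluble_carbohydrate", label$sugars, character())
  attr(v, "unresolved") <- unresolved
  v
}

#' Assemble one branded product
#'
#' Bundle of a branded product's label, solved recipe and harmonized
#' composition: weight estimation ([estimate_weights()]), micronutrient
#' retention ([apply_retention()]) and sub-profile rescaling
#' ([rescale_profiles()]), in that order, so the label totals stay
#' authoritative.
#'
#' @param recipe a [recipe_spec()].
#' @param ref_db reference ingredient table.
#' @param label a [label_declaration()].
#' @param retention a [retention_table()].
#' @param brand brand name.
#' @param options solver options.
#' @return Object of class `branded_product`: list with `id`, `brand`,
#'   `label`, `solution`, `vector` (harmonized composition) and `checks`
#'   (its [validate_item()] report).
#' @export
build_branded_product <- function(recipe, ref_db, label,
                                  retention = retention_table(),
                                  brand = "unbranded",
                                  options = solver_options()) {
  sol <- estimate_weights(recipe, ref_db, label, options)
  v <- apply_retention(sol$vector, recipe$steps, retention)
  v <- rescale_profiles(v, label)
  checks <- validate_item(v, item = recipe$id)
  structure(list(id = recipe$id, brand = brand, label = label,
                 solution = sol, vector = v, checks = checks),
            class = "branded_product")
}

#' The ten food categories of the database
#' @return Character vector of category names.
#' @export
food_categories <- function() {
  c("biscuits", "breakfast products", "cakes and desserts", "sweet snacks",
    "breads", "pizzas", "savory snacks", "flours", "pasta dishes",
    "ready-to-eat dishes")
}

#' Aggregate branded products into a food item
#'
#' The final composition of a food item combines the mean of the brand labels
#' with the mean of the brand recipe calculations: for components present on
#' the mandatory declaration the item value is the unweighted mean of (label
#' mean, recipe mean); label-absent components (micronutrients and
#' sub-profiles) take the recipe mean over the non-missing brands (with a
#' coverage note when fewer than half contribute). Starch is then
#' recalculated by difference and energy recomputed from the combined
#' macronutrients.
#'
#' @param products list of `branded_product` objects (>= 1).
#' @param name item name.
#' @param category one of [food_categories()].
#' @param moisture `"by_difference"` or `"analytical"`.
#' @param convention carbohydrate convention for the energy recomputation.
#' @return Object of class `food_item`: list with `item`, `category`,
#'   `n_brands`, `moisture`, `vector`, `checks`, `coverage_notes`.
#' @export
aggregate_item <- function(products, name, category,
                           moisture = c("by_difference", "analytical"),
                           convention = "as_such") {
  moisture <- match.arg(moisture)
  if (!length(products)) stop("at least one branded product is required")
  stopifnot(all(vapply(products, inherits, logical(1), "branded_product")))
  if (!category %in% food_categories()) {
    stop("unknown category: ", category)
  }
  map <- label_component_map()
  labels <- do.call(rbind, lapply(products, function(p) {
    l <- unlist(p$label[names(map)])
    l["salt"] <- sodium_from_salt(l[["salt"]])   # compare in sodium mg
    l
  }))
  recipes <- do.call(rbind, lapply(products, function(p) p$vector))

  v <- nutrient_vector()
  notes <- character()
  nb <- length(products)
  for (comp in component_codes()) {
    rvals <- recipes[, comp]
    rmean <- if (all(is.na(rvals))) NA_real_ else mean(rvals, na.rm = TRUE)
    if (sum(!is.na(rvals)) > 0 && sum(!is.na(rvals)) < nb / 2) {
      notes <- c(notes, sprintf("%s: %d/%d brands contribute", comp,
                                sum(!is.na(rvals)), nb))
    }
    if (comp %in% map) {
      lab <- names(map)[map == comp]
      lmean <- mean(labels[, lab], na.rm = TRUE)
      if (is.nan(lmean)) lmean <- NA_real_
      v[comp] <- if (is.na(lmean)) rmean else
        if (is.na(rmean)) lmean else (lmean + rmean) / 2
    } else {
      v[comp] <- rmean
    }
  }
  if (!is.na(v[["available_carbohydrate"]]) && !is.na(v[["soluble_carbohydrate"]])) {
    v["starch"] <- starch_by_difference(v[["available_carbohydrate"]],
                                        v[["soluble_carbohydrate"]])
  }
  e <- compute_energy(v[["available_carbohydrate"]], v[["protein_total"]],
                      v[["lipid_total"]], v[["fiber"]], convention)
  v["energy_kcal"] <- e$energy_kcal
  v["energy_kJ"] <- e$energy_kJ
  checks <- validate_item(v, item = name)
  structure(list(item = name, category = category, n_brands = nb,
                 moisture = moisture, vector = v, checks = checks,
                 coverage_notes = notes),
            class = "food_item")
}

#' Assemble the database table and category census
#'
#' @param items list of `food_item` objects with unique names.
#' @return List with `table` (one row per item: `item`, `category`,
#'   `moisture`, `n_brands`, then all component columns) and `census` (see
#'   [fcdb_census()]).
#' @export
build_database <- function(items) {
  if (!length(items)) {
    tab <- data.frame(item = character(), category = character(),
                      moisture = character(), n_brands = integer())
    for (comp in component_codes()) tab[[comp]] <- numeric()
    return(list(table = tab, census = fcdb_census(tab)))
  }
  stopifnot(all(vapply(items, inherits, logical(1), "food_item")))
  nms <- vapply(items, `[[`, character(1), "item")
  if (anyDuplicated(nms)) {
    stop("duplicate item name(s): ", paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  tab <- do.call(rbind, lapply(items, function(it) {
    row <- data.frame(item = it$item, category = it$category,
                      moisture = it$moisture, n_brands = it$n_brands,
                      stringsAsFactors = FALSE)
    cbind(row, as.data.frame(as.list(it$vector)))
  }))
  list(table = tab, census = fcdb_census(tab))
}

#' Category census of an item table
#'
#' @param tab item table with `category` and optionally `moisture` columns.
#' @return List with `n_items`, `by_category` (named integer vector over the
#'   fixed ten categories, in order) and `n_analytical_moisture`.
#' @export
fcdb_census <- function(tab) {
  counts <- table(factor(tab$category, levels = food_categories()))
  list(n_items = nrow(tab),
       by_category = stats::setNames(as.integer(counts), food_categories()),
       n_analytical_moisture = if ("moisture" %in% names(tab))
         sum(tab$moisture == "analytical") else NA_integer_)
}
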