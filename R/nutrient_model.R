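#' Nutrient component dictionary
#'
#' The versioned dictionary of food components handled by the package: one row
#' per component with its code, display name, unit and class. All readers and
#' writers of tabular composition data share this dictionary; a composition
#' table column is valid if and only if its name is a component code (or one of
#' the bookkeeping columns `item`, `category`, `moisture`, `n_brands`,
#' `cho_convention`).
#'
#' Component classes:
#' \describe{
#'   \item{energy}{energy in kJ and kcal per 100 g}
#'   \item{proximate}{water, protein, lipid, fiber, ash (g/100 g)}
#'   \item{carbohydrate}{available and soluble carbohydrate and starch
#'     (g/100 g); their basis is governed by the carbohydrate-expression
#'     convention, see [compute_energy()]}
#'   \item{fatty_acid}{fatty-acid classes and named fatty acids (g/100 g)}
#'   \item{mineral}{minerals (mg/100 g)}
#'   \item{vitamin}{vitamins (units as listed)}
#' }
#'
#' Minerals and vitamins together form the "micronutrients", the components
#' subject to retention-factor adjustment ([apply_retention()]).
#'
#' @return A data frame with columns `code`, `name`, `unit`, `class`,
#'   `on_label` (logical: appears on the mandatory EU nutrition declaration),
#'   and the dictionary `version` as an attribute.
#' @export
#' @examples
#' head(nutrient_components())
nutrient_components <- function() {
  d <- rbind(
    data.frame(code = "energy_kJ",   name = "Energy",                 unit = "kJ/100 g",  class = "energy",       on_label = TRUE),
    data.frame(code = "energy_kcal", name = "Energy",                 unit = "kcal/100 g", class = "energy",      on_label = TRUE),
    data.frame(code = "water",       name = "Water",                  unit = "g/100 g",   class = "proximate",    on_label = FALSE),
    data.frame(code = "protein_total",     name = "Protein",          unit = "g/100 g",   class = "proximate",    on_label = TRUE),
    data.frame(code = "protein_animal",    name = "Animal protein",   unit = "g/100 g",   class = "proximate",    on_label = FALSE),
    data.frame(code = "protein_vegetable", name = "Vegetable protein", unit = "g/100 g",  class = "proximate",    on_label = FALSE),
    data.frame(code = "lipid_total",       name = "Lipids",           unit = "g/100 g",   class = "proximate",    on_label = TRUE),
    data.frame(code = "lipid_animal",      name = "Animal lipids",    unit = "g/100 g",   class = "proximate",    on_label = FALSE),
    data.frame(code = "lipid_vegetable",   name = "Vegetable lipids", unit = "g/100 g",   class = "proximate",    on_label = FALSE),
    data.frame(code = "available_carbohydrate", name = "Available carbohydrates", unit = "g/100 g", class = "carbohydrate", on_label = TRUE),
    data.frame(code = "soluble_carbohydrate",   name = "Soluble carbohydrates",   unit = "g/100 g", class = "carbohydrate", on_label = TRUE),
    data.frame(code = "starch",      name = "Starch",                 unit = "g/100 g",   class = "carbohydrate", on_label = FALSE),
    data.frame(code = "fiber",       name = "Fiber",                  unit = "g/100 g",   class = "proximate",    on_label = TRUE),
    data.frame(code = "ash",         name = "Ash",                    unit = "g/100 g",   class = "proximate",    on_label = FALSE),
    data.frame(code = "sfa",         name = "Saturated fatty acids",  unit = "g/100 g",   class = "fatty_acid",   on_label = TRUE),
    data.frame(code = "mufa",        name = "Monounsaturated fatty acids", unit = "g/100 g", class = "fatty_acid", on_label = FALSE),
    data.frame(code = "pufa",        name = "Polyunsaturated fatty acids", unit = "g/100 g", class = "fatty_acid", on_label = FALSE),
    data.frame(code = "oleic",       name = "Oleic acid",             unit = "g/100 g",   class = "fatty_acid",   on_label = FALSE),
    data.frame(code = "linoleic",    name = "Linoleic acid",          unit = "g/100 g",   class = "fatty_acid",   on_label = FALSE),
    data.frame(code = "linolenic",   name = "Linolenic acid",         unit = "g/100 g",   class = "fatty_acid",   on_label = FALSE),
    data.frame(code = "sodium",      name = "Sodium",                 unit = "mg/100 g",  class = "mineral",      on_label = TRUE),
    data.frame(code = "potassium",   name = "Potassium",              unit = "mg/100 g",  class = "mineral",      on_label = FALSE),
    data.frame(code = "calcium",     name = "Calcium",                unit = "mg/100 g",  class = "mineral",      on_label = FALSE),
    data.frame(code = "phosphorus",  name = "Phosphorus",             unit = "mg/100 g",  class = "mineral",      on_label = FALSE),
    data.frame(code = "iron",        name = "Iron",                   unit = "mg/100 g",  class = "mineral",      on_label = FALSE),
    data.frame(code = "zinc",        name = "Zinc",                   unit = "mg/100 g",  class = "mineral",      on_label = FALSE),
    data.frame(code = "vitamin_D",   name = "Vitamin D",              unit = "ug/100 g",  class = "vitamin",      on_label = FALSE),
    data.frame(code = "vitamin_E",   name = "Vitamin E",              unit = "mg/100 g",  class = "vitamin",      on_label = FALSE),
    data.frame(code = "retinol_eq",  name = "Retinol equivalents",    unit = "ug/100 g",  class = "vitamin",      on_label = FALSE),
    data.frame(code = "thiamin",     name = "Vitamin B1",             unit = "mg/100 g",  class = "vitamin",      on_label = FALSE),
    data.frame(code = "riboflavin",  name = "Vitamin B2",             unit = "mg/100 g",  class = "vitamin",      on_label = FALSE),
    data.frame(code = "niacin",      name = "Niacin",                 unit = "mg/100 g",  class = "vitamin",      on_label = FALSE),
    data.frame(code = "vitamin_B6",  name = "Vitamin B6",             unit = "mg/100 g",  class = "vitamin",      on_label = FALSE),
    data.frame(code = "folate",      name = "Folates",                unit = "ug/100 g",  class = "vitamin",      on_label = FALSE),
    data.frame(code = "vitamin_C",   name = "Vitamin C",              unit = "mg/100 g",  class = "vitamin",      on_label = FALSE)
  )
  attr(d, "version") <- "gffcdb-components-1"
  d
}

#' @rdname nutrient_components
#' @param path file to write the dictionary to (CSV, dot decimal, UTF-8).
#' @export
write_component_dictionary <- function(path) {
  d <- nutrient_components()
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", attr(d, "version")), con)
  utils::write.csv(d, con, row.names = FALSE)
  invisible(path)
}

component_codes <- function() nutrient_components()$code

micronutrient_codes <- function() {
  d <- nutrient_components()
  d$code[d$class %in% c("mineral", "vitamin")]
}

#' Construct a nutrient vector
#'
#' A nutrient vector is a named numeric vector holding per-100 g amounts for
#' every component in [nutrient_components()]. Components not supplied are set
#' to `NA`, which means *missing* — a distinct state from a true zero. All
#' supplied amounts must be non-negative.
#'
#' @param ... named component amounts, e.g. `protein_total = 3.8`.
#' @param .data optionally, a named numeric vector or single-row data frame to
#'   take amounts from (names must be component codes).
#' @return Named numeric vector over all component codes.
#' @export
#' @examples
#' nutrient_vector(available_carbohydrate = 67.7, protein_total = 3.8)
nutrient_vector <- function(..., .data = NULL) {
  v <- stats::setNames(rep(NA_real_, length(component_codes())), component_codes())
  supplied <- c(list(...), as.list(.data))
  if (length(supplied)) {
    supplied <- vapply(supplied, function(x) as.numeric(x)[1], numeric(1))
    bad <- setdiff(names(supplied), names(v))
    if (length(bad)) {
      stop("unknown nutrient component(s): ", paste(bad, collapse = ", "))
    }
    neg <- names(supplied)[!is.na(supplied) & supplied < 0]
    if (length(neg)) {
      stop("negative amount for component(s): ", paste(neg, collapse = ", "))
    }
    v[names(supplied)] <- supplied
  }
  v
}

#' Round half away from zero
#'
#' Presentation rounding used throughout the database: ties go up (440.5 ->
#' 441), unlike [base::round()]'s round-half-even. Energies are presented as
#' integers and gram quantities to one decimal.
#'
#' @param x numeric vector.
#' @param digits decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Energy conversion factor sets
#'
#' Macronutrient-specific energy conversion factors, including fiber. Protein,
#' lipid and fiber factors are fixed (4/17, 9/37 and 2/8 kcal/kJ per g). The
#' available-carbohydrate factor depends on the carbohydrate-expression
#' convention: carbohydrate expressed as monosaccharide equivalents (hydrated
#' basis) carries 3.75 kcal/g and 16 kJ/g; carbohydrate expressed by weight
#' ("as such") carries 4 kcal/g and 17 kJ/g.
#'
#' @param convention `"monosaccharide_equivalent"` or `"as_such"`.
#' @return List with numeric vectors `kcal` and `kJ`, each named
#'   `cho`, `protein`, `lipid`, `fiber`.
#' @export
energy_factors <- function(convention = c("monosaccharide_equivalent", "as_such")) {
  convention <- match.arg(convention)
  if (convention == "monosaccharide_equivalent") {
    list(kcal = c(cho = 3.75, protein = 4, lipid = 9, fiber = 2),
         kJ   = c(cho = 16,   protein = 17, lipid = 37, fiber = 8))
  } else {
    list(kcal = c(cho = 4, protein = 4, lipid = 9, fiber = 2),
         kJ   = c(cho = 17, protein = 17, lipid = 37, fiber = 8))
  }
}

#' Compute energy from macronutrients
#'
#' Energy per 100 g from available carbohydrate, protein, lipid and fiber
#' using the factor sets of [energy_factors()]. Values are returned unrounded;
#' apply [round_half_up()] for presentation (integers for both kJ and kcal).
#'
#' @param available_carbohydrate g/100 g, in the basis named by `convention`.
#' @param protein,lipid,fiber g/100 g.
#' @param convention carbohydrate-expression convention, see [energy_factors()].
#' @return Data frame with columns `energy_kcal` and `energy_kJ` (unrounded).
#'   Inputs are vectorized.
#' @export
#' @examples
#' # a shortbread-style biscuit: 440 kcal/100 g after presentation rounding
#' e <- compute_energy(67.7, 3.8, 18.7, 1.4, "monosaccharide_equivalent")
#' round_half_up(e$energy_kcal)
compute_energy <- function(available_carbohydrate, protein, lipid, fiber,
                           convention = c("monosaccharide_equivalent", "as_such")) {
  convention <- match.arg(convention)
  args <- list(available_carbohydrate = available_carbohydrate,
               protein = protein, lipid = lipid, fiber = fiber)
  for (nm in names(args)) {
    if (anyNA(args[[nm]])) {
      stop("missing required component for energy computation: ", nm)
    }
  }
  f <- energy_factors(convention)
  kcal <- f$kcal["cho"] * available_carbohydrate + f$kcal["protein"] * protein +
    f$kcal["lipid"] * lipid + f$kcal["fiber"] * fiber
  kJ <- f$kJ["cho"] * available_carbohydrate + f$kJ["protein"] * protein +
    f$kJ["lipid"] * lipid + f$kJ["fiber"] * fiber
  data.frame(energy_kcal = unname(kcal), energy_kJ = unname(kJ))
}

#' Salt from sodium
#'
#' Labelling conversion salt (g) = sodium (mg) x 2.5 / 1000, on whatever basis
#' the sodium figure carries (per 100 g or per day). Reported to one decimal by
#' default; pass `digits = NA` for the exact value.
#'
#' @param sodium_mg sodium in mg; must be non-negative.
#' @param digits decimal places for presentation rounding, or `NA` for none.
#' @return Salt in g.
#' @export
#' @examples
#' salt_from_sodium(2947) # 7.4
salt_from_sodium <- function(sodium_mg, digits = 1) {
  if (anyNA(sodium_mg)) stop("sodium is missing")
  if (any(sodium_mg < 0)) stop("sodium must be non-negative")
  salt <- sodium_mg * 2.5 / 1000
  if (!is.na(digits)) salt <- round_half_up(salt, digits)
  salt
}

#' @rdname salt_from_sodium
#' @param salt_g salt in g.
#' @return `sodium_from_salt()`: sodium in mg (exact).
#' @export
sodium_from_salt <- function(salt_g) {
  if (anyNA(salt_g)) stop("salt is missing")
  if (any(salt_g < 0)) stop("salt must be non-negative")
  salt_g * 1000 / 2.5
}

#' Starch by difference
#'
#' Starch is recalculated as available minus soluble carbohydrate, in the same
#' carbohydrate-expression basis as its inputs.
#'
#' @param available,soluble g/100 g, same convention.
#' @return Starch in g/100 g.
#' @export
starch_by_difference <- function(available, soluble) {
  if (anyNA(available) || anyNA(soluble)) {
    stop("available and soluble carbohydrate must both be present")
  }
  if (any(soluble > available + 1e-9)) {
    i <- which(soluble > available + 1e-9)[1]
    stop(sprintf(
      "soluble carbohydrate (%.6g) exceeds available carbohydrate (%.6g)",
      soluble[i], available[i]))
  }
  available - soluble
}

#' Convert available carbohydrate between expression bases
#'
#' Monosaccharide-equivalent carbohydrate is the hydrated weight of the
#' constituent monosaccharides: 100 g of starch corresponds to 110 g of
#' glucose, and 100 g of disaccharide-dominated sugars to about 105 g. The
#' conversion is applied component-wise: starch (available - soluble) uses the
#' 1.10 hydration factor, soluble carbohydrate 1.05. This is an approximation
#' (the sugar factor assumes disaccharides dominate).
#'
#' @param available,soluble g/100 g in the `from` basis.
#' @param from basis the inputs are expressed in.
#' @param starch_factor,sugar_factor hydration factors.
#' @return List with `available` and `soluble` in the other basis.
#' @export
convert_cho_basis <- function(available, soluble,
                              from = c("monosaccharide_equivalent", "as_such"),
                              starch_factor = 1.10, sugar_factor = 1.05) {
  from <- match.arg(from)
  starch <- starch_by_difference(available, soluble)
  if (from == "monosaccharide_equivalent") {
    list(available = starch / starch_factor + soluble / sugar_factor,
         soluble = soluble / sugar_factor)
  } else {
    list(available = starch * starch_factor + soluble * sugar_factor,
         soluble = soluble * sugar_factor)
  }
}

#' Water by difference
#'
#' Water = 100 - (protein + lipid + available carbohydrate as such + fiber +
#' ash). When the component sum exceeds 100 g by at most 1 g the result is
#' clamped at 0 with a warning; a larger excess raises a consistency error.
#'
#' @param v nutrient vector ([nutrient_vector()]); `protein_total`,
#'   `lipid_total`, `available_carbohydrate`, `soluble_carbohydrate` and
#'   `fiber` must be present.
#' @param ash g/100 g (the printed composition tables omit ash, so it must be
#'   supplied explicitly; use 0 only deliberately).
#' @param convention basis of the carbohydrate figures in `v`; converted to
#'   "as such" before differencing.
#' @return Water in g/100 g.
#' @export
water_by_difference <- function(v, ash,
                                convention = c("as_such", "monosaccharide_equivalent")) {
  convention <- match.arg(convention)
  need <- c("protein_total", "lipid_total", "available_carbohydrate",
            "soluble_carbohydrate", "fiber")
  miss <- need[is.na(v[need])]
  if (length(miss)) stop("missing component(s) for water by difference: ",
                         paste(miss, collapse = ", "))
  if (is.na(ash)) stop("ash must be supplied")
  cho <- v[["available_carbohydrate"]]
  if (convention == "monosaccharide_equivalent") {
    cho <- convert_cho_basis(cho, v[["soluble_carbohydrate"]], from = convention)$available
  }
  s <- v[["protein_total"]] + v[["lipid_total"]] + cho + v[["fiber"]] + ash
  if (s > 101) {
    stop(sprintf("proximate sum %.2f g exceeds 101 g: inconsistent composition", s))
  }
  w <- 100 - s
  if (w < 0) {
    warning(sprintf("proximate sum %.2f g exceeds 100 g; water clamped at 0", s))
    w <- 0
  }
  w
}

#' Detect the carbohydrate convention of a printed item
#'
#' Recomputes energy under both carbohydrate-expression conventions and
#' returns the one whose kcal value is closest to the printed energy.
#'
#' @param v nutrient vector with `energy_kcal` and the four energy
#'   macronutrients present.
#' @return List: `convention`, `residual_kcal`, `residual_kJ` (signed,
#'   recomputed minus printed, at the best convention).
#' @export
detect_cho_convention <- function(v) {
  res <- lapply(c("monosaccharide_equivalent", "as_such"), function(conv) {
    e <- compute_energy(v[["available_carbohydrate"]], v[["protein_total"]],
                        v[["lipid_total"]], v[["fiber"]], conv)
    list(convention = conv,
         residual_kcal = round_half_up(e$energy_kcal) - v[["energy_kcal"]],
         residual_kJ = if (is.na(v[["energy_kJ"]])) NA_real_
                       else round_half_up(e$energy_kJ) - v[["energy_kJ"]])
  })
  best <- if (abs(res[[1]]$residual_kcal) <= abs(res[[2]]$residual_kcal)) 1L else 2L
  res[[best]]
}

check_row <- function(check, severity, message, value) {
  data.frame(check = check, severity = severity, message = message,
             value = value, stringsAsFactors = FALSE)
}

#' Consistency-check battery for a composition record
#'
#' Runs the automated checks used to control the compiled database for errors
#' and omissions: non-negativity, soluble <= available carbohydrate,
#' fatty-acid classes vs total lipids, animal/vegetable origin splits vs
#' totals, sodium/salt coherence, and recomputation of energy under both
#' carbohydrate conventions (the item is flagged when even the
#' better-fitting convention misses the declared energy by more than
#' `tol_kcal` / `tol_kJ`). Comparisons involving missing components are
#' skipped and logged at severity `"info"`. Violations are reported, never
#' raised.
#'
#' @param v nutrient vector.
#' @param item item identifier used in the report.
#' @param tol_kcal,tol_kJ energy recomputation tolerances (kcal, kJ per 100 g).
#' @param slack additive slack (g) for sum checks on split profiles.
#' @param salt optional declared salt g/100 g to check against sodium.
#' @return A check report: data frame with columns `item`, `check`,
#'   `severity` (`"error"`, `"warning"`, `"info"`), `message`, `value`. Zero
#'   `"error"`/`"warning"` rows means the item passed. The detected
#'   carbohydrate convention is attached as attribute `"convention"`.
#' @export
validate_item <- function(v, item = "item", tol_kcal = 2, tol_kJ = 5,
                          slack = 0.05, salt = NA_real_) {
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  skip <- function(check, comps) {
    add(check_row(check, "info",
                  paste0("skipped: missing ", paste(comps, collapse = ", ")), NA_real_))
  }

  neg <- names(v)[!is.na(v) & v < 0]
  if (length(neg)) {
    add(check_row("non_negativity", "error",
                  paste0("negative amount: ", paste(neg, collapse = ", ")),
                  min(v, na.rm = TRUE)))
  }

  if (!is.na(v[["soluble_carbohydrate"]]) && !is.na(v[["available_carbohydrate"]])) {
    if (v[["soluble_carbohydrate"]] > v[["available_carbohydrate"]] + 1e-9) {
      add(check_row("soluble_le_available", "error",
                    "soluble carbohydrate exceeds available carbohydrate",
                    v[["soluble_carbohydrate"]] - v[["available_carbohydrate"]]))
    }
  } else skip("soluble_le_available", "carbohydrate fractions")

  fa <- c("sfa", "mufa", "pufa")
  if (!anyNA(v[fa]) && !is.na(v[["lipid_total"]])) {
    excess <- sum(v[fa]) - v[["lipid_total"]]
    if (excess > slack) {
      add(check_row("fatty_acid_sum", "error",
                    "sfa + mufa + pufa exceeds total lipids", excess))
    }
  } else skip("fatty_acid_sum", "fatty-acid classes or total lipids")

  for (split in list(c(total = "protein_total", a = "protein_animal", b = "protein_vegetable"),
                     c(total = "lipid_total", a = "lipid_animal", b = "lipid_vegetable"))) {
    nm <- paste0(sub("_total", "", split[["total"]]), "_origin_split")
    if (!anyNA(v[split])) {
      dev <- abs(v[[split[["a"]]]] + v[[split[["b"]]]] - v[[split[["total"]]]])
      if (dev > slack) {
        add(check_row(nm, "error", "origin split does not sum to total", dev))
      }
    } else skip(nm, "origin split components")
  }

  emac <- c("available_carbohydrate", "protein_total", "lipid_total", "fiber")
  if (!anyNA(v[emac]) && !is.na(v[["energy_kcal"]])) {
    d <- detect_cho_convention(v)
    attr_conv <- d$convention
    if (abs(d$residual_kcal) > tol_kcal ||
        (!is.na(d$residual_kJ) && abs(d$residual_kJ) > tol_kJ)) {
      add(check_row("energy_recomputation", "warning",
                    sprintf("declared energy not reproduced (best convention %s)",
                            d$convention),
                    d$residual_kcal))
    }
  } else {
    attr_conv <- NA_character_
    skip("energy_recomputation", "energy macronutrients or declared energy")
  }

  if (!is.na(salt) && !is.na(v[["sodium"]])) {
    dev <- abs(salt_from_sodium(v[["sodium"]], digits = NA) - salt)
    if (dev > 0.1) {
      add(check_row("sodium_salt_coherence", "warning",
                    "declared salt inconsistent with sodium x 2.5/1000", dev))
    }
  }

  rep <- if (length(rows)) do.call(rbind, rows) else
    data.frame(check = character(), severity = character(),
               message = character(), value = numeric(), stringsAsFactors = FALSE)
  rep <- cbind(item = rep(item, nrow(rep)), rep)
  attr(rep, "convention") <- attr_conv
  rep
}

#' @rdname validate_item
#' @param report a check report.
#' @return `checks_passed()`: `TRUE` if the report has no error or warning rows.
#' @export
checks_passed <- function(report) {
  !any(report$severity %in% c("error", "warning"))
}

#' Sweep the consistency checks over a composition table
#'
#' Runs [validate_item()] on every row of an item table (as returned by
#' [read_fcdb()] or [load_gf_items()]), auto-detecting the carbohydrate
#' convention per row, and collects the flagged rows.
#'
#' @param tab item table with columns `item`, `energy_kcal`, `energy_kJ`,
#'   `available_carbohydrate`, `soluble_carbohydrate`, `fiber`,
#'   `protein_total`, `lipid_total`.
#' @param ... passed to [validate_item()].
#' @return Data frame, one row per item: `item`, `convention`,
#'   `residual_kcal`, `flagged` (energy residual beyond tolerance or any other
#'   error), ordered as the input.
#' @export
validate_table <- function(tab, ...) {
  out <- lapply(seq_len(nrow(tab)), function(i) {
    v <- nutrient_vector(.data = tab[i, intersect(names(tab), component_codes())])
    rep <- validate_item(v, item = tab$item[i], ...)
    d <- detect_cho_convention(v)
    data.frame(item = tab$item[i],
               convention = d$convention,
               residual_kcal = d$residual_kcal,
               flagged = !checks_passed(rep),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
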