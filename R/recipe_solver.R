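#' Recipe specification objects
#'
#' A recipe models a branded product as an ordered list of coded ingredients
#' (rank 1 = heaviest on the label) plus processing steps. Declared label
#' percentages, when present, fix the corresponding formulation weight.
#'
#' @param id product identifier.
#' @param ingredients data frame with columns `key` (reference-table key),
#'   `rank` (1 = heaviest; must be contiguous from 1), optional `percent`
#'   (declared percentage of the formulation mass, `NA` if undeclared).
#' @param steps data frame with columns `name`, `yield` (output mass / input
#'   mass, water loss only, in (0, 1.5]), `retention_key` (key into a
#'   retention table, `NA` for none); or `NULL` for an unprocessed product.
#' @param moisture_target optional analytical moisture of the product,
#'   g/100 g as sold.
#' @return An object of class `recipe_spec`.
#' @export
#' @examples
#' recipe_spec("biscuit01",
#'   ingredients = data.frame(key = c("flour", "sugar", "oil"), rank = 1:3),
#'   steps = data.frame(name = "baking", yield = 0.9, retention_key = "baking"))
recipe_spec <- function(id, ingredients, steps = NULL, moisture_target = NA_real_) {
  stopifnot(is.data.frame(ingredients), nrow(ingredients) >= 1)
  if (is.null(ingredients$percent)) ingredients$percent <- NA_real_
  if (is.null(ingredients$rank)) ingredients$rank <- seq_len(nrow(ingredients))
  ingredients <- ingredients[order(ingredients$rank), , drop = FALSE]
  if (!identical(as.integer(ingredients$rank), seq_len(nrow(ingredients)))) {
    stop("ingredient ranks must be unique and contiguous from 1")
  }
  p <- ingredients$percent
  if (any(!is.na(p) & (p <= 0 | p > 100))) {
    stop("declared percentages must lie in (0, 100]")
  }
  if (!is.null(steps)) {
    stopifnot(is.data.frame(steps))
    if (is.null(steps$retention_key)) steps$retention_key <- NA_character_
    if (any(steps$yield <= 0 | steps$yield > 1.5)) {
      stop("process yields must lie in (0, 1.5]")
    }
  }
  structure(list(id = id, ingredients = ingredients, steps = steps,
                 moisture_target = moisture_target),
            class = "recipe_spec")
}

#' Mandatory nutrition declaration
#'
#' The EU label panel used as the fitting target: energy, fat, saturates,
#' carbohydrate, sugars, fiber (optional on labels), protein and salt, all per
#' 100 g. Carbohydrate figures on labels are by weight ("as such" basis).
#'
#' @param energy_kJ,energy_kcal declared energy per 100 g.
#' @param fat,saturates,carbohydrate,sugars,protein,salt g/100 g.
#' @param fiber g/100 g, or `NA` when not declared.
#' @return An object of class `label_declaration` (named list).
#' @export
label_declaration <- function(energy_kJ, energy_kcal, fat, saturates,
                              carbohydrate, sugars, fiber = NA_real_,
                              protein, salt) {
  l <- list(energy_kJ = energy_kJ, energy_kcal = energy_kcal, fat = fat,
            saturates = saturates, carbohydrate = carbohydrate,
            sugars = sugars, fiber = fiber, protein = protein, salt = salt)
  num <- unlist(l)
  if (any(!is.na(num) & num < 0)) stop("label amounts must be non-negative")
  if (!is.na(saturates) && saturates > fat + 1e-9) {
    stop("saturates exceed fat on the declaration")
  }
  if (!is.na(sugars) && sugars > carbohydrate + 1e-9) {
    stop("sugars exceed carbohydrate on the declaration")
  }
  structure(l, class = "label_declaration")
}

# label nutrient -> component code mapping shared by solver and aggregation
label_component_map <- function() {
  c(fat = "lipid_total", saturates = "sfa",
    carbohydrate = "available_carbohydrate", sugars = "soluble_carbohydrate",
    fiber = "fiber", protein = "protein_total", salt = "sodium")
}

#' Derive a label panel from a nutrient vector
#'
#' @param v nutrient vector (as-such carbohydrate basis).
#' @return A [label_declaration()] with energy recomputed from the
#'   macronutrients.
#' @export
label_from_vector <- function(v) {
  e <- compute_energy(v[["available_carbohydrate"]], v[["protein_total"]],
                      v[["lipid_total"]], v[["fiber"]], "as_such")
  label_declaration(
    energy_kJ = e$energy_kJ, energy_kcal = e$energy_kcal,
    fat = v[["lipid_total"]], saturates = v[["sfa"]],
    carbohydrate = v[["available_carbohydrate"]],
    sugars = v[["soluble_carbohydrate"]], fiber = v[["fiber"]],
    protein = v[["protein_total"]],
    salt = salt_from_sodium(v[["sodium"]], digits = NA))
}

overall_yield <- function(steps) {
  if (is.null(steps) || nrow(steps) == 0) 1 else prod(steps$yield)
}

ref_matrix <- function(ref_db, keys) {
  if (!all(keys %in% ref_db$ingredient)) {
    stop("unknown ingredient key(s): ",
         paste(setdiff(keys, ref_db$ingredient), collapse = ", "))
  }
  rows <- ref_db[match(keys, ref_db$ingredient), , drop = FALSE]
  comps <- intersect(component_codes(), names(rows))
  m <- as.matrix(rows[, comps, drop = FALSE])
  rownames(m) <- keys
  m
}

#' Evaluate a recipe into an as-sold nutrient vector
#'
#' Component-wise weighted sum of the reference ingredient vectors for a
#' 100 g formulation, with process water loss applied: each step's yield
#' factor removes mass that is attributed entirely to water, after which the
#' vector is renormalized to the 100 g as-sold basis. Micronutrient retention
#' is applied separately (see [apply_retention()]).
#'
#' @param weights formulation weights, g per 100 g formulation, in ingredient
#'   order (optionally named by ingredient key); must sum to 100.
#' @param ref_db reference ingredient table: data frame with an `ingredient`
#'   key column and component-code columns.
#' @param keys ingredient keys matching `weights` (defaults to
#'   `names(weights)`).
#' @param steps process steps (data frame with `yield`), or `NULL`.
#' @return Nutrient vector per 100 g as sold. Energy components are left `NA`
#'   (energy is recomputed downstream from the macronutrients).
#' @export
evaluate_recipe <- function(weights, ref_db, keys = names(weights), steps = NULL) {
  if (is.null(keys)) stop("ingredient keys are required")
  if (abs(sum(weights) - 100) > 1e-6) {
    stop(sprintf("formulation weights must sum to 100 (got %.6f)", sum(weights)))
  }
  m <- ref_matrix(ref_db, keys)
  mix <- colSums(m * (weights / 100), na.rm = FALSE)
  y <- overall_yield(steps)
  water_loss <- 100 * (1 - y)
  if (!is.na(mix["water"]) && mix[["water"]] - water_loss < -1e-9) {
    stop(sprintf(
      "process yield %.3f would remove %.1f g water but the formulation holds only %.1f g",
      y, water_loss, mix[["water"]]))
  }
  out <- mix / y
  out["water"] <- (mix[["water"]] - water_loss) / y
  v <- nutrient_vector()
  v[names(out)] <- out
  v["energy_kJ"] <- NA_real_
  v["energy_kcal"] <- NA_real_
  v
}

# Affine map from formulation weights to the label nutrient space:
# label_j(w) = (M w)_j / yield ; salt derived from sodium.
label_design <- function(ref_db, keys, steps) {
  m <- ref_matrix(ref_db, keys)
  map <- label_component_map()
  M <- t(m[, map, drop = FALSE]) / 100
  rownames(M) <- names(map)
  M["salt", ] <- M["salt", ] * 2.5 / 1000   # sodium mg -> salt g
  M / overall_yield(steps)
}

# water(w) = c . w + b on the as-sold basis
water_design <- function(ref_db, keys, steps) {
  m <- ref_matrix(ref_db, keys)
  y <- overall_yield(steps)
  list(coef = m[, "water"] / 100 / y, offset = -100 * (1 - y) / y)
}

#' Solver options for [estimate_weights()]
#'
#' @param denominator_floor floor (g) applied to label denominators in the
#'   relative-deviation objective, preventing tiny-amount nutrients from
#'   dominating.
#' @param max_enum maximum ingredient count for the exact active-set
#'   enumeration path; larger recipes use multi-start projected
#'   quasi-Newton minimization.
#' @param tol convergence tolerance on the objective for the iterative
#'   fallback.
#' @param max_iter iteration cap per start for the iterative fallback.
#' @return List of options.
#' @export
solver_options <- function(denominator_floor = 0.5, max_enum = 10,
                           tol = 1e-8, max_iter = 500) {
  list(denominator_floor = denominator_floor, max_enum = max_enum,
       tol = tol, max_iter = max_iter)
}

# Solve min ||W (M x - t)||^2 subject to C x = d, by null-space elimination.
# Returns NULL when the equality system is inconsistent.
solve_constrained_ls <- function(M, t, wts, C, d) {
  n <- ncol(M)
  qrC <- qr(t(C))
  r <- qrC$rank
  x0 <- tryCatch(qr.coef(qr(C), d), error = function(e) NULL)
  if (is.null(x0)) return(NULL)
  x0[is.na(x0)] <- 0
  if (max(abs(C %*% x0 - d)) > 1e-7) return(NULL)
  Q <- qr.Q(qrC, complete = TRUE)
  Z <- if (r < n) Q[, (r + 1):n, drop = FALSE] else NULL
  if (is.null(Z)) return(as.numeric(x0))
  A <- (M %*% Z) * wts
  b <- (t - M %*% x0) * wts
  z <- tryCatch(qr.coef(qr(A), b), error = function(e) NULL)
  if (is.null(z)) return(NULL)
  z[is.na(z)] <- 0
  as.numeric(x0 + Z %*% z)
}

#' Estimate ingredient weights from an ordered ingredient list and a label
#'
#' Replaces the manual trial-and-error fitting of a branded product's recipe
#' with a deterministic constrained least-squares solve. The objective is the
#' sum of squared relative deviations between the evaluated recipe and the
#' declared panel over fat, saturates, carbohydrate, sugars, fiber (if
#' declared), protein and salt; energy is excluded (it is a linear
#' combination of the others) and used as a post-hoc check. Constraints:
#' weights non-negative and non-increasing in declared rank, declared
#' percentages fixed exactly, weights summing to 100 g formulation, and an
#' optional analytical moisture equality.
#'
#' Because the evaluated panel is affine in the weights, the problem is a
#' convex quadratic program over a polytope. For recipes of up to
#' `options$max_enum` ingredients the solver enumerates the active sets of
#' the ordering/non-negativity constraints and solves each
#' equality-constrained least-squares subproblem exactly, returning the
#' global optimum; ties in the objective are broken in favour of the largest
#' rank-1 weight. Larger recipes fall back to deterministic multi-start
#' bounded quasi-Newton minimization over the ordered-weight
#' reparameterization.
#'
#' @param recipe a [recipe_spec()].
#' @param ref_db reference ingredient table (see [evaluate_recipe()]).
#' @param label a [label_declaration()].
#' @param options a [solver_options()] list.
#' @return An object of class `weight_solution`: list with `weights` (named,
#'   g/100 g formulation), `vector` (as-sold nutrient vector), `residuals`
#'   (evaluated minus declared, label space), `objective`, `status`
#'   (`"converged"` or `"failed"`), `convention` (`"as_such"`).
#' @export
estimate_weights <- function(recipe, ref_db, label, options = solver_options()) {
  stopifnot(inherits(recipe, "recipe_spec"), inherits(label, "label_declaration"))
  keys <- recipe$ingredients$key
  n <- length(keys)
  pct <- recipe$ingredients$percent

  fixed <- which(!is.na(pct))
  if (length(fixed)) {
    if (sum(pct[fixed]) > 100 + 1e-9) {
      stop("declared percentages exceed 100 g of formulation")
    }
    # ordering feasibility among declared percentages
    if (length(fixed) > 1 && any(diff(pct[fixed]) > 1e-9)) {
      stop("declared percentages violate the rank ordering")
    }
    if (all(seq_len(n) %in% fixed) && abs(sum(pct) - 100) > 1e-6) {
      stop("fully declared recipe does not sum to 100")
    }
  }

  nutrients <- names(label_component_map())
  target <- unlist(label[nutrients])
  use <- !is.na(target)
  M <- label_design(ref_db, keys, recipe$steps)[use, , drop = FALSE]
  t_ <- target[use]
  wts <- 1 / pmax(t_, options$denominator_floor)

  # base equality constraints: simplex, declared percentages, moisture target
  C0 <- matrix(1, nrow = 1, ncol = n)
  d0 <- 100
  for (i in fixed) {
    e <- numeric(n); e[i] <- 1
    C0 <- rbind(C0, e); d0 <- c(d0, pct[i])
  }
  if (!is.na(recipe$moisture_target)) {
    wd <- water_design(ref_db, keys, recipe$steps)
    C0 <- rbind(C0, wd$coef)
    d0 <- c(d0, recipe$moisture_target - wd$offset)
  }

  # inequality constraints: w_i - w_{i+1} >= 0 (i < n), w_n >= 0
  ineq <- function(i) {
    e <- numeric(n)
    if (i < n) { e[i] <- 1; e[i + 1] <- -1 } else e[n] <- 1
    e
  }
  feasible <- function(x) {
    all(vapply(seq_len(n), function(i) sum(ineq(i) * x), numeric(1)) >= -1e-9) &&
      max(abs(C0 %*% x - d0)) < 1e-6
  }
  objective <- function(x) sum(((M %*% x - t_) * wts)^2)

  best <- NULL
  if (n <= options$max_enum) {
    for (mask in 0:(2^n - 1)) {
      act <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
      C <- C0; d <- d0
      for (i in act) { C <- rbind(C, ineq(i)); d <- c(d, 0) }
      x <- solve_constrained_ls(M, t_, wts, C, d)
      if (is.null(x) || !feasible(x)) next
      ob <- objective(x)
      if (is.null(best) || ob < best$objective - 1e-12 ||
          (abs(ob - best$objective) <= 1e-12 && x[1] > best$x[1] + 1e-12)) {
        best <- list(x = x, objective = ob)
      }
    }
    status <- if (is.null(best)) "failed" else "converged"
  } else {
    sol <- solve_multistart(M, t_, wts, C0, d0, n, fixed, pct, options)
    best <- sol$best
    status <- sol$status
  }
  if (is.null(best)) {
    stop("no feasible formulation satisfies the declared constraints")
  }

  w <- stats::setNames(pmax(best$x, 0), keys)
  # enforce exact simplex after numerical cleanup of free weights
  if (length(fixed)) {
    free <- setdiff(seq_len(n), fixed)
    if (length(free) && sum(w[free]) > 0) {
      w[free] <- w[free] * (100 - sum(w[fixed])) / sum(w[free])
    }
  } else if (sum(w) > 0) {
    w <- w * 100 / sum(w)
  }
  vec <- evaluate_recipe(w, ref_db, keys, recipe$steps)
  fitted <- as.numeric(M %*% w)
  residuals <- stats::setNames(fitted - t_, names(t_))
  structure(list(id = recipe$id, weights = w, vector = vec,
                 residuals = residuals, objective = objective(w),
                 status = status, convention = "as_such"),
            class = "weight_solution")
}

# multi-start bounded quasi-Newton fallback on the ordered-increment
# reparameterization w = U d (d >= 0), simplex enforced by normalization
solve_multistart <- function(M, t_, wts, C0, d0, n, fixed, pct, options) {
  U <- upper.tri(matrix(1, n, n), diag = TRUE) * 1
  w_of <- function(dv) {
    s <- sum(seq_len(n) * dv)
    if (s <= 0) return(rep(100 / n, n))
    100 * as.numeric(U %*% dv) / s
  }
  pen <- function(w) {
    p <- 0
    if (length(fixed)) p <- p + sum((w[fixed] - pct[fixed])^2) * 1e6
    if (nrow(C0) > 1 + length(fixed)) {
      extra <- C0[-seq_len(1 + length(fixed)), , drop = FALSE]
      dex <- d0[-seq_len(1 + length(fixed))]
      p <- p + sum((extra %*% w - dex)^2) * 1e4
    }
    p
  }
  f <- function(dv) {
    w <- w_of(dv)
    sum(((M %*% w - t_) * wts)^2) + pen(w)
  }
  starts <- list(rep(1e-6, n) + c(rep(0, n - 1), 1),        # equal split
                 rev(1 / seq_len(n)) / n,                   # rank-proportional
                 c(rep(0.05, n - 1), 1))                    # top-heavy
  best <- NULL
  for (s in starts) {
    o <- stats::optim(s, f, method = "L-BFGS-B", lower = 0,
                      control = list(maxit = options$max_iter,
                                     factr = options$tol / .Machine$double.eps))
    w <- w_of(o$par)
    ob <- sum(((M %*% w - t_) * wts)^2)
    if (is.null(best) || ob < best$objective) best <- list(x = w, objective = ob)
  }
  list(best = best, status = "converged")
}

#' @export
print.weight_solution <- function(x, ...) {
  cat("Recipe weight solution for", x$id, "-", x$status, "\n")
  cat("objective:", format(x$objective, digits = 6), "\n")
  print(round(x$weights, 2))
  invisible(x)
}

#' Label-match report for a solved recipe
#'
#' Grades each declared nutrient against tolerances in the style of the EU
#' guidance on declared-value tolerances: +/-15% relative for amounts of
#' 10 g/100 g and above, +/-1.5 g absolute below 10 g/100 g, and +/-0.375 g
#' for salt. The product passes when every declared mandatory nutrient
#' passes.
#'
#' @param solution a `weight_solution` from [estimate_weights()].
#' @param label the [label_declaration()] it was fitted to.
#' @param rel_tol,abs_tol,salt_tol tolerance profile.
#' @return Data frame with one row per declared nutrient (`nutrient`,
#'   `declared`, `computed`, `tolerance`, `pass`) and attribute
#'   `"overall_pass"`.
#' @export
fit_report <- function(solution, label, rel_tol = 0.15, abs_tol = 1.5,
                       salt_tol = 0.375) {
  stopifnot(inherits(solution, "weight_solution"))
  if (solution$status != "converged") stop("solution did not converge")
  nutrients <- names(solution$residuals)
  declared <- unlist(label[nutrients])
  computed <- declared + solution$residuals
  tol <- ifelse(nutrients == "salt", salt_tol,
                ifelse(declared >= 10, rel_tol * declared, abs_tol))
  pass <- abs(computed - declared) <= tol + 1e-12
  out <- data.frame(nutrient = nutrients, declared = unname(declared),
                    computed = unname(computed), tolerance = unname(tol),
                    pass = unname(pass), stringsAsFactors = FALSE)
  attr(out, "overall_pass") <- all(pass)
  out
}
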