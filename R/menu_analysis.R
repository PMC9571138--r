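#' Disassemble composite menu entries into simple ingredients
#'
#' Guideline menus list some entries as complex dishes. For nutrient totals
#' these are broken down into simple ingredients using a recipe book of
#' ingredient shares; nesting (a dish containing a composite sauce) is
#' flattened recursively and total mass is conserved.
#'
#' @param menu data frame with columns `day` (1-7), `food` (food key),
#'   `amount` (g as consumed) and optionally `composite` (logical; defaults to
#'   whether the food key has an entry in `recipe_book`).
#' @param recipe_book named list: food key -> data frame with columns
#'   `ingredient`, `share` (shares summing to 1).
#' @return The menu with composite rows replaced by ingredient rows.
#' @export
disassemble_menu <- function(menu, recipe_book = list()) {
  stopifnot(all(c("day", "food", "amount") %in% names(menu)))
  if (any(menu$amount <= 0)) stop("menu amounts must be positive")
  composite <- if ("composite" %in% names(menu)) menu$composite else
    menu$food %in% names(recipe_book)
  out <- vector("list", nrow(menu))
  for (i in seq_len(nrow(menu))) {
    if (!composite[i]) {
      out[[i]] <- data.frame(day = menu$day[i], food = menu$food[i],
                             amount = menu$amount[i], stringsAsFactors = FALSE)
      next
    }
    rec <- recipe_book[[menu$food[i]]]
    if (is.null(rec)) stop("missing recipe for composite food: ", menu$food[i])
    if (abs(sum(rec$share) - 1) > 1e-6) {
      stop("ingredient shares for ", menu$food[i], " do not sum to 1")
    }
    sub <- data.frame(day = menu$day[i], food = rec$ingredient,
                      amount = menu$amount[i] * rec$share,
                      stringsAsFactors = FALSE)
    # an ingredient may itself be composite: recurse
    out[[i]] <- disassemble_menu(sub, recipe_book)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Daily nutrient totals of a menu
#'
#' Amount-weighted sum of the per-100 g compositions over the foods of each
#' day. Daily energy is recomputed from the summed macronutrients (including
#' fiber), never by summing per-food energies, so mixed carbohydrate
#' conventions across foods cannot bias the total.
#'
#' @param menu simple-food menu (see [disassemble_menu()]).
#' @param fcdb composition table: data frame with an `item` column and
#'   component columns, per 100 g.
#' @param convention carbohydrate convention of the summed totals for the
#'   energy recomputation.
#' @return Data frame, one row per day (`day` column first), one column per
#'   nutrient component, amounts per day.
#' @export
daily_totals <- function(menu, fcdb, convention = "as_such") {
  missing_foods <- setdiff(menu$food, fcdb$item)
  if (length(missing_foods)) {
    stop("food key(s) not in the composition table: ",
         paste(missing_foods, collapse = ", "))
  }
  comps <- intersect(component_codes(), names(fcdb))
  m <- as.matrix(fcdb[match(menu$food, fcdb$item), comps, drop = FALSE])
  contrib <- m * (menu$amount / 100)
  days <- sort(unique(menu$day))
  tot <- do.call(rbind, lapply(days, function(d) {
    colSums(contrib[menu$day == d, , drop = FALSE])
  }))
  out <- data.frame(day = days)
  out <- cbind(out, as.data.frame(tot))
  e <- compute_energy(out$available_carbohydrate, out$protein_total,
                      out$lipid_total, out$fiber, convention)
  out$energy_kcal <- e$energy_kcal
  out$energy_kJ <- e$energy_kJ
  out
}

#' Build the paired GC and GF arms of a menu
#'
#' Swaps the composition source of the cereal-based foods covered by the
#' substitution map while keeping every gram amount fixed, and returns the
#' paired daily totals. Foods outside the map's scope must resolve in both
#' composition tables under the same key (they map to themselves).
#'
#' @param menu simple-food menu.
#' @param sub_map named character vector: GC cereal food key -> GF food key.
#' @param fcdb_gc,fcdb_gf composition tables for the gluten-containing and
#'   gluten-free arms.
#' @param convention passed to [daily_totals()].
#' @return List with `gc` and `gf` daily-total data frames, paired by day.
#' @export
apply_substitution <- function(menu, sub_map, fcdb_gc, fcdb_gf,
                               convention = "as_such") {
  menu_gf <- menu
  mapped <- menu$food %in% names(sub_map)
  menu_gf$food[mapped] <- unname(sub_map[menu$food[mapped]])
  gc <- daily_totals(menu, fcdb_gc, convention)
  gf <- daily_totals(menu_gf, fcdb_gf, convention)
  list(gc = gc, gf = gf)
}

#' Exact Wilcoxon signed-rank test for paired differences
#'
#' Signed-rank test on paired differences with the conventions required by
#' small-sample menu comparisons: zero differences dropped, tied absolute
#' differences mid-ranked, and the null distribution of the statistic
#' computed exactly (by convolution over the achievable rank sums, which
#' remains exact under ties) for up to `exact_limit` non-zero differences; a
#' normal approximation with tie correction and continuity correction is used
#' beyond that. The two-sided p-value doubles the smaller tail, capped at 1.
#'
#' @param d numeric vector of paired differences.
#' @param exact_limit maximum number of non-zero differences for the exact
#'   null distribution.
#' @return List with `statistic` (V, sum of positive ranks), `p.value`,
#'   `n_used` (non-zero differences), `method` (`"exact"`, `"normal"`, or
#'   `"degenerate"` when all differences are zero, in which case p = 1).
#' @export
wilcoxon_signed_rank <- function(d, exact_limit = 20) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    return(list(statistic = NA_real_, p.value = 1, n_used = 0L,
                method = "degenerate"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (m <= exact_limit) {
    # exact null pmf of V by convolution on doubled ranks (midranks -> .5)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    pmf <- numeric(total + 1)   # index i -> P(2V = i-1), unnormalized counts
    pmf[1] <- 1
    for (ri in r2) {
      shifted <- c(rep(0, ri), pmf[seq_len(total + 1 - ri)])
      pmf <- pmf + shifted
    }
    pmf <- pmf / 2^m
    v2 <- round(2 * v)
    p_le <- sum(pmf[seq_len(v2 + 1)])
    p_ge <- sum(pmf[(v2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = v, p.value = p, n_used = m, method = method)
}

#' Normality-routed paired comparison of one nutrient
#'
#' The routing used for every nutrient of the menu comparison: Shapiro-Wilk
#' on the paired differences at level 0.05; when normality is not rejected, a
#' paired t-test with mean +/- SD descriptives; otherwise the exact Wilcoxon
#' signed-rank test ([wilcoxon_signed_rank()]) with median (IQR)
#' descriptives. All-zero differences short-circuit to "no difference"
#' (p = 1, no test statistic).
#'
#' @param gc,gf paired daily totals for one nutrient (equal length >= 3).
#' @param alpha significance level.
#' @param shapiro_alpha level of the normality pre-test.
#' @return One-row data frame: `gc_center`, `gc_spread`, `gf_center`,
#'   `gf_spread`, `normal` (logical), `test` (`"paired_t"`,
#'   `"wilcoxon_signed_rank"` or `"none"`), `statistic`, `p_value`,
#'   `significant`.
#' @export
route_paired_test <- function(gc, gf, alpha = 0.05, shapiro_alpha = 0.05) {
  stopifnot(length(gc) == length(gf), length(gc) >= 3)
  d <- gf - gc
  if (all(d == 0)) {
    return(data.frame(gc_center = mean(gc), gc_spread = stats::sd(gc),
                      gf_center = mean(gf), gf_spread = stats::sd(gf),
                      normal = TRUE, test = "none", statistic = NA_real_,
                      p_value = 1, significant = FALSE,
                      stringsAsFactors = FALSE))
  }
  sw_p <- if (stats::sd(d) == 0) 0 else stats::shapiro.test(d)$p.value
  normal <- sw_p >= shapiro_alpha
  if (normal) {
    tt <- stats::t.test(gf, gc, paired = TRUE)
    data.frame(gc_center = mean(gc), gc_spread = stats::sd(gc),
               gf_center = mean(gf), gf_spread = stats::sd(gf),
               normal = TRUE, test = "paired_t",
               statistic = unname(tt$statistic), p_value = tt$p.value,
               significant = tt$p.value < alpha, stringsAsFactors = FALSE)
  } else {
    w <- wilcoxon_signed_rank(d)
    data.frame(gc_center = stats::median(gc), gc_spread = stats::IQR(gc),
               gf_center = stats::median(gf), gf_spread = stats::IQR(gf),
               normal = FALSE, test = "wilcoxon_signed_rank",
               statistic = w$statistic, p_value = w$p.value,
               significant = w$p.value < alpha, stringsAsFactors = FALSE)
  }
}

#' Compare paired GC and GF menu arms nutrient by nutrient
#'
#' Runs [route_paired_test()] on each nutrient column shared by the two
#' daily-total tables (paired by day index). No multiple-testing correction
#' is applied across nutrients.
#'
#' @param gc_days,gf_days daily-total data frames from [daily_totals()] /
#'   [apply_substitution()], equal day counts >= 3.
#' @param alpha significance level.
#' @param nutrients nutrient columns to compare (default: all shared
#'   component columns with no missing values).
#' @return Data frame of comparison rows, one per nutrient, with a leading
#'   `nutrient` column.
#' @export
compare_menus <- function(gc_days, gf_days, alpha = 0.05, nutrients = NULL) {
  stopifnot(nrow(gc_days) == nrow(gf_days), nrow(gc_days) >= 3)
  gc_days <- gc_days[order(gc_days$day), , drop = FALSE]
  gf_days <- gf_days[order(gf_days$day), , drop = FALSE]
  if (!identical(gc_days$day, gf_days$day)) {
    stop("GC and GF arms must cover the same day indices")
  }
  if (is.null(nutrients)) {
    shared <- intersect(intersect(names(gc_days), names(gf_days)),
                        component_codes())
    nutrients <- shared[vapply(shared, function(nm) {
      !anyNA(gc_days[[nm]]) && !anyNA(gf_days[[nm]])
    }, logical(1))]
  }
  rows <- lapply(nutrients, function(nm) {
    cbind(data.frame(nutrient = nm, stringsAsFactors = FALSE),
          route_paired_test(gc_days[[nm]], gf_days[[nm]], alpha))
  })
  do.call(rbind, rows)
}

fmt_num <- function(x, digits = 2) formatC(x, format = "f", digits = digits)

#' Render a comparison report grid
#'
#' Formats comparison rows the way the published grid presents them: one
#' block of columns per scenario, `mean +/- SD` descriptives for normally
#' distributed nutrients and `median (IQR)` in italics otherwise, with
#' significant p-values in bold.
#'
#' @param rows a comparison data frame from [compare_menus()], or a named
#'   list of them (one per scenario).
#' @param digits decimals for descriptives.
#' @return Character matrix (invisibly also printed with [cat()] when
#'   `print = TRUE`).
#' @param print print the grid.
#' @export
render_report <- function(rows, digits = 2, print = FALSE) {
  if (is.data.frame(rows)) rows <- list(scenario = rows)
  if (!length(rows) || !nrow(rows[[1]])) stop("no comparison rows to render")
  nutrients <- rows[[1]]$nutrient
  out <- matrix("", nrow = length(nutrients), ncol = 1 + 3 * length(rows))
  out[, 1] <- nutrients
  colnames(out) <- c("nutrient",
                     unlist(lapply(names(rows), function(s)
                       paste(s, c("GC", "GF", "p"), sep = "_"))))
  for (j in seq_along(rows)) {
    r <- rows[[j]]
    stopifnot(identical(r$nutrient, nutrients))
    desc <- function(center, spread, normal) {
      s <- ifelse(normal,
                  paste0(fmt_num(center, digits), " ± ", fmt_num(spread, digits)),
                  paste0("*", fmt_num(center, digits), " (", fmt_num(spread, digits), ")*"))
      s
    }
    pcol <- fmt_num(r$p_value, 3)
    pcol[r$significant] <- paste0("**", pcol[r$significant], "**")
    out[, 1 + 3 * (j - 1) + 1] <- desc(r$gc_center, r$gc_spread, r$normal)
    out[, 1 + 3 * (j - 1) + 2] <- desc(r$gf_center, r$gf_spread, r$normal)
    out[, 1 + 3 * (j - 1) + 3] <- pcol
  }
  if (print) {
    grid <- rbind(colnames(out), out)
    widths <- apply(grid, 2, function(x) max(nchar(x)))
    lines <- apply(grid, 1, function(x)
      paste(mapply(formatC, x, width = widths,
                   MoreArgs = list(flag = "-")), collapse = "  "))
    cat(lines, sep = "\n")
    return(invisible(out))
  }
  out
}
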