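#' Read and write composition tables
#'
#' One canonical tabular dialect for every composition table: CSV, UTF-8, dot
#' decimal, missing values as empty cells, a leading `#`-comment line carrying
#' the component-dictionary version. Columns other than the bookkeeping
#' columns (`item`, `category`, `moisture`, `n_brands`, `ingredient`,
#' `group`, `cho_convention`) must be component codes from
#' [nutrient_components()]; unknown columns, non-numeric cells and duplicate
#' item keys are parse errors reporting the offending coordinates.
#' `read_fcdb()` after `write_fcdb()` is the identity on valid tables.
#'
#' @param path file path.
#' @return `read_fcdb()`: the composition data frame.
#' @export
read_fcdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE, encoding = "UTF-8",
                         colClasses = "character")
  meta <- c("item", "category", "moisture", "n_brands", "ingredient",
            "group", "cho_convention")
  unknown <- setdiff(names(tab), c(meta, component_codes()))
  if (length(unknown)) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "))
  }
  key <- intersect(c("item", "ingredient"), names(tab))[1]
  if (is.na(key)) stop("table must have an 'item' or 'ingredient' key column")
  if (anyDuplicated(tab[[key]])) {
    dup <- unique(tab[[key]][duplicated(tab[[key]])])
    stop("duplicate ", key, " key(s): ", paste(dup, collapse = ", "))
  }
  for (nm in intersect(names(tab), c(component_codes(), "n_brands"))) {
    raw <- tab[[nm]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & is.na(val))
    if (length(bad)) {
      stop(sprintf("non-numeric cell at row %d, column '%s': '%s'",
                   bad[1], nm, raw[bad[1]]))
    }
    tab[[nm]] <- val
  }
  tab
}

#' @rdname read_fcdb
#' @param tab composition data frame to write.
#' @export
write_fcdb <- function(tab, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", attr(nutrient_components(), "version")), con)
  utils::write.csv(tab, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Path to the packaged 108-item composition fixture
#'
#' The energy and macronutrient composition per 100 g, as sold, of the 108
#' gluten-free food items across the ten database categories, as printed in
#' the published tables. The analytical-moisture flag reproduces the printed
#' per-category counts (42 items in total); which specific items were
#' analytically determined is not published, so the flag is assigned to the
#' first items of each category in table order — a documented synthetic
#' assignment.
#'
#' @return `gf_fixture_path()`: path to the installed CSV.
#' @export
gf_fixture_path <- function() {
  system.file("extdata", "gf_items.csv", package = "gffcdb", mustWork = TRUE)
}

#' @rdname gf_fixture_path
#' @return `load_gf_items()`: the fixture as a data frame (see [read_fcdb()]).
#' @export
load_gf_items <- function() {
  read_fcdb(gf_fixture_path())
}

#' Read and write recipe documents
#'
#' Recipes are stored as YAML: `id`, optional `moisture_target`, an ordered
#' `ingredients` block (`key`, `rank`, optional `percent`) and an optional
#' `steps` block (`name`, `yield`, `retention_key`).
#'
#' @param path file path.
#' @return `read_recipe()`: a [recipe_spec()].
#' @export
read_recipe <- function(path) {
  doc <- yaml::read_yaml(path)
  ing <- do.call(rbind, lapply(doc$ingredients, function(x) {
    data.frame(key = x$key, rank = x$rank,
               percent = if (is.null(x$percent)) NA_real_ else x$percent,
               stringsAsFactors = FALSE)
  }))
  steps <- if (length(doc$steps)) {
    do.call(rbind, lapply(doc$steps, function(x) {
      data.frame(name = x$name, yield = x$yield,
                 retention_key = if (is.null(x$retention_key)) NA_character_
                                 else x$retention_key,
                 stringsAsFactors = FALSE)
    }))
  } else NULL
  recipe_spec(doc$id, ing, steps,
              moisture_target = if (is.null(doc$moisture_target)) NA_real_
                                else doc$moisture_target)
}

#' @rdname read_recipe
#' @param recipe a [recipe_spec()] to write.
#' @export
write_recipe <- function(recipe, path) {
  doc <- list(id = recipe$id,
              ingredients = lapply(seq_len(nrow(recipe$ingredients)), function(i) {
                r <- recipe$ingredients[i, ]
                out <- list(key = r$key, rank = r$rank)
                if (!is.na(r$percent)) out$percent <- r$percent
                out
              }))
  if (!is.null(recipe$steps)) {
    doc$steps <- lapply(seq_len(nrow(recipe$steps)), function(i) {
      s <- recipe$steps[i, ]
      out <- list(name = s$name, yield = s$yield)
      if (!is.na(s$retention_key)) out$retention_key <- s$retention_key
      out
    })
  }
  if (!is.na(recipe$moisture_target)) doc$moisture_target <- recipe$moisture_target
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Read and write label declarations
#'
#' @param path file path (YAML with the panel fields of
#'   [label_declaration()]).
#' @return `read_label()`: a [label_declaration()].
#' @export
read_label <- function(path) {
  doc <- yaml::read_yaml(path)
  doc$fiber <- if (is.null(doc$fiber)) NA_real_ else doc$fiber
  do.call(label_declaration, doc)
}

#' @rdname read_label
#' @param label a [label_declaration()] to write.
#' @export
write_label <- function(label, path) {
  l <- label[!vapply(label, is.na, logical(1))]
  yaml::write_yaml(l, path)
  invisible(path)
}

#' Read and write menu documents
#'
#' Menus are YAML documents with one block per day (`day`, `foods` as
#' `food`/`amount` pairs) and an optional `substitutions` map.
#'
#' @param path file path.
#' @return `read_menu()`: list with `menu` (day/food/amount data frame) and
#'   `sub_map` (possibly empty named character vector).
#' @export
read_menu <- function(path) {
  doc <- yaml::read_yaml(path)
  menu <- do.call(rbind, lapply(doc$days, function(d) {
    do.call(rbind, lapply(d$foods, function(f) {
      data.frame(day = d$day, food = f$food, amount = f$amount,
                 stringsAsFactors = FALSE)
    }))
  }))
  sub_map <- if (length(doc$substitutions)) {
    unlist(doc$substitutions)
  } else stats::setNames(character(), character())
  list(menu = menu, sub_map = sub_map)
}

#' @rdname read_menu
#' @param menu day/food/amount data frame.
#' @param sub_map named character vector of substitutions (optional).
#' @export
write_menu <- function(menu, path, sub_map = NULL) {
  days <- lapply(sort(unique(menu$day)), function(d) {
    sub <- menu[menu$day == d, , drop = FALSE]
    list(day = d, foods = lapply(seq_len(nrow(sub)), function(i)
      list(food = sub$food[i], amount = sub$amount[i])))
  })
  doc <- list(days = days)
  if (length(sub_map)) doc$substitutions <- as.list(sub_map)
  yaml::write_yaml(doc, path)
  invisible(path)
}
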