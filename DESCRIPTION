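Package: gffcdb
Title: Construction Calculus for a Gluten-Free Food Composition Database
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for compiling a recipe-based food composition database of
    manufactured gluten-free cereal products. Ingredient weights of branded
    products are estimated from the ordered ingredient list under the
    constraint that the evaluated recipe matches the mandatory EU nutrition
    declaration; processing water losses and micronutrient retention factors
    are applied; nutrient sub-profiles are rescaled onto label totals; brands
    are aggregated into food items; energy, starch and water follow defined
    computation rules with an automated consistency-check battery. A menu
    analysis stage builds paired gluten-containing and gluten-free one-week
    guideline menus and compares daily nutrient totals with normality-routed
    paired tests. Synthetic generators provide ground-truth reference tables,
    labelled products and menus for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
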