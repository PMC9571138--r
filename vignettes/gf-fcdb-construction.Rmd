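---
title: "Recipe-based construction of a gluten-free food composition database"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recipe-based construction of a gluten-free food composition database}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gffcdb)
```

## The problem

Manufactured gluten-free (GF) substitutes of cereal products — breads,
pasta, biscuits, pizzas — carry only the mandatory EU nutrition declaration
(Regulation 1169/2011): energy, fat, saturates, carbohydrate, sugars,
protein, salt, sometimes fiber. Dietary assessment of celiac-disease
patients needs the *full* composition, micronutrients included. The recipe
approach closes this gap: a branded product is modelled as a weighted
mixture of reference ingredients (taken from a national composition table),
with the weights constrained by the label's ingredient order and fitted so
the evaluated mixture matches the declared panel. The full composition of
the mixture then supplies everything the label does not.

`gffcdb` implements this construction calculus end to end, together with
the downstream comparison of gluten-containing (GC) vs GF one-week
guideline menus.

## The per-item calculus

### Energy

Energy is computed from macronutrient-specific factors, including fiber:
protein 4 kcal/g (17 kJ/g), lipids 9 (37), fiber 2 (8), and available
carbohydrate at either 3.75 kcal/g (16 kJ/g) — when carbohydrate is
expressed as *monosaccharide equivalents*, the hydrated basis — or
4 kcal/g (17 kJ/g) when expressed by weight ("as such"). Published GF
composition tables mix both conventions across items: biscuit and pasta
rows reproduce their printed energies only under the
monosaccharide-equivalent pair, rusk and bread rows only under the as-such
pair. The convention is therefore a per-item flag, with an auto-detect mode
(`detect_cho_convention()`) that picks the lower-residual convention.
Presentation rounding is half-up, energies to integers, gram quantities to
one decimal — `round_half_up()`, not base R's round-half-even.

A handful of printed rows fit *neither* convention within 2 kcal (the
hamburger/hotdog-type bread misses by 3 kcal even at its best convention).
Plausibly those labels retained a declared energy verbatim rather than a
recomputed one. The package flags such rows (`validate_item()`,
`validate_table()`) rather than resolving them.

### Starch, water, salt

Starch is available minus soluble carbohydrate, in the input basis. Water
is 100 g minus protein, lipids, as-such carbohydrate, fiber and ash, with a
clamp at zero for excesses up to 1 g and a hard error beyond 101 g.
Printed item tables omit ash, so `water_by_difference()` requires ash as an
explicit argument — supplying 0 is a deliberate act, not a default. The
basis conversion between carbohydrate expressions uses hydration factors
1.10 (starch) and 1.05 (soluble, disaccharide-dominated) component-wise; it
is documented as an approximation. Salt is sodium × 2.5 / 1000, the
standard labelling conversion, reported to one decimal.

Missing and zero are distinct states throughout (`NA` vs `0` in a
`nutrient_vector()`); every check that would compare a missing component is
skipped and logged at severity `info` instead of guessing.

## The weight solver

Let $w \in \mathbb{R}^n_{\ge 0}$ be formulation weights (g per 100 g of
formulation, pre-processing). Processing steps lose water only: a step of
yield $y$ removes $100(1-y)$ g of water per 100 g input, and the result is
renormalized to the 100 g as-sold basis. Consequently every label nutrient
is an *affine* function $f_j(w)$ of the weights. The fit minimizes

$$\sum_{j} \left( \frac{f_j(w) - L_j}{\max(L_j, 0.5)} \right)^2$$

over fat, saturates, carbohydrate, sugars, fiber (when declared), protein
and salt, subject to: $\sum_i w_i = 100$; $w_i \ge w_{i+1}$ for consecutive
label ranks (EU labels order ingredients by incorporated weight, so the
ordering binds on the formulation basis); declared percentages fixed
exactly; and an optional analytical-moisture equality. Energy is excluded
from the objective — it is a linear combination of the fitted nutrients —
and used as a check instead. The 0.5 g denominator floor stops
trace-amount nutrients from dominating the relative deviations.

Because the objective is a convex weighted least-squares and all
constraints are affine, the problem is a small quadratic program. For up to
10 ingredients the solver enumerates all $2^n$ active sets of the
ordering/non-negativity constraints, solves each equality-constrained
least-squares subproblem exactly by null-space elimination, keeps the
feasible candidates, and returns the global optimum — deterministic, no
iteration caps, no convergence tolerance in the result. Ties in the
objective are broken toward the largest rank-1 weight. Recipes larger than
10 ingredients (rare in practice) fall back to deterministic multi-start
bounded quasi-Newton over the ordered-increment reparameterization, with
the three documented starts (equal split, rank-proportional $w_i \propto
1/i$, top-heavy).

Fit quality is graded by `fit_report()` against EU-guidance-style declared
value tolerances: ±15% relative at or above 10 g/100 g, ±1.5 g absolute
below, ±0.375 g for salt.

## Post-solve pipeline

Order of operations, chosen so the declared totals stay authoritative:

1. **Retention** (`apply_retention()`): each micronutrient is multiplied by
   the product of per-step retention factors in $[0,1]$; unresolved
   (process, component) pairs default to 1 and are logged. Proximates are
   untouched — water loss already lives in the yield.
2. **Rescaling** (`rescale_profiles()`): animal/vegetable protein and lipid
   splits, fatty-acid profiles and sugars are scaled by label total /
   recipe total and the totals replaced by the label values, preserving
   within-profile proportions exactly. The operation is idempotent.
3. **Aggregation** (`aggregate_item()`): for label-declared components the
   item value is the unweighted mean of (mean of brand labels, mean of
   brand recipe values); label-absent components take the recipe mean over
   non-missing brands, with a coverage note below 50% participation. The
   source description — "combining the mean label data and the mean
   calculated data" — does not pin down the combination rule; the
   unweighted mean of the two means was chosen as the symmetric,
   reproducible reading and is flagged to users as an assumption. Brand
   means carry no market-share weights. Starch and energy are then
   recomputed and the item re-validated.

`build_database()` assembles the item table and the category census over
the fixed ten categories.

## The packaged fixture

`load_gf_items()` ships the energy and macronutrient composition per 100 g,
as sold, of the 108 GF items (17 biscuits, 4 breakfast products, 11 cakes
and desserts, 21 sweet snacks, 13 breads, 4 pizzas, 10 savory snacks,
5 flours, 16 pasta dishes, 7 ready-to-eat dishes) as printed in the
published tables. 42 items carry an analytical-moisture flag with the
published per-category counts (7 biscuits, 6 cakes and desserts, 12 sweet
snacks, 10 breads, 3 pizzas, 1 savory snack, 3 pasta dishes); *which*
items were analytically determined is not published, so the flag is
assigned to the first items of each category in table order — a synthetic
assignment, documented here and in `?gf_fixture_path`.

## Menu analysis

`daily_totals()` sums amount-weighted compositions per day and recomputes
daily energy from the summed macronutrients — never by adding per-food
energies, which would mix carbohydrate conventions.
`apply_substitution()` swaps composition sources for the cereal-based
foods of the substitution map while conserving every gram amount, so
nutrients sourced outside the cereal scope are bit-identical between arms.

`compare_menus()` routes each nutrient through Shapiro–Wilk at 0.05 **on
the paired differences** — the quantity whose normality the paired t-test
actually assumes; the source's phrasing ("the distribution of each
nutrient per day") is ambiguous on this point, and per-difference testing
was chosen. Normal-looking nutrients get a paired t-test and mean ± SD
descriptives; the rest get the Wilcoxon signed-rank test and median (IQR).
No multiple-testing correction is applied across the ~30 nutrients,
matching the source analysis.

The signed-rank test is implemented in-package because the stats one
abandons the exact null distribution under ties or zeros, while 7-day
comparisons need exact routing: zeros are dropped (signed-rank
convention), ties are mid-ranked, and the exact null pmf of $V$ is built
by convolution over the (doubled, hence integer) midranks for up to 20
non-zero differences, with a tie-corrected normal approximation beyond.
The two-sided p doubles the smaller tail, capped at 1 — identical to
`stats::wilcox.test` on tie-free data, which serves as a cross-check in
the tests, alongside a brute-force sign-enumeration oracle. All-zero
difference vectors short-circuit to "no difference", p = 1.

In the mixed-cereals (MC) scenario the generator assigns wholegrain
products to the first ~60% of cereal serving slots in day order — a
deterministic, documented subset rather than a random draw.

## Synthetic generators: what they emulate, what they do not

The real inputs — the licensed national composition table, the branded
recipes, the guideline menu text — cannot ship. `gen_reference_db()`,
`gen_labeled_product()` and `gen_menu()` generate structurally faithful
stand-ins with known ground truth:

* ingredient rows drawn log-uniformly inside documented physiological
  ranges per group (flour, wholegrain flour, legume flour, sugar, oil,
  butter, egg, milk powder, cocoa, fruit filling, water, salt), with
  proximates + water + ash closing to 100 g exactly by construction, and
  salt generated as the minor, last-ranked ingredient (0.5–2% of the
  formulation) it is in real products;
* labelled products built from flour-led descending-weight formulations
  with a baking step that removes 40% of the formulation's water, and a
  label derived exactly or EU-rounded (energies to integers, grams to 1 g
  at/above 10 g else 0.1 g, salt to 0.01 g below 1 g) — so the ground
  truth is always a feasibility witness for the solver;
* 7-day menus with daily cereal servings plus dairy, fruit, vegetables,
  legumes, meat/fish and olive oil at guideline-like frequencies and mild
  day-to-day amount variation, paired GC/GF composition tables, and
  multiplicative GF effects injected on the components for which the GF
  reformulation literature reports systematic differences: pufa ×1.2,
  linoleic ×1.2, vitamin E ×1.2 in GF cereal items, zinc ×0.7 in GF
  wholegrain items. Setting `effects = NULL` yields an exact null.

Passing tests on these generators demonstrate the *calculus* — exact
recovery, constraint satisfaction, test routing, directional power — not
the numeric values of any real product or menu, which depend on licensed
data. In particular the published menu-comparison table is not numerically
reproducible here and the package does not attempt it.

Each generator seeds the base RNG once at entry from `cfg$seed` (single
seed surface, no hidden state); a fixed config is byte-reproducible.

## Problem sizes and numerical choices

The verification suite runs, among others: exact-recovery sweeps over 100
seeded synthetic products (3–6 ingredients each, both unrounded and
EU-rounded labels); 200-case equivalence of the signed-rank test against
exhaustive sign enumeration at n ≤ 10; a 2000-replicate null calibration
of the routed test at n = 7 (empirical level required within
[0.03, 0.07]); and 200 replicates of the full menu pipeline checking
directional recovery of the injected effects and the absence of
off-target flags. Grid-search cross-checks of the solver use a 0.1 g
ordered-simplex grid for 2–3 ingredient recipes.

Tolerances: solver feasibility 1e-9 on ordering, 1e-6 on the simplex;
energy check ±2 kcal / ±5 kJ; origin-split and fatty-acid slack 0.05 g;
water clamp 1 g; all stated in the function documentation.

## Known limitations

* The mono-eq/as-such hydration conversion is component-wise and
  approximate; sugar composition (mono- vs disaccharides) is not modelled.
* One level of recipe nesting is flattened in menus; compound ingredients
  inside product recipes must be pre-flattened by the user.
* Retention factors are user-supplied; the package ships only the identity
  table and the schema.
* The combination rule for label and recipe means is an interpretation
  (see above); users needing a different rule can aggregate from the
  per-brand objects directly.
* Fixture moisture flags are a synthetic assignment (see above).
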