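# Independent oracles and fixture builders used across the suite.

# Exhaustive sign-enumeration oracle for the signed-rank test: enumerates all
# 2^m sign assignments on the midranks of |d| (zeros dropped) and doubles the
# smaller tail. Independent of the convolution used by the implementation.
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  vs <- as.numeric(signs %*% r)
  p_le <- mean(vs <= v + 1e-9)
  p_ge <- mean(vs >= v - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# Ordered-simplex grid at `step` g resolution for n = 2 or 3 ingredients:
# matrix with one column per feasible weight vector (w1 >= w2 >= w3 >= 0,
# sum = 100).
ordered_weight_grid <- function(n, step = 0.1) {
  k <- round(100 / step)
  if (n == 2) {
    k1 <- ceiling(k / 2):k
    g <- rbind(k1, k - k1)
  } else if (n == 3) {
    cols <- list()
    for (k1 in ceiling(k / 3):k) {
      k2 <- 0:min(k1, k - k1)
      k3 <- k - k1 - k2
      keep <- k3 >= 0 & k3 <= k2
      if (any(keep)) cols[[length(cols) + 1L]] <-
          rbind(k1, k2[keep], k3[keep])
    }
    g <- do.call(cbind, cols)
  } else stop("grid oracle supports n = 2 or 3 only")
  g * step
}

# Label-space objective of the solver, recomputed independently for a grid of
# candidate weights (columns of `W`).
grid_objective <- function(W, ref_db, keys, steps, label, floor = 0.5) {
  nuts <- c(fat = "lipid_total", saturates = "sfa",
            carbohydrate = "available_carbohydrate",
            sugars = "soluble_carbohydrate", fiber = "fiber",
            protein = "protein_total", salt = "sodium")
  target <- unlist(label[names(nuts)])
  use <- !is.na(target)
  m <- as.matrix(ref_db[match(keys, ref_db$ingredient), nuts, drop = FALSE])
  M <- t(m) / 100
  M["sodium", ] <- M["sodium", ] * 2.5 / 1000
  y <- if (is.null(steps) || nrow(steps) == 0) 1 else prod(steps$yield)
  M <- M / y
  rownames(M) <- names(nuts)
  M <- M[use, , drop = FALSE]
  t_ <- target[use]
  wts <- 1 / pmax(t_, floor)
  colSums(((M %*% W - t_) * wts)^2)
}

# Minimal hand-built reference ingredients for toy recipes.
toy_ingredient <- function(key, ...) {
  v <- nutrient_vector(...)
  cbind(data.frame(ingredient = key, group = "toy", stringsAsFactors = FALSE),
        as.data.frame(as.list(v)))
}

toy_ref_db <- function() {
  rbind(
    toy_ingredient("sugar", water = 0, available_carbohydrate = 100,
                   soluble_carbohydrate = 100, starch = 0, fiber = 0,
                   protein_total = 0, lipid_total = 0, sfa = 0, sodium = 0,
                   ash = 0),
    toy_ingredient("oil", water = 0, available_carbohydrate = 0,
                   soluble_carbohydrate = 0, starch = 0, fiber = 0,
                   protein_total = 0, lipid_total = 100, sfa = 15, sodium = 0,
                   ash = 0),
    toy_ingredient("flourA", water = 12, available_carbohydrate = 70,
                   soluble_carbohydrate = 2, starch = 68, fiber = 4,
                   protein_total = 10, lipid_total = 2.2, sfa = 0.5,
                   sodium = 3, ash = 1.8),
    toy_ingredient("proteinB", water = 70, available_carbohydrate = 0,
                   soluble_carbohydrate = 0, starch = 0, fiber = 0,
                   protein_total = 20, lipid_total = 8, sfa = 3, sodium = 60,
                   ash = 2)
  )
}

# label whose panel equals an ingredient's own composition
label_of_ingredient <- function(ref_db, key) {
  v <- nutrient_vector(.data = ref_db[ref_db$ingredient == key,
                                      intersect(names(ref_db), names(nutrient_vector()))])
  label_from_vector(v)
}
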