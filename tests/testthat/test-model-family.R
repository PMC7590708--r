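test_that("specs expand the invariance constraints correctly", {
  somi <- fmm_spec("SoMI", 4, "uv")
  expect_false(somi$intercepts_vary)      # classification block invariant
  expect_false(somi$loadings_vary)
  expect_true(somi$factor_means_free)     # classes differ on the factor mean
  expect_true(somi$resid_vary)
  lca <- fmm_spec("LCA", 3, "ev")
  expect_false(lca$has_factor)            # no factor block at all
  expect_true(lca$intercepts_vary)
  expect_false(lca$resid_vary)
  nmi <- fmm_spec("NMI", 3, "uv")
  expect_true(nmi$intercepts_vary && nmi$loadings_vary && nmi$resid_vary)
  expect_error(fmm_spec("SiMI", 3, "uv"), "SiMI-uv")
})

test_that("free-parameter counts follow the identification rules", {
  g5 <- rep("gaussian", 5)
  expect_identical(n_parameters(fmm_spec("SoMI", 4, "ev", g5)), 21L)
  expect_identical(n_parameters(fmm_spec("LCA", 1, "ev", g5)), 10L)
  b5 <- rep("bernoulli", 5)
  expect_identical(n_parameters(fmm_spec("LCA", 3, "uv", b5)), 17L)
  expect_identical(n_parameters(fmm_spec("LCA", 2, "uv", b5)), 11L)
})

test_that("uv minus ev counts equal (K-1) x class-varying variance cells", {
  items <- frailty_item_models()   # 5 variance-bearing items + factor
  for (K in 2:4) {
    for (pair in list(c("LCA", "LCA"), c("SoMI", "SoMI"), c("WMI", "WMI"),
                      c("NMI", "NMI"))) {
      duv <- n_parameters(fmm_spec(pair[1], K, "uv", items)) -
        n_parameters(fmm_spec(pair[2], K, "ev", items))
      cells <- 5L + (if (pair[1] == "LCA") 0L else 1L)
      expect_identical(duv, (K - 1L) * cells)
    }
  }
})

test_that("hypothesis roles map one-class, invariance and class models", {
  expect_identical(hypothesis_role(fmm_spec("SoMI", 4, "uv")),
                   "null-categorical-approximation")
  expect_identical(hypothesis_role(fmm_spec("SiMI", 2, "ev")),
                   "null-categorical-approximation")
  expect_identical(hypothesis_role(fmm_spec("LCA", 4, "uv")), "non-null")
  expect_identical(hypothesis_role(fmm_spec("WMI", 3, "ev")), "non-null")
  for (fam in c("LCA", "SiMI", "SoMI", "WMI", "NMI")) {
    v <- if (fam == "SiMI") "ev" else "uv"
    expect_identical(hypothesis_role(fmm_spec(fam, 1, v)), "null-one-class")
  }
})

test_that("the nesting graph is acyclic and matches the tested pairs", {
  it <- frailty_item_models()
  sp <- function(f, K, v) fmm_spec(f, K, v, it)
  expect_true(is_nested(sp("LCA", 3, "ev"), sp("LCA", 3, "uv")))
  expect_true(is_nested(sp("SiMI", 2, "ev"), sp("SoMI", 2, "uv")))
  expect_true(is_nested(sp("WMI", 3, "ev"), sp("WMI", 3, "uv")))
  expect_true(is_nested(sp("NMI", 2, "ev"), sp("NMI", 2, "uv")))
  expect_true(is_nested(sp("SoMI", 3, "uv"), sp("WMI", 3, "uv")))
  expect_true(is_nested(sp("WMI", 3, "uv"), sp("NMI", 3, "uv")))
  expect_true(is_nested(sp("SoMI", 2, "uv"), sp("SoMI", 3, "uv")))
  # and the directions that must fail
  expect_false(is_nested(sp("LCA", 3, "uv"), sp("LCA", 3, "ev")))
  expect_false(is_nested(sp("NMI", 2, "uv"), sp("WMI", 2, "uv")))
  expect_false(is_nested(sp("SoMI", 3, "uv"), sp("LCA", 3, "uv")))
  expect_false(is_nested(sp("LCA", 2, "uv"), sp("SoMI", 2, "uv")))
  # acyclic: mutual nesting only for identical constraint sets
  fams <- list(sp("LCA", 2, "uv"), sp("SoMI", 2, "uv"), sp("WMI", 2, "uv"),
               sp("NMI", 2, "uv"))
  for (i in seq_along(fams)) for (j in seq_along(fams)) {
    if (i != j)
      expect_false(is_nested(fams[[i]], fams[[j]]) &&
                     is_nested(fams[[j]], fams[[i]]))
  }
})

test_that("the family listing reports roles and counts for all members", {
  fam <- family_members(K = 3)
  expect_equal(nrow(fam), 8L)
  expect_setequal(fam$role[fam$family %in% c("SiMI", "SoMI")],
                  "null-categorical-approximation")
  expect_true(all(fam$n_params[fam$variance == "uv"] >=
                    fam$n_params[fam$variance == "ev"]))
})

test_that("specs serialize to JSON and back", {
  sp <- fmm_spec("WMI", 3, "uv")
  p <- tempfile(fileext = ".json")
  write_spec(sp, p)
  expect_equal(read_spec(p), sp)
  unlink(p)
})
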