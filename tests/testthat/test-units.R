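test_that("units are detected from labels by exact match only", {
  expect_equal(format(detect_unit(list(label = "Height in cm"))), "cm")
  expect_equal(format(detect_unit(list(label = "Height in meter"))), "m")
  expect_null(detect_unit(list(label = "Hypertension")))
  # near-misses never match: exactness is the false-positive guard
  expect_null(detect_unit(list(label = "cms and more")))

  u <- detect_unit(list(label = "BMI (kg/m^2)"))
  expect_equal(u$symbol, c("kg", "m"))
  expect_equal(u$exponent, c(1L, -2L))

  two <- detect_unit(list(label = "Height in cm or m"))
  expect_true(attr(two, "ambiguous"))
})

test_that("composite unit expressions decompose into atomic units", {
  u <- parse_composite_unit("kg/m^2")
  expect_equal(u$symbol, c("kg", "m"))
  expect_equal(u$exponent, c(1L, -2L))
  expect_equal(parse_composite_unit("m")$symbol, "m")
  expect_equal(parse_composite_unit("kg/m²"), parse_composite_unit("kg/m^2"))
  expect_equal(parse_composite_unit("mg/dL")$exponent, c(-1L, 1L))
  expect_error(parse_composite_unit("kg//m"), "cannot parse")
  # store-resolved aliases are canonicalized
  st <- default_unit_store()
  expect_equal(parse_composite_unit("gram", st)$symbol, "g")
})

test_that("conversion factors match the printed rules and compose", {
  expect_equal(conversion_factor("m", "cm"), 100)
  expect_equal(conversion_factor("kg", "g"), 1000)
  expect_equal(conversion_factor("g", "kg"), 0.001)
  expect_equal(conversion_factor("cm", "cm"), 1)
  expect_equal(conversion_factor("mmHg", "mmHg"), 1)
  expect_equal(conversion_factor("week", "day"), 7)
  expect_equal(conversion_factor("year", "week"), 365.25 / 7,
               tolerance = 1e-12)
  expect_error(conversion_factor("cm", "kg"), "incompatible")
  expect_error(conversion_factor("cm", "furlong"), "unknown")
})

test_that("inverse and transitivity hold over the whole packaged table", {
  rules <- default_conversion_rules()
  symbols <- unique(c(rules$from, rules$to))
  # dimension = connected component
  compat <- function(a, b) {
    !inherits(tryCatch(conversion_factor(a, b, rules), error = identity),
              "error")
  }
  for (a in symbols) for (b in symbols) {
    if (compat(a, b)) {
      f <- conversion_factor(a, b, rules)
      g <- conversion_factor(b, a, rules)
      expect_equal(f * g, 1, tolerance = 1e-12,
                   info = paste(a, b))
      for (c_ in symbols) {
        if (compat(b, c_)) {
          expect_equal(conversion_factor(a, c_, rules),
                       f * conversion_factor(b, c_, rules),
                       tolerance = 1e-9, info = paste(a, b, c_))
        }
      }
    } else {
      expect_error(conversion_factor(a, b, rules), "incompatible")
    }
  }
})

test_that("alignment treats target atoms as the standard", {
  st <- default_unit_store()
  target <- parse_composite_unit("kg/m^2", st)
  plan_h <- align_units(target, parse_composite_unit("cm", st))
  expect_equal(plan_h$from, "cm")
  expect_equal(plan_h$to, "m")
  expect_equal(plan_h$factor, 0.01)
  plan_w <- align_units(target, parse_composite_unit("g", st))
  expect_equal(plan_w$to, "kg")
  expect_equal(plan_w$factor, 0.001)

  # one-sided or equal units: assume equal, no conversion
  expect_equal(nrow(align_units(NULL, parse_composite_unit("cm"))), 0)
  expect_equal(nrow(align_units(parse_composite_unit("cm"), NULL)), 0)
  expect_equal(nrow(align_units(parse_composite_unit("cm"),
                                parse_composite_unit("cm"))), 0)
  expect_error(align_units(parse_composite_unit("kg"),
                           parse_composite_unit("cm")), "incompatible")
})

test_that("both snippet styles reproduce the printed examples and agree numerically", {
  expect_equal(generate_unit_snippet("Height", "cm", "m", "chain"),
               "$('Height').unit('cm').toUnit('m').value()")
  expect_equal(generate_unit_snippet("Height", "cm", "m", "formula"),
               "$('Height').div(100).value()")
  expect_equal(generate_unit_snippet("Height", "cm", "cm"),
               "$('Height').value()")
  expect_equal(generate_unit_snippet("W", "kg", "g", "formula"),
               "$('W').times(1000).value()")

  e <- emx_entity("t", list(emx_attribute("x", "t", "decimal", "x")))
  rules <- default_conversion_rules()
  pairs <- rbind(c("cm", "m"), c("g", "kg"), c("mL", "L"), c("day", "week"),
                 c("year", "month"))
  set.seed(3)
  for (i in seq_len(nrow(pairs))) {
    chain <- dsl_parse(generate_unit_snippet("x", pairs[i, 1], pairs[i, 2],
                                             "chain"))
    formula <- dsl_parse(generate_unit_snippet("x", pairs[i, 1], pairs[i, 2],
                                               "formula"))
    for (v in round(runif(5, 0.1, 500), 2)) {
      row <- list(x = as.character(v))
      a <- dsl_evaluate(chain, row, e, rules)
      b <- dsl_evaluate(formula, row, e, rules)
      expect_equal(a, b, tolerance = 1e-9 * max(1, abs(a)),
                   info = paste(pairs[i, ], collapse = "->"))
    }
  }
})
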