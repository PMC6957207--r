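# Rule table contents, guards, and the exclusivity variant.

test_that("rule table emits the full rule set with the published rates", {
  rules <- rule_table(rate_table())
  df <- serialize_rules(rules)
  expect_setequal(df$name,
    c("undock", "dock", "activate", "inactivate", "cam_bind", "cam_release",
      "cam_full", "cam_decompact", "autophos", "pp_bind", "pp_release",
      "pp_catalysis", "t306_phos"))
  expect_equal(df$rate[df$name == "undock"], 0.63)
  expect_equal(df$rate[df$name == "autophos"], 1)
  expect_equal(df$rate[df$name == "pp_bind"], 3e6)
  # no rule reverses pT306
  expect_false(any(grepl("t306 <- uT306", df$effect)))
  # kon_PP_scale multiplies the PP association rate
  df10 <- serialize_rules(rule_table(rate_table(kon_PP_scale = 10)))
  expect_equal(df10$rate[df10$name == "pp_bind"], 3e7)
})

test_that("exclusive and non-exclusive rule sets differ in exactly two guard clauses", {
  ex <- serialize_rules(rule_table(rate_table(exclusivity = "exclusive")))
  nx <- serialize_rules(rule_table(rate_table(exclusivity = "non_exclusive")))
  differing <- ex$name[ex$guard != nx$guard]
  expect_setequal(differing, c("cam_bind", "pp_bind"))
  expect_match(ex$guard[ex$name == "pp_bind"], "cam == unbound")
  expect_false(grepl("cam == unbound", nx$guard[nx$name == "pp_bind"]))
  expect_match(ex$guard[ex$name == "cam_bind"], "t286 != PP_bound")
  expect_false(grepl("t286", nx$guard[nx$name == "cam_bind"]))
  # everything else identical (rates included)
  same <- setdiff(ex$name, differing)
  expect_equal(ex[ex$name %in% same, ], nx[nx$name %in% same, ])
})

test_that("set_exclusivity switches variants and is otherwise a no-op", {
  rules <- rule_table(rate_table())
  nx <- set_exclusivity(rules, "non_exclusive")
  expect_equal(attr(nx, "rates")$exclusivity, "non_exclusive")
  back <- set_exclusivity(nx, "exclusive")
  expect_equal(serialize_rules(back), serialize_rules(rules))
})

test_that("guards evaluate the documented conditions", {
  rules <- rule_table(rate_table())
  docked <- subunit_state("docked")
  undocked_active <- subunit_state("undocked", "active")
  # CaM cannot bind a docked (compact) subunit
  expect_false(guard_eval(rules$cam_bind, docked))
  expect_true(guard_eval(rules$cam_bind, subunit_state("undocked")))
  # autophosphorylation needs an active, undocked kinase neighbor
  expect_false(guard_eval(rules$autophos, undocked_active,
                          neighbor = subunit_state("undocked", "inactive")))
  expect_true(guard_eval(rules$autophos, undocked_active,
                         neighbor = undocked_active))
  # a fully CaM-bound subunit cannot inactivate
  expect_false(guard_eval(rules$inactivate,
                          subunit_state("undocked", "active", "full")))
  # ... nor can a pT286 subunit
  expect_false(guard_eval(rules$inactivate,
                          subunit_state("undocked", "active", t286 = "pT286")))
  expect_true(guard_eval(rules$inactivate, undocked_active))
  # neighbor contract
  expect_error(guard_eval(rules$autophos, undocked_active), "neighbor")
  expect_error(guard_eval(rules$dock, docked, neighbor = docked),
               "no neighbor")
})

test_that("K252a blocks the substrate role, and the kinase role per toggle", {
  inhibited <- subunit_state("undocked", "active", inhibitor_bound = TRUE)
  active <- subunit_state("undocked", "active")
  rules <- rule_table(rate_table())
  expect_false(guard_eval(rules$autophos, inhibited, neighbor = active))
  expect_false(guard_eval(rules$autophos, active, neighbor = inhibited))
  rules2 <- rule_table(rate_table(k252a_blocks_kinase_role = FALSE))
  expect_true(guard_eval(rules2$autophos, active, neighbor = inhibited))
})

test_that("PP binding requires pT286; exclusivity gates CaM occupancy", {
  rules <- rule_table(rate_table())
  phos_cam <- subunit_state("undocked", "active", "full", "pT286")
  phos_free <- subunit_state("undocked", "active", t286 = "pT286")
  expect_false(guard_eval(rules$pp_bind, phos_cam))    # CaM excludes PP
  expect_true(guard_eval(rules$pp_bind, phos_free))
  nx <- set_exclusivity(rules, "non_exclusive")
  expect_true(guard_eval(nx$pp_bind, phos_cam))        # agnostic binding
  expect_false(guard_eval(nx$pp_bind, subunit_state("undocked", "active")))
})

test_that("rule table serializes to a text file for audit", {
  path <- tempfile(fileext = ".tsv")
  write_rules(rule_table(rate_table()), path)
  df <- utils::read.delim(path)
  expect_equal(nrow(df), 13)
  expect_true(all(c("name", "guard", "rate", "effect") %in% names(df)))
  unlink(path)
})

test_that("dock_requires_inactive toggle adds the conformational clause", {
  r <- rule_table(rate_table(dock_requires_inactive = TRUE))
  expect_false(guard_eval(r$dock, subunit_state("undocked", "active")))
  expect_true(guard_eval(r$dock, subunit_state("undocked", "inactive")))
  r0 <- rule_table(rate_table())
  expect_true(guard_eval(r0$dock, subunit_state("undocked", "active")))
})
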